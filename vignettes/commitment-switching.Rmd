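---
title: "Switching Boolean networks for phosphatase-driven commitment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switching Boolean networks for phosphatase-driven commitment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

When epidermal stem cells are triggered to differentiate (classically by
placing them in suspension), they pass through a brief *commitment* window
around 4 hr before terminal differentiation at 12 hr.  A small module of six
protein phosphatases — DUSP6, PPTC7, PTPN1, PTPN13, PPP3CA and DUSP10 —
shows coordinated expression changes across this window.  Two questions
drive this package:

1. **Which phosphatase regulates which?**  Knocking down one phosphatase
   and measuring the transcript response of the other five at each time
   point yields a signed, weighted *mechanistic network* per time point.
2. **Is one regulatory network enough?**  Treating the module as a Boolean
   dynamical system, can a single interaction topology reproduce the
   discretised expression states observed at 0, 4, 8 and 12 hr — or must
   the topology itself change ("switch") as cells commit?

The package implements both analyses end to end, together with a
synthetic-data generator that stands in for the wet-lab inputs, and a SILAC
phospho-site ranking used to connect the module to upstream kinase
signalling.

## Edge inference from knockdown time courses

For each measured target gene $j$ we fit a two-way ANOVA on log2 relative
expression with factors *perturbation* (control plus each knockdown) and
*time* (0, 4, 8, 12 hr), including the interaction.  The contrast of
knockdown $i$ versus control at time $t$ uses the pooled residual variance:

$$t_{ij}(t) = \frac{\bar y_{ij}(t) - \bar y_{\mathrm{ctrl},j}(t)}
{\sqrt{\mathrm{MSE}_j\,(1/n_{ij} + 1/n_{\mathrm{ctrl}})}}$$

All knockdown-by-time contrasts for one target gene form a single
comparison family, adjusted by the **Holm–Šídák step-down** procedure: with
raw p-values sorted ascending, $\tilde p_{(i)} = \max_{k \le i}\,
\bigl(1 - (1 - p_{(k)})^{m-k+1}\bigr)$.  An edge $i \to j$ at time $t$ is
called iff $\tilde p_{ij} < \alpha$ (default $\alpha = 0.05$); its sign is
activating when the knockdown *lowered* the target and inhibiting when it
raised it, and its weight is the inverse adjusted p-value $w_{ij} =
1/\tilde p_{ij}$.

Design choices worth making explicit:

* **Family scope.** The comparison family is per target gene (all
  knockdown × time contrasts), matching a per-phosphatase "multiple
  comparisons" reading; the scope is an argument of the code, not a
  constant.
* **Self-edges** are not inferable from knockdown data — silencing a gene
  trivially lowers its own transcript — and are excluded from the contrast
  family.  Self-loops enter the analysis only as possible interactions of
  the Boolean stage networks.
* **Degenerate variance.** On noise-free (synthetic) data the residual MSE
  is zero.  A nonzero contrast is then assigned the smallest representable
  p-value and a zero contrast p = 1, which keeps p in (0, 1], keeps the
  weight finite, and makes noise-free recovery exact for any positive edge
  strength.
* A significant contrast with fold-change exactly 0 raises an error rather
  than guessing a sign: the sign is undefined and such a value indicates a
  degenerate input.

## Discretisation

A gene is ON at a time point iff its replicate-mean expression strictly
exceeds the average over the six module genes *within the same sample*;
equal-to-average ("similar") maps to OFF.  Averaging is on the linear
scale by default (a log-scale option exists), and the reference scope can
be replaced by an externally supplied genome-wide average.  The six-gene
within-sample mean is the default because the six-gene table is the only
expression set the Boolean analysis consumes; the choice only shifts the
ON/OFF threshold, and the discretisation depends solely on within-sample
ratios (it is invariant to rescaling all genes by a constant).

## Boolean dynamics

States are total 0/1 assignments over the gene list, updated
**synchronously**: every gene computes its next value from the same input
state, so evaluation order cannot matter.  One trajectory step corresponds
to 1 hr; observed states sit at steps 0, 4, 8 and 12 of a 12-step horizon.

The default per-gene update rule is *activator-disjunctive,
inhibitor-dominant, hold-if-no-activators*:

* ON next iff at least one activator is ON **and** no inhibitor is ON;
* a gene with no incoming activators holds its current value unless an
  inhibitor is ON (then OFF).

The published rule catalogue this formalism descends from is not
reproduced in the primary literature available to us, so the package fixes
this documented default and exposes a small pluggable catalogue
(`rule_catalogue()`: `default`, `require_all`, `ignite_hold`, `strict`),
every member of which is machine-checked for monotonicity — non-decreasing
in activator activity, non-increasing in inhibitor activity — over all
predicate combinations.  Per-gene rule choice sets can be attached to an
ABN, in which case they multiply the family of concrete networks.

## Abstract Boolean Networks and the solvers

An **ABN** couples *definite* interactions (always present) with
*possible* interactions (present or absent).  A pair listed as possible
with both signs is an **exclusive** three-way choice — absent, activating
or inhibiting — because a pair cannot be both at once.  This convention
reproduces the canonical family size of the unconstrained six-gene module:
36 ordered pairs (including self-loops) × 3 choices each = $3^{36} \approx
1.5\times10^{17}$ concrete networks, i.e. on the order of $10^{17}$.

The satisfiability machinery is a **complete explicit search**, not an SMT
encoding: concrete networks are enumerated in a deterministic
lexicographic order (bounded by a configurable limit, default $2^{20}$),
initial states are completed over the unobserved genes ($\le 2^6$
completions), and each candidate is a deterministic 12-step synchronous
simulation checked against the partial observations.  The constrained
ABNs arising in this analysis are small, and an explicit search has the decisive
advantage that it can be validated instance-by-instance against a naive
enumerate-and-simulate oracle — which the test suite does on hundreds of
random instances.  The price is that the *unconstrained* $10^{17}$-network
single-ABN instance is out of reach by construction; the shipped fixture
therefore pools the experimentally supported interactions (15 possible
interactions, 24 576 concrete networks) for its single-network test, which
is exhaustively refuted.

A possible interaction is classified **required** when forcing it absent
makes the constraint unsatisfiable, **disallowed** when forcing it present
does, and **optional** otherwise; forcing one sign of an exclusive pair
present removes the opposite sign from the family.  Promoting required
interactions to definite and deleting disallowed ones provably preserves
the solution set, and the tests assert this on random satisfiable
instances.

## Switching networks

A switching problem fixes an ordered sequence of ABNs (N0, N4, N8, N12 for
the four time points) sharing one gene list.  A solution chooses:

* a **monotone non-decreasing schedule** mapping steps 1–12 to network
  indices (forward switches only; there are $\binom{15}{3} = 455$ such
  schedules for 12 steps over 4 networks, enumerated explicitly),
* **one concrete network per ABN**, reused across its whole span, and
* an initial state consistent with the step-0 observation.

The system starts in the first network; a step-0 network requirement must
therefore be index 0.  *Mandatory switch* is encoded as "at least one step
uses a network index > 0".  `classify_switch_paths()` reports which
visited-ABN sequences (e.g. N0→N4→N8) admit at least one solution, and
`test_pattern_compatibility()` asks whether any concrete network of one
ABN can reach a partial target pattern from any initial state.  Every SAT
result is re-verified by an independent replay (`verify_witness()`) before
it is reported.

## The synthetic-data generator

The generator defines the study conditions for all statistical tests:

* **Knockdown tables.** Control (siSCR) log2 expression equals a per-gene
  baseline; under knockdown of gene $i$, gene $i$ itself shifts by
  $\log_2(\text{efficiency})$ (default efficiency 0.2, i.e. 80% knockdown)
  and each direct ground-truth target $j$ of an edge $i \to j$ with sign
  $s$ and strength $\beta$ shifts by $-s\beta$ log2 units.  Effects are
  deliberately **one-step only** (no transitive propagation) so that the
  inference ground truth is unambiguous: the ANOVA's edge calls are direct
  knockdown → measured-gene effects.  Gaussian noise of sd 0.2 log2 units
  is added per replicate (log-normal on the linear scale, a standard
  RT-qPCR error model); 3 replicates emulate three independent
  transfections.  The noise magnitude of the original assay is not
  published, so 0.2 is a convention, exposed as a parameter and stated
  here once.
* **Drug profiles** equal control plus a specified per-gene log2 shift.
* **SILAC tables** mix "changed" sites (|Δphospho| ≥ 0.3, negative with
  probability `frac_dephospho`) with "confounded" sites (|Δphospho| ≤ 0.1,
  total protein > +0.5 log2) that exercise the ranking exclusion rule
  exactly; total protein changes of changed sites stay within ±0.3 so the
  two populations are separable by construction.

What the generator does **not** emulate: microarray or raw MS data,
cell-to-cell heterogeneity, transitive regulatory effects, amplification
efficiency differences between primers, or correlated replicate noise.
Passing tests show the pipeline recovers what this generative model
encodes; they do not certify performance on real RT-qPCR data with
structured noise.

## Phospho-site ranking

Each site carries the log2 SILAC ratio of its phosphopeptide
(`d_phospho_log2`) and of its parent protein (`d_total_log2`), both versus
0 hr.  `dephospho_fraction()` reports, among sites changing by more than a
threshold, the fraction with negative phospho change.
`filter_and_rank_sites()` first excludes sites whose phosphorylation
remained constant while total protein rose by more than 0.5 log2 — their
apparent stability masks net dephosphorylation of a growing protein pool —
then ranks by ascending phospho change (largest decrease first).
"Remained constant" is operationalised as |Δphospho| ≤ 0.2 by default;
the value is a parameter because the original description leaves
"constant" unquantified.  The reported *discordance* is the log2
difference Δphospho − Δtotal (a ratio of ratios).  Ties in the ranking are
broken by site id so the output is invariant to input row order.

## The commitment fixture

The original discretised observation vectors live in supplementary
material that is not redistributable, so the package ships a
**constructed** fixture (`commitment_fixture()`, labelled synthetic
throughout) that reproduces the qualitative result chain with hand-built
stage networks over the six phosphatases:

* stage states S0 (stem: DUSP6, PPTC7 ON) → S4 (committed: PPTC7, PTPN1
  ON) → S8 (PTPN1, PTPN13 ON) → S12 (differentiated: PTPN13, PPP3CA,
  DUSP10 ON);
* each stage ABN holds its own state as a fixed point and drives the
  transition from the previous one (e.g. N4's PPTC7⊣DUSP6 switches DUSP6
  off during commitment);
* the pooled single-network ABN is exhaustively unsatisfiable, while
  monotonic switching is satisfiable with a verified witness;
* a PKCi-like constraint (stem pattern held to 12 hr) is satisfiable only
  by staying in N0 — the model analogue of arrest in the stem compartment;
* a TSA-like constraint (partial progression pattern) admits exactly the
  visited paths N0→N4→N8 and N0→N8, and no feasible drug path reaches N12;
  neither drug pattern is compatible with N12 at all.

An instructive wrinkle from constructing the fixture: an early draft gave
N0 a possible DUSP6→PPP3CA edge, and the solver found a legitimate
loophole — PPP3CA could be switched ON at step 11 and re-ignite DUSP6
exactly at a step-12 switch into N12, making a spurious N0→N12 path
feasible for the PKCi constraint.  The shipped fixture uses a redundant
activator (PPTC7→DUSP6) as N0's possible interaction instead.  The episode
is a good illustration of why every fixture property is asserted by the
solvers rather than by inspection.

## Problem sizes and tolerances

The shipped tests run the solvers against brute-force oracles on 200
random single-ABN instances (≤ 3 genes, ≤ 6 possible interactions,
horizon ≤ 6) and 100 random two-stage switching instances; edge-recovery
statistics use 50 simulated tables (8 signed edges, strength 1 log2, noise
sd 0.2, 3 replicates) and 200 null tables for the type-I error; SILAC
summaries use 1 000–3 000 sites.  These sizes give every Monte-Carlo
check a comfortable margin (binomial sds an order of magnitude below the
asserted bounds) while keeping the whole suite fast.  Numerical
comparisons of adjusted p-values use tolerances of 1e-10 to 1e-12 against
closed-form references; all Boolean results are exact.

## Known limitations

* The explicit solver cannot decide the unconstrained 36-pair single-ABN
  instance; that regime needs a symbolic (SMT/BDD) encoding.
* Synchronous updates and the default rule are one concrete semantics;
  asynchronous dynamics and richer rule catalogues are out of scope.
* The ANOVA contrast machinery assumes homoscedastic log2 noise across
  strata (pooled variance); strongly heteroscedastic data would need a
  per-stratum variance model.
* The inference ground truth identifies *direct* effects only; on real
  data, transitive regulation inflates apparent edge counts and the
  precision figures from synthetic recovery do not transfer.
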