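# Synthetic-data generators: knockdown RT-qPCR-style expression tables with
# a known signed ground-truth network, drug-treatment profiles, and SILAC
# phospho-site tables with a controlled dephosphorylation fraction and
# protein-abundance confounding.

PHOSPHATASES <- c("DUSP6", "PPTC7", "PTPN1", "PTPN13", "PPP3CA", "DUSP10")

.truth_times <- c(0, 4, 8, 12)

.normalise_truth_edges <- function(edges, genes) {
  df <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "sign") %in% names(df)))
  if (is.null(df$strength)) df$strength <- 1
  df$source <- as.character(df$source)
  df$target <- as.character(df$target)
  df$sign <- .normalise_sign(df$sign)
  bad <- !(df$source %in% genes) | !(df$target %in% genes)
  if (any(bad)) stop("unknown gene in edge list: ",
                     paste(unique(c(df$source[bad], df$target[bad])), collapse = ", "))
  if (any(!is.finite(df$strength)) || any(df$strength < 0)) {
    stop("edge strengths must be finite and non-negative")
  }
  df[, c("source", "target", "sign", "strength")]
}

#' Ground-truth series for the synthetic knockdown experiment
#'
#' Defines, per time point (0, 4, 8, 12 hr), the signed interaction network
#' that generates knockdown responses, together with per-gene baseline log2
#' relative expression.
#'
#' @param gene_names Gene identifiers (default: the six phosphatases).
#' @param networks Either one data frame of edges (`source`, `target`,
#'   `sign`, optional `strength` in log2 units, default 1) applied to every
#'   time point, or a list named by time (`"0"`, `"4"`, `"8"`, `"12"`).
#' @param baselines Optional matrix (genes x times) of baseline log2
#'   relative expression; defaults to 0 (expression equal to the
#'   housekeeping reference).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(gene_names = PHOSPHATASES, networks = NULL,
                         baselines = NULL) {
  stopifnot(is.character(gene_names), length(gene_names) >= 1)
  times <- .truth_times
  if (is.null(networks)) {
    networks <- data.frame(source = character(0), target = character(0),
                           sign = integer(0), strength = numeric(0))
  }
  if (is.data.frame(networks)) {
    networks <- stats::setNames(rep(list(networks), length(times)),
                                as.character(times))
  }
  if (!all(as.character(times) %in% names(networks))) {
    stop("networks must cover all four time points (0, 4, 8, 12)")
  }
  networks <- lapply(networks[as.character(times)], .normalise_truth_edges,
                     genes = gene_names)
  if (is.null(baselines)) {
    baselines <- matrix(0, length(gene_names), length(times),
                        dimnames = list(gene_names, as.character(times)))
  }
  baselines <- as.matrix(baselines)
  stopifnot(identical(rownames(baselines), gene_names),
            identical(colnames(baselines), as.character(times)),
            all(is.finite(baselines)))
  structure(list(gene_names = gene_names, networks = networks,
                 baselines = baselines, times = times),
            class = "ground_truth")
}

#' Simulation parameters for the synthetic knockdown tables
#'
#' @param knockdown_efficiency Fraction of residual target expression after
#'   knockdown, in (0, 1).  The default 0.2 leaves 20% of the transcript.
#' @param noise_sd Gaussian measurement noise sd on the log2 scale
#'   (log-normal on the linear scale).
#' @param n_replicates Independent replicates per stratum (default 3).
#' @param seed RNG seed; identical seeds give identical tables.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(knockdown_efficiency = 0.2, noise_sd = 0.2,
                       n_replicates = 3, seed = 1) {
  stopifnot(is.numeric(knockdown_efficiency), length(knockdown_efficiency) == 1,
            knockdown_efficiency > 0, knockdown_efficiency < 1,
            is.numeric(noise_sd), noise_sd >= 0,
            n_replicates >= 1)
  structure(list(knockdown_efficiency = knockdown_efficiency,
                 noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_params")
}

# run code with a private, restored RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# deterministic log2 expression of every gene under one perturbation
.det_log2 <- function(truth, time, perturbation, knockdown_efficiency) {
  mu <- truth$baselines[, as.character(time)]
  if (startsWith(perturbation, "kd:") || startsWith(perturbation, "oe:")) {
    oe <- startsWith(perturbation, "oe:")
    pg <- sub("^(kd|oe):", "", perturbation)
    if (!pg %in% truth$gene_names) stop("unknown gene in perturbation: ", pg)
    flip <- if (oe) -1 else 1
    mu[pg] <- mu[pg] + flip * log2(knockdown_efficiency)
    net <- truth$networks[[as.character(time)]]
    out <- net[net$source == pg & net$target != pg, , drop = FALSE]
    if (nrow(out)) {
      # knocking down an activator lowers its targets (shift -sign * beta);
      # overexpression is modelled as the sign-flipped knockdown shift
      for (i in seq_len(nrow(out))) {
        mu[out$target[i]] <- mu[out$target[i]] - flip * out$sign[i] * out$strength[i]
      }
    }
  }
  mu
}

#' Simulate a knockdown perturbation expression table
#'
#' Generates replicate-level relative expression (linear scale, versus a
#' housekeeping reference) for a control series and one knockdown series per
#' gene, at 0, 4, 8 and 12 hr.  Under knockdown of gene `i`, gene `i` itself
#' is shifted by `log2(knockdown_efficiency)` and every direct target `j` of
#' a ground-truth edge `i -> j` (sign `s`, strength `beta`) is shifted by
#' `-s * beta` log2 units relative to control; knockdown effects do not
#' propagate transitively.  Gaussian noise (sd `noise_sd`) is added per
#' replicate on the log2 scale.  Output is deterministic given the seed.
#'
#' @param truth A [ground_truth()].
#' @param params A [sim_params()].
#' @param include_oe Also generate overexpression series (`oe:<gene>`),
#'   modelled as the sign-flipped knockdown shift.
#' @return Data frame with columns `gene`, `time_hr`, `perturbation`,
#'   `replicate`, `rel_expr`; the control series is labelled `siSCR`.
#' @export
simulate_perturbation_table <- function(truth, params = sim_params(),
                                        include_oe = FALSE) {
  stopifnot(inherits(truth, "ground_truth"), inherits(params, "sim_params"))
  perts <- c("siSCR", .kd_label(truth$gene_names))
  if (include_oe) perts <- c(perts, paste0("oe:", truth$gene_names))
  .with_seed(params$seed, {
    rows <- list()
    for (t in truth$times) {
      for (p in perts) {
        mu <- .det_log2(truth, t, p, params$knockdown_efficiency)
        for (r in seq_len(params$n_replicates)) {
          noise <- if (params$noise_sd > 0) {
            stats::rnorm(length(mu), 0, params$noise_sd)
          } else rep(0, length(mu))
          rows[[length(rows) + 1L]] <- data.frame(
            gene = truth$gene_names, time_hr = t, perturbation = p,
            replicate = r, rel_expr = 2^(mu + noise),
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate drug-treatment expression profiles
#'
#' Drug rows equal the control baseline plus a specified per-gene log2 shift
#' plus noise; a control (`siSCR`) series is included.  Deterministic given
#' the seed.
#'
#' @param truth A [ground_truth()].
#' @param drug_shifts Named list, one element per drug (e.g. `PKCi`, `TSA`),
#'   each a named numeric vector of log2 shifts covering every gene.
#' @param params A [sim_params()].
#' @return Data frame in the same format as
#'   [simulate_perturbation_table()], with perturbations `drug:<name>`.
#' @export
simulate_drug_profiles <- function(truth, drug_shifts, params = sim_params()) {
  stopifnot(inherits(truth, "ground_truth"), is.list(drug_shifts),
            length(drug_shifts) >= 1, !is.null(names(drug_shifts)))
  for (d in names(drug_shifts)) {
    if (!all(truth$gene_names %in% names(drug_shifts[[d]]))) {
      stop("missing gene in shift map for drug ", d)
    }
  }
  .with_seed(params$seed, {
    rows <- list()
    for (t in truth$times) {
      base_mu <- truth$baselines[, as.character(t)]
      series <- c(list(siSCR = base_mu),
                  lapply(drug_shifts, function(sh) base_mu + sh[truth$gene_names]))
      names(series) <- c("siSCR", paste0("drug:", names(drug_shifts)))
      for (p in names(series)) {
        for (r in seq_len(params$n_replicates)) {
          noise <- if (params$noise_sd > 0) {
            stats::rnorm(length(base_mu), 0, params$noise_sd)
          } else rep(0, length(base_mu))
          rows[[length(rows) + 1L]] <- data.frame(
            gene = truth$gene_names, time_hr = t, perturbation = p,
            replicate = r, rel_expr = 2^(series[[p]] + noise),
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a SILAC phospho-site table
#'
#' Generates per-site log2 SILAC ratios for phosphopeptides (`d_phospho_log2`)
#' and total protein (`d_total_log2`).  A `frac_confounded` share of sites is
#' "confounded": near-constant phosphorylation (|change| <= 0.1) with total
#' protein increased by more than +0.5 log2, exercising the ranking
#' exclusion rule.  The remaining sites are "changed" (|d_phospho| >= 0.3),
#' dephosphorylated (negative) with probability `frac_dephospho`, with total
#' protein essentially stable.  Deterministic given the seed.
#'
#' @param n_sites Number of phospho-sites.
#' @param frac_dephospho Probability that a changed site is a
#'   dephosphorylation (negative log2 ratio).
#' @param frac_confounded Share of confounded sites.
#' @param effect_sd Sd of the half-normal magnitude component.
#' @param seed RNG seed.
#' @return Data frame with columns `site_id`, `protein`, `d_phospho_log2`,
#'   `d_total_log2`, plus a ground-truth `truth_class` column
#'   (`changed`/`confounded`) used only for validation.
#' @export
simulate_silac_table <- function(n_sites, frac_dephospho = 2 / 3,
                                 frac_confounded = 0.1, effect_sd = 0.5,
                                 seed = 1) {
  stopifnot(n_sites >= 1,
            frac_dephospho >= 0, frac_dephospho <= 1,
            frac_confounded >= 0, frac_confounded <= 1)
  .with_seed(seed, {
    confounded <- stats::runif(n_sites) < frac_confounded
    d_p <- numeric(n_sites)
    d_t <- numeric(n_sites)
    n_conf <- sum(confounded)
    if (n_conf) {
      d_p[confounded] <- stats::runif(n_conf, -0.1, 0.1)
      d_t[confounded] <- 0.6 + abs(stats::rnorm(n_conf, 0, effect_sd))
    }
    n_ch <- n_sites - n_conf
    if (n_ch) {
      sign_neg <- stats::runif(n_ch) < frac_dephospho
      mag <- 0.3 + abs(stats::rnorm(n_ch, 0, effect_sd))
      d_p[!confounded] <- ifelse(sign_neg, -mag, mag)
      d_t[!confounded] <- stats::runif(n_ch, -0.3, 0.3)
    }
    data.frame(
      site_id = sprintf("site_%05d", seq_len(n_sites)),
      protein = sprintf("P%04d", ((seq_len(n_sites) - 1L) %% max(1L, n_sites %/% 3L)) + 1L),
      d_phospho_log2 = d_p,
      d_total_log2 = d_t,
      truth_class = ifelse(confounded, "confounded", "changed"),
      stringsAsFactors = FALSE)
  })
}
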