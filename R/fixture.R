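# A constructed (synthetic) six-gene, four-stage switching fixture.  The
# true discretised expression vectors of the original suspension time
# course are not redistributable, so this fixture encodes the same
# qualitative logic with hand-built stage networks: a trajectory of
# stem -> committed -> differentiated states that no single network can
# recapitulate but a monotonic network switch can, plus drug-like
# constraints in which one treatment arrests the system in the first
# network and the other forces a partial progression that never reaches
# the final network.

.fx_edges <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(source = r[[1]], target = r[[2]], sign = as.integer(r[[3]]),
               stringsAsFactors = FALSE)
  }))
}

#' Synthetic commitment-switch fixture
#'
#' A six-phosphatase, four-stage fixture encoding the qualitative result
#' chain of suspension-induced epidermal commitment:
#' \itemize{
#'   \item stage states `S0 -> S4 -> S8 -> S12` (stem, committed,
#'     intermediate, differentiated) observed at steps 0/4/8/12 of a 12-step
#'     trajectory (1 step = 1 hr);
#'   \item four stage ABNs `N0, N4, N8, N12`, each holding its own state as
#'     a fixed point and driving the transition from the previous state;
#'   \item a single-network ABN pooling all stage interactions as possible
#'     interactions (2^15 concrete networks) for the non-switching check,
#'     which is unsatisfiable;
#'   \item an untreated constraint (mandatory switch), a PKCi-like
#'     constraint (stem pattern held to 12 hr) and a TSA-like constraint
#'     (partial progression pattern at 12 hr).
#' }
#' The fixture is synthetic: it reproduces the logical structure of the
#' biology, not measured expression values.
#'
#' @return List with elements `genes`, `states` (S0, S4, S8, S12),
#'   `stage_abns` (named N0, N4, N8, N12), `single_abn`, `constraints`
#'   (untreated, PKCi, TSA) and `patterns` (the 12-hr drug patterns).
#' @export
commitment_fixture <- function() {
  genes <- PHOSPHATASES
  st <- function(v) stats::setNames(as.integer(v), genes)
  S0 <- st(c(1, 1, 0, 0, 0, 0))
  S4 <- st(c(0, 1, 1, 0, 0, 0))
  S8 <- st(c(0, 0, 1, 1, 0, 0))
  S12 <- st(c(0, 0, 0, 1, 1, 1))

  N0 <- abn(genes,
            definite = .fx_edges(list("DUSP6", "DUSP6", 1),
                                 list("DUSP6", "PPTC7", 1)),
            possible = .fx_edges(list("PPTC7", "DUSP6", 1)))
  N4 <- abn(genes,
            definite = .fx_edges(list("PPTC7", "PPTC7", 1),
                                 list("PPTC7", "PTPN1", 1)),
            possible = .fx_edges(list("PPTC7", "DUSP6", -1)))
  N8 <- abn(genes,
            definite = .fx_edges(list("PTPN1", "PTPN1", 1),
                                 list("PTPN1", "PTPN13", 1),
                                 list("PTPN1", "PPTC7", -1),
                                 list("PPTC7", "PTPN1", 1)))
  N12 <- abn(genes,
             definite = .fx_edges(list("PTPN13", "PTPN13", 1),
                                  list("PTPN13", "PTPN1", -1),
                                  list("PTPN13", "PPP3CA", 1),
                                  list("PTPN13", "DUSP10", 1),
                                  list("PPP3CA", "DUSP6", 1),
                                  list("DUSP10", "DUSP6", -1)))
  stage_abns <- list(N0 = N0, N4 = N4, N8 = N8, N12 = N12)

  pool <- unique(rbind(N0$definite, N0$possible, N4$definite, N4$possible,
                       N8$definite, N12$definite))
  single_abn <- abn(genes, possible = pool)

  untreated <- experiment_constraint(
    "untreated", horizon = 12,
    observations = list("0" = S0, "4" = S4, "8" = S8, "12" = S12),
    mandatory_switch = TRUE)
  # same observations without the switching flag: the meaningful question
  # for the single-network test is whether any one topology can produce the
  # observed state sequence at all
  untreated_single <- experiment_constraint(
    "untreated_single", horizon = 12,
    observations = list("0" = S0, "4" = S4, "8" = S8, "12" = S12))

  pkci_pattern <- S0
  tsa_pattern <- st(c(NA, 0, 1, 1, 0, 0))
  tsa_pattern <- tsa_pattern[!is.na(tsa_pattern)]

  pkci <- experiment_constraint(
    "PKCi", horizon = 12,
    observations = list("0" = S0, "12" = pkci_pattern))
  tsa <- experiment_constraint(
    "TSA", horizon = 12,
    observations = list("0" = S0, "12" = tsa_pattern))

  list(genes = genes,
       states = list(S0 = S0, S4 = S4, S8 = S8, S12 = S12),
       stage_abns = stage_abns,
       single_abn = single_abn,
       constraints = list(untreated = untreated,
                          untreated_single = untreated_single,
                          PKCi = pkci, TSA = tsa),
       patterns = list(PKCi = pkci_pattern, TSA = tsa_pattern))
}
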