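# SILAC phospho-site summarisation: dephosphorylation fraction,
# phospho-vs-total discordance, the protein-abundance exclusion rule, and
# top-k ranking by log2-fold decrease.

.check_silac <- function(records) {
  df <- as.data.frame(records)
  stopifnot(all(c("site_id", "d_phospho_log2", "d_total_log2") %in% names(df)))
  if (!nrow(df)) stop("records must be non-empty")
  if (any(!is.finite(df$d_phospho_log2)) || any(!is.finite(df$d_total_log2))) {
    stop("SILAC ratios must be finite")
  }
  df
}

#' Fraction of changed phospho-sites that are dephosphorylations
#'
#' Among sites whose phosphopeptide log2 ratio changes by more than
#' `change_threshold` in absolute value, returns the fraction with a
#' negative change (dephosphorylation).
#'
#' @param records SILAC site table (columns `site_id`, `d_phospho_log2`,
#'   `d_total_log2`).
#' @param change_threshold Absolute log2 change above which a site counts as
#'   changed.
#' @return Fraction in `[0, 1]`.
#' @export
dephospho_fraction <- function(records, change_threshold = 0.2) {
  df <- .check_silac(records)
  changed <- abs(df$d_phospho_log2) > change_threshold
  if (!any(changed)) stop("no changed sites above the threshold")
  mean(df$d_phospho_log2[changed] < 0)
}

#' Rank phospho-sites by log2-fold decrease with an abundance exclusion rule
#'
#' Sites whose phosphorylation remained constant (|d_phospho| <=
#' `constant_band`) while total protein abundance increased by more than
#' `total_increase_threshold` log2 units are excluded: their apparent
#' phospho-stability masks a net dephosphorylation of the growing protein
#' pool.  Surviving sites are ranked by ascending phosphopeptide log2 ratio
#' (largest decrease first) and the top `k` are returned together with the
#' discordance (phospho change minus total-protein change, a log2 ratio of
#' ratios).
#'
#' @inheritParams dephospho_fraction
#' @param k Number of top sites to return (default 15).
#' @param constant_band Absolute log2 band within which phosphorylation
#'   counts as constant.
#' @param total_increase_threshold Total-protein log2 increase that triggers
#'   exclusion (default 0.5).
#' @return Data frame of the top `k` surviving sites with a `discordance`
#'   column, ordered by ascending `d_phospho_log2`.  If fewer than `k` sites
#'   survive, all are returned and the attribute `truncated` is set to TRUE
#'   with a warning.
#' @export
filter_and_rank_sites <- function(records, k = 15, constant_band = 0.2,
                                  total_increase_threshold = 0.5) {
  stopifnot(k >= 1)
  df <- .check_silac(records)
  excluded <- abs(df$d_phospho_log2) <= constant_band &
    df$d_total_log2 > total_increase_threshold
  keep <- df[!excluded, , drop = FALSE]
  keep$discordance <- keep$d_phospho_log2 - keep$d_total_log2
  # stable order: ties broken by site id so the ranking is invariant to
  # input row order
  keep <- keep[order(keep$d_phospho_log2, keep$site_id), , drop = FALSE]
  truncated <- nrow(keep) < k
  if (truncated) {
    warning("k exceeds the number of surviving records; returning all ",
            nrow(keep))
  }
  out <- utils::head(keep, k)
  rownames(out) <- NULL
  attr(out, "truncated") <- truncated
  attr(out, "n_excluded") <- sum(excluded)
  out
}
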