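# Perturbation-based inference of signed, weighted mechanistic networks
# from knockdown time courses: per-target two-way ANOVA, Holm-Sidak
# correction, p < alpha edge filter, inverse-p edge weights.

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Step-down Sidak procedure: with raw p-values sorted ascending, the i-th
#' adjusted value is `max_{j <= i} (1 - (1 - p_(j))^(m - j + 1))`, capped at
#' 1.  Adjusted values are monotone non-decreasing in the sorted order and
#' never below the raw values; with a single comparison the adjusted value
#' equals the raw value.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @examples
#' holm_sidak(c(0.01, 0.04))  # 0.0199, 0.04
#' @export
holm_sidak <- function(p) {
  stopifnot(is.numeric(p), all(is.finite(p)), all(p >= 0 & p <= 1))
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  ps <- p[ord]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

.kd_label <- function(gene) paste0("kd:", gene)

#' Per-target two-way ANOVA of knockdown effects
#'
#' For one measured target gene, fits a two-way ANOVA (factors: perturbation
#' and time, with interaction) on log2 expression, then computes per-cell
#' contrasts of each knockdown versus the control at each time point using
#' pooled-variance t statistics from the ANOVA residual.  The contrasts for
#' one target gene form a single comparison family adjusted by the
#' Holm-Sidak procedure.  Knockdown of the target itself is excluded: a
#' knockdown trivially lowers its own transcript, so self-edges are not
#' inferable from this design.
#'
#' @param table Perturbation expression table (data frame with columns
#'   `gene`, `time_hr`, `perturbation`, `replicate`, `rel_expr`).
#' @param target_gene Measured gene whose regulators are sought.
#' @param control Label of the control perturbation stratum.
#' @return Data frame with one row per (knockdown, time): `knockdown`,
#'   `time_hr`, `log2fc` (knockdown minus control on log2 scale), `p_raw`,
#'   `p_adj`.
#' @export
fit_knockdown_anova <- function(table, target_gene, control = "siSCR") {
  df <- as.data.frame(table)
  stopifnot(all(c("gene", "time_hr", "perturbation", "replicate", "rel_expr") %in% names(df)))
  kd_perts <- unique(df$perturbation[startsWith(df$perturbation, "kd:")])
  kd_perts <- setdiff(kd_perts, .kd_label(target_gene))
  df <- df[df$gene == target_gene & df$perturbation %in% c(control, kd_perts), ]
  if (!any(df$perturbation == control)) stop("missing control stratum")
  counts <- base::table(df$perturbation, df$time_hr)
  if (any(counts < 2L)) {
    stop("fewer than 2 replicates in some (perturbation, time) stratum")
  }
  df$y <- log2(df$rel_expr)
  df$pert <- factor(df$perturbation, levels = c(control, sort(kd_perts)))
  df$tf <- factor(df$time_hr)
  fit <- stats::lm(y ~ pert * tf, data = df)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  cell_mean <- tapply(df$y, list(df$pert, df$tf), mean)
  cell_n <- tapply(df$y, list(df$pert, df$tf), length)
  res <- expand.grid(knockdown = sort(kd_perts),
                     time_hr = sort(unique(df$time_hr)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$log2fc <- NA_real_
  res$p_raw <- NA_real_
  for (i in seq_len(nrow(res))) {
    kd <- res$knockdown[i]; tt <- as.character(res$time_hr[i])
    diffm <- cell_mean[kd, tt] - cell_mean[control, tt]
    se <- sqrt(mse * (1 / cell_n[kd, tt] + 1 / cell_n[control, tt]))
    res$log2fc[i] <- diffm
    if (se == 0) {
      # degenerate (noise-free) variance: a nonzero contrast is maximally
      # significant, a zero contrast carries no evidence
      res$p_raw[i] <- if (diffm == 0) 1 else .Machine$double.xmin
    } else {
      tstat <- diffm / se
      res$p_raw[i] <- 2 * stats::pt(-abs(tstat), fit$df.residual)
    }
  }
  res$p_adj <- pmax(holm_sidak(res$p_raw), .Machine$double.xmin)
  res$knockdown <- sub("^kd:", "", res$knockdown)
  res
}

#' Node log2 fold-changes relative to 0 hr
#'
#' Mean log2 expression change of each gene in the control condition at each
#' time point relative to the 0-hr time point (replicates averaged on the
#' log2 scale).
#'
#' @inheritParams fit_knockdown_anova
#' @return Data frame with columns `gene`, `time_hr`, `log2fc`.
#' @export
compute_node_foldchanges <- function(table, control = "siSCR") {
  df <- as.data.frame(table)
  df <- df[df$perturbation == control, ]
  if (!nrow(df)) stop("missing control stratum")
  m <- stats::aggregate(rel_expr ~ gene + time_hr, df,
                        function(v) mean(log2(v)))
  base <- m[m$time_hr == 0, ]
  if (!all(unique(m$gene) %in% base$gene)) stop("missing 0 hr data for some gene")
  m$log2fc <- m$rel_expr - base$rel_expr[match(m$gene, base$gene)]
  m[, c("gene", "time_hr", "log2fc")]
}

#' Call signed edges from adjusted p-values and fold-changes
#'
#' An edge `i -> j` at time `t` is emitted iff its Holm-Sidak adjusted
#' p-value is below `alpha`.  Its sign is +1 (activating) when the
#' knockdown fold-change is negative (silencing an activator lowers its
#' target) and -1 (inhibiting) when positive; a fold-change of exactly 0
#' with a significant p-value is a data error (the sign is undefined).  The
#' edge weight is the inverse adjusted p-value, `w = 1/p`.
#'
#' @param stats_df Output of [fit_knockdown_anova()] with an added `target`
#'   column (see [infer_mechanistic_networks()]), or that function's output
#'   for a single target plus `target =`.
#' @param alpha Significance threshold in (0, 1).
#' @param target Target gene name when `stats_df` lacks a `target` column.
#' @return Data frame of edge calls: `source`, `target`, `time_hr`, `sign`,
#'   `log2fc`, `p`, `weight`.
#' @export
call_edges <- function(stats_df, alpha = 0.05, target = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  df <- as.data.frame(stats_df)
  if (!"target" %in% names(df)) {
    if (is.null(target)) stop("need a target column or a target gene")
    df$target <- target
  }
  sig <- df[df$p_adj < alpha, , drop = FALSE]
  if (any(sig$log2fc == 0)) {
    stop("significant contrast with fold-change exactly 0: sign undefined")
  }
  data.frame(source = sig$knockdown, target = sig$target,
             time_hr = sig$time_hr,
             sign = ifelse(sig$log2fc < 0, 1L, -1L),
             log2fc = sig$log2fc, p = sig$p_adj, weight = 1 / sig$p_adj,
             stringsAsFactors = FALSE)
}

#' Infer per-time-point mechanistic networks from a knockdown table
#'
#' Runs [fit_knockdown_anova()] for every measured gene, calls signed
#' weighted edges with [call_edges()], and attaches node log2 fold-changes
#' relative to 0 hr.  Returns one `mechanistic_network` per time point.
#'
#' @inheritParams fit_knockdown_anova
#' @param alpha Per-family significance threshold (default 0.05).
#' @return Named list (by time) of `mechanistic_network` objects, each with
#'   fields `time_hr`, `edges` and `node_log2fc`; class
#'   `mechanistic_network_set`.
#' @export
infer_mechanistic_networks <- function(table, alpha = 0.05, control = "siSCR") {
  df <- as.data.frame(table)
  genes <- sort(unique(df$gene))
  allstats <- do.call(rbind, lapply(genes, function(g) {
    s <- fit_knockdown_anova(df, g, control = control)
    s$target <- g
    s
  }))
  edges <- call_edges(allstats, alpha = alpha)
  nodefc <- compute_node_foldchanges(df, control = control)
  times <- sort(unique(df$time_hr))
  out <- lapply(times, function(t) {
    e <- edges[edges$time_hr == t, , drop = FALSE]
    rownames(e) <- NULL
    structure(list(time_hr = t, edges = e,
                   node_log2fc = nodefc[nodefc$time_hr == t, ]),
              class = "mechanistic_network")
  })
  names(out) <- as.character(times)
  class(out) <- "mechanistic_network_set"
  out
}

#' @export
print.mechanistic_network <- function(x, ...) {
  cat("Mechanistic network at", x$time_hr, "hr:", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    lab <- ifelse(x$edges$sign == 1L, "->", "-|")
    cat(paste0("  ", x$edges$source, " ", lab, " ", x$edges$target,
               "  (w = ", signif(x$edges$weight, 3), ")", collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
print.mechanistic_network_set <- function(x, ...) {
  for (m in x) print(m)
  invisible(x)
}
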