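# Boolean discretisation of expression profiles and trajectory constraints.

#' Discretise expression profiles into Boolean states
#'
#' A gene is ON at a time point iff its mean expression strictly exceeds the
#' reference average for that sample; a gene equal to or below the average is
#' OFF ("similar/lower" maps to off).  By default the reference average is
#' the mean over the network genes within the same sample, so the result
#' depends only on within-sample expression ratios.
#'
#' @param timecourse Data frame with columns `gene`, `time_hr`, `rel_expr`
#'   (strictly positive, linear scale); replicate rows are averaged.
#' @param reference_scope Either a character vector naming the genes to
#'   average over (default: all genes in `timecourse`) or a named numeric
#'   vector supplying an external reference average per time point.
#' @param log_scale Average on log2 scale instead of the linear scale.
#' @return Named list mapping time (as character) to a named 0/1 state.
#' @export
discretise_states <- function(timecourse, reference_scope = NULL,
                              log_scale = FALSE) {
  df <- as.data.frame(timecourse)
  stopifnot(all(c("gene", "time_hr", "rel_expr") %in% names(df)))
  if (!nrow(df)) stop("empty gene set")
  if (any(!is.finite(df$rel_expr)) || any(df$rel_expr <= 0)) {
    stop("expression must be strictly positive")
  }
  mexpr <- stats::aggregate(rel_expr ~ gene + time_hr, df, mean)
  times <- sort(unique(mexpr$time_hr))
  out <- list()
  for (t in times) {
    sub <- mexpr[mexpr$time_hr == t, ]
    vals <- stats::setNames(sub$rel_expr, sub$gene)
    if (is.numeric(reference_scope)) {
      ref <- reference_scope[[as.character(t)]]
      if (is.null(ref) || is.na(ref)) stop("no external reference average for time ", t)
    } else {
      scope <- if (is.null(reference_scope)) names(vals) else reference_scope
      if (!all(scope %in% names(vals))) {
        stop("reference scope gene missing at time ", t)
      }
      ref <- if (log_scale) 2^mean(log2(vals[scope])) else mean(vals[scope])
    }
    out[[as.character(t)]] <- stats::setNames(as.integer(vals > ref), names(vals))
  }
  out
}

constraint_genes <- function(constraint) {
  unique(unlist(lapply(constraint$observations, names)))
}

#' Construct a trajectory constraint
#'
#' An experiment constraint couples partial expected Boolean states at given
#' trajectory steps with optional network-at-step requirements (which
#' network index must represent the system at a step; steps without a
#' requirement leave the representative network free) and an optional
#' mandatory-switch flag (the system must change its representative network
#' at least once).
#'
#' @param name Constraint label (e.g. "untreated", "PKCi", "TSA").
#' @param horizon Number of trajectory steps; one step corresponds to 1 hr,
#'   so the default horizon of 12 spans a 12-hr time course with observed
#'   states at 0, 4, 8 and 12 hr.
#' @param observations List mapping a step (coercible to integer) to a named
#'   partial 0/1 state.
#' @param network_requirements Optional list mapping a step to a 0-based
#'   network index; indices must be non-decreasing with step.
#' @param mandatory_switch Logical; require at least one step in a network
#'   with index > 0.
#' @return An object of class `experiment_constraint`.
#' @export
experiment_constraint <- function(name, horizon = 12, observations = list(),
                                  network_requirements = NULL,
                                  mandatory_switch = FALSE) {
  horizon <- as.integer(horizon)
  stopifnot(horizon >= 0L, is.list(observations))
  obs <- list()
  for (k in names(observations)) {
    step <- as.integer(k)
    if (is.na(step) || step < 0L || step > horizon) {
      stop("observation step outside 0..horizon: ", k)
    }
    o <- observations[[k]]
    v <- as.integer(o)
    if (is.null(names(o)) || !all(v %in% c(0L, 1L))) {
      stop("observations must be named 0/1 vectors")
    }
    obs[[as.character(step)]] <- stats::setNames(v, names(o))
  }
  obs <- obs[order(as.integer(names(obs)))]
  req <- NULL
  if (!is.null(network_requirements) && length(network_requirements)) {
    steps <- as.integer(names(network_requirements))
    idx <- as.integer(unlist(network_requirements))
    if (any(is.na(steps)) || any(steps < 0L | steps > horizon)) {
      stop("network requirement step outside 0..horizon")
    }
    if (any(idx < 0L)) stop("network indices must be >= 0")
    ord <- order(steps)
    if (is.unsorted(idx[ord])) {
      stop("network requirements must be non-decreasing with step")
    }
    req <- stats::setNames(as.list(idx[ord]), as.character(steps[ord]))
  }
  structure(list(name = as.character(name), horizon = horizon,
                 observations = obs, network_requirements = req,
                 mandatory_switch = isTRUE(mandatory_switch)),
            class = "experiment_constraint")
}

#' @export
print.experiment_constraint <- function(x, ...) {
  cat("Experiment constraint '", x$name, "': horizon ", x$horizon,
      " steps, ", length(x$observations), " observed steps",
      if (x$mandatory_switch) ", mandatory switch" else "", "\n", sep = "")
  for (k in names(x$observations)) {
    o <- x$observations[[k]]
    cat("  step ", k, ": ", paste0(names(o), "=", o, collapse = " "), "\n", sep = "")
  }
  if (!is.null(x$network_requirements)) {
    cat("  network requirements:",
        paste0("step ", names(x$network_requirements), " -> N",
               unlist(x$network_requirements), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assemble a trajectory constraint from discretised states
#'
#' Places each discretised state (from [discretise_states()]) at the
#' trajectory step equal to its time in hours (1 step = 1 hr).
#'
#' @param states Named list mapping time to a named 0/1 state.
#' @param horizon Trajectory length in steps.
#' @param network_requirements,mandatory_switch Passed to
#'   [experiment_constraint()].
#' @param name Constraint label.
#' @return An [experiment_constraint()].
#' @export
build_experiment_constraints <- function(states, horizon = 12,
                                         network_requirements = NULL,
                                         mandatory_switch = FALSE,
                                         name = "experiment") {
  experiment_constraint(name, horizon = horizon, observations = states,
                        network_requirements = network_requirements,
                        mandatory_switch = mandatory_switch)
}
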