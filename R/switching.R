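# Switching-network reasoning: an ordered sequence of ABNs through which the
# system progresses monotonically (forwards only), one concrete network
# chosen per ABN, synchronous dynamics within each span.

#' Construct a switching problem
#'
#' Couples an ordered list of ABNs (e.g. the networks derived at 0, 4, 8 and
#' 12 hr) with a trajectory constraint.  The system starts in the first ABN
#' and may only switch forwards (monotonic switching); the constraint's
#' network requirements pin the representative network at given steps, and
#' its mandatory-switch flag forces at least one switch away from the first
#' network.
#'
#' @param abns List of [abn()] objects sharing one gene list, in
#'   chronological order.
#' @param constraint An [experiment_constraint()].
#' @return An object of class `switching_problem`.
#' @export
switching_problem <- function(abns, constraint) {
  stopifnot(is.list(abns), length(abns) >= 1,
            all(vapply(abns, inherits, TRUE, "abn")),
            inherits(constraint, "experiment_constraint"))
  genes <- abns[[1]]$genes
  if (!all(vapply(abns, function(a) identical(a$genes, genes), TRUE))) {
    stop("all ABNs must share the same gene list")
  }
  if (!all(constraint_genes(constraint) %in% genes)) {
    stop("constraint mentions genes outside the shared gene list")
  }
  if (length(constraint$observations) &&
      constraint$horizon < max(as.integer(names(constraint$observations)))) {
    stop("horizon shorter than the last observation step")
  }
  req <- constraint$network_requirements
  if (!is.null(req)) {
    if (any(unlist(req) >= length(abns))) stop("network requirement index out of range")
    if (!is.null(req[["0"]]) && req[["0"]] != 0L) {
      stop("the system starts in the first network; a step-0 requirement must be 0")
    }
  }
  if (is.null(names(abns))) names(abns) <- paste0("N", seq_along(abns) - 1L)
  structure(list(abns = abns, constraint = constraint), class = "switching_problem")
}

# all monotone non-decreasing schedules of length `horizon` over indices
# 0..(k-1), as a matrix (one row per schedule), lexicographic order
.monotone_schedules <- function(horizon, k) {
  if (horizon == 0L) return(matrix(integer(0), nrow = 1, ncol = 0))
  acc <- list()
  rec <- function(pre, last) {
    if (length(pre) == horizon) { acc[[length(acc) + 1L]] <<- pre; return(invisible()) }
    for (v in last:(k - 1L)) rec(c(pre, v), v)
  }
  rec(integer(0), 0L)
  do.call(rbind, acc)
}

.schedule_ok <- function(sched, req, mandatory_switch) {
  if (!is.null(req)) {
    for (k in names(req)) {
      step <- as.integer(k)
      if (step == 0L) next  # validated to be index 0 at problem construction
      if (sched[step] != req[[k]]) return(FALSE)
    }
  }
  if (mandatory_switch && all(sched == 0L)) return(FALSE)
  TRUE
}

#' Solve a switching problem
#'
#' Complete explicit search over monotone switch schedules, concrete-network
#' choices (one per visited ABN, reused across its span) and initial-state
#' completions.  Returns the first solution in a deterministic order, or an
#' UNSAT result.
#'
#' @param problem A [switching_problem()].
#' @param limit Bound on concrete networks enumerated per ABN and on the
#'   joint combinations tried per schedule.
#' @return An object of class `switch_solution` when satisfiable (fields
#'   `schedule`, `networks`, `initial`, `trajectory`, `visited`), otherwise a
#'   `sat_result` with status UNSAT.
#' @export
solve_switching <- function(problem, limit = 2^20) {
  stopifnot(inherits(problem, "switching_problem"))
  cons <- problem$constraint
  genes <- problem$abns[[1]]$genes
  horizon <- cons$horizon
  scheds <- .monotone_schedules(horizon, length(problem$abns))
  keep <- apply(scheds, 1, .schedule_ok, req = cons$network_requirements,
                mandatory_switch = cons$mandatory_switch)
  scheds <- scheds[keep, , drop = FALSE]
  concretes <- vector("list", length(problem$abns))  # lazily enumerated
  inits <- .initial_candidates(genes, cons$observations)
  examined <- 0L
  for (r in seq_len(nrow(scheds))) {
    sched <- as.integer(scheds[r, ])
    visited <- unique(c(0L, sched))
    for (v in visited) {
      if (is.null(concretes[[v + 1L]])) {
        concretes[[v + 1L]] <- enumerate_concrete_networks(problem$abns[[v + 1L]], limit)
      }
    }
    sizes <- vapply(visited, function(v) length(concretes[[v + 1L]]), 1L)
    if (prod(sizes) > limit) {
      stop("joint concrete-network choices exceed the enumeration limit")
    }
    idx <- rep(1L, length(visited))
    repeat {
      nets_by_abn <- stats::setNames(
        lapply(seq_along(visited), function(i) concretes[[visited[i] + 1L]][[idx[i]]]),
        as.character(visited))
      nets <- if (horizon > 0L) nets_by_abn[as.character(sched)] else list()
      examined <- examined + 1L
      for (q in seq_len(nrow(inits))) {
        traj <- .run_and_check(nets, inits[q, ], horizon, cons$observations, genes)
        if (!is.null(traj)) {
          sol <- structure(
            list(schedule = sched, visited = visited,
                 networks = stats::setNames(nets_by_abn, names(problem$abns)[visited + 1L]),
                 initial = traj[[1]], trajectory = traj,
                 stats = list(combinations_examined = examined)),
            class = "switch_solution")
          return(sol)
        }
      }
      j <- length(idx)
      while (j >= 1L && idx[j] == sizes[j]) { idx[j] <- 1L; j <- j - 1L }
      if (j < 1L) break
      idx[j] <- idx[j] + 1L
    }
  }
  sat_result("UNSAT", stats = list(combinations_examined = examined))
}

#' @export
print.switch_solution <- function(x, ...) {
  cat("Switching solution: SAT\n")
  cat("  visited networks:", paste(names(x$networks), collapse = " -> "), "\n")
  cat("  schedule:", paste(x$schedule, collapse = " "), "\n")
  cat("  initial state:", paste0(names(x$initial), "=", x$initial, collapse = " "), "\n")
  invisible(x)
}

#' Enumerate the feasible switch paths of a switching problem
#'
#' Returns the set of visited-ABN sequences (in chronological order) over
#' all solutions of the problem, e.g. `{N0->N4->N8, N0->N8}`.  The empty set
#' means the problem is unsatisfiable.
#'
#' @inheritParams solve_switching
#' @return Character vector of feasible paths, labelled by ABN name joined
#'   with `->`; the corresponding 0-based index sequences are attached as
#'   attribute `indices`.
#' @export
classify_switch_paths <- function(problem, limit = 2^20) {
  stopifnot(inherits(problem, "switching_problem"))
  k <- length(problem$abns)
  nm <- names(problem$abns)
  cons <- problem$constraint
  # candidate visited sequences: 0 followed by any strictly increasing
  # subsequence of 1..k-1
  cands <- list(0L)
  if (k > 1L) {
    for (m in 1:(k - 1L)) {
      combos <- utils::combn(seq_len(k - 1L), m, simplify = FALSE)
      cands <- c(cands, lapply(combos, function(cc) c(0L, as.integer(cc))))
    }
  }
  feasible <- list()
  scheds <- .monotone_schedules(cons$horizon, k)
  keep <- apply(scheds, 1, .schedule_ok, req = cons$network_requirements,
                mandatory_switch = cons$mandatory_switch)
  scheds <- scheds[keep, , drop = FALSE]
  for (cand in cands) {
    rows <- which(apply(scheds, 1, function(sc) identical(unique(c(0L, as.integer(sc))), cand)))
    found <- FALSE
    for (r in rows) {
      sub <- .solve_fixed_schedule(problem, as.integer(scheds[r, ]), limit)
      if (!is.null(sub)) { found <- TRUE; break }
    }
    if (found) feasible[[length(feasible) + 1L]] <- cand
  }
  labels <- vapply(feasible, function(v) paste(nm[v + 1L], collapse = "->"), "")
  structure(labels, indices = feasible)
}

# search concrete choices + initials for one fixed schedule; NULL if none
.solve_fixed_schedule <- function(problem, sched, limit) {
  cons <- problem$constraint
  genes <- problem$abns[[1]]$genes
  horizon <- cons$horizon
  visited <- unique(c(0L, sched))
  concretes <- lapply(visited, function(v) enumerate_concrete_networks(problem$abns[[v + 1L]], limit))
  sizes <- vapply(concretes, length, 1L)
  if (prod(sizes) > limit) stop("joint concrete-network choices exceed the enumeration limit")
  inits <- .initial_candidates(genes, cons$observations)
  idx <- rep(1L, length(visited))
  repeat {
    nets_by_abn <- stats::setNames(
      lapply(seq_along(visited), function(i) concretes[[i]][[idx[i]]]),
      as.character(visited))
    nets <- if (horizon > 0L) nets_by_abn[as.character(sched)] else list()
    for (q in seq_len(nrow(inits))) {
      traj <- .run_and_check(nets, inits[q, ], horizon, cons$observations, genes)
      if (!is.null(traj)) return(list(networks = nets_by_abn, trajectory = traj))
    }
    j <- length(idx)
    while (j >= 1L && idx[j] == sizes[j]) { idx[j] <- 1L; j <- j - 1L }
    if (j < 1L) return(NULL)
    idx[j] <- idx[j] + 1L
  }
}

#' Test whether an ABN is compatible with a target expression pattern
#'
#' TRUE iff some concrete network of the ABN admits a synchronous trajectory
#' from some (any) initial state whose state at the horizon step matches the
#' partial target pattern.  Used to ask, e.g., whether a drug-arrested
#' expression pattern is compatible with the network derived at a given
#' differentiation stage.
#'
#' @param x An [abn()].
#' @param target_state Named partial 0/1 vector.
#' @param horizon Number of synchronous steps.
#' @param limit Enumeration bound.
#' @return Logical.
#' @export
test_pattern_compatibility <- function(x, target_state, horizon = 12, limit = 2^20) {
  stopifnot(inherits(x, "abn"))
  if (!all(names(target_state) %in% x$genes)) {
    stop("target pattern mentions genes outside the ABN gene list")
  }
  target <- stats::setNames(as.integer(target_state), names(target_state))
  inits <- .initial_candidates(x$genes, list())
  obs <- stats::setNames(list(target), as.character(horizon))
  it <- .abn_iterate(x, function(net) {
    nets <- rep(list(net), max(horizon, 1L))
    for (q in seq_len(nrow(inits))) {
      traj <- .run_and_check(nets, inits[q, ], horizon, obs, x$genes)
      if (!is.null(traj)) return(TRUE)
    }
    NULL
  }, limit)
  isTRUE(it$result)
}
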