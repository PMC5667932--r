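# Readers/writers for networks (SIF, JSON, GraphML), expression and SILAC
# tables, ABN/constraint JSON, witness verification and run configuration.

#' Read and write networks in SIF, JSON or GraphML
#'
#' The SIF dialect is one interaction per line,
#' `source<TAB>activates|inhibits<TAB>target`.  JSON stores the gene list and
#' the interaction table; GraphML export (via igraph) carries `sign` (and
#' `weight`, when present) edge attributes.  All formats round-trip the
#' topology and signs losslessly.
#'
#' @param path File path.  `read_network()`/`write_network()` guess the
#'   format from the extension (`.sif`, `.json`, `.graphml`).
#' @param network A [boolean_network()].
#' @param format One of `"sif"`, `"json"`, `"graphml"`.
#' @return `read_*` return a [boolean_network()]; `write_*` return the path
#'   invisibly.
#' @export
read_network <- function(path, format = NULL) {
  format <- format %||% .guess_format(path)
  switch(format,
         sif = read_network_sif(path),
         json = read_network_json(path),
         graphml = read_network_graphml(path),
         stop("unrecognised network format: ", format))
}

#' @rdname read_network
#' @export
write_network <- function(network, path, format = NULL) {
  format <- format %||% .guess_format(path)
  switch(format,
         sif = write_network_sif(network, path),
         json = write_network_json(network, path),
         graphml = write_network_graphml(network, path),
         stop("unrecognised network format: ", format))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sif", "json", "graphml")) ext
  else stop("cannot guess network format from extension: ", ext)
}

#' @rdname read_network
#' @export
read_network_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3) stop("malformed SIF line ", i, ": expected 3 tab-separated fields")
    if (!f[2] %in% c("activates", "inhibits")) {
      stop("unknown sign token on line ", i, ": '", f[2], "'")
    }
    data.frame(source = f[1], target = f[3],
               sign = if (f[2] == "activates") 1L else -1L,
               stringsAsFactors = FALSE)
  })
  ints <- do.call(rbind, rows)
  boolean_network(sort(unique(c(ints$source, ints$target))), ints)
}

#' @rdname read_network
#' @export
write_network_sif <- function(network, path) {
  stopifnot(inherits(network, "boolean_network"))
  ints <- network$interactions
  rel <- ifelse(ints$sign == 1L, "activates", "inhibits")
  writeLines(paste(ints$source, rel, ints$target, sep = "\t"), path)
  invisible(path)
}

#' @rdname read_network
#' @export
read_network_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ints <- as.data.frame(x$interactions)
  boolean_network(x$genes, ints,
                  rules = if (!is.null(x$rules)) unlist(x$rules) else "default")
}

#' @rdname read_network
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "boolean_network"))
  jsonlite::write_json(
    list(genes = network$genes, interactions = network$interactions,
         rules = as.list(network$rules)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname read_network
#' @export
write_network_graphml <- function(network, path) {
  stopifnot(inherits(network, "boolean_network"))
  ints <- network$interactions
  g <- igraph::graph_from_data_frame(
    ints[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = network$genes))
  igraph::E(g)$sign <- as.integer(ints$sign)
  if (!is.null(ints$weight)) igraph::E(g)$weight <- ints$weight
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname read_network
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  ints <- data.frame(source = el$from, target = el$to,
                     sign = as.integer(el$sign), stringsAsFactors = FALSE)
  boolean_network(igraph::V(g)$name, ints)
}

#' Read/write perturbation expression tables as TSV
#'
#' Header: `gene  time_hr  perturbation  replicate  rel_expr`.
#'
#' @param table Data frame as produced by [simulate_perturbation_table()].
#' @param path File path.
#' @return `read_perturbation_table()` returns the validated data frame.
#' @export
write_perturbation_table <- function(table, path) {
  stopifnot(all(c("gene", "time_hr", "perturbation", "replicate", "rel_expr")
                %in% names(table)))
  utils::write.table(table[, c("gene", "time_hr", "perturbation",
                               "replicate", "rel_expr")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_perturbation_table
#' @export
read_perturbation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "time_hr", "perturbation", "replicate", "rel_expr")
  if (!all(need %in% names(df))) {
    stop("perturbation table must have header: ", paste(need, collapse = "\t"))
  }
  if (any(df$rel_expr <= 0)) stop("rel_expr must be strictly positive")
  df
}

#' Read/write SILAC site tables as TSV
#'
#' Header: `site_id  protein  d_phospho_log2  d_total_log2`.
#'
#' @param records SILAC site data frame.
#' @param path File path.
#' @return `read_silac_table()` returns the validated data frame.
#' @export
write_silac_table <- function(records, path) {
  cols <- c("site_id", "protein", "d_phospho_log2", "d_total_log2")
  stopifnot(all(cols %in% names(records)))
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_silac_table
#' @export
read_silac_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check_silac(df)
}

#' Read/write ABNs and constraints as JSON
#'
#' @param x An [abn()] or [experiment_constraint()].
#' @param path File path.
#' @return Readers return the reconstructed object; a JSON round-trip is the
#'   identity.
#' @export
write_abn_json <- function(x, path) {
  stopifnot(inherits(x, "abn"))
  jsonlite::write_json(
    list(genes = x$genes, definite = x$definite, possible = x$possible,
         rules = as.list(x$rules), rule_choices = x$rule_choices),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_abn_json
#' @export
read_abn_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  abn(x$genes,
      definite = as.data.frame(x$definite),
      possible = as.data.frame(x$possible),
      rules = unlist(x$rules),
      rule_choices = x$rule_choices)
}

#' @rdname write_abn_json
#' @export
write_constraint_json <- function(x, path) {
  stopifnot(inherits(x, "experiment_constraint"))
  jsonlite::write_json(
    list(name = x$name, horizon = x$horizon,
         observations = lapply(x$observations, as.list),
         network_requirements = x$network_requirements,
         mandatory_switch = x$mandatory_switch),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_abn_json
#' @export
read_constraint_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  experiment_constraint(
    name = x$name, horizon = x$horizon,
    observations = lapply(x$observations, function(o) unlist(o)),
    network_requirements = x$network_requirements,
    mandatory_switch = isTRUE(x$mandatory_switch))
}

#' Independently verify a solver witness
#'
#' Replays the witness trajectory through the synchronous simulator and
#' checks every observation, the monotonicity of the switch schedule, and
#' all network-at-step requirements.  This is the acceptance gate applied to
#' every SAT output.
#'
#' @param solution A `switch_solution`, or a SAT `sat_result` from
#'   [check_consistency()].
#' @param problem The [switching_problem()] (or, for a single-ABN result,
#'   the [experiment_constraint()]).
#' @return TRUE, or FALSE with attribute `violation` describing the first
#'   violated check.
#' @export
verify_witness <- function(solution, problem) {
  fail <- function(msg) { r <- FALSE; attr(r, "violation") <- msg; r }
  if (inherits(solution, "sat_result")) {
    if (solution$status != "SAT") return(fail("solution does not claim SAT"))
    w <- solution$witness
    cons <- if (inherits(problem, "experiment_constraint")) problem else problem$constraint
    sched_nets <- rep(list(w$network), cons$horizon)
    sched_idx <- w$schedule
  } else if (inherits(solution, "switch_solution")) {
    if (!inherits(problem, "switching_problem")) stop("need the switching problem")
    cons <- problem$constraint
    w <- solution
    sched_idx <- solution$schedule
    # networks are stored under ABN names in solutions; re-key by index
    byidx <- stats::setNames(solution$networks, as.character(solution$visited))
    sched_nets <- unname(byidx[as.character(sched_idx)])
  } else {
    stop("unrecognised solution object")
  }
  if (length(sched_idx) && is.unsorted(sched_idx)) {
    return(fail("switch schedule is not monotone non-decreasing"))
  }
  req <- cons$network_requirements
  if (!is.null(req)) {
    for (k in names(req)) {
      step <- as.integer(k)
      have <- if (step == 0L) 0L else sched_idx[step]
      if (have != req[[k]]) {
        return(fail(paste0("network requirement violated at step ", k)))
      }
    }
  }
  if (isTRUE(cons$mandatory_switch) && all(sched_idx == 0L)) {
    return(fail("mandatory switch not honoured"))
  }
  genes <- names(w$initial)
  traj <- if (cons$horizon > 0L) {
    simulate_trajectory(sched_nets, w$initial, cons$horizon)
  } else {
    list(w$initial)
  }
  for (k in names(cons$observations)) {
    o <- cons$observations[[k]]
    s <- traj[[as.integer(k) + 1L]]
    if (any(s[names(o)] != o)) {
      return(fail(paste0("observation violated at step ", k, " (",
                         paste0(names(o)[s[names(o)] != o], collapse = ","), ")")))
    }
  }
  # the claimed trajectory must equal the replay
  if (!is.null(w$trajectory)) {
    for (i in seq_along(traj)) {
      if (any(traj[[i]] != w$trajectory[[i]][genes])) {
        return(fail(paste0("claimed trajectory diverges from replay at step ", i - 1L)))
      }
    }
  }
  TRUE
}

#' Validated run configuration
#'
#' Central defaults for a pipeline run: significance threshold, discretisation
#' reference scope, update-rule selection, solver enumeration limit, seed and
#' output directory.
#'
#' @param alpha Edge significance threshold in (0, 1).
#' @param reference_scope Discretisation reference (see
#'   [discretise_states()]).
#' @param rules Update rule id from [rule_catalogue()].
#' @param enumeration_limit Solver enumeration bound.
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param log_level One of "quiet", "info", "debug".
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(alpha = 0.05, reference_scope = NULL,
                       rules = "default", enumeration_limit = 2^20,
                       seed = 1, out_dir = ".", log_level = "info") {
  stopifnot(alpha > 0, alpha < 1,
            rules %in% names(rule_catalogue()),
            enumeration_limit >= 1,
            log_level %in% c("quiet", "info", "debug"))
  structure(list(alpha = alpha, reference_scope = reference_scope,
                 rules = rules, enumeration_limit = enumeration_limit,
                 seed = as.integer(seed), out_dir = out_dir,
                 log_level = log_level),
            class = "run_config")
}
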