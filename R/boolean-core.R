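#' Catalogue of monotone Boolean update rules
#'
#' Each rule maps the regulator summary of a gene to its next Boolean value.
#' All rules are monotone: non-decreasing in activator activity and
#' non-increasing in inhibitor activity, and each defines its behaviour
#' explicitly when a gene has no incoming activators or inhibitors.
#'
#' Available rules:
#' \describe{
#'   \item{`default`}{ON next iff at least one activator is ON and no
#'     inhibitor is ON. A gene with no incoming activators holds its current
#'     value unless an inhibitor is ON (then OFF).}
#'   \item{`require_all`}{as `default`, but all activators must be ON.}
#'   \item{`ignite_hold`}{ON next iff (an activator is ON or the gene is
#'     already ON) and no inhibitor is ON; once ignited the gene stays ON
#'     until inhibited.}
#'   \item{`strict`}{ON next iff at least one activator is ON and no
#'     inhibitor is ON; a gene with no activators always switches OFF.}
#' }
#'
#' Every rule is a function of `(any_act, all_act, any_inh, current,
#' has_act)` returning 0 or 1; `all_act` is defined as TRUE only when the
#' gene has at least one activator and all of them are ON.
#'
#' @return Named list of rule functions.
#' @export
rule_catalogue <- function() {
  list(
    default = function(any_act, all_act, any_inh, current, has_act) {
      if (has_act) as.integer(any_act && !any_inh)
      else as.integer(current == 1L && !any_inh)
    },
    require_all = function(any_act, all_act, any_inh, current, has_act) {
      if (has_act) as.integer(all_act && !any_inh)
      else as.integer(current == 1L && !any_inh)
    },
    ignite_hold = function(any_act, all_act, any_inh, current, has_act) {
      as.integer((any_act || current == 1L) && !any_inh)
    },
    strict = function(any_act, all_act, any_inh, current, has_act) {
      as.integer(any_act && !any_inh)
    }
  )
}

.normalise_sign <- function(sign) {
  if (is.character(sign)) {
    out <- ifelse(sign %in% c("activates", "activating", "+", "1"), 1L,
                  ifelse(sign %in% c("inhibits", "inhibiting", "-", "-1"), -1L,
                         NA_integer_))
  } else {
    out <- as.integer(sign)
    out[!out %in% c(-1L, 1L)] <- NA_integer_
  }
  if (anyNA(out)) stop("unknown sign token; use +1/-1 or activates/inhibits")
  out
}

.normalise_interactions <- function(interactions, genes) {
  if (is.null(interactions) || NROW(interactions) == 0) {
    return(data.frame(source = character(0), target = character(0),
                      sign = integer(0), stringsAsFactors = FALSE))
  }
  df <- as.data.frame(interactions, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "sign") %in% names(df)))
  df <- df[, c("source", "target", "sign")]
  df$source <- as.character(df$source)
  df$target <- as.character(df$target)
  df$sign <- .normalise_sign(df$sign)
  bad <- !(df$source %in% genes) | !(df$target %in% genes)
  if (any(bad)) {
    stop("interaction endpoint not in gene list: ",
         paste(unique(c(df$source[bad], df$target[bad])), collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Construct a concrete Boolean network
#'
#' A concrete network fixes a gene list, a set of signed directed
#' interactions and one update rule per gene.  States are updated
#' synchronously: every gene computes its next value from the same input
#' state.
#'
#' @param genes Character vector of gene names.
#' @param interactions Data frame with columns `source`, `target`, `sign`
#'   (+1/-1 or "activates"/"inhibits").  A `(source, target)` pair may carry
#'   at most one sign; self-interactions are allowed.
#' @param rules Update rule(s) from [rule_catalogue()]: a single rule name
#'   applied to all genes, or a named character vector with one rule per gene.
#' @return An object of class `boolean_network`.
#' @examples
#' net <- boolean_network(c("A", "B"),
#'                        data.frame(source = "A", target = "B", sign = 1))
#' update_state(net, c(A = 1, B = 0))
#' @export
boolean_network <- function(genes, interactions = NULL, rules = "default") {
  stopifnot(is.character(genes), length(genes) >= 1, !anyDuplicated(genes))
  ints <- .normalise_interactions(interactions, genes)
  if (anyDuplicated(ints[, c("source", "target")])) {
    stop("a (source, target) pair may carry at most one sign in a concrete network")
  }
  cat_rules <- rule_catalogue()
  if (length(rules) == 1 && is.null(names(rules))) {
    rules <- stats::setNames(rep(rules, length(genes)), genes)
  }
  if (!all(genes %in% names(rules))) stop("need one update rule per gene")
  rules <- rules[genes]
  if (!all(rules %in% names(cat_rules))) {
    stop("unknown rule id: ", paste(setdiff(rules, names(cat_rules)), collapse = ", "))
  }
  n <- length(genes)
  A <- matrix(0L, n, n, dimnames = list(genes, genes))
  I <- matrix(0L, n, n, dimnames = list(genes, genes))
  act <- ints[ints$sign == 1L, , drop = FALSE]
  inh <- ints[ints$sign == -1L, , drop = FALSE]
  A[cbind(act$source, act$target)] <- 1L
  I[cbind(inh$source, inh$target)] <- 1L
  structure(
    list(genes = genes, interactions = ints, rules = rules,
         act = A, inh = I, n_act = colSums(A)),
    class = "boolean_network"
  )
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Concrete Boolean network:", length(x$genes), "genes,",
      nrow(x$interactions), "interactions\n")
  if (nrow(x$interactions)) {
    lab <- ifelse(x$interactions$sign == 1L, "->", "-|")
    cat(paste0("  ", x$interactions$source, " ", lab, " ",
               x$interactions$target, collapse = "\n"), "\n")
  }
  invisible(x)
}

.check_state <- function(state, genes) {
  if (is.logical(state)) state <- as.integer(state)
  if (is.null(names(state))) {
    if (length(state) != length(genes)) stop("state missing a gene")
    names(state) <- genes
  }
  if (!all(genes %in% names(state))) {
    stop("state missing a gene: ", paste(setdiff(genes, names(state)), collapse = ", "))
  }
  state <- as.integer(state[genes])
  if (!all(state %in% c(0L, 1L))) stop("state values must be 0/1")
  stats::setNames(state, genes)
}

#' Synchronous one-step state update
#'
#' Computes the next Boolean state of every gene from the same input state.
#'
#' @param network A [boolean_network()].
#' @param state Named 0/1 vector covering all genes of the network.
#' @return Named integer vector: the next state.
#' @export
update_state <- function(network, state) {
  stopifnot(inherits(network, "boolean_network"))
  s <- .check_state(state, network$genes)
  n_on_act <- as.vector(s %*% network$act)
  n_on_inh <- as.vector(s %*% network$inh)
  any_act <- n_on_act > 0L
  all_act <- network$n_act > 0L & n_on_act == network$n_act
  any_inh <- n_on_inh > 0L
  has_act <- network$n_act > 0L
  cat_rules <- rule_catalogue()
  nxt <- integer(length(s))
  for (j in seq_along(s)) {
    nxt[j] <- cat_rules[[network$rules[[j]]]](any_act[j], all_act[j],
                                              any_inh[j], s[j], has_act[j])
  }
  stats::setNames(nxt, network$genes)
}

.normalise_schedule <- function(schedule, horizon) {
  if (inherits(schedule, "boolean_network")) {
    return(rep(list(schedule), horizon))
  }
  if (is.list(schedule) && length(schedule) &&
      all(vapply(schedule, inherits, TRUE, "boolean_network"))) {
    if (length(schedule) != horizon) {
      stop("per-step schedule must list one network per step 1..horizon")
    }
    return(schedule)
  }
  # spans: list of list(network =, steps =)
  if (is.list(schedule)) {
    out <- vector("list", horizon)
    for (sp in schedule) {
      if (!inherits(sp$network, "boolean_network")) stop("invalid schedule span")
      steps <- as.integer(sp$steps)
      if (any(steps < 1L | steps > horizon)) stop("schedule step outside 1..horizon")
      if (any(!vapply(out[steps], is.null, TRUE))) stop("overlapping schedule spans")
      out[steps] <- rep(list(sp$network), length(steps))
    }
    if (any(vapply(out, is.null, TRUE))) stop("schedule has gaps: steps 1..horizon must be covered")
    return(out)
  }
  stop("schedule must be a network, a list of networks, or a list of spans")
}

#' Simulate a synchronous Boolean trajectory
#'
#' Runs the deterministic synchronous dynamics for `horizon` steps.  The
#' network in force may change along the trajectory: the state at step `k`
#' is computed by the network active at step `k` from the state at step
#' `k - 1`.
#'
#' @param schedule A single [boolean_network()] (used at every step), a list
#'   of networks of length `horizon` (one per step), or a list of spans
#'   `list(network =, steps =)` covering steps `1..horizon` contiguously.
#' @param initial Named 0/1 vector: the state at step 0 (total, no missing
#'   genes).
#' @param horizon Number of update steps (>= 0).
#' @return List of `horizon + 1` named states, from step 0 to step `horizon`.
#' @export
simulate_trajectory <- function(schedule, initial, horizon) {
  horizon <- as.integer(horizon)
  stopifnot(horizon >= 0L)
  if (horizon == 0L) {
    net1 <- if (inherits(schedule, "boolean_network")) schedule else schedule[[1]]$network
    return(list(.check_state(initial, net1$genes)))
  }
  nets <- .normalise_schedule(schedule, horizon)
  s <- .check_state(initial, nets[[1]]$genes)
  traj <- vector("list", horizon + 1L)
  traj[[1]] <- s
  for (k in seq_len(horizon)) {
    s <- update_state(nets[[k]], s)
    traj[[k + 1L]] <- s
  }
  traj
}
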