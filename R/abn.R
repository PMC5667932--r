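# Abstract Boolean Networks: counting, enumeration, satisfiability and
# required/disallowed interaction classification.  The solver is a complete
# explicit search: concrete networks (bounded by `limit`) x initial-state
# completions x deterministic synchronous simulation.

#' Construct an Abstract Boolean Network (ABN)
#'
#' An ABN combines definite interactions (present in every concrete network)
#' with possible interactions (present or absent), implicitly defining a
#' family of concrete Boolean networks.  A `(source, target)` pair listed as
#' possible with both signs is treated as an exclusive choice: absent,
#' activating, or inhibiting (a pair cannot be both at once).
#'
#' @param genes Character vector of gene names.
#' @param definite,possible Data frames with columns `source`, `target`,
#'   `sign`; `definite` and `possible` must be disjoint.
#' @param rules Update rule name(s), as in [boolean_network()], shared by all
#'   concrete networks.
#' @param rule_choices Optional named list mapping a gene to a character
#'   vector of candidate rule ids; each combination defines further concrete
#'   networks.
#' @return An object of class `abn`.
#' @export
abn <- function(genes, definite = NULL, possible = NULL, rules = "default",
                rule_choices = NULL) {
  stopifnot(is.character(genes), length(genes) >= 1, !anyDuplicated(genes))
  def <- .normalise_interactions(definite, genes)
  pos <- .normalise_interactions(possible, genes)
  if (anyDuplicated(def[, c("source", "target")])) {
    stop("definite interactions carry contradictory signs for one pair")
  }
  if (anyDuplicated(def) || anyDuplicated(pos)) stop("duplicate interaction listed")
  both <- merge(def, pos, by = c("source", "target", "sign"))
  if (nrow(both)) stop("definite and possible interaction sets must be disjoint")
  clash <- merge(def[, c("source", "target")], pos[, c("source", "target")])
  if (nrow(clash)) {
    stop("a pair cannot be definite with one sign and possible with another")
  }
  if (!is.null(rule_choices)) {
    stopifnot(is.list(rule_choices), all(names(rule_choices) %in% genes),
              all(unlist(rule_choices) %in% names(rule_catalogue())))
  }
  if (length(rules) == 1 && is.null(names(rules))) {
    rules <- stats::setNames(rep(rules, length(genes)), genes)
  }
  structure(list(genes = genes, definite = def, possible = pos,
                 rules = rules[genes], rule_choices = rule_choices),
            class = "abn")
}

#' @export
print.abn <- function(x, ...) {
  cat("Abstract Boolean network:", length(x$genes), "genes;",
      nrow(x$definite), "definite,", nrow(x$possible), "possible interactions\n")
  cat("  concrete networks:", format(count_concrete_networks(x), big.mark = ","), "\n")
  invisible(x)
}

# Independent choice groups of an ABN, in deterministic lexicographic order
# (source, then target).  Each group lists its options as data frames of
# interactions to add (the empty option first, then activating, then
# inhibiting).  Rule choices follow, one group per gene with >1 candidate.
.abn_choices <- function(x) {
  groups <- list()
  if (nrow(x$possible)) {
    key <- paste(x$possible$source, x$possible$target, sep = "\r")
    ord <- order(x$possible$source, x$possible$target, -x$possible$sign)
    pos <- x$possible[ord, , drop = FALSE]
    key <- key[ord]
    for (k in unique(key)) {
      rows <- pos[key == k, , drop = FALSE]
      opts <- list(rows[0, , drop = FALSE])            # absent
      for (i in seq_len(nrow(rows))) opts[[length(opts) + 1L]] <- rows[i, , drop = FALSE]
      groups[[length(groups) + 1L]] <- list(type = "edge", options = opts)
    }
  }
  if (!is.null(x$rule_choices)) {
    for (g in sort(names(x$rule_choices))) {
      ch <- x$rule_choices[[g]]
      if (length(ch) > 1L) {
        groups[[length(groups) + 1L]] <- list(type = "rule", gene = g, options = ch)
      }
    }
  }
  groups
}

#' Count the concrete networks of an ABN
#'
#' Exact closed-form count: each exclusive activating/inhibiting pair
#' contributes a factor 3 (absent, activating, inhibiting), each independent
#' optional interaction a factor 2, and per-gene rule choice sets multiply.
#' No enumeration is performed.
#'
#' @param x An [abn()].
#' @return The exact count as a double (exact for counts below 2^53).
#' @examples
#' # all 36 ordered pairs of 6 genes, each an exclusive +/- possibility
#' pairs <- expand.grid(source = letters[1:6], target = letters[1:6])
#' pos <- rbind(cbind(pairs, sign = 1), cbind(pairs, sign = -1))
#' count_concrete_networks(abn(letters[1:6], possible = pos))  # 3^36 ~ 1.5e17
#' @export
count_concrete_networks <- function(x) {
  stopifnot(inherits(x, "abn"))
  groups <- .abn_choices(x)
  if (!length(groups)) return(1)
  prod(vapply(groups, function(g) length(g$options), 1))
}

# Odometer iteration over choice groups; calls fn(network) until it returns
# non-NULL, which is then propagated.  Deterministic order.  Networks passed
# to fn are lightweight (adjacency matrices plus a `pool_rows` field); use
# .materialise_network() to turn one into a full boolean_network.
.abn_iterate <- function(x, fn, limit) {
  groups <- .abn_choices(x)
  total <- count_concrete_networks(x)
  if (total > limit) {
    stop("ABN defines ", format(total, big.mark = ","),
         " concrete networks, above the enumeration limit (", limit,
         "); refusing to enumerate")
  }
  genes <- x$genes
  n <- length(genes)
  # pooled candidate rows: definite first, then each group option's rows
  pool <- x$definite
  opt_rows <- list()  # per group, per option: row indices into pool
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    if (g$type == "edge") {
      rows <- lapply(g$options, function(opt) {
        if (!nrow(opt)) return(integer(0))
        idx0 <- nrow(pool) + seq_len(nrow(opt))
        pool <<- rbind(pool, opt)
        idx0
      })
      opt_rows[[gi]] <- rows
    } else {
      opt_rows[[gi]] <- g$options
    }
  }
  src <- match(pool$source, genes)
  tgt <- match(pool$target, genes)
  sgn <- pool$sign
  def_idx <- seq_len(nrow(x$definite))
  zero <- matrix(0L, n, n, dimnames = list(genes, genes))
  radix <- vapply(groups, function(g) length(g$options), 1L)
  idx <- rep(1L, length(groups))
  examined <- 0L
  repeat {
    sel <- def_idx
    rules <- x$rules
    for (gi in seq_along(groups)) {
      if (groups[[gi]]$type == "edge") {
        sel <- c(sel, opt_rows[[gi]][[idx[gi]]])
      } else {
        rules[[groups[[gi]]$gene]] <- opt_rows[[gi]][[idx[gi]]]
      }
    }
    A <- zero; I <- zero
    a <- sel[sgn[sel] == 1L]; i2 <- sel[sgn[sel] == -1L]
    if (length(a)) A[cbind(src[a], tgt[a])] <- 1L
    if (length(i2)) I[cbind(src[i2], tgt[i2])] <- 1L
    net <- structure(list(genes = genes, rules = rules, act = A, inh = I,
                          n_act = colSums(A), pool_rows = sel, pool = pool),
                     class = "boolean_network")
    examined <- examined + 1L
    res <- fn(net)
    if (!is.null(res)) return(list(result = res, examined = examined))
    # advance odometer (last group fastest)
    if (!length(idx)) break
    j <- length(idx)
    while (j >= 1L && idx[j] == radix[j]) { idx[j] <- 1L; j <- j - 1L }
    if (j < 1L) break
    idx[j] <- idx[j] + 1L
  }
  list(result = NULL, examined = examined)
}

# turn a lightweight iterator network into a fully validated one
.materialise_network <- function(net) {
  if (!is.null(net$interactions)) return(net)
  boolean_network(net$genes,
                  net$pool[net$pool_rows, , drop = FALSE],
                  net$rules)
}

#' Enumerate all concrete networks of an ABN
#'
#' Yields each concrete network exactly once, in a deterministic order
#' (lexicographic over possible-interaction pairs, the empty option first,
#' then activating, then inhibiting).  Refuses to enumerate families larger
#' than `limit` so that astronomically large ABNs are never expanded by
#' accident.
#'
#' @param x An [abn()].
#' @param limit Maximum family size that will be materialised.
#' @return List of [boolean_network()] objects.
#' @export
enumerate_concrete_networks <- function(x, limit = 2^20) {
  stopifnot(inherits(x, "abn"))
  total <- count_concrete_networks(x)
  if (total > limit) {
    stop("ABN defines ", format(total, big.mark = ","),
         " concrete networks, above the enumeration limit (", limit,
         "); refusing to enumerate")
  }
  out <- vector("list", total)
  i <- 0L
  .abn_iterate(x, function(net) {
    i <<- i + 1L
    out[[i]] <<- .materialise_network(net)
    NULL
  }, limit)
  out
}

# fast synchronous step for all-default-rule networks (vectorised)
.fast_step <- function(net, s) {
  av <- as.vector(s %*% net$act) > 0L
  iv <- as.vector(s %*% net$inh) > 0L
  has <- net$n_act > 0L
  as.integer(ifelse(has, av & !iv, s == 1L & !iv))
}

.all_default <- function(net) all(net$rules == "default")

# simulate and test a (network schedule, initial) pair against partial
# observations; nets is a list of length horizon (network per step).
# obs: list mapping step (character) -> named partial 0/1 vector.
.run_and_check <- function(nets, initial, horizon, obs, genes) {
  s <- initial
  obs_steps <- as.integer(names(obs))
  if (0L %in% obs_steps) {
    o <- obs[["0"]]
    if (any(s[names(o)] != o)) return(NULL)
  }
  traj <- vector("list", horizon + 1L)
  traj[[1]] <- stats::setNames(s, genes)
  fast <- all(vapply(nets, .all_default, TRUE))
  for (k in seq_len(horizon)) {
    s <- if (fast) .fast_step(nets[[k]], s)
         else unname(update_state(nets[[k]], stats::setNames(s, genes)))
    kk <- as.character(k)
    if (!is.null(obs[[kk]])) {
      o <- obs[[kk]]
      if (any(s[match(names(o), genes)] != o)) return(NULL)
    }
    traj[[k + 1L]] <- stats::setNames(s, genes)
  }
  traj
}

# enumerate initial-state completions consistent with the observation at
# step 0; returns a matrix with one row per candidate initial state.
.initial_candidates <- function(genes, obs) {
  base <- stats::setNames(rep(NA_integer_, length(genes)), genes)
  if (!is.null(obs[["0"]])) base[names(obs[["0"]])] <- as.integer(obs[["0"]])
  free <- which(is.na(base))
  if (!length(free)) return(matrix(base, nrow = 1, dimnames = list(NULL, genes)))
  grid <- as.matrix(expand.grid(rep(list(0:1), length(free)), KEEP.OUT.ATTRS = FALSE))
  out <- matrix(rep(base, each = nrow(grid)), nrow = nrow(grid),
                dimnames = list(NULL, genes))
  out[, free] <- grid
  storage.mode(out) <- "integer"
  out
}

#' Test whether a single (non-switching) network can satisfy a constraint
#'
#' Complete decision procedure over one ABN: every concrete network of the
#' family and every completion of the partial initial observation is tried;
#' each candidate is a deterministic synchronous simulation over the
#' constraint horizon.  Returns SAT with a replayable witness, or UNSAT
#' meaning that no concrete network of the ABN admits a satisfying
#' trajectory.
#'
#' @param x An [abn()].
#' @param constraint An [experiment_constraint()].
#' @param limit Enumeration bound on the number of concrete networks.
#' @return An object of class `sat_result` with fields `status`
#'   ("SAT"/"UNSAT"), `witness` (network, initial state, trajectory,
#'   schedule) and `stats`.
#' @export
check_consistency <- function(x, constraint, limit = 2^20) {
  stopifnot(inherits(x, "abn"), inherits(constraint, "experiment_constraint"))
  if (!all(constraint_genes(constraint) %in% x$genes)) {
    stop("constraint mentions genes outside the ABN gene list")
  }
  horizon <- constraint$horizon
  if (length(constraint$observations)) {
    if (max(as.integer(names(constraint$observations))) > horizon) {
      stop("horizon is smaller than the largest observation step")
    }
  }
  req <- constraint$network_requirements
  if (!is.null(req) && length(req) && any(unlist(req) != 0L)) {
    stop("single-ABN check cannot honour a network requirement with index > 0")
  }
  if (isTRUE(constraint$mandatory_switch)) {
    res <- sat_result("UNSAT", stats = list(networks_examined = 0L,
                                            reason = "mandatory switch, single network"))
    return(res)
  }
  inits <- .initial_candidates(x$genes, constraint$observations)
  it <- .abn_iterate(x, function(net) {
    nets <- rep(list(net), max(horizon, 1L))
    for (r in seq_len(nrow(inits))) {
      traj <- .run_and_check(nets, inits[r, ], horizon,
                             constraint$observations, x$genes)
      if (!is.null(traj)) {
        return(list(network = .materialise_network(net),
                    initial = traj[[1]], trajectory = traj))
      }
    }
    NULL
  }, limit)
  if (is.null(it$result)) {
    sat_result("UNSAT", stats = list(networks_examined = it$examined))
  } else {
    w <- it$result
    w$schedule <- rep(0L, horizon)
    sat_result("SAT", witness = w, stats = list(networks_examined = it$examined))
  }
}

#' @rdname check_consistency
#' @param status "SAT" or "UNSAT".
#' @param witness Witness list for SAT results.
#' @param stats Search statistics.
#' @export
sat_result <- function(status, witness = NULL, stats = list()) {
  stopifnot(status %in% c("SAT", "UNSAT"))
  structure(list(status = status, witness = witness, stats = stats),
            class = "sat_result")
}

#' @export
print.sat_result <- function(x, ...) {
  cat("Constraint check:", x$status, "\n")
  if (!is.null(x$stats$networks_examined)) {
    cat("  concrete networks examined:", x$stats$networks_examined, "\n")
  }
  if (x$status == "SAT" && !is.null(x$witness$network)) {
    cat("  witness network:", nrow(x$witness$network$interactions),
        "interactions; trajectory length",
        length(x$witness$trajectory) - 1L, "steps\n")
  }
  invisible(x)
}

#' Classify possible interactions as required, disallowed or optional
#'
#' A possible interaction is *required* when forcing it absent makes the
#' constraint unsatisfiable (it is present in every consistent solution),
#' *disallowed* when forcing it present does, and *optional* otherwise.
#' Defined only for satisfiable instances.
#'
#' @inheritParams check_consistency
#' @return Data frame with columns `source`, `target`, `sign`,
#'   `classification`.
#' @export
classify_interactions <- function(x, constraint, limit = 2^20) {
  base <- check_consistency(x, constraint, limit)
  if (base$status != "SAT") {
    stop("classify_interactions requires a satisfiable instance")
  }
  pos <- x$possible
  cls <- character(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    absent <- abn(x$genes, x$definite, pos[-i, , drop = FALSE],
                  rules = x$rules, rule_choices = x$rule_choices)
    r_abs <- check_consistency(absent, constraint, limit)
    # forcing present: promote to definite; the opposite sign on the same
    # pair (exclusive possibility) is dropped
    same_pair <- pos$source == pos$source[i] & pos$target == pos$target[i]
    forced <- abn(x$genes, rbind(x$definite, pos[i, , drop = FALSE]),
                  pos[!same_pair, , drop = FALSE],
                  rules = x$rules, rule_choices = x$rule_choices)
    r_pres <- check_consistency(forced, constraint, limit)
    cls[i] <- if (r_abs$status == "UNSAT") "required"
              else if (r_pres$status == "UNSAT") "disallowed"
              else "optional"
  }
  cbind(pos, classification = cls)
}
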