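# Independent brute-force oracle for the ABN / switching solvers.
# Deliberately implemented in a different style from the package internals
# (plain edge-list simulation, expand.grid enumeration, no adjacency
# matrices) so that agreement is a genuine cross-check.

oracle_step <- function(edges, state) {
  genes <- names(state)
  nxt <- state
  for (g in genes) {
    acts <- edges$source[edges$target == g & edges$sign == 1]
    inhs <- edges$source[edges$target == g & edges$sign == -1]
    inh_on <- length(inhs) > 0 && any(state[inhs] == 1)
    if (length(acts) == 0) {
      nxt[g] <- if (inh_on) 0L else state[g]
    } else {
      nxt[g] <- as.integer(any(state[acts] == 1) && !inh_on)
    }
  }
  nxt
}

# all concrete edge sets of an ABN: expand.grid over per-pair choices
oracle_concretes <- function(x) {
  def <- x$definite
  pos <- x$possible
  if (!nrow(pos)) return(list(def))
  pair <- paste(pos$source, pos$target)
  upairs <- sort(unique(pair))
  choice_sets <- lapply(upairs, function(p) {
    rows <- which(pair == p)
    c(list(integer(0)), as.list(rows[order(-pos$sign[rows])]))
  })
  grid <- expand.grid(lapply(choice_sets, seq_along))
  lapply(seq_len(nrow(grid)), function(r) {
    sel <- unlist(lapply(seq_along(choice_sets),
                         function(j) choice_sets[[j]][[grid[r, j]]]))
    rbind(def, pos[sel, , drop = FALSE])
  })
}

oracle_inits <- function(genes, obs0) {
  fixed <- names(obs0)
  free <- setdiff(genes, fixed)
  if (length(free) == 0) {
    m <- matrix(obs0[genes], nrow = 1, dimnames = list(NULL, genes))
    return(m)
  }
  grid <- as.matrix(expand.grid(rep(list(0:1), length(free))))
  m <- matrix(0L, nrow(grid), length(genes), dimnames = list(NULL, genes))
  if (length(fixed)) m[, fixed] <- matrix(rep(obs0[fixed], each = nrow(grid)),
                                          nrow = nrow(grid))
  m[, free] <- grid
  m
}

oracle_traj_ok <- function(edge_sets_per_step, init, constraint) {
  s <- init
  obs <- constraint$observations
  if (!is.null(obs[["0"]]) && any(s[names(obs[["0"]])] != obs[["0"]])) return(FALSE)
  for (k in seq_len(constraint$horizon)) {
    s <- oracle_step(edge_sets_per_step[[k]], s)
    o <- obs[[as.character(k)]]
    if (!is.null(o) && any(s[names(o)] != o)) return(FALSE)
  }
  TRUE
}

oracle_check <- function(x, constraint) {
  if (isTRUE(constraint$mandatory_switch)) return("UNSAT")
  req <- constraint$network_requirements
  if (!is.null(req) && any(unlist(req) != 0)) return("UNSAT")
  inits <- oracle_inits(x$genes, constraint$observations[["0"]])
  for (edges in oracle_concretes(x)) {
    steps <- rep(list(edges), max(constraint$horizon, 1))
    for (r in seq_len(nrow(inits))) {
      s0 <- setNames(inits[r, ], x$genes)
      if (oracle_traj_ok(steps, s0, constraint)) return("SAT")
    }
  }
  "UNSAT"
}

# classification by enumerating every satisfying concrete network
oracle_classify <- function(x, constraint) {
  pos <- x$possible
  sat_sets <- list()
  inits <- oracle_inits(x$genes, constraint$observations[["0"]])
  for (edges in oracle_concretes(x)) {
    steps <- rep(list(edges), max(constraint$horizon, 1))
    ok <- FALSE
    for (r in seq_len(nrow(inits))) {
      s0 <- setNames(inits[r, ], x$genes)
      if (oracle_traj_ok(steps, s0, constraint)) { ok <- TRUE; break }
    }
    if (ok) sat_sets[[length(sat_sets) + 1]] <- edges
  }
  stopifnot(length(sat_sets) > 0)
  key <- function(df) paste(df$source, df$target, df$sign)
  vapply(seq_len(nrow(pos)), function(i) {
    k <- key(pos[i, , drop = FALSE])
    present <- vapply(sat_sets, function(e) k %in% key(e), TRUE)
    if (all(present)) "required" else if (!any(present)) "disallowed" else "optional"
  }, "")
}

oracle_monotone_scheds <- function(horizon, k) {
  grid <- expand.grid(rep(list(0:(k - 1)), horizon))
  keep <- apply(grid, 1, function(r) all(diff(r) >= 0))
  as.matrix(grid[keep, , drop = FALSE])
}

oracle_switch <- function(abns, constraint) {
  genes <- abns[[1]]$genes
  scheds <- oracle_monotone_scheds(constraint$horizon, length(abns))
  req <- constraint$network_requirements
  concs <- lapply(abns, oracle_concretes)
  inits <- oracle_inits(genes, constraint$observations[["0"]])
  for (r in seq_len(nrow(scheds))) {
    sc <- as.integer(scheds[r, ])
    if (isTRUE(constraint$mandatory_switch) && all(sc == 0)) next
    if (!is.null(req)) {
      bad <- FALSE
      for (k in names(req)) {
        step <- as.integer(k)
        have <- if (step == 0) 0L else sc[step]
        if (have != req[[k]]) { bad <- TRUE; break }
      }
      if (bad) next
    }
    vis <- unique(c(0L, sc))
    combos <- expand.grid(lapply(vis, function(v) seq_along(concs[[v + 1]])))
    for (cr in seq_len(nrow(combos))) {
      chosen <- lapply(seq_along(vis), function(i) concs[[vis[i] + 1]][[combos[cr, i]]])
      names(chosen) <- as.character(vis)
      steps <- lapply(as.character(sc), function(v) chosen[[v]])
      for (q in seq_len(nrow(inits))) {
        s0 <- setNames(inits[q, ], genes)
        if (oracle_traj_ok(steps, s0, constraint)) return("SAT")
      }
    }
  }
  "UNSAT"
}

# --- random instance generators (fixed seeds supplied by callers) ---

random_abn <- function(n_genes = sample(2:3, 1), max_possible = 6) {
  genes <- LETTERS[seq_len(n_genes)]
  pairs <- expand.grid(source = genes, target = genes,
                       stringsAsFactors = FALSE)
  mk <- function(k) {
    if (k == 0) return(NULL)
    idx <- sample(nrow(pairs), k, replace = TRUE)
    sgn <- sample(c(-1L, 1L), k, replace = TRUE)
    unique(data.frame(source = pairs$source[idx], target = pairs$target[idx],
                      sign = sgn, stringsAsFactors = FALSE))
  }
  def <- mk(sample(0:2, 1))
  if (!is.null(def)) {
    def <- def[!duplicated(paste(def$source, def$target)), , drop = FALSE]
  }
  pos <- mk(sample(1:max_possible, 1))
  if (!is.null(def) && !is.null(pos)) {
    # keep sets disjoint and avoid definite/possible sign clashes per pair
    clash <- paste(pos$source, pos$target) %in% paste(def$source, def$target)
    pos <- pos[!clash, , drop = FALSE]
  }
  if (is.null(pos) || nrow(pos) == 0) {
    pos <- data.frame(source = genes[1], target = genes[n_genes], sign = 1L)
    if (!is.null(def)) {
      def <- def[paste(def$source, def$target) != paste(genes[1], genes[n_genes]), ,
                 drop = FALSE]
    }
  }
  abn(genes, definite = def, possible = pos)
}

make_switch_problem <- function(n_abns = 2) {
  x1 <- random_abn()
  abns <- c(list(x1),
            lapply(seq_len(n_abns - 1), function(i) random_abn(length(x1$genes))))
  cons <- random_constraint(x1$genes, horizon = sample(2:5, 1))
  switching_problem(abns, cons)
}

random_constraint <- function(genes, horizon = sample(2:6, 1), n_obs = sample(1:3, 1)) {
  steps <- sort(sample(0:horizon, n_obs))
  obs <- lapply(steps, function(s) {
    gs <- sample(genes, sample(seq_along(genes), 1))
    setNames(sample(0:1, length(gs), replace = TRUE), gs)
  })
  names(obs) <- as.character(steps)
  experiment_constraint("random", horizon = horizon, observations = obs)
}
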