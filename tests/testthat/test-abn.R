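test_that("closed-form counting matches exhaustive enumeration", {
  # no possible interactions: exactly the definite network
  x0 <- abn(c("A", "B"),
            definite = data.frame(source = "A", target = "B", sign = 1))
  expect_equal(count_concrete_networks(x0), 1)
  nets <- enumerate_concrete_networks(x0)
  expect_length(nets, 1)
  expect_equal(nets[[1]]$interactions$source, "A")

  # 2 genes, every ordered pair (incl. self) an exclusive +/- choice: 3^4
  pairs <- expand.grid(source = c("A", "B"), target = c("A", "B"),
                       stringsAsFactors = FALSE)
  pos <- rbind(cbind(pairs, sign = 1L), cbind(pairs, sign = -1L))
  x <- abn(c("A", "B"), possible = pos)
  expect_equal(count_concrete_networks(x), 81)
  nets <- enumerate_concrete_networks(x)
  expect_length(nets, 81)
  keys <- vapply(nets, function(n) {
    paste(sort(paste(n$interactions$source, n$interactions$target,
                     n$interactions$sign)), collapse = ";")
  }, "")
  expect_equal(anyDuplicated(keys), 0L)

  # counting-enumeration consistency on random ABNs
  set.seed(101)
  for (i in 1:20) {
    r <- random_abn()
    expect_length(enumerate_concrete_networks(r), count_concrete_networks(r))
  }
})

test_that("the enumeration limit refuses astronomically large families", {
  genes <- letters[1:6]
  pairs <- expand.grid(source = genes, target = genes, stringsAsFactors = FALSE)
  pos <- rbind(cbind(pairs, sign = 1L), cbind(pairs, sign = -1L))
  x <- abn(genes, possible = pos)
  expect_error(enumerate_concrete_networks(x), "limit")
})

test_that("consistency checking decides simple reachability correctly", {
  # a gene with no possible incoming activators cannot turn ON
  x <- abn(c("A", "B"),
           possible = data.frame(source = "B", target = "A", sign = -1))
  cons <- experiment_constraint("up", horizon = 4,
                                observations = list("0" = c(A = 0), "3" = c(A = 1)))
  expect_equal(check_consistency(x, cons)$status, "UNSAT")

  # a definite self-loop holds an ON gene forever
  y <- abn("A", definite = data.frame(source = "A", target = "A", sign = 1))
  cons2 <- experiment_constraint("hold", horizon = 5,
                                 observations = list("0" = c(A = 1), "5" = c(A = 1)))
  r <- check_consistency(y, cons2)
  expect_equal(r$status, "SAT")
  expect_true(verify_witness(r, cons2))
})

test_that("solver status matches the brute-force oracle on random instances", {
  set.seed(7)
  n_sat <- 0L
  for (i in 1:60) {
    x <- random_abn()
    cons <- random_constraint(x$genes)
    r <- check_consistency(x, cons)
    expect_equal(r$status, oracle_check(x, cons), label = paste("instance", i))
    if (r$status == "SAT") {
      n_sat <- n_sat + 1L
      expect_true(verify_witness(r, cons))
    }
  }
  expect_gt(n_sat, 5)  # the generator must exercise both outcomes
})

test_that("interaction classification matches the enumerate-all oracle", {
  set.seed(21)
  done <- 0L
  while (done < 25L) {
    x <- random_abn()
    cons <- random_constraint(x$genes)
    if (check_consistency(x, cons)$status != "SAT") next
    done <- done + 1L
    cl <- classify_interactions(x, cons)
    expect_equal(cl$classification, oracle_classify(x, cons))
    # definitional soundness: forcing a required interaction absent is UNSAT
    for (i in which(cl$classification == "required")) {
      x_abs <- abn(x$genes, x$definite, x$possible[-i, , drop = FALSE])
      expect_equal(check_consistency(x_abs, cons)$status, "UNSAT")
    }
  }
  expect_error(classify_interactions(
    abn(c("A", "B"), possible = data.frame(source = "A", target = "B", sign = 1)),
    experiment_constraint("bad", horizon = 2,
                          observations = list("0" = c(A = 0, B = 0),
                                              "2" = c(A = 1)))),
    "satisfiable")
})

test_that("adding observations never turns UNSAT into SAT", {
  set.seed(33)
  n_unsat <- 0L
  for (i in 1:60) {
    if (n_unsat >= 10L) break
    x <- random_abn()
    cons <- random_constraint(x$genes, horizon = 5, n_obs = 2)
    base <- check_consistency(x, cons)$status
    if (base != "UNSAT") next
    n_unsat <- n_unsat + 1L
    extra <- cons$observations
    g <- sample(x$genes, 1)
    prev <- extra[["5"]]
    if (!is.null(prev) && g %in% names(prev)) next
    extra[["5"]] <- c(prev, setNames(sample(0:1, 1), g))
    more <- experiment_constraint("more", horizon = 5, observations = extra)
    expect_equal(check_consistency(x, more)$status, "UNSAT")
  }
  expect_gt(n_unsat, 0)
})

test_that("promoting required and deleting disallowed preserves satisfiability", {
  set.seed(55)
  done <- 0L
  while (done < 10L) {
    x <- random_abn()
    cons <- random_constraint(x$genes)
    if (check_consistency(x, cons)$status != "SAT") next
    done <- done + 1L
    cl <- classify_interactions(x, cons)
    keep <- cl$classification == "optional"
    promoted <- abn(x$genes,
                    definite = rbind(x$definite,
                                     x$possible[cl$classification == "required", ,
                                                drop = FALSE]),
                    possible = x$possible[keep, , drop = FALSE])
    expect_equal(check_consistency(promoted, cons)$status, "SAT")
  }
})
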