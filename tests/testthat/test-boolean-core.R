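test_that("default rule: activation, inhibitor dominance, hold and fixed points", {
  net <- boolean_network(c("A", "B", "C"),
                         data.frame(source = c("A", "C"), target = c("B", "B"),
                                    sign = c(1, -1)))
  # activator ON ignites the target
  expect_equal(update_state(net, c(A = 1, B = 0, C = 0))[["B"]], 1L)
  # inhibitor dominates an active activator
  expect_equal(update_state(net, c(A = 1, B = 0, C = 1))[["B"]], 0L)
  # no activators: hold current value unless inhibited
  expect_equal(update_state(net, c(A = 1, B = 0, C = 0))[["A"]], 1L)
  expect_equal(update_state(net, c(A = 0, B = 0, C = 0))[["A"]], 0L)

  self <- boolean_network("A", data.frame(source = "A", target = "A", sign = 1))
  traj <- simulate_trajectory(self, c(A = 1), 5)
  expect_true(all(vapply(traj, function(s) s[["A"]], 1L) == 1L))
})

test_that("every catalogue rule is monotone and defined on empty regulator sets", {
  rules <- rule_catalogue()
  # activator activity levels ordered none < some < all
  act_levels <- list(c(FALSE, FALSE), c(TRUE, FALSE), c(TRUE, TRUE))
  for (rn in names(rules)) {
    f <- rules[[rn]]
    for (cur in 0:1) {
      for (has_act in c(TRUE, FALSE)) {
        lv <- if (has_act) act_levels else act_levels[1]
        for (inh in c(FALSE, TRUE)) {
          vals <- vapply(lv, function(a) f(a[1], a[2], inh, cur, has_act), 0L)
          expect_true(all(diff(vals) >= 0),
                      label = paste(rn, "monotone in activators"))
        }
        for (a in lv) {
          v_noinh <- f(a[1], a[2], FALSE, cur, has_act)
          v_inh <- f(a[1], a[2], TRUE, cur, has_act)
          expect_true(v_inh <= v_noinh,
                      label = paste(rn, "non-increasing in inhibitors"))
        }
      }
    }
  }
})

test_that("synchronous update is independent of gene declaration order", {
  ints <- data.frame(source = c("A", "B", "C"), target = c("B", "C", "A"),
                     sign = c(1, -1, 1))
  n1 <- boolean_network(c("A", "B", "C"), ints)
  n2 <- boolean_network(c("C", "A", "B"), ints)
  s <- c(A = 1, B = 1, C = 0)
  u1 <- update_state(n1, s)
  u2 <- update_state(n2, s)
  expect_equal(u1[names(u2)], u2)
})

test_that("trajectory semantics: horizon 0, absorbing all-OFF, determinism, spans", {
  net <- boolean_network(c("A", "B"),
                         data.frame(source = "A", target = "B", sign = 1))
  expect_equal(simulate_trajectory(net, c(A = 0, B = 1), 0),
               list(c(A = 0L, B = 1L)))
  # all-OFF is absorbing when no activator-free gene is held ON
  traj <- simulate_trajectory(net, c(A = 0, B = 0), 4)
  expect_true(all(unlist(traj) == 0L))
  t1 <- simulate_trajectory(net, c(A = 1, B = 0), 6)
  t2 <- simulate_trajectory(net, c(A = 1, B = 0), 6)
  expect_identical(t1, t2)
  # span schedules must cover 1..horizon contiguously
  other <- boolean_network(c("A", "B"),
                           data.frame(source = "A", target = "B", sign = -1))
  spans <- list(list(network = net, steps = 1:2),
                list(network = other, steps = 3:4))
  tr <- simulate_trajectory(spans, c(A = 1, B = 0), 4)
  expect_equal(tr[[3]][["B"]], 1L)  # activated during first span
  expect_equal(tr[[5]][["B"]], 0L)  # inhibited during second span
  expect_error(simulate_trajectory(list(list(network = net, steps = 1:2)),
                                   c(A = 1, B = 0), 4),
               "gaps")
  expect_error(simulate_trajectory(list(list(network = net, steps = 1:3),
                                        list(network = other, steps = 3:4)),
                                   c(A = 1, B = 0), 4),
               "overlap")
})

test_that("state validation rejects missing genes and non-binary values", {
  net <- boolean_network(c("A", "B"))
  expect_error(update_state(net, c(A = 1)), "missing")
  expect_error(update_state(net, c(A = 1, B = 2)), "0/1")
  expect_error(boolean_network(c("A"), data.frame(source = "A", target = "Z",
                                                  sign = 1)),
               "not in gene list")
  expect_error(boolean_network(c("A", "B"),
                               data.frame(source = c("A", "A"),
                                          target = c("B", "B"),
                                          sign = c(1, -1))),
               "at most one sign")
})
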