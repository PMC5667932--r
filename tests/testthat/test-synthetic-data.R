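test_that("noise-free knockdown shifts follow the edge contract exactly", {
  tr <- ground_truth(networks = data.frame(source = "DUSP6", target = "PTPN1",
                                           sign = 1, strength = 1))
  tab <- simulate_perturbation_table(tr, sim_params(noise_sd = 0))
  ctrl <- tab[tab$perturbation == "siSCR" & tab$replicate == 1, ]
  kd <- tab[tab$perturbation == "kd:DUSP6" & tab$replicate == 1, ]
  for (t in c(0, 4, 8, 12)) {
    c_t <- ctrl[ctrl$time_hr == t, ]
    k_t <- kd[kd$time_hr == t, ]
    # the target of an activating edge of strength 1 is halved
    expect_equal(k_t$rel_expr[k_t$gene == "PTPN1"],
                 c_t$rel_expr[c_t$gene == "PTPN1"] / 2)
    # the knocked-down gene itself drops to the residual efficiency
    expect_equal(k_t$rel_expr[k_t$gene == "DUSP6"],
                 c_t$rel_expr[c_t$gene == "DUSP6"] * 0.2)
    # genes without an edge from DUSP6 are identical to control
    for (g in c("PPTC7", "PTPN13", "PPP3CA", "DUSP10")) {
      expect_equal(k_t$rel_expr[k_t$gene == g], c_t$rel_expr[c_t$gene == g])
    }
  }
})

test_that("tables are deterministic given the seed, with seed-independent signal", {
  tr <- truth_8edge()
  t1 <- simulate_perturbation_table(tr, sim_params(seed = 11))
  t2 <- simulate_perturbation_table(tr, sim_params(seed = 11))
  t3 <- simulate_perturbation_table(tr, sim_params(seed = 12))
  expect_identical(t1, t2)
  expect_false(isTRUE(all.equal(t1$rel_expr, t3$rel_expr)))
  # the deterministic component is identical across seeds
  d1 <- simulate_perturbation_table(tr, sim_params(noise_sd = 0, seed = 11))
  d2 <- simulate_perturbation_table(tr, sim_params(noise_sd = 0, seed = 99))
  expect_identical(d1, d2)
})

test_that("every (perturbation, time) stratum holds n_replicates rows per gene", {
  tab <- simulate_perturbation_table(truth_8edge(), sim_params(n_replicates = 3))
  counts <- table(tab$gene, tab$perturbation, tab$time_hr)
  expect_true(all(counts == 3))
})

test_that("replicate noise magnitude matches the declared log2 sd", {
  tr <- ground_truth(gene_names = c("g1", "g2", "g3"),
                     networks = data.frame(source = "g1", target = "g2",
                                           sign = 1, strength = 1))
  det <- simulate_perturbation_table(tr, sim_params(noise_sd = 0))
  devs <- unlist(lapply(1:100, function(i) {
    tab <- simulate_perturbation_table(tr, sim_params(noise_sd = 0.2, seed = i))
    log2(tab$rel_expr) - log2(det$rel_expr)
  }))
  expect_gt(sd(devs), 0.1)
  expect_lt(sd(devs), 0.35)
})

test_that("drug profiles equal control plus the specified log2 shift", {
  tr <- truth_empty()
  zero <- setNames(rep(0, 6), tr$gene_names)
  sh <- list(PKCi = zero, TSA = replace(zero, "DUSP6", 1))
  tab <- simulate_drug_profiles(tr, sh, sim_params(noise_sd = 0))
  ctrl <- tab[tab$perturbation == "siSCR", ]
  pk <- tab[tab$perturbation == "drug:PKCi", ]
  ts <- tab[tab$perturbation == "drug:TSA", ]
  expect_equal(pk$rel_expr, ctrl$rel_expr)
  expect_equal(ts$rel_expr[ts$gene == "DUSP6"],
               2 * ctrl$rel_expr[ctrl$gene == "DUSP6"])
  expect_equal(ts$rel_expr[ts$gene != "DUSP6"],
               ctrl$rel_expr[ctrl$gene != "DUSP6"])
  expect_error(simulate_drug_profiles(tr, list(PKCi = zero[-1]),
                                      sim_params(noise_sd = 0)),
               "missing gene")
})

test_that("strongly repressed drug profiles discretise to all-OFF states", {
  tr <- truth_empty()
  # one gene left high so the within-sample average is dominated by it
  sh <- list(PKCi = setNames(c(3, rep(-4, 5)), tr$gene_names))
  tab <- simulate_drug_profiles(tr, sh, sim_params(noise_sd = 0))
  drug <- tab[tab$perturbation == "drug:PKCi", ]
  states <- discretise_states(drug)
  for (st in states) expect_true(all(st[tr$gene_names[-1]] == 0L))
})

test_that("SILAC generator honours its class fractions", {
  all_neg <- simulate_silac_table(500, frac_dephospho = 1, frac_confounded = 0,
                                  seed = 3)
  changed <- abs(all_neg$d_phospho_log2) > 0.2
  expect_true(all(all_neg$d_phospho_log2[changed] < 0))

  tab <- simulate_silac_table(1000, frac_confounded = 0.1, seed = 5)
  n_conf <- sum(tab$truth_class == "confounded")
  expect_lt(abs(n_conf - 100), 3 * sqrt(1000 * 0.1 * 0.9) + 1)
  # confounded sites sit inside the exclusion region by construction
  conf <- tab[tab$truth_class == "confounded", ]
  expect_true(all(abs(conf$d_phospho_log2) <= 0.1))
  expect_true(all(conf$d_total_log2 > 0.5))
  expect_error(simulate_silac_table(100, frac_dephospho = 1.5), "frac")
})
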