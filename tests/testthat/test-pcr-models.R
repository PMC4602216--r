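test_that("degenerate efficiencies give deterministic cycle outcomes", {
  expect_equal(cycle_model1(5, efficiency = 1), 10)
  expect_equal(cycle_model1(5, efficiency = 0), 5)
  amp <- amplify(1, model_config(1, cycles = 3, efficiency = 1))
  expect_equal(amp$copies, 8)
  expect_equal(amp$trajectory, c(1, 2, 4, 8))
  amp0 <- amplify(1, model_config(1, cycles = 10, efficiency = 0))
  expect_equal(amp0$copies, 1)

  # model 2 with certain degradation of non-replicators empties the lineage
  expect_equal(cycle_model2(5, efficiency = 0, degradation = 1), 0)
  # model 6 extremes after c cycles: 2^c vs 1
  cp <- c(1, 1)
  for (i in 1:8) cp <- cycle_model6(cp, c(1, 0))
  expect_equal(cp, c(2^8, 1))
})

test_that("per-cycle growth matches expectation at large copy numbers", {
  set.seed(1)
  expect_equal(cycle_model1(1e6, 0.5) / 1e6, 1.5, tolerance = 0.002)
  # model 2 expectation: 1 + e - (1 - e) d
  expect_equal(cycle_model2(1e6, 0.5, 0.5) / 1e6, 1.25, tolerance = 0.002)
  # model 5 with huge sd is symmetric around 1/2 after restriction to [0,1]
  expect_equal(cycle_model5(1e6, 0.5, 10) / 1e6, 1.5, tolerance = 0.002)
  # per-molecule truncated draws marginalise to the truncated-normal mean
  em <- truncnorm_mean_quad(0.3, 0.3)
  expect_equal(cycle_model5(1e6, 0.3, 0.3) / 1e6, 1 + em, tolerance = 0.003)
})

test_that("resource competition caps growth at the resource capacity", {
  # abundant resource: certain replication, same as model 1 at e = 1
  expect_equal(cycle_model3(c(10, 20), resource = 1e6), c(20, 40))
  # population at twice capacity: replication probability 1/2
  set.seed(2)
  expect_equal(cycle_model3(1e6, resource = 5e5) / 1e6, 1.5,
               tolerance = 0.002)
  # long-run increments approach the capacity once M >> R
  amp <- amplify(1000, model_config(3, cycles = 12, resource = 2), seed = 3)
  incr <- diff(amp$trajectory)
  expect_equal(mean(tail(incr, 4)), 2000, tolerance = 0.1)

  # model 4 with no decay is model 3 draw for draw
  set.seed(7); a <- cycle_model3(rep(50, 100), resource = 2000)
  set.seed(7); b <- cycle_model4(rep(50, 100), resource = 2000,
                                 resource_decay = 0)
  expect_identical(a, b$copies)
  expect_equal(b$resource, 2000)

  # zero resource: no amplification, ever
  amp0 <- amplify(100, model_config(4, cycles = 5, resource = 1e-9,
                                    resource_decay = 1), seed = 1)
  expect_lte(amp0$total, 101)

  # full decay conserves resource: total successes bounded by k * M0
  k <- 3
  amp4 <- amplify(500, model_config(4, cycles = 20, resource = k,
                                    resource_decay = 1), seed = 4)
  expect_lte(amp4$total - 500, k * 500)
})

test_that("exact branching pmf matches simulated copy frequencies", {
  for (e in c(0.25, 0.5)) {
    pmf <- enum_final_pmf(e, cycles = 3)
    amp <- amplify(1e5, model_config(1, cycles = 3, efficiency = e),
                   seed = round(100 * e))
    obs <- tabulate(amp$copies, length(pmf)) / 1e5
    se <- sqrt(pmf * (1 - pmf) / 1e5)
    ok <- pmf > 1e-5
    expect_true(all(abs(obs[ok] - pmf[ok]) <= 3 * se[ok] + 1e-9))
  }
})

test_that("population trajectories respect model-specific monotonicity", {
  cfgs <- list(model_config(1, 10, efficiency = 0.7),
               model_config(3, 10, resource = 3),
               model_config(4, 10, resource = 3, resource_decay = 0.5),
               model_config(5, 10, eff_mean = 0.5, eff_sd = 0.3),
               model_config(6, 10, eff_mean = 0.5, eff_sd = 0.3))
  for (cfg in cfgs) {
    amp <- amplify(200, cfg, seed = 11)
    expect_length(amp$trajectory, 11)
    expect_true(all(diff(amp$trajectory) >= 0))
    expect_equal(amp$trajectory[11], sum(amp$copies))
  }
  # model 2 may shrink but never below zero
  amp2 <- amplify(200, model_config(2, 10, efficiency = 0.1,
                                    degradation = 0.9), seed = 12)
  expect_true(all(amp2$copies >= 0))
  expect_true(all(amp2$trajectory >= 0))
})

test_that("mean final copies grows with efficiency", {
  means_e <- vapply(c(0.2, 0.5, 0.8), function(e)
    mean(amplify(2000, model_config(1, 8, efficiency = e),
                 seed = 21)$copies), numeric(1))
  expect_true(all(diff(means_e) > 0))
  means_mu <- vapply(c(0.2, 0.5, 0.8), function(mu)
    mean(amplify(2000, model_config(6, 8, eff_mean = mu, eff_sd = 0.2),
                 seed = 22)$copies), numeric(1))
  expect_true(all(diff(means_mu) > 0))
})

test_that("closed-form branching expectation is (1+e)^c", {
  expect_equal(expected_final_copies(1, 10), 2^10)
  expect_equal(expected_final_copies(0, 7), 1)
  expect_equal(expected_final_copies(0.8, 15), 1.8^15)
  # 15 cycles at 80% efficiency: several-thousand-fold amplification
  expect_equal(expected_final_copies(0.8, 15), 6746.9, tolerance = 1e-4)
})

test_that("inherited efficiency spreads lineages far beyond constant efficiency", {
  amp6 <- amplify(3000, model_config(6, 25, eff_mean = 0.5, eff_sd = 0.5),
                  seed = 31)
  em <- truncnorm_mean_quad(0.5, 0.5)
  amp1 <- amplify(3000, model_config(1, 25, efficiency = em), seed = 32)
  cv6 <- sd(amp6$copies) / mean(amp6$copies)
  cv1 <- sd(amp1$copies) / mean(amp1$copies)
  # exact ratio of the two CVs at these parameters is ~4.5 (quadrature over
  # the truncated normal); assert it is well clear of parity
  expect_gt(cv6 / cv1, 3)
})

test_that("count and sequence paths agree in distribution", {
  lab <- label_molecules(make_pool(8), 1000, seed = 41)
  for (cfg in list(model_config(1, 6, efficiency = 0.7),
                   model_config(6, 6, eff_mean = 0.5, eff_sd = 0.3))) {
    a_cnt <- amplify(lab, cfg, seed = 42, path = "count")
    a_seq <- amplify(lab, cfg, seed = 43, path = "sequence")
    expect_equal(sum(a_seq$copies), a_seq$total)
    expect_gt(ks_p(a_cnt$copies, a_seq$copies), 0.01)
  }
})

test_that("replication error substitutes bases at the configured rate", {
  expect_equal(mutate_copy("ACGTACGT", 0), "ACGTACGT")
  x <- strrep("A", 100)
  y <- mutate_copy(x, 1, seed = 1)
  expect_true(!any(strsplit(y, "")[[1]] == "A"))   # substitution always changes
  expect_error(mutate_copy("ACGN", 0.1), "A, C, G, T")

  # binomial expectation: 1e4 bases at 1e-2, 100 repeats
  tmpl <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                collapse = "")
  mism <- vapply(1:100, function(i) {
    m <- mutate_copy(rep(tmpl, 100), 1e-2, seed = i)
    sum(utf8ToInt(paste(m, collapse = "")) !=
        utf8ToInt(strrep(tmpl, 100)))
  }, numeric(1))
  se <- sd(mism) / sqrt(100)
  expect_lt(abs(mean(mism) - 100), 3 * se)
})

test_that("invalid configurations and runaway growth fail loudly", {
  expect_error(model_config(7, 10), "1..6")
  expect_error(model_config(3, 10), "resource")
  expect_error(model_config(5, 10, eff_mean = 2, eff_sd = 0), "eff_mean")
  expect_error(amplify(10, model_config(1, 30, efficiency = 1), cap = 1e6),
               "cap")
  expect_error(cycle_model6(c(1, 1), 0.5), "per lineage")
})
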