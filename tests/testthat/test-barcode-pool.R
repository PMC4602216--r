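test_that("barcode space size is 4^L", {
  expect_equal(pool_size(12), 16777216)
  expect_equal(pool_size(1), 4)
  expect_equal(pool_size(6), 4096)
  expect_error(pool_size(0), "positive integer")
})

test_that("pools follow their declared weight distribution", {
  u <- make_pool(6, N = 1000)
  expect_null(u$weights)          # uniform pools need no explicit weights

  nm <- make_pool(10, N = 5000, dist = "normal", mean = 1, sd = 1, seed = 3)
  expect_true(all(nm$weights > 0))          # restricted to values > 0
  expect_equal(sum(nm$weights), 1, tolerance = 1e-9)

  ln1 <- make_pool(10, N = 2000, dist = "lognormal", sdlog = 1, seed = 7)
  ln2 <- make_pool(10, N = 2000, dist = "lognormal", sdlog = 1, seed = 7)
  expect_identical(ln1$weights, ln2$weights)   # seed contract

  mx <- make_pool(10, N = 1000, dist = "mixture",
                  mixture = data.frame(fraction = c(0.2, 0.8),
                                       weight = c(10, 1)))
  expect_equal(length(unique(mx$weights)), 2)
  expect_equal(sum(mx$weights), 1, tolerance = 1e-12)
  # 20% of barcodes carry 10x the propensity of the rest
  expect_equal(sum(mx$weights > stats::median(mx$weights)) / mx$N, 0.2)

  expect_error(make_pool(2, N = 17), "exceeds the barcode space")
  expect_error(make_pool(10, N = 10, dist = "mixture",
                         mixture = data.frame(fraction = c(0.5, 0.4),
                                              weight = c(1, 1))),
               "sum to 1")
})

test_that("barcode ids expand to nucleotide strings lazily", {
  expect_equal(barcode_seq(1:4, L = 2), c("AA", "AC", "AG", "AT"))
  expect_equal(barcode_seq(4^6, L = 6), "TTTTTT")
  expect_equal(nchar(barcode_seq(123456, L = 12)), 12)
  expect_error(barcode_seq(5, L = 1), "1..4\\^L")
})

test_that("labelling samples with replacement so clash can happen", {
  # single-barcode pool: a point mass, every molecule gets that barcode
  pm <- make_pool(1, N = 1)
  lab <- label_molecules(pm, 5, seed = 1)
  expect_equal(lab$multiplicity$count, 5)

  # heavy oversubscription guarantees a clash
  lab2 <- label_molecules(make_pool(2, N = 10), 10 * 1000, seed = 2)
  expect_gte(max(lab2$multiplicity$count), 2)

  # multiplicity table consistent with assignments
  expect_equal(sum(lab2$multiplicity$count), lab2$n)
  expect_true(all(lab2$multiplicity$barcode <= 10))
})

test_that("simulated unique fraction matches the analytic law", {
  cases <- list(c(n = 1e3, N = 1e4), c(n = 1e4, N = 1e4))
  for (cs in cases) {
    pool <- make_pool(12, N = cs[["N"]])
    fr <- vapply(1:50, function(i)
      clash_summary(label_molecules(pool, cs[["n"]], seed = i))$unique_fraction,
      numeric(1))
    se <- sd(fr) / sqrt(length(fr))
    expect_lt(abs(mean(fr) - expected_unique_fraction(cs[["n"]], cs[["N"]])),
              3 * se + 1e-12)
  }
  # n = N limit: unique fraction tends to e^-1 (Poisson multiplicities)
  pool <- make_pool(12, N = 1e4)
  fr <- vapply(1:50, function(i)
    clash_summary(label_molecules(pool, 1e4, seed = 100 + i))$unique_fraction,
    numeric(1))
  expect_lt(abs(mean(fr) - exp(-1)), 3 * sd(fr) / sqrt(50) + 1e-3)
})

test_that("no-clash probability matches brute-force enumeration", {
  for (n in 2:4) for (N in 2:6)
    expect_equal(prob_no_clash(n, N), enum_no_clash(n, N),
                 tolerance = 1e-12)
  expect_equal(prob_no_clash(1, 99), 1.0)
  expect_equal(prob_no_clash(2, 4), 0.75)
  expect_equal(prob_no_clash(5, 4), 0)        # pigeonhole
})

test_that("no-clash probability is monotone in n and N", {
  N <- 50
  p_n <- vapply(1:30, prob_no_clash, numeric(1), N = N)
  expect_true(all(diff(p_n) < 0))
  p_N <- vapply(10:60, function(N) prob_no_clash(8, N), numeric(1))
  expect_true(all(diff(p_N) > 0))
  # approximation tracks the exact value in the sparse regime
  expect_equal(prob_no_clash(100, 1e6, "approx"), prob_no_clash(100, 1e6),
               tolerance = 1e-3)
})

test_that("expected unique fraction matches enumeration and the 90% regime", {
  expect_equal(expected_unique_fraction(1, 5), 1.0)
  expect_equal(expected_unique_fraction(2, 2), enum_unique_fraction(2, 2))
  expect_equal(expected_unique_fraction(2, 2), 0.5)
  expect_equal(expected_unique_fraction(3, 3), enum_unique_fraction(3, 3))
  # ~90% of 1e6 molecules uniquely barcoded from a pool of 1e7
  expect_equal(expected_unique_fraction(1e6, 1e7), 0.905, tolerance = 0.001)
})

test_that("clash summary reports unique fraction, max clash and histogram", {
  lab <- labelling_from(c(1, 1, 2))
  cs <- clash_summary(lab)
  expect_equal(cs$unique_fraction, 1 / 3)
  expect_equal(cs$max_clash, 2)
  expect_equal(cs$histogram$n_barcodes, c(1, 1))

  all_distinct <- labelling_from(1:20)
  cs2 <- clash_summary(all_distinct)
  expect_equal(cs2$unique_fraction, 1.0)
  expect_equal(cs2$max_clash, 1)
})
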