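test_that("family sizes tabulate reads per originating template", {
  d <- family_size_distribution(c(2, 1, 2, 5))
  expect_equal(d$size, c(1, 2, 5))
  expect_equal(d$families, c(1, 2, 1))
  expect_equal(d$n_reads, 10)

  # sizes can come straight from a labelling's multiplicity table
  lab <- label_molecules(make_pool(12), 300, seed = 1)
  dl <- family_size_distribution(lab)
  expect_equal(dl$n_reads, 300)

  # S reads from S distinct lineages: {1: S}
  d1 <- family_size_distribution(rep(1, 40))
  expect_equal(d1$size, 1)
  expect_equal(d1$families, 40)
})

test_that("grouping by observed barcode merges clashed families", {
  # two molecules forced onto the same (single) barcode
  pool1 <- make_pool(2, N = 1)
  lab <- label_molecules(pool1, 2, seed = 4)
  amp <- amplify(lab, model_config(1, 2, efficiency = 1), seed = 5)
  s <- subsample(amp, size = amp$total, seed = 6)
  r <- sequence_reads(amp, s, error_rate = 0)
  by_lineage <- family_size_distribution(r, group_by = "lineage")
  by_barcode <- family_size_distribution(r, group_by = "barcode")
  expect_equal(by_lineage$n_families, 2)      # ground truth: two templates
  expect_equal(by_barcode$n_families, 1)      # observed: one clashed family
  expect_equal(by_barcode$size, 8)
})

test_that("coefficient of variation uses the population form", {
  expect_equal(coefficient_of_variation(c(1, 3)), 0.5)   # mean 2, sd 1
  expect_equal(coefficient_of_variation(rep(4, 10)), 0)
  expect_error(coefficient_of_variation(3), "at least 2")
  # sample form is switchable
  expect_equal(coefficient_of_variation(c(1, 3), sample = TRUE),
               sd(c(1, 3)) / 2)
  # matches the ZTP closed form on a large sample
  x <- rztpois(1e5, 1, seed = 7)
  expect_equal(coefficient_of_variation(x), ztp_moments(1)$cv,
               tolerance = 0.02)
})

test_that("ZTP maximum likelihood agrees with the moment equation", {
  for (lam in c(0.4, 0.9, 2.5)) {
    x <- rztpois(2e4, lam, seed = round(lam * 100))
    fit <- fit_ztp_mle(x, gof = FALSE)
    d <- family_size_distribution(x)
    expect_equal(fit$lambda, ztp_rate_from_mean(d$n_reads / d$n_families),
                 tolerance = 1e-6)
  }
})

test_that("ZTP fits recover the generating rate", {
  x <- rztpois(1e5, 0.9, seed = 11)
  fit <- fit_ztp_mle(x)
  expect_lt(abs(fit$lambda - 0.9), 0.01)
  expect_false(fit$boundary)

  # a sample mean of 1.582 corresponds to lambda = 1
  d <- family_size_distribution(c(rep(1, 418), rep(2, 582)))
  # (mean 1.582 engineered exactly)
  expect_equal(d$n_reads / d$n_families, 1.582)
  fit2 <- fit_ztp_mle(d, gof = FALSE)
  expect_equal(fit2$lambda, ztp_rate_from_mean(1.582), tolerance = 1e-6)
  expect_equal(fit2$lambda, 1.0, tolerance = 0.001)

  # all families of size one: boundary fit, flagged
  fit0 <- fit_ztp_mle(rep(1, 100))
  expect_true(fit0$boundary)
})

test_that("the chi-squared test holds its level on true ZTP data", {
  rejections <- sum(vapply(1:100, function(i) {
    x <- rztpois(2000, 1.5, seed = 1000 + i)
    f <- fit_ztp_mle(x, gof = FALSE)
    chi_squared_gof(x, f)$p < 0.05
  }, logical(1)))
  expect_lte(rejections, 10)    # nominal level 5%, allow sampling slack

  expect_error(chi_squared_gof(rep(1, 50), 0.5), "not computable")
})

test_that("inherited-efficiency family sizes are detectably non-Poisson", {
  amp6 <- amplify(2000, model_config(6, 15, eff_mean = 0.3, eff_sd = 0.3),
                  seed = 21)
  s6 <- subsample(amp6, ratio = 1, seed = 22)
  fam6 <- family_size_distribution(s6)
  fit6 <- fit_ztp_mle(fam6)
  expect_lt(fit6$chi2_p, 1e-6)

  em <- truncnorm_mean_quad(0.3, 0.3)
  amp1 <- amplify(2000, model_config(1, 15, efficiency = em), seed = 23)
  s1 <- subsample(amp1, ratio = 1, seed = 24)
  fam1 <- family_size_distribution(s1)
  expect_gt(coefficient_of_variation(fam6), coefficient_of_variation(fam1))
})

test_that("rank comparison of runs behaves at its reference points", {
  a <- setNames(rztpois(5000, 2, seed = 31), paste0("bc", 1:5000))
  expect_equal(compare_runs(a, a)$r_squared, 1.0)

  rev <- setNames(max(a) + 1 - a, names(a))
  cr <- compare_runs(a, rev)
  expect_equal(cr$r_squared, 1.0, tolerance = 1e-12)
  expect_lt(cr$slope, 0)

  b <- setNames(rztpois(5000, 2, seed = 32), names(a))
  expect_lt(compare_runs(a, b)$r_squared, 0.05)   # independent runs

  expect_error(compare_runs(a[1:5], a[1:5]), "at least 10")

  # ties share a rank and introduce no gap
  x <- setNames(c(5, 5, 5, 7, 7, 9, 2, 2, 11, 11, 11, 3), paste0("b", 1:12))
  y <- setNames(seq_along(x), names(x))
  cr2 <- compare_runs(x, y)
  expect_equal(cr2$ranks$rank_a, c(3, 3, 3, 4, 4, 5, 1, 1, 6, 6, 6, 2))
})

test_that("GC fraction counts G and C bases", {
  expect_equal(gc_fraction(c("GGCC", "AATT", "ACGT")), c(1, 0, 0.5))
  expect_error(gc_fraction("ACGU"), "A, C, G, T")
  expect_error(gc_fraction(character(0)), "non-empty")
  # 12-mer barcode GC content across a pool is centred on 1/2
  set.seed(41)
  gc <- gc_fraction(barcode_seq(sample.int(4^12, 500), 12))
  expect_equal(mean(gc), 0.5, tolerance = 0.05)
})
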