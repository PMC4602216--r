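# Independent oracles used across the suite: brute-force enumeration,
# closed-form inversions and quadrature, kept free of the code paths they
# check.

# Probability of no barcode clash by exhaustive enumeration of all N^n
# ordered assignments of n molecules to N equally likely barcodes.
enum_no_clash <- function(n, N) {
  grid <- do.call(expand.grid, rep(list(seq_len(N)), n))
  mean(apply(grid, 1, function(a) !anyDuplicated(a)))
}

# Expected unique-barcode fraction by the same enumeration.
enum_unique_fraction <- function(n, N) {
  grid <- do.call(expand.grid, rep(list(seq_len(N)), n))
  mean(apply(grid, 1, function(a) sum(table(a)[as.character(a)] == 1) / n))
}

# Exact pmf of the final copy number of one template after `cycles` rounds
# of constant-efficiency branching PCR, by convolving binomial offspring
# distributions (support 1..2^cycles).
enum_final_pmf <- function(e, cycles) {
  pmf <- c(1)   # index = copy number, start with 1 copy w.p. 1
  for (t in seq_len(cycles)) {
    new <- numeric(2^t)
    for (m in which(pmf > 0)) {
      s <- 0:m
      new[m + s] <- new[m + s] + pmf[m] * dbinom(s, m, e)
    }
    pmf <- new
  }
  pmf
}

# Moment-equation route to the zero-truncated Poisson MLE: solve
# lambda / (1 - exp(-lambda)) = mean observed size.
ztp_rate_from_mean <- function(m) {
  stopifnot(m > 1)
  uniroot(function(l) l / (1 - exp(-l)) - m,
          lower = 1e-12, upper = m, tol = 1e-12)$root
}

# Mean of the [0,1]-restricted normal by numerical quadrature.
truncnorm_mean_quad <- function(mean, sd) {
  z <- integrate(function(x) dnorm(x, mean, sd), 0, 1)$value
  integrate(function(x) x * dnorm(x, mean, sd) / z, 0, 1)$value
}

# two-sample KS p-value, silencing the ties warning (family sizes are
# discrete; the test is conservative under ties)
ks_p <- function(x, y) suppressWarnings(ks.test(x, y))$p.value

# quick labelling object from explicit assignments (for definitional checks)
labelling_from <- function(ids, N = max(ids), L = 12) {
  r <- rle(sort(ids))
  structure(list(n = length(ids), assignments = ids,
                 multiplicity = data.frame(barcode = r$values,
                                           count = r$lengths),
                 pool = list(L = L, N = N, dist = "uniform")),
            class = "labelling")
}
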