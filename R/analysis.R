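#' Barcode family-size distribution
#'
#' Tabulates how many reads (or sampled molecules) descend from each initial
#' template, i.e. the barcode family sizes.  Families with zero reads are
#' structurally excluded -- they are unobservable in sequencing output,
#' which is why family-size laws are zero-truncated.
#'
#' @param x A [sequence_reads()] read set, a [subsample()] molecule sample,
#'   a [label_molecules()] labelling (per-barcode labelling-event counts),
#'   or a plain numeric vector of family sizes.
#' @param group_by For read sets: `"lineage"` groups reads by their true
#'   originating template (simulation ground truth); `"barcode"` groups by
#'   the observed barcode sequence at the start of each read, so barcode
#'   clash merges families and barcode-position errors split them, as they
#'   would experimentally.
#' @return An object of class `famsize_dist`: `size` (distinct family sizes
#'   `k >= 1`), `families` (number of families of each size), `n_families`,
#'   `n_reads`.
#' @examples
#' family_size_distribution(c(2, 1, 2, 5))
#' @export
family_size_distribution <- function(x, group_by = c("lineage", "barcode")) {
  group_by <- match.arg(group_by)
  sizes <-
    if (inherits(x, "read_set")) {
      if (group_by == "lineage") as.numeric(table(x$reads$lineage))
      else {
        L <- x$barcode_length
        if (is.null(L)) stopf("read set carries no barcodes")
        as.numeric(table(substr(x$reads$sequence, 1L, L)))
      }
    } else if (inherits(x, "molecule_sample")) {
      x$count
    } else if (inherits(x, "labelling")) {
      x$multiplicity$count
    } else if (is.numeric(x)) {
      x
    } else stopf("unsupported input for family_size_distribution()")
  if (!length(sizes)) stopf("no families observed")
  if (any(sizes < 1 | sizes != floor(sizes)))
    stopf("family sizes must be integers >= 1")
  r <- rle(sort(as.numeric(sizes)))
  structure(list(size = r$values, families = r$lengths,
                 n_families = length(sizes),
                 n_reads = sum(sizes)),
            class = "famsize_dist")
}

#' @export
print.famsize_dist <- function(x, ...) {
  cat(sprintf("Family-size distribution: %s families, %s reads (mean size %.3f)\n",
              format(x$n_families, big.mark = ","),
              format(x$n_reads, big.mark = ","), x$n_reads / x$n_families))
  invisible(x)
}

#' @export
plot.famsize_dist <- function(x, ..., log = "xy", fit = NULL) {
  freq <- x$families / x$n_families
  plot(x$size, freq, log = log, xlab = "family size",
       ylab = "fraction of families", pch = 16, ...)
  if (!is.null(fit)) {
    lam <- if (inherits(fit, "ztp_fit")) fit$lambda else fit
    kk <- seq(min(x$size), max(x$size))
    points(kk, ztp_pmf(kk, lam), type = "l", lty = 2)
    legend("topright", legend = sprintf("ZTP(%.3g)", lam), lty = 2,
           bty = "n")
  }
  invisible(x)
}

# expand a famsize_dist back to one size per family
famsize_expand <- function(dist) rep(dist$size, times = dist$families)

as_famsize <- function(x)
  if (inherits(x, "famsize_dist")) x else family_size_distribution(x)

#' Coefficient of variation of family sizes
#'
#' The scalar heterogeneity summary: standard deviation of family sizes
#' divided by their mean.  The population form (denominator `n`) is the
#' default; set `sample = TRUE` for the `n - 1` form.
#'
#' @param x A `famsize_dist` or numeric vector of family sizes.
#' @param sample Use the sample (n-1) standard deviation instead of the
#'   population form.
#' @return The coefficient of variation.
#' @examples
#' coefficient_of_variation(c(1, 3))   # 0.5
#' @export
coefficient_of_variation <- function(x, sample = FALSE) {
  d <- as_famsize(x)
  if (d$n_families < 2) stopf("need at least 2 families for a CV")
  m <- d$n_reads / d$n_families
  ss <- sum(d$families * (d$size - m)^2)
  v <- if (sample) ss / (d$n_families - 1) else ss / d$n_families
  sqrt(v) / m
}

#' Maximum-likelihood zero-truncated Poisson fit to family sizes
#'
#' Fits the rate of a [ztp_pmf()] law to an observed family-size
#' distribution by maximising the log-likelihood with bracketed 1-D
#' numerical optimisation (tolerance 1e-10).  The optimum equivalently
#' solves the moment equation `lambda / (1 - exp(-lambda)) = mean size`.
#' When every family has size 1 the likelihood is maximised at the
#' `lambda -> 0` boundary; the fit is then flagged.
#'
#' @param x A `famsize_dist` or numeric vector of family sizes.
#' @param gof Also compute the chi-squared goodness of fit
#'   ([chi_squared_gof()])?
#' @return An object of class `ztp_fit`: `lambda`, `loglik`, `boundary`,
#'   `n_families`, `n_reads`, `data`, and (with `gof = TRUE`) `chi2_stat`,
#'   `chi2_df`, `chi2_p`.
#' @examples
#' fit_ztp_mle(rztpois(1000, 0.9, seed = 1))
#' @export
fit_ztp_mle <- function(x, gof = TRUE) {
  d <- as_famsize(x)
  mean_k <- d$n_reads / d$n_families
  negll <- function(lam) -sum(d$families * log(ztp_pmf(d$size, lam)))
  boundary <- mean_k <= 1 + 1e-12
  if (boundary) {
    lambda <- 1e-8
    ll <- -negll(lambda)
  } else {
    opt <- optimise(negll, interval = c(1e-10, mean_k), tol = 1e-10)
    lambda <- opt$minimum
    ll <- -opt$objective
  }
  fit <- structure(list(lambda = lambda, loglik = ll, boundary = boundary,
                        n_families = d$n_families, n_reads = d$n_reads,
                        data = d),
                   class = "ztp_fit")
  if (gof && !boundary) {
    g <- tryCatch(chi_squared_gof(d, fit), error = function(e) NULL)
    if (!is.null(g)) {
      fit$chi2_stat <- g$stat
      fit$chi2_df <- g$df
      fit$chi2_p <- g$p
    }
  }
  fit
}

#' @export
print.ztp_fit <- function(x, ...) {
  cat(sprintf("Zero-truncated Poisson fit: lambda = %.5g (logLik %.3f)%s\n",
              x$lambda, x$loglik,
              if (x$boundary) " [boundary: all families of size 1]" else ""))
  if (!is.null(x$chi2_p))
    cat(sprintf("  GOF: X2 = %.3f, df = %d, p = %.3g\n", x$chi2_stat,
                x$chi2_df, x$chi2_p))
  invisible(x)
}

#' @export
coef.ztp_fit <- function(object, ...) c(lambda = object$lambda)

#' @export
logLik.ztp_fit <- function(object, ...) {
  structure(object$loglik, df = 1L, class = "logLik")
}

#' Chi-squared goodness of fit of a family-size law
#'
#' Compares observed family-size counts to those expected under a fitted
#' zero-truncated (mixed) Poisson.  Bins with small expected counts are
#' pooled -- the right tail first, then the left -- until every bin expects
#' at least `min_expected`; degrees of freedom are
#' `bins - 1 - n_parameters` (one parameter for a ZTP fit, `2K - 1` for a
#' K-component mixture, none for a fixed rate).
#'
#' @param x A `famsize_dist` or numeric vector of family sizes.
#' @param fit A [fit_ztp_mle()] or [fit_zt_mixed_poisson()] object, or a
#'   plain numeric rate (treated as known, not estimated).
#' @param min_expected Minimum expected count per bin after pooling.
#' @return A list with `stat`, `df`, `p`, and the binned `table`.
#' @examples
#' x <- rztpois(2000, 1.5, seed = 1)
#' chi_squared_gof(x, fit_ztp_mle(x, gof = FALSE))
#' @export
chi_squared_gof <- function(x, fit, min_expected = 5) {
  d <- as_famsize(x)
  if (inherits(fit, "ztp_fit")) {
    pmf <- function(k) ztp_pmf(k, fit$lambda)
    surv <- function(k) ppois(k - 1, fit$lambda, lower.tail = FALSE) /
      (1 - exp(-fit$lambda))
    n_par <- 1L
  } else if (inherits(fit, "ztmix_fit")) {
    pmf <- function(k) ztmix_pmf(k, fit$weights, fit$rates)
    surv <- function(k) sum(fit$weights *
                            ppois(k - 1, fit$rates, lower.tail = FALSE)) /
      (1 - sum(fit$weights * exp(-fit$rates)))
    n_par <- 2L * fit$K - 1L
  } else if (is.numeric(fit) && length(fit) == 1L) {
    lam <- fit
    pmf <- function(k) ztp_pmf(k, lam)
    surv <- function(k) ppois(k - 1, lam, lower.tail = FALSE) /
      (1 - exp(-lam))
    n_par <- 0L
  } else stopf("`fit` must be a ztp_fit, ztmix_fit, or a rate")

  n <- d$n_families
  kmax <- max(d$size)
  obs_all <- numeric(kmax)
  obs_all[d$size] <- d$families
  exp_all <- n * pmf(seq_len(kmax))

  # pool the right tail: k >= K bin must expect >= min_expected
  K <- kmax
  while (K > 1 && n * surv(K) < min_expected) K <- K - 1
  obs <- c(obs_all[seq_len(K - 1)], sum(obs_all[K:kmax]))
  expd <- c(exp_all[seq_len(K - 1)], n * surv(K))
  # pool from the left if small-k bins are still thin (large rates)
  while (length(expd) > 1 && expd[1] < min_expected) {
    expd[2] <- expd[2] + expd[1]
    obs[2] <- obs[2] + obs[1]
    expd <- expd[-1]
    obs <- obs[-1]
  }
  df <- length(expd) - 1L - n_par
  if (length(expd) < 3 || df < 1)
    stopf("goodness of fit not computable: only %d bins after pooling",
          length(expd))
  stat <- sum((obs - expd)^2 / expd)
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
       table = data.frame(observed = obs, expected = expd))
}

#' Rank agreement of barcode family sizes between two runs
#'
#' Ranks the shared barcodes by family size in each run (ascending; tied
#' sizes share one rank, with no gap after a tie) and reports the linear
#' R-squared between the two rank vectors.  If barcode family size were a
#' property of the barcode sequence, ranks would correlate across runs;
#' independent runs give R-squared near 0.
#'
#' @param a,b Named numeric vectors of family sizes (names identify
#'   barcodes), or two-column data frames `(barcode, size)`.
#' @return An object of class `run_comparison`: `n_shared`, `r_squared`,
#'   `slope`, and the `ranks` data frame.
#' @export
compare_runs <- function(a, b) {
  a <- as_named_sizes(a)
  b <- as_named_sizes(b)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 10)
    stopf("only %d shared barcodes; need at least 10", length(shared))
  ra <- dense_rank(a[shared])
  rb <- dense_rank(b[shared])
  fit <- lm(rb ~ ra)
  # identical runs are a legitimate input; silence the perfect-fit note
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(n_shared = length(shared),
                 r_squared = r2,
                 slope = unname(coef(fit)[2]),
                 ranks = data.frame(barcode = shared, rank_a = ra,
                                    rank_b = rb)),
            class = "run_comparison")
}

as_named_sizes <- function(x) {
  if (is.data.frame(x)) return(setNames(as.numeric(x[[2]]),
                                        as.character(x[[1]])))
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stopf("runs must be named numeric vectors or (barcode, size) data frames")
}

# ascending ranks; ties share a rank and leave no gap
dense_rank <- function(x) match(x, sort(unique(x)))

#' @export
print.run_comparison <- function(x, ...) {
  cat(sprintf("Run comparison: %d shared barcodes, rank R^2 = %.4f (slope %.3f)\n",
              x$n_shared, x$r_squared, x$slope))
  invisible(x)
}

#' GC content of barcode sequences
#'
#' @param x Character vector of A/C/G/T sequences.
#' @return Fraction of G or C bases per sequence, in [0, 1].
#' @examples
#' gc_fraction(c("GGCC", "AATT", "ACGT"))   # 1, 0, 0.5
#' @export
gc_fraction <- function(x) {
  if (!is.character(x) || !length(x) || any(!nzchar(x)))
    stopf("`x` must be non-empty A/C/G/T strings")
  if (any(!grepl("^[ACGT]+$", x)))
    stopf("sequences must contain only A, C, G, T")
  dna <- Biostrings::DNAStringSet(x)
  as.numeric(Biostrings::letterFrequency(dna, "GC")) / nchar(x)
}
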