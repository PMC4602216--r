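#' Zero-truncated mixed-Poisson probability mass function
#'
#' A barcode pool made of classes with different labelling propensities
#' produces per-barcode labelling-event counts that follow a Poisson mixture;
#' barcodes never used are unobserved, so the mixture is zero-truncated as a
#' whole:
#' \deqn{P(k) = \frac{\sum_j w_j \mathrm{Pois}(k;\lambda_j)}
#'                   {1 - \sum_j w_j e^{-\lambda_j}}, \quad k \ge 1.}
#'
#' @param k Integer counts (values `< 1` have probability 0).
#' @param weights Mixture weights over pool classes (sum to 1).
#' @param rates Positive Poisson rates, one per class.
#' @return Vector of probabilities.
#' @export
ztmix_pmf <- function(k, weights, rates) {
  check_mixture(weights, rates)
  num <- rowSums(vapply(seq_along(rates),
                        function(j) weights[j] * dpois(k, rates[j]),
                        numeric(length(k))))
  p <- num / (1 - sum(weights * exp(-rates)))
  p[k < 1 | k != floor(k)] <- 0
  p
}

check_mixture <- function(weights, rates) {
  if (length(weights) != length(rates))
    stopf("`weights` and `rates` must have the same length")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6)
    stopf("`weights` must be non-negative and sum to 1")
  if (any(rates <= 0)) stopf("`rates` must be positive")
  invisible(TRUE)
}

#' Simulate barcode-labelling-event counts from a structured pool
#'
#' Draws per-barcode labelling-event counts from a Poisson mixture over pool
#' classes and discards barcodes with zero events (those are invisible in
#' sequencing data).  This is the generative counterpart of
#' [fit_zt_mixed_poisson()].
#'
#' @param n_barcodes Number of barcodes in the pool (before truncation).
#' @param weights Class fractions of the pool.
#' @param rates Expected labelling events per barcode of each class.
#' @param seed Optional integer seed.
#' @return Integer vector of event counts, one per observed barcode (all
#'   `>= 1`).
#' @export
simulate_labelling_events <- function(n_barcodes, weights, rates,
                                      seed = NULL) {
  check_mixture(weights, rates)
  with_seed_maybe(seed, {
    cls <- sample.int(length(rates), n_barcodes, replace = TRUE,
                      prob = weights)
    ev <- rpois(n_barcodes, rates[cls])
    ev[ev >= 1L]
  })
}

#' Fit a zero-truncated mixed-Poisson model to labelling-event counts
#'
#' Maximum-likelihood fit of the [ztmix_pmf()] model to a histogram of
#' barcode-labelling events (how many times each observed barcode labelled a
#' molecule).  The likelihood is maximised over an unconstrained
#' reparameterisation (log rates, softmax weights) with multiple random
#' restarts; with `K = NULL` the number of components is chosen by AIC over
#' `1..K_max`.  The fitted parameters describe the structure of the barcode
#' pool (see [infer_pool_structure()]).
#'
#' @param events Either an integer vector of per-barcode event counts (all
#'   `>= 1`), or a two-column data frame / matrix `(k, count)` giving the
#'   histogram of counts.
#' @param K Number of mixture components, or `NULL` to select by AIC.
#' @param K_max Largest K tried when `K = NULL`.
#' @param n_restarts Random restarts per K (the best optimum is kept).
#' @param seed Optional integer seed for the restart draws.
#' @return An object of class `ztmix_fit`: `K`, `weights`, `rates` (sorted
#'   by increasing rate), `loglik`, `aic`, `converged`, `boundary` (TRUE if
#'   a rate collapsed towards 0), `n_events`, `data` (the histogram), and
#'   `aic_table` when K was selected.
#' @examples
#' ev <- simulate_labelling_events(2000, 1, 2, seed = 1)
#' fit_zt_mixed_poisson(ev, K = 1)
#' @export
fit_zt_mixed_poisson <- function(events, K = NULL, K_max = 3,
                                 n_restarts = 10, seed = NULL) {
  h <- as_event_histogram(events)
  if (is.null(K)) {
    fits <- lapply(seq_len(K_max), function(k)
      fit_ztmix_one(h, k, n_restarts, seed))
    aics <- vapply(fits, `[[`, numeric(1), "aic")
    best <- fits[[which.min(aics)]]
    best$aic_table <- data.frame(K = seq_len(K_max), aic = aics)
    return(best)
  }
  fit_ztmix_one(h, K, n_restarts, seed)
}

as_event_histogram <- function(events) {
  if (is.data.frame(events) || is.matrix(events)) {
    h <- data.frame(k = as.numeric(events[, 1]),
                    count = as.numeric(events[, 2]))
  } else if (inherits(events, "famsize_dist")) {
    h <- data.frame(k = events$size, count = events$families)
  } else {
    if (!length(events)) stopf("`events` is empty")
    r <- rle(sort(as.numeric(events)))
    h <- data.frame(k = r$values, count = r$lengths)
  }
  h <- h[h$count > 0, , drop = FALSE]
  if (!nrow(h)) stopf("`events` is empty")
  if (any(h$k < 1 | h$k != floor(h$k)))
    stopf("event counts must be integers >= 1 (zero counts are unobservable)")
  h
}

# log P(k) of the ZT mixture for histogram k values, by log-sum-exp
ztmix_logpmf <- function(k, weights, rates) {
  lw <- log(weights)
  lp <- vapply(seq_along(rates),
               function(j) lw[j] + dpois(k, rates[j], log = TRUE),
               numeric(length(k)))
  lp <- matrix(lp, nrow = length(k))
  mx <- apply(lp, 1, max)
  num <- mx + log(rowSums(exp(lp - mx)))
  num - log(1 - sum(weights * exp(-rates)))
}

fit_ztmix_one <- function(h, K, n_restarts, seed) {
  stopifnot(K >= 1)
  n <- sum(h$count)
  mean_k <- sum(h$k * h$count) / n

  if (K == 1L) {
    # one free parameter: bracketed 1-D optimisation is exact and quiet
    negll1 <- function(loglam)
      -sum(h$count * ztmix_logpmf(h$k, 1, exp(loglam)))
    opt <- optimise(negll1, interval = log(c(1e-8, max(mean_k, 1e-6))),
                    tol = 1e-12)
    lam <- exp(opt$minimum)
    return(structure(list(K = 1L, weights = 1, rates = lam,
                          loglik = -opt$objective,
                          aic = 2 + 2 * opt$objective,
                          converged = TRUE, boundary = lam < 1e-4,
                          n_events = sum(h$k * h$count), n_barcodes = n,
                          data = h),
                     class = "ztmix_fit"))
  }

  unpack <- function(par) {
    rates <- exp(par[seq_len(K)])
    if (K == 1L) weights <- 1
    else {
      z <- c(par[-seq_len(K)], 0)
      z <- z - max(z)
      weights <- exp(z) / sum(exp(z))
    }
    list(weights = weights, rates = rates)
  }
  negll <- function(par) {
    p <- unpack(par)
    if (any(!is.finite(p$rates)) || any(p$rates > 1e6)) return(1e12)
    ll <- sum(h$count * ztmix_logpmf(h$k, p$weights, p$rates))
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  starts <- with_seed_maybe(seed, {
    lapply(seq_len(n_restarts), function(i) {
      lam0 <- if (i == 1L)
        # deterministic start: spread around the observed mean
        mean_k * seq(0.5, 1.5, length.out = K)
      else
        exp(log(mean_k) + rnorm(K, 0, 1))
      c(log(pmax(lam0, 1e-3)), rep(0, K - 1L))
    })
  })

  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      optim(st, negll, method = "Nelder-Mead",
            control = list(maxit = 5000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stopf("mixed-Poisson fit failed for every restart (K = %d)", K)

  p <- unpack(best$par)
  ord <- order(p$rates)
  n_par <- 2L * K - 1L
  structure(list(K = as.integer(K),
                 weights = p$weights[ord], rates = p$rates[ord],
                 loglik = -best$value, aic = 2 * n_par + 2 * best$value,
                 converged = best$convergence == 0L,
                 boundary = any(p$rates < 1e-4),
                 n_events = sum(h$k * h$count), n_barcodes = n,
                 data = h),
            class = "ztmix_fit")
}

#' @export
print.ztmix_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Zero-truncated mixed-Poisson fit (K = %d)\n", x$K))
  print(data.frame(weight = round(x$weights, digits),
                   rate = round(x$rates, digits)))
  cat(sprintf("logLik %.3f, AIC %.3f%s%s\n", x$loglik, x$aic,
              if (!x$converged) " [not converged]" else "",
              if (x$boundary) " [boundary rate]" else ""))
  invisible(x)
}

#' @export
logLik.ztmix_fit <- function(object, ...) {
  structure(object$loglik, df = 2L * object$K - 1L, class = "logLik")
}

#' @export
coef.ztmix_fit <- function(object, ...) {
  c(setNames(object$weights, paste0("w", seq_len(object$K))),
    setNames(object$rates, paste0("lambda", seq_len(object$K))))
}

#' Infer the structure of the barcode pool from a mixture fit
#'
#' Translates a fitted zero-truncated mixed-Poisson model of
#' labelling-event counts back into a description of the pool of available
#' barcodes: each mixture component is a class of barcodes whose share of
#' the pool is the component weight and whose relative labelling propensity
#' is proportional to its rate.  The returned `mixture` data frame can be
#' passed straight to [make_pool()] (`dist = "mixture"`) to simulate
#' labelling from the inferred pool.
#'
#' The fit constrains only the product of pool size and per-barcode
#' propensity, so absolute pool size is estimated from the truncation:
#' `n_barcodes / P(k >= 1)`.
#'
#' @param fit A [fit_zt_mixed_poisson()] object.
#' @return A list: `components` (data frame `fraction`, `rate`,
#'   `propensity`), `mixture` (a mixture table for [make_pool()]),
#'   `est_pool_size` and
#'   `est_molecules`.
#' @export
infer_pool_structure <- function(fit) {
  stopifnot(inherits(fit, "ztmix_fit"))
  p_obs <- 1 - sum(fit$weights * exp(-fit$rates))
  comp <- data.frame(fraction = fit$weights,
                     rate = fit$rates,
                     propensity = fit$rates / sum(fit$rates))
  list(components = comp,
       mixture = data.frame(fraction = fit$weights, weight = fit$rates),
       est_pool_size = fit$n_barcodes / p_obs,
       est_molecules = fit$n_events)
}
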