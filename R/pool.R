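#' Size of the barcode space for a given barcode length
#'
#' A random nucleotide barcode of length `L` can take `4^L` distinct
#' sequences; 12-mer UMIs give about 1.7e7 possible barcodes.
#'
#' @param L Barcode length in nucleotides (positive integer).
#' @return Number of distinct barcodes, `4^L`, as a double (the value
#'   exceeds the integer range for `L > 15`).
#' @examples
#' pool_size(12)   # 16777216
#' @export
pool_size <- function(L) {
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L < 1 || L != floor(L))
    stopf("`L` must be a positive integer (got %s)", format(L))
  4^L
}

#' Construct a pool of barcodes with a given frequency distribution
#'
#' Builds the pool of barcodes available for labelling.  Synthesised
#' oligonucleotide pools are rarely perfectly uniform, so besides the ideal
#' uniform pool the per-barcode frequencies can follow a normal distribution
#' (restricted to positive values by rejection, then normalised), a lognormal
#' distribution, or an empirical mixture of barcode classes with different
#' labelling propensities (as inferred by [infer_pool_structure()]).
#'
#' Barcodes are identified by integer ids `1..N`; nucleotide strings are only
#' materialised on demand by [barcode_seq()], so pools with millions of
#' barcodes stay cheap.
#'
#' @param L Barcode length in nucleotides.
#' @param N Number of distinct barcodes in the pool (default the full space
#'   `4^L`; must not exceed it).
#' @param dist Frequency distribution of the pool: `"uniform"`, `"normal"`,
#'   `"lognormal"` or `"mixture"`.
#' @param mean,sd Parameters of the normal weight distribution (draws `<= 0`
#'   are rejected and redrawn).
#' @param meanlog,sdlog Parameters of the lognormal weight distribution.
#' @param mixture A data frame with columns `fraction` (share of the pool's
#'   barcodes in each class, summing to 1) and `weight` (relative labelling
#'   propensity of one barcode of that class).
#' @param seed Optional integer seed; the same seed reproduces the same pool.
#' @return An object of class `barcode_pool` with elements `L`, `N`,
#'   `weights` (per-barcode sampling probabilities; `NULL` denotes uniform)
#'   and `dist`.
#' @examples
#' make_pool(6, N = 1000)                          # uniform
#' make_pool(6, N = 1000, dist = "normal", mean = 1, sd = 0.5, seed = 1)
#' @export
make_pool <- function(L, N = pool_size(L), dist = c("uniform", "normal",
                      "lognormal", "mixture"), mean = 1, sd = 0.25,
                      meanlog = 0, sdlog = 1, mixture = NULL, seed = NULL) {
  dist <- match.arg(dist)
  ps <- pool_size(L)
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1 || N != floor(N))
    stopf("`N` must be a positive integer")
  if (N > ps)
    stopf("N = %s exceeds the barcode space 4^%d = %s",
          format(N, big.mark = ","), L, format(ps, big.mark = ","))

  weights <- switch(dist,
    uniform = NULL,
    normal = {
      if (!is.finite(mean) || !is.finite(sd) || sd < 0)
        stopf("normal pool needs finite `mean` and `sd >= 0`")
      if (mean <= 0 && sd == 0)
        stopf("normal pool with sd = 0 needs mean > 0")
      with_seed_maybe(seed, rpositive_norm(N, mean, sd))
    },
    lognormal = {
      if (!is.finite(meanlog) || !is.finite(sdlog) || sdlog < 0)
        stopf("lognormal pool needs finite `meanlog` and `sdlog >= 0`")
      with_seed_maybe(seed, rlnorm(N, meanlog, sdlog))
    },
    mixture = {
      if (is.null(mixture) || !all(c("fraction", "weight") %in% names(mixture)))
        stopf("`mixture` must be a data frame with columns fraction, weight")
      f <- mixture$fraction
      a <- mixture$weight
      if (any(f < 0) || abs(sum(f) - 1) > 1e-6)
        stopf("mixture fractions must be non-negative and sum to 1")
      if (any(a <= 0)) stopf("mixture weights must be positive")
      sizes <- round(f * N)
      sizes[length(sizes)] <- N - sum(sizes[-length(sizes)])
      if (any(sizes < 0)) stopf("mixture fractions incompatible with N")
      rep(a, times = sizes)
    })

  if (!is.null(weights)) weights <- weights / sum(weights)
  structure(list(L = L, N = N, weights = weights, dist = dist),
            class = "barcode_pool")
}

# Normal draws restricted to values > 0, by rejection (no atom at zero).
rpositive_norm <- function(n, mean, sd) {
  out <- rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' @export
print.barcode_pool <- function(x, ...) {
  cat(sprintf("Barcode pool: %s barcodes of length %d (%s)\n",
              format(x$N, big.mark = ","), x$L, x$dist))
  if (!is.null(x$weights))
    cat(sprintf("  weight range: [%.3g, %.3g]\n",
                min(x$weights), max(x$weights)))
  invisible(x)
}

#' Nucleotide sequence of a barcode id
#'
#' Expands integer barcode ids into their nucleotide strings.  Id `i`
#' (1-based) is written as `i - 1` in base 4 over `L` digits, mapped
#' 0:3 -> A, C, G, T (most significant digit first).
#'
#' @param id Integer vector of barcode ids in `1..4^L`.
#' @param L Barcode length.
#' @return Character vector of `L`-mer sequences.
#' @examples
#' barcode_seq(1:4, L = 2)  # "AA" "AC" "AG" "AT"
#' @export
barcode_seq <- function(id, L) {
  if (any(id < 1) || any(id > pool_size(L)))
    stopf("barcode ids must lie in 1..4^L")
  x <- id - 1
  m <- matrix("", nrow = length(id), ncol = L)
  for (pos in L:1) {
    m[, pos] <- c("A", "C", "G", "T")[x %% 4 + 1]
    x <- x %/% 4
  }
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Label molecules by drawing barcodes from a pool
#'
#' Attaches one barcode to each of `n` template molecules by sampling from
#' the pool's frequency distribution *with replacement* -- two molecules can
#' receive the same barcode (a "barcode clash"); clash is an outcome of the
#' labelling chemistry, never prevented.
#'
#' @param pool A [make_pool()] object.
#' @param n Number of molecules to label.
#' @param seed Optional integer seed.
#' @return An object of class `labelling`: `n`, `assignments` (barcode id per
#'   molecule), and `multiplicity` (data frame `barcode`, `count` for every
#'   barcode used at least once).
#' @examples
#' pool <- make_pool(6, N = 100)
#' lab <- label_molecules(pool, 50, seed = 1)
#' clash_summary(lab)
#' @export
label_molecules <- function(pool, n, seed = NULL) {
  stopifnot(inherits(pool, "barcode_pool"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    stopf("`n` must be a positive integer")
  ids <- with_seed_maybe(seed,
    sample.int(pool$N, size = n, replace = TRUE, prob = pool$weights))
  r <- rle(sort(ids))
  structure(list(n = as.integer(n), assignments = ids,
                 multiplicity = data.frame(barcode = r$values,
                                           count = r$lengths),
                 pool = pool[c("L", "N", "dist")]),
            class = "labelling")
}

#' @export
print.labelling <- function(x, ...) {
  cs <- clash_summary(x)
  cat(sprintf("Labelling: %s molecules, %s distinct barcodes\n",
              format(x$n, big.mark = ","),
              format(nrow(x$multiplicity), big.mark = ",")))
  cat(sprintf("  uniquely barcoded: %.1f%%; max clash size: %d\n",
              100 * cs$unique_fraction, cs$max_clash))
  invisible(x)
}

#' Exact probability that no two molecules share a barcode
#'
#' The birthday-problem probability that `n` molecules drawn uniformly from
#' `N` barcodes are all distinct: the exact product
#' \eqn{\prod_{i=0}^{n-1} (1 - i/N)} (0 when `n > N`), or the classical
#' approximation \eqn{\exp(-n(n-1)/2N)}.
#'
#' @param n Number of molecules labelled.
#' @param N Number of barcodes in the (uniform) pool.
#' @param method `"exact"` (default) or `"approx"`.
#' @return Probability of no clash.
#' @examples
#' prob_no_clash(2, 4)                      # 0.75
#' prob_no_clash(1e6, 4^12, "approx")
#' @export
prob_no_clash <- function(n, N, method = c("exact", "approx")) {
  method <- match.arg(method)
  stopifnot(n >= 1, N >= 1)
  if (method == "approx") return(exp(-n * (n - 1) / (2 * N)))
  if (n > N) return(0)
  # sum of log1p for numerical stability at large n
  exp(sum(log1p(-(seq_len(n) - 1) / N)))
}

#' Expected fraction of molecules that receive a unique barcode
#'
#' Probability that a given molecule's barcode is drawn by none of the other
#' `n - 1` molecules in a uniform pool of `N` barcodes: `((N-1)/N)^(n-1)`.
#' Labelling on the order of 1e6 molecules from 1e7 barcodes leaves about
#' 90\% of molecules uniquely barcoded.
#'
#' @inheritParams prob_no_clash
#' @return Expected unique fraction.
#' @examples
#' expected_unique_fraction(1e6, 1e7)   # ~0.905
#' @export
expected_unique_fraction <- function(n, N) {
  stopifnot(n >= 1, N >= 1)
  ((N - 1) / N)^(n - 1)
}

#' Summarise barcode clash in a labelling
#'
#' @param labelling A [label_molecules()] object.
#' @return A list: `unique_fraction` (share of molecules whose barcode was
#'   drawn exactly once), `max_clash` (largest number of molecules sharing
#'   one barcode), and `histogram` (data frame `multiplicity`, `n_barcodes`).
#' @export
clash_summary <- function(labelling) {
  stopifnot(inherits(labelling, "labelling"))
  if (labelling$n < 1) stopf("empty labelling")
  cnt <- labelling$multiplicity$count
  h <- rle(sort(cnt))
  list(unique_fraction = sum(cnt == 1L) / labelling$n,
       max_clash = max(cnt),
       histogram = data.frame(multiplicity = h$values,
                              n_barcodes = h$lengths))
}
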