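#' PCR model configuration
#'
#' Bundles the model id and its parameters for [amplify()].  Six
#' branching-process models of per-cycle replication are supported:
#'
#' \describe{
#'   \item{Model 1}{Constant efficiency: each molecule replicates with
#'     probability `efficiency` in every cycle.}
#'   \item{Model 2}{Target degradation: as Model 1, but a molecule that
#'     fails to replicate in a cycle degrades with probability
#'     `degradation` and is lost to later cycles.}
#'   \item{Model 3}{Resource competition: a fixed resource pool can support
#'     at most `resource * n_initial` replications per cycle; the per-cycle
#'     replication probability is `min(1, R / M_t)` where `M_t` is the
#'     population at the start of the cycle, so efficiency falls once the
#'     population exceeds the capacity.}
#'   \item{Model 4}{Decaying resource: as Model 3, but the resource is
#'     consumed (`resource_decay` units per successful replication, floor
#'     0).}
#'   \item{Model 5}{Variable efficiency: each molecule in each cycle draws a
#'     fresh efficiency from a Normal(`eff_mean`, `eff_sd`) restricted to
#'     [0, 1].}
#'   \item{Model 6}{Inherited efficiency: each initial molecule draws one
#'     efficiency from the restricted normal before cycle 1, and every
#'     descendant of that molecule replicates with that same efficiency in
#'     every cycle.}
#' }
#'
#' @param model Model id, 1--6.
#' @param cycles Number of PCR cycles.
#' @param efficiency Per-cycle replication probability (Models 1--2).
#' @param degradation Probability that a molecule that failed to replicate
#'   degrades (Model 2).
#' @param resource Resource capacity as a multiple of the initial molecule
#'   count (Models 3--4).
#' @param resource_decay Resource consumed per successful replication
#'   (Model 4).
#' @param eff_mean,eff_sd Mean and sd of the efficiency distribution before
#'   restriction to [0, 1] (Models 5--6).
#' @param error_rate Per-base, per-replication substitution probability.
#'   Zero keeps the fast count path; a positive rate tracks every molecule's
#'   sequence.
#' @return An object of class `model_config`.
#' @examples
#' model_config(1, cycles = 25, efficiency = 0.9)
#' model_config(6, cycles = 25, eff_mean = 0.3, eff_sd = 0.3)
#' @export
model_config <- function(model, cycles, efficiency = 0.9, degradation = 0,
                         resource = NULL, resource_decay = 0,
                         eff_mean = 0.9, eff_sd = 0, error_rate = 0) {
  if (!model %in% 1:6) stopf("`model` must be an integer 1..6")
  if (cycles < 1 || cycles != floor(cycles))
    stopf("`cycles` must be a positive integer")
  if (error_rate < 0 || error_rate > 1)
    stopf("`error_rate` must lie in [0, 1]")
  if (model %in% 1:2 && (efficiency < 0 || efficiency > 1))
    stopf("`efficiency` must lie in [0, 1]")
  if (model == 2 && (degradation < 0 || degradation > 1))
    stopf("`degradation` must lie in [0, 1]")
  if (model %in% 3:4) {
    if (is.null(resource) || resource <= 0)
      stopf("Models 3-4 need `resource` > 0 (multiple of initial molecules)")
    if (resource_decay < 0) stopf("`resource_decay` must be >= 0")
  }
  if (model %in% 5:6) {
    if (eff_sd < 0) stopf("`eff_sd` must be >= 0")
    if (eff_sd == 0 && (eff_mean < 0 || eff_mean > 1))
      stopf("with eff_sd = 0, `eff_mean` must lie in [0, 1]")
  }
  structure(list(model = as.integer(model), cycles = as.integer(cycles),
                 efficiency = efficiency, degradation = degradation,
                 resource = resource, resource_decay = resource_decay,
                 eff_mean = eff_mean, eff_sd = eff_sd,
                 error_rate = error_rate),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  pars <- switch(x$model,
    sprintf("efficiency = %g", x$efficiency),
    sprintf("efficiency = %g, degradation = %g", x$efficiency,
            x$degradation),
    sprintf("resource = %g x initial", x$resource),
    sprintf("resource = %g x initial, decay = %g", x$resource,
            x$resource_decay),
    sprintf("efficiency ~ N(%g, %g) on [0,1], fresh each cycle", x$eff_mean,
            x$eff_sd),
    sprintf("efficiency ~ N(%g, %g) on [0,1], inherited per lineage",
            x$eff_mean, x$eff_sd))
  cat(sprintf("PCR model %d: %s; %d cycles; error rate %g\n",
              x$model, pars, x$cycles, x$error_rate))
  invisible(x)
}

#' Draw from a normal distribution restricted to [0, 1]
#'
#' Exact truncated-normal sampling by inversion of the CDF conditional on
#' [0, 1]; no probability mass accumulates at the boundaries (the
#' distribution is truncated, not clipped).  `sd = 0` returns `mean`
#' unchanged (which must then lie in [0, 1]).
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale of the unrestricted normal.
#' @param seed Optional integer seed.
#' @return Numeric vector of draws in (0, 1) (or exactly `mean` if
#'   `sd = 0`).
#' @export
rtrunc01_norm <- function(n, mean, sd, seed = NULL) {
  if (sd < 0) stopf("`sd` must be >= 0")
  if (sd == 0) {
    if (mean < 0 || mean > 1) stopf("with sd = 0, `mean` must lie in [0, 1]")
    return(rep(mean, n))
  }
  lo <- pnorm(0, mean, sd)
  hi <- pnorm(1, mean, sd)
  if (hi - lo < 1e-12)
    stopf("the normal(%g, %g) has essentially no mass in [0, 1]", mean, sd)
  with_seed_maybe(seed, qnorm(lo + runif(n) * (hi - lo), mean, sd))
}

# Mean of the [0,1]-truncated normal (closed form).
truncnorm01_mean <- function(mean, sd) {
  if (sd == 0) return(mean)
  a <- (0 - mean) / sd
  b <- (1 - mean) / sd
  z <- pnorm(b) - pnorm(a)
  mean + sd * (dnorm(a) - dnorm(b)) / z
}

check_copy_range <- function(copies) {
  if (max(copies) >= 2^31 - 1)
    stopf("per-lineage copy number exceeds 2^31 - 1; reduce cycles")
  invisible(TRUE)
}

#' One PCR cycle under each branching-process model (count path)
#'
#' Low-level per-cycle kernels operating on the vector of per-lineage copy
#' numbers; [amplify()] drives them over many cycles.  All use R's global
#' RNG (seed control belongs to the driver).
#'
#' @param copies Integer/numeric vector of current copy numbers per lineage.
#' @param efficiency Per-cycle replication probability.
#' @return Updated copy vector; `cycle_model4()` returns
#'   `list(copies, resource)`.
#' @seealso [amplify()], [model_config()]
#' @examples
#' set.seed(1)
#' cycle_model1(c(5, 5), efficiency = 1)   # deterministic doubling
#' @export
cycle_model1 <- function(copies, efficiency) {
  check_copy_range(copies)
  copies + rbinom(length(copies), copies, efficiency)
}

#' @rdname cycle_model1
#' @param degradation Probability that a molecule that failed to replicate
#'   degrades this cycle (Model 2).
#' @export
cycle_model2 <- function(copies, efficiency, degradation) {
  check_copy_range(copies)
  s <- rbinom(length(copies), copies, efficiency)
  g <- rbinom(length(copies), copies - s, degradation)
  copies + s - g
}

#' @rdname cycle_model1
#' @param resource Absolute resource capacity: the number of replications
#'   the reaction can support in one cycle (Models 3--4).
#' @export
cycle_model3 <- function(copies, resource) {
  check_copy_range(copies)
  if (resource <= 0) stopf("`resource` must be positive")
  p <- min(1, resource / sum(copies))
  copies + rbinom(length(copies), copies, p)
}

#' @rdname cycle_model1
#' @param resource_decay Resource consumed per successful replication
#'   (Model 4).
#' @export
cycle_model4 <- function(copies, resource, resource_decay) {
  check_copy_range(copies)
  if (resource < 0) stopf("`resource` must be >= 0")
  p <- if (resource <= 0) 0 else min(1, resource / sum(copies))
  s <- rbinom(length(copies), copies, p)
  list(copies = copies + s,
       resource = max(0, resource - resource_decay * sum(s)))
}

#' @rdname cycle_model1
#' @param eff_mean,eff_sd Efficiency distribution: Normal(`eff_mean`,
#'   `eff_sd`) restricted to [0, 1].  Model 5 draws a fresh efficiency for
#'   every molecule in every cycle.
#' @export
cycle_model5 <- function(copies, eff_mean, eff_sd) {
  check_copy_range(copies)
  m <- sum(copies)
  if (m >= 2^31 - 1)
    stopf("Model 5 draws one efficiency per molecule; population too large")
  e <- rtrunc01_norm(m, eff_mean, eff_sd)
  succ <- runif(m) < e
  cs <- cumsum(as.double(succ))
  bounds <- cumsum(copies)
  copies + diff(c(0, cs[bounds]))
}

#' @rdname cycle_model1
#' @param lineage_efficiency Vector of inherited efficiencies, one per
#'   lineage (Model 6; drawn once before cycle 1).
#' @export
cycle_model6 <- function(copies, lineage_efficiency) {
  check_copy_range(copies)
  if (length(lineage_efficiency) != length(copies))
    stopf("one inherited efficiency per lineage is required")
  if (any(is.na(lineage_efficiency)) || any(lineage_efficiency < 0) ||
      any(lineage_efficiency > 1))
    stopf("inherited efficiencies must lie in [0, 1]")
  copies + rbinom(length(copies), copies, lineage_efficiency)
}

#' Expected copies of one template after c cycles of branching PCR
#'
#' Closed form for the constant-efficiency branching process: each cycle
#' multiplies the expected population by `1 + e`, so one template yields
#' `(1 + e)^c` expected copies.
#'
#' @param efficiency Per-cycle replication probability `e`.
#' @param cycles Number of cycles `c`.
#' @return `(1 + efficiency)^cycles`.
#' @examples
#' expected_final_copies(1, 10)     # 1024
#' expected_final_copies(0.8, 15)   # ~1.47e4
#' @export
expected_final_copies <- function(efficiency, cycles) {
  stopifnot(efficiency >= 0, efficiency <= 1, cycles >= 0)
  (1 + efficiency)^cycles
}

#' Copy a sequence with per-base substitution error
#'
#' Models erroneous replication: each position of each input sequence is
#' substituted independently with probability `error_rate`; a substituted
#' position takes one of the three other bases uniformly at random.  The
#' input (the "parent" molecule) is never modified -- replication copies the
#' parent and mutates the copy.
#'
#' @param sequence Character vector of A/C/G/T sequences.
#' @param error_rate Per-base substitution probability in [0, 1].
#' @param seed Optional integer seed.
#' @return Character vector of mutated copies.
#' @examples
#' mutate_copy("ACGTACGT", 0)   # identical copy
#' mutate_copy("AAAA", 1, seed = 1)   # every base differs
#' @export
mutate_copy <- function(sequence, error_rate, seed = NULL) {
  if (error_rate < 0 || error_rate > 1)
    stopf("`error_rate` must lie in [0, 1]")
  if (!length(sequence)) return(sequence)
  codes <- utf8ToInt(paste(sequence, collapse = ""))
  base_codes <- utf8ToInt("ACGT")
  idx <- match(codes, base_codes)
  if (anyNA(idx)) stopf("sequences must contain only A, C, G, T")
  if (error_rate > 0) {
    with_seed_maybe(seed, {
      hit <- which(runif(length(codes)) < error_rate)
      if (length(hit)) {
        shift <- sample.int(3L, length(hit), replace = TRUE)
        codes[hit] <- base_codes[(idx[hit] - 1L + shift) %% 4L + 1L]
      }
    })
  }
  len <- nchar(sequence)
  ends <- cumsum(len)
  starts <- ends - len + 1L
  big <- intToUtf8(codes)
  substring(big, starts, ends)
}

#' Amplify labelled molecules through PCR cycles
#'
#' Runs `cycles` rounds of the configured branching-process model over a set
#' of lineages (one lineage per initial template molecule).  With
#' `error_rate = 0` amplification uses a fast count path (one binomial draw
#' per lineage per cycle); with a positive error rate every molecule's
#' sequence is tracked, each successful replication copies the parent and
#' applies [mutate_copy()].
#'
#' @param lineages One of: a positive integer (that many lineages, one
#'   starting copy each), a [label_molecules()] object (one lineage per
#'   labelled molecule, carrying its barcode), or a numeric vector of
#'   initial copy numbers per lineage.
#' @param config A [model_config()].
#' @param seed Optional integer seed.
#' @param insert Template sequence appended after the barcode when molecule
#'   sequences are materialised (sequence path only).
#' @param sequences Optional explicit character vector of initial molecule
#'   sequences (one per lineage); required on the sequence path if
#'   `lineages` is not a labelling.
#' @param cap Abort if the total population exceeds this many molecules
#'   (guards desk-scale runs; default 1e12 on the count path, 1e7 molecules
#'   on the sequence path).
#' @param path `"auto"` (count path when `error_rate = 0`, sequence path
#'   otherwise), or force `"count"` / `"sequence"`.  The two paths are
#'   distributionally equivalent in copy numbers; forcing `"sequence"` with
#'   a zero error rate is mainly useful for verifying that.
#' @return An object of class `amplified_pool`: `copies` (final copy number
#'   per lineage), `barcode` (barcode id per lineage or `NULL`),
#'   `inherited_efficiency` (Model 6), `trajectory` (total molecules after
#'   cycle 0..c), `total`, `molecules` (sequence path only: `sequence` and
#'   `lineage` vectors), `config`.
#' @examples
#' pool <- amplify(1000, model_config(1, cycles = 10, efficiency = 0.9),
#'                 seed = 1)
#' summary(pool)
#' @export
amplify <- function(lineages, config, seed = NULL, insert = "",
                    sequences = NULL, cap = NULL,
                    path = c("auto", "count", "sequence")) {
  stopifnot(inherits(config, "model_config"))
  path <- match.arg(path)
  lab <- NULL
  if (inherits(lineages, "labelling")) {
    lab <- lineages
    copies <- rep(1, lab$n)
    barcode <- lab$assignments
  } else if (is.numeric(lineages) && length(lineages) == 1L &&
             lineages >= 1 && lineages == floor(lineages)) {
    copies <- rep(1, lineages)
    barcode <- NULL
  } else if (is.numeric(lineages) && length(lineages) > 1L) {
    if (any(lineages < 1 | lineages != floor(lineages)))
      stopf("initial copy numbers must be positive integers")
    copies <- as.numeric(lineages)
    barcode <- NULL
  } else stopf("`lineages` must be a count, a labelling, or a copy vector")

  n_lin <- length(copies)
  seq_path <- switch(path, auto = config$error_rate > 0,
                     count = FALSE, sequence = TRUE)
  if (!seq_path && config$error_rate > 0)
    stopf("replication error requires the sequence path")
  if (is.null(cap)) cap <- if (seq_path) 1e7 else 1e12
  resource_abs <- if (config$model %in% 3:4) config$resource * sum(copies)

  with_seed_maybe(seed, {
    eff <- if (config$model == 6L)
      rtrunc01_norm(n_lin, config$eff_mean, config$eff_sd)

    if (seq_path) {
      if (is.null(sequences)) {
        if (is.null(lab))
          stopf("sequence path needs a labelling or explicit `sequences`")
        sequences <- paste0(barcode_seq(barcode, lab$pool$L), insert)
      }
      if (length(sequences) != n_lin)
        stopf("`sequences` must have one entry per lineage")
      res <- amplify_sequences(copies, sequences, config, eff, resource_abs,
                               cap)
    } else {
      res <- amplify_counts(copies, config, eff, resource_abs, cap)
    }
  })

  structure(list(copies = res$copies, barcode = barcode,
                 inherited_efficiency = eff,
                 trajectory = res$trajectory, total = sum(res$copies),
                 molecules = res$molecules,
                 n_lineages = n_lin, insert = insert,
                 pool = if (!is.null(lab)) lab$pool,
                 config = config, seed = seed),
            class = "amplified_pool")
}

amplify_counts <- function(copies, config, eff, resource_abs, cap) {
  trajectory <- numeric(config$cycles + 1L)
  trajectory[1L] <- sum(copies)
  for (t in seq_len(config$cycles)) {
    copies <- switch(config$model,
      cycle_model1(copies, config$efficiency),
      cycle_model2(copies, config$efficiency, config$degradation),
      cycle_model3(copies, resource_abs),
      {
        upd <- cycle_model4(copies, resource_abs, config$resource_decay)
        resource_abs <- upd$resource
        upd$copies
      },
      cycle_model5(copies, config$eff_mean, config$eff_sd),
      cycle_model6(copies, eff))
    trajectory[t + 1L] <- sum(copies)
    if (trajectory[t + 1L] > cap)
      stopf("population %.3g exceeds cap %.3g after cycle %d",
            trajectory[t + 1L], cap, t)
  }
  list(copies = copies, trajectory = trajectory, molecules = NULL)
}

amplify_sequences <- function(copies, sequences, config, eff, resource_abs,
                              cap) {
  # flat molecule store: sequence + lineage index
  n_lin <- length(copies)
  lin <- rep(seq_len(n_lin), times = copies)
  seqs <- rep(sequences, times = copies)
  trajectory <- numeric(config$cycles + 1L)
  trajectory[1L] <- length(seqs)

  for (t in seq_len(config$cycles)) {
    m <- length(seqs)
    p <- switch(config$model,
      config$efficiency,
      config$efficiency,
      min(1, resource_abs / m),
      if (resource_abs <= 0) 0 else min(1, resource_abs / m),
      rtrunc01_norm(m, config$eff_mean, config$eff_sd),
      eff[lin])
    sel <- runif(m) < p
    if (config$model == 4L)
      resource_abs <- max(0, resource_abs - config$resource_decay * sum(sel))
    offspring <- mutate_copy(seqs[sel], config$error_rate)
    off_lin <- lin[sel]
    if (config$model == 2L) {
      # molecules that failed to replicate may degrade this cycle
      deg <- !sel & runif(m) < config$degradation
      keep <- !deg
      seqs <- seqs[keep]
      lin <- lin[keep]
    }
    seqs <- c(seqs, offspring)
    lin <- c(lin, off_lin)
    trajectory[t + 1L] <- length(seqs)
    if (trajectory[t + 1L] > cap)
      stopf("population %.3g exceeds cap %.3g after cycle %d (sequence path)",
            trajectory[t + 1L], cap, t)
  }
  list(copies = as.numeric(tabulate(lin, n_lin)), trajectory = trajectory,
       molecules = list(sequence = seqs, lineage = lin))
}

#' @export
print.amplified_pool <- function(x, ...) {
  cat(sprintf("Amplified pool: %s lineages -> %s molecules after %d cycles (model %d)\n",
              format(x$n_lineages, big.mark = ","),
              format(x$total, big.mark = ","),
              x$config$cycles, x$config$model))
  invisible(x)
}

#' @export
summary.amplified_pool <- function(object, ...) {
  q <- stats::quantile(object$copies, c(0, 0.25, 0.5, 0.75, 1))
  out <- list(n_lineages = object$n_lineages, total = object$total,
              mean_copies = mean(object$copies),
              cv_copies = sd_pop(object$copies) / mean(object$copies),
              quantiles = q, config = object$config)
  class(out) <- "summary.amplified_pool"
  out
}

#' @export
print.summary.amplified_pool <- function(x, ...) {
  print(x$config)
  cat(sprintf("  %s lineages, %s molecules; mean copies %.4g, CV %.3f\n",
              format(x$n_lineages, big.mark = ","),
              format(x$total, big.mark = ","), x$mean_copies, x$cv_copies))
  cat("  copy quantiles:\n")
  print(x$quantiles)
  invisible(x)
}

# population standard deviation (denominator n)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
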