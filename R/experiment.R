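#' Run a full labelling / amplification / sampling experiment
#'
#' Drives the whole simulator pipeline -- barcode pool, labelling, PCR
#' amplification, subsampling, optional sequencing with error -- possibly
#' repeated, and aggregates the repeat family-size histograms as mean and
#' standard deviation per family-size bin.  Each stage of each repeat gets
#' its own deterministic seed derived from `seed`, so stages can be varied
#' independently and the whole run is reproducible bit for bit.
#'
#' @param n_molecules Number of initial template molecules to label.
#' @param model A [model_config()].
#' @param pool A [make_pool()] object, or `NULL` for a uniform pool of
#'   `4^barcode_length` barcodes.
#' @param barcode_length Barcode length used when `pool` is `NULL`.
#' @param sample_size,sample_ratio Molecules to sequence (exactly one;
#'   `sample_ratio` is relative to `n_molecules`).
#' @param seq_error_rate Per-base sequencing substitution rate (reads are
#'   only materialised when this is `> 0` or `emit_fastq = TRUE`).
#' @param repeats Number of repeated simulations.
#' @param seed Base integer seed.
#' @param dir Optional output directory: writes per-repeat family-size and
#'   trajectory TSVs, the aggregate table, a JSON summary and a JSON config
#'   sidecar (and FASTQ when reads are materialised).
#' @param emit_fastq Write reads as FASTQ when `dir` is given.
#' @param verbose Log one timestamped key=value line per stage.
#' @return An object of class `umi_experiment`: `repeats` (per repeat:
#'   `famsize`, `cv`, `ztp` fit, `total_molecules`), `aggregate` (data frame
#'   `family_size`, `mean_count`, `sd_count`), `files`, and the
#'   configuration echo.
#' @examples
#' ex <- run_experiment(500, model_config(1, cycles = 10, efficiency = 0.9),
#'                      sample_ratio = 1, repeats = 2, seed = 1)
#' ex$aggregate
#' @export
run_experiment <- function(n_molecules, model, pool = NULL,
                           barcode_length = 12,
                           sample_size = NULL, sample_ratio = NULL,
                           seq_error_rate = 0, repeats = 1, seed = 1,
                           dir = NULL, emit_fastq = FALSE,
                           verbose = FALSE) {
  stopifnot(inherits(model, "model_config"), repeats >= 1)
  if (is.null(pool)) pool <- make_pool(barcode_length)
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  files <- character(0)
  reps <- vector("list", repeats)
  want_reads <- seq_error_rate > 0 || emit_fastq

  for (r in seq_len(repeats)) {
    lab <- stage("labelling",
      label_molecules(pool, n_molecules, seed = stage_seed(seed, r, 1)),
      verbose, repeat_ = r, n = n_molecules)
    amp <- stage("amplification",
      amplify(lab, model, seed = stage_seed(seed, r, 2)),
      verbose, repeat_ = r, model = model$model, cycles = model$cycles)
    smp <- stage("sampling",
      subsample(amp, size = sample_size, ratio = sample_ratio,
                seed = stage_seed(seed, r, 3)),
      verbose, repeat_ = r, size = sample_size %||% sample_ratio)
    fam <- family_size_distribution(smp)
    reads <- NULL
    if (want_reads)
      reads <- stage("sequencing",
        sequence_reads(amp, smp, error_rate = seq_error_rate,
                       seed = stage_seed(seed, r, 4)),
        verbose, repeat_ = r, error_rate = seq_error_rate)
    reps[[r]] <- list(famsize = fam,
                      cv = if (fam$n_families >= 2)
                        coefficient_of_variation(fam) else NA_real_,
                      ztp = fit_ztp_mle(fam),
                      total_molecules = amp$total)
    if (!is.null(dir)) {
      f1 <- file.path(dir, sprintf("family_sizes_rep%d.tsv", r))
      write_family_sizes(fam, f1)
      f2 <- file.path(dir, sprintf("trajectory_rep%d.tsv", r))
      write_trajectory(amp, f2)
      files <- c(files, f1, f2)
      if (want_reads && emit_fastq) {
        f3 <- file.path(dir, sprintf("reads_rep%d.fastq", r))
        write_fastq(reads, f3)
        files <- c(files, f3)
      }
    }
  }

  agg <- aggregate_famsizes(lapply(reps, `[[`, "famsize"))
  cfg <- list(n_molecules = n_molecules,
              pool = pool[c("L", "N", "dist")],
              model = unclass(model),
              sample_size = sample_size, sample_ratio = sample_ratio,
              seq_error_rate = seq_error_rate,
              repeats = repeats, seed = seed)
  if (!is.null(dir)) {
    fa <- file.path(dir, "family_sizes_aggregate.tsv")
    write.table(agg, fa, sep = "\t", quote = FALSE, row.names = FALSE)
    fs <- file.path(dir, "summary.json")
    jsonlite::write_json(list(
      config = cfg,
      repeats = lapply(reps, function(x)
        list(n_families = x$famsize$n_families, cv = x$cv,
             lambda = x$ztp$lambda, total_molecules = x$total_molecules))),
      fs, auto_unbox = TRUE, digits = NA, null = "null")
    fc <- file.path(dir, "config.json")
    jsonlite::write_json(cfg, fc, auto_unbox = TRUE, digits = NA,
                         null = "null")
    files <- c(files, fa, fs, fc)
  }
  structure(list(config = cfg, repeats = reps, aggregate = agg,
                 files = files),
            class = "umi_experiment")
}

stage <- function(.name, .expr, .verbose = FALSE, ...) {
  if (.verbose) log_line(.name, ...)
  tryCatch(.expr, error = function(e)
    stopf("stage '%s' failed: %s", .name, conditionMessage(e)))
}

stage_seed <- function(seed, rep, stage) {
  as.integer((as.numeric(seed) * 1000003 + rep * 1009 + stage * 101) %%
             2147483647)
}

aggregate_famsizes <- function(fams) {
  sizes <- sort(unique(unlist(lapply(fams, `[[`, "size"))))
  counts <- vapply(fams, function(f) {
    out <- numeric(length(sizes))
    out[match(f$size, sizes)] <- f$families
    out
  }, numeric(length(sizes)))
  counts <- matrix(counts, nrow = length(sizes))
  data.frame(family_size = sizes,
             mean_count = rowMeans(counts),
             sd_count = apply(counts, 1, sd))
}

#' @export
print.umi_experiment <- function(x, ...) {
  cat(sprintf("UMI experiment: %s molecules, model %d, %d repeat(s)\n",
              format(x$config$n_molecules, big.mark = ","),
              x$config$model$model, x$config$repeats))
  cvs <- vapply(x$repeats, `[[`, numeric(1), "cv")
  lams <- vapply(x$repeats, function(r) r$ztp$lambda, numeric(1))
  cat(sprintf("  family-size CV: %.3f (mean over repeats); ZTP lambda: %.4g\n",
              mean(cvs), mean(lams)))
  invisible(x)
}

#' Tabulate barcode-clash analytics over a grid
#'
#' For every combination of barcode length and molecule count, computes the
#' exact no-clash probability, its birthday approximation, and the expected
#' fraction of uniquely barcoded molecules (all for a uniform pool of
#' `4^L` barcodes).
#'
#' @param lengths Vector of barcode lengths.
#' @param n_molecules Vector of molecule counts.
#' @param path Optional TSV output path.
#' @return A data frame with one row per (length, count) pair.
#' @examples
#' clash_scan(c(6, 12), c(10, 1000))
#' @export
clash_scan <- function(lengths, n_molecules, path = NULL) {
  if (!length(lengths) || !length(n_molecules))
    stopf("`lengths` and `n_molecules` must be non-empty")
  grid <- expand.grid(L = lengths, n = n_molecules)
  grid$N <- pool_size(1)^grid$L
  grid$p_no_clash <- mapply(prob_no_clash, grid$n, grid$N)
  grid$p_no_clash_approx <- mapply(prob_no_clash, grid$n, grid$N,
                                   MoreArgs = list(method = "approx"))
  grid$expected_unique_fraction <- mapply(expected_unique_fraction,
                                          grid$n, grid$N)
  if (!is.null(path)) {
    write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  grid
}
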