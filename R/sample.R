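#' Subsample molecules from an amplified pool for sequencing
#'
#' Emulates loading the sequencer: `size` molecules are drawn uniformly at
#' random *without replacement* from the amplified pool (each physical
#' molecule can be loaded at most once).  On the count path this is a
#' multivariate hypergeometric draw over lineage copy numbers; lineages from
#' which no molecule is drawn are simply unobserved, which is what makes
#' downstream family-size distributions zero-truncated.
#'
#' @param pool An [amplify()] object.
#' @param size Number of molecules to sequence, or
#' @param ratio alternatively the sample ratio: molecules sequenced per
#'   initial template molecule (`size = round(ratio * n_lineages)`).
#' @param seed Optional integer seed.
#' @return An object of class `molecule_sample`: `size`, `lineage`
#'   (lineage id per observed family), `count` (molecules sampled from that
#'   lineage), `barcode` (per observed family, when the pool carries
#'   barcodes), `molecule_index` (sequence path only: which molecule of each
#'   lineage), and provenance fields.
#' @examples
#' pool <- amplify(1000, model_config(1, cycles = 8, efficiency = 1),
#'                 seed = 1)
#' s <- subsample(pool, ratio = 1, seed = 2)
#' head(s$count)
#' @export
subsample <- function(pool, size = NULL, ratio = NULL, seed = NULL) {
  stopifnot(inherits(pool, "amplified_pool"))
  if (is.null(size) == is.null(ratio))
    stopf("give exactly one of `size` or `ratio`")
  if (!is.null(ratio)) {
    if (ratio <= 0) stopf("`ratio` must be positive")
    size <- round(ratio * pool$n_lineages)
  }
  if (size < 1 || size != floor(size))
    stopf("`size` must be a positive integer")
  total <- pool$total
  if (size > total)
    stopf("sampling stage: cannot draw %s molecules from a pool of %s",
          format(size, big.mark = ","), format(total, big.mark = ","))

  pos <- with_seed_maybe(seed, sample_positions(total, size))
  cs <- cumsum(pool$copies)
  idx <- findInterval(pos, c(0, cs), left.open = TRUE)
  counts <- tabulate(idx, pool$n_lineages)
  obs <- which(counts > 0L)

  mol_idx <- NULL
  if (!is.null(pool$molecules))
    mol_idx <- pos - c(0, cs)[idx]   # which molecule within its lineage

  structure(list(size = size, lineage = obs, count = counts[obs],
                 barcode = if (!is.null(pool$barcode)) pool$barcode[obs],
                 positions = pos, lineage_of_position = idx,
                 molecule_index = mol_idx,
                 n_lineages = pool$n_lineages, pool_total = total,
                 seed = seed),
            class = "molecule_sample")
}

# Uniform sample of `size` distinct positions from 1..total, supporting
# totals beyond the integer range (positions are exact doubles < 2^53).
sample_positions <- function(total, size) {
  if (size == total) return(seq_len(total))
  if (total <= .Machine$integer.max)
    return(sort(sample.int(total, size)))
  if (size > total / 2)
    stopf("sampling more than half of a pool larger than 2^31 is unsupported")
  pos <- unique(floor(runif(size) * total) + 1)
  while (length(pos) < size) {
    extra <- floor(runif(size - length(pos)) * total) + 1
    pos <- unique(c(pos, extra))
  }
  sort(pos)
}

#' @export
print.molecule_sample <- function(x, ...) {
  cat(sprintf("Molecule sample: %s molecules from %s (%s families observed)\n",
              format(x$size, big.mark = ","),
              format(x$pool_total, big.mark = ","),
              format(length(x$lineage), big.mark = ",")))
  invisible(x)
}

#' Sequence sampled molecules into reads
#'
#' Turns every sampled molecule into one read, applying per-base sequencing
#' error with the same substitution model as [mutate_copy()].  On the count
#' path (no PCR error was simulated) every molecule of a lineage carries the
#' lineage's pristine sequence (barcode + insert); on the sequence path each
#' sampled molecule contributes its own PCR-mutated sequence, so barcode
#' positions can already carry PCR errors before sequencing error is added.
#'
#' @param pool The [amplify()] object that was sampled.
#' @param sample A [subsample()] of that pool.
#' @param error_rate Per-base sequencing substitution probability.
#' @param read_length Optional read length; longer molecules are truncated,
#'   `NULL` reads the full molecule.
#' @param seed Optional integer seed.
#' @return An object of class `read_set`: a data frame `reads` with columns
#'   `read_id`, `lineage`, `barcode` (id or `NA`), `sequence`, plus fields
#'   `error_rate` and `quality_char` (constant placeholder quality,
#'   Phred 40).
#' @export
sequence_reads <- function(pool, sample, error_rate = 0, read_length = NULL,
                           seed = NULL) {
  stopifnot(inherits(pool, "amplified_pool"),
            inherits(sample, "molecule_sample"))
  if (sample$size < 1) stopf("empty sample")

  if (!is.null(pool$molecules)) {
    # sequence path: look up each sampled molecule's own sequence.
    # molecules are stored grouped by generation; the sampler indexes them
    # by (lineage, within-lineage rank), an arbitrary but fixed bijection
    # (molecules within a lineage are exchangeable).
    by_lin <- split(pool$molecules$sequence, pool$molecules$lineage)
    lin_pos <- sample$lineage_of_position
    within <- sample$molecule_index
    tmpl <- character(sample$size)
    for (grp in split(seq_len(sample$size), lin_pos))
      tmpl[grp] <- by_lin[[as.character(lin_pos[grp[1]])]][within[grp]]
    lineage <- lin_pos
    barcode <- if (!is.null(pool$barcode)) pool$barcode[lineage]
  } else {
    lineage <- rep(sample$lineage, times = sample$count)
    barcode <- if (!is.null(pool$barcode)) pool$barcode[lineage]
    tmpl <- if (!is.null(pool$barcode))
      paste0(barcode_seq(barcode, pool$pool$L), pool$insert)
    else if (nzchar(pool$insert))
      rep(pool$insert, length(lineage))
    else
      stopf("pool has no sequences: amplify a labelling or give an insert")
  }

  reads <- with_seed_maybe(seed, mutate_copy(tmpl, error_rate))
  if (!is.null(read_length))
    reads <- substr(reads, 1L, read_length)

  structure(list(reads = data.frame(
                   read_id = sprintf("read_%d", seq_along(reads)),
                   lineage = lineage,
                   barcode = if (is.null(barcode)) NA_integer_ else barcode,
                   sequence = reads,
                   stringsAsFactors = FALSE),
                 error_rate = error_rate, quality_char = "I",
                 barcode_length = if (!is.null(pool$pool)) pool$pool$L,
                 seed = seed),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("Read set: %s reads (sequencing error rate %g)\n",
              format(nrow(x$reads), big.mark = ","), x$error_rate))
  invisible(x)
}

#' Write a read set as FASTQ
#'
#' Standard 4-line FASTQ via Biostrings; the header comment carries the
#' originating lineage and barcode id so ground truth survives into the
#' file.  Qualities are a constant Phred-40 placeholder (quality simulation
#' is out of scope).  A `.gz` path is compressed.
#'
#' @param reads A [sequence_reads()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  r <- reads$reads
  dna <- Biostrings::DNAStringSet(r$sequence)
  names(dna) <- sprintf("%s lineage=%d barcode=%s", r$read_id, r$lineage,
                        ifelse(is.na(r$barcode), ".", r$barcode))
  qual <- Biostrings::BStringSet(strrep(reads$quality_char, nchar(r$sequence)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
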