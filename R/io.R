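#' Read and write family-size tables
#'
#' Family-size (and labelling-event) histograms travel as 2-column TSV with
#' a header line: `family_size`, `count`.
#'
#' @param x A `famsize_dist` (or anything [family_size_distribution()]
#'   accepts).
#' @param path File path.
#' @return `write_family_sizes()` returns `path` invisibly;
#'   `read_family_sizes()` returns a `famsize_dist`.
#' @export
write_family_sizes <- function(x, path) {
  d <- as_famsize(x)
  write.table(data.frame(family_size = d$size, count = d$families),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_family_sizes
#' @export
read_family_sizes <- function(path) {
  tab <- read.delim(path, header = TRUE)
  if (!all(c("family_size", "count") %in% names(tab)))
    stopf("%s: expected columns family_size, count", path)
  family_size_distribution(rep(tab$family_size, times = tab$count))
}

#' Write a fit as JSON
#'
#' Serialises a [fit_ztp_mle()] or [fit_zt_mixed_poisson()] result as a
#' small JSON object (`K`, `weights`, `rates`, `loglik`, `aic`,
#' `converged` for the mixture; `lambda`, `loglik` and the chi-squared GOF
#' for the plain ZTP fit).
#'
#' @param fit The fitted object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  out <- if (inherits(fit, "ztmix_fit")) {
    list(K = fit$K, weights = fit$weights, rates = fit$rates,
         loglik = fit$loglik, aic = fit$aic, converged = fit$converged)
  } else if (inherits(fit, "ztp_fit")) {
    list(lambda = fit$lambda, loglik = fit$loglik, boundary = fit$boundary,
         chi2_stat = fit$chi2_stat, chi2_df = fit$chi2_df,
         chi2_p = fit$chi2_p)
  } else stopf("`fit` must be a ztp_fit or ztmix_fit")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Export amplified-pool tables
#'
#' `write_lineages()` writes one row per lineage (`lineage_id`,
#' `barcode_id`, `inherited_efficiency`, `final_copies`);
#' `write_trajectory()` writes the per-cycle total population (`cycle`,
#' `total_molecules`, cycle 0 = before amplification).
#'
#' @param pool An [amplify()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineages <- function(pool, path) {
  stopifnot(inherits(pool, "amplified_pool"))
  tab <- data.frame(lineage_id = seq_len(pool$n_lineages),
                    barcode_id = pool$barcode %||% NA_integer_,
                    inherited_efficiency =
                      pool$inherited_efficiency %||% NA_real_,
                    final_copies = pool$copies)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lineages
#' @export
write_trajectory <- function(pool, path) {
  stopifnot(inherits(pool, "amplified_pool"))
  write.table(data.frame(cycle = seq_along(pool$trajectory) - 1L,
                         total_molecules = pool$trajectory),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# timestamped key=value log line
log_line <- function(stage, ...) {
  kv <- list(...)
  msg <- paste(sprintf("%s=%s", names(kv),
                       vapply(kv, function(v) format(v)[1], character(1))),
               collapse = " ")
  message(sprintf("[%s] stage=%s %s", format(Sys.time(), "%H:%M:%S"),
                  stage, msg))
}
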