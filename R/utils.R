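`%||%` <- function(a, b) if (is.null(a)) b else a

#' Logarithmically spaced bin edges
#'
#' @param from,to range of the bins.
#' @param per_decade number of bins per factor of 10.
#' @return numeric vector of bin edges.
#' @export
log_bins <- function(from = 1e3, to = 1e8, per_decade = 20) {
  stopifnot(from > 0, to > from, per_decade >= 1)
  n <- ceiling(log10(to / from) * per_decade)
  10^seq(log10(from), log10(to), length.out = n + 1)
}

#' Child seed for a replicate within an ensemble
#'
#' Deterministic counter scheme: replicate streams are derived from the
#' master seed, a condition index and a replicate index, so ensembles are
#' reproducible and independent of execution order.  The result is always
#' below 2^31 - 1.
#'
#' @param master_seed integer master seed.
#' @param condition integer condition index (1-based).
#' @param replicate integer replicate index (1-based).
#' @return integer seed.
#' @export
child_seed <- function(master_seed, condition = 1L, replicate = 1L) {
  m <- 2147483647
  as.integer((as.numeric(master_seed) %% m * 1000003 +
              as.numeric(condition) * 1009 +
              as.numeric(replicate)) %% m)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

geo_centers <- function(breaks) sqrt(breaks[-length(breaks)] * breaks[-1])

new_curve <- function(bin_centers, values, pair_counts, observable,
                      meta = list()) {
  stopifnot(length(bin_centers) == length(values),
            length(values) == length(pair_counts))
  structure(list(bin_centers = bin_centers, values = values,
                 pair_counts = pair_counts, observable = observable,
                 meta = meta),
            class = "srev_curve")
}

#' @export
print.srev_curve <- function(x, ...) {
  pop <- sum(x$pair_counts > 0)
  cat(sprintf("srev curve '%s': %d bins (%d populated), range [%g, %g]\n",
              x$observable, length(x$bin_centers), pop,
              min(x$bin_centers), max(x$bin_centers)))
  invisible(x)
}
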