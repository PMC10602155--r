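# Count, for every bead i, how many beads j > i have genomic separation
# cum[j] - cum[i] inside [lo, hi).  Separations are integers, so the
# half-open real window maps exactly onto the integer window
# [ceiling(lo), ceiling(hi) - 1]; findInterval on those integer offsets is
# exact.  Returns the per-bead counts and the first eligible j per bead.
.sep_counts <- function(cum, lo, hi) {
  hi_int <- ceiling(hi) - 1
  lo_int <- ceiling(lo)
  upper <- findInterval(cum + hi_int, cum)
  lower <- findInterval(cum + lo_int - 1, cum)
  counts <- upper - lower
  list(counts = counts, first = lower + 1L)
}

#' End-to-end distance versus genomic separation
#'
#' For each logarithmic genomic-separation bin, the mean squared spatial
#' distance over bead pairs whose separation falls in the bin, reported as
#' sqrt of the mean.  Pairs are subsampled uniformly (bead i drawn with
#' probability proportional to its number of eligible partners, partner j
#' uniform among them), capped at \code{max_pairs} per bin.
#'
#' @param config a relaxed \code{srev_config}.
#' @param annotation the matching \code{\link{annotate}} result.
#' @param bins genomic-separation bin edges in bp (default 20 per decade
#'   over 10^3..10^8).
#' @param max_pairs subsampling cap per bin.
#' @param seed optional seed for the subsampling.
#' @return \code{srev_curve} with values sqrt(<R^2(s)>) in nm;
#'   \code{meta$mean_sq} keeps <R^2> for ensemble averaging.
#' @export
end_to_end_curve <- function(config, annotation, bins = log_bins(),
                             max_pairs = 1e5, seed = NULL) {
  stopifnot(inherits(config, "srev_config"),
            inherits(annotation, "srev_annotation"))
  if (nrow(config$coords) < 2) stop("configuration has fewer than 2 beads")
  set_seed_if(seed)
  cum <- annotation$cumulative_bp
  nb <- length(bins) - 1L
  msq <- rep(NA_real_, nb)
  npairs <- numeric(nb)
  for (k in seq_len(nb)) {
    sc <- .sep_counts(cum, bins[k], bins[k + 1])
    tot <- sum(sc$counts)
    if (tot == 0) next
    m <- as.integer(min(max_pairs, tot))
    i <- sample.int(length(cum), m, replace = TRUE, prob = sc$counts)
    j <- sc$first[i] + floor(runif(m) * sc$counts[i])
    d2 <- .pair_sqdist_cpp(config$coords, i, as.integer(j))
    msq[k] <- mean(d2)
    npairs[k] <- m
  }
  cv <- new_curve(geo_centers(bins), sqrt(msq), npairs, "end_to_end",
                  meta = list(bins = bins, mean_sq = msq,
                              max_pairs = max_pairs))
  cv
}

#' Contact probability versus genomic separation
#'
#' All bead pairs closer than \code{cutoff} nm are enumerated with a cell
#' list and their genomic separations histogrammed; each bin is normalised
#' by the exact number of bead pairs at separations in the bin (computed
#' from the cumulative-bp sequence), so Cp(s) is a probability.
#'
#' @param config a relaxed \code{srev_config}.
#' @param annotation the matching annotation.
#' @param cutoff spatial contact distance, nm.
#' @param bins genomic-separation bin edges in bp.
#' @param method \code{"cell"} (cell list) or \code{"brute"} (O(N^2)
#'   oracle, small N only).
#' @return \code{srev_curve} with values in [0, 1]; \code{pair_counts} is
#'   the total number of bead pairs per bin.
#' @export
contact_probability <- function(config, annotation,
                                cutoff = config$params$contact_cutoff,
                                bins = log_bins(),
                                method = c("cell", "brute")) {
  stopifnot(inherits(config, "srev_config"),
            inherits(annotation, "srev_annotation"))
  if (cutoff <= 0) stop("cutoff must be positive")
  method <- match.arg(method)
  cum <- annotation$cumulative_bp
  counts <- if (method == "cell")
    .contact_hist_cpp(config$coords, cum, cutoff, bins)
  else
    .contact_hist_brute_cpp(config$coords, cum, cutoff, bins)
  nb <- length(bins) - 1L
  totals <- vapply(seq_len(nb), function(k)
    sum(.sep_counts(cum, bins[k], bins[k + 1])$counts), numeric(1))
  vals <- ifelse(totals > 0, counts / totals, NA_real_)
  new_curve(geo_centers(bins), vals, totals, "contact_probability",
            meta = list(bins = bins, cutoff = cutoff,
                        contact_counts = counts))
}

#' Log-log power-law fit of a curve
#'
#' Unweighted least squares of log(value) on log(abscissa) restricted to a
#' window; the slope is the scaling exponent (a Flory exponent for
#' end-to-end curves, the packing exponent D for G(r)).
#'
#' @param curve an \code{srev_curve}.
#' @param window abscissa window (same units as the curve's bin centers).
#' @return object of class \code{srev_fit}: \code{exponent},
#'   \code{prefactor}, \code{window}, \code{r_squared}, \code{n_points}.
#' @export
fit_power_law <- function(curve, window) {
  stopifnot(inherits(curve, "srev_curve"), length(window) == 2)
  keep <- curve$pair_counts > 0 & is.finite(curve$values) &
    curve$values > 0 & curve$bin_centers >= window[1] &
    curve$bin_centers <= window[2]
  if (sum(keep) < 3)
    stop(sprintf("power-law fit needs >= 3 populated bins in [%g, %g], got %d",
                 window[1], window[2], sum(keep)))
  lx <- log(curve$bin_centers[keep])
  ly <- log(curve$values[keep])
  fit <- lm(ly ~ lx)
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 1
  structure(list(exponent = unname(coef(fit)[2]),
                 prefactor = exp(unname(coef(fit)[1])),
                 window = window,
                 r_squared = r2,
                 n_points = sum(keep),
                 observable = curve$observable),
            class = "srev_fit")
}

#' @export
print.srev_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit (%s): exponent %.4f over [%g, %g] (R^2 = %.4f, %d points)\n",
    x$observable, x$exponent, x$window[1], x$window[2], x$r_squared,
    x$n_points))
  invisible(x)
}

#' Average curves over an ensemble of configurations
#'
#' Equal-weight average of per-configuration curves on a common bin grid.
#' End-to-end curves are averaged on the mean-squared scale (the ensemble
#' <R^2(s)>) and reported back as sqrt; other observables are averaged
#' directly.  Bins populated in no configuration stay empty.
#'
#' @param curves list of \code{srev_curve} objects with identical bins and
#'   observable.
#' @return an \code{srev_curve}.
#' @export
average_curves <- function(curves) {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, logical(1), "srev_curve")))
  obs <- unique(vapply(curves, `[[`, character(1), "observable"))
  stopifnot(length(obs) == 1)
  nb <- length(curves[[1]]$bin_centers)
  vals <- vapply(curves, function(cv)
    if (obs == "end_to_end") cv$meta$mean_sq else cv$values, numeric(nb))
  cnts <- vapply(curves, `[[`, numeric(nb), "pair_counts")
  if (nb == 1) { vals <- rbind(vals); cnts <- rbind(cnts) }
  pop <- unname(rowSums(cnts > 0))
  mean_vals <- unname(rowMeans(vals, na.rm = TRUE))
  mean_vals[pop == 0] <- NA_real_
  out_vals <- if (obs == "end_to_end") sqrt(mean_vals) else mean_vals
  cv <- new_curve(curves[[1]]$bin_centers, out_vals, pop, obs,
                  meta = c(curves[[1]]$meta,
                           list(n_configs = length(curves))))
  if (obs == "end_to_end") cv$meta$mean_sq <- mean_vals
  cv
}
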