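#' Geometric centre used by the density analyses
#'
#' The confinement during generation follows the running centre of mass,
#' so the centroid of the final configuration is the natural distinguished
#' point; all density analyses centre their grids and spheres on it unless
#' an explicit centre is given.
#'
#' @param config an \code{srev_config}.
#' @return length-3 numeric vector, nm.
#' @export
config_center <- function(config) {
  colMeans(config$coords)
}

#' Chromatin volume concentration in probing cubes
#'
#' Local volume fraction in a cubic grid of probing volumes (default
#' 6 x 6 x 6 cubes of edge 120 nm) centred on the configuration centre.
#' Each bead contributes its full volume to the cube containing its
#' centre; beads outside the grid are ignored.
#'
#' @param config a relaxed \code{srev_config}.
#' @param probe_edge cube edge, nm.
#' @param grid_n cubes per axis.
#' @param center grid centre (default \code{\link{config_center}}).
#' @return object of class \code{srev_cvc}: \code{values} (length
#'   grid_n^3 volume fractions), \code{counts}, and the grid spec.
#' @export
cvc_distribution <- function(config, probe_edge = config$params$probe_edge,
                             grid_n = 6L, center = NULL) {
  stopifnot(inherits(config, "srev_config"))
  center <- center %||% config_center(config)
  p <- config$params
  corner <- center - grid_n * probe_edge / 2
  ix <- floor((config$coords[, 1] - corner[1]) / probe_edge)
  iy <- floor((config$coords[, 2] - corner[2]) / probe_edge)
  iz <- floor((config$coords[, 3] - corner[3]) / probe_edge)
  inside <- ix >= 0 & ix < grid_n & iy >= 0 & iy < grid_n &
    iz >= 0 & iz < grid_n
  cell <- 1 + ix[inside] + grid_n * (iy[inside] + grid_n * iz[inside])
  counts <- tabulate(cell, nbins = grid_n^3)
  vbead <- 4 / 3 * pi * p$r0^3
  structure(list(values = counts * vbead / probe_edge^3,
                 counts = counts, probe_edge = probe_edge,
                 grid_n = as.integer(grid_n), center = center),
            class = "srev_cvc")
}

#' @export
print.srev_cvc <- function(x, ...) {
  cat(sprintf(
    "CVC over %d^3 cubes of edge %g nm: mean %.3f, max %.3f\n",
    x$grid_n, x$probe_edge, mean(x$values), max(x$values)))
  invisible(x)
}

#' Cumulative pair correlation G(r)
#'
#' Mean number of beads within distance r of a reference bead, tabulated
#' on a radial grid.  Reference beads are those inside a sphere of radius
#' \code{analysis_radius} about the centre (so the fit window stays clear
#' of edge effects); neighbours are counted anywhere.  G is an
#' unnormalised cumulative count: a constant factor does not affect the
#' log-log slope, which is the only quantity used downstream.
#'
#' @param config a relaxed \code{srev_config} (or any point cloud wrapped
#'   with \code{\link{as_chain_config}}).
#' @param analysis_radius reference-bead selection radius, nm.
#' @param r_max largest tabulated radius, nm.
#' @param dr radial grid spacing, nm.
#' @param center sphere centre (default configuration centroid).
#' @param method \code{"cell"} or \code{"brute"} (O(N_ref N) oracle).
#' @return \code{srev_curve} with values G(r) at the radial grid points;
#'   \code{pair_counts} is the reference-bead count.
#' @export
cumulative_pair_correlation <- function(config,
                                        analysis_radius =
                                          config$params$analysis_radius,
                                        r_max = 130, dr = 2, center = NULL,
                                        method = c("cell", "brute")) {
  stopifnot(inherits(config, "srev_config"))
  method <- match.arg(method)
  center <- center %||% config_center(config)
  x <- config$coords
  d2 <- (x[, 1] - center[1])^2 + (x[, 2] - center[2])^2 +
    (x[, 3] - center[3])^2
  ref <- which(d2 <= analysis_radius^2)
  if (length(ref) == 0) stop("no reference beads inside the analysis sphere")
  breaks <- seq(0, r_max, by = dr)
  G <- if (method == "cell") .gofr_cpp(x, ref, breaks)
       else .gofr_brute_cpp(x, ref, breaks)
  new_curve(breaks[-1], G, rep(length(ref), length(G)), "pair_correlation",
            meta = list(analysis_radius = analysis_radius, dr = dr,
                        n_ref = length(ref), center = center))
}

#' Packing exponent D of a G(r) curve
#'
#' Log-log least-squares slope of the cumulative pair correlation over the
#' fit window (default 40-120 nm).  Applied to a single configuration it
#' gives D_i; applied to an ensemble-mean curve it gives <D>.
#'
#' @param curve a G(r) \code{srev_curve}.
#' @param window radial fit window, nm.
#' @return an \code{srev_fit} whose \code{exponent} is D.
#' @export
packing_exponent <- function(curve, window = c(40, 120)) {
  fit_power_law(curve, window)
}

#' Local volume fraction in the analysis sphere
#'
#' phi_i = (number of bead centres within the sphere) (r0/radius)^3,
#' evaluated in the same sphere used for the per-configuration packing
#' exponent D_i.
#'
#' @param config a relaxed \code{srev_config}.
#' @param radius sphere radius, nm.
#' @param center sphere centre (default configuration centroid).
#' @return volume fraction.
#' @export
local_volume_fraction <- function(config,
                                  radius = config$params$analysis_radius,
                                  center = NULL) {
  stopifnot(inherits(config, "srev_config"))
  center <- center %||% config_center(config)
  x <- config$coords
  d2 <- (x[, 1] - center[1])^2 + (x[, 2] - center[2])^2 +
    (x[, 3] - center[3])^2
  sum(d2 <= radius^2) * (config$params$r0 / radius)^3
}

#' Block-average packing exponents
#'
#' Replaces consecutive non-overlapping groups of \code{group} D_i values
#' by their means (D_i*), mimicking measurements that average over a
#' larger region; any remainder is dropped.
#'
#' @param di numeric vector of per-configuration exponents.
#' @param group group size.
#' @return numeric vector of length \code{floor(length(di)/group)}.
#' @export
resample_di <- function(di, group = 10L) {
  n <- length(di)
  if (n < group) stop("need at least `group` values")
  m <- n %/% group
  colMeans(matrix(di[seq_len(m * group)], nrow = group))
}

#' Per-configuration packing summary
#'
#' D_i, phi_i and bookkeeping for one configuration, as used in ensemble
#' tables relating the packing exponent to the local volume fraction.
#'
#' @param config a relaxed \code{srev_config}.
#' @param annotation optional annotation (adds the mean linker).
#' @param window radial fit window for D_i, nm.
#' @return one-row \code{data.frame}.
#' @export
config_summary <- function(config, annotation = NULL, window = c(40, 120)) {
  g <- cumulative_pair_correlation(config, r_max = window[2] + 10)
  di <- packing_exponent(g, window)$exponent
  data.frame(alpha = config$params$alpha, phi = config$params$phi,
             Rc = config$params$Rc, n_beads = nrow(config$coords),
             seed = config$provenance$seed %||% NA_integer_,
             D_i = di,
             phi_i = local_volume_fraction(config),
             return_fraction = config$provenance$return_fraction %||% NA_real_,
             mean_linker = if (!is.null(annotation)) annotation$mean_linker
                           else NA_real_)
}
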