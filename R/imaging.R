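new_stack <- function(data, voxel_edge, origin, provenance = list()) {
  structure(list(data = data, voxel_edge = voxel_edge, origin = origin,
                 provenance = provenance),
            class = "srev_stack")
}

#' @export
print.srev_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "Density stack: %d x %d x %d voxels of %g nm (total intensity %.1f)\n",
    d[1], d[2], d[3], x$voxel_edge, sum(x$data)))
  invisible(x)
}

#' Voxelize a configuration into a density stack
#'
#' Each bead deposits one unit of mass as a 3-D Gaussian of width
#' \code{sigma}: its contribution to a voxel is the product over axes of
#' the integral of the 1-D normal density over the voxel extent
#' (differences of normal CDFs), truncated at \code{trunc_sd} standard
#' deviations so total deposited mass per bead is 1 to < 1e-4.
#'
#' @param config a relaxed \code{srev_config} or a coordinate matrix (nm).
#' @param voxel_edge voxel edge, nm.
#' @param sigma Gaussian width, nm (default: bead radius, keeping the
#'   stamp support about one bead across).
#' @param trunc_sd truncation of the stamp, standard deviations.
#' @param pad padding added around the bounding box, nm.
#' @return an \code{srev_stack}.
#' @export
voxelize <- function(config, voxel_edge = 5, sigma = 4.9, trunc_sd = 4.5,
                     pad = trunc_sd * sigma) {
  if (voxel_edge <= 0) stop("voxel_edge must be positive")
  coords <- if (inherits(config, "srev_config")) config$coords else config
  stopifnot(is.matrix(coords), ncol(coords) == 3)
  lo <- unname(apply(coords, 2, min)) - pad
  hi <- unname(apply(coords, 2, max)) + pad
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / voxel_edge)))
  v <- .voxelize_cpp(coords, lo, dims, voxel_edge, sigma, trunc_sd)
  new_stack(array(v, dim = dims), voxel_edge, lo,
            provenance = list(sigma = sigma, trunc_sd = trunc_sd,
                              n_beads = nrow(coords)))
}

#' Sum a stack along z into a single plane
#'
#' 2-D projection used to replicate image-based (tomography-style) domain
#' analysis on model stacks.
#'
#' @param stack an \code{srev_stack}.
#' @return an \code{srev_stack} whose third dimension is 1.
#' @export
project_stack <- function(stack) {
  stopifnot(inherits(stack, "srev_stack"))
  d <- dim(stack$data)
  flat <- array(rowSums(matrix(stack$data, nrow = d[1] * d[2], ncol = d[3])),
                dim = c(d[1], d[2], 1L))
  new_stack(flat, stack$voxel_edge, stack$origin,
            provenance = c(stack$provenance, list(projected = TRUE)))
}

#' Gaussian smoothing of a density stack
#'
#' Separable Gaussian filter with reflecting boundaries; 2-D stacks
#' (single plane) are smoothed in-plane only.
#'
#' @param stack an \code{srev_stack}.
#' @param sigma_vox Gaussian width in voxels.
#' @return smoothed \code{srev_stack}.
#' @export
smooth_stack <- function(stack, sigma_vox = 5) {
  stopifnot(inherits(stack, "srev_stack"), sigma_vox > 0)
  d <- dim(stack$data)
  v <- .smooth3d_cpp(as.numeric(stack$data), as.integer(d), sigma_vox)
  new_stack(array(v, dim = d), stack$voxel_edge, stack$origin,
            provenance = c(stack$provenance, list(smoothed = sigma_vox)))
}

#' Packing-domain centres as density maxima
#'
#' Gaussian-smooths the stack, then takes strict local maxima of the
#' density (26-neighbourhood; 8 in a projected plane) above a prominence
#' threshold, and greedily enforces a minimum mutual separation keeping
#' the brighter centre.
#'
#' @param stack an \code{srev_stack}.
#' @param smoothing_sigma Gaussian width in voxels applied before the
#'   maxima search (0 skips smoothing).
#' @param min_separation minimum centre separation, nm.
#' @param prominence intensity threshold; default twice the median
#'   non-zero voxel intensity of the (smoothed) stack.
#' @param clahe apply contrast-limited adaptive histogram equalisation
#'   (via EBImage) before the maxima search; available for projected
#'   (single-plane) stacks only, off by default for model stacks.
#' @param clahe_block CLAHE tile size in voxels.
#' @return matrix of centre coordinates (nm) with attribute
#'   \code{"intensity"}; zero rows when no maximum clears the threshold.
#' @export
find_domain_centers <- function(stack, smoothing_sigma = 5,
                                min_separation = 50, prominence = NULL,
                                clahe = FALSE, clahe_block = 120L) {
  stopifnot(inherits(stack, "srev_stack"))
  if (clahe) {
    d <- dim(stack$data)
    if (d[3] != 1L)
      stop("CLAHE preprocessing applies to projected (2-D) stacks only")
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("CLAHE preprocessing requires the EBImage package")
    mx <- max(stack$data)
    nx <- max(2L, as.integer(round(d[1] / clahe_block)))
    ny <- max(2L, as.integer(round(d[2] / clahe_block)))
    # clahe needs tile counts dividing the image; zero-pad, then crop
    px <- ceiling(d[1] / nx) * nx
    py <- ceiling(d[2] / ny) * ny
    padded <- matrix(0, px, py)
    padded[seq_len(d[1]), seq_len(d[2])] <- stack$data[, , 1] / mx
    plane <- EBImage::clahe(EBImage::Image(padded), nx = nx, ny = ny)
    eq <- as.matrix(plane)[seq_len(d[1]), seq_len(d[2])]
    stack <- new_stack(array(eq * mx, dim = d),
                       stack$voxel_edge, stack$origin,
                       provenance = c(stack$provenance,
                                      list(clahe = clahe_block)))
  }
  sm <- if (smoothing_sigma > 0) smooth_stack(stack, smoothing_sigma)
        else stack
  v <- sm$data
  if (is.null(prominence)) {
    nz <- v[v > 0]
    prominence <- if (length(nz)) 2 * median(nz) else Inf
  }
  d <- dim(v)
  idx <- .local_maxima_cpp(as.numeric(v), as.integer(d), prominence)
  if (nrow(idx) == 0)
    return(structure(matrix(numeric(0), 0, 3), intensity = numeric(0)))
  inten <- v[idx]
  ord <- order(inten, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  inten <- inten[ord]
  centers <- sweep((idx - 0.5) * stack$voxel_edge, 2, stack$origin, `+`)
  keep <- logical(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    sel <- centers[keep, , drop = FALSE]
    dmin <- sqrt(min(rowSums(sweep(sel, 2, centers[i, ], `-`)^2)))
    keep[i] <- dmin >= min_separation
  }
  structure(centers[keep, , drop = FALSE], intensity = inten[keep])
}

#' Mass-scaling curve about a domain centre
#'
#' For every voxel in a cubic window (default 11 voxels across) around the
#' centre, M(r) is the total stack intensity within radius r of that
#' voxel; the curves are averaged weighted by the seed-voxel intensity.
#' Distances are spherical in 3-D stacks and in-plane in projected stacks.
#'
#' @param stack an \code{srev_stack}.
#' @param center domain centre, nm.
#' @param window seed window width in voxels (odd).
#' @param r_max largest tabulated radius, nm.
#' @param dr radial spacing, nm (default one voxel).
#' @return \code{srev_curve} of M(r).
#' @export
mass_scaling <- function(stack, center, window = 11L, r_max = 150,
                         dr = stack$voxel_edge) {
  stopifnot(inherits(stack, "srev_stack"), length(center) >= 2)
  d <- dim(stack$data)
  e <- stack$voxel_edge
  cv <- as.integer(floor((center - stack$origin) / e)) + 1L
  hw <- window %/% 2
  margin <- hw + ceiling(r_max / e)
  lim <- if (d[3] == 1L) 2L else 3L
  for (ax in seq_len(lim)) {
    if (cv[ax] - margin < 1 || cv[ax] + margin > d[ax])
      stop("mass-scaling window exceeds the stack margin")
  }
  if (d[3] == 1L) cv[3] <- 1L
  breaks <- seq(0, r_max, by = dr)
  M <- .mass_scaling_cpp(as.numeric(stack$data), as.integer(d), e,
                         cv, as.integer(window), breaks)
  new_curve(breaks[-1], M, rep(1, length(M)), "mass_scaling",
            meta = list(center = center, window = window, dr = dr))
}

#' Radial chromatin concentration from a mass-scaling curve
#'
#' Converts cumulative mass (beads) within radius r into the volume
#' fraction occupied by bead volume: CVC(r) = M(r) (r0/r)^3.  In
#' projected (2-D) stacks the same ratio is used up to a constant
#' factor, which preserves the locations of minima — the only feature
#' the stopping criteria consume.
#'
#' @param mass_curve an M(r) \code{srev_curve}.
#' @param r0 bead radius, nm.
#' @return \code{srev_curve} of CVC(r).
#' @export
radial_cvc <- function(mass_curve, r0 = 4.9) {
  stopifnot(inherits(mass_curve, "srev_curve"),
            mass_curve$observable == "mass_scaling")
  r <- mass_curve$bin_centers
  new_curve(r, mass_curve$values * (r0 / r)^3, mass_curve$pair_counts,
            "radial_cvc", meta = mass_curve$meta)
}

#' Domain radius from the mass-scaling stopping criteria
#'
#' Fits M(r) = A r^D on an inner window, then walks outward and stops at
#' the smallest radius at which any of three criteria fires: (i) M(r)
#' deviates from the fitted power law by more than \code{dev_tol}
#' (relative); (ii) the local log-log slope over \code{slope_window}
#' consecutive samples reaches 3; (iii) the radial CVC passes a strict
#' local minimum and begins to increase.
#'
#' @param mass_curve an M(r) \code{srev_curve}.
#' @param cvc_curve matching radial-CVC curve (default derived from
#'   \code{mass_curve} via \code{\link{radial_cvc}}).
#' @param fit_window inner radial window (nm) for the power-law fit.
#' @param dev_tol relative deviation for criterion (i).
#' @param slope_window samples in the sliding local-slope fit.
#' @param center optional centre stored in the record.
#' @return a one-row \code{data.frame} (radius, criterion, exponent,
#'   centre) or \code{NULL} when no criterion fires before the curve ends
#'   (reason in attribute \code{"reason"}).
#' @export
domain_radius <- function(mass_curve, cvc_curve = NULL,
                          fit_window = c(10, 30), dev_tol = 0.05,
                          slope_window = 5L, center = c(NA, NA, NA)) {
  stopifnot(inherits(mass_curve, "srev_curve"))
  cvc_curve <- cvc_curve %||% radial_cvc(mass_curve)
  fit <- fit_power_law(mass_curve, fit_window)
  r <- mass_curve$bin_centers
  M <- mass_curve$values
  cvc <- cvc_curve$values
  lr <- log(r); lM <- log(pmax(M, .Machine$double.xmin))
  start <- which(r > fit_window[2])[1]
  if (is.na(start)) return(structure(NULL, reason = "curve ends inside fit window"))
  hw <- slope_window %/% 2
  for (k in start:length(r)) {
    pred <- fit$prefactor * r[k]^fit$exponent
    if (abs(M[k] - pred) / pred > dev_tol) {
      return(data.frame(x = center[1], y = center[2], z = center[3],
                        radius = r[k], criterion = "deviation",
                        exponent = fit$exponent))
    }
    # the CVC minimum is tested before the local slope: an upturn in the
    # radial CVC entails a local slope above 3, so on the sample where
    # both fire the minimum is the more specific description
    if (k >= 2 && k < length(r) &&
        cvc[k] < cvc[k - 1] && cvc[k + 1] > cvc[k]) {
      return(data.frame(x = center[1], y = center[2], z = center[3],
                        radius = r[k], criterion = "radial-CVC-minimum",
                        exponent = fit$exponent))
    }
    if (k - hw >= 1 && k + hw <= length(r)) {
      w <- (k - hw):(k + hw)
      sl <- coef(lm(lM[w] ~ lr[w]))[2]
      if (sl >= 3) {
        return(data.frame(x = center[1], y = center[2], z = center[3],
                          radius = r[k], criterion = "D=3",
                          exponent = fit$exponent))
      }
    }
  }
  structure(NULL, reason = "no stopping criterion fired")
}

#' Identify packing domains in a density stack
#'
#' Centre finding (\code{\link{find_domain_centers}}), mass scaling about
#' every centre and radius determination by the stopping criteria, in one
#' pass.  Centres too close to the stack boundary for the mass-scaling
#' window are skipped.
#'
#' @param stack an \code{srev_stack}.
#' @param smoothing_sigma,min_separation,prominence passed to the centre
#'   finder.
#' @param window,r_max passed to \code{\link{mass_scaling}}.
#' @param fit_window,dev_tol,slope_window passed to
#'   \code{\link{domain_radius}}.
#' @return \code{data.frame} of domain records (possibly zero rows).
#' @export
find_domains <- function(stack, smoothing_sigma = 5, min_separation = 50,
                         prominence = NULL, window = 11L, r_max = 150,
                         fit_window = c(10, 30), dev_tol = 0.05,
                         slope_window = 5L) {
  centers <- find_domain_centers(stack, smoothing_sigma, min_separation,
                                 prominence)
  recs <- list()
  for (i in seq_len(nrow(centers))) {
    rec <- tryCatch({
      m <- mass_scaling(stack, centers[i, ], window = window, r_max = r_max)
      domain_radius(m, fit_window = fit_window, dev_tol = dev_tol,
                    slope_window = slope_window, center = centers[i, ])
    }, error = function(e) NULL)
    if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
  }
  if (length(recs) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      radius = numeric(0), criterion = character(0),
                      exponent = numeric(0)))
  do.call(rbind, recs)
}

#' Summary statistics of domain radii
#'
#' @param records a domain \code{data.frame} from \code{\link{find_domains}}
#'   (optionally with condition columns).
#' @return list with mean, median, quartiles and count.
#' @export
domain_statistics <- function(records) {
  stopifnot(nrow(records) >= 1)
  q <- quantile(records$radius, c(0.25, 0.5, 0.75))
  list(n = nrow(records), mean_radius = mean(records$radius),
       q25 = unname(q[1]), median = unname(q[2]), q75 = unname(q[3]))
}
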