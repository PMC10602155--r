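#' Relaxation settings for overlap removal
#'
#' Tunables of the overdamped soft-repulsion relaxation that converts an
#' expanded SRRW trajectory into an overlap-free bead chain.  The repulsive
#' energy is k_rep (2 r0 - r)^2 for non-bonded pairs closer than the bead
#' diameter; bonds are harmonic with stiffness k_bond about an equilibrium
#' length of max(original step length, 2 r0).
#'
#' @param k_rep repulsion stiffness (energy nm^-2).
#' @param k_bond bond stiffness relative to the same energy unit.
#' @param step mobility: displacement per unit force per sweep (nm per
#'   force unit).
#' @param noise_amp amplitude (nm) of the zero-mean kicks applied to
#'   overlapping beads when convergence stalls; 0 disables noise.
#' @param tol relative overlap tolerance: relaxation stops once every
#'   non-bonded distance is >= 2 r0 (1 - tol).
#' @param check_interval sweeps between convergence checks.
#' @param max_sweeps hard cap on sweeps.
#' @param stall_boost factor applied to the repulsion stiffness (with the
#'   step shrunk by the same factor, preserving stability) whenever the
#'   minimum non-bonded distance stalls between checks: overlaps held in
#'   static balance against stretched bonds are squeezed out as the
#'   repulsion-to-bond stiffness ratio grows.  1 disables the boost.
#' @return object of class \code{srev_relax_settings}.
#' @export
relaxation_settings <- function(k_rep = 1, k_bond = 0.005, step = 0.2,
                                noise_amp = 0.1, tol = 1e-3,
                                check_interval = 10L, max_sweeps = 5000L,
                                stall_boost = 1.5) {
  stopifnot(k_rep > 0, k_bond > 0, step > 0, noise_amp >= 0,
            tol > 0, tol <= 1e-2, check_interval >= 1, max_sweeps >= 1,
            stall_boost >= 1)
  structure(list(k_rep = k_rep, k_bond = k_bond, step = step,
                 noise_amp = noise_amp, tol = tol,
                 check_interval = as.integer(check_interval),
                 max_sweeps = as.integer(max_sweeps),
                 stall_boost = stall_boost),
            class = "srev_relax_settings")
}

new_chain_config <- function(coords, params, bond_l0 = NULL, relaxed = FALSE,
                             provenance = list()) {
  n <- nrow(coords)
  bl <- if (n > 1) sqrt(rowSums((coords[-1, , drop = FALSE] -
                                 coords[-n, , drop = FALSE])^2)) else numeric(0)
  structure(list(coords = coords, bond_lengths = bl,
                 bond_l0 = bond_l0 %||% bl, params = params,
                 relaxed = relaxed, provenance = provenance),
            class = "srev_config")
}

#' @export
print.srev_config <- function(x, ...) {
  cat(sprintf(
    "SR-EV chain: %d beads (%s), alpha = %.3f, phi = %.3f\n",
    nrow(x$coords), if (x$relaxed) "relaxed" else "pre-relaxation",
    x$params$alpha, x$params$phi))
  if (!is.null(x$provenance$relaxation))
    cat(sprintf("  relaxation: %d sweeps, min non-bonded distance %.3f nm\n",
                x$provenance$relaxation$sweeps,
                x$provenance$relaxation$min_dist))
  invisible(x)
}

#' Expand an SRRW trajectory into a bead chain
#'
#' One bead per trajectory vertex, in trajectory order, with coordinates
#' scaled to nm.  Vertices made coincident by return steps are displaced by
#' independent uniform perturbations within a ball of radius 0.1 r0 so no
#' two centres coincide; this defines the separation directions for the
#' subsequent relaxation without distorting the clusters.  Bond equilibrium
#' lengths are taken from the unperturbed step lengths.
#'
#' @param traj an \code{\link{generate_srrw}} trajectory.
#' @param seed optional seed for the perturbations.
#' @return a pre-relaxation \code{srev_config}.
#' @export
expand_overlaps <- function(traj, seed = NULL) {
  stopifnot(inherits(traj, "srev_trajectory"))
  set_seed_if(seed)
  p <- traj$params
  coords <- traj$vertices * p$b
  n <- nrow(coords)
  # exact step lengths define the bond equilibria (in nm)
  step_len <- if (n > 1) sqrt(rowSums((coords[-1, , drop = FALSE] -
                                       coords[-n, , drop = FALSE])^2))
              else numeric(0)
  # group coincident vertices (retraced positions agree to rounding)
  key <- paste(round(coords[, 1], 6), round(coords[, 2], 6),
               round(coords[, 3], 6))
  dup <- duplicated(key)
  ndup <- sum(dup)
  if (ndup > 0) {
    r <- 0.1 * p$r0 * runif(ndup)^(1 / 3)
    z <- 2 * runif(ndup) - 1
    th <- 2 * pi * runif(ndup)
    s <- sqrt(pmax(0, 1 - z^2))
    coords[dup, ] <- coords[dup, , drop = FALSE] +
      cbind(r * s * cos(th), r * s * sin(th), r * z)
  }
  new_chain_config(coords, p, bond_l0 = pmax(step_len, 2 * p$r0),
                   relaxed = FALSE,
                   provenance = list(seed = seed,
                                     return_fraction = traj$return_fraction,
                                     n_coincident = ndup))
}

#' Relax bead overlaps with a soft repulsive potential
#'
#' Overdamped sweeps move every bead along the net force from (i) a soft
#' pairwise repulsion between non-bonded beads closer than the bead
#' diameter 2 r0, evaluated with a cell list of edge 2 r0, (ii) harmonic
#' bonds, and (iii) small zero-mean kicks to overlapping beads when the
#' minimum non-bonded distance stalls between checks.  The relaxation is
#' terminated at the first check at which all non-bonded distances are at
#' least 2 r0 (1 - tol).
#'
#' @param config a pre-relaxation \code{srev_config}.
#' @param settings a \code{\link{relaxation_settings}} object.
#' @param seed optional seed for the stall kicks.
#' @param record_energy record the repulsive energy per sweep (for
#'   diagnostics; adds negligible cost).
#' @return the relaxed \code{srev_config}; bond lengths are re-measured
#'   from the relaxed coordinates and \code{provenance$relaxation} carries
#'   the sweep count and final minimum non-bonded distance.
#' @export
relax_excluded_volume <- function(config, settings = relaxation_settings(),
                                  seed = NULL, record_energy = FALSE) {
  stopifnot(inherits(config, "srev_config"),
            inherits(settings, "srev_relax_settings"))
  set_seed_if(seed)
  p <- config$params
  res <- .relax_cpp(config$coords, config$bond_l0, p$r0,
                    settings$k_rep, settings$k_bond, settings$step,
                    settings$noise_amp, settings$tol,
                    settings$check_interval, settings$max_sweeps,
                    settings$stall_boost, record_energy)
  if (!res$converged)
    stop(sprintf(
      "relaxation did not resolve all overlaps in %d sweeps (min non-bonded distance %.4f nm, worst pair %d-%d)",
      res$sweeps, res$min_dist, res$worst_pair[1], res$worst_pair[2]))
  out <- new_chain_config(res$coords, p, bond_l0 = config$bond_l0,
                          relaxed = TRUE,
                          provenance = c(config$provenance,
                                         list(relaxation = list(
                                           sweeps = res$sweeps,
                                           min_dist = res$min_dist,
                                           converged = res$converged,
                                           energy_trace = res$energy_trace,
                                           settings = settings))))
  out
}

#' Validity report for a chain configuration
#'
#' Report-only checks of the configuration invariants: excluded volume
#' (minimum non-bonded distance >= 2 r0 (1 - tol)), linear connectivity,
#' finite coordinates, radius of gyration and maximum distance from the
#' centroid.
#'
#' @param config an \code{srev_config}.
#' @param tol relative overlap tolerance used for the pass/fail flag.
#' @return a list with per-check \code{pass} flags and measured values
#'   (including the indices of the worst non-bonded pair).
#' @export
verify_configuration <- function(config, tol = 1e-3) {
  stopifnot(inherits(config, "srev_config"))
  p <- config$params
  x <- config$coords
  n <- nrow(x)
  mn <- .min_nonbonded_cpp(x, 2 * p$r0)
  ctr <- colMeans(x)
  d2 <- rowSums((x - rep(ctr, each = n))^2)
  list(
    n_beads = n,
    overlap = list(pass = mn$min_dist >= 2 * p$r0 * (1 - tol),
                   min_dist = mn$min_dist, worst_pair = mn$pair),
    connectivity = list(pass = length(config$bond_lengths) == n - 1,
                        n_bonds = length(config$bond_lengths)),
    finite = list(pass = all(is.finite(x))),
    radius_of_gyration = sqrt(mean(d2)),
    max_from_centroid = sqrt(max(d2))
  )
}

#' Full SR-EV pipeline for one configuration
#'
#' Convenience wrapper: generate an SRRW, expand it into a bead chain and
#' relax the overlaps.  All randomness (walk, perturbations, stall kicks)
#' is drawn from a single stream seeded once with \code{seed}.
#'
#' @param params an \code{\link{model_params}} object.
#' @param seed integer seed for the configuration.
#' @param settings relaxation settings.
#' @param n_steps number of SRRW steps (default \code{params$n - 1}).
#' @return a relaxed \code{srev_config}; \code{provenance$return_fraction}
#'   records the SRRW return-step fraction.
#' @examples
#' \donttest{
#' p <- model_params(alpha = 1.15, phi = 0.12, Rc = 120)
#' cfg <- sr_ev_config(p, seed = 1)
#' verify_configuration(cfg)$overlap$pass
#' }
#' @export
sr_ev_config <- function(params, seed = NULL,
                         settings = relaxation_settings(),
                         n_steps = params$n - 1L) {
  set_seed_if(seed)
  traj <- generate_srrw(params, n_steps = n_steps)
  cfg <- expand_overlaps(traj)
  cfg <- relax_excluded_volume(cfg, settings)
  cfg$provenance$seed <- seed
  cfg
}
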