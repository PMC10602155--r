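#' Model parameters for an SR-EV configuration
#'
#' Collects the physical constants of the model and the two control
#' parameters: the folding parameter \code{alpha} (> 1), which governs both
#' the return probability and the tail of the jump-length distribution, and
#' the overall volume fraction \code{phi}, which sets the bead count via
#' \code{\link{n_beads_for_phi}}.
#'
#' Defaults correspond to nucleosome-scale chromatin: a unit (minimum jump)
#' length of 10 nm, bead non-overlap radius 4.9 nm (bead diameter 9.8 nm,
#' so beads across a minimum-length bond never overlap), and a spherical
#' confinement of radius 650 nm applied during generation relative to the
#' running centre of mass.
#'
#' @param alpha folding parameter, dimensionless, > 1.
#' @param phi overall volume fraction, in (0, 0.64).
#' @param Rc confinement radius in nm.
#' @param r0 bead non-overlap radius in nm (must satisfy r0 < b).
#' @param b unit length / minimum jump in nm.
#' @param Umax local jump cutoff in units of \code{b}; longer jumps are
#'   resampled.
#' @param contact_cutoff spatial contact distance in nm.
#' @param probe_edge edge of the CVC probing cubes in nm.
#' @param analysis_radius radius of the sphere selecting reference beads
#'   for G(r) and the local volume fraction, nm.
#' @param fit_window radial window (nm) for the packing-exponent fit.
#' @param bp_core base pairs wrapped per nucleosome bead.
#' @param bp_per_nm base pairs per nm of linker DNA.
#' @param seed optional integer seed recorded with the parameters.
#' @return an object of class \code{srev_params}; element \code{n} is the
#'   bead count implied by \code{phi}.
#' @examples
#' p <- model_params(alpha = 1.10, phi = 0.08)
#' p$n  # 186741
#' @export
model_params <- function(alpha, phi, Rc = 650, r0 = 4.9, b = 10,
                         Umax = 30, contact_cutoff = 35, probe_edge = 120,
                         analysis_radius = 240, fit_window = c(40, 120),
                         bp_core = 147L, bp_per_nm = 1 / 0.34,
                         seed = NULL) {
  stopifnot(alpha > 1, phi > 0, phi < 0.64, Rc > 0, r0 > 0, r0 < b,
            Umax > 1, contact_cutoff > 0, probe_edge > 0,
            analysis_radius > 0, length(fit_window) == 2,
            fit_window[1] > 0, fit_window[2] > fit_window[1])
  structure(list(alpha = alpha, phi = phi, Rc = Rc, r0 = r0, b = b,
                 Umax = Umax, contact_cutoff = contact_cutoff,
                 probe_edge = probe_edge, analysis_radius = analysis_radius,
                 fit_window = fit_window, bp_core = as.integer(bp_core),
                 bp_per_nm = bp_per_nm, seed = seed,
                 n = n_beads_for_phi(phi, r0, Rc)),
            class = "srev_params")
}

#' @export
print.srev_params <- function(x, ...) {
  cat(sprintf(
    "SR-EV parameters: alpha = %.3f, phi = %.3f (N = %d beads)\n",
    x$alpha, x$phi, x$n))
  cat(sprintf("  Rc = %g nm, r0 = %g nm, b = %g nm, Umax = %g b\n",
              x$Rc, x$r0, x$b, x$Umax))
  invisible(x)
}

#' Bead count for a target overall volume fraction
#'
#' The overall volume fraction of a configuration of N beads of radius
#' \code{r0} confined to radius \code{Rc} is phi = N (r0/Rc)^3; the bead
#' count for a requested phi is the floor of the inverse relation.
#'
#' @param phi overall volume fraction.
#' @param r0 bead radius, nm.
#' @param Rc confinement radius, nm.
#' @return integer bead count.
#' @examples
#' n_beads_for_phi(0.08)  # 186741
#' @export
n_beads_for_phi <- function(phi, r0 = 4.9, Rc = 650) {
  stopifnot(phi > 0, phi < 0.64)
  as.integer(floor(phi * (Rc / r0)^3))
}

#' Overall volume fraction of a bead count
#'
#' Inverse of \code{\link{n_beads_for_phi}} up to the floor: for any phi,
#' \code{phi_of(n_beads_for_phi(phi))} lies within one bead volume of phi.
#'
#' @param n bead count.
#' @param r0 bead radius, nm.
#' @param Rc confinement radius, nm.
#' @return volume fraction.
#' @export
phi_of <- function(n, r0 = 4.9, Rc = 650) {
  n * (r0 / Rc)^3
}
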