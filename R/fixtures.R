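#' Synthetic point-set fixtures with known ground truth
#'
#' Generators for oracle tests of the analysis operations:
#' \describe{
#'   \item{uniform_ball}{n points uniform in a ball of radius R; G(r) and
#'     M(r) scale as r^3.}
#'   \item{plane}{n points uniform on a square of side L in the z = 0
#'     plane; G(r) scales as r^2.}
#'   \item{ideal_chain}{freely jointed chain of n beads with fixed bond
#'     length; end-to-end exponent 1/2.}
#'   \item{power_law_blob}{n points with radial density proportional to
#'     r^(D0 - 3) inside radius R, so the cumulative count scales as
#'     r^D0.}
#'   \item{lattice}{simple cubic lattice of m^3 points with spacing a;
#'     first neighbours at distance a.}
#' }
#'
#' @param kind one of \code{"uniform_ball"}, \code{"plane"},
#'   \code{"ideal_chain"}, \code{"power_law_blob"}, \code{"lattice"}.
#' @param n number of points (ignored for \code{lattice}).
#' @param seed optional seed.
#' @param R ball/blob radius, nm.
#' @param L plane side, nm.
#' @param bond bond length for the ideal chain, nm.
#' @param D0 target scaling exponent of the blob.
#' @param a lattice spacing, nm; \code{m} points per axis.
#' @param m lattice points per axis.
#' @return numeric matrix of coordinates (nm).
#' @export
make_fixture <- function(kind, n = 1e4, seed = NULL, R = 300, L = 600,
                         bond = 10, D0 = 2.5, a = 20, m = 10L) {
  set_seed_if(seed)
  kind <- match.arg(kind, c("uniform_ball", "plane", "ideal_chain",
                            "power_law_blob", "lattice"))
  iso <- function(k) {
    z <- 2 * runif(k) - 1
    th <- 2 * pi * runif(k)
    s <- sqrt(pmax(0, 1 - z^2))
    cbind(s * cos(th), s * sin(th), z, deparse.level = 0)
  }
  switch(kind,
    uniform_ball = {
      r <- R * runif(n)^(1 / 3)
      iso(n) * r
    },
    plane = cbind(L * runif(n), L * runif(n), 0, deparse.level = 0),
    ideal_chain = {
      steps <- iso(n - 1) * bond
      rbind(c(0, 0, 0), apply(steps, 2, cumsum))
    },
    power_law_blob = {
      stopifnot(D0 > 0)
      r <- R * runif(n)^(1 / D0)
      iso(n) * r
    },
    lattice = {
      g <- seq_len(m) * a
      unname(as.matrix(expand.grid(x = g, y = g, z = g)))
    })
}

#' Wrap a coordinate matrix as a chain configuration
#'
#' Gives fixture point sets (or externally generated chains) the
#' \code{srev_config} interface so the analysis operations apply to them.
#'
#' @param coords numeric matrix of bead centres, nm.
#' @param params a \code{\link{model_params}} object (defaults to nominal
#'   chromatin constants).
#' @param relaxed logical flag stored on the object.
#' @return an \code{srev_config}.
#' @export
as_chain_config <- function(coords,
                            params = model_params(alpha = 1.15, phi = 0.12),
                            relaxed = TRUE) {
  stopifnot(is.matrix(coords), ncol(coords) == 3)
  new_chain_config(coords, params, relaxed = relaxed)
}
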