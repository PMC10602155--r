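#' Linker DNA length of a bond
#'
#' Base pairs of linker DNA carried by a bond of length U nm: the nearest
#' integer of (U - 9.8 nm) / 0.34 nm, clipped below at zero (bonds at or
#' under bead contact carry no linker; negative linkers are unphysical).
#'
#' @param U bond length(s) in nm, > 0.
#' @param bead_diameter bead diameter in nm (2 r0).
#' @param bp_per_nm base pairs per nm of B-DNA.
#' @return integer vector of base pairs.
#' @examples
#' linker_bp(9.8)   # 0
#' linker_bp(19.0)  # 27
#' @export
linker_bp <- function(U, bead_diameter = 9.8, bp_per_nm = 1 / 0.34) {
  if (any(U <= 0)) stop("bond lengths must be positive")
  pmax(0L, as.integer(round((U - bead_diameter) * bp_per_nm)))
}

#' Genomic annotation of a chain configuration
#'
#' Assigns 147 bp of core DNA to every bead and linker DNA to every bond
#' from its relaxed length via \code{\link{linker_bp}}.  The cumulative
#' coordinate of bead i is i * 147 plus all preceding linkers, so the
#' genomic separation s(i, j) = |cum[j] - cum[i]| is additive along the
#' chain.
#'
#' @param config a relaxed \code{srev_config}.
#' @return object of class \code{srev_annotation} with \code{linker_bp}
#'   (per bond), \code{cumulative_bp} (per bead), \code{total_bp},
#'   \code{mean_linker} and \code{bp_per_bead}.
#' @export
annotate <- function(config) {
  stopifnot(inherits(config, "srev_config"))
  p <- config$params
  lk <- linker_bp(config$bond_lengths, 2 * p$r0, p$bp_per_nm)
  n <- nrow(config$coords)
  cum <- as.numeric(p$bp_core) * seq_len(n) + c(0, cumsum(as.numeric(lk)))
  structure(list(linker_bp = lk, cumulative_bp = cum,
                 total_bp = cum[n],
                 mean_linker = if (n > 1) mean(lk) else NA_real_,
                 bp_per_bead = cum[n] / n,
                 n_beads = n),
            class = "srev_annotation")
}

#' @export
print.srev_annotation <- function(x, ...) {
  cat(sprintf(
    "Genomic annotation: %d nucleosomes, %.3g bp total (mean linker %.1f bp, %.1f bp/nucleosome)\n",
    x$n_beads, x$total_bp, x$mean_linker, x$bp_per_bead))
  invisible(x)
}
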