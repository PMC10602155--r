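fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a configuration as XYZ
#'
#' Plain-text XYZ: first line the bead count, second line a comment
#' carrying alpha, phi, Rc and seed, then one row per bead
#' (\code{N x y z}, nm, full double precision so the round-trip is
#' bit-stable).
#'
#' @param config an \code{srev_config}.
#' @param path output file.
#' @return \code{write_xyz}: the path, invisibly.  \code{read_xyz}: an
#'   \code{srev_config}.
#' @export
write_xyz <- function(config, path) {
  stopifnot(inherits(config, "srev_config"))
  p <- config$params
  hdr <- sprintf("srev alpha=%.17g phi=%.17g Rc=%.17g r0=%.17g seed=%s",
                 p$alpha, p$phi, p$Rc, p$r0,
                 config$provenance$seed %||% "NA")
  rows <- sprintf("N %s %s %s", fmt_num(config$coords[, 1]),
                  fmt_num(config$coords[, 2]), fmt_num(config$coords[, 3]))
  writeLines(c(as.character(nrow(config$coords)), hdr, rows), path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  hdr <- lines[2]
  gv <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    if (!length(m)) return(NA_real_)
    suppressWarnings(as.numeric(sub(paste0(key, "="), "", m)))
  }
  fields <- do.call(rbind, strsplit(lines[3:(2 + n)], " ", fixed = TRUE))
  coords <- matrix(as.numeric(fields[, 2:4]), ncol = 3)
  seed <- gv("seed")
  params <- model_params(alpha = gv("alpha"), phi = gv("phi"),
                         Rc = gv("Rc"), r0 = gv("r0"))
  new_chain_config(coords, params, relaxed = TRUE,
                   provenance = list(seed = if (is.na(seed)) NULL else seed,
                                     file = path))
}

#' Write / read a configuration as CSV
#'
#' Columns: bead index, x, y, z (nm) and the bond length to the next bead
#' (NA for the last bead).  Full double precision; round-trips bit-stably.
#'
#' @param config an \code{srev_config}.
#' @param path output file.
#' @export
write_config_csv <- function(config, path) {
  stopifnot(inherits(config, "srev_config"))
  n <- nrow(config$coords)
  df <- data.frame(index = seq_len(n),
                   x = fmt_num(config$coords[, 1]),
                   y = fmt_num(config$coords[, 2]),
                   z = fmt_num(config$coords[, 3]),
                   bond_length = c(fmt_num(config$bond_lengths), NA))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_config_csv
#' @param params parameters attached to the configuration read back.
#' @export
read_config_csv <- function(path, params = model_params(1.15, 0.12)) {
  df <- read.csv(path, colClasses = c("integer", "character", "character",
                                      "character", "character"))
  coords <- cbind(as.numeric(df$x), as.numeric(df$y), as.numeric(df$z))
  new_chain_config(coords, params, relaxed = TRUE,
                   provenance = list(file = path))
}

#' Write / read an SRRW trajectory
#'
#' \code{format = "table"}: plain-text table (index, x, y, z in units of
#' b, step kind).  \code{format = "rds"}: compact binary serialisation of
#' the full object.  Both round-trip losslessly.
#'
#' @param traj an \code{srev_trajectory}.
#' @param path output file.
#' @param format \code{"table"} or \code{"rds"}.
#' @export
write_trajectory <- function(traj, path, format = c("table", "rds")) {
  stopifnot(inherits(traj, "srev_trajectory"))
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(traj, path)
    return(invisible(path))
  }
  v <- traj$vertices
  rows <- sprintf("%d %s %s %s %s", seq_len(nrow(v)) - 1L,
                  fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3]),
                  c("start", traj$step_kind))
  writeLines(c("index x y z kind", rows), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @param params parameters attached to the trajectory read back (table
#'   format only; ignored for rds).
#' @export
read_trajectory <- function(path, format = c("table", "rds"),
                            params = model_params(1.15, 0.12)) {
  format <- match.arg(format)
  if (format == "rds") return(readRDS(path))
  lines <- readLines(path)[-1]
  fields <- do.call(rbind, strsplit(lines, " ", fixed = TRUE))
  v <- matrix(as.numeric(fields[, 2:4]), ncol = 3)
  kind <- fields[-1, 5]
  structure(list(vertices = v, step_kind = kind,
                 stack_depth = NULL, n_steps = nrow(v) - 1L,
                 return_fraction = mean(kind == "return"),
                 params = params, seed = NULL),
            class = "srev_trajectory")
}

#' Write a curve as CSV / read it back
#'
#' Columns bin_center, value, pair_count; the observable name travels in
#' a comment-free extra column so the file stays spreadsheet-friendly.
#'
#' @param curve an \code{srev_curve}.
#' @param path output file.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "srev_curve"))
  df <- data.frame(bin_center = fmt_num(curve$bin_centers),
                   value = ifelse(is.na(curve$values), "",
                                  fmt_num(curve$values)),
                   pair_count = fmt_num(curve$pair_counts),
                   observable = curve$observable)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- read.csv(path, colClasses = c("character", "character",
                                      "character", "character"))
  vals <- suppressWarnings(as.numeric(df$value))
  new_curve(as.numeric(df$bin_center), vals, as.numeric(df$pair_count),
            df$observable[1])
}

#' Write a power-law fit as JSON
#'
#' @param fit an \code{srev_fit}.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "srev_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a density stack as multi-page TIFF
#'
#' One 32-bit float page per z-slice, plus a JSON sidecar
#' (\code{<path>.json}) carrying origin, voxel edge, dimensions and
#' provenance.  Intensities are scaled by the recorded \code{scale}
#' factor so they survive the float TIFF range convention.
#'
#' @param stack an \code{srev_stack}.
#' @param path output TIFF path.
#' @param sidecar write the JSON sidecar.
#' @export
write_stack_tiff <- function(stack, path, sidecar = TRUE) {
  stopifnot(inherits(stack, "srev_stack"))
  d <- dim(stack$data)
  scale <- max(stack$data, 1e-300)
  pages <- lapply(seq_len(d[3]), function(k) stack$data[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(origin = stack$origin, voxel_edge = stack$voxel_edge,
           dims = d, scale = scale, provenance = stack$provenance),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(dim(pages[[1]]), length(pages))
  arr <- array(unlist(pages), dim = d)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    new_stack(arr * (meta$scale %||% 1), meta$voxel_edge, meta$origin,
              provenance = as.list(meta$provenance))
  } else {
    new_stack(arr, 1, c(0, 0, 0))
  }
}

#' Write the genomic annotation table as CSV
#'
#' Columns: bead index, x, y, z (nm), linker_bp (bond to the next bead)
#' and cumulative_bp.
#'
#' @param annotation an \code{srev_annotation}.
#' @param config the matching configuration.
#' @param path output file.
#' @export
write_annotation_csv <- function(annotation, config, path) {
  n <- annotation$n_beads
  df <- data.frame(index = seq_len(n),
                   x = config$coords[, 1], y = config$coords[, 2],
                   z = config$coords[, 3],
                   linker_bp = c(annotation$linker_bp, NA),
                   cumulative_bp = annotation$cumulative_bp)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
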