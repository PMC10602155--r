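#' Run manifest for a condition grid
#'
#' Describes a reproducible ensemble run: the (alpha, phi) grid, replicate
#' count, master seed and output layout.  Replicate seeds are derived with
#' \code{\link{child_seed}} from the master seed, the row index of the
#' condition in the expanded grid and the replicate index, so results are
#' independent of execution order.
#'
#' At reduced scale the confinement radius and bead count shrink together
#' at fixed phi (N = floor(phi (Rc/r0)^3)), which preserves all local
#' observables while keeping runs desk-sized.
#'
#' @param alphas folding parameters.
#' @param phis overall volume fractions.
#' @param replicates replicates per condition.
#' @param master_seed integer master seed.
#' @param Rc confinement radius, nm.
#' @param outdir output directory (created by \code{\link{run_ensemble}});
#'   \code{NULL} keeps results in memory only.
#' @param settings relaxation settings.
#' @return object of class \code{srev_manifest}; \code{conditions} is the
#'   expanded grid with per-condition bead counts.
#' @export
run_manifest <- function(alphas, phis, replicates = 1L, master_seed = 1L,
                         Rc = 650, outdir = NULL,
                         settings = relaxation_settings()) {
  grid <- expand.grid(alpha = alphas, phi = phis,
                      KEEP.OUT.ATTRS = FALSE)
  grid$n_beads <- vapply(grid$phi, n_beads_for_phi, integer(1), Rc = Rc)
  m <- structure(list(conditions = grid,
                      replicates = as.integer(replicates),
                      master_seed = as.integer(master_seed),
                      Rc = Rc, outdir = outdir, settings = settings),
                 class = "srev_manifest")
  m$hash <- manifest_hash(m)
  m
}

# order-stable fingerprint of the manifest parameters (djb2 over the
# deparsed fields; used for idempotent re-runs, not cryptographic)
manifest_hash <- function(m) {
  s <- paste(deparse(m$conditions), deparse(m$replicates),
             deparse(m$master_seed), deparse(m$Rc),
             deparse(unclass(m$settings)), collapse = ";")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' @export
print.srev_manifest <- function(x, ...) {
  cat(sprintf(
    "srev manifest %s: %d conditions x %d replicates, Rc = %g nm, master seed %d\n",
    x$hash, nrow(x$conditions), x$replicates, x$Rc, x$master_seed))
  invisible(x)
}

#' Run an ensemble over a condition grid
#'
#' For each condition and replicate: generate the SRRW, expand and relax
#' it, annotate it, and compute the per-configuration summary (D_i, phi_i,
#' return fraction, mean linker) plus optional curves.  Errors in a
#' replicate are recorded without aborting the ensemble; the call fails
#' only if every replicate fails.  With an output directory, summary and
#' curve files are written and completed replicates (matching manifest
#' hash) are skipped on re-runs.
#'
#' @param manifest an \code{\link{run_manifest}}.
#' @param curves which ensemble-mean curves to compute: any of
#'   \code{"gofr"}, \code{"end_to_end"}, \code{"contact"}.
#' @param write_configs also write each relaxed configuration as XYZ.
#' @param verbose print per-replicate progress.
#' @return list with \code{summary} (one row per completed replicate),
#'   \code{curves} (per condition, ensemble means), \code{errors}.
#' @export
run_ensemble <- function(manifest, curves = "gofr", write_configs = FALSE,
                         verbose = FALSE) {
  stopifnot(inherits(manifest, "srev_manifest"))
  outdir <- manifest$outdir
  if (!is.null(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sum_rows <- list()
  cond_curves <- list()
  errors <- list()
  for (ci in seq_len(nrow(manifest$conditions))) {
    cond <- manifest$conditions[ci, ]
    params <- model_params(alpha = cond$alpha, phi = cond$phi,
                           Rc = manifest$Rc)
    ccur <- list(gofr = list(), end_to_end = list(), contact = list())
    for (ri in seq_len(manifest$replicates)) {
      seed <- child_seed(manifest$master_seed, ci, ri)
      tag <- sprintf("a%.2f_p%.2f_r%02d", cond$alpha, cond$phi, ri)
      sum_file <- if (!is.null(outdir))
        file.path(outdir, sprintf("summary_%s_%s.csv", tag, manifest$hash))
      if (!is.null(outdir) && file.exists(sum_file)) {
        sum_rows[[tag]] <- read.csv(sum_file)
        if (verbose) message("skip (done): ", tag)
        next
      }
      res <- tryCatch({
        cfg <- sr_ev_config(params, seed = seed,
                            settings = manifest$settings)
        ann <- annotate(cfg)
        row <- config_summary(cfg, ann)
        row$replicate <- ri
        row$total_bp <- ann$total_bp
        if ("gofr" %in% curves)
          ccur$gofr[[length(ccur$gofr) + 1L]] <-
            cumulative_pair_correlation(cfg)
        if ("end_to_end" %in% curves)
          ccur$end_to_end[[length(ccur$end_to_end) + 1L]] <-
            end_to_end_curve(cfg, ann, seed = seed)
        if ("contact" %in% curves)
          ccur$contact[[length(ccur$contact) + 1L]] <-
            contact_probability(cfg, ann)
        if (!is.null(outdir)) {
          write.csv(row, sum_file, row.names = FALSE)
          if (write_configs)
            write_xyz(cfg, file.path(outdir, paste0("config_", tag, ".xyz")))
        }
        if (verbose)
          message(sprintf("done %s: D_i = %.3f", tag, row$D_i))
        row
      }, error = function(e) {
        errors[[tag]] <<- conditionMessage(e)
        if (verbose) message("FAILED ", tag, ": ", conditionMessage(e))
        NULL
      })
      if (!is.null(res)) sum_rows[[tag]] <- res
    }
    ckey <- sprintf("a%.2f_p%.2f", cond$alpha, cond$phi)
    cond_curves[[ckey]] <- lapply(
      Filter(function(l) length(l) > 0, ccur), average_curves)
    if (!is.null(outdir)) {
      for (nm in names(cond_curves[[ckey]]))
        write_curve_csv(cond_curves[[ckey]][[nm]],
                        file.path(outdir,
                                  sprintf("curve_%s_%s.csv", nm, ckey)))
    }
  }
  if (length(sum_rows) == 0)
    stop("all replicates failed; first error: ",
         if (length(errors)) errors[[1]] else "none recorded")
  summary <- do.call(rbind, sum_rows)
  rownames(summary) <- NULL
  if (!is.null(outdir))
    write.csv(summary, file.path(outdir, "ensemble_summary.csv"),
              row.names = FALSE)
  list(summary = summary, curves = cond_curves, errors = errors,
       manifest = manifest)
}
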