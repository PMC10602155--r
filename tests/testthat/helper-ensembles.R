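# Shared simulation ensembles for the acceptance suite, built once on
# first use and cached for the session.  Sizes follow the reduced-scale
# convention (Rc and N shrink together at fixed phi).

.acc_cache <- new.env(parent = emptyenv())

acc_memo <- function(key, builder) {
  if (!exists(key, envir = .acc_cache)) {
    assign(key, builder(), envir = .acc_cache)
  }
  get(key, envir = .acc_cache)
}

# 12-condition reduced grid (Rc = 225 nm), 2 replicates per condition:
# per-replicate D_i, phi_i, mean linker, plus per-condition G(r) curves.
acc_grid <- function() {
  acc_memo("grid", function() {
    grid <- expand.grid(alpha = c(1.10, 1.15, 1.20),
                        phi = c(0.08, 0.12, 0.16, 0.20))
    rows <- list()
    gcond <- list()
    for (ci in seq_len(nrow(grid))) {
      p <- model_params(alpha = grid$alpha[ci], phi = grid$phi[ci],
                        Rc = 225)
      curves <- list()
      for (ri in 1:2) {
        cfg <- sr_ev_config(p, seed = child_seed(2024, ci, ri))
        ann <- annotate(cfg)
        row <- config_summary(cfg, ann)
        row$replicate <- ri
        cvc <- cvc_distribution(cfg)
        row$cvc_mean <- mean(cvc$values)
        row$cvc_max <- max(cvc$values)
        rows[[length(rows) + 1L]] <- row
        curves[[ri]] <- cumulative_pair_correlation(cfg)
      }
      gcond[[ci]] <- average_curves(curves)
    }
    list(summary = do.call(rbind, rows), conditions = grid,
         gcurves = gcond)
  })
}

# phi = 0.16 ensembles at Rc = 325 nm, 5 replicates per alpha, as used for
# the packing-exponent and intra-domain Flory checks.
acc_packing <- function() {
  acc_memo("packing", function() {
    out <- list()
    for (al in c(1.10, 1.20)) {
      p <- model_params(alpha = al, phi = 0.16, Rc = 325)
      g <- list(); r2 <- list(); lk <- numeric(5)
      for (ri in 1:5) {
        cs <- child_seed(31, round(100 * al), ri)
        cfg <- sr_ev_config(p, seed = cs)
        ann <- annotate(cfg)
        lk[ri] <- ann$mean_linker
        g[[ri]] <- cumulative_pair_correlation(cfg)
        if (al == 1.10) r2[[ri]] <- end_to_end_curve(cfg, ann, seed = cs)
      }
      out[[sprintf("a%d", round(100 * al))]] <-
        list(g = average_curves(g),
             r2 = if (length(r2)) average_curves(r2),
             linkers = lk, n = p$n)
    }
    out
  })
}

# full-confinement replicates at alpha = 1.20, phi = 0.12 for the
# inter-domain window (the reduced chains are too short for 1e5-1e6 bp);
# two replicates tame the single-chain variance of <R^2(s)> at large s.
acc_inter <- function() {
  acc_memo("inter", function() {
    p <- model_params(alpha = 1.20, phi = 0.12)
    curves <- lapply(1:2, function(ri) {
      cfg <- sr_ev_config(p, seed = child_seed(31, 101, ri))
      end_to_end_curve(cfg, annotate(cfg), seed = ri)
    })
    list(r2 = average_curves(curves), n = p$n)
  })
}

# one full-scale phi = 0.20 configuration (largest simulated system).
acc_phi20 <- function() {
  acc_memo("phi20", function() {
    p <- model_params(alpha = 1.15, phi = 0.20)
    cfg <- sr_ev_config(p, seed = child_seed(31, 200, 1))
    list(annotation = annotate(cfg), n = p$n)
  })
}
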