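# Small constructors shared across test files.

# hand-built SRRW trajectory (vertices in units of b)
make_traj <- function(vertices, step_kind, params = model_params(1.15, 0.12)) {
  structure(list(vertices = vertices, step_kind = step_kind,
                 stack_depth = NULL, n_steps = nrow(vertices) - 1L,
                 return_fraction = mean(step_kind == "return"),
                 params = params, seed = NULL),
            class = "srev_trajectory")
}

# star motif: k consecutive jump-return pairs around the origin
star_traj <- function(k = 7, len = 1.2, params = model_params(1.15, 0.12)) {
  dirs <- make_fixture("uniform_ball", n = k, seed = 99, R = 1)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  verts <- matrix(0, 2 * k + 1, 3)
  kind <- character(2 * k)
  for (i in seq_len(k)) {
    verts[2 * i, ] <- len * dirs[i, ]
    kind[2 * i - 1] <- "jump"
    kind[2 * i] <- "return"
  }
  make_traj(verts, kind, params)
}

# small relaxed configuration for oracle tests
small_relaxed <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- model_params(alpha = 1.12, phi = 0.16, Rc = 100)
      cache <<- sr_ev_config(p, seed = 303)
    }
    cache
  }
})

# analytic blob stack: intensity ~ r^(D0-3) inside R, so M(r) ~ r^D0
blob_stack <- function(D0 = 2.5, R = 60, n = 61, edge = 5, bg = 0,
                       shell = NULL) {
  ax <- (seq_len(n) - (n + 1) / 2) * edge
  r <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  v <- ifelse(r < R, pmax(r, edge / 2)^(D0 - 3), bg)
  if (!is.null(shell)) {
    # density ramps linearly from 0 at the inner shell edge
    sel <- r >= shell[1] & r <= shell[2]
    v[sel] <- shell[3] * (r[sel] - shell[1]) / (shell[2] - shell[1])
  }
  srev:::new_stack(array(v, dim = c(n, n, n)), edge,
                   rep(-(n / 2) * edge, 3))
}

new_curve_for_test <- function(x, y) {
  srev:::new_curve(x, y, rep(1, length(x)), "test")
}

# brute-force O(N^2) minimum non-bonded distance
brute_min_nonbonded <- function(coords) {
  n <- nrow(coords)
  dm <- as.matrix(dist(coords))
  dm[cbind(seq_len(n), seq_len(n))] <- Inf
  if (n > 1) {
    dm[cbind(seq_len(n - 1), 2:n)] <- Inf
    dm[cbind(2:n, seq_len(n - 1))] <- Inf
  }
  min(dm)
}
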