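#' Return-step probability
#'
#' Probability that the walk retraces the step currently on top of the
#' backbone stack: P_R(U0) = U0^(-alpha) / alpha for a backbone step of
#' length U0 (units of the minimum jump b).  The 1/alpha prefactor is the
#' reading under which the probability never exceeds 1 (it equals 1/alpha
#' at the minimum step U0 = 1).
#'
#' @param U0 backbone step length(s), units of b, >= 1.
#' @param alpha folding parameter, > 1.
#' @return probability in (0, 1/alpha].
#' @examples
#' return_probability(1, 1.25)  # 0.8
#' @export
return_probability <- function(U0, alpha) {
  if (any(U0 < 1)) stop("U0 must be >= 1")
  if (alpha <= 1) stop("alpha must be > 1")
  U0^(-alpha) / alpha
}

#' Sample forward-jump lengths
#'
#' Draws from the jump-length pdf (alpha + 1) U^-(alpha + 2) on U > 1 by
#' inverse-CDF sampling, U = (1 - u)^(-1/(alpha+1)); draws exceeding the
#' local cutoff \code{Umax} are rejected and redrawn.
#'
#' @param n number of draws.
#' @param alpha folding parameter, > 1 (the analytic mean without cutoff is
#'   (alpha + 1)/alpha).
#' @param Umax local cutoff in units of b; \code{Inf} disables it.
#' @param max_attempts cap on resampling rounds.
#' @return numeric vector of lengths in units of b, all in (1, Umax].
#' @export
sample_jump_length <- function(n, alpha, Umax = 30, max_attempts = 1000L) {
  stopifnot(alpha > 1, Umax > 1, n >= 0)
  u <- (1 - runif(n))^(-1 / (alpha + 1))
  attempts <- 0L
  while (any(bad <- u > Umax)) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) stop("jump-length resampling cap exceeded")
    u[bad] <- (1 - runif(sum(bad)))^(-1 / (alpha + 1))
  }
  u
}

#' Generate a self-returning random walk
#'
#' At each step, if the backbone stack is non-empty, a return over the
#' top-of-stack step is attempted with probability
#' \code{\link{return_probability}}; a return retraces that step exactly
#' and pops it.  Otherwise the walk takes an isotropic forward jump with
#' length from \code{\link{sample_jump_length}}.  A proposed jump must land
#' within \code{Rc} of the centre of mass of all vertices generated so far;
#' violating jumps are redrawn in full (direction and length) up to
#' \code{attempt_cap} times.
#'
#' @param params an \code{\link{model_params}} object.
#' @param n_steps number of steps; the trajectory has n_steps + 1 vertices.
#'   Defaults to \code{params$n - 1} so bead count matches \code{params$phi}.
#' @param seed optional integer seed (set via \code{set.seed}); identical
#'   seed and parameters give a bit-identical trajectory.
#' @param attempt_cap resampling cap per step for the confinement test.
#' @return object of class \code{srev_trajectory} with elements
#'   \code{vertices} (matrix, units of b), \code{step_kind}
#'   (\code{"jump"}/\code{"return"}), \code{stack_depth},
#'   \code{return_fraction} and \code{params}.
#' @export
generate_srrw <- function(params, n_steps = params$n - 1L, seed = NULL,
                          attempt_cap = 1e4L) {
  stopifnot(inherits(params, "srev_params"), n_steps >= 1)
  set_seed_if(seed)
  res <- .srrw_generate_cpp(as.integer(n_steps), params$alpha, params$Umax,
                            params$Rc / params$b, as.integer(attempt_cap))
  structure(list(vertices = res$vertices,
                 step_kind = c("jump", "return")[res$step_kind + 1L],
                 stack_depth = res$stack_depth,
                 n_steps = as.integer(n_steps),
                 return_fraction = res$n_return / n_steps,
                 params = params, seed = seed),
            class = "srev_trajectory")
}

#' @export
print.srev_trajectory <- function(x, ...) {
  cat(sprintf(
    "SRRW trajectory: %d steps (%.1f%% returns), alpha = %.3f\n",
    x$n_steps, 100 * x$return_fraction, x$params$alpha))
  invisible(x)
}
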