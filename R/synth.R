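# Evaluate code under a temporary RNG seed, restoring .Random.seed after.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic trajectory
#'
#' Ground-truth generators for testing every analysis stage without
#' simulator or experimental input: an exact-discretisation
#' Ornstein-Uhlenbeck track (\code{kind = "ou"}: spring-like regular
#' positioning), reflected pure diffusion (\code{kind = "diffusion"}), and
#' a noisy triangle wave (\code{kind = "triangle"}: back-and-forth
#' oscillatory motion).
#'
#' @param kind one of \code{"ou"}, \code{"diffusion"}, \code{"triangle"}.
#' @param D diffusion coefficient, um^2/s (ou, diffusion).  Default
#'   2.27e-4, the magnitude fitted for the F-plasmid system.
#' @param tau relaxation time, s (ou).  Default 120 s.
#' @param mean_x home position relative to mid-cell, um.
#' @param amplitude triangle-wave amplitude, um.
#' @param period triangle-wave period, s.
#' @param noise_sd Gaussian measurement noise, um (triangle).
#' @param dt_sample sampling interval, s (default 60 s, the experimental
#'   frame rate).
#' @param n_steps number of samples (>= 2).
#' @param seed integer seed.
#' @param cell_length cell length, um; defaults to a length comfortably
#'   containing the motion.
#' @return An object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(kind = c("ou", "diffusion", "triangle"),
                           D = 2.27e-4, tau = 120, mean_x = 0,
                           amplitude = 0.8, period = 600, noise_sd = 0.02,
                           dt_sample = 60, n_steps = 100, seed = 1,
                           cell_length = NULL) {
  kind <- match.arg(kind)
  if (is.null(cell_length)) {
    cell_length <- switch(kind,
      ou = 2 * (abs(mean_x) + 10 * sqrt(D * tau)),
      diffusion = 2.53,
      triangle = 2 * (abs(mean_x) + amplitude + 6 * noise_sd) + 0.2)
    cell_length <- max(cell_length, 1)
  }
  spec <- list(kind = kind, D = D, tau = tau, mean_x = mean_x,
               amplitude = amplitude, period = period, noise_sd = noise_sd,
               dt_sample = dt_sample, n_steps = as.integer(n_steps),
               seed = as.integer(seed), cell_length = cell_length)
  if (spec$n_steps < 2) stop("'n_steps' must be at least 2")
  if (dt_sample <= 0) stop("'dt_sample' must be positive")
  if (kind %in% c("ou", "diffusion") && D <= 0) stop("'D' must be positive")
  if (kind == "ou" && tau <= 0) stop("'tau' must be positive")
  if (kind == "triangle") {
    if (amplitude <= 0 || period <= 0) stop("'amplitude' and 'period' must be positive")
    if (noise_sd < 0) stop("'noise_sd' must be non-negative")
    if (abs(mean_x) + amplitude > cell_length / 2)
      stop("|mean_x| + amplitude must not exceed cell_length / 2")
  }
  class(spec) <- "synthetic_spec"
  spec
}

.synth_traj <- function(spec, x) {
  tr <- new_trajectory(times = (seq_len(spec$n_steps) - 1) * spec$dt_sample,
                       positions = matrix(x, ncol = 1),
                       L = spec$cell_length,
                       sampling_interval = spec$dt_sample, seed = spec$seed,
                       cell_lengths = rep(spec$cell_length, spec$n_steps),
                       source = spec$kind)
  tr$spec <- spec
  tr
}

#' Generate a synthetic Ornstein-Uhlenbeck trajectory
#'
#' Uses the exact discrete transition density of the over-damped spring (no
#' Euler error): the first point is drawn from the stationary Gaussian
#' (variance \code{D * tau}) and each subsequent point from a Gaussian with
#' mean decaying towards \code{mean_x} by \code{exp(-dt/tau)} and variance
#' \code{D * tau * (1 - exp(-2 dt/tau))}.
#'
#' @param spec a \code{"synthetic_spec"} with \code{kind = "ou"}.
#' @return A \code{"par_trajectory"} (positions mid-cell-relative, um) with
#'   the generating spec attached as \code{$spec}.
#' @export
gen_ou <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "ou")
  a <- exp(-spec$dt_sample / spec$tau)
  sd_stat <- sqrt(spec$D * spec$tau)
  sd_step <- sd_stat * sqrt(1 - a^2)
  x <- with_seed(spec$seed, {
    z0 <- stats::rnorm(1, 0, sd_stat)
    e <- stats::rnorm(spec$n_steps - 1, 0, sd_step)
    c(z0, stats::filter(e, a, method = "recursive", init = z0))
  })
  .synth_traj(spec, spec$mean_x + as.numeric(x))
}

#' Generate a synthetic pure-diffusion trajectory
#'
#' Cumulative Gaussian steps of standard deviation
#' \code{sqrt(2 D dt_sample)}, reflected at the cell boundaries
#' \code{+/- cell_length/2}.
#'
#' @param spec a \code{"synthetic_spec"} with \code{kind = "diffusion"}.
#' @return A \code{"par_trajectory"}.
#' @export
gen_diffusion <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "diffusion")
  half <- spec$cell_length / 2
  raw <- with_seed(spec$seed, {
    cumsum(c(spec$mean_x,
             stats::rnorm(spec$n_steps - 1, 0,
                          sqrt(2 * spec$D * spec$dt_sample))))
  })
  # fold the unbounded walk into [-half, half]
  y <- (raw + half) %% (2 * spec$cell_length)
  y <- ifelse(y > spec$cell_length, 2 * spec$cell_length - y, y)
  .synth_traj(spec, y - half)
}

#' Generate a synthetic oscillatory (triangle-wave) trajectory
#'
#' A deterministic triangle wave of the given amplitude and period about
#' \code{mean_x}, plus independent Gaussian noise -- the phenomenology of
#' the confined oscillatory regime, in which the plasmid shuttles back and
#' forth at roughly constant speed.
#'
#' @param spec a \code{"synthetic_spec"} with \code{kind = "triangle"}.
#' @return A \code{"par_trajectory"}.
#' @export
gen_triangle <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "triangle")
  t <- (seq_len(spec$n_steps) - 1) * spec$dt_sample
  wave <- spec$amplitude * (2 / pi) * asin(sin(2 * pi * t / spec$period))
  noise <- if (spec$noise_sd > 0)
    with_seed(spec$seed, stats::rnorm(spec$n_steps, 0, spec$noise_sd))
  else numeric(spec$n_steps)
  .synth_traj(spec, spec$mean_x + wave + noise)
}

#' Generate a synthetic trajectory from a spec
#'
#' Dispatches on \code{spec$kind} to \code{\link{gen_ou}},
#' \code{\link{gen_diffusion}} or \code{\link{gen_triangle}}.
#'
#' @param spec a \code{"synthetic_spec"}.
#' @return A \code{"par_trajectory"}.
#' @export
gen_synthetic <- function(spec) {
  switch(spec$kind,
         ou = gen_ou(spec),
         diffusion = gen_diffusion(spec),
         triangle = gen_triangle(spec))
}
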