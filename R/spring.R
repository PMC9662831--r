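#' Step-wise velocities of a trajectory
#'
#' For a uniformly sampled trajectory, pairs each frame-to-frame velocity
#' \code{v_i = (x_{i+1} - x_i) / dt} with the position at the start of the
#' step, expressed relative to the trajectory mean,
#' \code{x_i - mean(x)}.  Velocities are reported in um/min and positions in
#' um, the conventions used for experimental velocity profiles.
#'
#' @param x a \code{"par_trajectory"}, or a numeric vector of positions (um).
#' @param dt_min sampling interval in minutes (taken from the trajectory
#'   when available).
#' @param plasmid which plasmid column of a multi-plasmid trajectory.
#' @return A data frame with columns \code{x_rel} (um) and \code{v}
#'   (um/min), one row per consecutive frame pair.
#' @export
stepwise_velocities <- function(x, dt_min = NULL, plasmid = 1) {
  if (inherits(x, "par_trajectory")) {
    dts <- diff(x$times)
    if (length(dts) && diff(range(dts)) > 1e-6 * max(dts))
      stop("trajectory sampling is not uniform")
    dt_min <- x$sampling_interval / 60
    x <- x$positions[, plasmid]
  }
  x <- as.numeric(x[!is.na(x)])
  if (length(x) < 2) stop("need at least 2 samples")
  if (is.null(dt_min) || dt_min <= 0) stop("'dt_min' must be a positive interval")
  n <- length(x)
  data.frame(x_rel = x[-n] - mean(x), v = diff(x) / dt_min)
}

#' Smallest symmetric central fit region
#'
#' The velocity profile is fitted on the smallest interval \code{[-q, q]} of
#' mean-relative position that contains at least the fraction \code{coverage}
#' of all (position, velocity) points: \code{q} is the \code{coverage}
#' quantile of \code{|x_rel|}.
#'
#' @param x_rel mean-relative positions.
#' @param coverage minimum fraction of points inside the region (default
#'   0.6827, one Gaussian standard deviation).
#' @return \code{c(lo, hi)} in um.
#' @keywords internal
fit_region <- function(x_rel, coverage = 0.6827) {
  q <- as.numeric(stats::quantile(abs(x_rel), coverage, type = 1))
  c(-q, q)
}

#' Binned velocity profile with linear fit
#'
#' Bins step-wise velocities by mean-relative position (per-bin mean, sd and
#' standard error) and fits a straight line to the raw (position, velocity)
#' pairs by ordinary least squares, restricted to the smallest symmetric
#' central region containing at least 68.27\% of the points.  For motion in
#' a harmonic well the slope is \code{m = (exp(-dt/tau) - 1)/dt}, giving
#' direct access to the relaxation time \code{tau}; the residual variance
#' about the fit estimates \code{Var[v]}.
#'
#' @param pairs data frame from \code{\link{stepwise_velocities}} (columns
#'   \code{x_rel}, \code{v}).
#' @param bin_width display bin width in um (default 0.05).
#' @param coverage fit-region coverage, see \code{\link{fit_region}}.
#' @return An object of class \code{"velocity_profile"}: list with the
#'   binned \code{profile} data frame (\code{bin_center}, \code{mean_v},
#'   \code{sd_v}, \code{se_v}, \code{count}), the fitted slope \code{m}
#'   (1/min), intercept, residual variance \code{var_v} ((um/min)^2), the
#'   \code{fit_region} and the number of points used.
#' @export
fit_velocity_profile <- function(pairs, bin_width = 0.05, coverage = 0.6827) {
  stopifnot(is.data.frame(pairs), all(c("x_rel", "v") %in% names(pairs)))
  pairs <- pairs[stats::complete.cases(pairs[c("x_rel", "v")]), ]
  if (nrow(pairs) < 2) stop("need at least 2 (position, velocity) pairs")

  brk <- seq(floor(min(pairs$x_rel) / bin_width) * bin_width,
             ceiling(max(pairs$x_rel) / bin_width) * bin_width + bin_width / 2,
             by = bin_width)
  idx <- findInterval(pairs$x_rel, brk, rightmost.closed = TRUE,
                      all.inside = TRUE)
  occupied <- sort(unique(idx))
  if (length(occupied) < 2)
    stop("all points fall in a single position bin; cannot fit a profile")
  prof <- data.frame(
    bin_center = (brk[occupied] + brk[occupied + 1]) / 2,
    mean_v = vapply(occupied, function(b) mean(pairs$v[idx == b]), 0),
    sd_v = vapply(occupied, function(b) {
      if (sum(idx == b) > 1) stats::sd(pairs$v[idx == b]) else 0
    }, 0),
    count = vapply(occupied, function(b) sum(idx == b), 0L))
  prof$se_v <- prof$sd_v / sqrt(prof$count)

  reg <- fit_region(pairs$x_rel, coverage)
  inside <- pairs$x_rel >= reg[1] & pairs$x_rel <= reg[2]
  sub <- pairs[inside, ]
  if (length(unique(sub$x_rel)) < 2)
    stop("fit region degenerate: no position spread inside it")
  fit <- stats::lm.fit(cbind(1, sub$x_rel), sub$v)
  m <- unname(fit$coefficients[2])
  var_v <- sum(fit$residuals^2) / (length(fit$residuals) - 2)

  out <- list(profile = prof, m = m, intercept = unname(fit$coefficients[1]),
              var_v = var_v, fit_region = reg, n_fit = nrow(sub),
              n_total = nrow(pairs), bin_width = bin_width)
  class(out) <- "velocity_profile"
  out
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf(
    "Velocity profile: slope m = %.4f 1/min (fit on %d/%d points in [%.3f, %.3f] um)\n",
    x$m, x$n_fit, x$n_total, x$fit_region[1], x$fit_region[2]))
  cat(sprintf("  Var[v] about the fit: %.4g (um/min)^2; %d occupied bins of %g um\n",
              x$var_v, nrow(x$profile), x$bin_width))
  invisible(x)
}

#' Over-damped-spring parameter estimates from a velocity profile
#'
#' Inverts the closed forms of the harmonic (Ornstein-Uhlenbeck) model.
#' With velocity-profile slope \code{m} (1/min) and residual velocity
#' variance \code{var_v} ((um/min)^2) at sampling interval \code{dt_min}:
#' \deqn{\tau = -\delta t / \log(\delta t\, m + 1)}
#' \deqn{D = Var[v]\,\log(\delta t\, m + 1) / (\delta t\, m^2 + 2 m)}
#' and the effective spring constant \code{k/kBT = 1/(D tau)}.
#'
#' @param m velocity-profile slope, 1/min; must lie in \code{(-1/dt, 0)} for
#'   a finite positive relaxation time.
#' @param var_v velocity variance about the fitted profile, (um/min)^2.
#' @param dt_min sampling interval, min.
#' @return An object of class \code{"ou_estimates"}: list with \code{tau_min}
#'   (min), \code{D_um2_s} (um^2/s), \code{k_over_kBT} (1/um^2), \code{m},
#'   \code{var_v}, \code{dt_min}.
#' @examples
#' ou_estimates(m = (exp(-1 / 2) - 1) / 1, var_v = 0.02, dt_min = 1)
#' @export
ou_estimates <- function(m, var_v, dt_min) {
  stopifnot(dt_min > 0, var_v > 0)
  if (!is.finite(m) || m >= 0 || m <= -1 / dt_min)
    stop("slope m must lie in (-1/dt, 0) for a finite positive tau; got m = ",
         format(m))
  a <- dt_min * m + 1                     # = exp(-dt/tau)
  tau <- -dt_min / log(a)
  D_min <- var_v * log(a) / (dt_min * m^2 + 2 * m)   # um^2/min
  out <- list(tau_min = tau, D_um2_s = D_min / 60,
              k_over_kBT = 1 / (D_min * tau), m = m, var_v = var_v,
              dt_min = dt_min)
  class(out) <- "ou_estimates"
  out
}

#' @export
print.ou_estimates <- function(x, ...) {
  cat(sprintf("Over-damped spring estimates (sampling %g min):\n", x$dt_min))
  cat(sprintf("  tau = %.3f min;  D = %.4g um^2/s;  k/kBT = %.3f 1/um^2\n",
              x$tau_min, x$D_um2_s, x$k_over_kBT))
  invisible(x)
}

#' Transition density of the over-damped spring
#'
#' The probability density of finding a Brownian particle in a harmonic
#' potential (minimum at 0, diffusion \code{D}, relaxation time \code{tau})
#' at position \code{x} a time \code{dt} after being at \code{x0}: a
#' Gaussian with mean \code{x0 * exp(-dt/tau)} and variance
#' \code{D * tau * (1 - exp(-2 dt/tau))}.
#'
#' @param x evaluation position(s), um.
#' @param dt_s elapsed time, s.
#' @param x0 initial position, um.
#' @param D diffusion coefficient, um^2/s.
#' @param tau relaxation time, s.
#' @return Probability density values, 1/um.
#' @export
ou_transition_density <- function(x, dt_s, x0, D, tau) {
  stopifnot(D > 0, tau > 0, dt_s >= 0)
  S <- 1 - exp(-2 * dt_s / tau)
  if (S == 0) return(ifelse(x == x0, Inf, 0))
  stats::dnorm(x, mean = x0 * exp(-dt_s / tau), sd = sqrt(D * tau * S))
}

#' Model autocorrelation functions of the over-damped spring
#'
#' Closed-form normalised autocorrelations for positions sampled every
#' \code{dt}: position \code{exp(-t/tau)}; step-wise velocity
#' \code{(2 exp(-t/tau) - exp(-|t - dt|/tau) - exp(-(t + dt)/tau)) /
#' (2 - 2 exp(-dt/tau))}.  The velocity autocorrelation is negative at lag
#' \code{t = dt} for every \code{tau} -- the signature of elastic (spring)
#' motion, as opposed to the positive value produced by processive
#' (oscillatory) motion.
#'
#' @param t lag time(s), same units as \code{tau}.
#' @param dt_sample sampling interval, same units.
#' @param tau relaxation time.
#' @return List with numeric vectors \code{position} and \code{velocity}.
#' @export
autocorr_models <- function(t, dt_sample, tau) {
  stopifnot(tau > 0, dt_sample > 0, all(t >= 0))
  pos <- exp(-t / tau)
  vel <- (2 * exp(-t / tau) - exp(-abs(t - dt_sample) / tau) -
            exp(-(t + dt_sample) / tau)) / (2 - 2 * exp(-dt_sample / tau))
  list(position = pos, velocity = vel)
}

#' Empirical normalised autocorrelation
#'
#' Mean-subtracted autocorrelation normalised to 1 at lag 0, using the
#' biased (1/n) covariance estimator.
#'
#' @param series numeric vector (non-constant).
#' @param max_lag largest lag (in samples); must be below the series length.
#' @return Numeric vector of length \code{max_lag + 1}, named by lag
#'   (starting at lag 0, which is exactly 1).
#' @export
empirical_autocorr <- function(series, max_lag) {
  series <- as.numeric(series)
  if (anyNA(series)) series <- series[!is.na(series)]
  n <- length(series)
  if (max_lag < 1 || max_lag >= n)
    stop("'max_lag' must be in [1, length(series) - 1]")
  z <- series - mean(series)
  v <- sum(z^2)
  if (v == 0) stop("series is constant: autocorrelation undefined")
  ac <- vapply(0:max_lag, function(k) {
    sum(z[seq_len(n - k)] * z[seq_len(n - k) + k]) / v
  }, 0)
  names(ac) <- 0:max_lag
  ac
}

#' Time-averaged mean squared displacement
#'
#' 1D (long-axis) time-averaged MSD of a trajectory at the requested lags.
#' For pure diffusion \code{MSD(t) = 2 D t}; for a stationary over-damped
#' spring \code{MSD(t) = 2 D tau (1 - exp(-t/tau))}, plateauing at
#' \code{2 D tau}.
#'
#' @param x a \code{"par_trajectory"} or numeric position vector (um).
#' @param lags lag times (s); must be multiples of the sampling interval and
#'   smaller than the trajectory span.
#' @param sampling_interval sampling interval (s) when \code{x} is a plain
#'   vector.
#' @param plasmid plasmid column for multi-plasmid trajectories.
#' @return Named numeric vector of MSD values (um^2) per lag.
#' @export
msd <- function(x, lags, sampling_interval = NULL, plasmid = 1) {
  if (inherits(x, "par_trajectory")) {
    sampling_interval <- x$sampling_interval
    x <- x$positions[, plasmid]
  }
  x <- as.numeric(x[!is.na(x)])
  if (is.null(sampling_interval) || sampling_interval <= 0)
    stop("'sampling_interval' required for plain position vectors")
  n <- length(x)
  out <- vapply(lags, function(lag) {
    k <- lag / sampling_interval
    if (abs(k - round(k)) > 1e-6)
      stop("lag ", lag, " is not a multiple of the sampling interval")
    k <- round(k)
    if (k < 1 || k >= n)
      stop("lag ", lag, " exceeds the trajectory span")
    mean((x[seq_len(n - k) + k] - x[seq_len(n - k)])^2)
  }, 0)
  names(out) <- lags
  out
}

#' Characteristic restoring force
#'
#' The force exerted by the effective spring at an extension of one standard
#' deviation of the equilibrium distribution, \code{F = sqrt(k * kBT) = kBT *
#' sqrt(k/kBT)}, reported in pN.
#'
#' @param k_over_kBT effective spring constant over kBT, 1/um^2.
#' @param T_kelvin absolute temperature (default 303.15 K, i.e. 30 C).
#' @return Force in pN.
#' @examples
#' characteristic_force(36.8)   # ~0.025 pN
#' @export
characteristic_force <- function(k_over_kBT, T_kelvin = 303.15) {
  stopifnot(k_over_kBT >= 0, T_kelvin > 0)
  kBT_pN_um <- 1.380649e-23 * T_kelvin * 1e18  # J -> pN um
  kBT_pN_um * sqrt(k_over_kBT)
}

#' Fit the over-damped-spring model to trajectories
#'
#' The main fitting interface: computes step-wise velocities (pooled over
#' the supplied trajectories, each relative to its own mean), fits the
#' velocity-vs-position profile, and inverts the harmonic-model closed forms
#' for the relaxation time \code{tau}, diffusion coefficient \code{D},
#' effective spring constant \code{k/kBT} and characteristic force.
#'
#' @param x a \code{"par_trajectory"}, a list of them (an ensemble), or a
#'   data frame of (\code{x_rel}, \code{v}) pairs.
#' @param dt_min sampling interval in minutes (required for a plain pairs
#'   data frame).
#' @param bin_width display bin width, um.
#' @param coverage central fit-region coverage (default 0.6827).
#' @param T_kelvin temperature for the characteristic force.
#' @return An object of class \code{"spring_fit"} with components
#'   \code{profile} (the \code{"velocity_profile"}), \code{estimates} (the
#'   \code{"ou_estimates"}), \code{force_pN} and \code{n_pairs}.  Methods:
#'   \code{print}, \code{summary}, \code{coef} (named vector \code{m},
#'   \code{var_v}, \code{tau_min}, \code{D_um2_s}, \code{k_over_kBT}),
#'   \code{predict} (mean velocity at given positions), \code{plot} (binned
#'   profile and fit), \code{simulate} (synthetic OU tracks at the fitted
#'   parameters), \code{residuals}.
#' @examples
#' tr <- gen_ou(synthetic_spec(kind = "ou", D = 2.27e-4, tau = 120,
#'                             dt_sample = 60, n_steps = 5000, seed = 2))
#' fit <- spring_fit(tr)
#' coef(fit)
#' @export
spring_fit <- function(x, dt_min = NULL, bin_width = 0.05, coverage = 0.6827,
                       T_kelvin = 303.15) {
  if (inherits(x, "par_trajectory")) x <- list(x)
  if (is.list(x) && !is.data.frame(x) && all(vapply(x, inherits, TRUE,
                                                    "par_trajectory"))) {
    ivals <- unique(vapply(x, function(tr) tr$sampling_interval, 0))
    if (length(ivals) != 1)
      stop("all trajectories in an ensemble must share one sampling interval")
    dt_min <- ivals / 60
    pairs <- do.call(rbind, lapply(x, function(tr) {
      do.call(rbind, lapply(seq_len(ncol(tr$positions)), function(j) {
        xs <- tr$positions[, j]
        if (sum(!is.na(xs)) < 2) return(NULL)
        stepwise_velocities(xs[!is.na(xs)], dt_min = dt_min)
      }))
    }))
  } else if (is.data.frame(x)) {
    if (is.null(dt_min)) stop("'dt_min' must be given with raw velocity pairs")
    pairs <- x
  } else stop("'x' must be a trajectory, a list of trajectories, or a pairs data frame")

  prof <- fit_velocity_profile(pairs, bin_width = bin_width,
                               coverage = coverage)
  est <- ou_estimates(prof$m, prof$var_v, dt_min)
  out <- list(profile = prof, estimates = est,
              force_pN = characteristic_force(est$k_over_kBT, T_kelvin),
              T_kelvin = T_kelvin, n_pairs = nrow(pairs), pairs = pairs)
  class(out) <- "spring_fit"
  out
}

#' @export
print.spring_fit <- function(x, ...) {
  cat("Over-damped-spring fit\n")
  cat(sprintf("  %d velocity pairs, sampling %g min\n", x$n_pairs,
              x$estimates$dt_min))
  cat(sprintf("  slope m      = %8.4f 1/min\n", x$estimates$m))
  cat(sprintf("  tau          = %8.3f min\n", x$estimates$tau_min))
  cat(sprintf("  D            = %8.3g um^2/s\n", x$estimates$D_um2_s))
  cat(sprintf("  k/kBT        = %8.3f 1/um^2\n", x$estimates$k_over_kBT))
  cat(sprintf("  char. force  = %8.4f pN at %g K\n", x$force_pN, x$T_kelvin))
  invisible(x)
}

#' @export
summary.spring_fit <- function(object, ...) {
  print(object)
  cat("\nBinned profile:\n")
  print(utils::head(object$profile$profile, 20))
  invisible(object)
}

#' @export
coef.spring_fit <- function(object, ...) {
  with(object$estimates,
       c(m = m, var_v = var_v, tau_min = tau_min, D_um2_s = D_um2_s,
         k_over_kBT = k_over_kBT))
}

#' @export
predict.spring_fit <- function(object, x_rel, ...) {
  if (missing(x_rel)) x_rel <- object$profile$profile$bin_center
  object$profile$intercept + object$profile$m * x_rel
}

#' @export
residuals.spring_fit <- function(object, ...) {
  object$pairs$v - predict(object, object$pairs$x_rel)
}

#' @export
plot.spring_fit <- function(x, ...) {
  p <- x$profile$profile
  graphics::plot(p$bin_center, p$mean_v, pch = 16,
                 xlab = "position relative to trajectory mean (um)",
                 ylab = "mean velocity (um/min)", ...)
  graphics::arrows(p$bin_center, p$mean_v - p$se_v, p$bin_center,
                   p$mean_v + p$se_v, angle = 90, code = 3, length = 0.02)
  graphics::abline(v = x$profile$fit_region, lty = 2, col = "grey")
  graphics::abline(a = x$profile$intercept, b = x$profile$m, col = "red")
  invisible(x)
}

#' @export
simulate.spring_fit <- function(object, nsim = 1, seed = NULL, n_steps = NULL,
                                cell_length = NULL, ...) {
  est <- object$estimates
  if (is.null(n_steps)) n_steps <- 100
  if (is.null(seed)) seed <- 1
  lapply(seq_len(nsim), function(i) {
    gen_ou(synthetic_spec(kind = "ou", D = est$D_um2_s,
                          tau = est$tau_min * 60,
                          dt_sample = est$dt_min * 60, n_steps = n_steps,
                          seed = seed + i - 1,
                          cell_length = cell_length))
  })
}
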