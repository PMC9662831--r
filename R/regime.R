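#' Regular-positioning goodness (phi)
#'
#' Triangle-wave score of the trajectory mean position along the nucleoid:
#' \code{phi = 1 - 2 * |frac(n x / L) - 0.5|}.  With \code{n} plasmids the
#' regular positions are at \code{(2i - 1) L / (2n)}, where \code{phi = 1};
#' at the poles and midway between regular positions \code{phi = 0}.
#'
#' @param mean_x mean position(s) along the nucleoid in absolute
#'   coordinates, \code{[0, L]} (um).
#' @param L nucleoid length, um.
#' @param n number of plasmids (>= 1).
#' @return phi in \code{[0, 1]}.
#' @examples
#' phi_regular(1.265, 2.53, 1)  # mid-nucleoid, one plasmid -> 1
#' phi_regular(0, 2.53, 1)      # pole -> 0
#' @export
phi_regular <- function(mean_x, L, n) {
  stopifnot(L > 0, n >= 1)
  if (any(mean_x < 0 | mean_x > L))
    stop("'mean_x' must lie within [0, L]")
  u <- n * mean_x / L
  1 - 2 * abs(u - floor(u) - 0.5)
}

#' Mobility descriptor (psi)
#'
#' Standard deviation of the trajectory positions divided by
#' \code{L / (n * sqrt(12))}, the standard deviation of a uniform
#' distribution of width \code{L/n}.  An oscillating plasmid sweeping its
#' share of the nucleoid gives psi near 1; a confined one gives psi much
#' below 1.  The raw (unclamped) value is returned; scores clamp it at 1.
#'
#' @param std_x standard deviation of positions, um.
#' @param L nucleoid length, um.
#' @param n number of plasmids.
#' @return psi >= 0.
#' @export
psi_mobility <- function(std_x, L, n) {
  stopifnot(std_x >= 0, L > 0, n >= 1)
  std_x * n * sqrt(12) / L
}

# Interior local extrema of a series by sign changes of first differences.
# Flat stretches are resolved by carrying the sign of the last non-zero
# difference forward.
.local_extrema <- function(y) {
  d <- sign(diff(y))
  for (i in seq_along(d)[-1]) if (d[i] == 0) d[i] <- d[i - 1]
  ch <- diff(d)
  list(minima = which(ch > 0) + 1L, maxima = which(ch < 0) + 1L)
}

#' Oscillation descriptor (chi)
#'
#' From the normalised position autocorrelation (lags up to half the series
#' length): locate the first local minimum with a negative value; chi is the
#' highest positive local maximum at any larger lag, or 0 when either
#' feature is absent.  Periodic trajectories give chi near 1 (the
#' autocorrelation recovers to ~1 at one full period); monotone-decaying
#' autocorrelations give 0.
#'
#' @param positions numeric position series (>= 4 samples, non-constant).
#' @param max_lag largest lag in samples (default half the series length).
#' @return chi in \code{[0, 1]}.
#' @export
chi_oscillation <- function(positions, max_lag = NULL) {
  positions <- as.numeric(positions[!is.na(positions)])
  if (length(positions) < 4) stop("need at least 4 samples")
  if (is.null(max_lag)) max_lag <- floor(length(positions) / 2)
  max_lag <- min(max_lag, length(positions) - 1)
  ac <- empirical_autocorr(positions, max_lag)
  ext <- .local_extrema(ac)
  neg_min <- ext$minima[ac[ext$minima] < 0]
  if (!length(neg_min)) return(0)
  first_min <- min(neg_min)
  cand <- ext$maxima[ext$maxima > first_min & ac[ext$maxima] > 0]
  if (!length(cand)) return(0)
  min(max(ac[cand]), 1)
}

#' Phase-regime descriptors of a trajectory
#'
#' Combines phi (regular-positioning goodness of the mean position), psi
#' (mobility; clamped at 1 for scoring) and chi (oscillation strength) into
#' the three regime scores: regular positioning \code{(1 - psi) * phi},
#' static \code{(1 - psi) * (1 - phi)} and oscillation \code{chi}.  The
#' dominant regime is the score argmax, or \code{"diffusive"} when all
#' scores fall below \code{diffusive_floor} (mobile but neither positioned
#' nor oscillating).  A display colour blends the three base colours (light
#' brown = regular, blue = static, pink = oscillation) weighted by score;
#' all-zero scores give black.
#'
#' @param traj a \code{"par_trajectory"}, a numeric vector of mid-relative
#'   positions (um), or a list of trajectories (an ensemble: descriptors
#'   are computed per trajectory and averaged before scoring, which damps
#'   the sampling noise of chi on short single tracks).
#' @param n number of plasmids defining the regular positions (defaults to
#'   the number of trajectory columns).
#' @param L nucleoid length (required for plain vectors).
#' @param diffusive_floor scores below this on all channels are called
#'   diffusive (default 0.1).
#' @return An object of class \code{"regime_descriptor"}: list with
#'   \code{phi}, \code{psi} (unclamped), \code{chi}, the three scores,
#'   \code{regime} and \code{colour} (RGB in 0..255).  For multi-plasmid
#'   trajectories phi/psi/chi are averaged over plasmids.
#' @export
regime_descriptors <- function(traj, n = NULL, L = NULL,
                               diffusive_floor = 0.1) {
  if (is.list(traj) && !inherits(traj, "par_trajectory")) {
    per <- lapply(traj, regime_descriptors, n = n, L = L,
                  diffusive_floor = diffusive_floor)
    m <- colMeans(do.call(rbind, lapply(per, function(d)
      c(phi = d$phi, psi = d$psi, chi = d$chi))))
    return(.regime_from_descriptors(m[["phi"]], m[["psi"]], m[["chi"]],
                                    if (is.null(n)) per[[1]]$n else n,
                                    diffusive_floor))
  }
  if (inherits(traj, "par_trajectory")) {
    pos <- traj$positions
    L <- traj$L
    if (is.null(n)) n <- ncol(pos)
  } else {
    pos <- matrix(as.numeric(traj), ncol = 1)
    if (is.null(L)) stop("'L' required for plain position vectors")
    if (is.null(n)) n <- 1
  }
  per <- lapply(seq_len(ncol(pos)), function(j) {
    x <- pos[, j]
    x <- x[!is.na(x)]
    xa <- pmin(pmax(x + L / 2, 0), L)   # absolute nucleoid coordinate
    c(phi = phi_regular(mean(xa), L, n),
      psi = psi_mobility(stats::sd(xa), L, n),
      chi = chi_oscillation(x))
  })
  m <- colMeans(do.call(rbind, per))
  .regime_from_descriptors(unname(m["phi"]), unname(m["psi"]),
                           unname(m["chi"]), n, diffusive_floor)
}

.regime_from_descriptors <- function(phi, psi, chi, n, diffusive_floor) {
  psi_c <- min(psi, 1)
  scores <- c(regular = (1 - psi_c) * phi,
              static = (1 - psi_c) * (1 - phi),
              oscillation = chi)
  regime <- if (all(scores < diffusive_floor)) "diffusive"
            else names(scores)[which.max(scores)]
  out <- list(phi = phi, psi = psi, chi = chi,
              score_regular = unname(scores["regular"]),
              score_static = unname(scores["static"]),
              score_osc = unname(scores["oscillation"]),
              regime = regime, colour = regime_colour(scores), n = n)
  class(out) <- "regime_descriptor"
  out
}

#' @export
print.regime_descriptor <- function(x, ...) {
  cat(sprintf("Regime: %s (phi = %.3f, psi = %.3f, chi = %.3f)\n",
              x$regime, x$phi, x$psi, x$chi))
  cat(sprintf("  scores: regular %.3f, static %.3f, oscillation %.3f; colour #%02X%02X%02X\n",
              x$score_regular, x$score_static, x$score_osc,
              x$colour[1], x$colour[2], x$colour[3]))
  invisible(x)
}

#' Score-weighted regime colour
#'
#' Blends the base colours light brown (255,193,7; regular positioning),
#' blue (30,136,229; static) and pink (216,27,96; oscillation) weighted by
#' the three scores, clamped to the 0..255 range.  All-zero scores give
#' black (diffusive).
#'
#' @param scores numeric vector \code{c(regular, static, oscillation)} in
#'   \code{[0, 1]}.
#' @return Integer RGB triple in 0..255.
#' @export
regime_colour <- function(scores) {
  base <- rbind(regular = c(255, 193, 7),
                static = c(30, 136, 229),
                oscillation = c(216, 27, 96))
  mix <- colSums(base * pmin(pmax(as.numeric(scores), 0), 1))
  as.integer(round(pmin(mix, 255)))
}

#' Phase-diagram grid scan
#'
#' Runs seeded simulations over a grid of the dimensionless parameters:
#' lambda is realised by varying the hopping coefficient
#' (\code{Dh = (lam L/2)^2 kd / 2}) and epsilon by varying the stimulated
#' hydrolysis rate (\code{kh = eps kd}), all other parameters fixed at
#' \code{base}.  Each grid cell is simulated once per seed, classified with
#' \code{\link{regime_descriptors}}, and descriptor values are averaged over
#' seeds.  Regime probes start the plasmid(s) away from their target
#' positions (at \code{L/6}) so that immobile trajectories score as static
#' rather than regular.
#'
#' @param lam_values,eps_values grid values of lambda (per plasmid) and
#'   epsilon.
#' @param base a \code{"par_params"} supplying everything except \code{Dh}
#'   and \code{kh} (its \code{np} defines \code{n}).
#' @param seeds one simulation per seed per cell.
#' @param duration,burn_in,sampling_interval passed to \code{\link{par_run}}.
#' @param plasmid_start long-axis start position of every plasmid as a
#'   fraction of L (default 1/6; \code{NULL} for the default regular
#'   placement).
#' @return A data frame in long format: \code{lam}, \code{eps},
#'   \code{lam_n}, \code{Dh}, \code{kh}, descriptor means (\code{phi},
#'   \code{psi}, \code{chi}, scores), the dominant \code{regime} and hex
#'   \code{colour} per cell.  Cells whose realised parameters are invalid
#'   are returned with \code{NA} descriptors.
#' @export
phase_grid <- function(lam_values, eps_values, base, seeds = 1,
                       duration = 2100, burn_in = 600,
                       sampling_interval = 60, plasmid_start = 1 / 6) {
  stopifnot(inherits(base, "par_params"))
  grid <- expand.grid(lam = lam_values, eps = eps_values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    lam <- grid$lam[i]; eps <- grid$eps[i]
    Dh <- dh_for_lambda(lam, base$L, base$kd)
    kh <- eps * base$kd
    cell <- data.frame(lam = lam, eps = eps, lam_n = base$np * lam,
                       Dh = Dh, kh = kh, phi = NA_real_, psi = NA_real_,
                       chi = NA_real_, score_regular = NA_real_,
                       score_static = NA_real_, score_osc = NA_real_,
                       regime = NA_character_, colour = NA_character_,
                       stringsAsFactors = FALSE)
    p <- tryCatch(validate_params(utils::modifyList(unclass(base),
                                                    list(Dh = Dh, kh = kh))),
                  error = function(e) NULL)
    if (is.null(p)) return(cell)
    pos <- if (is.null(plasmid_start)) NULL
           else lapply(seq_len(p$np),
                       function(j) c(plasmid_start * p$L, p$W / 2))
    desc <- lapply(seeds, function(s) {
      tr <- par_run(p, duration = duration, burn_in = burn_in,
                    sampling_interval = sampling_interval, seed = s,
                    plasmid_positions = pos)
      regime_descriptors(tr, n = p$np)
    })
    for (f in c("phi", "psi", "chi", "score_regular", "score_static",
                "score_osc"))
      cell[[f]] <- mean(vapply(desc, `[[`, 0, f))
    sc <- c(regular = cell$score_regular, static = cell$score_static,
            oscillation = cell$score_osc)
    cell$regime <- if (all(sc < 0.1)) "diffusive" else names(sc)[which.max(sc)]
    col <- regime_colour(sc)
    cell$colour <- sprintf("#%02X%02X%02X", col[1], col[2], col[3])
    cell
  })
  out <- do.call(rbind, rows)
  attr(out, "n") <- base$np
  out
}

#' Smooth phase-diagram score channels
#'
#' Optional display smoothing of a gridded score channel: morphological
#' opening (3x3 square structuring element) followed by a 2-D Gaussian
#' filter (sd of one grid cell).  Requires the \pkg{EBImage} package.
#' Smoothing is cosmetic and is never applied before numeric analysis.
#'
#' @param grid_df output of \code{\link{phase_grid}}.
#' @param channel score column to smooth.
#' @param sigma Gaussian sd in grid cells.
#' @return \code{grid_df} with the channel replaced by its smoothed values.
#' @export
smooth_phase_grid <- function(grid_df, channel = "score_regular", sigma = 1) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("smooth_phase_grid() requires the EBImage package")
  lam <- sort(unique(grid_df$lam)); eps <- sort(unique(grid_df$eps))
  m <- matrix(NA_real_, length(lam), length(eps))
  m[cbind(match(grid_df$lam, lam), match(grid_df$eps, eps))] <-
    grid_df[[channel]]
  if (anyNA(m)) stop("smoothing requires a complete grid")
  kern <- EBImage::makeBrush(3, shape = "box")
  sm <- EBImage::gblur(EBImage::opening(m, kern), sigma = sigma)
  grid_df[[channel]] <- sm[cbind(match(grid_df$lam, lam),
                                 match(grid_df$eps, eps))]
  grid_df
}
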