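#' @useDynLib hoprelay, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

new_trajectory <- function(times, positions, L, sampling_interval, seed,
                           params = NULL, tether_counts = NULL,
                           bound_counts = NULL, counters = NULL,
                           accounted_duration = NULL, dimer_x = NULL,
                           cell_lengths = NULL, source = "simulation",
                           ids = NULL) {
  positions <- as.matrix(positions)
  stopifnot(length(times) == nrow(positions))
  obj <- list(times = as.numeric(times), positions = positions,
              tether_counts = tether_counts, bound_counts = bound_counts,
              sampling_interval = as.numeric(sampling_interval),
              L = as.numeric(L), seed = seed, params = params,
              counters = counters, accounted_duration = accounted_duration,
              dimer_x = dimer_x, cell_lengths = cell_lengths,
              source = source, ids = ids)
  class(obj) <- "par_trajectory"
  obj
}

#' Plasmid trajectory objects
#'
#' Sampled long-axis plasmid positions at a fixed interval.  Positions are
#' relative to mid-nucleoid (um; negative towards one designated pole), one
#' column per plasmid; \code{NA} before a plasmid exists (replication runs).
#' Simulator output carries the parameter snapshot, the seed, per-sample
#' tether counts, the total nucleoid-bound dimer count and the post-burn-in
#' hydrolysis event counters.
#'
#' @param x a \code{"par_trajectory"} object.
#' @param ... further arguments (ignored by \code{print}; passed to
#'   \code{matplot} by \code{plot}).
#' @return \code{print} returns \code{x} invisibly.
#' @name par_trajectory
NULL

#' @rdname par_trajectory
#' @export
print.par_trajectory <- function(x, ...) {
  np <- ncol(x$positions)
  cat(sprintf(
    "Plasmid trajectory (%s): %d plasmid(s), %d samples every %g s (%.1f min)\n",
    x$source, np, nrow(x$positions), x$sampling_interval,
    diff(range(x$times)) / 60))
  cat(sprintf("  nucleoid length L = %g um; positions relative to mid-nucleoid\n",
              x$L))
  for (j in seq_len(np)) {
    pos <- x$positions[, j]
    cat(sprintf("  plasmid %d: mean %+.3f um, sd %.3f um\n", j,
                mean(pos, na.rm = TRUE), stats::sd(pos, na.rm = TRUE)))
  }
  if (!is.null(x$counters))
    cat(sprintf("  events: %d associations, %d basal, %d stimulated hydrolyses\n",
                as.integer(x$counters[["associations"]]),
                as.integer(x$counters[["basal_hydrolysis_events"]]),
                as.integer(x$counters[["stimulated_hydrolysis_events"]])))
  invisible(x)
}

#' @rdname par_trajectory
#' @export
plot.par_trajectory <- function(x, ...) {
  graphics::matplot(x$times / 60, x$positions, type = "l", lty = 1,
                    xlab = "time (min)",
                    ylab = "long-axis position from mid-nucleoid (um)",
                    ylim = c(-x$L / 2, x$L / 2), ...)
  graphics::abline(h = 0, col = "grey", lty = 2)
  invisible(x)
}

#' Initialise a simulation state
#'
#' All \code{nA} dimers start cytosolic; plasmids are placed at the supplied
#' positions or, by default, at the regular positions along the long axis
#' (mid-nucleoid for a single plasmid) at mid-width.  The random stream is
#' seeded from \code{seed} and carried inside the state, so stepping is
#' bit-reproducible and independent of R's global RNG.
#'
#' @param params a \code{"par_params"} object.
#' @param seed integer seed for the simulation's random stream.
#' @param plasmid_positions optional list (or 2-column matrix) of (x, y)
#'   absolute positions in um, one per plasmid, inside the nucleoid
#'   rectangle.
#' @return An object of class \code{"par_state"}.
#' @export
init_state <- function(params, seed, plasmid_positions = NULL) {
  p <- validate_params(params)
  np <- p$np
  if (is.null(plasmid_positions)) {
    px <- if (np > 0) (2 * seq_len(np) - 1) * p$L / (2 * np) else numeric(0)
    py <- rep(p$W / 2, np)
  } else {
    m <- do.call(rbind, lapply(plasmid_positions, as.numeric))
    if (is.matrix(plasmid_positions)) m <- plasmid_positions
    if (nrow(m) != np || ncol(m) != 2)
      stop("'plasmid_positions' must supply one (x, y) pair per plasmid (np = ",
           np, ")")
    if (any(m[, 1] < 0 | m[, 1] > p$L | m[, 2] < 0 | m[, 2] > p$W))
      stop("plasmid position outside the nucleoid rectangle [0,L] x [0,W]")
    px <- m[, 1]; py <- m[, 2]
  }
  st <- list(
    time = 0,
    state = integer(p$nA),
    x = numeric(p$nA), y = numeric(p$nA),
    hx = numeric(p$nA), hy = numeric(p$nA),
    partner = rep(-1L, p$nA),
    px = as.numeric(px), py = as.numeric(py),
    counters = c(associations = 0, basal_hydrolysis_events = 0,
                 stimulated_hydrolysis_events = 0),
    rng = cpp_rng_state(as.integer(seed)),
    seed = as.integer(seed)
  )
  class(st) <- "par_state"
  st
}

#' @export
print.par_state <- function(x, ...) {
  tab <- tabulate(x$state + 1L, nbins = 3L)
  cat(sprintf(
    "Simulation state at t = %.3f s: %d cytosolic, %d bound, %d tethered dimers; %d plasmid(s)\n",
    x$time, tab[1], tab[2], tab[3], length(x$px)))
  invisible(x)
}

.counters_c2r <- function(cn) {
  stats::setNames(as.numeric(cn), c("associations", "basal_hydrolysis_events",
                                    "stimulated_hydrolysis_events"))
}
.counters_r2c <- function(counters) as.numeric(counters)

.state_to_cpp <- function(state) {
  list(time = state$time, state = state$state, x = state$x, y = state$y,
       hx = state$hx, hy = state$hy, partner = state$partner,
       px = state$px, py = state$py,
       counters = .counters_r2c(state$counters), rng = state$rng)
}

.state_from_cpp <- function(cs, template) {
  st <- template
  for (f in c("time", "state", "x", "y", "hx", "hy", "partner", "px", "py",
              "rng"))
    st[[f]] <- cs[[f]]
  st$counters <- .counters_c2r(cs$counters)
  st
}

#' Advance a simulation state
#'
#' Applies \code{n} discrete time steps of length \code{dt}.  Each step
#' performs, in fixed order: cytosolic association (probability
#' \code{ka*dt}, uniform landing site), basal dissociation of bound dimers
#' (\code{kd*dt}), tether breakage (\code{kh*dt}), elastic + hopping motion
#' of bound dimers, tether formation on contact (centre distance within
#' \code{Rp + RA}), plasmid motion under the resultant tether spring (pure
#' diffusion when untethered), and reflection at the nucleoid boundary.
#'
#' @param state a \code{"par_state"} object.
#' @param params the \code{"par_params"} used to create it.
#' @param n number of steps.
#' @param tether_mode motion scheme for tethered dimers.  \code{"fixed"}
#'   (default): the dimer is pinned to the plasmid surface and translates
#'   rigidly with it while its chromosomal home position stays put, so each
#'   tether spring relaxes through plasmid motion -- the relay mechanism.
#'   \code{"hopping"}: as \code{"fixed"} but the home position keeps hopping
#'   with \code{Dh} while tethered.  \code{"relay"}: tethered dimers keep
#'   fluctuating elastically about a frozen home without pinning, the
#'   tether only transmitting force.  Alternatives are provided because the
#'   behaviour of tethered dimers is the one under-determined ingredient of
#'   the scheme; only \code{"fixed"} reproduces spring-like regular
#'   positioning at the fitted parameter point.
#' @return The advanced \code{"par_state"}.
#' @export
par_step <- function(state, params, n = 1,
                     tether_mode = c("fixed", "hopping", "relay")) {
  p <- validate_params(params)
  mode <- c(fixed = 1L, hopping = 0L, relay = 2L)[[match.arg(tether_mode)]]
  stopifnot(inherits(state, "par_state"), length(state$state) == p$nA,
            length(state$px) == p$np, n >= 0)
  if (n == 0) return(state)
  res <- cpp_run(.state_to_cpp(state), p, as.numeric(n), 0L, FALSE, mode)
  .state_from_cpp(res$state, state)
}

.steps_of <- function(t, dt, what) {
  k <- t / dt
  if (abs(k - round(k)) > 1e-6)
    stop("'", what, "' (", t, " s) must be a multiple of dt (", dt, " s)")
  round(k)
}

#' Run a simulation and record a trajectory
#'
#' Executes \code{burn_in} seconds (to reach the stochastic steady state),
#' resets the event counters, then records plasmid positions and tether
#' counts every \code{sampling_interval} seconds for \code{duration} seconds
#' of production.  With \code{replicate_at}, plasmid \code{replicate_id} is
#' duplicated at that production time: the copy appears at the identical
#' position with zero tethers (positions before replication are \code{NA}
#' for the copy).
#'
#' @param params a \code{"par_params"} object.
#' @param duration production length in seconds (default 35 min, the
#'   analysis cadence used throughout).
#' @param burn_in equilibration time in seconds before recording (default
#'   600 s, about six basal-hydrolysis lifetimes).
#' @param sampling_interval recording interval in seconds (default 60 s).
#' @param seed integer seed.
#' @param plasmid_positions optional initial positions, see
#'   \code{\link{init_state}}.
#' @param replicate_at optional production time (s) of a replication event.
#' @param replicate_id plasmid to duplicate (1-based).
#' @param tether_mode tethered-dimer motion scheme, see
#'   \code{\link{par_step}}.
#' @param record_dimers record bound-dimer long-axis positions per sample
#'   (needed for \code{\link{para_kymograph}}).
#' @return A \code{"par_trajectory"} (see \code{\link{par_trajectory}});
#'   times are production-relative, positions mid-nucleoid-relative.
#' @examples
#' \donttest{
#' traj <- par_run(par_preset("fig4", nA = 50), duration = 600,
#'                 burn_in = 120, sampling_interval = 60, seed = 1)
#' print(traj)
#' }
#' @export
par_run <- function(params, duration = 2100, burn_in = 600,
                    sampling_interval = 60, seed = 1,
                    plasmid_positions = NULL, replicate_at = NULL,
                    replicate_id = 1, record_dimers = FALSE,
                    tether_mode = c("fixed", "hopping", "relay")) {
  p <- validate_params(params)
  tether_mode <- match.arg(tether_mode)
  mode <- c(fixed = 1L, hopping = 0L, relay = 2L)[[tether_mode]]
  if (sampling_interval < p$dt)
    stop("'sampling_interval' must be at least dt")
  n_burn <- .steps_of(burn_in, p$dt, "burn_in")
  n_prod <- .steps_of(duration, p$dt, "duration")
  rec <- .steps_of(sampling_interval, p$dt, "sampling_interval")
  if (n_prod %% rec != 0)
    stop("'duration' must be a multiple of 'sampling_interval'")

  state <- init_state(p, seed, plasmid_positions)
  if (n_burn > 0) state <- par_step(state, p, n_burn, tether_mode)
  state$counters[] <- 0
  t0 <- state$time

  run_block <- function(state, p, n_steps) {
    res <- cpp_run(.state_to_cpp(state), p, as.numeric(n_steps), as.integer(rec),
                   isTRUE(record_dimers), mode)
    list(state = .state_from_cpp(res$state, state), res = res)
  }

  if (is.null(replicate_at)) {
    b <- run_block(state, p, n_prod)
    state <- b$state
    times <- seq(0, duration, by = sampling_interval)
    pos <- b$res$pos
    teth <- b$res$tethers
    bound <- b$res$bound
    dimer_x <- if (record_dimers) b$res$dimer_x else NULL
  } else {
    n_rep <- .steps_of(replicate_at, p$dt, "replicate_at")
    if (n_rep %% rec != 0 || n_rep <= 0 || n_rep >= n_prod)
      stop("'replicate_at' must be a sampling time strictly inside the production window")
    b1 <- run_block(state, p, n_rep)
    state <- replicate_plasmid(b1$state, replicate_id)
    p2 <- p; p2$np <- p$np + 1L
    b2 <- run_block(state, p2, n_prod - n_rep)
    state <- b2$state
    # block 2 re-records the replication-time sample; drop block 1's copy
    keep <- seq_len(length(b1$res$times) - 1L)
    times <- seq(0, duration, by = sampling_interval)
    pad <- matrix(NA_real_, length(keep), 1)
    pos <- rbind(cbind(b1$res$pos[keep, , drop = FALSE], pad), b2$res$pos)
    teth <- rbind(cbind(b1$res$tethers[keep, , drop = FALSE], pad),
                  b2$res$tethers)
    bound <- c(b1$res$bound[keep], b2$res$bound)
    dimer_x <- if (record_dimers) c(b1$res$dimer_x[keep], b2$res$dimer_x)
               else NULL
    p <- p2
  }

  new_trajectory(times = times, positions = pos - p$L / 2, L = p$L,
                 sampling_interval = sampling_interval, seed = seed,
                 params = p, tether_counts = teth, bound_counts = bound,
                 counters = state$counters, accounted_duration = duration,
                 dimer_x = dimer_x,
                 cell_lengths = rep(p$L, length(times)),
                 source = "simulation")
}

#' Duplicate a plasmid in place
#'
#' Models a replication event: the new plasmid appears at the identical
#' position of its parent, but every existing ParA tether stays with the
#' parent -- the copy starts with zero tethers.  The tether count
#' equilibrates rapidly afterwards.
#'
#' @param state a \code{"par_state"}.
#' @param plasmid_id 1-based index of the plasmid to duplicate.
#' @return The state with one more plasmid (use params with \code{np + 1}
#'   for subsequent stepping).
#' @export
replicate_plasmid <- function(state, plasmid_id) {
  stopifnot(inherits(state, "par_state"))
  plasmid_id <- as.integer(plasmid_id)
  if (plasmid_id < 1 || plasmid_id > length(state$px))
    stop("unknown plasmid id ", plasmid_id)
  state$px <- c(state$px, state$px[plasmid_id])
  state$py <- c(state$py, state$py[plasmid_id])
  state
}

#' ATP consumption rate
#'
#' Every dissociation of a ParA dimer from the nucleoid -- basal or
#' ParB-stimulated -- corresponds to one ATP hydrolysis event.  The rate is
#' the total number of such events divided by the accounted (post-burn-in)
#' duration.
#'
#' @param x a \code{"par_trajectory"} from \code{\link{par_run}}, or a
#'   \code{"par_state"} together with the accounted \code{duration}.
#' @param duration accounted duration in seconds (required for a state).
#' @return Hydrolysis events per second.
#' @export
atp_consumption_rate <- function(x, duration = NULL) {
  if (inherits(x, "par_trajectory")) {
    counters <- x$counters
    duration <- x$accounted_duration
  } else if (inherits(x, "par_state")) {
    counters <- x$counters
    if (is.null(duration)) stop("'duration' must be given for a state")
  } else stop("'x' must be a par_trajectory or par_state")
  if (is.null(counters)) stop("no event counters available")
  if (is.null(duration) || duration <= 0) stop("accounted duration must be positive")
  unname(counters[["basal_hydrolysis_events"]] +
         counters[["stimulated_hydrolysis_events"]]) / duration
}

#' ParA kymograph
#'
#' Bins the recorded long-axis positions of nucleoid-associated (bound or
#' tethered) ParA dimers per sample time.  Row \code{t} sums to the
#' instantaneous nucleoid-bound dimer count at that sample.
#'
#' @param x a \code{"par_trajectory"} run with \code{record_dimers = TRUE},
#'   or a list of numeric vectors of dimer long-axis positions (one vector
#'   per sample, absolute coordinates in \code{[0, L]}).
#' @param n_bins number of long-axis bins (at least 2).
#' @param L nucleoid length (taken from the trajectory when available).
#' @return An integer matrix, time samples by long-axis bins, with bin
#'   centres as column names.
#' @export
para_kymograph <- function(x, n_bins = 50, L = NULL) {
  if (inherits(x, "par_trajectory")) {
    if (is.null(x$dimer_x))
      stop("trajectory was not run with record_dimers = TRUE")
    L <- x$L
    x <- x$dimer_x
  }
  if (is.null(L)) stop("'L' must be supplied for raw position lists")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2) stop("'n_bins' must be at least 2")
  breaks <- seq(0, L, length.out = n_bins + 1)
  rows <- lapply(x, function(xs) {
    if (!length(xs)) return(integer(n_bins))
    idx <- findInterval(xs, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(idx, nbins = n_bins)
  })
  m <- do.call(rbind, rows)
  if (is.null(m)) m <- matrix(0L, 0, n_bins)
  colnames(m) <- sprintf("%.3f", (breaks[-1] + breaks[-length(breaks)]) / 2)
  m
}

#' Run an ensemble of independent simulations
#'
#' Convenience wrapper running \code{\link{par_run}} once per seed.
#'
#' @param params a \code{"par_params"} object.
#' @param seeds integer vector of seeds, one run each.
#' @param ... passed to \code{\link{par_run}}.
#' @return List of \code{"par_trajectory"} objects.
#' @export
par_ensemble <- function(params, seeds, ...) {
  lapply(seeds, function(s) par_run(params, seed = s, ...))
}
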