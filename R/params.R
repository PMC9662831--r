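#' Model parameters for the hopping-and-relay simulator
#'
#' Constructs and validates the full parameter set of the stochastic model.
#' Units are micrometres and seconds throughout.  The nucleoid is a rectangle
#' of length \code{L} (long axis) by width \code{W} (short axis).  Cytosolic
#' ParA-ATP dimers bind the nucleoid at rate \code{ka}; nucleoid-bound dimers
#' dissociate by basal hydrolysis at rate \code{kd}, hop diffusively with
#' coefficient \code{Dh}, and fluctuate elastically about their home position
#' with diffusion coefficient \code{DA} and fluctuation widths
#' \code{sigma_x}, \code{sigma_y}.  A plasmid is a ParB-coated disk of radius
#' \code{Rp}; tethers to dimers (radius \code{RA}) break by stimulated
#' hydrolysis at rate \code{kh}, and the plasmid's intrinsic diffusion
#' coefficient is \code{Dp}.
#'
#' \code{kh} and \code{Dh} have no single canonical value (they are the two
#' axes of the phase diagram) and must always be supplied, either directly or
#' via \code{\link{par_preset}}.  All other arguments default to the fitted
#' reference values for the F-plasmid system.
#'
#' @param kh ParB-stimulated hydrolysis (tether breakage) rate, 1/s.
#' @param Dh hopping diffusion coefficient of bound ParA home positions,
#'   um^2/s.
#' @param ka association rate of cytosolic ParA to the nucleoid, 1/s.
#' @param kd basal hydrolysis (dissociation) rate of bound ParA, 1/s.
#' @param Dp intrinsic diffusion coefficient of the plasmid, um^2/s.
#' @param DA diffusion coefficient of bound ParA due to chromosome
#'   fluctuations, um^2/s.
#' @param sigma_x,sigma_y widths of the elastic chromosome fluctuations along
#'   the long and short axes, um.
#' @param Rp plasmid disk radius, um.
#' @param RA ParA dimer radius, um.
#' @param nA total number of ParA dimers.
#' @param np number of plasmids.
#' @param L,W nucleoid length and width, um.
#' @param dt simulation time step, s.
#' @return An object of class \code{"par_params"}: a validated named list of
#'   the above fields.
#' @seealso \code{\link{par_preset}}, \code{\link{dimensionless_params}},
#'   \code{\link{par_run}}
#' @examples
#' p <- par_params(kh = 0.5642, Dh = 0.056760)
#' dimensionless_params(p)
#' @export
par_params <- function(kh, Dh, ka = 0.19, kd = 0.01, Dp = 3e-3, DA = 0.01,
                       sigma_x = 0.1, sigma_y = 0.05, Rp = 0.05, RA = 0.002,
                       nA = 500, np = 1, L = 2.53, W = 0.95, dt = 0.001) {
  if (missing(kh) || missing(Dh))
    stop("'kh' and 'Dh' must be supplied (directly or via par_preset())")
  p <- list(ka = ka, kd = kd, kh = kh, Dp = Dp, Dh = Dh, DA = DA,
            sigma_x = sigma_x, sigma_y = sigma_y, Rp = Rp, RA = RA,
            nA = nA, np = np, L = L, W = W, dt = dt)
  p <- lapply(p, as.numeric)
  class(p) <- "par_params"
  validate_params(p)
}

#' Validate a model parameter record
#'
#' Checks every invariant of the model parameters and returns the canonical
#' record.  A plain named list (possibly partial) is accepted: missing fields
#' are filled with the \code{\link{par_params}} defaults (\code{kh} and
#' \code{Dh} always required).
#'
#' Invariants: all rates and diffusion coefficients non-negative; all lengths
#' positive; \code{dt * max(ka, kd, kh) < 0.1} so that per-step event
#' probabilities remain small; \code{2 * (Rp + RA) < W} so the plasmid disk
#' fits inside the nucleoid; \code{nA} and \code{np} non-negative integers.
#'
#' @param params a \code{"par_params"} object or named list of overrides.
#' @return A validated \code{"par_params"} object.
#' @export
validate_params <- function(params) {
  if (!inherits(params, "par_params")) {
    if (!is.list(params))
      stop("'params' must be a list or a 'par_params' object")
    known <- c("ka", "kd", "kh", "Dp", "Dh", "DA", "sigma_x", "sigma_y",
               "Rp", "RA", "nA", "np", "L", "W", "dt")
    bad <- setdiff(names(params), known)
    if (length(bad))
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
    return(do.call(par_params, params))
  }
  p <- params
  chk <- function(ok, field, what) {
    if (!isTRUE(ok))
      stop(sprintf("invalid parameter '%s': %s (got %s)", field, what,
                   format(p[[field]])), call. = FALSE)
  }
  for (f in c("ka", "kd", "kh", "Dp", "Dh", "DA"))
    chk(is.finite(p[[f]]) && p[[f]] >= 0, f, "must be a finite rate/coefficient >= 0")
  for (f in c("sigma_x", "sigma_y", "Rp", "RA", "L", "W", "dt"))
    chk(is.finite(p[[f]]) && p[[f]] > 0, f, "must be a finite length/time > 0")
  chk(p$dt * max(p$ka, p$kd, p$kh) < 0.1, "dt",
      "dt * max(ka, kd, kh) must be < 0.1 so event probabilities stay << 1")
  chk(2 * (p$Rp + p$RA) < p$W, "Rp",
      "plasmid contact diameter 2*(Rp+RA) must be smaller than the nucleoid width W")
  for (f in c("nA", "np")) {
    chk(is.finite(p[[f]]) && p[[f]] >= 0 && p[[f]] == round(p[[f]]), f,
        "must be a non-negative integer")
    p[[f]] <- as.integer(round(p[[f]]))
  }
  p
}

#' @export
print.par_params <- function(x, ...) {
  cat("Hopping-and-relay model parameters (um, s):\n")
  cat(sprintf("  rates      ka = %g, kd = %g, kh = %g  [1/s]\n", x$ka, x$kd, x$kh))
  cat(sprintf("  diffusion  Dp = %g, Dh = %g, DA = %g  [um^2/s]\n", x$Dp, x$Dh, x$DA))
  cat(sprintf("  elasticity sigma_x = %g, sigma_y = %g  [um]\n", x$sigma_x, x$sigma_y))
  cat(sprintf("  geometry   L = %g x W = %g, Rp = %g, RA = %g  [um]\n",
              x$L, x$W, x$Rp, x$RA))
  cat(sprintf("  counts     nA = %d dimers, np = %d plasmid(s); dt = %g s\n",
              x$nA, x$np, x$dt))
  dp <- tryCatch(suppressWarnings(dimensionless_params(x)), error = function(e) NULL)
  if (!is.null(dp))
    cat(sprintf("  dimensionless: lambda = %.3g, epsilon = %.3g, theta = %.3g\n",
                dp$lam, dp$eps, dp$theta))
  invisible(x)
}

# Named parameter presets: the per-figure (kh, Dh, L, np) combinations used
# for the published phase-diagram panels and fits.  All other fields are the
# par_params() defaults unless overridden.
.par_presets <- list(
  fig3C     = list(kh = 0.0133, Dh = 0.000440, L = 2.53, np = 1),
  fig3D     = list(kh = 0.0769, Dh = 0.000440, L = 2.53, np = 1),
  fig3E     = list(kh = 0.1785, Dh = 0.000623, L = 2.53, np = 1),
  fig3F     = list(kh = 0.0752, Dh = 0.002497, L = 2.53, np = 1),
  fig3G     = list(kh = 0.5642, Dh = 0.014162, L = 2.53, np = 1),
  fig3H     = list(kh = 0.5642, Dh = 0.056760, L = 2.53, np = 1),
  fig4      = list(kh = 0.5642, Dh = 0.056760, L = 2.53, np = 1),
  fig5A     = list(kh = 0.5642, Dh = 0.056760, L = 2.91, np = 2),
  fig5E     = list(kh = 0.5642, Dh = 0.007179, L = 2.91, np = 1),
  fig6short = list(kh = 0.5642, Dh = 0.056760, L = 1.82, np = 1),
  fig6long  = list(kh = 0.5642, Dh = 0.056760, L = 4.93, np = 1),
  fig5S1    = list(kh = 0.5642, Dh = 0.056760, L = 3.54, np = 1)
)

#' Named parameter presets
#'
#' Returns the model parameters used for each published figure panel: the
#' single-plasmid phase-diagram examples (\code{"fig3C"} static,
#' \code{"fig3D"} diffusive, \code{"fig3E"} oscillatory, \code{"fig3F"},
#' \code{"fig3G"}, \code{"fig3H"} regular positioning), the fitted F-plasmid
#' point \code{"fig4"}, the two-plasmid runs \code{"fig5A"}, the replication
#' run \code{"fig5E"}, the short/long nucleoid runs \code{"fig6short"} /
#' \code{"fig6long"} and the five-plasmid length \code{"fig5S1"}.
#'
#' @param name preset name; see Details.  \code{par_preset()} with no
#'   arguments lists available presets.
#' @param ... further overrides passed to \code{\link{par_params}}
#'   (e.g. \code{nA = 100}).
#' @return A \code{"par_params"} object, or a character vector of preset
#'   names if \code{name} is missing.
#' @examples
#' par_preset("fig4")
#' par_preset("fig3E", nA = 100)
#' @export
par_preset <- function(name, ...) {
  if (missing(name)) return(names(.par_presets))
  name <- match.arg(name, names(.par_presets))
  args <- utils::modifyList(.par_presets[[name]], list(...))
  do.call(par_params, args)
}

#' Dimensionless parameters of the hopping-and-relay model
#'
#' Computes the dimensionless quantities that organise the phase space of the
#' model:
#' \describe{
#'   \item{\code{s}}{\code{sqrt(2 * Dh / kd)}, the average distance (um) a
#'     bound ParA dimer diffuses along one axis before basal hydrolysis.}
#'   \item{\code{lam}}{lambda \code{= s / (L/2)}: the diffusive length scale
#'     relative to half the nucleoid length.  Regular positioning requires
#'     roughly \code{lam >= 1}.}
#'   \item{\code{eps}}{epsilon \code{= kh / kd}: stimulated relative to basal
#'     hydrolysis.  Large epsilon depletes ParA at the plasmid and gates the
#'     oscillatory instability; small epsilon enriches it.}
#'   \item{\code{theta}}{\code{nA * ka / (ka + kd)}: the steady-state number
#'     of nucleoid-bound dimers in the absence of stimulated hydrolysis.}
#'   \item{\code{lam_n}}{\code{np * lam}: the collapse variable for
#'     \code{np} plasmids; regular positioning requires \code{lam_n >= 1}.}
#' }
#'
#' When \code{kd = 0} the diffusive length scale is unbounded and
#' \code{lam = Inf} is returned with a warning (the limit in which bound
#' dimers only ever dissociate at the cargo).
#'
#' @param params a \code{"par_params"} object.
#' @return An object of class \code{"par_dimensionless"}: list with fields
#'   \code{s}, \code{lam}, \code{eps}, \code{theta}, \code{lam_n}, \code{n}.
#' @examples
#' dimensionless_params(par_preset("fig4"))  # lambda = 2.66, epsilon = 56.42
#' @export
dimensionless_params <- function(params) {
  p <- validate_params(params)
  if (p$ka + p$kd <= 0)
    stop("ka + kd must be positive to define theta")
  if (p$kd == 0) {
    warning("kd = 0: diffusive length scale is unbounded, lambda = Inf")
    s <- if (p$Dh > 0) Inf else 0
    lam <- s / (p$L / 2)
    eps <- if (p$kh > 0) Inf else NaN
  } else {
    s <- sqrt(2 * p$Dh / p$kd)
    lam <- s / (p$L / 2)
    eps <- p$kh / p$kd
  }
  theta <- p$nA * p$ka / (p$ka + p$kd)
  out <- list(s = s, lam = lam, eps = eps, theta = theta,
              lam_n = p$np * lam, n = p$np)
  class(out) <- "par_dimensionless"
  out
}

#' @export
print.par_dimensionless <- function(x, ...) {
  cat(sprintf(
    "s = %.4g um; lambda = %.4g; epsilon = %.4g; theta = %.4g; lambda_n (n = %d) = %.4g\n",
    x$s, x$lam, x$eps, x$theta, x$n, x$lam_n))
  invisible(x)
}

#' Solve for the hopping coefficient realising a given lambda
#'
#' Inverse of the lambda formula: \code{Dh = (lam * L/2)^2 * kd / 2}.  Used
#' by phase scans, which realise lambda by varying \code{Dh} and epsilon by
#' varying \code{kh = eps * kd}.
#'
#' @param lam target lambda (dimensionless, per plasmid).
#' @param L nucleoid length, um.
#' @param kd basal hydrolysis rate, 1/s.
#' @return Hopping diffusion coefficient \code{Dh} in um^2/s.
#' @export
dh_for_lambda <- function(lam, L, kd) {
  stopifnot(lam >= 0, L > 0, kd >= 0)
  (lam * L / 2)^2 * kd / 2
}

#' Read / write a flat key-value parameter configuration
#'
#' The configuration format is one \code{key = value} pair per line, keys
#' exactly the \code{\link{par_params}} field names, values in um/s units.
#' Blank lines and lines starting with \code{#} are ignored.  A \code{preset}
#' key may name a \code{\link{par_preset}} to start from.
#'
#' @param path file path.
#' @return \code{read_params}: a \code{"par_params"} object.
#' @export
read_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad))
    stop("malformed parameter line ", bad[1], ": '", lines[bad[1]], "'")
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  args <- list()
  if ("preset" %in% keys) {
    base <- .par_presets[[match.arg(vals[keys == "preset"], names(.par_presets))]]
    args <- base
    vals <- vals[keys != "preset"]
    keys <- keys[keys != "preset"]
  }
  num <- suppressWarnings(as.numeric(vals))
  if (anyNA(num))
    stop("non-numeric value for key '", keys[which(is.na(num))[1]], "'")
  args[keys] <- num
  validate_params(args)
}

#' @param params a \code{"par_params"} object to write.
#' @return \code{write_params}: \code{path}, invisibly.
#' @rdname read_params
#' @export
write_params <- function(params, path) {
  p <- validate_params(params)
  writeLines(sprintf("%s = %.17g", names(p), unlist(p)), path)
  invisible(path)
}
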