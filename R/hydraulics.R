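#' Hydraulic profile along the flume
#'
#' A table mapping streamwise position to the hydraulic descriptors the
#' morphometric analysis regresses against: mean flow velocity (m/s), bed
#' shear stress (Pa) and Reynolds number. The profile is an input (typically
#' exported from a CFD solution or measured); it is never computed here.
#' Positions must be strictly increasing; a non-monotone shear or Reynolds
#' column triggers a warning (for a narrowing flume both increase downstream)
#' but is accepted.
#'
#' @param x data frame with columns `x_m`, `U_m_s`, `tau_Pa`, `Re`, or the
#'   path to a CSV file with that header.
#' @return a `hydraulic_profile` data frame.
#' @export
hydraulic_profile <- function(x) {
  if (is.character(x)) x <- utils::read.csv(x)
  stopifnot(is.data.frame(x), all(c("x_m", "U_m_s", "tau_Pa", "Re") %in% names(x)))
  x <- x[order(x$x_m), c("x_m", "U_m_s", "tau_Pa", "Re")]
  if (any(diff(x$x_m) <= 0)) stop("x_m must be strictly increasing")
  if (any(x$U_m_s < 0) || any(x$tau_Pa < 0) || any(x$Re < 0))
    stop("U, tau and Re must be non-negative")
  if (any(diff(x$tau_Pa) < 0) || any(diff(x$Re) < 0))
    warning("tau or Re decrease along x; expected non-decreasing for a narrowing flume")
  class(x) <- c("hydraulic_profile", "data.frame")
  x
}

#' Interpolate hydraulic descriptors at a streamwise position
#'
#' Linear interpolation between bracketing table rows; exact at table nodes.
#' No extrapolation: positions outside the tabulated range are an error.
#'
#' @param profile a [hydraulic_profile()].
#' @param x streamwise position(s), m.
#' @return data frame with columns `x_m`, `U_m_s`, `tau_Pa`, `Re`, one row
#'   per requested position.
#' @export
shear_profile_lookup <- function(profile, x) {
  stopifnot(inherits(profile, "hydraulic_profile"))
  rng <- range(profile$x_m)
  if (any(x < rng[1] | x > rng[2]))
    stop(sprintf("position outside tabulated range [%.4g, %.4g] m", rng[1], rng[2]))
  data.frame(
    x_m    = x,
    U_m_s  = stats::approx(profile$x_m, profile$U_m_s, xout = x)$y,
    tau_Pa = stats::approx(profile$x_m, profile$tau_Pa, xout = x)$y,
    Re     = stats::approx(profile$x_m, profile$Re, xout = x)$y)
}

#' Analytic open-channel flow numbers
#'
#' Reynolds number for open-channel flow based on the hydraulic radius
#' `R_h = (width * depth) / (width + 2 * depth)`: `Re = factor * U * R_h / nu`
#' (`factor = 1` by default; some conventions use `4 * R_h`, set
#' `factor = 4`). The laminar bed shear estimate `tau = 3 * mu * U / depth`
#' assumes a plane Poiseuille-like profile and is a rough analytic check on a
#' CFD-derived shear value, not a substitute for one.
#'
#' @param U mean velocity, m/s.
#' @param width channel width, m.
#' @param depth flow depth, m.
#' @param nu kinematic viscosity, m^2/s (default water at 20 C).
#' @param mu dynamic viscosity, Pa s.
#' @param factor hydraulic-radius multiplier in the Re definition (1 or 4).
#' @return list with `Re`, `tau_laminar` (Pa) and `R_h` (m).
#' @export
open_channel_numbers <- function(U, width, depth, nu = 1e-6, mu = 1e-3,
                                 factor = 1) {
  if (any(c(U, width, depth, nu, mu) <= 0)) stop("all inputs must be > 0")
  R_h <- (width * depth) / (width + 2 * depth)
  list(Re = factor * U * R_h / nu, tau_laminar = 3 * mu * U / depth, R_h = R_h)
}
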