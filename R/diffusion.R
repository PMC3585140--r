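## Diffusion theory for allelic age conditional on current frequency.
##
## Scaling conventions used throughout (documented prominently because the
## literature varies): selection is genic (additive, no dominance) with
## genotype fitnesses 1, 1+s, 1+2s; gamma = 2*N*s is the scaled selection
## coefficient; time is measured in units of 2N generations.  On that scale
## the Wright-Fisher diffusion has infinitesimal mean gamma*y*(1-y) and
## variance y*(1-y).

# log(1 - exp(-a)) for a > 0, numerically stable at both ends
.log1mexp <- function(a) {
  out <- numeric(length(a))
  big <- a > log(2)
  out[big] <- log1p(-exp(-a[big]))
  out[!big] <- log(-expm1(-a[!big]))
  out
}

.GAMMA_NEUTRAL_TOL <- 1e-8
.GAMMA_MAX <- 200

.checkGamma <- function(gamma) {
  if (!is.finite(gamma))
    stop("gamma must be finite")
  if (abs(gamma) > .GAMMA_MAX)
    stop("supported range is |gamma| <= ", .GAMMA_MAX)
  gamma
}

# log S(y): scale function S(y) = (1 - exp(-2 gamma y)) / (2 gamma),
# S(y) = y in the neutral limit.  Evaluated in log space so that
# |gamma| up to .GAMMA_MAX never overflows.
.logS <- function(y, gamma) {
  if (abs(gamma) < .GAMMA_NEUTRAL_TOL) return(log(y))
  g <- abs(gamma)
  if (gamma > 0) .log1mexp(2 * g * y) - log(2 * g)
  else 2 * g * y + .log1mexp(2 * g * y) - log(2 * g)
}

# log (S(1) - S(y))
.logSbar <- function(y, gamma) {
  if (abs(gamma) < .GAMMA_NEUTRAL_TOL) return(log1p(-y))
  g <- abs(gamma)
  if (gamma > 0) -2 * g * y + .log1mexp(2 * g * (1 - y)) - log(2 * g)
  else 2 * g + .log1mexp(2 * g * (1 - y)) - log(2 * g)
}

# log psi(y), psi = exp(-2 gamma y) (derivative of the scale function)
.logPsi <- function(y, gamma) -2 * gamma * y

# log of the Green's function (expected sojourn density at b for the
# unconditioned diffusion started at a, before absorption at 0 or 1)
.logGreen <- function(a, b, gamma) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  log(2) + .logS(lo, gamma) + .logSbar(hi, gamma) - .logS(1, gamma) -
    log(b * (1 - b)) - .logPsi(b, gamma)
}

#' Sojourn-time density of an allele conditional on its current frequency
#'
#' Mean time (in units of 2N generations, per unit frequency) that an allele
#' currently observed at population frequency \code{x} has spent at frequency
#' \code{y} since it arose, under genic selection with scaled coefficient
#' \code{gamma} in a constant-size population.  This is the Green's-function
#' sojourn density of the Wright-Fisher diffusion conditioned on the allele
#' presently segregating at \code{x}, in the new-mutation limit
#' \code{p0 -> 0} by default.  The density has two analytic branches joined
#' continuously at \code{y = x}; for \code{gamma = 0} it is flat below
#' \code{x}, and it is exactly symmetric under \code{gamma -> -gamma}.
#'
#' @param y numeric vector of past frequencies in (0,1) at which to evaluate.
#' @param x current population frequency, a single value in (0,1).
#' @param gamma scaled selection coefficient (2Ns, additive selection, no
#'   dominance); negative means deleterious.  Supported range
#'   \code{|gamma| <= 200}; exponential terms are evaluated in log space.
#' @param p0 initial frequency; the default 0 denotes the new-mutation limit.
#' @return numeric vector of densities, same length as \code{y}.
#' @seealso [meanAge()], [sojournProfile()]
#' @examples
#' sojournDensity(c(0.01, 0.02, 0.05), x = 0.03, gamma = -10)
#' @export
sojournDensity <- function(y, x, gamma, p0 = 0) {
  .checkGamma(gamma)
  if (length(x) != 1 || !is.finite(x) || x <= 0 || x >= 1)
    stop("x must be a single frequency in (0,1)")
  if (p0 < 0 || p0 >= 1)
    stop("p0 must be in [0,1)")
  stopifnot(all(y > 0 & y < 1))
  if (p0 == 0) {
    lt <- .logSbar(y, gamma) - .logPsi(y, gamma) - log(y * (1 - y)) -
      (.logSbar(x, gamma) - .logPsi(x, gamma) - log(x * (1 - x))) +
      .logGreen(y, x, gamma)
  } else {
    lt <- .logGreen(p0, y, gamma) + .logGreen(y, x, gamma) -
      .logGreen(p0, x, gamma)
  }
  exp(lt)
}

#' Mean age of an allele conditional on its current frequency
#'
#' Integrates the sojourn density over all past frequencies.  Units are 2N
#' generations unless \code{units = "generations"}, in which case the
#' reference diploid size \code{nRef} is used for the conversion (the theory
#' itself depends on the population size only through the constant-size
#' assumption).
#'
#' @inheritParams sojournDensity
#' @param units \code{"2N"} (default) or \code{"generations"}.
#' @param nRef reference diploid population size, required when
#'   \code{units = "generations"}.
#' @param relTol relative quadrature tolerance on the age.
#' @return positive scalar mean age.
#' @examples
#' meanAge(0.1, gamma = 0)            # ~0.512 in 2N-generation units
#' meanAge(0.03, gamma = -10)
#' @export
meanAge <- function(x, gamma, p0 = 0, units = c("2N", "generations"),
                    nRef = NULL, relTol = 1e-6) {
  units <- match.arg(units)
  .checkGamma(gamma)
  if (length(x) != 1 || !is.finite(x) || x <= 0 || x >= 1)
    stop("x must be a single frequency in (0,1)")
  f <- function(y) sojournDensity(y, x = x, gamma = gamma, p0 = p0)
  cuts <- sort(unique(c(0, p0, x, 1)))
  pieces <- lapply(seq_len(length(cuts) - 1), function(i) {
    stats::integrate(f, cuts[i], cuts[i + 1], rel.tol = relTol,
                     stop.on.error = FALSE)
  })
  age <- sum(vapply(pieces, function(p) p$value, 0))
  err <- sum(vapply(pieces, function(p) p$abs.error, 0))
  if (!is.finite(age) || age <= 0 || err > 1e-3 * age)
    stop(sprintf(
      "quadrature did not converge: achieved relative tolerance %.3g", err / age))
  if (units == "generations") {
    if (is.null(nRef)) stop("nRef is required when units = 'generations'")
    age <- age * 2 * nRef
  }
  age
}

#' Frequency grid for sojourn profiles
#'
#' Strictly increasing points in the open interval (0,1), log-spaced towards
#' both endpoints to resolve the integrable boundary behaviour of sojourn
#' densities.
#'
#' @param n approximate number of points.
#' @param eps distance of the extreme points from 0 and 1.
#' @return numeric vector of frequencies.
#' @export
frequencyGrid <- function(n = 2000, eps = 1e-6) {
  if (n < 16) stop("n must be at least 16")
  if (eps <= 0 || eps >= 0.5) stop("eps must be in (0, 0.5)")
  half <- exp(seq(log(eps), log(0.5), length.out = ceiling(n / 2)))
  sort(unique(c(half, 1 - half)))
}

#' Sojourn profile of an allele at a given current frequency
#'
#' Evaluates [sojournDensity()] on a grid and packages it together with the
#' quadrature mean age as a \linkS4class{SojournProfile}.  The current
#' frequency \code{x} is inserted into the grid so both analytic branches are
#' represented up to their junction.  If the trapezoidal integral of the
#' gridded density deviates from the adaptive-quadrature mean age by more
#' than \code{checkTol} (relative), a warning reports the achieved agreement:
#' the grid is too coarse.
#'
#' @inheritParams sojournDensity
#' @param grid frequencies at which to evaluate, see [frequencyGrid()].
#' @param checkTol relative tolerance for the grid-vs-quadrature check.
#' @return a \linkS4class{SojournProfile}.
#' @examples
#' prof <- sojournProfile(0.03, gamma = -10)
#' prof
#' @export
sojournProfile <- function(x, gamma, grid = frequencyGrid(), p0 = 0,
                           checkTol = 1e-3) {
  if (any(diff(grid) <= 0) || any(grid <= 0) || any(grid >= 1))
    stop("grid must be strictly increasing within (0,1)")
  y <- sort(unique(c(grid, x)))
  dens <- sojournDensity(y, x = x, gamma = gamma, p0 = p0)
  age <- meanAge(x, gamma, p0 = p0)
  gridAge <- sum(diff(y) * (dens[-1] + dens[-length(dens)]) / 2)
  achieved <- abs(gridAge - age) / age
  if (achieved > checkTol)
    warning(sprintf(
      "grid too coarse: trapezoidal age agrees with quadrature only to %.3g relative",
      achieved))
  new("SojournProfile", x = x, gamma = gamma, p0 = p0, y = y,
      density = dens, meanAge = age)
}

#' Theoretical mean age averaged over a frequency bin
#'
#' Expected age of a segregating allele whose current frequency falls in a
#' bin, under stationary mutation influx in a constant-size population.  This
#' is the occupancy-weighted average of [meanAge()] over the bin, the
#' quantity estimated by forward simulation when ages are tallied per
#' frequency bin; for narrow bins it is close to, but not identical with,
#' the mean age at the bin centre.
#'
#' @param bins numeric vector of bin edges in [0,1] (length >= 2).
#' @param gamma scaled selection coefficient.
#' @param nodes number of Gauss-Legendre nodes per bin.
#' @return data.frame with columns \code{bin_low}, \code{bin_high},
#'   \code{mean_age} (2N-generation units).
#' @export
predictedAgeByFrequency <- function(bins, gamma, nodes = 24) {
  .checkGamma(gamma)
  stopifnot(length(bins) >= 2, !is.unsorted(bins, strictly = TRUE))
  lo <- pmax(bins[-length(bins)], 1e-8)
  hi <- pmin(bins[-1], 1 - 1e-8)
  out <- data.frame(bin_low = bins[-length(bins)], bin_high = bins[-1],
                    mean_age = NA_real_)
  gl <- pracma::gaussLegendre(nodes, 0, 1)
  for (i in seq_along(lo)) {
    if (hi[i] <= lo[i]) next
    y <- lo[i] + (hi[i] - lo[i]) * gl$x
    w <- (hi[i] - lo[i]) * gl$w
    # stationary density of segregating alleles at y, up to a constant that
    # cancels in the within-bin ratio; shifted by its max for overflow safety
    logocc <- .logSbar(y, gamma) - .logPsi(y, gamma) - log(y * (1 - y))
    occ <- exp(logocc - max(logocc))
    ages <- vapply(y, meanAge, 0, gamma = gamma)
    out$mean_age[i] <- sum(w * occ * ages) / sum(w * occ)
  }
  out
}
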