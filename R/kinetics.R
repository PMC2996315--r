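#' Kinetic rate-law parameters
#'
#' Constants of the strain-dependent three-state cycle. The attachment step
#' is a Monte-Carlo two-step process (thermal diffusion of the head followed
#' by a distance-dependent binding test, see [rate_attach()]); the power
#' stroke and detachment are deterministic functions of state free-energy
#' differences; reverse rates follow from detailed balance.
#'
#' * `r23_max`, `gamma`: the power-stroke rate is a saturating sigmoid in the
#'   free-energy drop, `r23 = r23_max/2 * (1 + tanh(gamma * (G2 - G3)))`,
#'   maximal when the stroke is strongly downhill.
#' * `r31_unstrained`, `detach_sensitivity`: detachment accelerates
#'   exponentially with post-stroke strain,
#'   `r31 = r31_unstrained * exp(detach_sensitivity * U3)` with `U3` the
#'   converter-relaxed elastic energy in pN nm. The two constants are
#'   calibrated so the detachment minimum spans 20/s at the 34 nm rest
#'   spacing to 260/s at 38 nm (see the methods vignette).
#' * `clamp`: detailed-balance and detachment exponents are clamped to
#'   `[-clamp, clamp]`; clamp events are counted in [clamp_log()].
#' * `conversion`: per-time-step probabilities are converted to rate
#'   constants by `r = -log(1 - P)/dt` (`"log"`, default) or `r = P/dt`
#'   (`"linear"`).
#'
#' @param r23_max Maximum power-stroke rate, 1/s.
#' @param gamma Power-stroke free-energy sensitivity, per kT.
#' @param r31_unstrained Detachment rate of an unstrained post-stroke
#'   cross-bridge, 1/s.
#' @param detach_sensitivity Strain sensitivity of detachment, 1/(pN nm).
#' @param clamp Exponent clamp bound (dimensionless).
#' @param conversion Probability-to-rate convention.
#' @return List of class `"xb_kinetics"`.
#' @export
kinetic_params <- function(r23_max = 1000, gamma = 0.5,
                           r31_unstrained = 20, detach_sensitivity = 0.68344,
                           clamp = 50, conversion = c("log", "linear")) {
  stopifnot(r23_max > 0, gamma > 0, r31_unstrained > 0,
            detach_sensitivity > 0, clamp > 0)
  structure(list(r23_max = r23_max, gamma = gamma,
                 r31_unstrained = r31_unstrained,
                 detach_sensitivity = detach_sensitivity,
                 clamp = clamp, conversion = match.arg(conversion)),
            class = "xb_kinetics")
}

# clamp bookkeeping ("logged" rather than warned: scans hit the landscape
# corners routinely and a warning flood would drown real ones)
.xb_log <- new.env(parent = emptyenv())
.xb_log$clamped <- 0L

#' Count of clamped kinetic exponents
#'
#' Detailed-balance and detachment exponents larger in magnitude than the
#' `clamp` bound of [kinetic_params()] are truncated; every truncation is
#' counted here. `reset = TRUE` zeroes the counter.
#'
#' @param reset Reset the counter after reading?
#' @return Integer count (invisibly the previous count when resetting).
#' @export
clamp_log <- function(reset = FALSE) {
  n <- .xb_log$clamped
  if (reset) .xb_log$clamped <- 0L
  n
}

clamp_exp <- function(x, clamp) {
  out <- pmin(pmax(x, -clamp), clamp)
  n <- sum(out != x)
  if (n > 0) .xb_log$clamped <- .xb_log$clamped + n
  exp(out)
}

#' Convert a per-time-step probability to a rate constant (and back)
#'
#' @param p Probability per time step, in `[0, 1)`.
#' @param r Rate constant, 1/s.
#' @param dt Time step, s.
#' @param conversion `"log"` for `-log(1-p)/dt`, `"linear"` for `p/dt`.
#' @return Rate in 1/s, or probability per step.
#' @export
prob_to_rate <- function(p, dt = 1e-3, conversion = c("log", "linear")) {
  conversion <- match.arg(conversion)
  stopifnot(all(p >= 0 & p < 1))
  if (conversion == "log") -log1p(-p) / dt else p / dt
}

#' @rdname prob_to_rate
#' @export
rate_to_prob <- function(r, dt = 1e-3) {
  stopifnot(all(r >= 0))
  -expm1(-r * dt)
}

#' Distance-dependent binding probability
#'
#' Probability that a diffusing head at distance `distance` from an open
#' binding site attaches within one time step:
#' \eqn{P = \exp(-d^2/\tau)}, maximal (1) at the site and decreasing
#' exponentially in the squared distance. The scale factor \eqn{\tau}
#' (nm^2; 12 for the 4sXB, 72 for the 2sXB) absorbs the different diffusion
#' footprints of the two spring systems so their ensemble attachment rates
#' are comparable.
#'
#' @param distance Tip-to-site distance, nm (vectorised, `>= 0`).
#' @param tau Scale factor, nm^2.
#' @return Probability in `[0, 1]`.
#' @export
binding_probability <- function(distance, tau) {
  stopifnot(tau > 0, all(distance >= 0))
  exp(-distance^2 / tau)
}

#' Thermally diffused head positions
#'
#' Draws `n` tip positions of the detached head. Each spring is offset from
#' its state-1/2 rest value independently, with the offset drawn from the
#' Boltzmann distribution of a harmonic degree of freedom: a Gaussian with
#' variance kT/k (equipartition). Tips follow by forward kinematics. Uses
#' the current RNG state; seed with [set.seed()] for reproducible streams.
#'
#' @param xb A [crossbridge()].
#' @param n Number of draws.
#' @param thermo A [thermo_params()] (supplies kT).
#' @param springs Also return the drawn spring values?
#' @return An `n x 2` matrix with columns `axial`, `radial` (radial is `NA`
#'   for the 1sXB); if `springs = TRUE`, the per-spring values are attached
#'   as attribute `"spring_values"`.
#' @export
diffuse_tip <- function(xb, n = 1L, thermo = thermo_params(),
                        springs = FALSE) {
  stopifnot(inherits(xb, "crossbridge"), n >= 1)
  k <- vapply(xb$springs, `[[`, numeric(1), "stiffness")
  rest <- vapply(xb$springs, `[[`, numeric(1), "rest_pre")
  vals <- vapply(seq_along(k), function(j)
    stats::rnorm(n, rest[j], sqrt(thermo$kT / k[j])), numeric(n))
  vals <- matrix(vals, nrow = n)
  tips <- switch(xb$name,
    "1sXB" = cbind(axial = vals[, 1], radial = NA_real_),
    "2sXB" = cbind(axial = vals[, 2] * cos(vals[, 1]),
                   radial = vals[, 2] * sin(vals[, 1])),
    "4sXB" = {
      cx <- vals[, 2] * cos(vals[, 1]); cy <- vals[, 2] * sin(vals[, 1])
      cbind(axial = cx - vals[, 4] * cos(vals[, 3]),
            radial = cy + vals[, 4] * sin(vals[, 3]))
    })
  if (springs) attr(tips, "spring_values") <- vals
  tips
}

#' Ensemble Monte-Carlo attachment rate (1 -> 2)
#'
#' Estimates the attachment rate constant at a binding site from `n`
#' independent diffuse-then-bind trials: each trial diffuses the head
#' ([diffuse_tip()]), evaluates the binding probability at the post-diffusion
#' distance to the site, and the ensemble mean probability per 1 ms step is
#' converted to a rate constant. The standard error is propagated from the
#' Monte-Carlo standard error of the mean probability.
#'
#' @param xb A [crossbridge()].
#' @param site_axial Axial offset of the binding site, nm.
#' @param d10 Lattice spacing, nm.
#' @param n Ensemble size (>= 1000 recommended for reported values).
#' @param kin A [kinetic_params()].
#' @param thermo A [thermo_params()].
#' @param cal A [lattice_calibration()].
#' @param tau Binding scale factor; defaults to the model's own.
#' @param seed Optional integer seed for a reproducible stream.
#' @return List of class `"xb_rate"`: `value` (1/s), `se` (1/s),
#'   `transition = c(1, 2)`, `site_axial`, `d10`, `n`, `seed`.
#' @export
rate_attach <- function(xb, site_axial, d10, n = 1e4,
                        kin = kinetic_params(), thermo = thermo_params(),
                        cal = lattice_calibration(), tau = xb$tau,
                        seed = NULL) {
  if (!is.finite(tau))
    stop("model has no default binding scale factor; supply tau", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  site <- site_tip(site_axial, d10, cal)
  tips <- diffuse_tip(xb, n, thermo)
  dy <- if (xb$name == "1sXB") 0 else tips[, 2] - site[[2]]
  d <- sqrt((tips[, 1] - site[[1]])^2 + dy^2)
  p <- binding_probability(d, tau)
  pbar <- mean(p)
  se_p <- stats::sd(p) / sqrt(n)
  deriv <- if (kin$conversion == "log") 1 / (1 - pbar) else 1
  structure(list(value = prob_to_rate(pbar, thermo$dt, kin$conversion),
                 se = deriv * se_p / thermo$dt,
                 transition = c(1L, 2L), site_axial = site_axial, d10 = d10,
                 n = n, seed = seed),
            class = "xb_rate")
}

#' @export
print.xb_rate <- function(x, ...) {
  cat(sprintf("<xb_rate> %d->%d: %.4g +/- %.2g /s (site %.3g nm, d10 %.3g nm, n = %g)\n",
              x$transition[1], x$transition[2], x$value, x$se,
              x$site_axial, x$d10, x$n))
  invisible(x)
}

#' Power-stroke rate constant (2 -> 3)
#'
#' Saturating sigmoid in the free-energy difference between the pre- and
#' post-stroke states with the tip co-located at the binding site (the 4sXB
#' converter is re-optimised in each state):
#' \deqn{r_{23} = \tfrac{1}{2} r_{23}^{max} (1 + \tanh(\gamma (G_2 - G_3))).}
#' Depends only on the difference, so it is invariant under a common shift
#' of both state energies.
#'
#' @inheritParams rate_attach
#' @return Rate constant, 1/s.
#' @export
rate_stroke <- function(xb, site_axial, d10, kin = kinetic_params(),
                        thermo = thermo_params(), cal = lattice_calibration()) {
  tip <- site_tip(site_axial, d10, cal)
  dg <- free_energy(xb, 2, tip, thermo) - free_energy(xb, 3, tip, thermo)
  0.5 * kin$r23_max * (1 + tanh(kin$gamma * dg))
}

#' Detachment rate constant (3 -> 1)
#'
#' Exponential in the post-stroke strain energy with the tip co-located at
#' the binding site:
#' \deqn{r_{31} = r_{31}^{0} \exp(\alpha U_3),}
#' where \eqn{U_3} is the converter-relaxed elastic energy (pN nm), i.e. the
#' strain part of the state-3 free energy; the position dependence of the
#' classic single-spring detachment law is deliberately absent, leaving only
#' the asymmetry carried by the spring geometry.
#'
#' @inheritParams rate_attach
#' @return Rate constant, 1/s.
#' @export
rate_detach <- function(xb, site_axial, d10, kin = kinetic_params(),
                        thermo = thermo_params(), cal = lattice_calibration()) {
  tip <- site_tip(site_axial, d10, cal)
  u3 <- elastic_energy(xb, tip[[1]], tip[[2]], 3)
  kin$r31_unstrained * clamp_exp(kin$detach_sensitivity * u3, kin$clamp)
}

#' Detailed-balance reverse rate
#'
#' Thermodynamically balancing formula: for a forward transition i -> j with
#' free-energy change `dg = G_j - G_i` (kT units), the reverse rate is
#' \deqn{r_{ji} = r_{ij} \exp(\Delta G_{ij}),}
#' so that the pair satisfies detailed balance against the Boltzmann factor.
#' Exponents are clamped at the `clamp` bound of [kinetic_params()] to guard
#' against overflow (see [clamp_log()]).
#'
#' @param forward Forward rate constant, 1/s (`>= 0`).
#' @param dg Free-energy change of the forward transition, kT units.
#' @param kin A [kinetic_params()] (supplies the clamp bound).
#' @return Reverse rate constant, 1/s.
#' @examples
#' rate_reverse(100, 0)  # equal energies: reverse == forward
#' @export
rate_reverse <- function(forward, dg, kin = kinetic_params()) {
  stopifnot(all(forward >= 0))
  forward * clamp_exp(dg, kin$clamp)
}
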