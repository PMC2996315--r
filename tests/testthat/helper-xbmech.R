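# Report every failed expectation rather than stopping at the default cap:
# the acceptance checks are diagnostic and must all be visible.
options(testthat.progress.max_fails = 1000)

# Shared fixtures. Models and the lattice calibration are deterministic and
# cheap but used everywhere, so build them once per test run.
.fix <- new.env()

get_xb <- function(name) {
  if (is.null(.fix[[name]])) .fix[[name]] <- crossbridge(name)
  .fix[[name]]
}

get_cal <- function() {
  if (is.null(.fix$cal)) .fix$cal <- lattice_calibration(get_xb("4sXB"))
  .fix$cal
}

get_thermo <- function() {
  if (is.null(.fix$thermo)) .fix$thermo <- thermo_params()
  .fix$thermo
}

get_kin <- function() {
  if (is.null(.fix$kin)) .fix$kin <- kinetic_params()
  .fix$kin
}

# Random tips inside the studied landscape window.
random_tips <- function(n, seed = 1) {
  set.seed(seed)
  cbind(axial = runif(n, -5, 25), radial = runif(n, 12, 19))
}

# Independent brute-force oracle for the 4sXB converter placement: exhaustive
# grid search over converter positions in a generous window around the rest
# converter point, evaluated straight from the spring definitions (no shared
# code with the package solver beyond the spring parameters).
brute_energy_4s <- function(xb, tx, ty, state, res = 0.05, half_width = 8) {
  s <- xb$springs
  slot <- if (state == 3) "rest_post" else "rest_pre"
  a1 <- s[[1]][[slot]]; k1 <- s[[1]]$stiffness
  r1 <- s[[2]][[slot]]; kl1 <- s[[2]]$stiffness
  a2 <- s[[3]][[slot]]; k2 <- s[[3]]$stiffness
  r2 <- s[[4]][[slot]]; kl2 <- s[[4]]$stiffness
  c0 <- r1 * c(cos(s[[1]]$rest_pre), sin(s[[1]]$rest_pre))
  cx <- seq(c0[1] - half_width, c0[1] + half_width, by = res)
  cy <- seq(max(0.2, c0[2] - half_width), c0[2] + half_width, by = res)
  g <- expand.grid(cx = cx, cy = cy)
  th1 <- atan2(g$cy, g$cx); l1 <- sqrt(g$cx^2 + g$cy^2)
  dx <- tx - g$cx; dy <- ty - g$cy; l2 <- sqrt(dx^2 + dy^2)
  th2 <- atan2(dy, -dx)
  u <- 0.5 * k1 * (th1 - a1)^2 + 0.5 * kl1 * (l1 - r1)^2 +
       0.5 * k2 * (th2 - a2)^2 + 0.5 * kl2 * (l2 - r2)^2
  i <- which.min(u)
  # guard: the window must actually contain the minimum
  stopifnot(g$cx[i] > min(cx), g$cx[i] < max(cx),
            g$cy[i] > min(cy), g$cy[i] < max(cy))
  u[i]
}

# Central-difference gradient of the (converter-relaxed) elastic energy with
# respect to the tip position.
numeric_force <- function(xb, tx, ty, state, h = 1e-4) {
  tx <- unname(tx); ty <- unname(ty)
  c(axial  = -(elastic_energy(xb, tx + h, ty, state) -
               elastic_energy(xb, tx - h, ty, state)) / (2 * h),
    radial = -(elastic_energy(xb, tx, ty + h, state) -
               elastic_energy(xb, tx, ty - h, state)) / (2 * h))
}
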