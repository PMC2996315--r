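#' Thermodynamic parameters
#'
#' The free energy liberated by one ATP hydrolysis,
#' \eqn{\Delta G = \Delta G_0 + \ln([\mathrm{ATP}]/([\mathrm{ADP}][\mathrm{P_i}]))}
#' in kT units, follows the classic three-state cross-bridge literature:
#' standard free energy 13 kT and millimolar-scale nucleotide concentrations
#' give about 23.9 kT per cycle. Only a state-dependent fraction is available
#' to the cross-bridge: 28% in the weakly bound pre-stroke state and 68% in
#' the strongly bound post-stroke state.
#'
#' @param kT Thermal energy in pN nm. Default 4.11 (T around 298 K);
#'   configurable because the model temperature is a modelling choice.
#' @param g_atp_standard Standard free energy of ATP hydrolysis, kT units.
#' @param atp,adp,phosphate Concentrations in molar.
#' @param eff_weak,eff_strong Efficiency factors of states 2 and 3
#'   (dimensionless, `0 < eff_weak < eff_strong < 1`).
#' @param dt Kinetic time step in seconds (1 ms).
#' @return List of class `"xb_thermo"`; `dg_total` is the per-cycle free
#'   energy in kT units.
#' @export
thermo_params <- function(kT = 4.11, g_atp_standard = 13,
                          atp = 5e-3, adp = 30e-6, phosphate = 3e-3,
                          eff_weak = 0.28, eff_strong = 0.68, dt = 1e-3) {
  stopifnot(kT > 0, dt > 0, atp > 0, adp > 0, phosphate > 0)
  if (!(eff_weak > 0 && eff_weak < eff_strong && eff_strong < 1))
    stop("need 0 < eff_weak < eff_strong < 1", call. = FALSE)
  structure(list(kT = kT,
                 dg_total = abs(-g_atp_standard - log(atp / (adp * phosphate))),
                 eff = c(NA_real_, eff_weak, eff_strong),
                 dt = dt),
            class = "xb_thermo")
}

#' @export
print.xb_thermo <- function(x, ...) {
  cat(sprintf(
    "<xb_thermo> kT = %.3g pN nm, dG(ATP) = %.4g kT, eff = %.2f/%.2f, dt = %g s\n",
    x$kT, x$dg_total, x$eff[2], x$eff[3], x$dt))
  invisible(x)
}

#' State free energy of a cross-bridge
#'
#' The detached state is the reference: it supports no strain and its free
#' energy is 0 at every tip position and lattice spacing. A bound state `i`
#' combines the efficiency-limited ATP budget with the strain energy of all
#' springs at the state's rest values (the 4sXB converter relaxed to its
#' minimum-energy placement):
#' \deqn{G_i = -\epsilon_i \, \Delta G + U_i(\mathrm{tip}) / kT,\qquad i = 2, 3,}
#' in kT units, with \eqn{\epsilon_2 = 0.28}, \eqn{\epsilon_3 = 0.68}.
#'
#' @param xb A [crossbridge()].
#' @param state Kinetic state 1-3.
#' @param tip A [tip_position()] (usually from [site_tip()], co-locating the
#'   tip with a binding site).
#' @param thermo A [thermo_params()].
#' @return Free energy in kT units (multiply by `thermo$kT` for pN nm).
#' @examples
#' th <- thermo_params()
#' free_energy(crossbridge("2sXB"), 1, tip_position(5, 15), th) # 0
#' @export
free_energy <- function(xb, state, tip, thermo = thermo_params()) {
  state <- check_state(state)
  if (state == 1L) return(0)
  tip <- check_tip_domain(as_tip(tip))
  u <- elastic_energy(xb, tip[[1]], tip[[2]], state)
  -thermo$eff[state] * thermo$dg_total + u / thermo$kT
}

#' Reaction force holding the tip at a position
#'
#' Negative gradient of the total elastic energy with respect to the tip
#' position, decomposed into an axial component (along the filament axis)
#' and a radial component (positive = expansive, pushing the filaments
#' apart). For the 4sXB the gradient of the converter-optimised energy
#' equals, by the envelope property, the explicit tip-gradient at the optimal
#' converter placement, which is what is evaluated. The 1sXB produces no
#' radial force by construction.
#'
#' @param xb A [crossbridge()].
#' @param state Bound state, 2 or 3.
#' @param tip A [tip_position()].
#' @return Named numeric `c(axial =, radial =)` in pN.
#' @export
reaction_force <- function(xb, state, tip) {
  state <- check_state(state)
  if (state == 1L) stop("forces are defined for bound states (2 or 3)",
                        call. = FALSE)
  UseMethod("reaction_force")
}

#' @export
reaction_force.xb_1s <- function(xb, state, tip) {
  tip <- as_tip(tip)
  s <- xb$springs[[1]]
  c(axial = -s$stiffness * (tip[[1]] - spring_rest(s, state)), radial = 0)
}

#' @export
reaction_force.xb_2s <- function(xb, state, tip) {
  tip <- check_tip_domain(as_tip(tip))
  p <- xb2_parts(xb); slot <- state_slot(state)
  tx <- tip[[1]]; ty <- tip[[2]]
  lsq <- tx^2 + ty^2; l <- sqrt(lsq)
  tq <- p$kth * (atan2(ty, tx) - p$a[slot])
  eq <- p$kl * (l - p$r[slot])
  c(axial  = -(tq * (-ty / lsq) + eq * (tx / l)),
    radial = -(tq * ( tx / lsq) + eq * (ty / l)))
}

#' @export
reaction_force.xb_4s <- function(xb, state, tip) {
  tip <- check_tip_domain(as_tip(tip))
  p <- xb4_parts(xb); slot <- state_slot(state)
  sol <- xb4_solve(xb, tip[[1]], tip[[2]], state)
  dx <- tip[[1]] - sol$par[1]; dy <- tip[[2]] - sol$par[2]
  l2sq <- dx^2 + dy^2; l2 <- sqrt(l2sq)
  tq <- p$k2  * (atan2(dy, -dx) - p$a2[slot])
  eq <- p$kl2 * (l2 - p$r2[slot])
  c(axial  = -(tq * ( dy / l2sq) + eq * (dx / l2)),
    radial = -(tq * (-dx / l2sq) + eq * (dy / l2)))
}

#' Axial offset minimising a state's free energy
#'
#' Locates the axial offset at which the bound-state free energy is lowest
#' with the tip on the thin-filament line of the given lattice spacing.
#' A coarse grid brackets the minimum, then golden-section refinement
#' (`stats::optimize`) narrows it to `tol`.
#'
#' @param xb A [crossbridge()].
#' @param state Bound state, 2 or 3.
#' @param d10 Lattice spacing, nm.
#' @param cal A [lattice_calibration()].
#' @param window Axial search window, nm.
#' @param tol Axial tolerance of the refinement, nm.
#' @return Axial offset in nm.
#' @export
argmin_energy_offset <- function(xb, state, d10, cal = lattice_calibration(),
                                 window = c(-25, 25), tol = 1e-4) {
  y <- ssls_from_d10(d10, as_correction(cal))
  u <- function(x) elastic_energy(xb, x, y, state)
  xs <- seq(window[1], window[2], by = 0.5)
  i <- which.min(u(xs))
  lo <- xs[max(1L, i - 2L)]; hi <- xs[min(length(xs), i + 2L)]
  stats::optimize(function(x) vapply(x, u, numeric(1)),
                  interval = c(lo, hi), tol = tol)$minimum
}

#' Power-stroke step size at a lattice spacing
#'
#' The axial distance between the pre- and post-power-stroke equilibrium
#' positions of the myosin head: the axial offset with the lowest free energy
#' in state 2 minus the axial offset with the lowest free energy in state 3,
#' both with the tip on the thin-filament line at the given `d10`. The sign
#' convention makes a forward stroke (head equilibrium moving toward the
#' attachment point) positive. For the one-dimensional 1sXB this is the
#' difference of the two rest lengths, independent of lattice spacing.
#'
#' @inheritParams argmin_energy_offset
#' @return Step size in nm.
#' @examples
#' \donttest{
#' cal <- lattice_calibration()
#' step_size(crossbridge("1sXB"), 34, cal) # 5 nm at every spacing
#' }
#' @export
step_size <- function(xb, d10, cal = lattice_calibration(),
                      window = c(-25, 25), tol = 1e-4) {
  if (xb$name == "1sXB") {
    s <- xb$springs[[1]]
    return(s$rest_pre - s$rest_post)
  }
  argmin_energy_offset(xb, 2, d10, cal, window, tol) -
    argmin_energy_offset(xb, 3, d10, cal, window, tol)
}
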