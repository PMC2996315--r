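#' Cross-bridge tip position
#'
#' The tip is the distal end of the spring chain (the universal joint where
#' the rigid globular domain attaches; the globular domain's fixed length and
#' attachment angle are absorbed into the rest geometry). `axial` is the
#' offset along the thick-filament axis from the cross-bridge's attachment
#' point, positive toward the binding sites; `radial` is the surface-to-
#' surface thick-to-thin filament separation (ssLS).
#'
#' @param axial Axial offset, nm.
#' @param radial Radial separation, nm; must be positive (`NA` allowed for
#'   the one-dimensional 1sXB).
#' @return Named numeric `c(axial =, radial =)` of class `"xb_tip"`.
#' @export
tip_position <- function(axial, radial) {
  stopifnot(is.numeric(axial), length(axial) == 1L, length(radial) == 1L)
  if (!is.na(radial) && radial <= 0)
    stop("radial separation must be positive", call. = FALSE)
  structure(c(axial = as.numeric(axial), radial = as.numeric(radial)),
            class = "xb_tip")
}

as_tip <- function(tip) {
  if (inherits(tip, "xb_tip")) return(tip)
  if (is.numeric(tip) && length(tip) == 2L) return(tip_position(tip[1], tip[2]))
  stop("tip must be a tip_position() or a length-2 numeric (axial, radial)",
       call. = FALSE)
}

# Reject tips outside the physical lattice window rather than extrapolating.
check_tip_domain <- function(tip, min_radial = 0.5) {
  if (!is.na(tip[2]) && tip[2] <= min_radial)
    stop(sprintf("degenerate tip: radial separation %.3g nm <= %.3g nm",
                 tip[2], min_radial), call. = FALSE)
  tip
}

# ---- internal parameter extraction -----------------------------------------

xb4_parts <- function(xb) {
  s <- xb$springs
  list(a1 = c(s[[1]]$rest_pre, s[[1]]$rest_post), k1 = s[[1]]$stiffness,
       r1 = c(s[[2]]$rest_pre, s[[2]]$rest_post), kl1 = s[[2]]$stiffness,
       a2 = c(s[[3]]$rest_pre, s[[3]]$rest_post), k2 = s[[3]]$stiffness,
       r2 = c(s[[4]]$rest_pre, s[[4]]$rest_post), kl2 = s[[4]]$stiffness)
}

xb2_parts <- function(xb) {
  s <- xb$springs
  list(a = c(s[[1]]$rest_pre, s[[1]]$rest_post), kth = s[[1]]$stiffness,
       r = c(s[[2]]$rest_pre, s[[2]]$rest_post), kl = s[[2]]$stiffness)
}

state_slot <- function(state) if (check_state(state) == 3L) 2L else 1L

# Four-spring energy as a function of the converter point (cx, cy) for a
# fixed tip (tx, ty); used by the solver. Vectorised over cx/cy.
xb4_conv_energy <- function(cx, cy, tx, ty, p, slot) {
  th1 <- atan2(cy, cx); l1 <- sqrt(cx^2 + cy^2)
  dx <- tx - cx; dy <- ty - cy; l2 <- sqrt(dx^2 + dy^2)
  th2 <- atan2(dy, -dx)
  0.5 * p$k1  * (th1 - p$a1[slot])^2 + 0.5 * p$kl1 * (l1 - p$r1[slot])^2 +
  0.5 * p$k2  * (th2 - p$a2[slot])^2 + 0.5 * p$kl2 * (l2 - p$r2[slot])^2
}

xb4_conv_gradient <- function(cx, cy, tx, ty, p, slot) {
  th1 <- atan2(cy, cx); l1 <- sqrt(cx^2 + cy^2)
  dx <- tx - cx; dy <- ty - cy; l2sq <- dx^2 + dy^2; l2 <- sqrt(l2sq)
  th2 <- atan2(dy, -dx)
  t1 <- p$k1 * (th1 - p$a1[slot]); e1 <- p$kl1 * (l1 - p$r1[slot])
  t2 <- p$k2 * (th2 - p$a2[slot]); e2 <- p$kl2 * (l2 - p$r2[slot])
  c(t1 * (-cy / l1^2) + e1 * (cx / l1) + t2 * (-dy / l2sq) + e2 * (-dx / l2),
    t1 * ( cx / l1^2) + e1 * (cy / l1) + t2 * ( dx / l2sq) + e2 * (-dy / l2))
}

# Minimise the converter placement for a fixed tip. Quasi-Newton with the
# analytic gradient, starting from the state's rest converter point; jittered
# restarts guard against the rare failed line search far from rest.
xb4_solve <- function(xb, tx, ty, state, tol = 1e-8, maxit = 500L,
                      restarts = 5L) {
  p <- xb4_parts(xb); slot <- state_slot(state)
  c0 <- p$r1[slot] * c(cos(p$a1[slot]), sin(p$a1[slot]))
  f <- function(q) xb4_conv_energy(q[1], q[2], tx, ty, p, slot)
  g <- function(q) xb4_conv_gradient(q[1], q[2], tx, ty, p, slot)
  best <- NULL
  starts <- c0
  for (i in seq_len(restarts + 1L)) {
    o <- tryCatch(
      stats::optim(starts, f, g, method = "BFGS",
                   control = list(maxit = maxit, reltol = tol * 1e-4,
                                  abstol = tol)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    if (!is.null(best) && best$convergence == 0 &&
        sum(g(best$par)^2) < 1e-10) break
    # jitter the start; deterministic offsets so solves stay reproducible
    starts <- c0 + 0.5 * i * c(cos(2.4 * i), sin(2.4 * i))
  }
  if (is.null(best))
    stop("4sXB converter optimisation failed at tip (", tx, ", ", ty, ")",
         call. = FALSE)
  if (best$convergence != 0 && sum(g(best$par)^2) >= 1e-8) {
    cond <- simpleError(sprintf(
      "4sXB converter optimisation did not converge at tip (%.3f, %.3f)",
      tx, ty))
    cond$last_iterate <- best$par
    stop(cond)
  }
  best
}

# ---- elastic energy ---------------------------------------------------------

#' Total elastic energy at a tip position
#'
#' Sum of the spring energies with the given state's rest values, the
#' remaining geometric freedom (the 4sXB converter point) relaxed to its
#' minimum-energy placement. Vectorised over `axial`/`radial`.
#'
#' @param xb A [crossbridge()].
#' @param axial,radial Tip coordinates in nm (recycled to common length).
#' @param state Kinetic state 1-3.
#' @param ... Passed to the 4sXB solver ([solve_geometry()] tolerances).
#' @return Elastic energy in pN nm.
#' @export
elastic_energy <- function(xb, axial, radial, state, ...) {
  UseMethod("elastic_energy")
}

#' @export
elastic_energy.xb_1s <- function(xb, axial, radial, state, ...) {
  s <- xb$springs[[1]]
  0.5 * s$stiffness * (axial - spring_rest(s, state))^2
}

#' @export
elastic_energy.xb_2s <- function(xb, axial, radial, state, ...) {
  p <- xb2_parts(xb); slot <- state_slot(state)
  th <- atan2(radial, axial); l <- sqrt(axial^2 + radial^2)
  0.5 * p$kth * (th - p$a[slot])^2 + 0.5 * p$kl * (l - p$r[slot])^2
}

#' @export
elastic_energy.xb_4s <- function(xb, axial, radial, state, ...) {
  n <- max(length(axial), length(radial))
  axial <- rep_len(axial, n); radial <- rep_len(radial, n)
  vapply(seq_len(n), function(i)
    xb4_solve(xb, axial[i], radial[i], state, ...)$value, numeric(1))
}

# ---- full geometry solutions ------------------------------------------------

#' Solve the spring lengths and angles for a tip position
#'
#' For the 2sXB the solution is closed-form: the arm length is the Euclidean
#' base-to-tip distance and the base angle the inclination of the base-to-tip
#' vector over the thick-filament axis. For the 4sXB the converter point is
#' free and is found by minimising the total elastic energy (quasi-Newton
#' with analytic gradient, started from the state's rest converter
#' placement); the remaining angles and lengths then follow analytically from
#' the converter point.
#'
#' @param xb A [crossbridge()].
#' @param tip A [tip_position()] (or length-2 numeric `(axial, radial)`).
#' @param state Kinetic state 1-3 (selects the rest values).
#' @param tol Energy tolerance for the 4sXB converter optimisation, pN nm.
#' @param maxit Iteration budget for the optimiser.
#' @return An object of class `"xb_geometry"`: list with `spring_values`
#'   (named, in spring order), `converter_point` (4sXB only),
#'   `elastic_energy` (pN nm) and `state`.
#' @examples
#' solve_geometry(crossbridge("2sXB"), tip_position(10, 10), state = 2)
#' @export
solve_geometry <- function(xb, tip, state, tol = 1e-8, maxit = 500L) {
  UseMethod("solve_geometry")
}

xb_geometry <- function(xb, values, energy, state, converter = NULL) {
  names(values) <- vapply(xb$springs, `[[`, character(1), "label")
  structure(list(model = xb$name, spring_values = values,
                 converter_point = converter,
                 elastic_energy = energy, state = check_state(state)),
            class = "xb_geometry")
}

#' @export
solve_geometry.xb_1s <- function(xb, tip, state, tol = 1e-8, maxit = 500L) {
  tip <- as_tip(tip)
  xb_geometry(xb, tip[[1]],
              elastic_energy(xb, tip[[1]], tip[[2]], state), state)
}

#' @export
solve_geometry.xb_2s <- function(xb, tip, state, tol = 1e-8, maxit = 500L) {
  tip <- check_tip_domain(as_tip(tip))
  l <- sqrt(sum(tip^2))
  if (l < 1e-9)
    stop("tip coincides with the cross-bridge base: angle undefined",
         call. = FALSE)
  vals <- c(atan2(tip[[2]], tip[[1]]), l)
  xb_geometry(xb, vals, elastic_energy(xb, tip[[1]], tip[[2]], state), state)
}

#' @export
solve_geometry.xb_4s <- function(xb, tip, state, tol = 1e-8, maxit = 500L) {
  tip <- check_tip_domain(as_tip(tip))
  sol <- xb4_solve(xb, tip[[1]], tip[[2]], state, tol = tol, maxit = maxit)
  cx <- sol$par[1]; cy <- sol$par[2]
  dx <- tip[[1]] - cx; dy <- tip[[2]] - cy
  vals <- c(atan2(cy, cx), sqrt(cx^2 + cy^2), atan2(dy, -dx),
            sqrt(dx^2 + dy^2))
  xb_geometry(xb, vals, sol$value, state,
              converter = c(axial = cx, radial = cy))
}

#' Forward kinematics: tip position from spring values
#'
#' Inverse of [solve_geometry()] (up to the 4sXB's converter redundancy):
#' given one current value per spring, in the model's spring order, return
#' the tip position.
#'
#' @param xb A [crossbridge()].
#' @param values Numeric vector, one value per spring (radians / nm).
#' @return A [tip_position()].
#' @export
tip_from_springs <- function(xb, values) {
  stopifnot(inherits(xb, "crossbridge"),
            is.numeric(values), length(values) == length(xb$springs))
  switch(xb$name,
    "1sXB" = tip_position(values[1], NA_real_),
    "2sXB" = tip_position(values[2] * cos(values[1]),
                          values[2] * sin(values[1])),
    "4sXB" = {
      cx <- values[2] * cos(values[1]); cy <- values[2] * sin(values[1])
      tip_position(cx - values[4] * cos(values[3]),
                   cy + values[4] * sin(values[3]))
    })
}

#' @export
print.xb_geometry <- function(x, ...) {
  cat(sprintf("<xb_geometry> %s, state %d: U = %.6g pN nm\n",
              x$model, x$state, x$elastic_energy))
  print(signif(x$spring_values, 6))
  if (!is.null(x$converter_point))
    cat(sprintf("  converter point: (%.4f, %.4f) nm\n",
                x$converter_point[1], x$converter_point[2]))
  invisible(x)
}
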