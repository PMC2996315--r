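#' Linear-elastic cross-bridge springs
#'
#' A cross-bridge is assembled from linearly elastic elements of three kinds:
#' `"torsional"` (watch-spring; value is an angle in radians, stiffness in
#' pN nm/rad), `"extensional"` (Hookean; value is a length in nm, stiffness in
#' pN/nm, rest length strictly positive) and `"axial"` (a signed Hookean
#' offset along the filament axis, used by the single-spring reference model,
#' whose rest value may be any real number including zero).
#'
#' Each spring carries two rest values: `rest_pre` applies in the detached and
#' pre-power-stroke states (states 1 and 2) and `rest_post` in the
#' post-power-stroke state (state 3). The power stroke is represented purely
#' as this switch of rest values; no spring is added or removed between
#' states.
#'
#' @param kind One of `"torsional"`, `"extensional"`, `"axial"`.
#' @param rest_pre,rest_post Rest value in the pre- (states 1-2) and
#'   post-power-stroke (state 3) conformations. Radians for torsional
#'   springs, nm otherwise. `rest_post` defaults to `rest_pre` (a spring that
#'   does not participate in the stroke).
#' @param stiffness Spring constant, `> 0`. pN nm/rad for torsional springs
#'   (a printed "pN/rad" convention is interpreted this way so that
#'   \eqn{\frac{1}{2} k \Delta\theta^2} is an energy in pN nm), pN/nm
#'   otherwise.
#' @param label Optional short name used in printing and solver output.
#' @return An object of class `"xb_spring"`.
#' @examples
#' s2 <- xb_spring("extensional", rest_pre = 10.5, stiffness = 10, label = "S2")
#' spring_energy(s2, 11.5, state = 2) # 0.5 * 10 * 1^2 = 5 pN nm
#' @export
xb_spring <- function(kind = c("torsional", "extensional", "axial"),
                      rest_pre, rest_post = rest_pre, stiffness,
                      label = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(rest_pre), length(rest_pre) == 1L,
            is.numeric(rest_post), length(rest_post) == 1L,
            is.numeric(stiffness), length(stiffness) == 1L)
  if (!is.finite(stiffness) || stiffness <= 0)
    stop("spring stiffness must be a positive number", call. = FALSE)
  if (kind == "torsional" &&
      (rest_pre <= 0 || rest_pre >= pi || rest_post <= 0 || rest_post >= pi))
    stop("torsional rest angles must lie in (0, pi) radians", call. = FALSE)
  if (kind == "extensional" && (rest_pre <= 0 || rest_post <= 0))
    stop("extensional rest lengths must be > 0 nm", call. = FALSE)
  structure(list(kind = kind, rest_pre = rest_pre, rest_post = rest_post,
                 stiffness = stiffness,
                 label = label %||% kind),
            class = "xb_spring")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rest value of a spring in a given kinetic state
#'
#' States 1 (detached) and 2 (pre-power-stroke) use `rest_pre`; state 3
#' (post-power-stroke) uses `rest_post`.
#'
#' @param spring An [xb_spring()].
#' @param state Kinetic state, 1, 2 or 3.
#' @return Rest value (nm or radians).
#' @export
spring_rest <- function(spring, state) {
  stopifnot(inherits(spring, "xb_spring"))
  state <- check_state(state)
  if (state == 3L) spring$rest_post else spring$rest_pre
}

#' Elastic energy stored in one spring
#'
#' \eqn{U = \frac{1}{2} k (v - v_0(\mathrm{state}))^2} in pN nm, with the rest
#' value \eqn{v_0} switching between the pre- and post-power-stroke
#' conformations.
#'
#' @inheritParams spring_rest
#' @param value Current spring value (nm or radians); vectorised.
#' @return Energy in pN nm, same length as `value`.
#' @export
spring_energy <- function(spring, value, state) {
  stopifnot(inherits(spring, "xb_spring"), is.numeric(value))
  if (spring$kind == "extensional" && any(value <= 0))
    stop("extensional spring length must be > 0 nm", call. = FALSE)
  0.5 * spring$stiffness * (value - spring_rest(spring, state))^2
}

check_state <- function(state) {
  if (!is.numeric(state) || length(state) != 1L || !(state %in% 1:3))
    stop("state must be 1 (detached), 2 (pre-stroke) or 3 (post-stroke)",
         call. = FALSE)
  as.integer(state)
}

#' @export
print.xb_spring <- function(x, ...) {
  unit <- if (x$kind == "torsional") c("rad", "pN nm/rad") else c("nm", "pN/nm")
  cat(sprintf("<xb_spring> %s (%s): rest %.4g -> %.4g %s, k = %.4g %s\n",
              x$label, x$kind, x$rest_pre, x$rest_post, unit[1],
              x$stiffness, unit[2]))
  invisible(x)
}
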