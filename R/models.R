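#' Default cross-bridge parameter set
#'
#' Returns the shipped parameter table for the three cross-bridge models:
#' the four-spring 4sXB (torsional spring at the S2/rod junction, extensional
#' S2, torsional converter between S2 and the light-chain domain, extensional
#' LCD), the two-spring 2sXB (one torsional spring at the filament backbone
#' plus one extensional lever arm) and the one-dimensional single-spring
#' reference 1sXB. Angles are stored in degrees in the parameter file and
#' converted to radians when a [crossbridge()] is built.
#'
#' The 2sXB rest values are not free parameters: they are derived so that the
#' 2sXB tip coincides with the 4sXB tip in both the pre- and post-power-stroke
#' rest conformations (`rest_pre`/`rest_post: "derived"` in the file).
#'
#' @param file Path to a YAML parameter file; the default is the copy shipped
#'   with the package.
#' @return A nested list with one entry per model, each holding `springs`
#'   (list of spring descriptions) and the Monte-Carlo binding scale factor
#'   `tau` (nm^2) where applicable.
#' @seealso [read_xb_params()], [write_xb_params()], [crossbridge()]
#' @export
xb_params_default <- function(file = system.file("extdata", "xb_params.yaml",
                                                 package = "xbmech")) {
  read_xb_params(file)
}

#' Read / write a cross-bridge parameter file
#'
#' The parameter file is YAML with one block per model; each spring has
#' `kind` (torsional/extensional/axial), `rest_pre`, `rest_post`, `stiffness`
#' and `label`. Torsional rest values are in degrees, extensional in nm;
#' stiffnesses in pN nm/rad and pN/nm respectively. A rest value may be the
#' string `"derived"` for the 2sXB (computed from the 4sXB rest geometry).
#'
#' @param path File path.
#' @return `read_xb_params()` returns the parameter list; `write_xb_params()`
#'   returns `path` invisibly.
#' @export
read_xb_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  prm <- yaml::read_yaml(path)
  if (is.null(prm$models)) stop("parameter file has no 'models' block", call. = FALSE)
  prm
}

#' @rdname read_xb_params
#' @param params Parameter list as returned by [xb_params_default()].
#' @export
write_xb_params <- function(params, path) {
  yaml::write_yaml(params, path)
  invisible(path)
}

#' Build a cross-bridge model
#'
#' Assembles the named spring system from a parameter set. The 4sXB places
#' its base (the S2/rod junction) at the origin of a two-dimensional frame
#' whose x axis is the thick-filament axis (axial direction, positive toward
#' the binding sites) and whose y axis is the radial thick-to-thin filament
#' separation. Its converter angle is measured between the light-chain domain
#' and the thick-filament axis, so that the LCD direction is
#' \eqn{(-\cos\theta, \sin\theta)}; the power stroke rotates this rest angle
#' from 125 to 70 degrees. The 2sXB rest angle/length pairs are computed so
#' that its tip coincides with the 4sXB tip in both rest conformations.
#'
#' @param name `"4sXB"`, `"2sXB"` or `"1sXB"`.
#' @param params Parameter list, by default the shipped defaults.
#' @return An object of class `c("xb_<name>", "crossbridge")` with elements
#'   `name`, `springs` (list of [xb_spring()]) and `tau` (binding scale
#'   factor, `NA` for the 1sXB).
#' @examples
#' xb <- crossbridge("2sXB")
#' tip_rest(xb, state = 3)
#' @export
crossbridge <- function(name = c("4sXB", "2sXB", "1sXB"),
                        params = xb_params_default()) {
  name <- match.arg(name)
  spec <- params$models[[name]]
  if (is.null(spec)) stop("no parameters for model ", name, call. = FALSE)

  build <- function(s, rest_pre = NULL, rest_post = NULL) {
    to_native <- function(v) if (s$kind == "torsional") v * pi / 180 else v
    xb_spring(s$kind,
              rest_pre  = rest_pre  %||% to_native(s$rest_pre),
              rest_post = rest_post %||% to_native(s$rest_post),
              stiffness = s$stiffness, label = s$label)
  }

  if (name == "2sXB" && any(vapply(spec$springs, function(s)
        identical(s$rest_pre, "derived") || identical(s$rest_post, "derived"),
        logical(1)))) {
    ref <- crossbridge(spec$derive_rest_from %||% "4sXB", params = params)
    pre <- unname(tip_rest(ref, state = 2))
    post <- unname(tip_rest(ref, state = 3))
    rests <- list(
      torsional   = c(atan2(pre[2], pre[1]), atan2(post[2], post[1])),
      extensional = c(sqrt(sum(pre^2)),      sqrt(sum(post^2))))
    springs <- lapply(spec$springs, function(s)
      build(s, rest_pre = rests[[s$kind]][1], rest_post = rests[[s$kind]][2]))
  } else {
    springs <- lapply(spec$springs, build)
  }

  n_expect <- c(`4sXB` = 4L, `2sXB` = 2L, `1sXB` = 1L)[[name]]
  if (length(springs) != n_expect)
    stop(name, " requires ", n_expect, " springs, got ", length(springs),
         call. = FALSE)

  structure(list(name = name, springs = springs,
                 tau = spec$tau %||% NA_real_),
            class = c(paste0("xb_", tolower(substr(name, 1, 2))), "crossbridge"))
}

#' Unstrained tip position of a cross-bridge
#'
#' Forward kinematics at the rest spring values of the given state. For the
#' 1sXB (a purely axial spring) the radial coordinate is `NA`: the model has
#' no radial geometry.
#'
#' @param xb A [crossbridge()].
#' @param state Kinetic state 1-3 (states 1 and 2 share rest values).
#' @return A [tip_position()]: named numeric `c(axial =, radial =)` in nm.
#' @export
tip_rest <- function(xb, state) {
  stopifnot(inherits(xb, "crossbridge"))
  tip_from_springs(xb, vapply(xb$springs, spring_rest, numeric(1),
                              state = state))
}

#' @export
print.crossbridge <- function(x, ...) {
  cat(sprintf("<crossbridge> %s (%d spring%s)\n", x$name, length(x$springs),
              if (length(x$springs) > 1) "s" else ""))
  for (s in x$springs) print(s)
  if (is.finite(x$tau)) cat(sprintf("  binding scale tau = %g nm^2\n", x$tau))
  pre <- tip_rest(x, 2); post <- tip_rest(x, 3)
  cat(sprintf("  rest tip: pre (%.3f, %.3f) -> post (%.3f, %.3f) nm\n",
              pre[1], pre[2], post[1], post[2]))
  invisible(x)
}
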