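#' Scan cross-bridge landscapes over axial offset and lattice spacing
#'
#' Evaluates the requested layers on the rectangular axial x d10 grid used
#' throughout the package's landscape figures. Available layers:
#' free energies `"energy2"`, `"energy3"` (pN nm, efficiency-scaled ATP term
#' plus strain), forward rates `"r12"` (Monte-Carlo, with standard error),
#' `"r23"`, `"r31"`, reverse rates `"r21"`, `"r32"`, `"r13"` (detailed
#' balance; the 3 -> 1 step crosses the ATP-turnover boundary so its reverse
#' balances against the full per-cycle budget), and post-stroke reaction
#' forces `"f_axial"`, `"f_radial"` (pN). Aliases: `"energy"` for both
#' energies, `"force"` for both force components.
#'
#' Deterministic layers are exact grid evaluations (bit-identical across
#' runs); stochastic layers record ensemble size and a per-cell seed derived
#' from `seed`. Cells where the geometry solver fails are recorded as `NaN`
#' and counted in the `failures` attribute rather than aborting the scan.
#'
#' @param xb A [crossbridge()].
#' @param layers Character vector of layer names (see Details).
#' @param axial,d10 Grid vectors, nm.
#' @param n Monte-Carlo ensemble size per cell for stochastic layers.
#' @param seed Base integer seed for stochastic layers.
#' @param kin,thermo,cal Parameter objects ([kinetic_params()],
#'   [thermo_params()], [lattice_calibration()]).
#' @return An `xb_landscape`: data frame with one row per grid cell, columns
#'   `model`, `d10_nm`, `axial_nm` and one column per layer (`r12_se`,
#'   `mc_n`, `mc_seed` accompany stochastic layers), with provenance in
#'   attributes.
#' @examples
#' \donttest{
#' g <- scan_landscape(crossbridge("2sXB"), layers = "energy",
#'                     axial = seq(0, 20, 1), d10 = c(32, 34, 36))
#' head(g)
#' }
#' @export
scan_landscape <- function(xb, layers = c("energy", "r12", "r31", "force"),
                           axial = seq(-5, 25, by = 0.25),
                           d10 = seq(30, 38, by = 0.5),
                           n = 1e4, seed = NULL,
                           kin = kinetic_params(), thermo = thermo_params(),
                           cal = lattice_calibration()) {
  stopifnot(inherits(xb, "crossbridge"), length(axial) > 0, length(d10) > 0)
  layers <- expand_layers(layers)
  grid <- expand.grid(axial_nm = axial, d10_nm = d10,
                      KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(model = xb$name, d10_nm = grid$d10_nm,
                    axial_nm = grid$axial_nm)
  y <- ssls_from_d10(grid$d10_nm, as_correction(cal))
  failures <- 0L

  cell_energy <- function(x, yy, state) {
    tryCatch(elastic_energy(xb, x, yy, state), error = function(e) NaN)
  }
  need_u2 <- any(c("energy2", "r23", "r32", "r21") %in% layers)
  need_u3 <- any(c("energy3", "r23", "r32", "r31", "r13") %in% layers)
  if (need_u2) u2 <- mapply(cell_energy, grid$axial_nm, y, 2L)
  if (need_u3) u3 <- mapply(cell_energy, grid$axial_nm, y, 3L)
  if (need_u2) failures <- failures + sum(is.nan(u2))
  if (need_u3) failures <- failures + sum(is.nan(u3))

  gk <- function(state, u) -thermo$eff[state] * thermo$dg_total + u / thermo$kT
  if ("energy2" %in% layers) out$energy2 <- gk(2, u2) * thermo$kT
  if ("energy3" %in% layers) out$energy3 <- gk(3, u3) * thermo$kT
  if (any(c("r23", "r32") %in% layers)) {
    dg23 <- gk(3, u3) - gk(2, u2)
    r23 <- 0.5 * kin$r23_max * (1 + tanh(-kin$gamma * dg23))
    if ("r23" %in% layers) out$r23 <- r23
    if ("r32" %in% layers) out$r32 <- rate_reverse(r23, dg23, kin)
  }
  if (any(c("r31", "r13") %in% layers)) {
    r31 <- kin$r31_unstrained * clamp_exp(kin$detach_sensitivity * u3,
                                          kin$clamp)
    if ("r31" %in% layers) out$r31 <- r31
    if ("r13" %in% layers)
      out$r13 <- rate_reverse(r31, -thermo$dg_total - gk(3, u3), kin)
  }
  if (any(c("f_axial", "f_radial") %in% layers)) {
    ff <- mapply(function(x, yy) {
      tryCatch(reaction_force(xb, 3, c(x, yy)),
               error = function(e) { c(NaN, NaN) })
    }, grid$axial_nm, y)
    failures <- failures + sum(is.nan(ff[1, ]))
    if ("f_axial" %in% layers) out$f_axial <- ff[1, ]
    if ("f_radial" %in% layers) out$f_radial <- ff[2, ]
  }
  if (any(c("r12", "r21") %in% layers)) {
    seeds <- if (is.null(seed)) rep(NA_integer_, nrow(grid)) else
      as.integer((seed + 7919 * (seq_len(nrow(grid)) - 1)) %% .Machine$integer.max)
    est <- mapply(function(x, d, s) {
      r <- rate_attach(xb, x, d, n = n, kin = kin, thermo = thermo,
                       cal = cal, seed = if (is.na(s)) NULL else s)
      c(r$value, r$se)
    }, grid$axial_nm, grid$d10_nm, seeds)
    if ("r12" %in% layers) { out$r12 <- est[1, ]; out$r12_se <- est[2, ] }
    if ("r21" %in% layers) {
      if (!exists("u2", inherits = FALSE))
        u2 <- mapply(cell_energy, grid$axial_nm, y, 2L)
      out$r21 <- rate_reverse(est[1, ], gk(2, u2), kin)
    }
    out$mc_n <- n; out$mc_seed <- seeds
  }

  if (failures > 0)
    message("scan_landscape: ", failures, " cell evaluations failed (NaN)")
  structure(out,
            xb = xb, kin = kin, thermo = thermo, cal = cal,
            layers = layers, seed = seed, failures = failures,
            axial = axial, d10 = d10,
            class = c("xb_landscape", class(out)))
}

expand_layers <- function(layers) {
  known <- c("energy2", "energy3", "r12", "r21", "r23", "r32", "r31", "r13",
             "f_axial", "f_radial")
  out <- unlist(lapply(layers, function(l) switch(l,
    energy = c("energy2", "energy3"), force = c("f_axial", "f_radial"), l)))
  bad <- setdiff(out, known)
  if (length(bad)) stop("unknown layer(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  unique(out)
}

#' @export
print.xb_landscape <- function(x, ...) {
  cat(sprintf("<xb_landscape> %s: %d x %d grid (axial x d10), layers: %s\n",
              x$model[1], length(attr(x, "axial")), length(attr(x, "d10")),
              paste(attr(x, "layers"), collapse = ", ")))
  NextMethod()
}

#' Locate landscape extrema per lattice spacing
#'
#' For every d10 in the grid, finds the axial offsets of the
#' pre-/post-stroke free-energy minima (refined continuously from the best
#' grid cell), the attachment-rate maximum (quadratic refinement of the
#' Monte-Carlo profile when present), the power-stroke inflection (steepest
#' descent of `r23` on the grid), and the detachment minimum (refined), plus
#' the step size.
#'
#' @param grid An [scan_landscape()] result.
#' @return Data frame of class `"xb_offsets"`, one row per d10.
#' @export
summarize_offsets <- function(grid) {
  stopifnot(inherits(grid, "xb_landscape"))
  xb <- attr(grid, "xb"); cal <- attr(grid, "cal")
  kin <- attr(grid, "kin"); thermo <- attr(grid, "thermo")
  axial <- attr(grid, "axial")
  window <- range(axial)
  rows <- lapply(attr(grid, "d10"), function(d) {
    sub <- grid[grid$d10_nm == d, ]
    a2 <- argmin_energy_offset(xb, 2, d, cal, window = window)
    a3 <- argmin_energy_offset(xb, 3, d, cal, window = window)
    peak_r12 <- if ("r12" %in% names(sub))
      quad_peak(sub$axial_nm, sub$r12) else NA_real_
    infl_r23 <- if ("r23" %in% names(sub) && nrow(sub) > 2) {
      dr <- diff(sub$r23) / diff(sub$axial_nm)
      mid <- (sub$axial_nm[-1] + sub$axial_nm[-nrow(sub)]) / 2
      mid[which.max(abs(dr))]
    } else NA_real_
    min_r31 <- if ("r31" %in% names(sub)) {
      o <- stats::optimize(function(x)
        rate_detach(xb, x, d, kin, thermo, cal),
        interval = bracket_around(sub$axial_nm, which.min(sub$r31)),
        tol = 1e-4)
      c(o$minimum, o$objective)
    } else c(NA_real_, NA_real_)
    data.frame(d10_nm = d, argmin_energy2_nm = a2, argmin_energy3_nm = a3,
               step_nm = a2 - a3, argmax_r12_nm = peak_r12,
               inflection_r23_nm = infl_r23,
               argmin_r31_nm = min_r31[1], min_r31_per_s = min_r31[2])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("xb_offsets", class(out))
  out
}

bracket_around <- function(x, i) {
  c(x[max(1L, i - 2L)], x[min(length(x), i + 2L)])
}

# vertex of a local quadratic fit around the best grid point (two cells to
# either side, where available); falls back to the grid argmax when the fit
# is not concave or the peak sits on the window edge
quad_peak <- function(x, yv) {
  i <- which.max(yv)
  if (i == 1L || i == length(x)) return(x[i])
  j <- max(1L, i - 2L):min(length(x), i + 2L)
  co <- stats::coef(stats::lm(yv[j] ~ x[j] + I(x[j]^2)))
  if (!is.finite(co[3]) || co[3] >= 0) return(x[i])
  vertex <- -co[2] / (2 * co[3])
  if (vertex < min(x[j]) || vertex > max(x[j])) x[i] else unname(vertex)
}

#' Mask grid cells where a cross-bridge is unlikely to generate force
#'
#' Scores each cell by the attachment rate plus the inverse detachment rate
#' (fast binding or long post-stroke dwell = likely to be occupied) and
#' flags cells scoring below a threshold. When `threshold` is `NULL` it is
#' chosen as the largest value that keeps cells carrying at least `retain`
#' of the total attachment flux; the rule and threshold are recorded in the
#' `mask_rule` attribute. Raising the threshold never unmasks a cell.
#'
#' @param grid An [scan_landscape()] with `r12` and `r31` layers.
#' @param threshold Score cutoff; `NULL` for the flux-retention default.
#' @param retain Fraction of attachment flux the default threshold retains.
#' @return The grid with a logical `unlikely` column added.
#' @export
mask_unlikely <- function(grid, threshold = NULL, retain = 0.95) {
  stopifnot(inherits(grid, "xb_landscape"))
  if (!all(c("r12", "r31") %in% names(grid)))
    stop("mask rule needs the r12 and r31 layers", call. = FALSE)
  score <- grid$r12 + 1 / grid$r31
  if (is.null(threshold)) {
    o <- order(score, decreasing = TRUE)
    flux <- cumsum(grid$r12[o]) / sum(grid$r12)
    keep <- o[seq_len(which(flux >= retain)[1])]
    threshold <- min(score[keep])
  }
  grid$unlikely <- score < threshold
  attr(grid, "mask_rule") <- list(rule = "r12 + 1/r31 < threshold",
                                  threshold = threshold, retain = retain)
  grid
}

#' Step-size curve over a lattice-spacing window
#'
#' @param xb A [crossbridge()].
#' @param d10 Lattice-spacing grid, nm.
#' @param cal A [lattice_calibration()].
#' @param ... Passed to [step_size()].
#' @return `step_size_curve()`: data frame `d10_nm`, `step_nm`.
#'   `max_step_size()`: list with the maximum `step_nm` and its `d10_nm`,
#'   located by refining around the best grid point.
#' @export
step_size_curve <- function(xb, d10 = seq(30, 38, by = 0.5),
                            cal = lattice_calibration(), ...) {
  data.frame(d10_nm = d10,
             step_nm = vapply(d10, function(d) step_size(xb, d, cal, ...),
                              numeric(1)))
}

#' @rdname step_size_curve
#' @export
max_step_size <- function(xb, d10 = seq(30, 38, by = 0.5),
                          cal = lattice_calibration(), ...) {
  curve <- step_size_curve(xb, d10, cal, ...)
  i <- which.max(curve$step_nm)
  br <- bracket_around(curve$d10_nm, i)
  o <- stats::optimize(function(d) -step_size(xb, d, cal, ...),
                       interval = br, tol = 1e-3)
  if (-o$objective >= curve$step_nm[i])
    list(step_nm = -o$objective, d10_nm = o$minimum)
  else # maximum sits on the window edge
    list(step_nm = curve$step_nm[i], d10_nm = curve$d10_nm[i])
}

#' Write landscape CSVs
#'
#' `write_energy_csv()` emits the energetics schema (`model`, `state`,
#' `d10_nm`, `axial_nm`, `energy_pNnm`, `f_axial_pN`, `f_radial_pN`; forces
#' are post-stroke and reported on state-3 rows). `write_rate_csv()` emits
#' the rate-map schema (`model`, `transition`, `d10_nm`, `axial_nm`,
#' `rate_per_s`, `se_per_s`, `n`, `seed`).
#'
#' @param grid An [scan_landscape()] result with the relevant layers.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_energy_csv <- function(grid, path) {
  stopifnot(inherits(grid, "xb_landscape"),
            all(c("energy2", "energy3") %in% names(grid)))
  rows <- lapply(c(2L, 3L), function(s) {
    data.frame(model = grid$model, state = s, d10_nm = grid$d10_nm,
               axial_nm = grid$axial_nm,
               energy_pNnm = grid[[paste0("energy", s)]],
               f_axial_pN = if (s == 3L && "f_axial" %in% names(grid))
                 grid$f_axial else NA_real_,
               f_radial_pN = if (s == 3L && "f_radial" %in% names(grid))
                 grid$f_radial else NA_real_)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_energy_csv
#' @export
write_rate_csv <- function(grid, path) {
  stopifnot(inherits(grid, "xb_landscape"))
  trans <- intersect(c("r12", "r21", "r23", "r32", "r31", "r13"), names(grid))
  if (!length(trans)) stop("no rate layers in grid", call. = FALSE)
  rows <- lapply(trans, function(tr) {
    data.frame(model = grid$model, transition = tr, d10_nm = grid$d10_nm,
               axial_nm = grid$axial_nm, rate_per_s = grid[[tr]],
               se_per_s = if (tr == "r12" && "r12_se" %in% names(grid))
                 grid$r12_se else 0,
               n = if (tr %in% c("r12", "r21") && "mc_n" %in% names(grid))
                 grid$mc_n else NA_integer_,
               seed = if (tr %in% c("r12", "r21") && "mc_seed" %in% names(grid))
                 grid$mc_seed else NA_integer_)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Image plot of one landscape layer
#'
#' @param x An [scan_landscape()] result.
#' @param layer Column to plot.
#' @param ... Passed to [graphics::image()].
#' @export
plot.xb_landscape <- function(x, layer = intersect(attr(x, "layers"),
                                                   names(x))[1], ...) {
  axial <- attr(x, "axial"); d10 <- attr(x, "d10")
  z <- matrix(x[[layer]], nrow = length(axial), ncol = length(d10))
  graphics::image(axial, d10, z, col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "axial offset (nm)", ylab = "d10 (nm)",
                  main = sprintf("%s: %s", x$model[1], layer), ...)
  graphics::contour(axial, d10, z, add = TRUE, col = "white", lwd = 0.5)
  invisible(x)
}
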