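#' Configuration for a single cross-bridge simulation
#'
#' Bundles everything a stochastic trajectory needs. The default binding
#' site sits at the axial offset minimising the pre-stroke free energy at
#' the chosen spacing (the head's bound equilibrium position).
#'
#' @param model Model name or a [crossbridge()].
#' @param d10 Lattice spacing, nm.
#' @param duration Simulated time, s.
#' @param seed Integer seed; trajectories with equal seed and configuration
#'   are identical.
#' @param site_axial Axial position(s) of the binding site, nm; the first
#'   site is used by [simulate_xb()].
#' @param thermo A [thermo_params()] (supplies the 1 ms time step).
#' @param kin A [kinetic_params()].
#' @param cal A [lattice_calibration()].
#' @param n_attach Ensemble size used once per simulation to estimate the
#'   attachment rate entering the detailed-balance 2 -> 1 reverse rate.
#' @return List of class `"xb_simconfig"`.
#' @export
sim_config <- function(model = "4sXB", d10 = 34, duration = 10, seed = NULL,
                       site_axial = NULL, thermo = thermo_params(),
                       kin = kinetic_params(),
                       cal = NULL, n_attach = 1e4) {
  xb <- if (inherits(model, "crossbridge")) model else crossbridge(model)
  if (xb$name == "1sXB")
    stop("trajectory simulation targets the two-dimensional models",
         call. = FALSE)
  cal <- cal %||% lattice_calibration(crossbridge("4sXB"))
  if (duration < thermo$dt) stop("duration must cover at least one time step",
                                 call. = FALSE)
  site_axial <- site_axial %||% argmin_energy_offset(xb, 2, d10, cal)
  structure(list(xb = xb, d10 = d10, duration = duration, seed = seed,
                 site_axial = site_axial, thermo = thermo, kin = kin,
                 cal = cal, n_attach = n_attach),
            class = "xb_simconfig")
}

#' Simulate a single cross-bridge through the three-state cycle
#'
#' Fixed-time-step (1 ms) Monte Carlo: at each step a detached head diffuses
#' thermally and attempts to bind to the site with the distance-dependent
#' probability; a bound head tests its forward transition (stroke from
#' state 2, detachment from state 3) and then, if no forward event fired,
#' the detailed-balance reverse transition (2 -> 1 or 3 -> 2). At most one
#' event resolves per step; with per-step probabilities at the 1 ms scale
#' the ordering is a second-order detail. The direct 1 -> 3 reverse entry is
#' many orders of magnitude below the binding path and is not simulated.
#'
#' All random draws derive from the configuration seed, so trajectories are
#' exactly reproducible.
#'
#' @param config An [sim_config()].
#' @return Object of class `"xb_trajectory"`: a data frame with columns
#'   `time_s`, `state`, `axial_nm`, `radial_nm`, `event` (`""`, `"bind"`,
#'   `"stroke"`, `"detach"`, `"reverse"`), with the configuration and the
#'   site rates stored in attributes.
#' @examples
#' \donttest{
#' tr <- simulate_xb(sim_config("2sXB", d10 = 34, duration = 0.5, seed = 1))
#' summary(tr)
#' }
#' @export
simulate_xb <- function(config) {
  stopifnot(inherits(config, "xb_simconfig"))
  xb <- config$xb; th <- config$thermo; kin <- config$kin
  if (!is.null(config$seed)) set.seed(config$seed)
  nstep <- as.integer(round(config$duration / th$dt))
  site <- site_tip(config$site_axial[1], config$d10, config$cal)

  # site-context rates (constant along the trajectory)
  r12 <- rate_attach(xb, site[[1]], config$d10, n = config$n_attach,
                     kin = kin, thermo = th, cal = config$cal)
  g2 <- free_energy(xb, 2, site, th); g3 <- free_energy(xb, 3, site, th)
  r23 <- rate_stroke(xb, site[[1]], config$d10, kin, th, config$cal)
  r31 <- rate_detach(xb, site[[1]], config$d10, kin, th, config$cal)
  r21 <- rate_reverse(r12$value, g2, kin)
  r32 <- rate_reverse(r23, g3 - g2, kin)
  p <- rate_to_prob(c(r23 = r23, r31 = r31, r21 = r21, r32 = r32), th$dt)

  # pre-drawn randomness, in a fixed order, for exact reproducibility
  tips <- diffuse_tip(xb, nstep, th)
  dist <- sqrt((tips[, 1] - site[[1]])^2 + (tips[, 2] - site[[2]])^2)
  p_bind <- binding_probability(dist, xb$tau)
  u_bind <- stats::runif(nstep)
  u_fwd <- stats::runif(nstep); u_rev <- stats::runif(nstep)

  state <- integer(nstep); ax <- numeric(nstep); rad <- numeric(nstep)
  event <- character(nstep)
  s <- 1L
  for (i in seq_len(nstep)) {
    e <- ""
    if (s == 1L) {
      if (u_bind[i] < p_bind[i]) { s <- 2L; e <- "bind" }
    } else if (s == 2L) {
      if (u_fwd[i] < p[["r23"]]) { s <- 3L; e <- "stroke" }
      else if (u_rev[i] < p[["r21"]]) { s <- 1L; e <- "reverse" }
    } else {
      if (u_fwd[i] < p[["r31"]]) { s <- 1L; e <- "detach" }
      else if (u_rev[i] < p[["r32"]]) { s <- 2L; e <- "reverse" }
    }
    state[i] <- s; event[i] <- e
    if (s == 1L) { ax[i] <- tips[i, 1]; rad[i] <- tips[i, 2] }
    else { ax[i] <- site[[1]]; rad[i] <- site[[2]] }
  }

  out <- data.frame(time_s = seq_len(nstep) * th$dt, state = state,
                    axial_nm = ax, radial_nm = rad, event = event)
  attr(out, "config") <- config
  attr(out, "rates") <- c(r12 = r12$value, r21 = r21, r23 = r23,
                          r32 = r32, r31 = r31)
  class(out) <- c("xb_trajectory", class(out))
  out
}

#' @export
summary.xb_trajectory <- function(object, ...) {
  st <- object$state
  occ <- tabulate(st, nbins = 3L) / length(st)
  bound <- st != 1L
  runs <- rle(bound)
  bt <- runs$lengths[runs$values]
  cfg <- attr(object, "config")
  out <- list(model = cfg$xb$name, d10 = cfg$d10,
              site_axial = cfg$site_axial[1],
              duration = cfg$duration, seed = cfg$seed,
              occupancy = stats::setNames(occ, paste0("state", 1:3)),
              frac_bound = sum(occ[2:3]),
              mean_bound_time_s = if (length(bt)) mean(bt) * cfg$thermo$dt
                                  else NA_real_,
              events = table(factor(object$event[object$event != ""],
                                    levels = c("bind", "stroke", "detach",
                                               "reverse"))),
              rates = attr(object, "rates"))
  class(out) <- "summary.xb_trajectory"
  out
}

#' @export
print.summary.xb_trajectory <- function(x, ...) {
  cat(sprintf("<xb_trajectory> %s, d10 = %g nm, site %.3f nm, %g s (seed %s)\n",
              x$model, x$d10, x$site_axial, x$duration,
              x$seed %||% "unset"))
  cat(sprintf("  occupancy: unbound %.3f | pre-stroke %.3f | post-stroke %.3f\n",
              x$occupancy[1], x$occupancy[2], x$occupancy[3]))
  cat(sprintf("  bound fraction %.3f, mean bound time %.4g s\n",
              x$frac_bound, x$mean_bound_time_s))
  cat("  events: ", paste(names(x$events), as.integer(x$events),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Steady state of the site-context master equation
#'
#' Stationary distribution of the three-state Markov chain assembled from
#' the same per-step transition probabilities a [simulate_xb()] trajectory
#' uses at a fixed site (the mean binding probability standing in for the
#' stochastic diffuse-and-bind step). Used as the small-instance oracle for
#' long-run trajectory occupancies.
#'
#' @param config An [sim_config()].
#' @param n Ensemble size for the mean binding probability.
#' @return Numeric length-3 stationary distribution over states.
#' @export
steady_state_occupancy <- function(config, n = 1e5) {
  xb <- config$xb; th <- config$thermo; kin <- config$kin
  site <- site_tip(config$site_axial[1], config$d10, config$cal)
  r12 <- rate_attach(xb, site[[1]], config$d10, n = n, kin = kin,
                     thermo = th, cal = config$cal)
  g2 <- free_energy(xb, 2, site, th); g3 <- free_energy(xb, 3, site, th)
  r23 <- rate_stroke(xb, site[[1]], config$d10, kin, th, config$cal)
  r31 <- rate_detach(xb, site[[1]], config$d10, kin, th, config$cal)
  r21 <- rate_reverse(r12$value, g2, kin)
  r32 <- rate_reverse(r23, g3 - g2, kin)
  p12 <- rate_to_prob(r12$value, th$dt)
  p <- rate_to_prob(c(r23, r21, r31, r32), th$dt)
  # one-step transition matrix mirroring the simulator's forward-then-reverse
  # resolution order
  P <- rbind(c(1 - p12, p12, 0),
             c(p[2] * (1 - p[1]), (1 - p[1]) * (1 - p[2]), p[1]),
             c(p[3], (1 - p[3]) * p[4], (1 - p[3]) * (1 - p[4])))
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}
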