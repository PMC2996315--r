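test_that("the detached state is the zero of free energy everywhere", {
  th <- get_thermo()
  tips <- random_tips(5, seed = 2)
  for (m in c("1sXB", "2sXB", "4sXB"))
    for (i in seq_len(nrow(tips)))
      expect_identical(free_energy(get_xb(m), 1, tips[i, ], th), 0)
})

test_that("bound-state energy at the rest tip is the pure ATP term", {
  th <- get_thermo()
  for (m in c("2sXB", "4sXB")) {
    xb <- get_xb(m)
    expect_equal(free_energy(xb, 2, tip_rest(xb, 2), th),
                 -0.28 * th$dg_total, tolerance = 1e-10)
    expect_equal(free_energy(xb, 3, tip_rest(xb, 3), th),
                 -0.68 * th$dg_total, tolerance = 1e-10)
  }
})

test_that("reaction force is minus the energy gradient (finite differences)", {
  tips <- random_tips(25, seed = 7)
  for (m in c("2sXB", "4sXB")) {
    xb <- get_xb(m)
    for (i in seq_len(nrow(tips))) {
      state <- 2 + i %% 2
      fd <- numeric_force(xb, tips[i, 1], tips[i, 2], state)
      an <- reaction_force(xb, state, tips[i, ])
      expect_equal(an, fd, tolerance = 1e-4)
    }
  }
})

test_that("forces vanish at each state's rest tip", {
  for (m in c("2sXB", "4sXB")) {
    xb <- get_xb(m)
    for (state in c(2, 3)) {
      f <- reaction_force(xb, state, tip_rest(xb, state))
      expect_lt(sqrt(sum(f^2)), 1e-6)
    }
  }
})

test_that("the single-spring reference produces no radial force", {
  xb <- get_xb("1sXB")
  for (x in seq(-5, 25, by = 5)) {
    f <- reaction_force(xb, 3, tip_position(x, NA))
    expect_identical(f[["radial"]], 0)
    expect_equal(f[["axial"]], -5 * x) # k = 5 pN/nm about rest 0
  }
  # and its step size is the rest-length difference at every spacing
  for (d in c(30, 34, 38))
    expect_equal(step_size(xb, d, get_cal()), 5)
})

test_that("radial force turns from expansive to compressive through rest", {
  xb <- get_xb("4sXB"); cal <- get_cal()
  x0 <- tip_rest(xb, 3)[[1]]
  f32 <- reaction_force(xb, 3, site_tip(x0, 32, cal))
  f36 <- reaction_force(xb, 3, site_tip(x0, 36, cal))
  expect_gt(f32[["radial"]], 0) # compressed lattice -> expansive
  expect_lt(f36[["radial"]], 0) # swollen lattice -> compressive
})

test_that("energy-minimising offsets shift down by > 3 nm from 32 to 38 nm", {
  cal <- get_cal()
  for (m in c("2sXB", "4sXB")) {
    xb <- get_xb(m)
    shift <- argmin_energy_offset(xb, 2, 32, cal) -
             argmin_energy_offset(xb, 2, 38, cal)
    expect_gt(shift, 3)
  }
})

test_that("the 2sXB step-size curve has one interior maximum", {
  xb <- get_xb("2sXB"); cal <- get_cal()
  curve <- step_size_curve(xb, seq(30, 38, by = 1), cal)
  i <- which.max(curve$step_nm)
  expect_gt(i, 1); expect_lt(i, nrow(curve))
  # single peak: increasing before, decreasing after
  expect_true(all(diff(curve$step_nm[1:i]) > 0))
  expect_true(all(diff(curve$step_nm[i:nrow(curve)]) < 0))
  expect_true(all(curve$step_nm > 0)) # forward stroke is positive
})

test_that("envelope property: converter-frozen force equals relaxed force", {
  xb <- get_xb("4sXB")
  tips <- random_tips(10, seed = 9)
  for (i in seq_len(nrow(tips))) {
    tx <- unname(tips[i, 1]); ty <- unname(tips[i, 2])
    g <- solve_geometry(xb, tip_position(tx, ty), 3)
    cv <- g$converter_point
    h <- 1e-5
    frozen <- function(x, y) {
      # energy with the converter frozen at the optimum found for (tx, ty)
      dx <- x - cv[[1]]; dy <- y - cv[[2]]
      l2 <- sqrt(dx^2 + dy^2)
      0.5 * 40 * (atan2(dy, -dx) - 70 * pi / 180)^2 + 0.5 * 5 * (l2 - 9.6)^2 +
        0.5 * 100 * (atan2(cv[[2]], cv[[1]]) - 40 * pi / 180)^2 +
        0.5 * 10 * (sqrt(cv[[1]]^2 + cv[[2]]^2) - 10.5)^2
    }
    f_frozen <- c(-(frozen(tx + h, ty) - frozen(tx - h, ty)) / (2 * h),
                  -(frozen(tx, ty + h) - frozen(tx, ty - h)) / (2 * h))
    expect_equal(unname(reaction_force(xb, 3, tips[i, ])), f_frozen,
                 tolerance = 1e-3)
  }
})
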