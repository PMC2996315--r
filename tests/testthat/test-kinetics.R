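test_that("binding probability is maximal at contact and decays in distance", {
  d <- seq(0, 10, by = 0.25)
  p <- binding_probability(d, tau = 72)
  expect_equal(p[1], 1)
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0 & p <= 1))
  # literal re-implementation of the probability form
  expect_equal(p, exp(-d^2 / 72), tolerance = 1e-15)
  expect_equal(binding_probability(3, 12), exp(-9 / 12))
  expect_error(binding_probability(-1, 12))
})

test_that("rate/probability conversions are consistent inverses", {
  r <- c(0, 20, 500, 5000)
  expect_equal(prob_to_rate(rate_to_prob(r, 1e-3), 1e-3), r)
  expect_equal(prob_to_rate(0.5, 1e-3, "linear"), 500)
})

test_that("thermal diffusion satisfies equipartition spring by spring", {
  th <- get_thermo()
  for (m in c("2sXB", "4sXB")) {
    xb <- get_xb(m)
    set.seed(101)
    tips <- diffuse_tip(xb, 1e5, th, springs = TRUE)
    vals <- attr(tips, "spring_values")
    k <- vapply(xb$springs, `[[`, numeric(1), "stiffness")
    rest <- vapply(xb$springs, `[[`, numeric(1), "rest_pre")
    for (j in seq_along(k)) {
      expect_equal(var(vals[, j]), th$kT / k[j], tolerance = 0.03)
      expect_equal(mean(vals[, j]), rest[j], tolerance = 0.01)
    }
  }
})

test_that("an infinitely stiff cross-bridge does not diffuse", {
  xb <- get_xb("2sXB")
  for (j in seq_along(xb$springs)) xb$springs[[j]]$stiffness <- 1e12
  set.seed(1)
  tips <- diffuse_tip(xb, 100, get_thermo())
  rest <- tip_rest(xb, 2)
  expect_equal(max(abs(tips[, 1] - rest[[1]])), 0, tolerance = 1e-4)
  expect_equal(max(abs(tips[, 2] - rest[[2]])), 0, tolerance = 1e-4)
})

test_that("seeded diffusion and attachment estimates are reproducible", {
  xb <- get_xb("2sXB"); th <- get_thermo()
  set.seed(42); a <- diffuse_tip(xb, 50, th)
  set.seed(42); b <- diffuse_tip(xb, 50, th)
  expect_identical(a, b)
  r1 <- rate_attach(xb, 12, 34, n = 2000, cal = get_cal(), seed = 5)
  r2 <- rate_attach(xb, 12, 34, n = 2000, cal = get_cal(), seed = 5)
  expect_identical(r1$value, r2$value)
})

test_that("attachment is negligible far beyond thermal reach", {
  r <- rate_attach(get_xb("2sXB"), 100, 34, n = 2000, cal = get_cal(),
                   seed = 3)
  expect_lt(r$value, 1e-6)
})

test_that("Monte-Carlo attachment estimates converge as 1/sqrt(N)", {
  xb <- get_xb("2sXB"); cal <- get_cal()
  a <- rate_attach(xb, 12, 34, n = 4000, cal = cal, seed = 10)
  b <- rate_attach(xb, 12, 34, n = 16000, cal = cal, seed = 11)
  expect_lt(abs(a$value - b$value), 2 * sqrt(a$se^2 + b$se^2))
  expect_lt(b$se, a$se)
})

test_that("power-stroke rate depends only on the free-energy difference", {
  xb <- get_xb("4sXB"); th <- get_thermo(); kin <- get_kin(); cal <- get_cal()
  for (x in c(2, 8, 14)) {
    tip <- site_tip(x, 34, cal)
    dg <- free_energy(xb, 2, tip, th) - free_energy(xb, 3, tip, th)
    expect_equal(rate_stroke(xb, x, 34, kin, th, cal),
                 0.5 * kin$r23_max * (1 + tanh(kin$gamma * dg)))
  }
  # neutral point of the sigmoid: half the maximal rate
  expect_equal(0.5 * kin$r23_max * (1 + tanh(kin$gamma * 0)),
               kin$r23_max / 2)
})

test_that("detachment accelerates with strain and slows only at rest spacing", {
  xb <- get_xb("4sXB"); kin <- get_kin(); th <- get_thermo(); cal <- get_cal()
  min_r31 <- vapply(c(30, 32, 34, 36, 38), function(d)
    stats::optimize(function(x) rate_detach(xb, x, d, kin, th, cal),
                    c(-10, 25), tol = 1e-5)$objective, numeric(1))
  expect_equal(min_r31[3], kin$r31_unstrained, tolerance = 1e-4)
  expect_true(all(diff(min_r31[1:3]) < 0)) # falls toward rest spacing
  expect_true(all(diff(min_r31[3:5]) > 0)) # rises beyond it
})

test_that("reverse rates satisfy detailed balance to machine precision", {
  kin <- get_kin()
  dg <- seq(-20, 20, by = 0.5)
  fwd <- 123.4
  rev <- rate_reverse(fwd, dg, kin)
  expect_equal(rev / fwd, exp(dg), tolerance = 1e-12)
  expect_identical(rate_reverse(fwd, 0, kin), fwd)
  expect_lt(rate_reverse(fwd, -40, kin), 1e-12)
})

test_that("kinetic exponents clamp at the overflow guard and are logged", {
  kin <- get_kin()
  clamp_log(reset = TRUE)
  r <- rate_reverse(1, 100, kin)
  expect_equal(r, exp(50))
  expect_gte(clamp_log(), 1)
  clamp_log(reset = TRUE)
})
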