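test_that("1sXB energy landscape is a symmetric parabola, identical in d10", {
  g <- scan_landscape(get_xb("1sXB"), layers = "energy2",
                      axial = seq(-5, 15, by = 0.5), d10 = c(30, 34, 38),
                      cal = get_cal())
  for (d in c(30, 38))
    expect_equal(g$energy2[g$d10_nm == d], g$energy2[g$d10_nm == 34])
  sub <- g[g$d10_nm == 34, ]
  # symmetric about the pre-stroke rest offset (5 nm)
  for (delta in c(1, 3, 7))
    expect_equal(sub$energy2[sub$axial_nm == 5 + delta],
                 sub$energy2[sub$axial_nm == 5 - delta])
})

test_that("deterministic layers are bit-identical and refine consistently", {
  xb <- get_xb("2sXB"); cal <- get_cal()
  coarse <- scan_landscape(xb, layers = c("energy", "r31", "force"),
                           axial = seq(0, 20, 1), d10 = c(32, 36), cal = cal)
  again <- scan_landscape(xb, layers = c("energy", "r31", "force"),
                          axial = seq(0, 20, 1), d10 = c(32, 36), cal = cal)
  expect_identical(as.data.frame(coarse), as.data.frame(again))
  fine <- scan_landscape(xb, layers = c("energy", "r31", "force"),
                         axial = seq(0, 20, 0.5), d10 = c(32, 36), cal = cal)
  shared <- merge(as.data.frame(coarse), as.data.frame(fine),
                  by = c("model", "d10_nm", "axial_nm"))
  expect_equal(shared$energy3.x, shared$energy3.y)
  expect_equal(shared$r31.x, shared$r31.y)
  expect_equal(shared$f_radial.x, shared$f_radial.y)
})

test_that("stochastic layers carry standard errors and reproducible seeds", {
  xb <- get_xb("2sXB"); cal <- get_cal()
  g1 <- scan_landscape(xb, layers = "r12", axial = seq(8, 16, 2),
                       d10 = 34, n = 2000, seed = 99, cal = cal)
  g2 <- scan_landscape(xb, layers = "r12", axial = seq(8, 16, 2),
                       d10 = 34, n = 2000, seed = 99, cal = cal)
  expect_identical(g1$r12, g2$r12)
  expect_true(all(g1$r12_se > 0))
  expect_true(all(g1$mc_seed >= 0))
})

test_that("4sXB landscape is skewed while the 1sXB parabola is not", {
  cal <- get_cal()
  g <- scan_landscape(get_xb("4sXB"), layers = "energy2",
                      axial = seq(-5, 25, 0.5), d10 = 34, cal = cal)
  i <- which.min(g$energy2)
  x0 <- g$axial_nm[i]
  left <- g$energy2[g$axial_nm == x0 - 5]
  right <- g$energy2[g$axial_nm == x0 + 5]
  expect_gt(abs(left - right), 1) # pN nm: visibly asymmetric well
})

test_that("offset summaries locate the expected extrema", {
  xb <- get_xb("4sXB"); cal <- get_cal()
  g <- scan_landscape(xb, layers = c("energy", "r23", "r31"),
                      axial = seq(-2, 22, 0.5),
                      d10 = seq(30, 38, 2), cal = cal)
  s <- summarize_offsets(g)
  expect_equal(nrow(s), 5)
  # energy argmin falls by > 3 nm over 32 -> 38 (here 30 -> 38 brackets it)
  expect_gt(s$argmin_energy2_nm[1] - s$argmin_energy2_nm[5], 3)
  # detachment offset is nearly invariant with lattice spacing
  expect_lt(diff(range(s$argmin_r31_nm)), 1.5)
  # the detachment minimum is slowest at rest spacing
  expect_equal(min(s$min_r31_per_s), s$min_r31_per_s[s$d10_nm == 34])
  expect_equal(s$step_nm, s$argmin_energy2_nm - s$argmin_energy3_nm)
})

test_that("1sXB offset summary is independent of lattice spacing", {
  g <- scan_landscape(get_xb("1sXB"), layers = "energy",
                      axial = seq(-5, 15, 0.5), d10 = c(30, 34, 38),
                      cal = get_cal())
  s <- summarize_offsets(g)
  expect_equal(diff(range(s$argmin_energy2_nm)), 0, tolerance = 1e-6)
  expect_equal(s$step_nm, rep(5, 3), tolerance = 1e-6)
})

test_that("the unlikely-region mask is monotone and retains binding flux", {
  xb <- get_xb("2sXB"); cal <- get_cal()
  g <- scan_landscape(xb, layers = c("r12", "r31"), axial = seq(0, 20, 1),
                      d10 = c(32, 34, 36), n = 2000, seed = 12, cal = cal)
  m0 <- mask_unlikely(g, threshold = 0)
  expect_true(!any(m0$unlikely))
  md <- mask_unlikely(g)
  rule <- attr(md, "mask_rule")
  kept_flux <- sum(md$r12[!md$unlikely]) / sum(md$r12)
  expect_gte(kept_flux, rule$retain - 1e-12)
  hi <- mask_unlikely(g, threshold = 2 * rule$threshold)
  expect_true(all(md$unlikely[hi$unlikely == FALSE] == FALSE))
  expect_true(all(which(md$unlikely) %in% which(hi$unlikely)))
})

test_that("landscape CSV writers emit the documented schemas", {
  xb <- get_xb("2sXB"); cal <- get_cal()
  g <- scan_landscape(xb, layers = c("energy", "r12", "r31", "force"),
                      axial = seq(2, 18, 4), d10 = c(34, 36), n = 500,
                      seed = 8, cal = cal)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_energy_csv(g, f1)
  e <- read.csv(f1)
  expect_named(e, c("model", "state", "d10_nm", "axial_nm", "energy_pNnm",
                    "f_axial_pN", "f_radial_pN"))
  expect_setequal(unique(e$state), c(2, 3))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_rate_csv(g, f2)
  r <- read.csv(f2)
  expect_named(r, c("model", "transition", "d10_nm", "axial_nm", "rate_per_s",
                    "se_per_s", "n", "seed"))
  expect_setequal(unique(r$transition), c("r12", "r31"))
})
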