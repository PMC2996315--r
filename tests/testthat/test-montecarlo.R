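test_that("a cross-bridge with no reachable site never leaves state 1", {
  cfg <- sim_config("2sXB", d10 = 34, duration = 0.5, seed = 2,
                    site_axial = 100, cal = get_cal())
  tr <- simulate_xb(cfg)
  expect_true(all(tr$state == 1L))
  expect_true(all(tr$event == ""))
})

test_that("trajectories are exactly reproducible from the seed", {
  cfg <- sim_config("2sXB", d10 = 34, duration = 1, seed = 17, cal = get_cal())
  a <- simulate_xb(cfg); b <- simulate_xb(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  cfg2 <- sim_config("2sXB", d10 = 34, duration = 1, seed = 18,
                     cal = get_cal())
  expect_false(identical(as.data.frame(simulate_xb(cfg2)),
                         as.data.frame(a)))
})

test_that("state changes follow the allowed three-state cycle", {
  cfg <- sim_config("4sXB", d10 = 34, duration = 2, seed = 5, cal = get_cal())
  tr <- simulate_xb(cfg)
  s <- c(1L, tr$state)
  steps <- cbind(from = s[-length(s)], to = s[-1])
  changed <- steps[, 1] != steps[, 2]
  allowed <- paste(steps[changed, 1], steps[changed, 2]) %in%
    c("1 2", "2 3", "3 1", "2 1", "3 2")
  expect_true(all(allowed))
  # event flags are consistent with the transitions they mark
  ev <- tr$event[changed]
  expect_true(all(ev != ""))
})

test_that("mean post-stroke dwell matches the competing-exponential rates", {
  # site at the post-stroke energy minimum: detachment is slowest there and
  # the reverse stroke is strongly disfavoured
  xb <- get_xb("2sXB"); cal <- get_cal()
  site <- argmin_energy_offset(xb, 3, 34, cal)
  cfg <- sim_config(xb, d10 = 34, duration = 150, seed = 31,
                    site_axial = site, cal = cal)
  tr <- simulate_xb(cfg)
  rates <- attr(tr, "rates")
  runs <- rle(tr$state)
  dwell3 <- runs$lengths[runs$values == 3L]
  expect_gt(length(dwell3), 25)
  expected <- 1 / (rates[["r31"]] + rates[["r32"]]) # in seconds
  se <- expected / sqrt(length(dwell3))
  expect_lt(abs(mean(dwell3) * 1e-3 - expected), 3 * se)
})

test_that("long-run occupancies match the master-equation steady state", {
  xb <- get_xb("2sXB"); cal <- get_cal()
  site <- argmin_energy_offset(xb, 3, 34, cal)
  cfg <- sim_config(xb, d10 = 34, duration = 250, seed = 23,
                    site_axial = site, cal = cal)
  tr <- simulate_xb(cfg)
  occ <- summary(tr)$occupancy
  ss <- steady_state_occupancy(cfg, n = 2e5)
  expect_lt(max(abs(occ - ss)), 0.03)
})

test_that("cross-bridges spend less time bound away from rest spacing", {
  cal <- get_cal()
  frac <- vapply(c(34, 38), function(d) {
    site <- argmin_energy_offset(get_xb("2sXB"), 2, d, cal)
    mean(vapply(1:100, function(i) {
      cfg <- sim_config("2sXB", d10 = d, duration = 10, seed = 1000 + i,
                        site_axial = site, cal = cal, n_attach = 2000)
      summary(simulate_xb(cfg))$frac_bound
    }, numeric(1)))
  }, numeric(1))
  expect_lt(frac[2], frac[1])
})
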