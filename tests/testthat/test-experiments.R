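test_that("experiment configurations encode the factorial toggle patterns", {
  ctl <- experiment_config("control")
  expect_true(ctl$zn_mn_competition)
  expect_false(ctl$zn_hyperacc_affects_mn)
  expect_false(ctl$mnsod_enabled)
  expect_true(is.na(ctl$chl_psii_override))

  expect_false(experiment_config("no_zn_mn_competition")$zn_mn_competition)
  expect_true(experiment_config("zn_hyperaccumulation")$zn_hyperacc_affects_mn)
  expect_true(experiment_config("mnsod")$mnsod_enabled)
  expect_equal(experiment_config("other_sods")$mnsod_reliance, 0.5)
  expect_equal(experiment_config("increase_sod_efficiency")$kcat_multiplier, 2)

  # antenna experiments override Chl:PSII for all PFTs; "large" = higher ratio
  large <- experiment_config("antenna_large")
  small <- experiment_config("antenna_small")
  expect_gt(large$chl_psii_override, default_pft("diatom")$chl_psii)
  expect_lt(small$chl_psii_override, default_pft("diatom")$chl_psii)
  combo <- experiment_config("antenna_large_mnsod")
  expect_true(combo$mnsod_enabled)
  expect_equal(combo$chl_psii_override, large$chl_psii_override)

  expect_error(experiment_config("bogus"), "valid names")
  expect_length(experiment_names(), 9)
})

test_that("seasonal extreme selection picks the smallest ratio with earliest-month ties", {
  flat <- matrix(0.8, nrow = 2, ncol = 12)
  ext <- seasonal_extreme_deficiency(flat)
  expect_equal(ext$extreme, c(0.8, 0.8))
  expect_equal(ext$month, c(1, 1))

  dipped <- matrix(1.2, nrow = 1, ncol = 12)
  dipped[1, 12] <- 0.6
  ext2 <- seasonal_extreme_deficiency(dipped)
  expect_equal(ext2$extreme, 0.6)
  expect_equal(ext2$month, 12)

  # never-deficient cell: extreme stays >= 1
  ok <- matrix(runif(12, 1, 2), nrow = 1)
  expect_gte(seasonal_extreme_deficiency(ok)$extreme, 1)

  expect_error(seasonal_extreme_deficiency(matrix(1, 1, 11)), "12")
})

test_that("footprint areas accumulate cell areas of deficient cells south of 30 degS", {
  area <- c(10, 20, 30, 40)
  lat <- c(-35, -45, -55, -25)    # last cell north of the cut
  expect_equal(deficiency_footprint_area(rep(0.5, 4), area, lat), 60)
  expect_equal(deficiency_footprint_area(rep(1.5, 4), area, lat), 0)
  expect_equal(deficiency_footprint_area(c(0.5, 1.0, 0.99, 0.2), area, lat), 40)

  # exactly the 60-70 degS band deficient -> analytic band area within 0.1%
  g <- generate_forcing(forcing_spec(), seed = 1)
  f <- as_monthly_forcing(g)
  band <- abs(f$lat) >= 60 & abs(f$lat) <= 70
  ext <- ifelse(band, 0.5, 1.5)
  r <- 6371
  analytic <- 2 * pi * r^2 * abs(sin(-61.5 * pi / 180) - sin(-70.5 * pi / 180))
  expect_equal(deficiency_footprint_area(ext, f$cell_area_km2, f$lat),
               analytic, tolerance = 1e-3)
})

test_that("percent-change comparison is exact arithmetic with zero-control masking", {
  g <- generate_forcing(forcing_spec(n_lat = 3, n_lon = 2), seed = 2)
  pfts <- default_pft()["nano"]
  ctl <- run_grid(g, experiment_config("control"), pfts)
  cmp_same <- compare_to_control(ctl, ctl)
  expect_true(all(abs(cmp_same$npp_pct) < 1e-12, na.rm = TRUE))
  expect_true(all(abs(cmp_same$footprints$pct_change) < 1e-12,
                  na.rm = TRUE))

  # scaled experiment: +20% everywhere
  scaled <- ctl
  scaled$results$nano$monthly$npp <- ctl$results$nano$monthly$npp * 1.2
  scaled$results$nano$monthly$export <- ctl$results$nano$monthly$export * 1.2
  cmp <- compare_to_control(scaled, ctl)
  expect_equal(unname(cmp$npp_pct[ctl$results$nano$monthly$npp[, 1] > 0][1]), 20,
               tolerance = 1e-9)

  # zero-control cells are masked, not infinite
  zeroed <- ctl
  zeroed$results$nano$monthly$npp[1, ] <- 0
  cmp0 <- compare_to_control(ctl, zeroed)
  expect_true(is.na(cmp0$npp_pct[1]))

  # grid mismatch rejected
  g_small <- generate_forcing(forcing_spec(n_lat = 2, n_lon = 2), seed = 2)
  ctl_small <- run_grid(g_small, experiment_config("control"), pfts)
  expect_error(compare_to_control(ctl, ctl_small), "different grids")
})

test_that("NPP and export diagnostics are non-negative with a plausible e-ratio", {
  fx <- worked_single_cell_fixture()
  f <- fx$forcing
  sim <- run_grid(f, experiment_config("control"))
  ne <- npp_and_export(sim)
  expect_gte(min(ne$npp), 0)
  expect_gte(min(ne$export), 0)
  # annual export does not exceed annual NPP; e-ratio strictly inside (0, 1)
  expect_lt(ne$total_export_tg, ne$total_npp_tg)
  expect_gt(ne$e_ratio, 0)
  expect_lt(ne$e_ratio, 1)

  # refusal on unconverged results
  sim_bad <- sim
  sim_bad$results$diatom$converged <- FALSE
  expect_error(npp_and_export(sim_bad), "non-converged")

  # linearity: doubling biomass at fixed mu doubles NPP
  sim2 <- sim
  for (nm in names(sim2$results)) {
    sim2$results[[nm]]$monthly$npp <- sim$results[[nm]]$monthly$npp * 2
  }
  expect_equal(npp_and_export(sim2)$total_npp_tg, 2 * ne$total_npp_tg)
})

test_that("parameter sets round-trip through the YAML configuration format", {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  params_to_yaml(default_pft(), tmp)
  back <- params_from_yaml(tmp)
  expect_equal(names(back), c("diatom", "nano", "pico"))
  for (nm in names(back)) {
    orig <- default_pft(nm)
    expect_equal(back[[nm]][names(back[[nm]]) != "sod"],
                 orig[names(orig) != "sod"], tolerance = 1e-12)
    expect_equal(unclass(back[[nm]]$sod), unclass(orig$sod), tolerance = 1e-12)
  }
})
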