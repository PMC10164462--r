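# closed-box engine state with benign mid-range values for conservation runs
closed_box <- function(p, n = 1) {
  list(
    biomass = rep(1.5, n),
    q_n = rep(0.12, n), q_p = rep(0.008, n),
    q_si = rep(if (p$name == "diatom") 0.1 else 0, n),
    q_fe = rep(8, n), q_mn = rep(2, n), q_zn = rep(6, n),
    chl_c = rep(0.02, n),
    d_n = rep(20, n), d_p = rep(1.5, n), d_si = rep(30, n),
    d_fe = rep(0.3, n), d_mn = rep(0.25, n), d_zn = rep(3, n),
    det = rep(0.2, n), dic = rep(5, n)
  )
}

box_totals <- function(box) {
  c(C = box$biomass + box$det + box$dic,
    N = box$q_n * box$biomass + box$d_n,
    P = box$q_p * box$biomass + box$d_p,
    Si = box$q_si * box$biomass + box$d_si,
    Fe = box$q_fe * box$biomass * 1e-3 + box$d_fe,
    Mn = box$q_mn * box$biomass * 1e-3 + box$d_mn,
    Zn = box$q_zn * box$biomass * 1e-3 + box$d_zn)
}

test_that("closed-box elemental totals drift below 1e-10 over 1000 Euler steps", {
  opts <- sim_options(closed = TRUE)
  env <- list(par = 15, temperature = 3)
  tgt <- list(n = 20, p = 1.5, si = 30, d_fe = 0.3, d_mn = 0.25, d_zn = 3)
  for (pft in c("diatom", "pico")) {
    p <- default_pft(pft)
    box <- closed_box(p)
    t0 <- box_totals(box)
    for (i in 1:1000) {
      box <- step_cell(box, env, tgt, p, opts = opts)$box
    }
    drift <- abs(box_totals(box) - t0) / t0
    expect_lt(max(drift), 1e-10)
    expect_true(all(unlist(box[c("q_n", "q_fe", "q_mn", "q_zn")]) >= 0))
  }
})

test_that("darkness with no losses leaves biomass constant while quotas fill by uptake", {
  p <- default_pft("nano")
  opts <- sim_options(loss_rate = 0, loss_quad = 0)
  env <- list(par = 0, temperature = 3)
  tgt <- list(n = 20, p = 1.5, si = 30, d_fe = 0.3, d_mn = 0.25, d_zn = 3)
  box <- closed_box(p)
  q_mn0 <- box$q_mn
  b0 <- box$biomass
  for (i in 1:100) box <- step_cell(box, env, tgt, p, opts = opts)$box
  expect_equal(box$biomass, b0)          # mu = 0 in darkness, no loss
  expect_gt(box$q_mn, q_mn0)             # uptake continues
})

test_that("NaN state aborts with a diagnostic naming the offending field", {
  p <- default_pft("nano")
  box <- closed_box(p)
  box$biomass <- NaN
  expect_error(
    step_cell(box, list(par = 10, temperature = 3),
              list(n = 20, p = 1.5, si = 30, d_fe = 0.3, d_mn = 0.25, d_zn = 3), p),
    "biomass")
})

test_that("constant forcing reaches a steady periodic state within a few cycles", {
  p <- default_pft("pico")
  f <- single_box_forcing(
    par = rep(12, 12), temperature = rep(4, 12), n = rep(22, 12),
    p = rep(1.6, 12), si = rep(35, 12), d_fe = rep(0.15, 12),
    d_mn = rep(0.2, 12), d_zn = rep(2, 12))
  r <- run_annual_cycle(f, p)
  expect_true(r$converged)
  expect_lt(r$cycles, 8)
  # under constant forcing the monthly climatology is ~flat
  expect_lt(diff(range(r$monthly$mu[1, ])) / mean(r$monthly$mu[1, ]), 0.05)

  # determinism: identical inputs -> bit-identical outputs
  r2 <- run_annual_cycle(f, p)
  expect_identical(r$monthly, r2$monthly)
})

test_that("seasonal forcing yields month-resolved deficiency enabling extreme selection", {
  fx <- worked_single_cell_fixture()
  r <- run_annual_cycle(fx$forcing, fx$pft)
  expect_true(r$converged)
  ratios <- r$monthly$mn_def[1, ]
  expect_length(ratios, 12)
  expect_gt(diff(range(ratios)), 0)      # deficiency varies over the season
  ext <- seasonal_extreme_deficiency(r$monthly$mn_def)
  expect_equal(ext$extreme, min(ratios))
  expect_equal(ext$month, which.min(ratios))
})

test_that("grid evaluation is order-independent and matches the single-cell run", {
  g <- generate_forcing(forcing_spec(n_lat = 4, n_lon = 3), seed = 3)
  f <- as_monthly_forcing(g)
  p <- default_pft("nano")
  r_all <- run_annual_cycle(f, p)

  # one-cell forcing == the corresponding row of the full run
  i <- 5
  f1 <- single_box_forcing(
    par = f$par[i, ], temperature = f$temperature[i, ],
    day_fraction = f$day_fraction[i, ],
    n = f$n[i, ], p = f$p[i, ], si = f$si[i, ],
    d_fe = f$d_fe[i, ], d_mn = f$d_mn[i, ], d_zn = f$d_zn[i, ],
    lat = f$lat[i], lon = f$lon[i])
  r_one <- run_annual_cycle(f1, p)
  expect_equal(r_one$monthly$biomass[1, ], r_all$monthly$biomass[i, ],
               tolerance = 1e-12)
  expect_equal(r_one$monthly$mn_def[1, ], r_all$monthly$mn_def[i, ],
               tolerance = 1e-12)

  # permuting box order permutes the output identically
  perm <- rev(seq_along(f$lat))
  fp <- f
  for (v in c("par", "temperature", "day_fraction", "n", "p", "si",
              "d_fe", "d_mn", "d_zn")) {
    fp[[v]] <- f[[v]][perm, , drop = FALSE]
  }
  fp$lat <- f$lat[perm]; fp$lon <- f$lon[perm]
  fp$cell_area_km2 <- f$cell_area_km2[perm]
  r_perm <- run_annual_cycle(fp, p)
  expect_identical(r_perm$monthly$biomass, r_all$monthly$biomass[perm, ])
})
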