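test_that("light-limited growth follows the saturating growth-irradiance law", {
  p <- default_pft("nano")
  st <- mid_state(p)

  # darkness: no photosynthesis
  expect_equal(light_limited_growth(replete_env(par = 0), st, p), 0)

  # saturation: approaches mu_max * f(T)
  mu_t <- p$mu_max * temperature_factor(5, p)
  expect_equal(light_limited_growth(replete_env(par = 1e6), st, p), mu_t,
               tolerance = 1e-10)

  # closed form at alpha*chl*par == mu_max*f(T): v_e = mu_t*(1 - exp(-1))
  pp <- pft_parameters(name = "pico", mu_max = 1, temp_coeff = 1, t_ref = 20,
                       alpha_light = 1, theta_max = 0.05,
                       q_mn_max = 15, q_fe_min = 2, q_fe_opt = 8, q_fe_max = 30,
                       q_zn_max = 60, vmax_fe = 20, vmax_mn = 4.5, vmax_zn = 12,
                       k_n = 0.3, k_fe = 0.08, k_mn = 0.1, k_zn = 0.8)
  st2 <- mid_state(pp, chl_c = 0.05)
  env2 <- replete_env(par = 1 / 0.05)   # alpha*chl*par = 1
  env2$temperature <- 20
  expect_equal(light_limited_growth(env2, st2, pp), 1 - exp(-1),
               tolerance = 1e-12)

  # monotone in PAR and Chl:C
  pars <- seq(0, 40, by = 2)
  ves <- vapply(pars, function(x) light_limited_growth(replete_env(x), st, p),
                numeric(1))
  expect_true(all(diff(ves) >= 0))
  st_lo <- st; st_lo$chl_c <- 0.01
  expect_lte(light_limited_growth(replete_env(), st_lo, p),
             light_limited_growth(replete_env(), st, p))

  # non-finite forcing rejected with a named diagnostic
  bad <- replete_env(); bad$par <- NaN
  expect_error(light_limited_growth(bad, st, p), "par")
})

test_that("photoacclimation relaxes Chl:C toward a bounded target", {
  p <- default_pft("diatom")
  st <- mid_state(p)

  # direction: higher light -> lower Chl:C after one step
  hi <- photoacclimate(st, replete_env(par = 30), p, dt = 1)
  lo <- photoacclimate(st, replete_env(par = 2), p, dt = 1)
  expect_lte(hi$chl_c, lo$chl_c)

  # bounds hold and other fields untouched
  expect_gte(hi$chl_c, p$theta_min)
  expect_lte(lo$chl_c, p$theta_max)
  expect_equal(hi$q_fe, st$q_fe)

  # dt -> 0: change -> 0 (continuity)
  tiny <- photoacclimate(st, replete_env(par = 30), p, dt = 1e-9)
  expect_equal(tiny$chl_c, st$chl_c, tolerance = 1e-6)

  # fixed point: state already at target stays put
  env <- replete_env(par = 10)
  target <- st
  for (i in 1:2000) target <- photoacclimate(target, env, p, dt = 1)
  once_more <- photoacclimate(target, env, p, dt = 1)
  expect_equal(once_more$chl_c, target$chl_c, tolerance = 1e-9)
})

test_that("required Fe quota counts 15 Fe atoms per photosystem unit at PSII:PSI = 1", {
  p <- default_pft("nano")
  st <- mid_state(p)

  # no chlorophyll -> basal only
  st0 <- st; st0$chl_c <- 0
  expect_equal(fe_required_quota(st0, p), p$q_fe_min)

  # photosynthetic coefficient = fe_per_psii + fe_per_psi / ratio = 3 + 12
  photo <- fe_required_quota(st, p) - p$q_fe_min
  expect_equal(photo, 15 * chl_mass_to_mol(st$chl_c) / p$chl_psii * 1e6,
               tolerance = 1e-12)

  # doubling the antenna halves the photosynthetic term
  photo2 <- fe_required_quota(st, p, chl_psii = 2 * p$chl_psii) - p$q_fe_min
  expect_equal(photo2, photo / 2, tolerance = 1e-12)

  # monotone: increasing in chl_c, decreasing in chl_psii
  st_hi <- st; st_hi$chl_c <- st$chl_c * 1.5
  expect_gt(fe_required_quota(st_hi, p), fe_required_quota(st, p))
  expect_error(fe_required_quota(st, p, chl_psii = 0), "chl_psii")
})

test_that("Liebig aggregation keeps limitation distinct from deficiency", {
  p <- default_pft("pico")
  st <- mid_state(p)
  env <- replete_env()

  # fully replete: mu = v_e
  st_rep <- st
  st_rep$q_n <- p$q_n_max; st_rep$q_p <- p$q_p_max
  st_rep$q_fe <- p$q_fe_max; st_rep$q_mn <- 50
  lims <- growth_limitation(env, st_rep, p)
  expect_equal(lims$mu, lims$v_e, tolerance = 1e-12)

  # Fe at subsistence: mu = 0 but mu_no_fe > 0
  st_fe0 <- st_rep; st_fe0$q_fe <- p$q_fe_min
  lims0 <- growth_limitation(env, st_fe0, p)
  expect_equal(lims0$mu, 0)
  expect_gt(lims0$mu_no_fe, 0)

  # arithmetic of the minimum rule: lim_fe = 0.5, rest replete
  q_req <- fe_required_quota(st_rep, p)
  st_half <- st_rep
  st_half$q_fe <- p$q_fe_min + 0.5 * (q_req - p$q_fe_min)
  lh <- growth_limitation(env, st_half, p)
  expect_equal(lh$lim_fe, 0.5, tolerance = 1e-12)
  expect_equal(lh$mu, 0.5 * lh$v_e, tolerance = 1e-12)
  expect_equal(lh$mu_no_fe, lh$v_e, tolerance = 1e-12)
})

test_that("growth-limitation invariants hold over random states", {
  set.seed(7)
  for (pft in c("diatom", "nano", "pico")) {
    p <- default_pft(pft)
    for (i in 1:200) {
      st <- list(
        biomass_c = runif(1, 0, 5),
        q_n = runif(1, 0, 0.2), q_p = runif(1, 0, 0.015),
        q_si = if (pft == "diatom") runif(1, 0, 0.2) else NA_real_,
        q_fe = runif(1, 0, 40), q_mn = runif(1, 0, 20),
        q_zn = runif(1, 0, 60),
        chl_c = runif(1, p$theta_min, p$theta_max)
      )
      env <- list(par = runif(1, 0, 40), temperature = runif(1, -2, 10),
                  n = 20, p = 1.5, si = 30, d_fe = 0.1, d_mn = 0.2, d_zn = 3)
      lims <- growth_limitation(env, st, p)
      facs <- c(lims$lim_n, lims$lim_p, lims$lim_si, lims$lim_fe, lims$lim_mn)
      expect_true(all(facs >= 0 & facs <= 1))
      expect_lte(lims$mu, lims$v_e + 1e-12)
      expect_lte(lims$mu, p$mu_max * temperature_factor(env$temperature, p) + 1e-12)
      # removing a constraint cannot slow growth
      expect_gte(lims$mu_no_fe, lims$mu - 1e-12)
    }
  }
})
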