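test_that("electron leakage steps between 30% and 5% at the Fe-repletion boundary", {
  sp <- sod_parameters()
  expect_equal(electron_leakage_fraction(0.5, sp), 0.30)
  expect_equal(electron_leakage_fraction(2.0, sp), 0.05)
  # boundary belongs to the replete branch; negative ratios are deficient
  expect_equal(electron_leakage_fraction(1.0, sp), 0.05)
  expect_equal(electron_leakage_fraction(-0.3, sp), 0.30)
  # step function: no interpolation anywhere in between
  expect_equal(unique(electron_leakage_fraction(seq(-1, 0.999, by = 0.05), sp)),
               0.30)
})

test_that("ROS balance and consumption follow their defining arithmetic", {
  expect_equal(ros_balance(0.3, 1, 1, 0.3), 0.0)          # production == consumption
  expect_equal(ros_balance(0.3, 1, 1, 0), 1.0)            # no consumption
  expect_equal(ros_balance(0.5, 2, 3, 1), -0.5)           # eps_p*v_e=1, eps_a*v_ros=3
  expect_error(ros_balance(0, 0, 1, 0), "positive")

  expect_equal(ros_consumption_rate(100, 0.06), 6.0)
  expect_equal(ros_consumption_rate(5, 0), 0)
  expect_equal(ros_consumption_rate(5, 2), 2 * ros_consumption_rate(5, 1))
})

test_that("closed-form steady-state MnSOD matches the bisection root of the ROS balance", {
  sp0 <- sod_parameters(eps_a = 1, kcat_ros = 0.05)
  expect_equal(steady_state_mnsod(0.30, 1.0, sp0), 6.0)
  expect_equal(steady_state_mnsod(0, 1, sp0), 0)
  expect_equal(steady_state_mnsod(0.3, 0, sp0), 0)
  # doubling kcat halves the requirement
  sp2 <- sod_parameters(eps_a = 1, kcat_ros = 0.10)
  expect_equal(steady_state_mnsod(0.30, 1.0, sp2),
               steady_state_mnsod(0.30, 1.0, sp0) / 2)

  # independent oracle: bisection on omega(mnsod) = 0 composed from the
  # balance and consumption laws, over random parameter draws
  bisect_root <- function(f, lo, hi, iter = 200) {
    for (i in seq_len(iter)) {
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  set.seed(42)
  for (i in 1:1000) {
    eps_p <- runif(1, 0.01, 0.5)
    v_e <- runif(1, 0.01, 2)
    sp <- sod_parameters(eps_a = runif(1, 0.1, 5), kcat_ros = runif(1, 0.01, 200))
    omega <- function(m) ros_balance(eps_p, v_e, sp$eps_a,
                                     ros_consumption_rate(sp$kcat_ros, m))
    root <- bisect_root(omega, 1e-12, 1e4)
    closed <- steady_state_mnsod(eps_p, v_e, sp)
    expect_equal(closed, root, tolerance = 1e-10)
    # plugging back gives omega = 0 exactly
    expect_equal(omega(closed), 0, tolerance = 1e-14)
  }
})

test_that("Fe deficiency amplifies the SOD basal Mn demand by exactly eps_p_max/eps_p_min", {
  sp <- sod_parameters()
  v_e <- c(0.05, 0.3, 1.0, 1.7)
  q_def <- basal_mn_quota_from_sod(
    steady_state_mnsod(electron_leakage_fraction(0.2, sp), v_e, sp), sp)
  q_rep <- basal_mn_quota_from_sod(
    steady_state_mnsod(electron_leakage_fraction(1.5, sp), v_e, sp), sp)
  expect_equal(q_def / q_rep, rep(sp$eps_p_max / sp$eps_p_min, length(v_e)),
               tolerance = 1e-12)
  expect_equal(sp$eps_p_max / sp$eps_p_min, 6)

  # reliance scaling: the "other SODs" halving
  sp_half <- sod_parameters(mnsod_reliance = 0.5)
  expect_equal(basal_mn_quota_from_sod(6, sp_half), 3.0)
  expect_equal(basal_mn_quota_from_sod(6, sp), 6.0)
  expect_equal(basal_mn_quota_from_sod(0, sp), 0)
})

test_that("enabling the MnSOD pathway never lowers the Mn requirement", {
  p <- default_pft("nano")
  set.seed(5)
  for (i in 1:300) {
    q_def_fe <- runif(1, -1, 3)
    v_e <- runif(1, 0, 1.5)
    chl <- runif(1, 0.005, 0.045)
    off <- effective_basal_mn_quota(q_def_fe, v_e, p, mnsod_enabled = FALSE)
    on <- effective_basal_mn_quota(q_def_fe, v_e, p, mnsod_enabled = TRUE)
    req_off <- required_mn_quota(off$q_mn_min_effective, chl, p$chl_psii, p)
    req_on <- required_mn_quota(on$q_mn_min_effective, chl, p$chl_psii, p)
    expect_gte(req_on, req_off - 1e-12)
    # Fe-replete reference calibration: v_e = 1 d^-1 replete -> basal = control
    ref <- effective_basal_mn_quota(2, 1.0, p, mnsod_enabled = TRUE)
    expect_equal(ref$q_mn_min_effective, p$q_mn_min)
  }
  # a kcat multiplier reduces the SOD-driven demand
  hi <- effective_basal_mn_quota(0.5, 1.0, p, mnsod_enabled = TRUE)
  eff <- effective_basal_mn_quota(0.5, 1.0, p, mnsod_enabled = TRUE,
                                  kcat_multiplier = 2)
  expect_lt(eff$q_mn_min_effective, hi$q_mn_min_effective)
})
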