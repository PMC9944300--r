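test_that("radius growth rate matches direct arithmetic at nucleation", {
  p <- gv_params()
  dp <- mmHg_to_pN_um2(30)
  P <- 2 * p$sigma_0 / p$R0   # 82.8
  want <- (0.25 / 1e5) * (dp - P - 2 * 40 / 0.25)
  expect_equal(radius_rhs(0.25, 40, P, dp, p), want)
  expect_equal(want, 8.992179e-3, tolerance = 1e-6)
  # fixed point: balanced pressures give zero rate
  expect_equal(radius_rhs(2, 100, dp - 2 * 100 / 2, dp, p), 0)
  # with no pressure drop both tension terms resist
  expect_lt(radius_rhs(2, p$sigma_0, P, 0, p), 0)
})

test_that("integrator matches the linear frozen-cell closed form to 1e-6", {
  p <- gv_params()
  dp <- mmHg_to_pN_um2(30)
  alpha <- (dp - 2 * p$sigma_0 / p$R0) / (4 * p$mu)
  beta <- p$sigma_0 / (2 * p$mu)
  r0 <- 0.5
  traj <- gvbleb:::simulate_blebs(p, gv_protocol(delta_p_mmHg = 30, t_max = 50),
                                  r0 = r0, Sigma0 = p$sigma_0,
                                  frozen_R = TRUE, fixed_Sigma = p$sigma_0,
                                  n_out = 201)
  st <- traj$states
  closed <- (r0 - beta / alpha) * exp(alpha * st$t) + beta / alpha
  expect_lt(max(abs(st$r - closed) / closed), 1e-6)
})

test_that("large pressure drops drive growth to the membrane-branch steady state", {
  p <- gv_params()
  traj <- gv_simulate(p, gv_protocol(delta_p_mmHg = 30, t_max = 300))
  eq <- gv_equilibria(mmHg_to_pN_um2(30), p)
  expect_equal(nrow(eq), 1L)
  r_ss <- eq$r[1]
  expect_true(all(diff(traj$states$r) >= -1e-9))       # monotone growth
  expect_lt(abs(tail(traj$states$r, 1) - r_ss) / r_ss, 0.01)
  tts <- time_to_steady(traj)
  expect_true(is.finite(tts))
  expect_lt(tts, 3)                                     # minutes
  expect_true(any(traj$events$kind == "regime_switch"))
})

test_that("at physiological pressure the fate depends on the nucleation radius", {
  p <- gv_params()
  pr <- gv_protocol(delta_p_mmHg = 7, t_max = 600)
  small <- gv_simulate(p, pr, r0 = p$a)      # below ~1 um threshold
  expect_true(any(small$events$kind == "collapsed"))
  big <- gv_simulate(p, pr, r0 = 2)          # above threshold
  expect_false(any(big$events$kind == "collapsed"))
  expect_true(is.finite(time_to_steady(big)))
})

test_that("volume conservation and the Laplace law hold along trajectories", {
  p <- gv_params()
  for (dp in c(7, 30)) {
    traj <- gv_simulate(p, gv_protocol(delta_p_mmHg = dp, t_max = 200),
                        r0 = 1.5, n_out = 201)
    expect_lt(max(volume_residual(traj)), 1e-9)
    expect_equal(traj$states$P, 2 * traj$states$sigma / traj$states$R)
  }
})

test_that("collapse takes longer than growth, and longer still with a weak cortex", {
  p <- gv_params()
  grow <- gv_simulate(p, gv_protocol(delta_p_mmHg = 30, t_max = 300))
  t_grow <- time_to_steady(grow)
  coll <- gv_collapse(p)
  t_coll <- attr(coll, "collapse_time_min")
  expect_true(is.finite(t_coll))
  expect_gt(t_coll, t_grow)
  # reduced cortical tension slows deflation
  p_soft <- gv_params(sigma_c = 187)
  t_soft <- attr(gv_collapse(p_soft), "collapse_time_min")
  expect_gt(t_soft, t_coll)
  # without removing the pressure the steady vacuole persists
  eq <- gv_equilibria(mmHg_to_pN_um2(30), p)
  keep <- gv_simulate(p, gv_protocol(delta_p_mmHg = 30, t_max = 600),
                      r0 = eq$r[1], Sigma0 = p$sigma_0)
  expect_false(any(keep$events$kind == "collapsed"))
  expect_lt(max(abs(keep$states$r - eq$r[1])) / eq$r[1], 1e-4)
})

test_that("the lytic overflow guard terminates the run with a labelled event", {
  # a tight lytic bound is crossed on the way to the 30 mmHg steady state
  p <- gv_params()
  traj <- gvbleb:::simulate_blebs(p, gv_protocol(delta_p_mmHg = 30, t_max = 300),
                                  r0 = p$a, Sigma0 = p$sigma_m,
                                  exp_cap = 0.05)
  expect_true(any(traj$events$kind == "lytic"))
  t_lytic <- traj$events$time[traj$events$kind == "lytic"]
  expect_lt(max(traj$states$t) - t_lytic, 1e-6)   # terminal
})
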