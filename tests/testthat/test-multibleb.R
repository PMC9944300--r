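test_that("independent patches reproduce single-vacuole dynamics", {
  p <- gv_params()
  pr <- gv_protocol(delta_p_mmHg = 30, t_max = 200)
  tm <- gv_simulate_multi(p, pr, r0 = c(0.5, 0.5), shared = FALSE, n_out = 201)
  ts <- gv_simulate(p, pr, r0 = 0.5, n_out = 201)
  # identical blebs track each other exactly and match the single-bleb run
  # (up to the weak coupling through the common cell volume)
  expect_equal(tm$states$r_1, tm$states$r_2)
  expect_lt(max(abs(tm$states$r_1 - ts$states$r) / ts$states$r), 1e-3)
})

test_that("shared-patch growth is indistinguishable while reservoirs last", {
  p <- gv_params()
  pr <- gv_protocol(delta_p_mmHg = 7, t_max = 120)  # well before exhaustion
  sh <- gv_simulate_multi(p, pr, r0 = c(1.2, 1.2), shared = TRUE, n_out = 121)
  ind <- gv_simulate_multi(p, pr, r0 = c(1.2, 1.2), shared = FALSE, n_out = 121)
  expect_true(all(sh$states$eps_B_1 < p$eps_star))
  expect_equal(sh$states$r_1, ind$states$r_1, tolerance = 1e-8)
})

test_that("exactly symmetric shared blebs never break symmetry numerically", {
  p <- gv_params()
  tr <- gv_simulate_multi(p, gv_protocol(delta_p_mmHg = 7, t_max = 1200),
                          r0 = c(1.124, 1.124), shared = TRUE, n_out = 301)
  expect_identical(tr$states$r_1, tr$states$r_2)
})

test_that("a small initial imbalance ripens into one winner", {
  p <- gv_params()
  tr <- gv_simulate_multi(p, gv_protocol(delta_p_mmHg = 7, t_max = 3600),
                          r0 = c(1.1238, 1.1241), shared = TRUE, n_out = 601)
  cs <- coarsening_summary(tr)
  expect_equal(cs$survivors, 1L)
  expect_equal(cs$winner, 2L)   # the larger-initialised bleb wins
  expect_true(is.finite(cs$symmetry_breaking_time_min))
  expect_lt(max(volume_residual(tr)), 1e-9)
})

test_that("the ripening field decouples on the cortex plateau and destabilises equal sizes", {
  p <- gv_params()
  rf <- ripening_field(p, 7, seq(0.3, 4, length.out = 30))
  # both small: the shared target tension sits on the constant plateau, so
  # dr1/dt is (nearly) independent of r2 -- only the weak coupling through
  # the common cell volume remains, orders of magnitude below the strong
  # membrane-regime coupling at large radii
  small <- which(rf$r_grid < 1.5)
  large <- which(rf$r_grid > 3.6)
  vary_r2 <- function(idx) max(abs(rf$drdt[idx, idx] -
                                     rf$drdt[idx, idx[1]]))
  expect_lt(vary_r2(small), 1e-5)
  expect_gt(vary_r2(large) / vary_r2(small), 100)
  # on the diagonal beyond exhaustion, find the symmetric zero and perturb:
  # the larger bleb grows, the smaller shrinks (Ostwald instability)
  r_star2 <- gvbleb:::reservoir_radius(p, 2L)
  f_sym <- function(r) gvbleb:::slaved_drdt(r, mmHg_to_pN_um2(7), p, 2L)
  r_eq <- uniroot(f_sym, c(r_star2, 10), tol = 1e-10)$root
  del <- 1e-3
  ev <- function(r1, r2) {
    e <- gvbleb:::sys_eval(c(r1, r2), rep(p$sigma_0, 2), p,
                           delta_p = mmHg_to_pN_um2(7), shared = TRUE,
                           active = c(TRUE, TRUE))
    Sb <- gvbleb:::target_tension_capped(e$S[1], pi * p$d^2, p)
    radius_rhs(c(r1, r2), Sb, e$P, mmHg_to_pN_um2(7), p)
  }
  rates <- ev(r_eq + del, r_eq - del)
  expect_gt(rates[1], 0)
  expect_lt(rates[2], 0)
})

test_that("sharing a patch raises the nucleation threshold and shrinks vacuoles", {
  p <- gv_params()
  sh <- shared_patch_shift(p, 7)
  expect_gt(sh$delta_p_star_2_mmHg, sh$delta_p_star_1_mmHg)
  expect_lt(sh$r_eq_2, sh$r_eq_1)
})
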