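test_that("equilibria match an independent dense-scan oracle", {
  p <- gv_params()
  # 7 mmHg: two roots, cortex ~0.97 um (the ~1 um nucleation threshold)
  # and membrane ~3.6 um
  eq7 <- gv_equilibria(mmHg_to_pN_um2(7), p)
  or7 <- oracle_equilibria(mmHg_to_pN_um2(7), p)
  expect_equal(nrow(eq7), 2L)
  expect_equal(length(or7), 2L)
  expect_equal(eq7$r, or7, tolerance = 1e-8)
  expect_equal(eq7$branch, c("cortex", "membrane"))
  expect_equal(round(eq7$r[1]), 1)
  # 30 mmHg: the cortex root would fall below r = a; only membrane remains
  eq30 <- gv_equilibria(mmHg_to_pN_um2(30), p)
  or30 <- oracle_equilibria(mmHg_to_pN_um2(30), p)
  expect_equal(nrow(eq30), 1L)
  expect_equal(eq30$r, or30, tolerance = 1e-8)
  expect_equal(eq30$branch, "membrane")
  # below the nucleation threshold: no steady state at all
  expect_equal(nrow(gv_equilibria(mmHg_to_pN_um2(1), p)), 0L)
  # every record satisfies the balance to <= 1e-9 relative
  expect_lt(max(c(eq7$residual, eq30$residual)), 1e-9)
})

test_that("membrane-branch equilibria are stable, cortex-branch unstable", {
  p <- gv_params()
  eq <- gv_equilibria(mmHg_to_pN_um2(7), p)
  expect_false(eq$stable[eq$branch == "cortex"])
  expect_true(eq$stable[eq$branch == "membrane"])
  expect_true(gv_equilibria(mmHg_to_pN_um2(30), p)$stable)
})

test_that("pressure scan locates both thresholds and the 0/2/1 branch pattern", {
  p <- gv_params()
  sc <- pressure_scan(p, seq(1, 30, by = 1))
  # delta_p_dagger: cortex root at r = a; closed form 2 s0/a + 2 s0/R0
  expect_equal(sc$delta_p_dagger_mmHg,
               (2 * 414 / 0.25 + 2 * 414 / 10) / 133.322387415,
               tolerance = 1e-4)   # ~25.46 mmHg
  # delta_p*: existence bisection agrees with the saddle-node estimate
  est <- pN_um2_to_mmHg(nucleation_pressure(p))
  expect_lt(abs(sc$delta_p_star_mmHg - est) / est, 0.05)
  expect_equal(est, 2.36, tolerance = 0.01)   # ~2.4 mmHg
  # 0 equilibria below, 2 inside, 1 above
  g <- sc$delta_p_grid_mmHg
  expect_true(all(sc$counts[g < sc$delta_p_star_mmHg] == 0))
  expect_true(all(sc$counts[g > sc$delta_p_star_mmHg + 0.5 &
                              g < sc$delta_p_dagger_mmHg - 0.5] == 2))
  expect_true(all(sc$counts[g > sc$delta_p_dagger_mmHg + 0.5] == 1))
  # membrane-branch vacuole volume grows monotonically with pressure
  mem <- sc$records[sc$records$branch == "membrane", ]
  mem <- mem[order(mem$delta_p), ]
  expect_true(all(diff(mem$volume) > 0))
})

test_that("nucleation pressure scales with cortical tension and reservoirs", {
  p <- gv_params()
  base <- nucleation_pressure(p)
  # linear in sigma_0: doubling both tension components doubles it exactly
  expect_equal(nucleation_pressure(gv_params(sigma_m = 80, sigma_c = 748)),
               2 * base)
  # weaker cortex -> lower threshold; stronger -> higher
  expect_lt(nucleation_pressure(gv_params(sigma_c = 187)), base)
  expect_gt(nucleation_pressure(gv_params(sigma_c = 748)), base)
  # bigger membrane reservoir -> lower threshold
  expect_lt(nucleation_pressure(gv_params(eps_star = 1.0)), base)
  # and larger steady vacuoles when the cortex is weakened
  dp <- mmHg_to_pN_um2(7)
  v_ref <- gv_equilibria(dp, p)
  v_soft <- gv_equilibria(dp, gv_params(sigma_c = 187))
  expect_gt(v_soft$volume[v_soft$branch == "membrane"],
            v_ref$volume[v_ref$branch == "membrane"])
})

test_that("degenerate reservoirs are rejected with a clear error", {
  # eps* below a^2/d^2 leaves no admissible exhaustion radius
  expect_error(nucleation_pressure(gv_params(eps_star = 0)),
               "reservoir")
})
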