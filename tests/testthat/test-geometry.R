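test_that("opening angle solves the pore constraint on the physical branch", {
  expect_equal(opening_angle(0.25, 0.25), pi / 2)     # hemispherical nucleus
  expect_equal(opening_angle(0.5, 0.25), 5 * pi / 6)  # asin(1/2) = pi/6
  r <- seq(0.25, 25, length.out = 200)
  th <- opening_angle(r, 0.25)
  expect_true(all(diff(th) > 0))                      # theta -> pi monotonically
  expect_lt(pi - th[length(th)], 0.011)
  expect_true(all(abs(r * sin(th) - 0.25) < 1e-12))   # identity on [a, 100a]
  expect_error(opening_angle(0.2, 0.25), "r < pore")
})

test_that("cap volume and area match closed forms and quadrature", {
  r <- 1.7
  expect_equal(cap_volume(r, pi / 2), (2 * pi / 3) * r^3)  # hemisphere
  expect_equal(cap_volume(r, pi), (4 * pi / 3) * r^3)      # full sphere
  expect_equal(cap_volume(1, 2 * pi / 3), 9 * pi / 8)      # sin^4(pi/3) = 9/16
  expect_equal(cap_area(r, pi / 2), 2 * pi * r^2)
  expect_equal(cap_area(r, pi), 4 * pi * r^2)
  expect_equal(cap_area(r, 2 * pi / 3), 3 * pi * r^2)
  for (rr in c(0.25, 1, 3.86)) for (th in seq(pi / 2, pi, length.out = 7)) {
    expect_lt(abs(cap_volume(rr, th) - oracle_cap_volume(rr, th)) /
                oracle_cap_volume(rr, th), 1e-8)
    expect_lt(abs(cap_area(rr, th) - oracle_cap_area(rr, th)) /
                oracle_cap_area(rr, th), 1e-8)
  }
})

test_that("cell radius conserves hemisphere volume exactly", {
  expect_equal(cell_radius(numeric(0), 0.25, 10), 10)
  expect_lt(abs(cell_radius(0.25, 0.25, 10) - 10), 1e-4)  # nucleus is tiny
  # oracle: add the quadrature cap volume to the hemisphere and invert
  r <- 3.86; a <- 0.25; R0 <- 10
  th <- opening_angle(r, a)
  R_oracle <- (R0^3 + oracle_cap_volume(r, th) * 3 / (2 * pi))^(1 / 3)
  expect_equal(cell_radius(r, a, R0), R_oracle, tolerance = 1e-9)
  # two blebs sum their caps
  expect_equal(cell_radius(c(2, 3), a, R0)^3 - R0^3,
               (cell_radius(2, a, R0)^3 - R0^3) +
                 (cell_radius(3, a, R0)^3 - R0^3))
})

test_that("patch area: nucleation values and reservoir exhaustion", {
  a <- 0.25; d <- 10
  expect_equal(patch_area(a, a, d), pi * d^2 + pi * a^2)         # one nucleus
  expect_equal(patch_area(c(a, a), a, d), pi * d^2 + 2 * pi * a^2)
  expect_error(patch_area(rep(1, 5), a = 3, d = 6), "infeasible")
  # the radius exhausting the reservoir for eps* = 0.5 has S = S* ~ 471.2
  p <- gv_params()
  r_star <- oracle_reservoir_radius(p)
  expect_equal(r_star, 3.538, tolerance = 1e-3)
  expect_equal(patch_area(r_star, p$a, p$d), pi * p$d^2 * 1.5,
               tolerance = 1e-12)
})

test_that("area strains use the patch and cell resting areas", {
  p <- gv_params()
  s <- area_strains(S = pi * p$d^2, A = cell_area(p$R0, p$d), p)
  expect_equal(s$eps_B, 0)
  expect_equal(s$eps_C, 0)   # R = R0
  s2 <- area_strains(S = pi * p$d^2 * (1 + p$eps_star),
                     A = cell_area(p$R0, p$d), p)
  expect_equal(s2$eps_B, p$eps_star)
  # nucleation: eps_B = a^2 / d^2
  Snuc <- patch_area(p$a, p$a, p$d)
  expect_equal(area_strains(Snuc, cell_area(p$R0, p$d), p)$eps_B,
               p$a^2 / p$d^2)  # 6.25e-4
})
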