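test_that("circular variance has the closed-form limits", {
  # single angle -> 0
  expect_equal(circular_variance_values(37, 1), 0)
  # uniform over the full period -> 1 (resultant vanishes)
  expect_equal(circular_variance_values(seq(0, 350, 10), rep(1, 36)), 1)
  # two equal-mass directions 90 degrees apart -> 1 - cos(45 deg)
  expect_equal(circular_variance_values(c(30, 120), c(1, 1)), 1 - cos(pi / 4))
  # scale invariance in the weights
  set.seed(5)
  w <- runif(18); a <- seq(-180, 160, 20)
  expect_equal(circular_variance_values(a, w),
               circular_variance_values(a, 9 * w))
})

test_that("map-level circular variance works on folded projections", {
  # delta map -> 0 on both axes
  d <- matrix(0, 18, 18); d[5, 5] <- 1
  fd <- fold_map(rama_map(d))
  expect_equal(circular_variance(fd, "phi"), 0)
  expect_equal(circular_variance(fd, "psi"), 0)
  # two psi bins 120 degrees apart -> 1 - cos(60 deg) = 0.5
  d2 <- matrix(0, 18, 18)
  d2[5, 4] <- 1   # psi = -120
  d2[5, 10] <- 1  # psi = 0
  fd2 <- fold_map(rama_map(d2))
  expect_equal(circular_variance(fd2, "psi"), 0.5)
  # uniform folded map: psi covers the full period -> exactly 1
  uni <- rama_map(matrix(1, 10, 18), folded = TRUE)
  expect_equal(circular_variance(uni, "psi"), 1)
  # phi covers only the folded half-period: V stays within [0, 1] under
  # both conventions but cannot reach 1 (documented behaviour)
  v_raw <- circular_variance(uni, "phi", "raw")
  v_dbl <- circular_variance(uni, "phi", "doubled")
  expect_true(v_raw >= 0 && v_raw < 1)
  expect_true(v_dbl > v_raw)  # doubling spreads axial data over the circle
  expect_error(circular_variance(rama_map(matrix(1, 18, 18)), "phi"),
               "folded")
})

test_that("entropies hit the analytic limits in nats", {
  # single populated bin
  d <- matrix(0, 18, 18); d[3, 3] <- 1
  expect_equal(shannon_entropy(fold_map(rama_map(d))), 0)
  # uniform folded map and its projections
  uni <- rama_map(matrix(1, 10, 18), folded = TRUE)
  expect_equal(shannon_entropy(uni), log(180))
  expect_equal(shannon_entropy(project_map(uni, "phi")), log(10))
  expect_equal(shannon_entropy(project_map(uni, "psi")), log(18))
  # the printed approximations
  expect_equal(log(180), 5.19, tolerance = 2e-3)
  expect_equal(log(10), 2.3, tolerance = 2e-3)
  expect_equal(log(18), 2.89, tolerance = 2e-3)
  expect_error(shannon_entropy(c(0.5, -0.1)), "non-negative")
})

test_that("excess entropy is the plain difference against the reference", {
  expect_equal(excess_entropy(3.17, 3.17), 0)
  # maximal excess: uniform map against a confined-helix reference of 3.17
  expect_equal(excess_entropy(log(180), 3.17), 2.02, tolerance = 0.01)
  # a heterogeneous-sample value against the same reference
  expect_equal(excess_entropy(4.46, 3.17), 1.30, tolerance = 0.015)
})

test_that("flatness reports the top-bin abundance and its complement", {
  d <- matrix(0, 18, 18); d[2, 2] <- 1
  f <- flatness(rama_map(d))
  expect_equal(f$peak_fraction, 1)
  expect_equal(f$complement, 0)
  uni <- rama_map(matrix(1, 10, 18), folded = TRUE)
  fu <- flatness(uni)
  expect_equal(fu$peak_fraction, 1 / 180)
  expect_equal(fu$complement, 1 - 1 / 180)
  two <- matrix(0, 18, 18); two[1, 1] <- 0.6; two[9, 9] <- 0.4
  expect_equal(flatness(rama_map(two))$peak_fraction, 0.6)
})

test_that("the helix/extended ratio integrates the region masks", {
  base <- matrix(0, 10, 18)
  helix_bin <- c(which(seq(-180, 0, 20) == -80), which(seq(-180, 160, 20) == -40))
  ext_bin <- c(which(seq(-180, 0, 20) == -140), which(seq(-180, 160, 20) == 140))
  d <- base; d[helix_bin[1], helix_bin[2]] <- 0.6; d[ext_bin[1], ext_bin[2]] <- 0.4
  m <- rama_map(d, folded = TRUE)
  rr <- ss_ratio(m)
  expect_equal(rr$R, 1.5)
  expect_identical(rr$dominant, "H")
  expect_false(rr$infinite)
  # pure helix: the minor class has zero mass -> infinity flag
  d2 <- base; d2[helix_bin[1], helix_bin[2]] <- 1
  rr2 <- ss_ratio(rama_map(d2, folded = TRUE))
  expect_identical(rr2$R, Inf)
  expect_true(rr2$infinite)
  # perfectly balanced
  d3 <- base; d3[helix_bin[1], helix_bin[2]] <- 0.5
  d3[ext_bin[1], ext_bin[2]] <- 0.5
  expect_equal(ss_ratio(rama_map(d3, folded = TRUE))$R, 1)
  # degenerate: no mass in either region
  d4 <- base; d4[1, 10] <- 1
  expect_error(ss_ratio(rama_map(d4, folded = TRUE)), "undefined")
})

test_that("score_all bundles all scores consistently", {
  helix_i <- c(which(seq(-180, 0, 20) == -80), which(seq(-180, 160, 20) == -40))
  ext_i <- c(which(seq(-180, 0, 20) == -140), which(seq(-180, 160, 20) == 140))
  d <- matrix(0, 10, 18)
  d[helix_i[1], helix_i[2]] <- 0.5
  d[ext_i[1], ext_i[2]] <- 0.5
  m <- rama_map(d, folded = TRUE)
  s <- score_all(m, reference = m)
  expect_equal(s$dS_total, 0)
  expect_equal(s$S_total, log(2))
  expect_equal(s$F_peak_fraction, 0.5)
  expect_equal(s$F, 0.5)  # complement convention
  expect_equal(s$R, 1)
  expect_s3_class(as.data.frame(s), "data.frame")
  # numeric reference and convention switches
  s2 <- score_all(m, reference = 0.2, flatness_convention = "peak_fraction",
                  phi_convention = "doubled")
  expect_equal(s2$dS_total, log(2) - 0.2)
  expect_equal(s2$F, 0.5)
  expect_identical(s2$phi_convention, "doubled")
})

test_that("score invariants hold on random folded maps", {
  set.seed(23)
  for (k in 1:20) {
    m <- fold_map(random_map(normalize = FALSE))
    mn <- rama_map(m$raw_density, folded = TRUE)   # normalized copy
    v_phi <- circular_variance(mn, "phi"); v_psi <- circular_variance(mn, "psi")
    expect_true(v_phi >= 0 && v_phi <= 1)
    expect_true(v_psi >= 0 && v_psi <= 1)
    s_phi <- shannon_entropy(project_map(mn, "phi"))
    s_psi <- shannon_entropy(project_map(mn, "psi"))
    s_tot <- shannon_entropy(mn)
    expect_lte(s_phi, log(10) + 1e-12)
    expect_lte(s_psi, log(18) + 1e-12)
    expect_lte(s_tot, log(180) + 1e-12)
    # marginal-entropy bounds
    expect_gte(s_tot, max(s_phi, s_psi) - 1e-12)
    expect_lte(s_tot, s_phi + s_psi + 1e-12)
    # scores are invariant to uniform density rescaling
    ms <- rama_map(7.3 * m$raw_density, folded = TRUE)
    expect_equal(circular_variance(ms, "psi"), v_psi)
    expect_equal(shannon_entropy(ms), s_tot)
    expect_equal(flatness(ms)$peak_fraction, flatness(mn)$peak_fraction)
  }
})
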