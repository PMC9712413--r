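test_that("database CSVs load with validation and residue filtering", {
  db <- rbind(make_db(6, residue = "A", stride = "H"),
              make_db(4, residue = "L", stride = "E"))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(db, path, row.names = FALSE)
  all_entries <- load_database(path)
  expect_identical(nrow(all_entries), 10L)
  expect_equal(all_entries$CA, db$CA)
  ala <- load_database(path, residue_type = "A")
  expect_identical(nrow(ala), 6L)
  expect_true(all(ala$residue == "A"))
  # out-of-range angle
  bad <- db; bad$phi[1] <- 200
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_database(path), "-180, 180")
  # unknown STRIDE code
  bad <- db; bad$stride[2] <- "Z"
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_database(path), "STRIDE")
  # schema violation
  write.csv(db[, -4], path, row.names = FALSE)
  expect_error(load_database(path), "missing columns")
})

test_that("quality filtering keeps exactly the PIQC-passing entries", {
  db <- make_db(10)
  db$piqc_pass <- rep(c(TRUE, FALSE), c(7, 3))
  expect_identical(nrow(filter_quality(db)), 7L)
  db$piqc_pass <- TRUE
  expect_identical(nrow(filter_quality(db)), 10L)
  db$piqc_pass <- FALSE
  expect_identical(nrow(filter_quality(db)), 0L)
})

test_that("STRIDE codes simplify to the four coarse classes", {
  expect_identical(simplify_class(c("H", "G", "I")), rep("helix", 3))
  expect_identical(simplify_class("E"), "extended")
  expect_identical(simplify_class(c("T", "B", "b")), rep("other", 3))
  expect_identical(simplify_class("C"), "coil")
  expect_error(simplify_class("Q"), "unknown STRIDE")
})

test_that("envelope selection matches a brute-force threshold scan", {
  set.seed(13)
  pk <- gauss_peak(n = 12L)
  n <- 100
  db <- make_db(n)
  for (nu in c("H", "N", "CA", "CB")) {
    r <- axis_range(pk$axes[[nu]])
    width <- r[2] - r[1]
    db[[nu]] <- runif(n, r[1] - 0.2 * width, r[2] + 0.2 * width)
  }
  sel <- select_in_envelope(db, pk, threshold_fraction = 0.2)
  # oracle: direct per-entry check with the independent interpolator
  inside <- vapply(seq_len(n), function(i) {
    x <- as.numeric(db[i, c("H", "N", "CA", "CB")])
    ok <- all(vapply(1:4, function(d) {
      r <- axis_range(pk$axes[[d]])
      x[d] >= r[1] && x[d] <= r[2]
    }, TRUE))
    ok && oracle_interp(pk, x) >= 0.2 * pk$max_intensity
  }, TRUE)
  expect_identical(sort(sel$resid), sort(db$resid[inside]))
  expect_equal(sel$intensity[order(sel$resid)],
               vapply(which(inside)[order(db$resid[inside])], function(i)
                 oracle_interp(pk, as.numeric(db[i, c("H", "N", "CA", "CB")])), 0))
})

test_that("envelope selection excludes coil entries and skips incomplete ones", {
  pk <- gauss_peak(n = 8L)
  mx <- peak_maximum_shifts(pk)
  db <- make_db(4, shifts = mx)
  db$stride <- c("H", "C", "E", "H")
  db$CB[4] <- NA
  expect_message(sel <- select_in_envelope(db, pk), "skipped 1 entry")
  expect_identical(sort(sel$resid), c(1L, 3L))  # coil and incomplete dropped
  expect_equal(sel$intensity, rep(pk$max_intensity, 2))
  # an entry far outside the region is dropped
  db2 <- make_db(1, shifts = mx + c(5, 0, 0, 0))
  expect_identical(nrow(select_in_envelope(db2, pk)), 0L)
})

test_that("local density reflects entry clustering", {
  bw <- c(H = 0.05, N = 0.2, CA = 0.2, CB = 0.2)
  # two well-separated clusters of sizes 9 and 1
  x9 <- matrix(rep(c(8.3, 120, 55, 18), each = 9), ncol = 4)
  x1 <- matrix(c(9.5, 130, 45, 28), ncol = 4)
  dens <- local_density(rbind(x9, x1), bandwidths = bw)
  expect_equal(mean(dens[1:9]) / dens[10], 9, tolerance = 1e-6)
  # identical shifts give equal densities
  expect_true(all(abs(dens[1:9] - dens[1]) < 1e-12))
  # a uniform lattice probed with a wide bandwidth is near-uniform away
  # from the boundary
  g <- as.matrix(expand.grid(H = seq(8, 8.8, 0.1), N = 120, CA = 55, CB = 18))
  dg <- local_density(g, bandwidths = c(H = 2, N = 1, CA = 1, CB = 1))
  expect_lt(stats::sd(dg) / mean(dg), 0.01)
  # degenerate single entry
  expect_warning(d1 <- local_density(x1, bandwidths = bw), "fewer than 2")
  expect_identical(d1, 1)
})

test_that("weighted entries bin into a normalized map; duplication cancels", {
  db <- make_db(2)
  db$phi <- c(-80, -130); db$psi <- c(-30, 140)
  db$weight <- c(3, 1)
  m <- entries_to_map(db)
  # psi = -30 falls in the bin centred at -20 ([-30, -10)); 140 in [130, 150)
  expect_equal(m$density[m$phi_centers == -80, m$psi_centers == -20], 0.75)
  expect_equal(m$density[m$phi_centers == -130 + 10, m$psi_centers == 140],
               0.25)
  expect_equal(sum(m$density), 1)
  expect_equal(sort(unique(as.vector(m$density))), c(0, 0.25, 0.75))
  # single entry -> delta map
  m1 <- entries_to_map(db[1, ], weights = 5)
  expect_equal(max(m1$density), 1)
  # duplication invariance: k copies multiply the local density by ~k,
  # which the inverse-density weight cancels
  set.seed(3)
  pk <- gauss_peak(n = 10L)
  n <- 250
  db2 <- make_db(n)
  for (nu in c("H", "N", "CA", "CB")) {
    r <- axis_range(pk$axes[[nu]])
    db2[[nu]] <- runif(n, r[1], r[2])
  }
  db2$phi <- runif(n, -179, 180); db2$psi <- runif(n, -179, 180)
  sel <- select_in_envelope(db2, pk, threshold_fraction = 0.05)
  expect_gt(nrow(sel), 10)
  w1 <- weight_entries(sel)
  map1 <- entries_to_map(w1)
  dup <- sel[rep(seq_len(nrow(sel)), 3), ]
  w3 <- weight_entries(dup)
  map3 <- entries_to_map(w3)
  expect_equal(map3$density, map1$density, tolerance = 1e-8)
})

test_that("density compensation removes database composition bias", {
  # peak is a 70/30 helix/extended mixture, but the database is
  # helix-poor (30/70): the reconstruction must still be helix-dominant
  model <- forward_model()
  ens <- list(class_conformer(model, "helix", 0.7),
              class_conformer(model, "extended", 0.3))
  pk <- simulate_peak(ens, model)
  db <- generate_mock_database(3000,
                               populations = c(helix = 0.3, extended = 0.7),
                               model = model, piqc_fail_rate = 0, seed = 21)
  rec <- reconstruct_from_database(db, pk)
  rr <- ss_ratio(rec$map)
  expect_identical(rr$dominant, "H")
  p_hat <- rr$H_mass / (rr$H_mass + rr$E_mass)
  expect_gt(p_hat, 0.6)
  expect_false(rec$low_confidence)
})
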