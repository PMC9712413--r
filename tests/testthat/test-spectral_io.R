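test_that("portable hypercube container round-trips arrays and calibration", {
  pk <- gauss_peak(n = 8L)
  path <- withr::local_tempfile(fileext = ".json")
  write_hypercube(pk, path)
  back <- read_hypercube(path)
  expect_equal(back$intensity, pk$intensity)
  for (d in 1:4) expect_equal(axis_ppm(back$axes[[d]]), axis_ppm(pk$axes[[d]]))
  expect_equal(back$max_intensity, pk$max_intensity)
})

test_that("container axes stored in another order are permuted to (H,N,CA,CB)", {
  pk <- gauss_peak(n = 6L)
  # store as (CA, CB, N, H) by hand
  perm <- c(3L, 4L, 2L, 1L)
  obj <- list(format = "peakrama-hypercube", version = 1L,
              axes = unname(lapply(pk$axes[perm], function(a)
                list(nucleus = a$nucleus, n_points = a$n_points,
                     ppm_start = a$ppm_start, ppm_step = a$ppm_step))),
              intensity = as.vector(aperm(pk$intensity, perm)))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  back <- read_hypercube(path)
  expect_equal(vapply(back$axes, `[[`, "", "nucleus"), c(H = "H", N = "N", CA = "CA", CB = "CB"),
               ignore_attr = TRUE)
  expect_equal(back$intensity, pk$intensity)
})

test_that("NMRPipe single-file stream round-trips within float32 precision", {
  pk <- gauss_peak(n = 8L)
  path <- withr::local_tempfile(fileext = ".ft4")
  write_nmrpipe(pk, path)
  back <- read_nmrpipe(path)
  expect_equal(back$intensity, pk$intensity, tolerance = 1e-6)
  for (d in 1:4) {
    expect_identical(back$axes[[d]]$nucleus, pk$axes[[d]]$nucleus)
    expect_equal(axis_ppm(back$axes[[d]]), axis_ppm(pk$axes[[d]]),
                 tolerance = 1e-4)
  }
  # format auto-detection
  auto <- read_spectrum(path)
  expect_equal(auto$intensity, back$intensity)
})

test_that("malformed spectra are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".json")
  # 3-dimensional container
  obj <- list(format = "peakrama-hypercube", version = 1L,
              axes = list(list(nucleus = "H", n_points = 4L,
                               ppm_start = 9, ppm_step = -0.2),
                          list(nucleus = "N", n_points = 4L,
                               ppm_start = 126, ppm_step = -1),
                          list(nucleus = "CA", n_points = 4L,
                               ppm_start = 58, ppm_step = -1)),
              intensity = rep(0, 64))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_hypercube(path), "4 axes")
  writeLines("not json at all {", path)
  expect_error(read_hypercube(path), "readable JSON|hypercube")
  # NMRPipe stream with a 3D dimension count
  pk <- gauss_peak(n = 6L)
  p2 <- withr::local_tempfile(fileext = ".ft3")
  write_nmrpipe(pk, p2)
  raw <- readBin(p2, "raw", file.size(p2))
  raw[(9 * 4 + 1):(9 * 4 + 4)] <- writeBin(3, raw(), size = 4L)  # FDDIMCOUNT
  writeBin(raw, p2)
  expect_error(read_nmrpipe(p2), "4-dimensional")
})

test_that("interpolation is exact on nodes, linear between, and multilinear overall", {
  set.seed(42)
  axes <- tiny_axes(8L)
  # globally multilinear field: product of per-axis affine terms
  ab <- matrix(runif(8, 0.5, 2), nrow = 2)
  ppm <- lapply(axes, axis_ppm)
  vals <- lapply(1:4, function(d) ab[1, d] + ab[2, d] * (ppm[[d]] - mean(ppm[[d]])))
  arr <- array(outer(outer(vals[[1]], vals[[2]]), outer(vals[[3]], vals[[4]])),
               dim = rep(8L, 4L))
  pk <- peak_region(arr, axes, clip_negative = FALSE)
  # node identity
  expect_equal(interpolate_intensity(pk, c(ppm[[1]][3], ppm[[2]][5],
                                           ppm[[3]][2], ppm[[4]][7])),
               arr[3, 5, 2, 7])
  # midpoint along H only: arithmetic mean of the two neighbours
  mid <- c(mean(ppm[[1]][3:4]), ppm[[2]][5], ppm[[3]][2], ppm[[4]][7])
  expect_equal(interpolate_intensity(pk, mid), mean(arr[3:4, 5, 2, 7]))
  # random interior points reproduce the analytic multilinear field
  for (k in 1:25) {
    x <- vapply(1:4, function(d) runif(1, min(ppm[[d]]), max(ppm[[d]])), 0)
    analytic <- prod(vapply(1:4, function(d)
      ab[1, d] + ab[2, d] * (x[d] - mean(ppm[[d]])), 0))
    expect_equal(interpolate_intensity(pk, x), analytic, tolerance = 1e-10)
  }
  expect_error(interpolate_intensity(pk, c(99, 126, 58, 24)), "H axis")
})

test_that("a delta peak with voxel-sized spacing yields exactly one grid point", {
  pk <- delta_peak(n = 8L)
  sp <- vapply(pk$axes, function(a) abs(a$ppm_step), 0)
  g <- sample_grid(pk, spacings = sp, threshold_fraction = 0.2)
  expect_identical(nrow(g), 1L)
  expect_equal(unlist(g[1, c("H", "N", "CA", "CB")]),
               peak_maximum_shifts(pk), ignore_attr = TRUE)
  expect_equal(g$intensity, pk$max_intensity)
})

test_that("sample_grid matches a brute-force lattice scan and is scale invariant", {
  pk <- gauss_peak(n = 12L, center_frac = 0.45)
  sp <- c(H = 0.25, N = 1.3, CA = 1.1, CB = 1.4)
  g <- sample_grid(pk, spacings = sp, threshold_fraction = 0.2)
  oracle <- oracle_grid_scan(pk, sp, 0.2)
  expect_identical(nrow(g), nrow(oracle))
  key <- function(m) sort(apply(round(m, 6), 1, paste, collapse = "/"))
  expect_identical(key(as.matrix(g[, 1:4])), key(oracle[, 1:4, drop = FALSE]))
  # uniform intensity rescaling leaves the selection unchanged
  pk5 <- peak_region(pk$intensity * 5, pk$axes)
  g5 <- sample_grid(pk5, spacings = sp, threshold_fraction = 0.2)
  expect_equal(g5[, 1:4], g[, 1:4])
  expect_equal(g5$intensity, 5 * g$intensity)
  # nearest-voxel probing stays available
  gn <- sample_grid(pk, spacings = sp, threshold_fraction = 0.2,
                    method = "nearest")
  expect_true(nrow(gn) > 0)
})

test_that("a signal-free region produces an empty-selection warning", {
  pk <- peak_region(array(0, dim = rep(4L, 4L)), tiny_axes(4L))
  expect_warning(g <- sample_grid(pk), "no lattice point")
  expect_identical(nrow(g), 0L)
})
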