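# Fixtures built in code: tiny axes, peaks, shift tables, random maps, and
# independent brute-force oracles kept deliberately separate from the
# package implementations they check.

tiny_axes <- function(n = 8L) {
  list(spectral_axis("H", n, 9.0, -0.2),
       spectral_axis("N", n, 126.0, -1.0),
       spectral_axis("CA", n, 58.0, -1.0),
       spectral_axis("CB", n, 24.0, -1.0))
}

delta_peak <- function(n = 8L, at = c(4L, 4L, 4L, 4L)) {
  arr <- array(0, dim = rep(n, 4L))
  arr[at[1], at[2], at[3], at[4]] <- 1
  peak_region(arr, tiny_axes(n))
}

# separable Gaussian test peak on the tiny axes
gauss_peak <- function(n = 12L, center_frac = 0.5, widths = c(0.3, 1.2, 1.2, 1.2)) {
  axes <- tiny_axes(n)
  ppm <- lapply(axes, axis_ppm)
  mu <- vapply(ppm, function(p) p[1] + center_frac * (p[n] - p[1]), 0)
  prof <- lapply(1:4, function(d) exp(-(ppm[[d]] - mu[d])^2 / (2 * widths[d]^2)))
  arr <- array(outer(outer(prof[[1]], prof[[2]]), outer(prof[[3]], prof[[4]])),
               dim = rep(n, 4L))
  peak_region(arr, axes)
}

# Independent multilinear interpolation: explicit nested corner loops,
# structured differently from the package implementation.
oracle_interp <- function(peak, shift) {
  f <- numeric(4); i0 <- integer(4)
  for (d in 1:4) {
    ax <- peak$axes[[d]]
    t <- (shift[d] - ax$ppm_start) / ax$ppm_step
    stopifnot(t >= -1e-9, t <= ax$n_points - 1 + 1e-9)
    t <- min(max(t, 0), ax$n_points - 1)
    i0[d] <- min(floor(t), ax$n_points - 2)
    f[d] <- t - i0[d]
  }
  val <- 0
  for (a in 0:1) for (b in 0:1) for (c in 0:1) for (e in 0:1) {
    w <- (if (a) f[1] else 1 - f[1]) * (if (b) f[2] else 1 - f[2]) *
         (if (c) f[3] else 1 - f[3]) * (if (e) f[4] else 1 - f[4])
    val <- val + w * peak$intensity[i0[1] + a + 1, i0[2] + b + 1,
                                    i0[3] + c + 1, i0[4] + e + 1]
  }
  val
}

# Brute-force lattice scan oracle for sample_grid.
oracle_grid_scan <- function(peak, spacings, threshold_fraction) {
  anchor <- peak_maximum_shifts(peak)
  pts <- list()
  coords <- lapply(1:4, function(d) {
    r <- axis_range(peak$axes[[d]])
    lo <- -floor((anchor[d] - r[1]) / spacings[d])
    hi <- floor((r[2] - anchor[d]) / spacings[d])
    anchor[d] + (lo:hi) * spacings[d]
  })
  for (h in coords[[1]]) for (n in coords[[2]])
    for (ca in coords[[3]]) for (cb in coords[[4]]) {
      v <- oracle_interp(peak, c(h, n, ca, cb))
      if (v >= threshold_fraction * peak$max_intensity)
        pts[[length(pts) + 1]] <- c(h, n, ca, cb, v)
    }
  if (length(pts) == 0) return(matrix(numeric(0), ncol = 5))
  do.call(rbind, pts)
}

# Small constructed shift tables (independent of the shipped CSVs).
make_rc <- function() {
  df <- data.frame(
    kind = "base",
    residue = rep(c("A", "G", "L"), each = 4),
    nucleus = rep(c("H", "N", "CA", "CB"), 3),
    value = c(8.2, 123.8, 52.5, 19.1,
              8.3, 108.8, 45.1, NA,
              8.1, 121.8, 55.1, 42.4))
  df <- df[!is.na(df$value), ]
  corr <- data.frame(
    kind = c("prev", "prev", "next", "next"),
    residue = c("G", "L", "G", "L"),
    nucleus = c("N", "N", "CA", "CA"),
    value = c(-0.5, 0.3, -0.1, 0.2))
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  write.csv(rbind(df, corr), path, row.names = FALSE)
  load_random_coil(path)
}

make_cog <- function(ca_span_A = 4, ca_span_L = 2) {
  df <- data.frame(
    residue = rep(c("A", "G", "L"), each = 4),
    nucleus = rep(c("H", "N", "CA", "CB"), 3),
    helix = c(8.0, 122.0, 52.5 + 0, 18.3,
              8.1, 107.5, 46.0, NA,
              7.9, 120.0, 56.0, 41.5),
    extended = c(8.5, 126.0, 52.5 + 0, 21.5,
                 8.6, 111.0, 44.5, NA,
                 8.4, 124.0, 56.0, 44.0))
  df$helix[df$residue == "A" & df$nucleus == "CA"] <- 52.5 + ca_span_A / 2
  df$extended[df$residue == "A" & df$nucleus == "CA"] <- 52.5 - ca_span_A / 2
  df$helix[df$residue == "L" & df$nucleus == "CA"] <- 55.1 + ca_span_L / 2
  df$extended[df$residue == "L" & df$nucleus == "CA"] <- 55.1 - ca_span_L / 2
  df <- df[!is.na(df$helix), ]
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  write.csv(df, path, row.names = FALSE)
  load_cog(path)
}

# random unfolded maps for property tests
random_map <- function(normalize = TRUE) {
  rama_map(matrix(runif(324), 18, 18), folded = FALSE, normalize = normalize)
}

# a small database data frame in the load_database schema
make_db <- function(n = 10, residue = "A", stride = "H", piqc = TRUE,
                    shifts = c(H = 8.3, N = 123, CA = 55, CB = 18),
                    phi = -80, psi = -30) {
  data.frame(protein_id = sprintf("P%03d", seq_len(n)), resid = seq_len(n),
             residue = residue, H = shifts["H"], N = shifts["N"],
             CA = shifts["CA"], CB = shifts["CB"], phi = phi, psi = psi,
             stride = stride, piqc_pass = piqc, row.names = NULL)
}
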