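# Synthetic ground truth: 4D peaks from conformer mixtures, mock
# shift/structure databases, and a mock shift-to-angle predictor.  All
# randomness runs through an explicit seed so fixtures are reproducible.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Forward model linking conformational class to chemical shifts
#'
#' Defines, per simplified secondary-structure class, the shift centroid
#' (ppm), the within-class conformer shift scatter (ppm, standard
#' deviation), the (phi, psi) angular mode and angular spread (degrees),
#' plus homogeneous linewidths (ppm, FWHM) shared by all classes.
#'
#' Defaults emulate an alanine spin system: helix and extended carbon
#' centroids are anti-correlated (helix CA 55 / CB 18; extended CA 50 /
#' CB 23 ppm), H/N centroids differ only mildly between classes (amide
#' shifts report H-bonding more than backbone angles), within-class
#' carbon scatter is 1.5 ppm, and homogeneous linewidths are
#' 0.5 / 0.3 / 0.5 ppm FWHM for H / N / C.
#'
#' @param classes Named list of class definitions (`shifts`, `scatter`,
#'   `angles`, `angle_sd`); see the default for the expected shape.
#' @param linewidth_fwhm Named homogeneous linewidths (ppm FWHM).
#' @return An object of class `forward_model`.
#' @export
forward_model <- function(classes = NULL,
                          linewidth_fwhm = c(H = 0.5, N = 0.3,
                                             CA = 0.5, CB = 0.5)) {
  default_classes <- list(
    helix = list(shifts = c(H = 8.25, N = 122.5, CA = 55.0, CB = 18.0),
                 scatter = c(H = 0.40, N = 1.80, CA = 1.50, CB = 1.50),
                 angles = c(phi = -80, psi = -30), angle_sd = 15),
    extended = list(shifts = c(H = 8.45, N = 124.5, CA = 50.0, CB = 23.0),
                    scatter = c(H = 0.40, N = 1.80, CA = 1.50, CB = 1.50),
                    angles = c(phi = -130, psi = 140), angle_sd = 15),
    other = list(shifts = c(H = 8.35, N = 123.5, CA = 52.5, CB = 20.5),
                 scatter = c(H = 0.40, N = 1.80, CA = 1.20, CB = 1.20),
                 angles = c(phi = -100, psi = 60), angle_sd = 25),
    coil = list(shifts = c(H = 8.30, N = 123.0, CA = 52.5, CB = 19.1),
                scatter = c(H = 0.40, N = 1.80, CA = 1.20, CB = 1.20),
                angles = NULL, angle_sd = NA))
  classes <- classes %||% default_classes
  lw <- linewidth_fwhm[.NUCLEI]
  if (anyNA(lw) || any(lw <= 0))
    stop("forward_model: 'linewidth_fwhm' must be positive for H, N, CA, CB")
  hx <- classes$helix$shifts; ex <- classes$extended$shifts
  if (!is.null(hx) && !is.null(ex) &&
      !(hx["CA"] > ex["CA"] && hx["CB"] < ex["CB"]))
    stop("forward_model: helix/extended CA and CB centroids must be ",
         "anti-correlated (helix CA high & CB low)")
  structure(list(classes = classes, linewidth_fwhm = lw,
                 linewidth_sd = lw / (2 * sqrt(2 * log(2)))),
            class = "forward_model")
}

#' One conformer of a synthetic ensemble
#'
#' @param phi,psi Backbone dihedral angles (degrees).
#' @param population Ensemble fraction.
#' @param shift_centroid Named shift quadruple (ppm).
#' @param shift_scatter Named per-nucleus shift standard deviations (ppm).
#' @return A `conformer_spec` list.
#' @export
conformer <- function(phi, psi, population, shift_centroid, shift_scatter) {
  if (population < 0) stop("conformer: negative population")
  if (any(shift_scatter[.NUCLEI] < 0)) stop("conformer: negative scatter")
  structure(list(phi = phi, psi = psi, population = population,
                 shift_centroid = shift_centroid[.NUCLEI],
                 shift_scatter = shift_scatter[.NUCLEI]),
            class = "conformer_spec")
}

#' Conformer at a forward-model class mode
#'
#' @param model A [forward_model()].
#' @param class Class name (`"helix"`, `"extended"`, ...).
#' @param population Ensemble fraction.
#' @return A [conformer()] at the class's angular mode and shift centroid.
#' @export
class_conformer <- function(model, class, population) {
  stopifnot(inherits(model, "forward_model"))
  cl <- model$classes[[class]]
  if (is.null(cl)) stop("class_conformer: unknown class '", class, "'")
  conformer(cl$angles["phi"] %||% NA_real_, cl$angles["psi"] %||% NA_real_,
            population, cl$shifts, cl$scatter)
}

#' Spectral axes covering a forward model
#'
#' Axes spanning all class centroids plus a margin of `margin_sd` total
#' widths (scatter plus homogeneous linewidth), stored high-to-low ppm as
#' in processed spectra.
#'
#' @param model A [forward_model()].
#' @param n_points Points per axis (default 24 each).
#' @param margin_sd Margin in units of the total per-nucleus width.
#' @return List of four [spectral_axis()] objects (H, N, CA, CB).
#' @export
default_axes <- function(model, n_points = c(H = 24, N = 24, CA = 24, CB = 24),
                         margin_sd = 4) {
  stopifnot(inherits(model, "forward_model"))
  lapply(seq_along(.NUCLEI), function(d) {
    nu <- .NUCLEI[d]
    cents <- vapply(model$classes, function(cl) cl$shifts[[nu]], 0)
    scats <- vapply(model$classes, function(cl) cl$scatter[[nu]], 0)
    tot <- sqrt(max(scats)^2 + model$linewidth_sd[[nu]]^2)
    lo <- min(cents) - margin_sd * tot
    hi <- max(cents) + margin_sd * tot
    n <- n_points[[nu]]
    spectral_axis(nu, n, hi, -(hi - lo) / (n - 1))
  })
}

#' Simulate a heterogeneously broadened 4D peak
#'
#' Sums population-weighted separable 4D Gaussians, one per conformer,
#' with per-nucleus width equal to the conformer shift scatter convolved
#' with the model's homogeneous linewidth, and optionally adds white
#' noise.  Deterministic for a fixed seed.
#'
#' @param ensemble List of [conformer()] specs; populations must sum to 1.
#' @param model A [forward_model()] (supplies homogeneous linewidths).
#' @param axes Four [spectral_axis()] objects (default [default_axes()]).
#' @param noise_level White-noise standard deviation as a fraction of the
#'   noiseless peak maximum (default 0).
#' @param seed Integer seed for the noise draw.
#' @return A [peak_region()].
#' @export
simulate_peak <- function(ensemble, model = forward_model(),
                          axes = default_axes(model), noise_level = 0,
                          seed = NULL) {
  stopifnot(inherits(model, "forward_model"))
  if (inherits(ensemble, "conformer_spec")) ensemble <- list(ensemble)
  pops <- vapply(ensemble, `[[`, 0, "population")
  if (abs(sum(pops) - 1) > 1e-6)
    stop("simulate_peak: conformer populations must sum to 1")
  ppm <- lapply(axes, axis_ppm)
  dims <- vapply(axes, `[[`, 1L, "n_points")
  arr <- array(0, dim = dims)
  for (cf in ensemble) {
    prof <- vector("list", 4L)
    for (d in seq_len(4L)) {
      nu <- .NUCLEI[d]
      sdev <- sqrt(cf$shift_scatter[[nu]]^2 + model$linewidth_sd[[nu]]^2)
      mu <- cf$shift_centroid[[nu]]
      r <- range(ppm[[d]])
      if (mu < r[1] || mu > r[2])
        stop("simulate_peak: centroid of a conformer lies outside the ", nu,
             " axis")
      prof[[d]] <- stats::dnorm(ppm[[d]], mean = mu, sd = sdev)
    }
    g <- outer(outer(prof[[1]], prof[[2]]), outer(prof[[3]], prof[[4]]))
    arr <- arr + cf$population * array(g, dim = dims)
  }
  if (noise_level > 0) {
    arr <- .with_seed(seed, arr + stats::rnorm(length(arr),
                                               sd = noise_level * max(arr)))
  }
  peak_region(arr, axes)
}

#' Generate a mock chemical-shift/structure database
#'
#' Draws entries from the forward model: a class per entry (multinomial in
#' the class populations), shifts at the class centroid plus scatter,
#' angles wrapped-normal around the class mode (uniform for coil), a
#' STRIDE code consistent with the class, and a PIQC flag failing at a
#' configurable rate.
#'
#' @param n_entries Number of entries.
#' @param populations Named class fractions (must sum to 1); the default
#'   mixes helix 0.40, extended 0.40, other 0.15, coil 0.05.
#' @param model A [forward_model()].
#' @param residue_type One-letter code written into the entries.
#' @param piqc_fail_rate Fraction of proteins flagged as failing quality
#'   control (default 0.05).
#' @param seed Integer seed.
#' @return A data frame in the [load_database()] schema.
#' @export
generate_mock_database <- function(n_entries,
                                   populations = c(helix = 0.40,
                                                   extended = 0.40,
                                                   other = 0.15, coil = 0.05),
                                   model = forward_model(),
                                   residue_type = "A",
                                   piqc_fail_rate = 0.05, seed = NULL) {
  stopifnot(inherits(model, "forward_model"))
  if (n_entries < 1L) stop("generate_mock_database: 'n_entries' must be >= 1")
  if (abs(sum(populations) - 1) > 1e-6)
    stop("generate_mock_database: class populations must sum to 1")
  stride_for <- list(
    helix = function(n) sample(c("H", "G", "I"), n, TRUE, c(0.8, 0.15, 0.05)),
    extended = function(n) rep("E", n),
    other = function(n) sample(c("T", "B", "b"), n, TRUE, c(0.8, 0.1, 0.1)),
    coil = function(n) rep("C", n))
  .with_seed(seed, {
    cls <- sample(names(populations), n_entries, TRUE, populations)
    df <- data.frame(
      protein_id = sprintf("SYN%04d", sample.int(max(2L, n_entries %/% 8L),
                                                 n_entries, TRUE)),
      resid = sample.int(200L, n_entries, TRUE),
      residue = residue_type,
      H = NA_real_, N = NA_real_, CA = NA_real_, CB = NA_real_,
      phi = NA_real_, psi = NA_real_, stride = NA_character_,
      piqc_pass = stats::rbinom(n_entries, 1L, 1 - piqc_fail_rate) == 1L,
      stringsAsFactors = FALSE)
    for (cl_name in unique(cls)) {
      idx <- which(cls == cl_name)
      cl <- model$classes[[cl_name]]
      if (is.null(cl))
        stop("generate_mock_database: class '", cl_name,
             "' not in the forward model")
      for (nu in .NUCLEI)
        df[idx, nu] <- cl$shifts[[nu]] +
          stats::rnorm(length(idx), sd = cl$scatter[[nu]])
      if (is.null(cl$angles)) {
        df$phi[idx] <- stats::runif(length(idx), -180, 180)
        df$psi[idx] <- stats::runif(length(idx), -180, 180)
      } else {
        df$phi[idx] <- wrap_angle(cl$angles["phi"] +
                                    stats::rnorm(length(idx), sd = cl$angle_sd))
        df$psi[idx] <- wrap_angle(cl$angles["psi"] +
                                    stats::rnorm(length(idx), sd = cl$angle_sd))
      }
      df$stride[idx] <- stride_for[[cl_name]](length(idx))
    }
    # angles live in (-180, 180]
    df$phi[df$phi == -180] <- 180
    df$psi[df$psi == -180] <- 180
    df
  })
}

# wrapped-normal density at bin centres (degrees), normalized over the grid
.angular_kernel <- function(centers_phi, centers_psi, mode, sd) {
  wn <- function(x, mu) {
    d <- 0
    for (k in -1:1) d <- d + stats::dnorm(x - mu + 360 * k, sd = sd)
    d
  }
  dens <- outer(wn(centers_phi, mode["phi"]), wn(centers_psi, mode["psi"]))
  dens / sum(dens)
}

#' Mock shift-to-angle predictor
#'
#' Desk-scale stand-in for an ANN-style shift-based dihedral predictor,
#' for closed-loop tests.  Given one shift quadruple it computes the
#' posterior probability of the helix and extended classes under the
#' forward model (equal priors; Gaussian class likelihoods with variance
#' scatter plus homogeneous linewidth), together with a flat background
#' class whose likelihood equals the class likelihood at
#' `background_sd_multiple` total widths from a centroid.  The returned
#' 18 x 18 map mixes wrapped-Gaussian angular kernels at the class modes
#' (weighted by the class posteriors) with a uniform component (weighted
#' by the background posterior): shifts at a centroid give a confined map
#' in that class's region, shifts equidistant between the centroids split
#' evenly, and shifts far from all centroids flatten towards uniform.
#'
#' @param shifts Named shift quadruple (ppm).
#' @param model A [forward_model()].
#' @param background_sd_multiple Mahalanobis distance (in total widths)
#'   at which a shift is as likely under the background as under a class
#'   (default 3).
#' @return An unfolded, normalized [rama_map()].
#' @export
mock_predictor <- function(shifts, model = forward_model(),
                           background_sd_multiple = 3) {
  stopifnot(inherits(model, "forward_model"))
  shifts <- unlist(shifts)[.NUCLEI]
  use <- c("helix", "extended")
  loglik <- vapply(use, function(cl_name) {
    cl <- model$classes[[cl_name]]
    sum(vapply(.NUCLEI, function(nu) {
      sdev <- sqrt(cl$scatter[[nu]]^2 + model$linewidth_sd[[nu]]^2)
      stats::dnorm(shifts[[nu]], cl$shifts[[nu]], sdev, log = TRUE)
    }, 0))
  }, 0)
  # background: as likely as a class is at Mahalanobis distance
  # background_sd_multiple from its own centroid
  peak_ll <- max(vapply(use, function(cl_name) {
    cl <- model$classes[[cl_name]]
    sum(vapply(.NUCLEI, function(nu) {
      sdev <- sqrt(cl$scatter[[nu]]^2 + model$linewidth_sd[[nu]]^2)
      stats::dnorm(0, 0, sdev, log = TRUE)
    }, 0))
  }, 0))
  ll <- c(loglik, background = peak_ll - background_sd_multiple^2 / 2)
  post <- exp(ll - max(ll))
  post <- post / sum(post)
  dens <- post["background"] * matrix(1 / 324, 18L, 18L)
  for (cl_name in use) {
    cl <- model$classes[[cl_name]]
    dens <- dens + post[cl_name] *
      .angular_kernel(.phi_centers_unfolded, .psi_centers,
                      cl$angles, cl$angle_sd)
  }
  rama_map(dens, folded = FALSE, normalize = TRUE)
}
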