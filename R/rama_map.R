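# Binned phi/psi probability maps.
#
# The unfolded lattice is the 18 x 18 grid used by ANN-style shift-based
# predictors: bin centres at multiples of 20 degrees from -180 to +160 on
# both axes (bin k covers [centre - 10, centre + 10), with +180 identified
# with -180).  "Folding" merges right- and left-handed senses of winding by
# point reflection about (0, 0): every bin with phi > 0 is added onto its
# reflected partner (-phi, -psi).  The columns phi = 0 and phi = -180 map
# onto themselves, so the folded lattice has exactly 10 phi columns
# (-180, -160, ..., 0) by 18 psi rows — 180 bins.

.phi_centers_unfolded <- seq(-180, 160, by = 20)
.psi_centers <- seq(-180, 160, by = 20)
.phi_centers_folded <- seq(-180, 0, by = 20)

#' Construct a Ramachandran probability map
#'
#' @param density Numeric matrix of non-negative bin densities, rows
#'   indexed by phi centres and columns by psi centres (18 x 18 unfolded,
#'   10 x 18 folded).
#' @param folded Logical; is this a folded (10 phi-column) map?
#' @param normalize Normalize the density to unit sum (default `TRUE`).
#'   The unnormalized input is retained in `$raw_density` for diagnostics.
#' @return An object of class `rama_map` with elements `density`,
#'   `raw_density`, `phi_centers`, `psi_centers`, `folded`, `normalized`.
#' @export
rama_map <- function(density, folded = FALSE, normalize = TRUE) {
  density <- as.matrix(density)
  phi_centers <- if (folded) .phi_centers_folded else .phi_centers_unfolded
  if (!identical(dim(density), c(length(phi_centers), length(.psi_centers))))
    stop("rama_map: density must be ", length(phi_centers), " x ",
         length(.psi_centers), " (phi x psi) for ",
         if (folded) "a folded" else "an unfolded", " map")
  if (any(!is.finite(density)) || any(density < 0))
    stop("rama_map: density must be finite and non-negative")
  raw <- density
  total <- sum(density)
  if (normalize) {
    if (total <= 0) stop("rama_map: cannot normalize a zero-mass map")
    density <- density / total
  }
  dimnames(density) <- list(phi = phi_centers, psi = .psi_centers)
  structure(list(density = density, raw_density = raw,
                 phi_centers = phi_centers, psi_centers = .psi_centers,
                 folded = folded, normalized = normalize),
            class = "rama_map")
}

#' @export
print.rama_map <- function(x, ...) {
  cat(sprintf("<rama_map %s, %d x %d bins, %s, total mass %.4g>\n",
              if (x$folded) "folded" else "unfolded",
              nrow(x$density), ncol(x$density),
              if (x$normalized) "normalized" else "raw",
              sum(x$density)))
  invisible(x)
}

.bin_index <- function(angle, centers) {
  a <- wrap_angle(angle)
  idx <- floor((a - (centers[1] - 10)) / 20) + 1L
  idx[idx < 1L | idx > length(centers)] <- NA_integer_
  idx
}

#' Parse a per-residue phi/psi probability-grid file
#'
#' Reads the 18 x 18 (phi, psi) probability grid emitted per residue by
#' ANN-style shift-based dihedral predictors.  The accepted layout
#' (dialect `"grid"`) is whitespace-separated `phi psi density` triplets,
#' one per line, for all 324 bin-centre combinations; `#`, `REMARK`,
#' `VARS`, `FORMAT` and `DATA` lines are ignored.  The map is normalized
#' to unit sum on parse.
#'
#' @param path Grid output file.
#' @param dialect File layout tag; only `"grid"` is currently supported.
#' @return An unfolded, normalized [rama_map()].
#' @export
parse_ann_output <- function(path, dialect = "grid") {
  if (!identical(dialect, "grid"))
    stop("parse_ann_output: unsupported dialect '", dialect, "'")
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|REMARK|VARS|FORMAT|DATA|$)", lines)]
  fields <- strsplit(trimws(lines), "\\s+")
  if (!all(lengths(fields) == 3L))
    stop("parse_ann_output: expected 'phi psi density' triplets")
  m <- matrix(as.numeric(unlist(fields)), ncol = 3L, byrow = TRUE)
  if (any(!is.finite(m))) stop("parse_ann_output: non-numeric grid values")
  if (nrow(m) != 324L)
    stop("parse_ann_output: expected 324 grid values, found ", nrow(m))
  if (any(m[, 3] < 0))
    stop("parse_ann_output: negative probabilities in grid file")
  pi_ <- .bin_index(m[, 1], .phi_centers_unfolded)
  qi <- .bin_index(m[, 2], .psi_centers)
  if (anyNA(pi_) || anyNA(qi) || anyDuplicated(cbind(pi_, qi)))
    stop("parse_ann_output: grid coordinates do not form the 18 x 18 lattice")
  dens <- matrix(0, 18L, 18L)
  dens[cbind(pi_, qi)] <- m[, 3]
  rama_map(dens, folded = FALSE, normalize = TRUE)
}

#' Write a phi/psi probability grid file
#'
#' Inverse of [parse_ann_output()]; used by the mock predictor and for
#' fixtures.
#'
#' @param map An unfolded [rama_map()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ann_output <- function(map, path) {
  stopifnot(inherits(map, "rama_map"))
  if (map$folded) stop("write_ann_output: grid files hold unfolded maps")
  lines <- c("REMARK phi/psi probability grid",
             "VARS PHI PSI DENSITY", "FORMAT %8.1f %8.1f %12.6e")
  for (i in seq_along(map$phi_centers))
    for (j in seq_along(map$psi_centers))
      lines <- c(lines, sprintf("%8.1f %8.1f %12.6e", map$phi_centers[i],
                                map$psi_centers[j], map$density[i, j]))
  writeLines(lines, path)
  invisible(path)
}

#' Intensity-weighted aggregation of per-grid-point maps
#'
#' Combines the per-grid-point probability maps \eqn{D_{ki}} into the map
#' of the whole heterogeneous peak, \eqn{D_k = \sum_i D_{ki} I_i}, with
#' \eqn{I_i} the spectrum intensity at grid point \eqn{i}; the result is
#' normalized to unit sum.  Aggregation is linear and permutation-invariant
#' in the (map, weight) pairs, and invariant under uniform rescaling of the
#' weights.
#'
#' @param maps List of [rama_map()] objects sharing binning and folded
#'   state.
#' @param intensities Non-negative weights, one per map.
#' @return A normalized [rama_map()].
#' @export
aggregate_maps <- function(maps, intensities) {
  if (length(maps) == 0L) stop("aggregate_maps: no maps supplied")
  if (length(maps) != length(intensities))
    stop("aggregate_maps: 'maps' and 'intensities' lengths differ")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("aggregate_maps: intensities must be finite and non-negative")
  if (sum(intensities) <= 0)
    stop("aggregate_maps: all weights are zero")
  folded <- maps[[1]]$folded
  dims <- dim(maps[[1]]$density)
  acc <- matrix(0, dims[1], dims[2])
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    if (!inherits(m, "rama_map") || !identical(dim(m$density), dims) ||
        !identical(m$folded, folded))
      stop("aggregate_maps: maps must share binning and folded state")
    acc <- acc + m$density * intensities[i]
  }
  out <- rama_map(acc, folded = folded, normalize = TRUE)
  out$raw_density <- acc
  out
}

#' Fold a Ramachandran map
#'
#' Merges left- and right-handed senses of winding: each bin with phi > 0
#' is added to its point-reflected partner at (-phi, -psi).  Total mass is
#' conserved exactly; the result has 10 phi columns by 18 psi rows.
#'
#' @param map An unfolded [rama_map()].
#' @return A folded [rama_map()] (normalized if the input was).
#' @export
fold_map <- function(map) {
  stopifnot(inherits(map, "rama_map"))
  if (map$folded) stop("fold_map: map is already folded")
  nfold <- length(.phi_centers_folded)
  dens <- matrix(0, nfold, length(.psi_centers))
  for (i in seq_along(map$phi_centers)) {
    phi <- map$phi_centers[i]
    if (phi <= 0) {
      ti <- match(phi, .phi_centers_folded)
      tj <- seq_along(.psi_centers)
    } else {
      ti <- match(-phi, .phi_centers_folded)
      tj <- .bin_index(-map$psi_centers, .psi_centers)
    }
    dens[cbind(ti, tj)] <- dens[cbind(ti, tj)] + map$density[i, ]
  }
  out <- rama_map(dens, folded = TRUE, normalize = map$normalized)
  out$raw_density <- dens
  out
}

#' Project a map onto one dihedral axis
#'
#' Marginal distribution over phi (column sums per phi row) or psi.
#'
#' @param map A normalized [rama_map()].
#' @param axis `"phi"` or `"psi"`.
#' @return Named numeric vector over the axis bin centres, summing to the
#'   map's total mass.
#' @export
project_map <- function(map, axis = c("phi", "psi")) {
  stopifnot(inherits(map, "rama_map"))
  axis <- match.arg(axis)
  if (axis == "phi") stats::setNames(rowSums(map$density), map$phi_centers)
  else stats::setNames(colSums(map$density), map$psi_centers)
}

#' Heatmap of a Ramachandran map
#'
#' Minimal base-graphics display (grey scale, white = maximum) for quick
#' inspection.
#'
#' @param x A [rama_map()].
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
plot.rama_map <- function(x, main = NULL, ...) {
  graphics::image(x = x$phi_centers, y = x$psi_centers, z = x$density,
                  col = grDevices::gray.colors(64, start = 0, end = 1),
                  xlab = expression(phi ~ "(deg)"),
                  ylab = expression(psi ~ "(deg)"),
                  main = main %||%
                    sprintf("Ramachandran map (%s)",
                            if (x$folded) "folded" else "unfolded"), ...)
  graphics::box()
  invisible(x)
}
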