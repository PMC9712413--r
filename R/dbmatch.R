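# Database-matching route: reconstruct the phi/psi ensemble directly from a
# chemical-shift/structure database (PACSY-style per-residue table relating
# shifts, dihedral angles, a STRIDE class and a quality flag).

.STRIDE_CODES <- c("H", "G", "I", "E", "T", "B", "b", "C")

#' Load a per-residue chemical-shift/structure database table
#'
#' Schema: CSV with columns `protein_id`, `resid`, `residue`, `H`, `N`,
#' `CA`, `CB` (ppm; empty where unobserved), `phi`, `psi` (degrees in
#' (-180, 180]), `stride` (one of H, G, I, E, T, B, b, C) and `piqc_pass`
#' (logical quality flag).  An optional `CO` column is tolerated and
#' ignored.
#'
#' @param path CSV file.
#' @param residue_type Optional one-letter code; keep only entries of this
#'   residue type.
#' @return A `data.frame` of database entries.
#' @export
load_database <- function(path, residue_type = NULL) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("protein_id", "resid", "residue", "H", "N", "CA", "CB",
            "phi", "psi", "stride", "piqc_pass")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("load_database: missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(df$stride %in% .STRIDE_CODES))
    stop("load_database: unknown STRIDE code(s): ",
         paste(unique(setdiff(df$stride, .STRIDE_CODES)), collapse = ", "))
  ang_ok <- function(a) is.finite(a) & a > -180 & a <= 180
  if (!all(ang_ok(df$phi) & ang_ok(df$psi)))
    stop("load_database: phi/psi must lie in (-180, 180] degrees")
  df$piqc_pass <- as.logical(df$piqc_pass)
  if (anyNA(df$piqc_pass))
    stop("load_database: 'piqc_pass' must be logical")
  if (!is.null(residue_type))
    df <- df[df$residue == toupper(residue_type), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Drop entries from proteins failing shift quality control
#'
#' @param entries A [load_database()] data frame.
#' @return Entries with `piqc_pass == TRUE`.
#' @export
filter_quality <- function(entries) {
  out <- entries[entries$piqc_pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simplify a STRIDE class code
#'
#' Alpha-, 3-10 and pi-helices (H, G, I) become `"helix"`; E becomes
#' `"extended"`; turn/bridge codes (T, B, b) become `"other"`; C becomes
#' `"coil"`.
#'
#' @param stride_class Character vector of STRIDE codes.
#' @return Character vector in \{helix, extended, other, coil\}.
#' @export
simplify_class <- function(stride_class) {
  bad <- setdiff(unique(stride_class), .STRIDE_CODES)
  if (length(bad) > 0L)
    stop("simplify_class: unknown STRIDE code(s): ", paste(bad, collapse = ", "))
  out <- rep("other", length(stride_class))
  out[stride_class %in% c("H", "G", "I")] <- "helix"
  out[stride_class == "E"] <- "extended"
  out[stride_class == "C"] <- "coil"
  out
}

#' Select database entries inside the 4D peak envelope
#'
#' Keeps entries whose shift quadruple falls inside the peak region with
#' interpolated intensity at or above `threshold_fraction` of the peak
#' maximum, pairing each with its intensity \eqn{I_i}.  Coil-class entries
#' are excluded: in a rigidified sample, conformational averaging to
#' random-coil shifts does not occur, so coil database shifts do not
#' correspond to any single backbone conformation.  Entries missing one of
#' the four shifts are skipped (a message reports the count).
#'
#' @param entries A [load_database()] data frame.
#' @param peak A [peak_region()].
#' @param threshold_fraction Fraction of the peak maximum (default 0.2).
#' @return The kept entries with columns `intensity` and `class` appended.
#' @export
select_in_envelope <- function(entries, peak, threshold_fraction = 0.2) {
  stopifnot(inherits(peak, "peak_region"))
  cls <- simplify_class(entries$stride)
  keep_class <- cls != "coil"
  complete <- !is.na(entries$H) & !is.na(entries$N) &
    !is.na(entries$CA) & !is.na(entries$CB)
  n_skipped <- sum(!complete)
  if (n_skipped > 0L)
    message("select_in_envelope: skipped ", n_skipped,
            " entr", if (n_skipped == 1L) "y" else "ies",
            " with incomplete shift quadruples")
  cand <- which(keep_class & complete)
  shifts <- as.matrix(entries[cand, .NUCLEI, drop = FALSE])
  inside <- rep(TRUE, length(cand))
  for (d in seq_len(4L)) {
    r <- axis_range(peak$axes[[d]])
    inside <- inside & shifts[, d] >= r[1] & shifts[, d] <= r[2]
  }
  inten <- rep(0, length(cand))
  if (any(inside))
    inten[inside] <- interpolate_intensity(peak, shifts[inside, , drop = FALSE])
  kept <- inten >= threshold_fraction * peak$max_intensity & inside
  out <- entries[cand[kept], , drop = FALSE]
  out$intensity <- inten[kept]
  out$class <- cls[cand[kept]]
  rownames(out) <- NULL
  out
}

#' Local 4D entry density
#'
#' Product-Gaussian kernel density estimate over the 4D shift coordinates
#' of the selected entries (each entry contributes to its own density).
#' The inverse of this density compensates for the shift-combination-
#' specific sparsity of database entries when weighting the reconstruction.
#'
#' @param entries Data frame with H, N, CA, CB columns (or an `n x 4`
#'   matrix).
#' @param bandwidths Named per-nucleus kernel bandwidths in ppm; the
#'   default reuses the grid spacings of [sample_grid()] so that the two
#'   reconstruction routes resolve shift space at the same scale.
#' @return Numeric vector of densities \eqn{P_i > 0}, one per entry.  A
#'   single entry yields a degenerate-density warning and `P = 1`.
#' @export
local_density <- function(entries,
                          bandwidths = c(H = 0.4, N = 1.5, CA = 1.0, CB = 1.5)) {
  x <- if (is.data.frame(entries)) as.matrix(entries[, .NUCLEI, drop = FALSE])
       else as.matrix(entries)
  if (ncol(x) != 4L) stop("local_density: entries must have 4 shift columns")
  bandwidths <- bandwidths[.NUCLEI]
  if (anyNA(bandwidths) || any(bandwidths <= 0))
    stop("local_density: 'bandwidths' must be positive for H, N, CA, CB")
  n <- nrow(x)
  if (n < 2L) {
    warning("local_density: fewer than 2 entries; returning uniform density")
    return(rep(1, n))
  }
  dens <- rep(0, n)
  # accumulate product-kernel sums; O(n^2) but n is the envelope selection
  for (j in seq_len(n)) {
    k <- rep(1, n)
    for (d in seq_len(4L))
      k <- k * stats::dnorm(x[, d] - x[j, d], sd = bandwidths[d])
    dens <- dens + k
  }
  dens / n
}

#' Inverse-density, intensity-proportional entry weights
#'
#' Final weight of the i-th selected entry: \eqn{w_i = I_i / P_i}, the
#' peak intensity at its shift position over the local database entry
#' density there.
#'
#' @param selection Output of [select_in_envelope()].
#' @param density Densities from [local_density()] (computed by default
#'   over the selection itself).
#' @param bandwidths Passed to [local_density()] when `density` is NULL.
#' @return `selection` with columns `density` and `weight` appended.
#' @export
weight_entries <- function(selection, density = NULL,
                           bandwidths = c(H = 0.4, N = 1.5, CA = 1.0, CB = 1.5)) {
  if (is.null(density)) density <- local_density(selection, bandwidths)
  if (length(density) != nrow(selection))
    stop("weight_entries: density length does not match selection")
  if (any(density <= 0)) stop("weight_entries: densities must be positive")
  selection$density <- density
  selection$weight <- selection$intensity / density
  selection
}

#' Bin weighted entries into a Ramachandran map
#'
#' Weighted two-dimensional histogram of the entries' (phi, psi) angles on
#' the unfolded 18 x 18 lattice (20-degree bins), normalized; fold with
#' [fold_map()] to obtain the 10 x 18 format shared with the prediction
#' route.
#'
#' @param entries Data frame with `phi`, `psi` and (unless `weights` is
#'   given) `weight` columns.
#' @param weights Optional explicit weights.
#' @param bin_width Bin width in degrees; must divide 360 and currently
#'   must be 20, the lattice shared with the prediction route.
#' @return An unfolded, normalized [rama_map()].
#' @export
entries_to_map <- function(entries, weights = NULL, bin_width = 20) {
  if (nrow(entries) == 0L) stop("entries_to_map: empty selection")
  if (bin_width != 20)
    stop("entries_to_map: only the shared 20-degree lattice is supported")
  weights <- weights %||% entries$weight
  if (is.null(weights)) stop("entries_to_map: no weights available")
  if (length(weights) != nrow(entries))
    stop("entries_to_map: weights length does not match entries")
  pi_ <- .bin_index(entries$phi, .phi_centers_unfolded)
  qi <- .bin_index(entries$psi, .psi_centers)
  dens <- matrix(0, 18L, 18L)
  for (k in seq_len(nrow(entries)))
    dens[pi_[k], qi[k]] <- dens[pi_[k], qi[k]] + weights[k]
  rama_map(dens, folded = FALSE, normalize = TRUE)
}

#' Full database-matching reconstruction
#'
#' Convenience chain: quality filter, envelope selection, local-density
#' weighting, and binning into a folded map.
#'
#' @param entries A [load_database()] data frame.
#' @param peak A [peak_region()].
#' @param threshold_fraction Envelope threshold (default 0.2).
#' @param bandwidths Kernel bandwidths for [local_density()].
#' @param density_scope `"envelope"` (default) estimates the entry density
#'   from the selected entries only; `"all"` uses every quality-passing
#'   entry of the residue type.
#' @param min_entries Selections smaller than this are flagged low
#'   confidence (default 20).
#' @return List with `map` (folded [rama_map()]), `selection` (weighted
#'   entries), `n_selected`, and `low_confidence`.
#' @export
reconstruct_from_database <- function(entries, peak, threshold_fraction = 0.2,
                                      bandwidths = c(H = 0.4, N = 1.5,
                                                     CA = 1.0, CB = 1.5),
                                      density_scope = c("envelope", "all"),
                                      min_entries = 20L) {
  density_scope <- match.arg(density_scope)
  ok <- filter_quality(entries)
  sel <- select_in_envelope(ok, peak, threshold_fraction)
  if (nrow(sel) == 0L)
    stop("reconstruct_from_database: no database entries inside the peak envelope")
  dens <- if (density_scope == "envelope") {
    local_density(sel, bandwidths)
  } else {
    complete <- !is.na(ok$H) & !is.na(ok$N) & !is.na(ok$CA) & !is.na(ok$CB)
    pool <- as.matrix(ok[complete, .NUCLEI, drop = FALSE])
    n <- nrow(pool)
    vapply(seq_len(nrow(sel)), function(i) {
      k <- rep(1, n)
      for (d in seq_len(4L))
        k <- k * stats::dnorm(pool[, d] - as.numeric(sel[i, .NUCLEI][d]),
                              sd = bandwidths[.NUCLEI][d])
      sum(k) / n
    }, 0)
  }
  sel <- weight_entries(sel, density = dens)
  map <- fold_map(entries_to_map(sel))
  list(map = map, selection = sel, n_selected = nrow(sel),
       low_confidence = nrow(sel) < min_entries)
}
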