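# Heterogeneity scores for folded Ramachandran maps: circular variance,
# Shannon and excess entropy, flatness, helix/extended population ratio.

#' Circular variance of a weighted angular distribution
#'
#' \eqn{V = 1 - |\bar v|}, where \eqn{\bar v} is the mean resultant vector
#' of the distribution: components \eqn{\sum_k \sin\theta_k D_k / \sum_k D_k}
#' and \eqn{\sum_k \cos\theta_k D_k / \sum_k D_k}.  V is 0 for mass in a
#' single angular bin and 1 for a vanishing resultant (e.g. the uniform
#' distribution over the full period).
#'
#' @param angles Bin angles in degrees.
#' @param weights Non-negative bin weights (need not be normalized).
#' @return Circular variance in [0, 1].
#' @export
circular_variance_values <- function(angles, weights) {
  if (length(angles) != length(weights))
    stop("circular_variance_values: lengths differ")
  if (any(weights < 0)) stop("circular_variance_values: negative weights")
  total <- sum(weights)
  if (total <= 0) stop("circular_variance_values: zero total weight")
  th <- angles * pi / 180
  s <- sum(sin(th) * weights) / total
  c_ <- sum(cos(th) * weights) / total
  max(0, min(1, 1 - sqrt(s^2 + c_^2)))
}

#' Circular variance of a folded map along one dihedral axis
#'
#' Projects the folded map onto phi or psi and applies
#' [circular_variance_values()] to the marginal.  After folding, phi spans
#' only half the circle; with `phi_convention = "raw"` (the default) the
#' bin centres enter as-is, with `"doubled"` the phi angles are doubled so
#' the half-period axial data wrap the full circle before the resultant is
#' formed.
#'
#' @param map A folded, normalized [rama_map()].
#' @param axis `"phi"` or `"psi"`.
#' @param phi_convention `"raw"` or `"doubled"` (phi axis only).
#' @return Circular variance in [0, 1].
#' @export
circular_variance <- function(map, axis = c("phi", "psi"),
                              phi_convention = c("raw", "doubled")) {
  stopifnot(inherits(map, "rama_map"))
  axis <- match.arg(axis)
  phi_convention <- match.arg(phi_convention)
  if (!map$folded)
    stop("circular_variance: scores are defined on folded maps")
  p <- project_map(map, axis)
  ang <- as.numeric(names(p))
  if (axis == "phi" && phi_convention == "doubled") ang <- 2 * ang
  circular_variance_values(ang, p)
}

#' Shannon entropy of a distribution or map (nats)
#'
#' \eqn{S = -\sum_k D_k \ln D_k} over the bins of a map or 1-dimensional
#' projection, with \eqn{0 \ln 0 := 0}.  The input is normalized to unit
#' sum first, so S ranges from 0 (single populated bin) to
#' \eqn{\ln(n_{bins})} (uniform).
#'
#' @param x A [rama_map()] or a non-negative numeric vector.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(x) {
  p <- if (inherits(x, "rama_map")) as.vector(x$density) else as.numeric(x)
  if (any(!is.finite(p)) || any(p < 0))
    stop("shannon_entropy: input must be finite and non-negative")
  total <- sum(p)
  if (total <= 0) stop("shannon_entropy: zero total mass")
  p <- p[p > 0] / total
  -sum(p * log(p))
}

#' Excess entropy relative to a reference
#'
#' \eqn{\Delta S = S - S_{ref}}; with the entropy of a conformationally
#' confined helix as reference this corrects for the intrinsic ambiguity a
#' shift-based prediction has even for a well-defined conformation.
#'
#' @param S Entropy (nats).
#' @param S_ref Reference entropy on the same bin structure (nats).
#' @return \eqn{\Delta S} in nats.
#' @export
excess_entropy <- function(S, S_ref) S - S_ref

#' Flatness of a map
#'
#' Relative abundance of the highest-probability bin,
#' `peak_fraction = max(D_k) / sum(D_k)`, together with its complement
#' `1 - peak_fraction`.  The complement grows from confined towards flat
#' distributions and is used as the reported flatness `F` by default;
#' the convention is configurable in [score_all()] and recorded in its
#' output.
#'
#' @param map A [rama_map()] (any folded state) with positive mass.
#' @return List with `peak_fraction` and `complement`.
#' @export
flatness <- function(map) {
  stopifnot(inherits(map, "rama_map"))
  total <- sum(map$density)
  if (total <= 0) stop("flatness: zero-mass map")
  pf <- max(map$density) / total
  list(peak_fraction = pf, complement = 1 - pf)
}

#' Rectangular region mask on the folded lattice
#'
#' @param map A folded [rama_map()].
#' @param phi_range,psi_range Two-element degree ranges; a bin belongs to
#'   the mask if its centre lies inside (psi treated circularly, so 180 is
#'   identified with -180).
#' @return Logical matrix over the map's bins.
#' @export
region_mask <- function(map, phi_range, psi_range) {
  stopifnot(inherits(map, "rama_map"), map$folded)
  inside <- function(centers, range) {
    hit <- centers >= range[1] & centers <= range[2]
    # circular identification of the psi seam
    if (range[2] >= 180) hit <- hit | (centers + 360) <= range[2]
    hit
  }
  outer(inside(map$phi_centers, phi_range),
        inside(map$psi_centers, psi_range), FUN = "&")
}

#' Default helix and extended region masks
#'
#' Approximate rectangular regions on the folded lattice: helix
#' phi in [-120, -40], psi in [-70, 10]; extended phi in [-180, -80],
#' psi in [100, 180].  The two masks are disjoint (separated in psi) and
#' fully user-configurable.
#'
#' @param map A folded [rama_map()].
#' @return List with logical matrices `H` and `E`.
#' @export
default_region_masks <- function(map) {
  list(H = region_mask(map, c(-120, -40), c(-70, 10)),
       E = region_mask(map, c(-180, -80), c(100, 180)))
}

#' Helix/extended population ratio
#'
#' Integrates the map over the helix and extended masks and returns
#' \eqn{R = \max(H, E) / \min(H, E)} (>= 1), flagging the dominant class.
#' A zero minor-class mass yields `R = Inf` with `infinite = TRUE` — the
#' signature of a clean single-class reconstruction.
#'
#' @param map A folded, normalized [rama_map()].
#' @param masks List with logical matrices `H` and `E`
#'   (default [default_region_masks()]).
#' @return List with `R`, `dominant` (`"H"` or `"E"`), `infinite`,
#'   `H_mass`, `E_mass`.
#' @export
ss_ratio <- function(map, masks = default_region_masks(map)) {
  stopifnot(inherits(map, "rama_map"))
  if (!map$folded) stop("ss_ratio: scores are defined on folded maps")
  if (any(masks$H & masks$E)) stop("ss_ratio: H and E masks overlap")
  H <- sum(map$density[masks$H])
  E <- sum(map$density[masks$E])
  if (H == 0 && E == 0)
    stop("ss_ratio: both region masses are zero; ratio undefined")
  dominant <- if (H > E) "H" else "E"
  lo <- min(H, E)
  list(R = if (lo == 0) Inf else max(H, E) / lo,
       dominant = dominant, infinite = lo == 0, H_mass = H, E_mass = E)
}

#' All heterogeneity scores for one folded map
#'
#' Computes circular variance on both axes, Shannon entropies of the full
#' map and its projections, excess entropy against a reference map (or
#' reference entropy), flatness, and the helix/extended ratio.
#'
#' @param map A folded, normalized [rama_map()].
#' @param reference Either a folded [rama_map()] whose total entropy
#'   serves as the excess-entropy reference (typically a confined-helix
#'   prediction), a numeric reference entropy in nats, or `NULL`
#'   (`dS_total = NA`).
#' @param masks Region masks for [ss_ratio()].
#' @param phi_convention Passed to [circular_variance()].
#' @param flatness_convention `"complement"` (default) reports
#'   `1 - peak_fraction` as F; `"peak_fraction"` reports the raw maximum
#'   abundance.
#' @return An object of class `heterogeneity_scores` (also a list) with
#'   fields `V_phi`, `V_psi`, `S_phi`, `S_psi`, `S_total`, `dS_total`,
#'   `F`, `F_peak_fraction`, `R`, `dominant`, `infinite`, and the
#'   conventions used.
#' @export
score_all <- function(map, reference = NULL, masks = default_region_masks(map),
                      phi_convention = c("raw", "doubled"),
                      flatness_convention = c("complement", "peak_fraction")) {
  stopifnot(inherits(map, "rama_map"))
  if (!map$folded) stop("score_all: scores are defined on folded maps")
  phi_convention <- match.arg(phi_convention)
  flatness_convention <- match.arg(flatness_convention)
  s_ref <- if (inherits(reference, "rama_map")) shannon_entropy(reference)
           else if (is.numeric(reference)) reference
           else NA_real_
  fl <- flatness(map)
  rr <- ss_ratio(map, masks)
  s_total <- shannon_entropy(map)
  structure(list(
    V_phi = circular_variance(map, "phi", phi_convention),
    V_psi = circular_variance(map, "psi"),
    S_phi = shannon_entropy(project_map(map, "phi")),
    S_psi = shannon_entropy(project_map(map, "psi")),
    S_total = s_total,
    dS_total = excess_entropy(s_total, s_ref),
    F = if (flatness_convention == "complement") fl$complement
        else fl$peak_fraction,
    F_peak_fraction = fl$peak_fraction,
    R = rr$R, dominant = rr$dominant, infinite = rr$infinite,
    H_mass = rr$H_mass, E_mass = rr$E_mass,
    phi_convention = phi_convention,
    flatness_convention = flatness_convention),
    class = "heterogeneity_scores")
}

#' @export
print.heterogeneity_scores <- function(x, ...) {
  cat("Heterogeneity scores\n")
  cat(sprintf("  V_phi %.3f   V_psi %.3f   (phi convention: %s)\n",
              x$V_phi, x$V_psi, x$phi_convention))
  cat(sprintf("  S_phi %.3f   S_psi %.3f   S_total %.3f   dS_total %s\n",
              x$S_phi, x$S_psi, x$S_total,
              if (is.na(x$dS_total)) "NA" else sprintf("%.3f", x$dS_total)))
  cat(sprintf("  F %.3f (%s; peak fraction %.3f)\n",
              x$F, x$flatness_convention, x$F_peak_fraction))
  cat(sprintf("  R %s (%s-dominant; H %.3f, E %.3f)\n",
              if (is.infinite(x$R)) "Inf" else sprintf("%.3f", x$R),
              x$dominant, x$H_mass, x$E_mass))
  invisible(x)
}

#' One-row data frame of a score set
#'
#' Tidy record (one row per scored map) mirroring the usual table layout
#' of such analyses.
#'
#' @param x A `heterogeneity_scores` object.
#' @param row.names,optional,... Standard [as.data.frame()] arguments.
#' @export
as.data.frame.heterogeneity_scores <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
  data.frame(V_phi = x$V_phi, V_psi = x$V_psi, S_phi = x$S_phi,
             S_psi = x$S_psi, S_total = x$S_total, dS_total = x$dS_total,
             F = x$F, F_peak_fraction = x$F_peak_fraction, R = x$R,
             dominant = x$dominant, H_mass = x$H_mass, E_mass = x$E_mass,
             row.names = row.names, stringsAsFactors = FALSE)
}
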