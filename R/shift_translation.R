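# Translating one grid point's shift quadruple into a predictor-ready shift
# table for the whole sequence.
#
# Shift-based dihedral predictors use the shifts of a window of consecutive
# residues.  For a heterogeneously broadened peak the neighbours' sub-peak
# elements cannot be paired with those of the residue of interest, so the
# ROI's secondary-shift deviation is propagated onto the neighbours
# instead: the deviation r_i of grid point i from the ROI's
# neighbour-corrected random-coil shift is rescaled per neighbour type and
# nucleus (ratio of helix-minus-extended centre-of-gravity spans) and added
# to each neighbour's own random-coil shift.

#' Secondary-shift deviation of a grid point from random coil
#'
#' @param shifts Named shift quadruple (H, N, CA, CB) in ppm, e.g. one row
#'   of [sample_grid()] output.
#' @param sequence One-letter residue sequence.
#' @param roi_index Position of the residue of interest.
#' @param rc A [load_random_coil()] table.
#' @return Named numeric vector of per-nucleus deviations (ppm); a nucleus
#'   the ROI lacks is dropped.
#' @export
deviation_vector <- function(shifts, sequence, roi_index, rc) {
  shifts <- unlist(shifts)[.NUCLEI]
  out <- numeric(0)
  for (nu in .NUCLEI) {
    rcv <- random_coil_shift(rc, sequence, roi_index, nu)
    if (is.na(rcv)) next
    if (is.na(shifts[nu])) next
    out[nu] <- unname(shifts[nu] - rcv)
  }
  out
}

#' Nucleus- and residue-type-specific rescaling factor
#'
#' Ratio of the helix-minus-extended centre-of-gravity span of the
#' neighbour's residue type to that of the ROI's type, reflecting how
#' strongly secondary structure modulates that nucleus's shift in each
#' type.  A nucleus the neighbour type lacks (glycine CB) yields 0.
#'
#' @param roi_type,neighbor_type One-letter residue types.
#' @param nucleus One of H, N, CA, CB.
#' @param cog A [load_cog()] table.
#' @return Scalar rescaling factor.
#' @export
rescale_factor <- function(roi_type, neighbor_type, nucleus, cog) {
  stopifnot(inherits(cog, "cog_table"))
  nucleus <- match.arg(nucleus, .NUCLEI)
  span <- function(type) {
    key <- paste(toupper(type), nucleus, sep = ".")
    unname(cog$helix[key] - cog$extended[key])
  }
  s_n <- span(neighbor_type)
  if (is.na(s_n)) return(0)   # nucleus absent for the neighbour type
  s_r <- span(roi_type)
  if (is.na(s_r))
    stop("rescale_factor: no centre-of-gravity entry for ROI type '",
         roi_type, "' nucleus ", nucleus)
  if (s_r == 0)
    stop("rescale_factor: degenerate helix/extended span for ROI type '",
         roi_type, "' nucleus ", nucleus)
  s_n / s_r
}

#' Build the predictor input table for one grid point
#'
#' The ROI keeps the grid point's shifts verbatim; residues at `j +/- 1`
#' and `j +/- 2` receive their own neighbour-corrected random-coil shift
#' plus the rescaled deviation `r_i`; all other residues (and optional
#' terminal padding residues) sit at plain neighbour-corrected random-coil
#' values.  The construction is affine in `r_i`.
#'
#' @inheritParams deviation_vector
#' @param cog A [load_cog()] table.
#' @param pad Residue type used to extend the termini (default `"G"`).
#' @param n_pad Number of padding residues added per terminus (default 1,
#'   so a 5-mer with a central ROI becomes a 7-mer and window-based
#'   predictors can use full windows around the ROI).
#' @return A `data.frame` of class `predictor_input_table` with columns
#'   `resid`, `residue`, `H`, `N`, `CA`, `CB` and attributes `roi_index`
#'   (position in the padded sequence) and `sequence`.
#' @export
translate_to_neighbors <- function(shifts, sequence, roi_index, rc, cog,
                                   pad = "G", n_pad = 1L) {
  seqv <- .as_residues(sequence)
  if (length(seqv) < 1L) stop("translate_to_neighbors: empty sequence")
  roi_index <- as.integer(roi_index)
  if (roi_index < 1L || roi_index > length(seqv))
    stop("translate_to_neighbors: 'roi_index' outside the sequence")
  n_pad <- as.integer(n_pad)
  if (n_pad < 0L) stop("translate_to_neighbors: 'n_pad' must be >= 0")
  r_i <- deviation_vector(shifts, sequence, roi_index, rc)
  roi_type <- seqv[roi_index]
  seq_ext <- c(rep(toupper(pad), n_pad), seqv, rep(toupper(pad), n_pad))
  roi_ext <- roi_index + n_pad
  shifts <- unlist(shifts)[.NUCLEI]
  tab <- data.frame(resid = seq_along(seq_ext), residue = seq_ext,
                    H = NA_real_, N = NA_real_, CA = NA_real_, CB = NA_real_)
  for (j in seq_along(seq_ext)) {
    for (nu in .NUCLEI) {
      rcv <- random_coil_shift(rc, seq_ext, j, nu)
      if (is.na(rcv)) next
      if (j == roi_ext) {
        tab[j, nu] <- unname(shifts[nu])
      } else if (abs(j - roi_ext) <= 2L && nu %in% names(r_i)) {
        f <- rescale_factor(roi_type, seq_ext[j], nu, cog)
        tab[j, nu] <- rcv + f * r_i[nu]
      } else {
        tab[j, nu] <- rcv
      }
    }
  }
  structure(tab, roi_index = roi_ext, sequence = paste(seq_ext, collapse = ""),
            class = c("predictor_input_table", "data.frame"))
}

#' Write a predictor input shift table
#'
#' Writes the table in the TALOS-style whitespace format (`DATA SEQUENCE`,
#' `VARS RESID RESNAME ATOMNAME SHIFT`) consumed by common shift-based
#' dihedral predictors.  Residues lacking a nucleus (glycine CB) produce no
#' atom line.  Formatting is deterministic.
#'
#' @param table A [translate_to_neighbors()] table.
#' @param path Output file.
#' @param dialect Output dialect; only `"talos"` is currently supported.
#' @return `path`, invisibly.
#' @export
write_predictor_input <- function(table, path, dialect = "talos") {
  stopifnot(inherits(table, "predictor_input_table"))
  if (!identical(dialect, "talos"))
    stop("write_predictor_input: unsupported dialect '", dialect, "'")
  atom_names <- c(H = "HN", N = "N", CA = "CA", CB = "CB")
  lines <- c(
    sprintf("REMARK predictor input (ROI residue %d)", attr(table, "roi_index")),
    "DATA FIRST_RESID 1",
    paste("DATA SEQUENCE", attr(table, "sequence")),
    "VARS RESID RESNAME ATOMNAME SHIFT",
    "FORMAT %4d %1s %4s %8.3f")
  for (j in seq_len(nrow(table))) {
    for (nu in .NUCLEI) {
      v <- table[j, nu]
      if (is.na(v)) next
      lines <- c(lines, sprintf("%4d %1s %4s %8.3f",
                                table$resid[j], table$residue[j],
                                atom_names[nu], v))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a predictor input shift table
#'
#' @param path File written by [write_predictor_input()].
#' @return A `predictor_input_table`.
#' @export
read_predictor_input <- function(path) {
  lines <- readLines(path)
  seq_line <- grep("^DATA SEQUENCE", lines, value = TRUE)
  if (length(seq_line) != 1L)
    stop("read_predictor_input: missing DATA SEQUENCE line")
  seqv <- .as_residues(sub("^DATA SEQUENCE +", "", seq_line))
  roi <- suppressWarnings(
    as.integer(sub(".*ROI residue +([0-9]+).*", "\\1",
                   grep("ROI residue", lines, value = TRUE)[1])))
  dat <- lines[grepl("^ *[0-9]+ +[A-Z] +[A-Z]+ +[-0-9.]+ *$", lines)]
  if (length(dat) == 0L) stop("read_predictor_input: no shift rows found")
  fields <- do.call(rbind, strsplit(trimws(dat), " +"))
  atom_to_nuc <- c(HN = "H", H = "H", N = "N", CA = "CA", CB = "CB")
  tab <- data.frame(resid = seq_along(seqv), residue = seqv,
                    H = NA_real_, N = NA_real_, CA = NA_real_, CB = NA_real_)
  for (k in seq_len(nrow(fields))) {
    nu <- atom_to_nuc[fields[k, 3]]
    if (is.na(nu)) next
    tab[as.integer(fields[k, 1]), nu] <- as.numeric(fields[k, 4])
  }
  structure(tab, roi_index = roi, sequence = paste(seqv, collapse = ""),
            class = c("predictor_input_table", "data.frame"))
}
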