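# Random-coil and conformation-specific centre-of-gravity shift tables.
#
# Both tables are plain CSV with a documented schema so users can drop in
# their preferred reference set (e.g. the neighbour-corrected random-coil
# shifts of Tamiola and co-workers, or database-derived centres of
# gravity).  The copies shipped under inst/extdata are approximate
# synthetic stand-ins (see their provenance headers).

#' Load a neighbour-corrected random-coil shift table
#'
#' Schema: comment lines start with `#`; columns `kind`, `residue`,
#' `nucleus`, `value`.  `kind = "base"` rows give the random-coil shift of
#' `residue` for `nucleus`; `kind = "prev"` / `"next"` rows give the
#' additive ppm correction a flanking residue of type `residue` exerts on
#' its right / left neighbour.  A missing base row means the residue lacks
#' that nucleus (glycine CB); a missing correction row means zero
#' correction.
#'
#' @param path CSV file; default is the synthetic table shipped with the
#'   package.
#' @return An object of class `random_coil_table`.
#' @export
load_random_coil <- function(path = NULL) {
  path <- path %||% system.file("extdata", "synthetic_random_coil.csv",
                                package = "peakrama", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("kind", "residue", "nucleus", "value")
  if (!all(need %in% names(df)))
    stop("load_random_coil: CSV must have columns ", paste(need, collapse = ", "))
  if (!all(df$kind %in% c("base", "prev", "next")))
    stop("load_random_coil: 'kind' must be base, prev or next")
  tab <- lapply(c(base = "base", prev = "prev", nxt = "next"), function(k) {
    sub <- df[df$kind == k, ]
    stats::setNames(sub$value, paste(sub$residue, sub$nucleus, sep = "."))
  })
  structure(tab, class = "random_coil_table")
}

#' Load conformation-specific centre-of-gravity shifts
#'
#' Schema: comment lines start with `#`; columns `residue`, `nucleus`,
#' `helix`, `extended` — the centre of gravity (ppm) of the shift
#' distribution of that residue type and nucleus within helical and
#' extended conformations.  Rows are simply absent for nuclei a residue
#' type lacks (glycine CB).
#'
#' @param path CSV file; default is the synthetic table shipped with the
#'   package.
#' @return An object of class `cog_table`.
#' @export
load_cog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "synthetic_cog.csv",
                                package = "peakrama", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("residue", "nucleus", "helix", "extended")
  if (!all(need %in% names(df)))
    stop("load_cog: CSV must have columns ", paste(need, collapse = ", "))
  key <- paste(df$residue, df$nucleus, sep = ".")
  structure(list(helix = stats::setNames(df$helix, key),
                 extended = stats::setNames(df$extended, key)),
            class = "cog_table")
}

#' Neighbour-corrected random-coil shift of one residue in context
#'
#' @param rc A [load_random_coil()] table.
#' @param sequence One-letter residue string (or character vector).
#' @param index Position of the residue within `sequence`.
#' @param nucleus One of H, N, CA, CB.
#' @return Shift in ppm, or `NA` if the residue lacks the nucleus.
#' @export
random_coil_shift <- function(rc, sequence, index, nucleus) {
  stopifnot(inherits(rc, "random_coil_table"))
  seqv <- .as_residues(sequence)
  if (index < 1L || index > length(seqv))
    stop("random_coil_shift: 'index' outside the sequence")
  nucleus <- match.arg(nucleus, .NUCLEI)
  res <- seqv[index]
  base <- rc$base[paste(res, nucleus, sep = ".")]
  if (res == "G" && nucleus == "CB") return(NA_real_)
  if (is.na(base))
    stop("random_coil_shift: no random-coil entry for residue '", res,
         "' nucleus ", nucleus)
  corr <- 0
  if (index > 1L) {
    d <- rc$prev[paste(seqv[index - 1L], nucleus, sep = ".")]
    if (!is.na(d)) corr <- corr + d
  }
  if (index < length(seqv)) {
    d <- rc$nxt[paste(seqv[index + 1L], nucleus, sep = ".")]
    if (!is.na(d)) corr <- corr + d
  }
  unname(base + corr)
}

.as_residues <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  toupper(sequence)
}
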