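# Reading and writing processed 4D spectrum regions.
#
# Two on-disk forms are supported:
#   * a self-describing portable JSON container (axes metadata + flattened
#     column-major intensities), used by the synthetic module and tests;
#   * single-file NMRPipe streams (512-float header + float32 data) holding
#     a fully transformed, real-valued 4D hypercube.

#' Write a peak region to the portable JSON hypercube container
#'
#' @param peak A [peak_region()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hypercube <- function(peak, path) {
  stopifnot(inherits(peak, "peak_region"))
  obj <- list(
    format = "peakrama-hypercube",
    version = 1L,
    axes = unname(lapply(peak$axes, function(a)
      list(nucleus = a$nucleus, n_points = a$n_points,
           ppm_start = a$ppm_start, ppm_step = a$ppm_step))),
    intensity = as.vector(peak$intensity))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a portable JSON hypercube container
#'
#' @param path File written by [write_hypercube()].
#' @return A [peak_region()].
#' @export
read_hypercube <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("read_hypercube: not a readable JSON container: ",
                         conditionMessage(e)))
  if (!identical(obj$format, "peakrama-hypercube"))
    stop("read_hypercube: file is not a peakrama hypercube container")
  axes <- if (is.data.frame(obj$axes)) {
    lapply(seq_len(nrow(obj$axes)), function(i)
      spectral_axis(obj$axes$nucleus[i], obj$axes$n_points[i],
                    obj$axes$ppm_start[i], obj$axes$ppm_step[i]))
  } else {
    lapply(obj$axes, function(a)
      spectral_axis(a$nucleus, a$n_points, a$ppm_start, a$ppm_step))
  }
  if (length(axes) != 4L)
    stop("read_hypercube: expected 4 axes, found ", length(axes))
  arr <- array(obj$intensity, dim = unname(vapply(axes, `[[`, 1L, "n_points")))
  labels <- unname(vapply(axes, `[[`, "", "nucleus"))
  if (!setequal(labels, .NUCLEI))
    stop("read_hypercube: axes must identify H, N, CA, CB")
  perm <- match(.NUCLEI, labels)
  peak_region(aperm(arr, perm), axes[perm])
}

# NMRPipe 512-float header word offsets (0-based), standard fdatap layout.
.PIPE <- list(
  FDMAGIC = 0L, FDFLTFORMAT = 1L, FDFLTORDER = 2L, FDDIMCOUNT = 9L,
  FDDIMORDER = 24L:27L, FDPIPEFLAG = 57L, FDSIZE = 99L, FDSPECNUM = 219L,
  FDQUADFLAG = 106L, FDTRANSPOSED = 221L, FDFILECOUNT = 442L,
  # per spectral dimension: OBS (MHz), SW (Hz), ORIG (Hz), SIZE, FTFLAG, LABEL
  F2 = c(OBS = 119L, SW = 100L, ORIG = 101L, FT = 220L, LAB = 16L),
  F1 = c(OBS = 218L, SW = 229L, ORIG = 249L, FT = 222L, LAB = 18L),
  F3 = c(OBS = 10L,  SW = 11L,  ORIG = 12L,  FT = 13L,  LAB = 20L, SIZE = 15L),
  F4 = c(OBS = 28L,  SW = 29L,  ORIG = 30L,  FT = 31L,  LAB = 22L, SIZE = 32L))

# default spectrometer frequencies (MHz at 18.8 T) used when writing
.OBS_DEFAULT <- c(H = 800.13, N = 81.08, CA = 201.19, CB = 201.19)

.pipe_label <- function(header_raw, word) {
  b <- header_raw[(word * 4 + 1):(word * 4 + 8)]
  lab <- rawToChar(b[b != as.raw(0)])
  trimws(lab)
}

#' Read a single-file NMRPipe 4D spectrum
#'
#' Minimal reader for fully processed, real-valued 4D data stored as a
#' single NMRPipe stream (512-float header followed by float32 intensities).
#' Axis calibration is taken from the per-dimension observe frequency,
#' sweep width and origin; point `i` of an `N`-point dimension resonates at
#' `(ORIG + SW * (N - i) / N) / OBS` ppm.
#'
#' @param path NMRPipe file.
#' @param axis_order Optional character vector of four nucleus labels
#'   giving the identity of the stored dimensions in storage order
#'   (fastest-varying first); defaults to the labels in the file header.
#' @return A [peak_region()] with axes permuted to (H, N, CA, CB).
#' @export
read_nmrpipe <- function(path, axis_order = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hraw <- readBin(con, "raw", n = 2048L)
  if (length(hraw) < 2048L) stop("read_nmrpipe: truncated header")
  hdr <- readBin(hraw, "numeric", n = 512L, size = 4L, endian = "little")
  swapped <- FALSE
  if (abs(hdr[.PIPE$FDFLTORDER + 1] - 2.345) > 1e-4) {
    hdr <- readBin(hraw, "numeric", n = 512L, size = 4L, endian = "big")
    swapped <- TRUE
    if (abs(hdr[.PIPE$FDFLTORDER + 1] - 2.345) > 1e-4)
      stop("read_nmrpipe: not an NMRPipe stream (bad float-order sentinel)")
  }
  ndim <- as.integer(round(hdr[.PIPE$FDDIMCOUNT + 1]))
  if (ndim != 4L)
    stop("read_nmrpipe: expected a 4-dimensional spectrum, found ", ndim,
         " dimensions")
  sizes <- c(as.integer(round(hdr[.PIPE$FDSIZE + 1])),
             as.integer(round(hdr[.PIPE$FDSPECNUM + 1])),
             as.integer(round(hdr[.PIPE$F3["SIZE"] + 1])),
             as.integer(round(hdr[.PIPE$F4["SIZE"] + 1])))
  ndata <- prod(sizes)
  dat <- readBin(con, "numeric", n = ndata, size = 4L,
                 endian = if (swapped) "big" else "little")
  if (length(dat) != ndata)
    stop("read_nmrpipe: data block shorter than header sizes imply")
  # storage order: fastest axis is F-dim FDDIMORDER[1], then [2], [3], [4]
  dimorder <- as.integer(round(hdr[.PIPE$FDDIMORDER + 1]))
  fslots <- list(.PIPE$F1, .PIPE$F2, .PIPE$F3, .PIPE$F4)
  stored <- lapply(seq_len(4L), function(d) {
    f <- fslots[[dimorder[d]]]
    obs <- hdr[f["OBS"] + 1]; sw <- hdr[f["SW"] + 1]; orig <- hdr[f["ORIG"] + 1]
    if (!is.finite(obs) || obs == 0)
      stop("read_nmrpipe: missing observe-frequency calibration for stored dim ", d)
    n <- sizes[d]
    list(label = .pipe_label(hraw, f["LAB"]),
         ppm_start = (orig + sw * (n - 1) / n) / obs,
         ppm_step = -sw / (n * obs), n = n)
  })
  labels <- toupper(vapply(stored, `[[`, "", "label"))
  if (!is.null(axis_order)) {
    if (length(axis_order) != 4L)
      stop("read_nmrpipe: 'axis_order' must name all four stored dimensions")
    labels <- toupper(axis_order)
  }
  if (!setequal(labels, .NUCLEI))
    stop("read_nmrpipe: stored axis labels (", paste(labels, collapse = ", "),
         ") do not identify H, N, CA, CB; pass 'axis_order'")
  arr <- array(dat, dim = sizes)
  perm <- match(.NUCLEI, labels)
  arr <- aperm(arr, perm)
  axes <- lapply(seq_len(4L), function(k) {
    s <- stored[[perm[k]]]
    spectral_axis(.NUCLEI[k], s$n, s$ppm_start, s$ppm_step)
  })
  peak_region(arr, axes)
}

#' Write a peak region as a single-file NMRPipe 4D stream
#'
#' Counterpart of [read_nmrpipe()]; intended for interchange with
#' NMRPipe-based tooling and for round-trip testing.
#'
#' @param peak A [peak_region()].
#' @param path Output file.
#' @param obs_mhz Named observe frequencies (MHz) per nucleus used to
#'   convert the ppm calibration to the Hz-based header fields.
#' @return `path`, invisibly.
#' @export
write_nmrpipe <- function(peak, path, obs_mhz = .OBS_DEFAULT) {
  stopifnot(inherits(peak, "peak_region"))
  hdr <- numeric(512L)
  hdr[.PIPE$FDFLTFORMAT + 1] <- readBin(as.raw(c(0xef, 0xee, 0xee, 0xee)),
                                        "numeric", size = 4L, endian = "little")
  hdr[.PIPE$FDFLTORDER + 1] <- 2.345
  hdr[.PIPE$FDDIMCOUNT + 1] <- 4
  hdr[.PIPE$FDPIPEFLAG + 1] <- 0
  hdr[.PIPE$FDFILECOUNT + 1] <- 1
  hdr[.PIPE$FDQUADFLAG + 1] <- 1      # real data
  hdr[.PIPE$FDDIMORDER + 1] <- c(2, 1, 3, 4)  # storage order H, N, CA, CB
  fslots <- list(.PIPE$F2, .PIPE$F1, .PIPE$F3, .PIPE$F4)
  labs <- raw(0)
  hraw_labels <- list()
  for (d in seq_len(4L)) {
    ax <- peak$axes[[d]]
    f <- fslots[[d]]
    obs <- obs_mhz[[ax$nucleus]]
    n <- ax$n_points
    sw <- -ax$ppm_step * n * obs
    orig <- (ax$ppm_start + (n - 1) * ax$ppm_step) * obs
    hdr[f["OBS"] + 1] <- obs
    hdr[f["SW"] + 1] <- sw
    hdr[f["ORIG"] + 1] <- orig
    hdr[f["FT"] + 1] <- 1
    hraw_labels[[d]] <- list(word = f["LAB"], label = ax$nucleus)
  }
  hdr[.PIPE$FDSIZE + 1] <- dim(peak$intensity)[1]
  hdr[.PIPE$FDSPECNUM + 1] <- dim(peak$intensity)[2]
  hdr[.PIPE$F3["SIZE"] + 1] <- dim(peak$intensity)[3]
  hdr[.PIPE$F4["SIZE"] + 1] <- dim(peak$intensity)[4]
  hbytes <- writeBin(hdr, raw(), size = 4L, endian = "little")
  for (hl in hraw_labels) {
    b <- charToRaw(sprintf("%-8s", substr(hl$label, 1, 8)))
    b[b == charToRaw(" ")] <- as.raw(0)
    hbytes[(hl$word * 4 + 1):(hl$word * 4 + 8)] <- b[1:8]
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hbytes, con)
  writeBin(as.vector(peak$intensity), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a processed 4D spectrum region
#'
#' Dispatches on the on-disk format: NMRPipe streams are recognised by
#' their header sentinel, everything else is treated as the portable JSON
#' hypercube container.  Axes are always returned in (H, N, CA, CB) order.
#'
#' @param path Spectrum file.
#' @param axis_order Optional nucleus labels of the stored dimensions
#'   (passed to [read_nmrpipe()]); ignored for the JSON container, which is
#'   self-describing.
#' @return A [peak_region()].
#' @export
read_spectrum <- function(path, axis_order = NULL) {
  if (!file.exists(path)) stop("read_spectrum: no such file: ", path)
  head4 <- readBin(path, "raw", n = 8L)
  is_pipe <- length(head4) == 8L && all(head4[1:4] == as.raw(0))
  if (is_pipe) read_nmrpipe(path, axis_order = axis_order)
  else read_hypercube(path)
}
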