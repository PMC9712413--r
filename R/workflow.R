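# End-to-end orchestration of the two reconstruction branches.

#' Assemble and validate a run configuration
#'
#' Collects every tunable of both branches with their defaults.  Paths are
#' checked at validation time; either a path or an in-memory object can be
#' supplied for the peak and the database at run time.
#'
#' @param peak_path Spectrum file for [read_spectrum()] (optional if the
#'   peak object is passed to the branch runners directly).
#' @param database_path Database CSV for [load_database()] (database
#'   branch).
#' @param branch `"prediction"`, `"database"`, or `"both"`.
#' @param spacings,threshold_fraction Passed to [sample_grid()].
#' @param bandwidths,density_scope,min_entries Passed to
#'   [reconstruct_from_database()].
#' @param sequence,roi_index,pad,n_pad Sequence context for
#'   [translate_to_neighbors()].
#' @param predictor `"mock"` (closed-loop, in-process) or `"files"`
#'   (read per-grid-point grid files from `predictor_dir`).
#' @param predictor_dir Directory holding `point_<i>.rama` grid files when
#'   `predictor = "files"`.
#' @param on_missing `"error"` or `"skip"` for grid points without a
#'   predictor output file.
#' @param residue_type Database residue type.
#' @param phi_convention,flatness_convention Passed to [score_all()].
#' @param reference Excess-entropy reference: `"confined_helix"` (mock
#'   prediction at the helix centroid), a numeric entropy, or `NULL`.
#' @param seed Integer seed recorded in the provenance and used for any
#'   stochastic stage.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(peak_path = NULL, database_path = NULL,
                       branch = c("both", "prediction", "database"),
                       spacings = c(H = 0.4, N = 1.5, CA = 1.0, CB = 1.5),
                       threshold_fraction = 0.2,
                       bandwidths = c(H = 0.4, N = 1.5, CA = 1.0, CB = 1.5),
                       density_scope = "envelope", min_entries = 20L,
                       sequence = "GGAGG", roi_index = 3L,
                       pad = "G", n_pad = 1L,
                       predictor = c("mock", "files"), predictor_dir = NULL,
                       on_missing = c("error", "skip"),
                       residue_type = "A",
                       phi_convention = "raw",
                       flatness_convention = "complement",
                       reference = "confined_helix", seed = 1L) {
  branch <- match.arg(branch)
  predictor <- match.arg(predictor)
  on_missing <- match.arg(on_missing)
  if (!is.null(peak_path) && !file.exists(peak_path))
    stop("run_config: 'peak_path' does not exist: ", peak_path)
  if (!is.null(database_path) && !file.exists(database_path))
    stop("run_config: 'database_path' does not exist: ", database_path)
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("run_config: 'threshold_fraction' must lie in (0, 1)")
  if (predictor == "files" &&
      (is.null(predictor_dir) || !dir.exists(predictor_dir)))
    stop("run_config: 'predictor_dir' must exist when predictor = 'files'")
  structure(list(
    peak_path = peak_path, database_path = database_path, branch = branch,
    spacings = spacings, threshold_fraction = threshold_fraction,
    bandwidths = bandwidths, density_scope = density_scope,
    min_entries = as.integer(min_entries), sequence = sequence,
    roi_index = as.integer(roi_index), pad = pad, n_pad = as.integer(n_pad),
    predictor = predictor, predictor_dir = predictor_dir,
    on_missing = on_missing, residue_type = residue_type,
    phi_convention = phi_convention,
    flatness_convention = flatness_convention,
    reference = reference, seed = as.integer(seed)), class = "run_config")
}

.provenance <- function(config, extra = list()) {
  c(list(package = "peakrama",
         version = as.character(utils::packageVersion("peakrama")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = config$seed,
         config = config[setdiff(names(config), c("peak_path",
                                                  "database_path"))],
         peak_path = config$peak_path %||% NA_character_,
         database_path = config$database_path %||% NA_character_),
    extra)
}

.reference_map <- function(config, model) {
  ref <- config$reference
  if (is.null(ref)) return(NULL)
  if (is.numeric(ref)) return(ref)
  if (identical(ref, "confined_helix"))
    return(fold_map(mock_predictor(model$classes$helix$shifts, model)))
  stop("unknown excess-entropy reference: ", ref)
}

#' Write predictor inputs for every grid point
#'
#' Materializes one shift table per grid point (for an out-of-process
#' shift-based predictor) plus a manifest CSV linking point index, shifts
#' and intensity to file names.  The predictor itself is never executed:
#' its per-point grid outputs are read back as `point_<i>.rama` files by
#' [run_prediction_branch()] with `predictor = "files"`.
#'
#' @param grid Output of [sample_grid()].
#' @param config A [run_config()] (sequence context and tables).
#' @param dir Output directory (created if needed).
#' @param rc,cog Shift tables (defaults: the tables shipped with the
#'   package).
#' @return Path of the manifest CSV, invisibly.
#' @export
prepare_predictor_inputs <- function(grid, config, dir,
                                     rc = load_random_coil(),
                                     cog = load_cog()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tab <- translate_to_neighbors(grid[i, .NUCLEI], config$sequence,
                                  config$roi_index, rc, cog,
                                  pad = config$pad, n_pad = config$n_pad)
    files[i] <- file.path(dir, sprintf("point_%d.tab", i))
    write_predictor_input(tab, files[i])
  }
  manifest <- cbind(point = seq_len(nrow(grid)), grid,
                    input_file = basename(files),
                    output_file = sprintf("point_%d.rama", seq_len(nrow(grid))))
  mpath <- file.path(dir, "grid_manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Run the prediction-based branch
#'
#' Samples the peak on the chemical-shift lattice, obtains one phi/psi
#' probability map per grid point (mock predictor in-process, or
#' per-point grid files produced by an external predictor), aggregates
#' them weighted by grid-point intensity, folds the result, and scores it.
#'
#' @param config A [run_config()].
#' @param peak Optional [peak_region()] (otherwise read from
#'   `config$peak_path`).
#' @param model [forward_model()] used by the mock predictor and the
#'   confined-helix reference.
#' @return List with `map` (folded [rama_map()]), `scores`
#'   ([score_all()]), `grid` (the manifest of grid points with shifts and
#'   intensities), `n_points`, and `provenance`.
#' @export
run_prediction_branch <- function(config, peak = NULL,
                                  model = forward_model()) {
  stopifnot(inherits(config, "run_config"))
  peak <- peak %||% read_spectrum(config$peak_path %||%
                                    stop("run_prediction_branch: no peak"))
  grid <- sample_grid(peak, spacings = config$spacings,
                      threshold_fraction = config$threshold_fraction)
  if (nrow(grid) == 0L)
    stop("run_prediction_branch: empty grid selection")
  if (config$predictor == "mock") {
    maps <- lapply(seq_len(nrow(grid)), function(i)
      mock_predictor(grid[i, .NUCLEI], model))
    weights <- grid$intensity
    used <- seq_len(nrow(grid))
  } else {
    files <- file.path(config$predictor_dir,
                       sprintf("point_%d.rama", seq_len(nrow(grid))))
    present <- file.exists(files)
    if (!all(present)) {
      msg <- paste0(sum(!present), " grid point(s) lack predictor output (",
                    paste(utils::head(basename(files[!present]), 5L),
                          collapse = ", "), if (sum(!present) > 5L) ", ...",
                    ")")
      if (config$on_missing == "error") stop("run_prediction_branch: ", msg)
      warning("run_prediction_branch: skipping ", msg)
    }
    used <- which(present)
    if (length(used) == 0L)
      stop("run_prediction_branch: no predictor outputs found in ",
           config$predictor_dir)
    maps <- lapply(files[used], parse_ann_output)
    weights <- grid$intensity[used]
  }
  folded <- fold_map(aggregate_maps(maps, weights))
  scores <- score_all(folded, reference = .reference_map(config, model),
                      phi_convention = config$phi_convention,
                      flatness_convention = config$flatness_convention)
  grid$used <- seq_len(nrow(grid)) %in% used
  list(map = folded, scores = scores, grid = grid, n_points = length(used),
       provenance = .provenance(config, list(branch = "prediction",
                                             n_grid_points = length(used))))
}

#' Run the database-matching branch
#'
#' Loads and quality-filters the database, selects entries inside the
#' peak envelope, weights them by intensity over local entry density,
#' bins and folds the map, and scores it.
#'
#' @param config A [run_config()].
#' @param peak Optional [peak_region()] (otherwise read from
#'   `config$peak_path`).
#' @param entries Optional database data frame (otherwise loaded from
#'   `config$database_path`).
#' @param model [forward_model()] for the confined-helix reference.
#' @return List with `map`, `scores`, `selection` (weighted entries),
#'   `n_selected`, `low_confidence`, and `provenance`.
#' @export
run_database_branch <- function(config, peak = NULL, entries = NULL,
                                model = forward_model()) {
  stopifnot(inherits(config, "run_config"))
  peak <- peak %||% read_spectrum(config$peak_path %||%
                                    stop("run_database_branch: no peak"))
  entries <- entries %||% load_database(
    config$database_path %||% stop("run_database_branch: no database"),
    residue_type = config$residue_type)
  rec <- reconstruct_from_database(entries, peak,
                                   threshold_fraction = config$threshold_fraction,
                                   bandwidths = config$bandwidths,
                                   density_scope = config$density_scope,
                                   min_entries = config$min_entries)
  scores <- score_all(rec$map, reference = .reference_map(config, model),
                      phi_convention = config$phi_convention,
                      flatness_convention = config$flatness_convention)
  if (rec$low_confidence)
    warning("run_database_branch: only ", rec$n_selected,
            " entries in the envelope; scores are low-confidence")
  list(map = rec$map, scores = scores, selection = rec$selection,
       n_selected = rec$n_selected, low_confidence = rec$low_confidence,
       provenance = .provenance(config, list(branch = "database",
                                             n_selected = rec$n_selected)))
}

#' Run both branches and tabulate their scores side by side
#'
#' @param config A [run_config()] with `branch = "both"`.
#' @param peak,entries,model As in the individual branch runners.
#' @return List with `prediction`, `database`, and `comparison` (a
#'   two-row score data frame).
#' @export
run_both_branches <- function(config, peak = NULL, entries = NULL,
                              model = forward_model()) {
  pred <- run_prediction_branch(config, peak = peak, model = model)
  db <- run_database_branch(config, peak = peak, entries = entries,
                            model = model)
  comparison <- rbind(
    cbind(branch = "prediction", as.data.frame(pred$scores)),
    cbind(branch = "database", as.data.frame(db$scores)))
  list(prediction = pred, database = db, comparison = comparison)
}
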