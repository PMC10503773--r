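#' Write and read field images as 16-bit grayscale TIFF
#'
#' One file per channel, named `{plate}_{well}_f{field}_{dna|foci}.tif`.
#'
#' @param field a [field_image()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the two file paths written.
#' @export
write_field_tiff <- function(field, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- sprintf("%s_%s_f%d", field$plate_id, field$well_id, field$field_index)
  paths <- file.path(dir, paste0(stem, "_", c("dna", "foci"), ".tif"))
  tiff::writeTIFF(t(field$dna) / 65535, paths[1L], bits.per.sample = 16L)
  tiff::writeTIFF(t(field$foci) / 65535, paths[2L], bits.per.sample = 16L)
  invisible(paths)
}

#' @rdname write_field_tiff
#' @param plate_id,well_id,field_index,experiment_index identifiers of the
#'   field to read back.
#' @export
read_field_tiff <- function(dir, plate_id, well_id, field_index,
                            experiment_index = 1L) {
  stem <- sprintf("%s_%s_f%d", plate_id, well_id, field_index)
  rd <- function(ch) {
    m <- tiff::readTIFF(file.path(dir, paste0(stem, "_", ch, ".tif")))
    matrix(as.integer(round(t(m) * 65535)), ncol(m), nrow(m))
  }
  field_image(rd("dna"), rd("foci"), plate_id, well_id, field_index,
              experiment_index)
}

#' Save and load generator settings as a YAML key-value file
#'
#' The seed used for a simulation can be recorded alongside the parameters so
#' a rendered data set is fully reproducible from its metadata.
#'
#' @param params a [sim_params()] object.
#' @param path file path.
#' @param seed optional seed to record.
#' @export
save_sim_params <- function(params, path, seed = NULL) {
  validate_sim_params(params)
  x <- unclass(params)
  x$mn_count_given_positive <- as.list(params$mn_count_given_positive)
  if (!is.null(seed)) x$seed <- as.integer(seed)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_sim_params
#' @return `load_sim_params()` returns a list with elements `params` (a
#'   [sim_params()]) and `seed` (or `NULL` when none was recorded).
#' @export
load_sim_params <- function(path) {
  x <- yaml::read_yaml(path)
  seed <- x$seed
  x$seed <- NULL
  x$mn_count_given_positive <- unlist(x$mn_count_given_positive)
  p <- do.call(sim_params, x)
  list(params = p, seed = seed)
}

#' Write a simulated field and its ground truth to disk
#'
#' TIFF channels via [write_field_tiff()] plus a CSV of the truth table
#' (`{plate}_{well}_f{field}_truth.csv`).
#'
#' @param sim_field result of [simulate_field()] or [simulate_mn_field()].
#' @param dir output directory.
#' @export
write_sim_field <- function(sim_field, dir = ".") {
  if (is.null(sim_field$field))
    stop("field was generated with render = FALSE; nothing to write")
  paths <- write_field_tiff(sim_field$field, dir)
  f <- sim_field$field
  truth_path <- file.path(dir, sprintf("%s_%s_f%d_truth.csv",
                                       f$plate_id, f$well_id, f$field_index))
  utils::write.csv(sim_field$truth, truth_path, row.names = FALSE)
  invisible(c(paths, truth_path))
}
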