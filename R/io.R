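#' Readers and writers
#'
#' All inputs and outputs travel as plain CSV (long or wide gridded series,
#' tidy metrics, weighted edge lists, one-row-per-species pools) plus a JSON
#' run manifest. Cell ids are stable integers, row-major from the grid's
#' northwest corner; row/column positions are carried as metadata columns.
#' Every file written by the package is re-readable by its own readers.
#'
#' @name io
NULL

#' Write a gridded series as long CSV
#'
#' Columns: `cell_id`, `row`, `col`, `year`, `month` (monthly series only),
#' `value`.
#'
#' @param values cells x time matrix.
#' @param path output file.
#' @param nrow,ncol grid dimensions (cells are row-major).
#' @param freq `"monthly"` or `"yearly"`.
#' @export
write_grid_series <- function(values, path, nrow, ncol,
                              freq = c("monthly", "yearly")) {
  freq <- match.arg(freq)
  n_cells <- nrow * ncol
  stopifnot(base::nrow(values) == n_cells)
  n_t <- base::ncol(values)
  cell_id <- rep(seq_len(n_cells), times = n_t)
  df <- data.frame(
    cell_id = cell_id,
    row = rep(rep(seq_len(nrow), each = ncol), times = n_t),
    col = rep(rep(seq_len(ncol), times = nrow), times = n_t))
  if (freq == "monthly") {
    t_idx <- rep(seq_len(n_t), each = n_cells)
    df$year <- (t_idx - 1) %/% 12 + 1
    df$month <- (t_idx - 1) %% 12 + 1
  } else {
    df$year <- rep(seq_len(n_t), each = n_cells)
  }
  df$value <- as.vector(values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a gridded series
#'
#' Accepts the long CSV layout written by [write_grid_series()] (monthly:
#' `cell_id, row, col, year, month, value`; yearly: the same without
#' `month`) or a wide layout (`cell_id, row, col` followed by one column
#' per time step). The series must be complete: a missing cell/time
#' combination is an error naming the gap.
#'
#' @param path CSV file.
#' @return list with `values` (cells x time matrix), `nrow`, `ncol`, `freq`.
#' @export
read_grid_series <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cell_id", "row", "col")
  if (!all(need %in% names(df)))
    stop("grid series must have columns cell_id, row, col")
  grid_nrow <- max(df$row)
  grid_ncol <- max(df$col)
  n_cells <- grid_nrow * grid_ncol

  if (!("value" %in% names(df))) {
    # wide layout: remaining columns are time steps
    tcols <- setdiff(names(df), need)
    df <- df[order(df$cell_id), ]
    if (!identical(as.integer(df$cell_id), seq_len(n_cells)))
      stop("wide grid series: cell_id must cover 1..", n_cells)
    values <- as.matrix(df[, tcols, drop = FALSE])
    dimnames(values) <- NULL
    return(list(values = values, nrow = grid_nrow, ncol = grid_ncol,
                freq = if (length(tcols) %% 12 == 0) "monthly" else "yearly"))
  }

  monthly <- "month" %in% names(df)
  t_idx <- if (monthly) (df$year - 1) * 12 + df$month else df$year
  n_t <- max(t_idx)
  expected <- n_cells * n_t
  key <- (t_idx - 1) * n_cells + df$cell_id
  if (anyDuplicated(key))
    stop("duplicate cell/time entries at data rows: ",
         paste(utils::head(which(duplicated(key))), collapse = ", "))
  if (length(key) < expected) {
    missing_key <- setdiff(seq_len(expected), key)[1]
    miss_t <- (missing_key - 1) %/% n_cells + 1
    miss_cell <- (missing_key - 1) %% n_cells + 1
    stop("incomplete grid series: missing cell ", miss_cell,
         if (monthly)
           paste0(", year ", (miss_t - 1) %/% 12 + 1,
                  ", month ", (miss_t - 1) %% 12 + 1)
         else paste0(", year ", miss_t))
  }
  values <- matrix(NA_real_, n_cells, n_t)
  values[cbind(df$cell_id, t_idx)] <- df$value
  list(values = values, nrow = grid_nrow, ncol = grid_ncol,
       freq = if (monthly) "monthly" else "yearly")
}

#' Write climate / land-use fixtures to a directory
#'
#' @param climate a `climate_grid` (or NULL).
#' @param landuse a `landuse_grid` (or NULL).
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_world_inputs <- function(climate = NULL, landuse = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(climate)) {
    write_grid_series(climate$T, file.path(dir, "temperature.csv"),
                      climate$nrow, climate$ncol, "monthly")
    write_grid_series(climate$P, file.path(dir, "precipitation.csv"),
                      climate$nrow, climate$ncol, "monthly")
  }
  if (!is.null(landuse)) {
    write_grid_series(landuse$u, file.path(dir, "landuse.csv"),
                      landuse$nrow, landuse$ncol, "yearly")
  }
  invisible(dir)
}

#' Read climate fixtures back from a directory
#'
#' @param dir directory written by [write_world_inputs()].
#' @param calib_years calibration-window length to record on the object.
#' @return a `climate_grid`.
#' @export
read_climate <- function(dir, calib_years = 5) {
  Tm <- read_grid_series(file.path(dir, "temperature.csv"))
  Pm <- read_grid_series(file.path(dir, "precipitation.csv"))
  stopifnot(Tm$nrow == Pm$nrow, Tm$ncol == Pm$ncol)
  structure(list(T = Tm$values, P = Pm$values, nrow = Tm$nrow,
                 ncol = Tm$ncol, years = ncol(Tm$values) / 12,
                 calib_years = calib_years, stationary = NA),
            class = "climate_grid")
}

#' Read a land-use series back from a directory
#'
#' @param dir directory written by [write_world_inputs()].
#' @return a `landuse_grid`.
#' @export
read_landuse <- function(dir) {
  u <- read_grid_series(file.path(dir, "landuse.csv"))
  structure(list(u = u$values, nrow = u$nrow, ncol = u$ncol,
                 years = ncol(u$values)),
            class = "landuse_grid")
}

#' Serialize a species pool to CSV (niche parameters inline)
#'
#' @param pool a `species_pool`.
#' @param path output file.
#' @export
write_species_pool <- function(pool, path) {
  utils::write.csv(as.data.frame(pool), path, row.names = FALSE)
  invisible(path)
}

#' Read a species pool written by [write_species_pool()]
#'
#' @param path CSV file.
#' @return a `species_pool`.
#' @export
read_species_pool <- function(path) {
  pool <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(pool) <- c("species_pool", "data.frame")
  pool
}

#' Write an experiment bundle to a directory
#'
#' Produces `metrics.csv`, `summary.csv`, `effect.csv` (when both arms ran)
#' and `manifest.json` carrying the master seed, per-replicate seeds and the
#' full configuration. Deterministic: rerunning the same experiment writes
#' byte-identical files.
#'
#' @param bundle a `coexsim_experiment`.
#' @param outdir output directory (created if needed).
#' @return invisible path of the manifest.
#' @export
write_outputs <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$metrics))
    utils::write.csv(bundle$metrics, file.path(outdir, "metrics.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$summary))
    utils::write.csv(bundle$summary, file.path(outdir, "summary.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$effect))
    utils::write.csv(bundle$effect, file.path(outdir, "effect.csv"),
                     row.names = FALSE)
  manifest <- list(
    package = "coexsim",
    version = as.character(utils::packageVersion("coexsim")),
    master_seed = bundle$master_seed,
    replicate_seeds = bundle$replicate_seeds,
    config = unclass(bundle$config))
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a metrics CSV written by [write_outputs()]
#'
#' @param path the `metrics.csv` file.
#' @return data.frame of metrics records.
#' @export
read_metrics <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
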