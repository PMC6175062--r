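#' Dataset column dictionary
#'
#' The NONMEM-like long format used throughout the package:
#' \describe{
#'   \item{ID}{subject identifier (integer)}
#'   \item{OCC}{occasion index; time is relative to the occasion's dose}
#'   \item{TIME}{event time (h); urine rows carry the interval end}
#'   \item{TSTART}{urine collection interval start (h); `NA` otherwise}
#'   \item{AMT}{dose amount (mg) for dose rows; `NA` otherwise}
#'   \item{CMT}{compartment code (1 RIF depot, 2 RIF plasma, 3 CPI plasma,
#'     4 CPI urine, 5 RSV depot, 6 RSV plasma, 7 RSV peripheral,
#'     8 RSV urine)}
#'   \item{EVID}{1 dose, 0 observation}
#'   \item{DV}{observed value: plasma uM (RIF, RSV) or nM (CPI); urine
#'     amount nmol (CPI) or umol (RSV)}
#'   \item{MDV}{1 when `DV` is missing/ignored}
#'   \item{STREAM}{observation stream label (`rif_plasma`, `cpi_plasma`,
#'     `cpi_urine`, `rsv_plasma`, `rsv_urine`); `NA` for dose rows}
#' }
#' @name dataset_format
#' @keywords internal
NULL

.dataset_cols <- c("ID", "OCC", "TIME", "TSTART", "AMT", "CMT", "EVID",
                   "DV", "MDV", "STREAM")
.known_streams <- c("rif_plasma", "cpi_plasma", "cpi_urine", "rsv_plasma",
                    "rsv_urine")
.units_header <- c(
  "# units: TIME h; AMT mg; DV rif_plasma uM, cpi_plasma nM, cpi_urine nmol, rsv_plasma uM, rsv_urine umol")

#' Write a dataset to CSV
#'
#' Writes the documented CSV dialect with a units header line so molar and
#' mass units cannot be confused silently.  [read_dataset()] round-trips
#' the result losslessly.
#'
#' @param dataset a `pk_dataset`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(all(.dataset_cols %in% names(dataset)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.units_header, con)
  utils::write.csv(dataset[, .dataset_cols], con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a dataset from CSV
#'
#' Validates the column set, per-subject time ordering of dose versus
#' post-dose observations, and the stream labels.
#'
#' @param path CSV file written by [write_dataset()] (or hand-built in the
#'   same dialect; the units comment line is optional)
#' @return a `pk_dataset` data.frame
#' @export
read_dataset <- function(path) {
  ds <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(.dataset_cols, names(ds))
  if (length(missing_cols))
    stop("dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  ds$STREAM[ds$STREAM %in% c("", "NA")] <- NA_character_
  bad <- !is.na(ds$STREAM) & !ds$STREAM %in% .known_streams
  if (any(bad))
    stop("unknown stream(s): ", paste(unique(ds$STREAM[bad]), collapse = ", "))
  obs <- ds[ds$EVID == 0 & is.na(ds$TSTART), ]
  for (id in unique(obs$ID)) {
    for (k in unique(obs$OCC[obs$ID == id])) {
      tt <- obs$TIME[obs$ID == id & obs$OCC == k &
                       obs$STREAM %in% c("rif_plasma", "rsv_plasma")]
      if (length(tt) && is.unsorted(tt))
        stop("non-monotone post-dose times for subject ", id,
             " occasion ", k)
      dose_t <- ds$TIME[ds$ID == id & ds$OCC == k & ds$EVID == 1]
      if (length(dose_t) && length(tt) && any(tt < max(dose_t)))
        stop("post-dose drug observation precedes dose for subject ", id,
             " occasion ", k)
    }
  }
  class(ds) <- c("pk_dataset", "data.frame")
  ds
}

#' Run configuration for reproducible stochastic analyses
#'
#' A light container tying a seed and the analysis settings together;
#' round-trips losslessly through YAML so any stochastic output can be
#' regenerated from its logged configuration.
#'
#' @param seed integer seed (mandatory)
#' @param ... further named settings (rep counts, scenario grids, paths)
#' @return object of class `run_config`
#' @export
run_config <- function(seed, ...) {
  stopifnot(!missing(seed), is.numeric(seed), length(seed) == 1)
  structure(list(seed = as.integer(seed), settings = list(...),
                 package_version = as.character(utils::packageVersion("copropk"))),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`
#' @param path YAML file path
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- do.call(run_config, c(list(seed = y$seed), y$settings))
  cfg$package_version <- y$package_version
  cfg
}
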