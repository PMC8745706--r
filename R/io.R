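#' Droplet CSV dialect
#'
#' Column naming and delimiter of a per-droplet amplitude export (one row
#' per droplet: well, sample, channel-1 amplitude, channel-2 amplitude), in
#' the style of instrument-software CSV exports.
#'
#' @param well,sample,ch1,ch2 Column names.
#' @param delim Field delimiter (default `","`).
#' @param header Logical, file carries a header row (default TRUE).
#' @return An object of class `droplet_csv_dialect`.
#' @export
droplet_csv_dialect <- function(well = "well", sample = "sample",
                                ch1 = "ch1_amplitude",
                                ch2 = "ch2_amplitude",
                                delim = ",", header = TRUE) {
  structure(list(well = well, sample = sample, ch1 = ch1, ch2 = ch2,
                 delim = delim, header = header),
            class = "droplet_csv_dialect")
}

#' Read / write per-droplet amplitude CSVs
#'
#' `read_droplet_csv` loads every well of a droplet amplitude table into a
#' named list of `droplet_set` (droplet order preserved); rows whose
#' amplitudes do not parse as finite numbers fail with their line numbers.
#' `write_droplet_csv` is its inverse; together they round-trip.
#'
#' @param path File path.
#' @param dialect A [droplet_csv_dialect()].
#' @return `read_droplet_csv`: named list of `droplet_set`, one per well
#'   (empty list for a header-only file). `write_droplet_csv`: `path`,
#'   invisibly.
#' @export
read_droplet_csv <- function(path, dialect = droplet_csv_dialect()) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, sep = dialect$delim,
                          header = dialect$header,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!dialect$header)
    names(df) <- c(dialect$well, dialect$sample, dialect$ch1, dialect$ch2)
  for (col in c(dialect$well, dialect$sample, dialect$ch1, dialect$ch2))
    if (!col %in% names(df))
      stop("droplet CSV is missing required column '", col, "': ", path)
  if (!nrow(df)) return(setNames(list(), character(0)))
  parse_num <- function(col) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(x))
    if (length(bad))
      stop("non-numeric amplitude in column '", col, "' at line(s) ",
           paste(bad + as.integer(dialect$header), collapse = ", "),
           " of ", path)
    x
  }
  ch1 <- parse_num(dialect$ch1)
  ch2 <- parse_num(dialect$ch2)
  wells <- df[[dialect$well]]
  out <- lapply(unique(wells), function(w) {
    sel <- wells == w
    droplet_set(w, df[[dialect$sample]][sel][1], ch1[sel], ch2[sel])
  })
  setNames(out, unique(wells))
}

#' @rdname read_droplet_csv
#' @param wells A `droplet_set` or list of them.
#' @export
write_droplet_csv <- function(wells, path,
                              dialect = droplet_csv_dialect()) {
  if (inherits(wells, "droplet_set")) wells <- list(wells)
  df <- do.call(rbind, lapply(wells, function(ds)
    setNames(data.frame(ds$well_id, ds$sample_id,
                        ds$amplitudes$ch1, ds$amplitudes$ch2,
                        stringsAsFactors = FALSE),
             c(dialect$well, dialect$sample, dialect$ch1, dialect$ch2))))
  if (is.null(df))
    df <- setNames(data.frame(character(0), character(0), numeric(0),
                              numeric(0)),
                   c(dialect$well, dialect$sample, dialect$ch1, dialect$ch2))
  utils::write.table(df, path, sep = dialect$delim, row.names = FALSE,
                     col.names = dialect$header, qmethod = "double")
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with columns `sample_id`, `sex`, `disease_state` and optionally
#' `chemo`, `enz_abi` (logical flags) and per-assay well ids. Sample ids
#' must be unique; referenced wells, when `wells` is supplied, must exist.
#'
#' @param path File path.
#' @param wells Optional named list of `droplet_set` to validate well
#'   references against.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path, wells = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("sample_id", "sex", "disease_state"))
    if (!col %in% names(df))
      stop("sample sheet is missing required column '", col, "': ", path)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "))
  if (!is.null(wells))
    for (col in grep("^well", names(df), value = TRUE)) {
      bad <- setdiff(stats::na.omit(df[[col]]), names(wells))
      if (length(bad))
        stop("sample sheet references unknown well(s): ",
             paste(bad, collapse = ", "))
    }
  df
}

#' Write / read a per-sample results table
#'
#' Tab-separated, one row per sample per assay: per-target concentrations
#' (as `conc_<target>` columns), AR:reference ratio, CN, amplification
#' flag, mutation call and Chr X CN where applicable. Deterministic column
#' order; numeric fields round-trip at 6 significant digits or better.
#'
#' @param results Data frame (e.g. accumulated from [analyze_sample()]
#'   output via [result_row()]).
#' @param path File path.
#' @return `write_results`: `path`, invisibly; `read_results`: data frame.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Flatten one sample analysis into a results row
#'
#' @param sample_id Sample identifier.
#' @param res Output of [analyze_sample()].
#' @return One-row data frame.
#' @export
result_row <- function(sample_id, res) {
  conc <- vapply(res$concentrations, `[[`, numeric(1), "copies_per_uL")
  names(conc) <- paste0("conc_", gsub("[^A-Za-z0-9]", "_", names(conc)))
  cbind(data.frame(sample_id = sample_id, assay = res$cn$assay_id,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(conc)),
        data.frame(ar_ref_ratio = res$cn$ar_ref_ratio, cn = res$cn$cn,
                   amplified = res$cn$amplified,
                   t877a_detected = if (!is.null(res$t877a))
                     res$t877a$detected else NA,
                   mutant_fraction = if (!is.null(res$t877a))
                     res$t877a$mutant_fraction else NA_real_,
                   chrx_cn = if (!is.null(res$chrx)) res$chrx$chrx_cn
                     else NA_real_))
}

run_config_defaults <- function() {
  list(assay = "AR-Amp-1/T877A",
       droplet_volume_uL = 0.00085,
       amplification_threshold = 2,
       min_mutant_droplets = 3L,
       gate_file = NULL,
       seed = NULL)
}

#' Read and validate a run configuration
#'
#' YAML with any subset of the keys `assay`, `droplet_volume_uL`,
#' `amplification_threshold`, `min_mutant_droplets`, `gate_file`, `seed`.
#' Missing keys take defaults (threshold 2, QX200 droplet volume); unknown
#' keys are rejected, listed by name.
#'
#' @param path File path, or NULL for pure defaults.
#' @return Named list of validated settings.
#' @export
run_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (length(user)) {
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  problems <- character(0)
  if (cfg$droplet_volume_uL <= 0)
    problems <- c(problems, "droplet_volume_uL must be > 0")
  if (cfg$amplification_threshold < 0)
    problems <- c(problems, "amplification_threshold must be >= 0")
  if (cfg$min_mutant_droplets < 0)
    problems <- c(problems, "min_mutant_droplets must be >= 0")
  if (length(problems))
    stop("invalid run config: ", paste(problems, collapse = "; "))
  cfg
}
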