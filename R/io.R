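COHORT_SCHEMA_VERSION <- 1L

#' Write a cohort to disk
#'
#' One CSV per recording (`time_s`, `ppg`), a cohort `metadata.csv`, and
#' a JSON `manifest.json` carrying the schema version and seed. Plain
#' delimiter-separated text is used throughout: recordings are small
#' and inspectability wins over a binary format.
#'
#' @param cohort a `ppg_cohort` from [gen_cohort()] or [read_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings) {
    # %.17g round-trips doubles exactly through text
    fwrite(data.table(time_s = sprintf("%.10g", (seq_along(rec$samples) - 1) /
                                         rec$sampling_rate),
                      ppg = sprintf("%.17g", rec$samples)),
           file.path(dir, paste0(rec$recording_id, ".csv")))
  }
  meta_txt <- copy(cohort$metadata)
  for (col in names(meta_txt)) {
    if (is.double(meta_txt[[col]]))
      meta_txt[[col]] <- sprintf("%.17g", meta_txt[[col]])
  }
  fwrite(meta_txt, file.path(dir, "metadata.csv"))
  manifest <- list(schema_version = COHORT_SCHEMA_VERSION,
                   seed = cohort$seed %||% NA,
                   n_recordings = length(cohort$recordings),
                   sampling_rates = sort(unique(cohort$metadata$sampling_rate_hz)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort from disk
#'
#' Strict validation: the manifest must be present and
#' schema-compatible, every metadata row's recording file must exist,
#' and malformed numeric fields are reported with their row.
#'
#' @param dir directory written by [write_cohort()].
#' @return a `ppg_cohort`.
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("manifest.json not found in ", dir)
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  if (is.null(manifest$schema_version) ||
      manifest$schema_version != COHORT_SCHEMA_VERSION)
    stop("unknown cohort schema version: ",
         manifest$schema_version %||% "<missing>")
  meta <- fread(file.path(dir, "metadata.csv"))
  req <- c("subject_id", "day", "timepoint_min", "repeat_index",
           "sampling_rate_hz", "reference_bgl_mgdl", "file", "recording_id")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols) > 0)
    stop("metadata.csv is missing columns: ",
         paste(missing_cols, collapse = ", "))
  for (i in seq_len(nrow(meta))) {
    if (!is.finite(meta$sampling_rate_hz[i]) || meta$sampling_rate_hz[i] <= 0)
      stop(sprintf("metadata row %d: invalid sampling rate", i))
    if (!is.finite(meta$reference_bgl_mgdl[i]))
      stop(sprintf("metadata row %d: malformed reference BGL", i))
    if (!file.exists(file.path(dir, meta$file[i])))
      stop(sprintf("metadata row %d: recording file '%s' is missing",
                   i, meta$file[i]))
  }
  recordings <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    sig <- fread(file.path(dir, meta$file[i]))
    if (!all(c("time_s", "ppg") %in% names(sig)))
      stop(sprintf("recording file '%s': expected columns time_s, ppg",
                   meta$file[i]))
    if (anyNA(sig$ppg))
      stop(sprintf("recording file '%s': malformed PPG values", meta$file[i]))
    recordings[[i]] <- structure(list(
      subject_id = meta$subject_id[i],
      phenotype = if ("phenotype" %in% names(meta)) meta$phenotype[i] else NA,
      day = meta$day[i], timepoint = meta$timepoint_min[i],
      repeat_index = meta$repeat_index[i],
      recording_id = meta$recording_id[i],
      sampling_rate = meta$sampling_rate_hz[i],
      samples = sig$ppg,
      reference_bgl = meta$reference_bgl_mgdl[i],
      true_bgl = if ("true_bgl_mgdl" %in% names(meta))
        meta$true_bgl_mgdl[i] else NA_real_
    ), class = "ppg_recording")
  }
  names(recordings) <- meta$recording_id
  structure(list(recordings = recordings, metadata = meta,
                 seed = manifest$seed), class = "ppg_cohort")
}
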