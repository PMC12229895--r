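# Persistent storage for cohort datasets.
#
# A dataset is stored as a directory: JSON metadata with a schema-version tag,
# CSV sidecars for the neuron and stimulus tables, and one RDS file holding
# the trial tensors and presence masks (bit-exact for all arrays).

#' Save a cohort dataset to disk
#'
#' Writes `meta.json` (schema version, days, ablation day), `neurons.csv`,
#' `stimuli.csv` and `arrays.rds` (trial tensors and presence masks) into
#' `path`. The round trip through [load_dataset()] reproduces every array
#' bit-exactly and all metadata.
#'
#' @param ds a `cohort_dataset`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "cohort_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(schema_version = ds$schema_version,
               days = ds$days, ablation_day = ds$ablation_day)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  utils::write.csv(ds$neurons, file.path(path, "neurons.csv"), row.names = FALSE)
  utils::write.csv(ds$stimuli, file.path(path, "stimuli.csv"), row.names = FALSE)
  saveRDS(list(tensors = ds$tensors, present = ds$present),
          file.path(path, "arrays.rds"))
  invisible(path)
}

#' Load a cohort dataset from disk
#'
#' Checks the schema-version tag and validates structural integrity (every
#' FOV must carry every session day); a missing session raises a classed
#' error naming the FOV and day.
#'
#' @param path directory written by [save_dataset()].
#' @return A `cohort_dataset`.
#' @export
load_dataset <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) {
    dm_stop("driftmap_schema_error", "no dataset found at %s", path)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  if (!identical(as.character(meta$schema_version), DM_SCHEMA_VERSION)) {
    dm_stop("driftmap_schema_error",
            "schema version mismatch: file has %s, reader expects %s",
            meta$schema_version, DM_SCHEMA_VERSION)
  }
  neurons <- utils::read.csv(file.path(path, "neurons.csv"),
                             stringsAsFactors = FALSE,
                             colClasses = c(neuron_id = "character",
                                            fov_id = "character",
                                            mouse_id = "character"))
  class(neurons) <- c("neuron_records", "data.frame")
  stimuli <- utils::read.csv(file.path(path, "stimuli.csv"),
                             stringsAsFactors = FALSE)
  class(stimuli) <- c("stimulus_set", "data.frame")
  arrays <- readRDS(file.path(path, "arrays.rds"))
  cohort_dataset(neurons = neurons, tensors = arrays$tensors,
                 present = arrays$present, stimuli = stimuli,
                 days = as.integer(meta$days),
                 ablation_day = as.integer(meta$ablation_day))
}
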