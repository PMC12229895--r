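# Shared data model: trial tensors, neuron records, cohort datasets.

DM_SCHEMA_VERSION <- "1.0"

#' Session days and ablation day of the longitudinal design
#'
#' The standard design images each field of view at six time points at 2-day
#' intervals and a final session 4 days later (days 1, 3, 5, 7, 9, 11, 15),
#' with the (sham) microablation on day 6, between the third and fourth
#' sessions.
#' @return Integer vector of session days.
#' @export
default_days <- function() c(1L, 3L, 5L, 7L, 9L, 11L, 15L)

#' Construct a trial tensor for one field of view and session
#'
#' The trial tensor is the central currency of the pipeline: evoked response
#' amplitudes `A[neuron, stimulus, trial]` in %dF/F (post-stimulus peak window
#' minus pre-stimulus baseline window), together with the matching
#' pre-stimulus baseline values used as the paired "spontaneous activity"
#' reference by the responsiveness test.
#'
#' @param A numeric array `[n_neurons, n_stimuli, n_trials]`.
#' @param pre numeric array of the same shape: per-trial pre-stimulus values.
#' @param fov_id,day provenance labels.
#' @return A list of class `trial_tensor`.
#' @export
trial_tensor <- function(A, pre, fov_id, day) {
  if (!identical(dim(A), dim(pre))) {
    dm_stop("driftmap_invalid_argument",
            "trial_tensor: A and pre must have identical dimensions")
  }
  if (length(dim(A)) != 3) {
    dm_stop("driftmap_invalid_argument",
            "trial_tensor: A must be a 3-d array [neuron, stimulus, trial]")
  }
  structure(list(A = A, pre = pre, fov_id = fov_id, day = as.integer(day)),
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$A)
  cat(sprintf("<trial_tensor> fov %s day %d: %d neurons x %d stimuli x %d trials\n",
              x$fov_id, x$day, d[1], d[2], d[3]))
  invisible(x)
}

#' Construct a neuron record table
#'
#' One row per tracked neuron: stable string identity, field-of-view / mouse /
#' cohort keys, 3-d position in micrometres, inhibitory flag, and an
#' eligibility flag (FALSE for e.g. optically occluded nuclei that cannot be
#' targeted).
#'
#' @param neuron_id character, unique within mouse.
#' @param fov_id,mouse_id,cohort grouping keys; `cohort` one of
#'   `"responsive_ablation"`, `"nonresponsive_ablation"`,
#'   `"inhibitory_ablation"`, `"control"`.
#' @param x,y,z finite positions in micrometres.
#' @param inhibitory logical.
#' @param eligible logical, default TRUE.
#' @return data.frame of class `neuron_records`.
#' @export
neuron_records <- function(neuron_id, fov_id, mouse_id, cohort, x, y, z,
                           inhibitory, eligible = TRUE) {
  if (anyDuplicated(neuron_id)) {
    dm_stop("driftmap_invalid_argument", "neuron_id values must be unique")
  }
  if (!all(is.finite(c(x, y, z)))) {
    dm_stop("driftmap_invalid_argument", "neuron positions must be finite")
  }
  inhibitory <- rep_len(inhibitory, length(neuron_id))
  eligible <- rep_len(eligible, length(neuron_id))
  out <- data.frame(neuron_id = as.character(neuron_id),
                    fov_id = as.character(fov_id),
                    mouse_id = as.character(mouse_id),
                    cohort = as.character(cohort),
                    x = x, y = y, z = z,
                    inhibitory = inhibitory,
                    eligible = eligible,
                    stringsAsFactors = FALSE)
  class(out) <- c("neuron_records", "data.frame")
  out
}

#' Assemble a cohort dataset
#'
#' Bundles neuron records, per-FOV/session trial tensors, per-day presence
#' (quality) masks and the stimulus set into the container consumed by every
#' analysis stage. Neurons absent on a day (quality gate FALSE) are excluded
#' from the numerator and denominator of every statistic.
#'
#' @param neurons `neuron_records` table for all FOVs.
#' @param tensors named list: `tensors[[fov_id]][[as.character(day)]]` is a
#'   [trial_tensor()].
#' @param present named list: `present[[fov_id]]` is an `n_neurons x n_days`
#'   logical matrix (columns named by day) of per-day quality gates.
#' @param stimuli a [build_stimulus_set()] table.
#' @param days session days, default [default_days()].
#' @param ablation_day day of the (sham) ablation; must fall strictly between
#'   the third and fourth sessions.
#' @return A list of class `cohort_dataset`.
#' @export
cohort_dataset <- function(neurons, tensors, present,
                           stimuli = build_stimulus_set(),
                           days = default_days(), ablation_day = 6L) {
  if (length(days) >= 4 && !(ablation_day > days[3] && ablation_day < days[4])) {
    dm_stop("driftmap_invalid_argument",
            "ablation_day must lie strictly between sessions 3 and 4 (days %d and %d)",
            days[3], days[4])
  }
  ds <- structure(list(neurons = neurons, tensors = tensors, present = present,
                       stimuli = stimuli, days = as.integer(days),
                       ablation_day = as.integer(ablation_day),
                       schema_version = DM_SCHEMA_VERSION),
                  class = "cohort_dataset")
  check_dataset_structure(ds)
  ds
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(paste0("<cohort_dataset> %d neurons, %d FOVs, %d mice, days %s",
                     " (ablation day %d), %d stimuli\n"),
              nrow(x$neurons), length(unique(x$neurons$fov_id)),
              length(unique(x$neurons$mouse_id)),
              paste(x$days, collapse = ","), x$ablation_day, nrow(x$stimuli)))
  invisible(x)
}

#' FOV identifiers of a cohort dataset
#' @param ds a `cohort_dataset`.
#' @export
fov_ids <- function(ds) unique(ds$neurons$fov_id)

#' Neuron records of one FOV, in tensor row order
#' @param ds a `cohort_dataset`.
#' @param fov FOV identifier.
#' @export
fov_neurons <- function(ds, fov) ds$neurons[ds$neurons$fov_id == fov, , drop = FALSE]

#' Trial tensor of one FOV and day
#' @param ds a `cohort_dataset`.
#' @param fov FOV identifier.
#' @param day session day.
#' @export
get_tensor <- function(ds, fov, day) {
  tt <- ds$tensors[[fov]][[as.character(day)]]
  if (is.null(tt)) {
    dm_stop("driftmap_missing_session", "FOV %s has no session for day %s", fov, day)
  }
  tt
}

#' Presence (quality-gate) flags of one FOV and day
#' @inheritParams get_tensor
#' @export
get_present <- function(ds, fov, day) ds$present[[fov]][, as.character(day)]

# Structural integrity: every FOV has every day, dims agree with neuron table.
check_dataset_structure <- function(ds) {
  if (nrow(ds$neurons) == 0) return(invisible(ds))  # empty dataset is valid
  for (fov in fov_ids(ds)) {
    n <- nrow(fov_neurons(ds, fov))
    for (day in ds$days) {
      tt <- ds$tensors[[fov]][[as.character(day)]]
      if (is.null(tt)) {
        dm_stop("driftmap_missing_session",
                "dataset invalid: FOV %s is missing day %d", fov, day)
      }
      if (dim(tt$A)[1] != n) {
        dm_stop("driftmap_schema_error",
                "dataset invalid: FOV %s day %d has %d tensor rows for %d neurons",
                fov, day, dim(tt$A)[1], n)
      }
    }
    pm <- ds$present[[fov]]
    if (is.null(pm) || nrow(pm) != n ||
        !identical(colnames(pm), as.character(ds$days))) {
      dm_stop("driftmap_schema_error",
              "dataset invalid: FOV %s presence mask malformed", fov)
    }
  }
  invisible(ds)
}

#' Validate FOV inclusion criteria of a cohort dataset
#'
#' Applies the field-of-view inclusion rules: a FOV enters analysis only when
#' it (1) contains at least `min_rois` quality-passing neurons and (2)
#' contains strictly more than `min_responsive` significantly sound-responsive
#' neurons on the baseline days. "More than ten" is read literally, so a FOV
#' with exactly ten responsive neurons fails; the bound is configurable.
#'
#' @param ds a `cohort_dataset`.
#' @param resp optional responsiveness table from [classify_responsiveness()]
#'   covering the baseline days; computed on the fly when NULL.
#' @param min_rois minimum quality-passing neuron count (inclusive), default 100.
#' @param min_responsive responsive-count bound (exclusive), default 10.
#' @param baseline_days days counted as baseline, default pre-ablation days.
#' @return data.frame, one row per FOV: counts, `pass` and `reason`.
#' @export
validate_dataset <- function(ds, resp = NULL, min_rois = 100,
                             min_responsive = 10,
                             baseline_days = ds$days[ds$days < ds$ablation_day]) {
  if (is.null(resp)) {
    resp <- classify_responsiveness(ds, days = baseline_days)
  }
  resp <- resp[resp$day %in% baseline_days, , drop = FALSE]
  out <- lapply(fov_ids(ds), function(fov) {
    nr <- fov_neurons(ds, fov)
    pm <- ds$present[[fov]]
    n_quality <- sum(apply(pm, 1, all))
    r <- resp[resp$neuron_id %in% nr$neuron_id & resp$responsive, , drop = FALSE]
    n_resp <- length(unique(r$neuron_id))
    reasons <- c(if (n_quality < min_rois) "ROI count",
                 if (n_resp <= min_responsive) "responsive count")
    data.frame(fov_id = fov, n_quality = n_quality, n_responsive = n_resp,
               pass = length(reasons) == 0,
               reason = if (length(reasons)) paste(reasons, collapse = "; ") else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
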