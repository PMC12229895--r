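# Microablation target selection, category assignment, spared-network mask.

#' Select microablation targets for every FOV
#'
#' Implements the three targeting modes, all based on the two baseline
#' sessions (days 3 and 5) before the day-6 ablation:
#'
#' * `responsive`: per day, each responsive neuron's amplitude is its mean
#'   trial-mean amplitude over the stimuli with significant responses; the
#'   two days' descending distributions are merged, sorted by amplitude and
#'   deduplicated keeping the higher-ranked (larger-amplitude) entry, and
#'   targets are taken from the top.
#' * `nonresponsive`: neurons responsive on neither day are ranked per day by
#'   absolute mean amplitude (ascending, among that day's nonresponsive
#'   neurons), the two ranks averaged, and targets taken from the smallest
#'   average rank.
#' * `inhibitory`: the responsive-mode criterion restricted to inhibitory
#'   neurons; if fewer than `n_per_fov` qualify, nonsignificant ("apparent
#'   sound-responsive") interneurons with the largest mean amplitude across
#'   the two baseline days fill the remainder.
#'
#' Ineligible neurons (occluded nuclei etc., `eligible = FALSE`) are skipped.
#' Plans with fewer candidates than requested are truncated with a warning.
#' Per-target ablation success is drawn with probability `success_prob`.
#'
#' @param ds a `cohort_dataset`.
#' @param resp a `responsiveness_table` covering the baseline days.
#' @param mode `"responsive"`, `"nonresponsive"` or `"inhibitory"`.
#' @param n_per_fov targets per FOV (the standard protocol achieves 4-8).
#' @param baseline_days the two selection days, default `c(3, 5)`.
#' @param success_prob per-target ablation success probability, default 1.
#' @param seed seed for the success draws.
#' @param dedup_key amplitude used for a neuron appearing on both days in
#'   responsive mode: `"max"` (default) or `"day3"`/`"day5"`.
#' @return A list of class `ablation_plan`: `mode`, `targets` data.frame
#'   (`fov_id`, `neuron_id`, `rank`, `amplitude`, `success`), `candidates`
#'   (full ordered candidate lists), `warnings`.
#' @export
select_targets <- function(ds, resp, mode = c("responsive", "nonresponsive",
                                              "inhibitory"),
                           n_per_fov = 6, baseline_days = c(3, 5),
                           success_prob = 1, seed = 1L,
                           dedup_key = c("max", "day3", "day5")) {
  mode <- match.arg(mode)
  dedup_key <- match.arg(dedup_key)
  stopifnot(length(baseline_days) == 2)
  targets <- list(); cands <- list(); warns <- character(0)
  for (fov in fov_ids(ds)) {
    nr <- fov_neurons(ds, fov)
    r <- resp[resp$fov_id == fov & resp$day %in% baseline_days, , drop = FALSE]
    cand <- switch(mode,
      responsive = candidates_responsive(r, baseline_days, dedup_key),
      nonresponsive = candidates_nonresponsive(r, baseline_days),
      inhibitory = candidates_inhibitory(r, nr, baseline_days, dedup_key))
    cand <- cand[cand$neuron_id %in% nr$neuron_id[nr$eligible], , drop = FALSE]
    if (nrow(cand) == 0) {
      warns <- c(warns, sprintf("FOV %s: no %s candidates", fov, mode))
    } else if (nrow(cand) < n_per_fov) {
      warns <- c(warns, sprintf("FOV %s: only %d of %d requested targets",
                                fov, nrow(cand), n_per_fov))
    }
    cand$rank <- seq_len(nrow(cand))
    cand$fov_id <- rep(fov, nrow(cand))
    cands[[fov]] <- cand
    sel <- utils::head(cand, n_per_fov)
    if (nrow(sel)) {
      sel$success <- with_seed(seed_stream(seed, "ablate", fov),
                               stats::runif(nrow(sel)) < success_prob)
      targets[[fov]] <- sel
    }
  }
  if (length(warns)) for (w in warns) warning(w, call. = FALSE)
  tg <- if (length(targets)) do.call(rbind, targets) else
    data.frame(fov_id = character(0), neuron_id = character(0),
               rank = integer(0), amplitude = numeric(0), success = logical(0))
  rownames(tg) <- NULL
  structure(list(mode = mode, n_per_fov = n_per_fov, targets = tg,
                 candidates = cands, warnings = warns),
            class = "ablation_plan")
}

#' @export
print.ablation_plan <- function(x, ...) {
  cat(sprintf("<ablation_plan> mode %s: %d targets in %d FOVs (%d successful)\n",
              x$mode, nrow(x$targets), length(unique(x$targets$fov_id)),
              sum(x$targets$success)))
  invisible(x)
}

# merged, amplitude-sorted, deduplicated responsive candidate list
candidates_responsive <- function(r, baseline_days, dedup_key = "max",
                                  restrict_ids = NULL) {
  r <- r[r$responsive %in% TRUE, , drop = FALSE]
  if (!is.null(restrict_ids)) r <- r[r$neuron_id %in% restrict_ids, , drop = FALSE]
  if (nrow(r) == 0) {
    return(data.frame(neuron_id = character(0), amplitude = numeric(0)))
  }
  amp_by_day <- split(r, r$day)
  merged <- do.call(rbind, lapply(amp_by_day, function(g) {
    data.frame(neuron_id = g$neuron_id, amplitude = g$mean_sig_amp,
               day = g$day, stringsAsFactors = FALSE)
  }))
  if (dedup_key != "max") {
    keep_day <- as.integer(sub("day", "", dedup_key))
    pref <- merged[merged$day == keep_day, , drop = FALSE]
    rest <- merged[merged$day != keep_day &
                     !(merged$neuron_id %in% pref$neuron_id), , drop = FALSE]
    merged <- rbind(pref, rest)
  }
  merged <- merged[order(-merged$amplitude, merged$neuron_id), , drop = FALSE]
  merged <- merged[!duplicated(merged$neuron_id), , drop = FALSE]  # higher rank kept
  data.frame(neuron_id = merged$neuron_id, amplitude = merged$amplitude,
             stringsAsFactors = FALSE)
}

# neurons responsive on neither day, ranked by averaged per-day |amplitude| rank
candidates_nonresponsive <- function(r, baseline_days) {
  d1 <- r[r$day == baseline_days[1] & r$present %in% TRUE, , drop = FALSE]
  d2 <- r[r$day == baseline_days[2] & r$present %in% TRUE, , drop = FALSE]
  nonresp <- intersect(d1$neuron_id[!d1$responsive], d2$neuron_id[!d2$responsive])
  if (length(nonresp) == 0) {
    return(data.frame(neuron_id = character(0), amplitude = numeric(0)))
  }
  rank_in <- function(g) {
    g <- g[g$neuron_id %in% nonresp, , drop = FALSE]
    g <- g[order(abs(g$mean_amp_all), g$neuron_id), , drop = FALSE]
    stats::setNames(seq_len(nrow(g)), g$neuron_id)
  }
  r1 <- rank_in(d1); r2 <- rank_in(d2)
  avg <- (r1[nonresp] + r2[nonresp]) / 2
  ord <- order(avg, nonresp)
  amp <- stats::setNames(abs(d2$mean_amp_all), d2$neuron_id)
  data.frame(neuron_id = nonresp[ord], amplitude = unname(amp[nonresp[ord]]),
             stringsAsFactors = FALSE)
}

candidates_inhibitory <- function(r, nr, baseline_days, dedup_key) {
  inhib_ids <- nr$neuron_id[nr$inhibitory]
  if (length(inhib_ids) == 0) {
    return(data.frame(neuron_id = character(0), amplitude = numeric(0)))
  }
  primary <- candidates_responsive(r, baseline_days, dedup_key,
                                   restrict_ids = inhib_ids)
  # "apparent sound-responsive" interneurons: nonsignificant but large mean
  # amplitude across the two baseline days
  rr <- r[r$neuron_id %in% inhib_ids & !(r$neuron_id %in% primary$neuron_id) &
            r$present %in% TRUE, , drop = FALSE]
  if (nrow(rr)) {
    amp <- tapply(rr$mean_amp_all, rr$neuron_id, mean)
    fill <- data.frame(neuron_id = names(amp), amplitude = as.vector(amp),
                       stringsAsFactors = FALSE)
    fill <- fill[order(-fill$amplitude, fill$neuron_id), , drop = FALSE]
  } else {
    fill <- data.frame(neuron_id = character(0), amplitude = numeric(0))
  }
  rbind(primary, fill)
}

#' Assign high- and low-category neurons per FOV
#'
#' High-category: the `n_each` responsive neurons with the highest amplitudes
#' per FOV (from the merged baseline candidate distribution); for the
#' inhibitory-ablation cohort, ablated sound-responsive interneurons are
#' excluded from the set. Low-category: the `n_each` nonresponsive neurons
#' with minimum absolute amplitudes per FOV. These are the digital-exclusion
#' sets that equalize the spared populations across cohorts: the
#' responsive-ablation cohort additionally excludes its low-category set, the
#' nonresponsive-ablation cohort its high-category set, and the control
#' cohort both. Ties at the boundary break deterministically by neuron id;
#' FOVs with fewer than `n_each` eligible neurons contribute what they have
#' (logged in `shortfall`).
#'
#' @param ds a `cohort_dataset`.
#' @param resp a `responsiveness_table` covering the baseline days.
#' @param plan the finalized [select_targets()] plan (used to exclude ablated
#'   interneurons for the inhibitory cohort).
#' @param cohort cohort label.
#' @param n_each set size per FOV, default 5.
#' @param baseline_days default `c(3, 5)`.
#' @return list of class `category_sets`: `high`, `low` (data.frames
#'   `fov_id`, `neuron_id`), `exclude` (which sets apply to this cohort),
#'   `shortfall` messages.
#' @export
assign_categories <- function(ds, resp, plan, cohort, n_each = 5,
                              baseline_days = c(3, 5)) {
  high <- list(); low <- list(); shortfall <- character(0)
  ablated_ids <- plan$targets$neuron_id[plan$targets$success]
  for (fov in fov_ids(ds)) {
    r <- resp[resp$fov_id == fov & resp$day %in% baseline_days, , drop = FALSE]
    hc <- candidates_responsive(r, baseline_days)
    if (cohort == "inhibitory_ablation") {
      hc <- hc[!(hc$neuron_id %in% ablated_ids), , drop = FALSE]
    }
    lc <- candidates_nonresponsive(r, baseline_days)
    if (nrow(hc) < n_each || nrow(lc) < n_each) {
      shortfall <- c(shortfall,
                     sprintf("FOV %s: %d high / %d low eligible for %d requested",
                             fov, nrow(hc), nrow(lc), n_each))
    }
    if (nrow(hc)) {
      high[[fov]] <- data.frame(fov_id = fov,
                                neuron_id = utils::head(hc$neuron_id, n_each),
                                stringsAsFactors = FALSE)
    }
    if (nrow(lc)) {
      low[[fov]] <- data.frame(fov_id = fov,
                               neuron_id = utils::head(lc$neuron_id, n_each),
                               stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(fov_id = character(0), neuron_id = character(0))
  exclude <- switch(cohort,
                    responsive_ablation = "low",
                    nonresponsive_ablation = "high",
                    inhibitory_ablation = "high",
                    control = c("high", "low"),
                    character(0))
  structure(list(high = if (length(high)) do.call(rbind, high) else empty,
                 low = if (length(low)) do.call(rbind, low) else empty,
                 exclude = exclude, shortfall = shortfall),
            class = "category_sets")
}

#' Build the spared-neuron mask
#'
#' Excludes (1) all targeted neurons, successful or not, (2) every neuron
#' within `radius` micrometres (3-d Euclidean, boundary inclusive) of any
#' successfully ablated neuron, and (3) the cohort's applicable high-/
#' low-category sets; everything else is spared. Neurons with missing
#' positions are conservatively excluded. Each neuron gets at most one
#' primary reason, in the priority order targeted > within_radius >
#' high_category > low_category.
#'
#' @param ds a `cohort_dataset`.
#' @param plan an `ablation_plan`.
#' @param categories a `category_sets` from [assign_categories()].
#' @param radius exclusion radius in micrometres, default 15.
#' @return data.frame of class `spared_mask`: `neuron_id`, `fov_id`,
#'   `spared`, `reason` (NA when spared).
#' @export
build_spared_mask <- function(ds, plan, categories, radius = 15) {
  nr <- ds$neurons
  reason <- rep(NA_character_, nrow(nr))
  targeted <- nr$neuron_id %in% plan$targets$neuron_id
  reason[targeted] <- "targeted"

  ablated <- plan$targets[plan$targets$success, , drop = FALSE]
  for (fov in unique(ablated$fov_id)) {
    idx <- which(nr$fov_id == fov & is.na(reason))
    if (length(idx) == 0) next
    abl <- nr[nr$neuron_id %in% ablated$neuron_id[ablated$fov_id == fov], ,
              drop = FALSE]
    P <- as.matrix(nr[idx, c("x", "y", "z")])
    Q <- as.matrix(abl[, c("x", "y", "z")])
    missing_pos <- !stats::complete.cases(P)
    d2 <- outer(rowSums(P^2), rep(1, nrow(Q))) +
      outer(rep(1, nrow(P)), rowSums(Q^2)) - 2 * P %*% t(Q)
    near <- apply(d2, 1, min) <= radius^2 + 1e-9
    reason[idx[near | missing_pos]] <- "within_radius"
  }

  apply_set <- function(set, label) {
    hit <- nr$neuron_id %in% set$neuron_id & is.na(reason)
    reason[hit] <<- label
  }
  if ("high" %in% categories$exclude) apply_set(categories$high, "high_category")
  if ("low" %in% categories$exclude) apply_set(categories$low, "low_category")

  out <- data.frame(neuron_id = nr$neuron_id, fov_id = nr$fov_id,
                    spared = is.na(reason), reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("spared_mask", "data.frame")
  out
}
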