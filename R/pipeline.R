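# Cohort-level convenience wrappers composing the module operations.

#' Per-FOV similarity matrices and map summary for a whole cohort
#'
#' Builds one similarity matrix per FOV and day (masking neurons absent that
#' day and, optionally, non-spared neurons) and summarizes the grand-average
#' day course.
#'
#' @param ds a `cohort_dataset`.
#' @param spared_ids optional spared-neuron ids; default all.
#' @param mode similarity mode, see [similarity_matrix()].
#' @param days days to include, default all.
#' @param baseline_days normalization baseline, default `c(1, 3, 5)`.
#' @return list: `mats` (list of `similarity_matrix`), `summary`, `grand`,
#'   and `by_fov` (data.frame fov/mouse/day/diag/offdiag).
#' @export
cohort_map_summary <- function(ds, spared_ids = NULL,
                               mode = "trial_averaged", days = ds$days,
                               baseline_days = c(1, 3, 5)) {
  mats <- list(); rows <- list()
  for (fov in fov_ids(ds)) {
    nrf <- fov_neurons(ds, fov)
    mouse <- nrf$mouse_id[1]
    for (day in days) {
      mask <- get_present(ds, fov, day)
      if (!is.null(spared_ids)) mask <- mask & nrf$neuron_id %in% spared_ids
      if (sum(mask) < 2) next
      sm <- similarity_matrix(get_tensor(ds, fov, day), mode = mode,
                              neuron_mask = mask)
      mats[[paste(fov, day)]] <- sm
      rows[[paste(fov, day)]] <- data.frame(
        fov_id = fov, mouse_id = mouse, day = day,
        diag = mean(diag(sm$M)), offdiag = offdiag_mean(sm$M),
        stringsAsFactors = FALSE)
    }
  }
  sm <- summarize_map(mats, baseline_days = baseline_days)
  list(mats = mats, summary = sm$summary, grand = sm$grand,
       by_fov = do.call(rbind, rows))
}

#' Mean same-day split-half reliability per FOV and day
#'
#' @param ds a `cohort_dataset`.
#' @param resp a `responsiveness_table`; reliability is computed over the
#'   neurons responsive on each day.
#' @param spared_ids optional restriction.
#' @param days days to include.
#' @param n_repeats splits per neuron.
#' @param seed RNG seed.
#' @return data.frame: `fov_id`, `mouse_id`, `day`, `r`, `n_neurons`.
#' @export
cohort_reliability <- function(ds, resp, spared_ids = NULL, days = ds$days,
                               n_repeats = 10, seed = 1L) {
  rows <- list()
  for (fov in fov_ids(ds)) {
    mouse <- fov_neurons(ds, fov)$mouse_id[1]
    for (day in days) {
      ids <- resp$neuron_id[resp$fov_id == fov & resp$day == day &
                              resp$responsive]
      if (!is.null(spared_ids)) ids <- intersect(ids, spared_ids)
      if (length(ids) == 0) next
      sh <- split_half_tuning_correlation(ds, fov, day_ref = day,
                                          neuron_ids = ids,
                                          n_repeats = n_repeats, seed = seed)
      rows[[paste(fov, day)]] <- data.frame(
        fov_id = fov, mouse_id = mouse, day = day,
        r = mean(sh$r, na.rm = TRUE), n_neurons = nrow(sh),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize a per-group day course by its baseline mean
#'
#' @param df data.frame with a `day` column.
#' @param value_col column to normalize.
#' @param group_cols columns defining the groups (e.g. `"mouse_id"`).
#' @param baseline_days days whose mean forms the denominator.
#' @return `df` with an added `<value_col>_norm` column.
#' @export
normalize_by_baseline <- function(df, value_col, group_cols = "mouse_id",
                                  baseline_days = c(1, 3, 5)) {
  key <- interaction(df[group_cols], drop = TRUE)
  base <- tapply(df[[value_col]][df$day %in% baseline_days],
                 droplevels(key[df$day %in% baseline_days]), mean,
                 na.rm = TRUE)
  df[[paste0(value_col, "_norm")]] <- df[[value_col]] / as.vector(base[as.character(key)])
  df
}

#' Estimate the per-2-day tuning retention (drift) from split-half
#' correlations
#'
#' Cross-day tuning correlations (one half of trials from the reference day,
#' one from the other day) are attenuated by trial noise exactly like the
#' same-day reliability, so their ratio estimates the pure tuning retention
#' `rho^lag` (lag in 2-day units). Fits `log(ratio) ~ lag` through the
#' origin, pooling neurons responsive on both days of each comparison.
#'
#' @param ds a `cohort_dataset`.
#' @param resp a `responsiveness_table` covering `days`.
#' @param ref_day reference day, default 5.
#' @param days comparison days, default all others.
#' @param n_repeats splits per estimate.
#' @param seed RNG seed.
#' @return list: `rho` (point estimate), `by_lag` data.frame.
#' @export
estimate_drift_rho <- function(ds, resp, ref_day = 5,
                               days = setdiff(ds$days, ref_day),
                               n_repeats = 10, seed = 1L) {
  ratios <- list()
  for (fov in fov_ids(ds)) {
    ids_ref <- resp$neuron_id[resp$fov_id == fov & resp$day == ref_day &
                                resp$responsive]
    if (length(ids_ref) == 0) next
    r0 <- split_half_tuning_correlation(ds, fov, day_ref = ref_day,
                                        neuron_ids = ids_ref,
                                        n_repeats = n_repeats, seed = seed)
    for (day in days) {
      ids <- intersect(ids_ref,
                       resp$neuron_id[resp$fov_id == fov & resp$day == day &
                                        resp$responsive])
      if (length(ids) == 0) next
      rx <- split_half_tuning_correlation(ds, fov, day_ref = ref_day,
                                          day_other = day, neuron_ids = ids,
                                          n_repeats = n_repeats, seed = seed)
      lag <- abs(day - ref_day) / 2
      ratios[[paste(fov, day)]] <- data.frame(
        fov_id = fov, day = day, lag = lag,
        r_same = mean(r0$r[r0$neuron_id %in% ids], na.rm = TRUE),
        r_cross = mean(rx$r, na.rm = TRUE))
    }
  }
  tab <- do.call(rbind, ratios)
  by_lag <- do.call(rbind, lapply(split(tab, tab$lag), function(g) {
    data.frame(lag = g$lag[1], ratio = sum(g$r_cross) / sum(g$r_same),
               n_fov = nrow(g))
  }))
  ok <- by_lag$ratio > 0
  fit <- stats::lm(log(ratio) ~ 0 + lag, data = by_lag[ok, , drop = FALSE],
                   weights = by_lag$n_fov[ok])
  list(rho = exp(unname(stats::coef(fit))), by_lag = by_lag)
}

#' Estimate the spatial decay length of an ablation effect
#'
#' Fits `effect = a * exp(-distance / L)` to per-neuron effect values versus
#' distance to the nearest ablated neuron (nonlinear least squares, started
#' from a log-linear fit on the binned profile). Per-neuron effects built
#' from amplitude ratios are heavy-tailed (small denominators), so effects
#' are winsorized at the `trim` quantiles before fitting.
#'
#' @param profile result of [spatial_effect_profile()] (its `"per_neuron"`
#'   attribute is used).
#' @param trim winsorization quantiles for the per-neuron effects.
#' @return list: `L` (decay length, um), `a` (amplitude at distance 0),
#'   `fit` the nls object.
#' @export
estimate_spatial_scale <- function(profile, trim = c(0.01, 0.99)) {
  per <- attr(profile, "per_neuron")
  qs <- stats::quantile(per$effect, trim, na.rm = TRUE)
  per$effect <- pmin(pmax(per$effect, qs[1]), qs[2])
  ok <- profile[!is.na(profile$mean_effect) & profile$mean_effect > 0, ,
                drop = FALSE]
  mid <- (ok$bin_lo + ok$bin_hi) / 2
  start_fit <- stats::lm(log(ok$mean_effect) ~ mid)
  L0 <- -1 / stats::coef(start_fit)[2]
  if (!is.finite(L0) || L0 <= 0) L0 <- 100
  fit <- stats::nls(effect ~ a * exp(-distance / L), data = per,
                    start = list(a = exp(stats::coef(start_fit)[1]), L = L0),
                    control = stats::nls.control(warnOnly = TRUE))
  co <- stats::coef(fit)
  list(L = unname(co["L"]), a = unname(co["a"]), fit = fit)
}
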