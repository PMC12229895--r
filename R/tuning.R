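# Single-neuron and pairwise tuning statistics.

#' Trial-averaged tuning curves for one FOV and day
#'
#' @param ds a `cohort_dataset`.
#' @param fov FOV id.
#' @param day session day.
#' @param neuron_ids optional subset (default: neurons present that day).
#' @return numeric matrix `[n_neurons, n_stimuli]` with neuron_id rownames.
#' @export
tuning_curves <- function(ds, fov, day, neuron_ids = NULL) {
  tt <- get_tensor(ds, fov, day)
  pres <- get_present(ds, fov, day)
  ids <- fov_neurons(ds, fov)$neuron_id
  keep <- pres
  if (!is.null(neuron_ids)) keep <- keep & ids %in% neuron_ids
  Ak <- tt$A[keep, , , drop = FALSE]
  dd <- dim(Ak)
  m <- matrix(rowMeans(matrix(Ak, dd[1] * dd[2]), na.rm = TRUE), dd[1], dd[2])
  rownames(m) <- ids[keep]
  m
}

#' Split-half tuning correlation (response reliability and cross-day tuning
#' correlation)
#'
#' Trials are pseudorandomly split into two halves, stratified by stimulus
#' (5 + 5 of the 10 trials) so both half curves cover all stimuli. The
#' Pearson correlation between the two half-mean tuning curves is averaged
#' over `n_repeats` random splits. With `day_other = NULL` both halves come
#' from `day_ref` (same-day response reliability); otherwise one half comes
#' from `day_ref` and the other from `day_other` (cross-day tuning
#' correlation). Repeats where either half curve has zero variance are
#' skipped; a neuron with no usable repeat gets NA.
#'
#' @param ds a `cohort_dataset`.
#' @param fov FOV id.
#' @param day_ref reference day (day 5, the last pre-ablation session, in
#'   cross-day use).
#' @param day_other second day, or NULL for same-day reliability.
#' @param neuron_ids neurons to evaluate (typically the responsive ones on
#'   the reference day).
#' @param n_repeats number of random splits, default 10.
#' @param seed RNG seed for the splits.
#' @return data.frame: `neuron_id`, `r` (mean correlation), `n_used` repeats.
#' @export
split_half_tuning_correlation <- function(ds, fov, day_ref, day_other = NULL,
                                          neuron_ids = NULL, n_repeats = 10,
                                          seed = 1L) {
  tt1 <- get_tensor(ds, fov, day_ref)
  tt2 <- if (is.null(day_other)) tt1 else get_tensor(ds, fov, day_other)
  ids <- fov_neurons(ds, fov)$neuron_id
  pres <- get_present(ds, fov, day_ref) &
    (if (is.null(day_other)) TRUE else get_present(ds, fov, day_other))
  keep <- which(if (is.null(neuron_ids)) pres else pres & ids %in% neuron_ids)
  S <- dim(tt1$A)[2]; Tt <- dim(tt1$A)[3]
  half <- floor(Tt / 2)
  sums <- matrix(0, length(keep), 1)
  nuse <- integer(length(keep))
  with_seed(seed_stream(seed, "split", fov, day_ref, day_other %||% "same"), {
    for (rep in seq_len(n_repeats)) {
      pick <- replicate(S, sample.int(Tt, half))  # half x S, per-stimulus split
      h1 <- h2 <- matrix(NA_real_, length(keep), S)
      for (s in seq_len(S)) {
        sel <- pick[, s]
        h1[, s] <- rowMeans(tt1$A[keep, s, sel, drop = FALSE], na.rm = TRUE)
        h2[, s] <- rowMeans(tt2$A[keep, s, -sel, drop = FALSE], na.rm = TRUE)
      }
      for (i in seq_along(keep)) {
        r <- safe_cor(h1[i, ], h2[i, ])
        if (!is.na(r)) {
          sums[i] <- sums[i] + r
          nuse[i] <- nuse[i] + 1L
        }
      }
    }
  })
  data.frame(neuron_id = ids[keep],
             r = ifelse(nuse > 0, sums / pmax(1, nuse), NA_real_),
             n_used = nuse, stringsAsFactors = FALSE)
}

#' Sorted-normalized tuning profiles and tuning width
#'
#' Each responsive neuron's tuning curve is sorted in descending order and
#' normalized by its largest amplitude; profiles are averaged within best
#' response amplitude bins. The tuning width statistic is the normalized
#' amplitude at sorted stimulus index `width_index` (default 15): 0 for a
#' one-hot tuning curve, 1 for flat tuning. Neurons whose maximum amplitude
#' is not positive are excluded.
#'
#' @param curves matrix `[n_neurons, n_stimuli]` of trial-mean amplitudes.
#' @param amp_bin integer bin (1-4) per neuron.
#' @param width_index sorted index of the width statistic, default 15.
#' @return list: `profiles` (per-neuron sorted-normalized matrix), `width`
#'   (per neuron), `bin_profiles` (bin x stimulus mean profile), `bin_width`,
#'   `excluded` (ids of non-positive-peak neurons).
#' @export
tuning_width_profile <- function(curves, amp_bin, width_index = 15) {
  mx <- apply(curves, 1, max)
  ok <- is.finite(mx) & mx > 0
  prof <- t(apply(curves[ok, , drop = FALSE], 1,
                  function(x) sort(x, decreasing = TRUE) / max(x)))
  width <- prof[, width_index]
  bins <- amp_bin[ok]
  bin_profiles <- do.call(rbind, lapply(sort(unique(bins)), function(b) {
    colMeans(prof[bins == b, , drop = FALSE])
  }))
  rownames(bin_profiles) <- sort(unique(bins))
  bin_width <- vapply(split(width, bins), mean, numeric(1))
  list(profiles = prof, width = width, bin_profiles = bin_profiles,
       bin_width = bin_width,
       excluded = rownames(curves)[!ok] %||% character(0))
}

#' Pairwise signal correlations within a FOV
#'
#' Signal correlation is the Pearson correlation of the trial-averaged tuning
#' curves of two responsive neurons. All unordered within-FOV pairs are
#' formed; each pair's amplitude bin is the bin of the mean of the two best
#' amplitudes. Pairs with a constant tuning curve have undefined correlation
#' and are excluded (counted in `n_undefined`).
#'
#' @param curves matrix `[n_neurons, n_stimuli]` (responsive neurons only).
#' @param best_amp best response amplitude per neuron.
#' @param threshold high-correlation cut, default 0.7.
#' @return list: `pairs` data.frame (`id1`, `id2`, `r`, `pair_bin`),
#'   `frac_high_by_bin` (fraction of pairs with `r > threshold` per bin),
#'   `frac_high` overall, `n_undefined`.
#' @export
signal_correlations <- function(curves, best_amp, threshold = 0.7) {
  n <- nrow(curves)
  if (n < 2) {
    dm_stop("driftmap_invalid_argument",
            "signal_correlations: need at least 2 responsive neurons")
  }
  sds <- apply(curves, 1, stats::sd)
  C <- suppressWarnings(stats::cor(t(curves)))
  ut <- which(upper.tri(C), arr.ind = TRUE)
  r <- C[ut]
  undef <- sds[ut[, 1]] == 0 | sds[ut[, 2]] == 0
  pair_amp <- (best_amp[ut[, 1]] + best_amp[ut[, 2]]) / 2
  pairs <- data.frame(
    id1 = rownames(curves)[ut[, 1]], id2 = rownames(curves)[ut[, 2]],
    r = ifelse(undef, NA_real_, r),
    pair_bin = amp_bin_of(pair_amp), stringsAsFactors = FALSE)
  ok <- pairs[!is.na(pairs$r), , drop = FALSE]
  frac_by_bin <- vapply(1:4, function(b) {
    g <- ok[ok$pair_bin == b, , drop = FALSE]
    if (nrow(g) == 0) NA_real_ else mean(g$r > threshold)
  }, numeric(1))
  names(frac_by_bin) <- paste0("bin", 1:4)
  list(pairs = pairs, frac_high_by_bin = frac_by_bin,
       frac_high = if (nrow(ok)) mean(ok$r > threshold) else NA_real_,
       n_undefined = sum(undef))
}

#' Signal-correlation profile of spared neurons against reference tuning
#'
#' Correlates the tuning of every spared neuron on each day with the (frozen)
#' reference tuning curves of the high-category neurons on the reference day,
#' pooling each spared x reference pair as one observation. Neurons are split
#' into group `R5` (responsive on the reference day) and group `G`
#' (unresponsive on the reference day but responsive on at least one other
#' day); neurons responsive on no day belong to neither. Correlations are
#' binned (default -0.6 to 1.0, width 0.2, values below -0.6 clamped into the
#' first bin); per group and day the fraction per bin is reported, along with
#' the baseline-subtracted fraction (baseline = mean of `baseline_days`) and
#' the summary fraction with `r > high_threshold`.
#'
#' By default all spared neurons are profiled each day regardless of that
#' day's responsiveness; `responsive_on_day = TRUE` restricts to neurons
#' responsive on the profiled day.
#'
#' @param ds a `cohort_dataset`.
#' @param resp a `responsiveness_table` covering all days.
#' @param reference data.frame with `neuron_id` and `fov_id` of the
#'   high-category reference neurons.
#' @param spared_ids character vector of spared neuron ids.
#' @param ref_day day the reference curves are frozen at, default 5.
#' @param days days to profile, default all.
#' @param breaks correlation bin edges.
#' @param baseline_days default `c(1, 3)`.
#' @param high_threshold default 0.6.
#' @param responsive_on_day restrict to neurons responsive on the profiled
#'   day (Methods-conformant variant), default FALSE.
#' @return list: `fractions` (day x bin x group array of fractions),
#'   `baseline_subtracted` (same minus baseline), `high_frac` data.frame
#'   (day, group, fraction of pooled pairs with r > threshold), `n_pairs`.
#' @export
reference_correlation_profile <- function(ds, resp, reference, spared_ids,
                                          ref_day = 5, days = ds$days,
                                          breaks = seq(-0.6, 1.0, by = 0.2),
                                          baseline_days = c(1, 3),
                                          high_threshold = 0.6,
                                          responsive_on_day = FALSE) {
  if (nrow(reference) == 0) {
    dm_stop("driftmap_invalid_argument",
            "reference_correlation_profile: empty reference set")
  }
  # group membership from responsiveness history
  rh <- resp[resp$neuron_id %in% spared_ids, , drop = FALSE]
  r5_ids <- unique(rh$neuron_id[rh$day == ref_day & rh$responsive])
  any_ids <- unique(rh$neuron_id[rh$responsive])
  g_ids <- setdiff(any_ids, r5_ids)
  groups <- list(R5 = r5_ids, G = g_ids)

  nb <- length(breaks) - 1
  fr <- array(NA_real_, c(length(days), nb, 2),
              dimnames = list(as.character(days),
                              sprintf("(%.1f,%.1f]", breaks[-length(breaks)],
                                      breaks[-1]),
                              names(groups)))
  high <- expand.grid(day = days, group = names(groups),
                      stringsAsFactors = FALSE)
  high$frac <- NA_real_; high$n_pairs <- 0L

  ref_curves <- list()
  for (fov in unique(reference$fov_id)) {
    ids <- reference$neuron_id[reference$fov_id == fov]
    ref_curves[[fov]] <- tuning_curves(ds, fov, ref_day, neuron_ids = ids)
  }

  for (di in seq_along(days)) {
    day <- days[di]
    pooled <- list(R5 = numeric(0), G = numeric(0))
    for (fov in unique(ds$neurons$fov_id[ds$neurons$neuron_id %in% spared_ids])) {
      rc <- ref_curves[[fov]]
      if (is.null(rc) || nrow(rc) == 0) next
      ids_here <- intersect(spared_ids,
                            fov_neurons(ds, fov)$neuron_id)
      if (responsive_on_day) {
        rd <- resp[resp$day == day & resp$responsive, "neuron_id"]
        ids_here <- intersect(ids_here, rd)
      }
      if (length(ids_here) == 0) next
      cv <- tuning_curves(ds, fov, day, neuron_ids = ids_here)
      if (nrow(cv) == 0) next
      cc <- suppressWarnings(stats::cor(t(cv), t(rc)))  # spared x ref
      for (g in names(groups)) {
        sel <- rownames(cv) %in% groups[[g]]
        if (any(sel)) {
          v <- as.vector(cc[sel, , drop = FALSE])
          pooled[[g]] <- c(pooled[[g]], v[!is.na(v)])
        }
      }
    }
    for (gi in seq_along(groups)) {
      v <- pooled[[names(groups)[gi]]]
      if (length(v) == 0) next
      v <- pmax(v, breaks[1] + 1e-9)  # clamp below-range values into bin 1
      h <- tabulate(findInterval(v, breaks, left.open = TRUE), nbins = nb)
      fr[di, , gi] <- h / length(v)
      row <- high$day == day & high$group == names(groups)[gi]
      high$frac[row] <- mean(v > high_threshold)
      high$n_pairs[row] <- length(v)
    }
  }
  base_idx <- which(days %in% baseline_days)
  base <- apply(fr[base_idx, , , drop = FALSE], c(2, 3), mean)
  bs <- fr
  for (di in seq_along(days)) bs[di, , ] <- fr[di, , ] - base
  list(fractions = fr, baseline_subtracted = bs, high_frac = high,
       groups = groups, breaks = breaks)
}
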