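# Single-neuron statistical front end: raw traces -> trial amplitudes ->
# responsiveness classification.

#' Bundle raw fluorescence traces for one neuron
#'
#' @param soma fluorescence per frame (arbitrary units), sampled at
#'   `frame_rate`.
#' @param neuropil surrounding-neuropil fluorescence, same length.
#' @param contamination_ratio neuropil contamination ratio in `[0, 1]`.
#' @param stimulus_onsets integer matrix `[n_stimuli, n_trials]` of onset
#'   frame indices.
#' @param frame_rate acquisition rate in Hz (fixed at 5 for this pipeline).
#' @return A list of class `trace_bundle`.
#' @export
trace_bundle <- function(soma, neuropil, contamination_ratio,
                         stimulus_onsets, frame_rate = 5) {
  stopifnot(length(soma) == length(neuropil),
            contamination_ratio >= 0, contamination_ratio <= 1)
  if (any(stimulus_onsets < 1) || any(stimulus_onsets > length(soma))) {
    dm_stop("driftmap_invalid_argument",
            "stimulus onsets must lie within the trace")
  }
  structure(list(soma = soma, neuropil = neuropil,
                 contamination_ratio = contamination_ratio,
                 stimulus_onsets = stimulus_onsets,
                 frame_rate = frame_rate),
            class = "trace_bundle")
}

# Moving rank-order filter: q-th percentile over frames [i - before, i + after],
# window truncated at the trace edges.
moving_percentile <- function(x, q = 0.30, before = 100, after = 100) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    stats::quantile(x[max(1, i - before):min(n, i + after)],
                    probs = q, names = FALSE)
  }, numeric(1))
}

#' Compute a neuropil-corrected dF/F0 trace
#'
#' Subtracts the neuropil trace scaled by the contamination ratio, estimates
#' the baseline F0 as a moving rank-order filter (30th percentile of the 200
#' surrounding frames, 100 before and 100 after, truncated at the edges) and
#' returns `dff = (F_corr - F0) / F0`. Frames where F0 <= 0 are flagged
#' invalid and masked (NA) rather than propagated.
#'
#' @param tb a [trace_bundle()].
#' @param percentile baseline percentile, default 0.30.
#' @param window frames on each side of the baseline window, default 100.
#' @return A list of class `dff_trace` with elements `dff` (fractional dF/F0
#'   per frame), `f0`, and `invalid` (logical per frame).
#' @export
compute_dff <- function(tb, percentile = 0.30, window = 100) {
  f_corr <- tb$soma - tb$contamination_ratio * tb$neuropil
  f0 <- moving_percentile(f_corr, q = percentile, before = window,
                          after = window)
  invalid <- !is.finite(f0) | f0 <= 0
  dff <- (f_corr - f0) / f0
  dff[invalid] <- NA_real_
  structure(list(dff = dff, f0 = f0, invalid = invalid,
                 frame_rate = tb$frame_rate,
                 stimulus_onsets = tb$stimulus_onsets),
            class = "dff_trace")
}

#' Extract per-trial response amplitudes from a dF/F trace
#'
#' Amplitude = mean dF/F over the two post-stimulus peak frames (200-400 ms
#' after onset) minus the mean over the two pre-stimulus frames (-200-0 ms).
#' At 5 Hz these windows are exactly two frames each. Trials whose windows
#' fall off the trace (or hit invalid frames) are masked NA.
#'
#' @param dt a `dff_trace` from [compute_dff()].
#' @param onsets optional onset matrix overriding the bundle's.
#' @param scale multiplier applied to the fractional dF/F (default 100, so
#'   amplitudes are in %dF/F as used by the rest of the pipeline).
#' @return A list with matrices `amplitude` and `pre` (`[n_stimuli,
#'   n_trials]`, %dF/F) and `n_masked`.
#' @export
extract_amplitudes <- function(dt, onsets = dt$stimulus_onsets, scale = 100) {
  frames_per_200ms <- round(0.2 * dt$frame_rate)
  n <- length(dt$dff)
  amp <- pre <- matrix(NA_real_, nrow(onsets), ncol(onsets))
  for (s in seq_len(nrow(onsets))) {
    for (tr in seq_len(ncol(onsets))) {
      on <- onsets[s, tr]
      pre_idx <- (on - frames_per_200ms):on
      post_idx <- (on + frames_per_200ms):(on + 2 * frames_per_200ms)
      if (pre_idx[1] < 1 || post_idx[length(post_idx)] > n) next  # masked
      p <- mean(dt$dff[pre_idx]); q <- mean(dt$dff[post_idx])
      if (is.na(p) || is.na(q)) next
      pre[s, tr] <- scale * p
      amp[s, tr] <- scale * (q - p)
    }
  }
  list(amplitude = amp, pre = pre, n_masked = sum(is.na(amp)))
}

#' Exact Wilcoxon signed-rank p-values per neuron and stimulus
#'
#' For every neuron x stimulus cell, compares the trial amplitudes against
#' the paired pre-stimulus values with a Wilcoxon signed-rank test. Zero
#' differences are discarded before ranking. The exact null distribution is
#' used for n <= `exact_max_n` when the absolute differences are tie-free;
#' otherwise a normal approximation with continuity and tie correction is
#' used. Benjamini-Hochberg adjustment is applied across the stimuli of each
#' neuron (cells with fewer than `min_n` usable pairs are excluded from the
#' family and get NA).
#'
#' @param A,pre numeric arrays `[n_neurons, n_stimuli, n_trials]`.
#' @param alternative "two.sided" (default) or "greater".
#' @param exact_max_n largest n for the exact null, default 15.
#' @param min_n minimum usable pairs per cell, default 5.
#' @return list with matrices `p` and `q` (`[n_neurons, n_stimuli]`).
#' @export
signed_rank_pq <- function(A, pre, alternative = c("two.sided", "greater"),
                           exact_max_n = 15, min_n = 5) {
  alternative <- match.arg(alternative)
  stopifnot(identical(dim(A), dim(pre)))
  N <- dim(A)[1]; S <- dim(A)[2]; Tt <- dim(A)[3]
  D <- matrix(A - pre, nrow = N * S)  # cells x trials
  p <- rep(NA_real_, N * S)

  # fast vectorized path: complete, zero-free, tie-free cells with the full
  # trial count share one exact null distribution
  clean <- rowSums(is.na(D) | D == 0) == 0
  if (Tt <= exact_max_n && any(clean)) {
    Dc <- abs(D[clean, , drop = FALSE])
    R <- matrix(1, nrow(Dc), Tt)
    for (i in seq_len(Tt)) {
      for (k in seq_len(Tt)) {
        if (k != i) R[, i] <- R[, i] + (Dc[, k] < Dc[, i]) +
            0.5 * (Dc[, k] == Dc[, i])
      }
    }
    tied <- rowSums(R != round(R)) > 0 |
      apply(Dc, 1, anyDuplicated) > 0
    W <- rowSums(R * (D[clean, , drop = FALSE] > 0))
    p_le <- stats::psignrank(W, Tt)
    p_ge <- 1 - stats::psignrank(W - 1, Tt)
    pf <- if (alternative == "greater") p_ge else pmin(1, 2 * pmin(p_le, p_ge))
    pf[tied] <- NA  # recomputed below
    p[clean] <- pf
  }

  todo <- which(is.na(p))
  for (idx in todo) {
    d <- D[idx, ]
    d <- d[!is.na(d)]
    d <- d[d != 0]  # standard convention: zeros discarded
    if (length(d) < min_n) next
    p[idx] <- signed_rank_p(d, alternative, exact_max_n)
  }
  p <- matrix(p, N, S)
  q <- t(apply(p, 1, function(row) stats::p.adjust(row, method = "BH")))
  if (S == 1) q <- matrix(q, ncol = 1)
  list(p = p, q = q)
}

# p-value for non-zero differences d (zeros already removed).
signed_rank_p <- function(d, alternative = "two.sided", exact_max_n = 15) {
  n <- length(d)
  if (n == 0) return(1)
  a <- abs(d)
  ties <- anyDuplicated(a) > 0
  r <- rank(a)
  W <- sum(r[d > 0])
  if (!ties && n <= exact_max_n) {
    p_le <- stats::psignrank(W, n)
    p_ge <- 1 - stats::psignrank(W - 1, n)
    if (alternative == "greater") return(p_ge)
    return(min(1, 2 * min(p_le, p_ge)))
  }
  # normal approximation with continuity and tie correction (as in the
  # standard large-sample signed-rank test)
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  zval <- function(corr) (W - mu - corr) / sqrt(sig2)
  if (alternative == "greater") return(stats::pnorm(zval(0.5), lower.tail = FALSE))
  z <- (W - mu)
  cc <- sign(z) * 0.5
  min(1, 2 * stats::pnorm(abs((z - cc) / sqrt(sig2)), lower.tail = FALSE))
}

#' Best-response amplitude bin
#'
#' Assigns the four standard best-amplitude categories (cut points 15, 25
#' and 55 %dF/F; left-closed, right-open). Values at or above 1000 clamp
#' into bin 4 with a warning.
#'
#' @param best_amp numeric best response amplitudes (%dF/F).
#' @param edges upper edges of the bins.
#' @return Integer bins 1-4.
#' @export
amp_bin_of <- function(best_amp, edges = c(15, 25, 55, 1000)) {
  bin <- findInterval(best_amp, edges[-length(edges)]) + 1L
  over <- !is.na(best_amp) & best_amp >= edges[length(edges)]
  if (any(over)) {
    warning(sprintf("%d best amplitude(s) above %g %%dF/F clamped into bin 4",
                    sum(over), edges[length(edges)]))
    bin[over] <- length(edges)
  }
  bin
}

#' Classify sound responsiveness of every neuron
#'
#' Runs the signed-rank/Benjamini-Hochberg classification
#' ([signed_rank_pq()]) for each FOV and day of a cohort dataset. A neuron is
#' responsive on a day when any adjusted value falls below `alpha`. The best
#' stimulus is the stimulus with maximal trial-mean amplitude among the
#' significant stimuli only; amplitude bins use the standard cut points
#' 15/25/55 %dF/F (left-closed, right-open; values above 1000 clamp into bin
#' 4 with a warning). Neurons absent on a day (quality gate) get NA rows.
#'
#' @param ds a `cohort_dataset`.
#' @param days subset of days to classify, default all.
#' @param alpha significance level after adjustment, default 0.05.
#' @param alternative sidedness of the signed-rank test, default two-sided.
#' @return data.frame of class `responsiveness_table`: one row per neuron x
#'   day with columns `neuron_id`, `fov_id`, `mouse_id`, `day`, `present`,
#'   `responsive`, `n_sig`, `best_stimulus`, `best_amplitude`, `amp_bin`,
#'   `mean_sig_amp` (mean trial-mean amplitude over significant stimuli),
#'   `mean_amp_all` (over all stimuli) and `min_q`.
#' @export
classify_responsiveness <- function(ds, days = ds$days, alpha = 0.05,
                                    alternative = "two.sided") {
  out <- list()
  for (fov in fov_ids(ds)) {
    nr <- fov_neurons(ds, fov)
    for (day in days) {
      tt <- get_tensor(ds, fov, day)
      pres <- get_present(ds, fov, day)
      pq <- signed_rank_pq(tt$A, tt$pre, alternative = alternative)
      dd <- dim(tt$A)
      mean_amp <- matrix(rowMeans(matrix(tt$A, dd[1] * dd[2]), na.rm = TRUE),
                         dd[1], dd[2])  # N x S
      sig <- !is.na(pq$q) & pq$q < alpha
      n_sig <- rowSums(sig)
      best_stim <- best_amp <- mean_sig <- rep(NA_real_, nrow(nr))
      for (i in seq_len(nrow(nr))) {
        if (n_sig[i] > 0) {
          cand <- which(sig[i, ])
          b <- cand[which.max(mean_amp[i, cand])]
          best_stim[i] <- b
          best_amp[i] <- mean_amp[i, b]
          mean_sig[i] <- mean(mean_amp[i, cand])
        }
      }
      df <- data.frame(
        neuron_id = nr$neuron_id, fov_id = fov, mouse_id = nr$mouse_id,
        day = day, present = pres,
        responsive = pres & n_sig > 0, n_sig = n_sig,
        best_stimulus = best_stim, best_amplitude = best_amp,
        amp_bin = amp_bin_of(best_amp),
        mean_sig_amp = mean_sig,
        mean_amp_all = rowMeans(mean_amp),
        min_q = apply(pq$q, 1, function(x) if (all(is.na(x))) NA_real_
                      else min(x, na.rm = TRUE)),
        stringsAsFactors = FALSE)
      df[!pres, c("responsive")] <- FALSE
      df[!pres, c("n_sig", "best_stimulus", "best_amplitude", "amp_bin",
                  "mean_sig_amp", "mean_amp_all", "min_q")] <- NA
      out[[paste(fov, day)]] <- df
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("responsiveness_table", "data.frame")
  res
}

#' Per-FOV, per-day responsiveness summary
#'
#' @param resp a `responsiveness_table`.
#' @return data.frame per FOV x day: number present, number responsive,
#'   responsive fraction, mean best amplitude and amplitude-bin counts.
#' @export
summarize_responsiveness <- function(resp) {
  sp <- split(resp, list(resp$fov_id, resp$day), drop = TRUE)
  out <- lapply(sp, function(g) {
    rsp <- g[g$responsive %in% TRUE, , drop = FALSE]
    bins <- tabulate(rsp$amp_bin, nbins = 4)
    data.frame(fov_id = g$fov_id[1], day = g$day[1],
               n_present = sum(g$present), n_responsive = nrow(rsp),
               frac_responsive = nrow(rsp) / max(1, sum(g$present)),
               mean_best_amplitude = if (nrow(rsp)) mean(rsp$best_amplitude)
                                     else NA_real_,
               bin1 = bins[1], bin2 = bins[2], bin3 = bins[3], bin4 = bins[4],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$fov_id, res$day), ]
}
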