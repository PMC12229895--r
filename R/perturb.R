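# Bespoke inference machinery: cohort permutation tests, FOV-shuffle null,
# tuning-width scaling simulation, stability overlap, spatial profiles, E/I
# balance.

#' Cohort permutation test on mouse-level statistics
#'
#' Pools the mouse-level values, permutes the cohort labels `n_perm` times
#' and recomputes the between-cohort difference statistic (difference of
#' cohort means for two cohorts; maximum absolute pairwise mean difference
#' for more). The p-value is the add-one-smoothed fraction of null draws at
#' least as extreme (two-sided, by absolute value). Constant pooled values
#' give p = 1.
#'
#' @param values numeric mouse-level statistic values.
#' @param groups cohort label per value (>= 2 cohorts, >= 2 mice each).
#' @param n_perm number of label permutations, default 200.
#' @param seed RNG seed.
#' @return list of class `permutation_result`: `observed`, `null` (length
#'   `n_perm`), `p`, `seed`.
#' @export
permutation_group_test <- function(values, groups, n_perm = 200, seed = 1L) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    dm_stop("driftmap_invalid_argument",
            "permutation_group_test: need >= 2 cohorts with >= 2 mice each")
  }
  stat <- function(v, g) {
    m <- tapply(v, g, mean)
    if (length(m) == 2) unname(m[1] - m[2])
    else max(abs(outer(m, m, `-`)))
  }
  obs <- stat(values, groups)
  if (stats::sd(values) == 0) {
    return(structure(list(observed = obs, null = rep(0, n_perm), p = 1,
                          seed = seed), class = "permutation_result"))
  }
  null <- with_seed(seed_stream(seed, "perm_test"), {
    vapply(seq_len(n_perm), function(i) stat(values, sample(groups)),
           numeric(1))
  })
  p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
  structure(list(observed = obs, null = null, p = p, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed %.4g, %d null draws", x$observed,
              length(x$null)))
  if (!is.null(x$p)) cat(sprintf(", p = %.4g", x$p))
  if (!is.null(x$ci)) cat(sprintf(", 95%% CI [%.4g, %.4g]", x$ci[1], x$ci[2]))
  cat("\n")
  invisible(x)
}

#' FOV-shuffle null for the similarity-matrix off-diagonal mean
#'
#' Destroys local (within-FOV) tuning co-structure while preserving every
#' single-neuron tuning curve: each draw randomly reassigns neurons to
#' pseudo-FOVs of the original sizes, rebuilds the trial-averaged similarity
#' matrix per pseudo-FOV and records the across-FOV mean of the off-diagonal
#' mean. Reported against the observed value with a 95% envelope (2.5/97.5
#' percentiles of the null draws).
#'
#' @param curve_list named list of `[n_neurons x n_stimuli]` trial-averaged
#'   tuning-curve matrices, one per FOV (e.g. from [tuning_curves()]).
#' @param n_shuffle number of shuffle draws, default 500.
#' @param seed RNG seed.
#' @return list of class `permutation_result`: `observed`, `null`, `ci`,
#'   `outside` (is the observed value outside the envelope), `seed`.
#' @export
fov_shuffle_similarity_null <- function(curve_list, n_shuffle = 500,
                                        seed = 1L) {
  sizes <- vapply(curve_list, nrow, integer(1))
  if (length(curve_list) == 1) {
    warning("single FOV: the shuffle is the identity; null is degenerate")
  }
  offdiag_of <- function(m) offdiag_mean(suppressWarnings(stats::cor(m)))
  observed <- mean(vapply(curve_list, offdiag_of, numeric(1)))
  pool <- do.call(rbind, curve_list)
  n <- nrow(pool)
  groups_end <- cumsum(sizes)
  groups_start <- c(1, utils::head(groups_end, -1) + 1)
  null <- with_seed(seed_stream(seed, "fov_shuffle"), {
    vapply(seq_len(n_shuffle), function(i) {
      perm <- sample.int(n)
      mean(vapply(seq_along(sizes), function(g) {
        offdiag_of(pool[perm[groups_start[g]:groups_end[g]], , drop = FALSE])
      }, numeric(1)))
    }, numeric(1))
  })
  # type-6 quantiles interpolate the (n+1)p order statistic, keeping the
  # two-sided envelope's coverage at its nominal level for permutation draws
  ci <- stats::quantile(null, c(0.025, 0.975), names = FALSE, type = 6)
  structure(list(observed = observed, null = null, ci = ci,
                 outside = observed < ci[1] || observed > ci[2], seed = seed),
            class = "permutation_result")
}

#' Tuning-width scaling simulation for the similarity matrix
#'
#' Rescales every neuron's baseline tuning curve so that its
#' sorted-normalized profile follows a target profile (per best-amplitude
#' bin) instead of the bin's baseline profile, preserving each neuron's
#' stimulus order and peak amplitude: sorted value r becomes `value_r *
#' target[r] / baseline_profile[r]`. Ranks where the baseline profile is zero
#' are set to `peak * target[r]` directly. The trial-averaged similarity
#' matrix is rebuilt from the scaled curves and compared with the untouched
#' baseline matrix.
#'
#' @param curves `[n_neurons x n_stimuli]` baseline trial-averaged curves
#'   (responsive neurons).
#' @param amp_bin integer bin (1-4) per neuron.
#' @param target_profiles matrix of target sorted-normalized profiles, one
#'   row per bin (rownames = bin).
#' @param baseline_profiles bin profiles to divide out; default: computed
#'   from `curves` via [tuning_width_profile()] (so a target equal to the
#'   baseline is an identity operation to machine precision).
#' @return list: `matrix` (scaled `similarity_matrix`-style correlation
#'   matrix), `baseline_matrix`, `offdiag`, `baseline_offdiag`,
#'   `scaled_curves`.
#' @export
width_scaling_similarity_sim <- function(curves, amp_bin, target_profiles,
                                         baseline_profiles = NULL) {
  if (is.null(baseline_profiles)) {
    baseline_profiles <- tuning_width_profile(curves, amp_bin)$bin_profiles
  }
  S <- ncol(curves)
  scaled <- curves
  for (i in seq_len(nrow(curves))) {
    b <- as.character(amp_bin[i])
    if (!(b %in% rownames(target_profiles)) ||
        !(b %in% rownames(baseline_profiles))) next
    tgt <- target_profiles[b, ]; base <- baseline_profiles[b, ]
    ord <- order(curves[i, ], decreasing = TRUE)
    v <- curves[i, ord]
    ratio <- ifelse(base != 0, tgt / base, NA)
    newv <- ifelse(is.na(ratio), max(v) * tgt, v * ratio)
    scaled[i, ord] <- newv
  }
  Mb <- suppressWarnings(stats::cor(curves)); diag(Mb) <- 1
  Ms <- suppressWarnings(stats::cor(scaled)); diag(Ms) <- 1
  list(matrix = Ms, baseline_matrix = Mb,
       offdiag = offdiag_mean(Ms), baseline_offdiag = offdiag_mean(Mb),
       scaled_curves = scaled)
}

#' Responsiveness stability across consecutive sessions
#'
#' Fraction of neurons classified sound responsive on both of two consecutive
#' imaging days, computed on the spared neurons. The default denominator is
#' the union of the two days' responsive sets; `"first"` (first day's set)
#' and `"total"` (all neurons present both days) are available.
#'
#' @param resp a `responsiveness_table`.
#' @param spared_ids neurons to include, default all.
#' @param denominator `"union"`, `"first"` or `"total"`.
#' @return data.frame: `day_from`, `day_to`, `overlap` (NA when no neuron is
#'   responsive on either day).
#' @export
stability_overlap <- function(resp, spared_ids = unique(resp$neuron_id),
                              denominator = c("union", "first", "total")) {
  denominator <- match.arg(denominator)
  r <- resp[resp$neuron_id %in% spared_ids, , drop = FALSE]
  days <- sort(unique(r$day))
  out <- lapply(seq_len(length(days) - 1), function(i) {
    d1 <- days[i]; d2 <- days[i + 1]
    s1 <- unique(r$neuron_id[r$day == d1 & r$responsive])
    s2 <- unique(r$neuron_id[r$day == d2 & r$responsive])
    both <- length(intersect(s1, s2))
    denom <- switch(denominator,
                    union = length(union(s1, s2)),
                    first = length(s1),
                    total = length(intersect(
                      r$neuron_id[r$day == d1 & r$present],
                      r$neuron_id[r$day == d2 & r$present])))
    data.frame(day_from = d1, day_to = d2,
               overlap = if (denom == 0) NA_real_ else both / denom)
  })
  do.call(rbind, out)
}

#' Effect size versus distance from the ablated neurons
#'
#' Assigns every spared neuron its 3-d Euclidean distance to the nearest
#' successfully ablated neuron (within its FOV) and averages an effect value
#' per distance bin. Empty bins give NA, not zero.
#'
#' @param ds a `cohort_dataset`.
#' @param plan an `ablation_plan`.
#' @param effect named numeric vector of per-neuron effect values
#'   (names = neuron_id); neurons missing from it are skipped.
#' @param bin_edges distance bin edges in micrometres.
#' @return data.frame: `bin_lo`, `bin_hi`, `n`, `mean_effect`, plus the
#'   per-neuron table as attribute `"per_neuron"`.
#' @export
spatial_effect_profile <- function(ds, plan, effect,
                                   bin_edges = seq(0, 350, by = 50)) {
  abl <- plan$targets[plan$targets$success, , drop = FALSE]
  per <- list()
  for (fov in unique(abl$fov_id)) {
    nrf <- fov_neurons(ds, fov)
    aidx <- match(abl$neuron_id[abl$fov_id == fov], nrf$neuron_id)
    P <- as.matrix(nrf[, c("x", "y", "z")])
    Q <- P[aidx, , drop = FALSE]
    d2 <- outer(rowSums(P^2), rowSums(Q^2), `+`) - 2 * P %*% t(Q)
    dmin <- sqrt(pmax(0, apply(d2, 1, min)))
    keep <- nrf$neuron_id %in% names(effect) & !(seq_len(nrow(nrf)) %in% aidx)
    per[[fov]] <- data.frame(neuron_id = nrf$neuron_id[keep],
                             distance = dmin[keep],
                             effect = unname(effect[nrf$neuron_id[keep]]),
                             stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  bin <- findInterval(per$distance, bin_edges, rightmost.closed = TRUE)
  nb <- length(bin_edges) - 1
  rows <- lapply(seq_len(nb), function(b) {
    sel <- bin == b
    data.frame(bin_lo = bin_edges[b], bin_hi = bin_edges[b + 1], n = sum(sel),
               mean_effect = if (any(sel)) mean(per$effect[sel]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "per_neuron") <- per
  out
}

#' Excitation/inhibition balance of sound-evoked responses
#'
#' Per mouse and day, the "total response" of a cell class is the fraction of
#' responsive neurons times the mean best response amplitude of the
#' responsive ones; the balance is `total_E / (total_E + total_I)` in
#' `[0, 1]`. Missing when both totals are zero.
#'
#' @param resp a `responsiveness_table`.
#' @param inhibitory named logical vector (names = neuron_id).
#' @return data.frame: `mouse_id`, `day`, `total_e`, `total_i`, `balance`.
#' @export
ei_balance <- function(resp, inhibitory) {
  r <- resp[resp$present %in% TRUE, , drop = FALSE]
  r$inhib <- inhibitory[r$neuron_id]
  sp <- split(r, list(r$mouse_id, r$day), drop = TRUE)
  out <- lapply(sp, function(g) {
    total <- function(cls) {
      gg <- g[g$inhib == cls, , drop = FALSE]
      if (nrow(gg) == 0) return(NA_real_)
      rsp <- gg[gg$responsive, , drop = FALSE]
      if (nrow(rsp) == 0) return(0)
      (nrow(rsp) / nrow(gg)) * mean(rsp$best_amplitude)
    }
    te <- total(FALSE); ti <- total(TRUE)
    bal <- if (is.na(te) || is.na(ti) || te + ti == 0) NA_real_
           else te / (te + ti)
    data.frame(mouse_id = g$mouse_id[1], day = g$day[1],
               total_e = te, total_i = ti, balance = bal,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$mouse_id, res$day), ]
}
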