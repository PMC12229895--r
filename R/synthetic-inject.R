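# Ground-truth ablation effects injected into a simulated cohort.

#' Inject microablation (and its network effects) into a simulated cohort
#'
#' Masks the targeted neurons absent from the first post-ablation session
#' onward and perturbs the spared network according to
#' [ablation_effects()], regenerating the post-ablation trial tensors from
#' the (possibly modified) ground-truth tuning curves. Pre-ablation sessions
#' are untouched, and with all effect parameters at their null values the
#' spared data are returned bit-identical (only the target masking is
#' applied).
#'
#' Effect schedules, per spared neuron with spatial weight
#' `w = exp(-d / spatial_scale)` (`d` = distance to the nearest successfully
#' ablated neuron in the FOV):
#' * trial noise s.d. is divided by `1 - reliability_dip * w * exp(-(day -
#'   d1) / recovery_tau)` (`d1` = first post-ablation day), i.e. a transient
#'   fractional SNR drop with exponential recovery;
#' * below-peak tuning entries of neurons responsive before ablation are
#'   multiplied by `1 - (1 - narrowing_factor) * w` (persistent);
#' * the per-session gain rate increases by `gain_boost * w` and the
#'   post-ablation responsiveness chain is re-simulated from the last
#'   pre-ablation state;
#' * newly responsive neurons' tuning latents are mixed with the mean latent
#'   of the ablated targets with weight `gain_alignment * w`;
#' * amplitudes are scaled by `1 +/- ei_shift * w * exp(-(day - d1) /
#'   recovery_tau)` (+ excitatory, - inhibitory).
#'
#' @param ds a simulated `cohort_dataset` (with ground truth).
#' @param plan an [select_targets()] plan whose targets all exist in `ds`.
#' @param effects an [ablation_effects()] list.
#' @return The modified `cohort_dataset` (ground truth updated to match).
#' @export
inject_ablation <- function(ds, plan, effects = ablation_effects()) {
  tr <- attr(ds, "truth")
  if (is.null(tr)) {
    dm_stop("driftmap_unsupported",
            "inject_ablation: dataset carries no ground truth (not simulated)")
  }
  missing <- setdiff(plan$targets$neuron_id, ds$neurons$neuron_id)
  if (length(missing)) {
    dm_stop("driftmap_invalid_argument",
            "inject_ablation: targets absent from dataset: %s",
            paste(missing, collapse = ", "))
  }
  params <- tr$params
  days <- ds$days
  post <- which(days > ds$ablation_day)
  j5 <- max(which(days < ds$ablation_day))  # last pre-ablation session
  d1 <- days[post[1]]

  # mask targeted neurons from the first post-ablation session onward
  for (fov in unique(plan$targets$fov_id)) {
    tids <- plan$targets$neuron_id[plan$targets$fov_id == fov]
    rows <- match(tids, fov_neurons(ds, fov)$neuron_id)
    ds$present[[fov]][rows, as.character(days[post])] <- FALSE
    tr$fov[[fov]]$states[rows, post] <- FALSE
    tr$fov[[fov]]$curves[rows, , post] <- 0
  }

  if (!is_null_effects(effects)) {
    inhib <- ds$neurons$inhibitory
    names(inhib) <- ds$neurons$neuron_id
    for (fov in fov_ids(ds)) {
      tf <- tr$fov[[fov]]
      nrf <- fov_neurons(ds, fov)
      abl_ids <- plan$targets$neuron_id[plan$targets$fov_id == fov &
                                          plan$targets$success]
      if (length(abl_ids) == 0) next
      abl_rows <- match(abl_ids, nrf$neuron_id)
      P <- as.matrix(nrf[, c("x", "y", "z")])
      d2 <- outer(rowSums(P^2), rowSums(P[abl_rows, , drop = FALSE]^2), `+`) -
        2 * P %*% t(P[abl_rows, , drop = FALSE])
      dmin <- sqrt(pmax(0, apply(d2, 1, min)))
      w <- exp(-dmin / effects$spatial_scale)
      w[abl_rows] <- 0  # targets are gone, not perturbed
      N <- nrow(nrf)

      # post-ablation responsiveness chain with boosted gain rate
      if (effects$gain_boost > 0) {
        gain_n <- pmin(1, params$gain_rate + effects$gain_boost * w)
        with_seed(seed_stream(tr$seed, "post_states", fov), {
          prev <- tf$states[, j5]
          for (j in post) {
            u <- stats::runif(N)
            st <- ifelse(prev, u >= params$drop_rate, u < gain_n)
            tgt <- match(plan$targets$neuron_id[plan$targets$fov_id == fov],
                         nrf$neuron_id)
            st[tgt] <- FALSE
            tf$states[, j] <- st
            prev <- st
          }
        })
      }

      newly <- !tf$states[, j5] & rowSums(tf$states[, post, drop = FALSE]) > 0

      # align newly responsive neurons' latents with the ablated mean tuning
      if (effects$gain_alignment > 0 && any(newly)) {
        zref <- apply(tf$z[abl_rows, , j5, drop = FALSE], 2, mean)
        zref <- (zref - mean(zref)) / stats::sd(zref)
        for (j in post) {
          a <- effects$gain_alignment * w
          zj <- tf$z[, , j]
          mixed <- outer(a, zref) + sqrt(1 - a^2) * zj
          zj[newly, ] <- mixed[newly, ]
          tf$z[, , j] <- zj
        }
      }

      resp5 <- tf$states[, j5]
      for (j in post) {
        day <- days[j]
        decay <- exp(-(day - d1) / effects$recovery_tau)
        ei <- 1 + ifelse(inhib[nrf$neuron_id], -1, 1) *
          effects$ei_shift * w * decay
        amp_j <- tf$amp * ei
        cj <- latent_to_curves(tf$z[, , j], tf$offset, amp_j)
        # persistent narrowing of below-peak entries, pre-responsive neurons
        nu <- 1 - (1 - effects$narrowing_factor) * w
        if (effects$narrowing_factor < 1 && any(resp5)) {
          for (i in which(resp5)) {
            pk <- which.max(cj[i, ])
            cj[i, -pk] <- cj[i, -pk] * nu[i]
          }
        }
        cj[!tf$states[, j], ] <- 0
        tf$curves[, , j] <- cj
        dipfrac <- pmin(0.999, effects$reliability_dip * w * decay)
        tf$noise[, j] <- params$noise_sigma / (1 - dipfrac)
      }

      # regenerate post-ablation trial tensors from the modified truth
      S <- dim(tf$curves)[2]; Tt <- dim(ds$tensors[[fov]][[1]]$A)[3]
      for (j in post) {
        day <- days[j]
        arrs <- with_seed(seed_stream(tr$seed, "inject", fov, day), {
          A <- array(stats::rnorm(N * S * Tt, sd = rep(tf$noise[, j], S * Tt)),
                     c(N, S, Tt)) + as.vector(tf$curves[, , j])
          pre <- array(stats::rnorm(N * S * Tt, sd = rep(tf$noise[, j], S * Tt)),
                       c(N, S, Tt))
          list(A = A, pre = pre)
        })
        dimnames(arrs$A) <- dimnames(arrs$pre) <- list(tf$ids, NULL, NULL)
        ds$tensors[[fov]][[as.character(day)]] <-
          trial_tensor(arrs$A, arrs$pre, fov, day)
      }
      tr$fov[[fov]] <- tf
    }
  }
  tr$effects <- effects
  tr$plan_mode <- plan$mode
  attr(ds, "truth") <- tr
  ds
}
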