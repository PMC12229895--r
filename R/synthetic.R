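# Synthetic cohort generator with exportable ground truth.
#
# The generator produces trial-amplitude tensors directly (additive Gaussian
# trial noise on amplitude); raw-trace simulation is a thin optional layer in
# traces.R used only to exercise the event-extraction operations.

#' Simulation parameters for a synthetic cohort
#'
#' Defaults emulate the longitudinal imaging conditions the pipeline was
#' designed for: cohorts of 10 mice with 7 fields of view each, 140-180
#' tracked neurons per FOV of which ~12% are sound responsive and ~10%
#' inhibitory (with broader tuning), 34 stimuli x 10 trials x 7 sessions,
#' log-normal best-amplitude marginal calibrated so the four amplitude bins
#' (cut points 15/25/55 %dF/F) each hold roughly a quarter of responsive
#' neurons, and gradual symmetric tuning drift.
#'
#' Tuning latents are built from `k_latent` FOV-shared factors plus private
#' components (`latent_weight` is the shared variance fraction), which gives
#' the within-FOV signal-correlation excess that the FOV-shuffle null detects.
#' Each neuron's latent evolves as a stationary AR(1) across sessions with
#' per-2-day retention `drift_rho`; responsiveness follows a drop/gain Markov
#' chain started at its stationary distribution so day summaries are
#' trend-free without ablation.
#'
#' @param n_mice number of mice.
#' @param n_fov_per_mouse fields of view per mouse.
#' @param n_neurons_range inclusive range neurons per FOV are drawn from.
#' @param p_responsive stationary probability of being sound responsive.
#' @param p_inhibitory probability a neuron is inhibitory.
#' @param amp_meanlog,amp_sdlog log-normal parameters of the per-neuron
#'   amplitude scale (%dF/F).
#' @param k_latent number of FOV-shared tuning factors.
#' @param latent_weight fraction of tuning variance carried by shared factors.
#' @param stim_structure_weight fraction of tuning variance carried by the
#'   fixed stimulus-similarity kernel (tonotopic smoothness across the tone
#'   ladder plus a common complex-sound component); this is what makes the
#'   population-level representational map reproducible across days, FOVs and
#'   neuron subsets. `latent_weight + stim_structure_weight` must be <= 1.
#' @param latent_loading_mean mean of the (Gaussian, unit-variance) neuron
#'   loadings on the FOV-shared factors. A positive mean gives each FOV a
#'   regional tuning bias (a nonzero FOV-mean tuning profile), so shuffling
#'   neurons across FOVs mixes differently-biased subpopulations and lowers
#'   the similarity-matrix off-diagonal — the signature the FOV-shuffle null
#'   is built to detect.
#' @param drift_rho per-2-day tuning retention in `[0, 1]`.
#' @param drop_rate per-session probability responsive -> nonresponsive.
#' @param gain_rate per-session probability nonresponsive -> responsive;
#'   default `NULL` picks the rate that makes `p_responsive` stationary.
#' @param noise_sigma s.d. of additive trial noise (%dF/F).
#' @param tuning_offset mean shift of the tuning latent controlling baseline
#'   tuning width (larger = broader).
#' @param inhibitory_width_factor multiplier on `tuning_offset` for
#'   inhibitory neurons (>= 1, broader tuning).
#' @param seed integer; fully determines the simulated dataset.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_mice = 10, n_fov_per_mouse = 7,
                       n_neurons_range = c(140, 180),
                       p_responsive = 0.12, p_inhibitory = 0.10,
                       amp_meanlog = log(25), amp_sdlog = 0.963,
                       k_latent = 5, latent_weight = 0.25,
                       stim_structure_weight = 0.35, latent_loading_mean = 0.5,
                       drift_rho = 0.85, drop_rate = 0.25, gain_rate = NULL,
                       noise_sigma = 8, tuning_offset = 0.6,
                       inhibitory_width_factor = 1.5, seed = 1L) {
  stopifnot(p_responsive >= 0, p_responsive <= 1,
            p_inhibitory >= 0, p_inhibitory <= 1,
            drift_rho >= 0, drift_rho <= 1,
            drop_rate >= 0, drop_rate <= 1,
            latent_weight >= 0, stim_structure_weight >= 0,
            latent_weight + stim_structure_weight <= 1,
            inhibitory_width_factor >= 1, noise_sigma >= 0)
  if (is.null(gain_rate)) {
    gain_rate <- if (p_responsive >= 1) 1
                 else drop_rate * p_responsive / (1 - p_responsive)
  }
  stopifnot(gain_rate >= 0, gain_rate <= 1)
  structure(list(n_mice = n_mice, n_fov_per_mouse = n_fov_per_mouse,
                 n_neurons_range = n_neurons_range,
                 p_responsive = p_responsive, p_inhibitory = p_inhibitory,
                 amp_meanlog = amp_meanlog, amp_sdlog = amp_sdlog,
                 k_latent = k_latent, latent_weight = latent_weight,
                 stim_structure_weight = stim_structure_weight,
                 latent_loading_mean = latent_loading_mean,
                 drift_rho = drift_rho, drop_rate = drop_rate,
                 gain_rate = gain_rate, noise_sigma = noise_sigma,
                 tuning_offset = tuning_offset,
                 inhibitory_width_factor = inhibitory_width_factor,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Microablation effect parameters for the generator
#'
#' Encodes the phenomenology the pipeline is meant to detect after targeted
#' microablation; all effects vanish at their defaults (null ablation), apply
#' only to post-ablation sessions, and are scaled per neuron by
#' `exp(-d / spatial_scale)` where `d` is the 3-d distance to the nearest
#' successfully ablated neuron.
#'
#' @param reliability_dip fractional increase in trial noise s.d. on the first
#'   post-ablation day (0 = none), decaying with `recovery_tau`.
#' @param recovery_tau recovery time constant in days for transient effects.
#' @param narrowing_factor multiplicative compression (< 1 narrows) of the
#'   below-peak tuning entries of neurons responsive before ablation;
#'   persistent once applied.
#' @param gain_boost additive increase of the per-session gain rate after
#'   ablation.
#' @param gain_alignment correlation in `[0, 1]` of newly responsive neurons'
#'   tuning latent with the mean latent of the ablated targets.
#' @param ei_shift transient fractional amplitude asymmetry: excitatory
#'   amplitudes scaled by `1 + ei_shift`, inhibitory by `1 - ei_shift`,
#'   decaying with `recovery_tau`.
#' @param spatial_scale length scale (um) of the exponential spatial decay of
#'   all effects around ablated neurons.
#' @return A list of class `ablation_effects`.
#' @export
ablation_effects <- function(reliability_dip = 0, recovery_tau = 2,
                             narrowing_factor = 1, gain_boost = 0,
                             gain_alignment = 0, ei_shift = 0,
                             spatial_scale = 100) {
  stopifnot(reliability_dip >= 0, recovery_tau > 0,
            narrowing_factor > 0, narrowing_factor <= 1,
            gain_boost >= 0, gain_alignment >= 0, gain_alignment <= 1,
            abs(ei_shift) < 1, spatial_scale > 0)
  structure(list(reliability_dip = reliability_dip,
                 recovery_tau = recovery_tau,
                 narrowing_factor = narrowing_factor,
                 gain_boost = gain_boost, gain_alignment = gain_alignment,
                 ei_shift = ei_shift, spatial_scale = spatial_scale),
            class = "ablation_effects")
}

is_null_effects <- function(fx) {
  fx$reliability_dip == 0 && fx$narrowing_factor == 1 &&
    fx$gain_boost == 0 && fx$gain_alignment == 0 && fx$ei_shift == 0
}

#' Fixed stimulus-similarity kernel of the generator
#'
#' Correlation structure imposed on every neuron's tuning latent: pure tones
#' decorrelate smoothly along the tone ladder (`exp(-distance_octaves /
#' ell)`), complex sounds share a common component (`cs_cor`), and the two
#' classes are weakly related (`pt_cs_cor`). The kernel is projected onto the
#' positive semi-definite cone and rescaled to unit diagonal.
#'
#' @param stimuli a [build_stimulus_set()] table.
#' @param ell tonotopic correlation length in octaves.
#' @param cs_cor correlation between distinct complex sounds.
#' @param pt_cs_cor correlation between tones and complex sounds.
#' @return list: `K` (S x S correlation matrix), `A` (factor with
#'   `A %*% t(A) = K`).
#' @export
stimulus_similarity_kernel <- function(stimuli, ell = 0.5, cs_cor = 0.4,
                                       pt_cs_cor = 0.15) {
  S <- nrow(stimuli)
  is_pt <- stimuli$class == "PT"
  K <- matrix(pt_cs_cor, S, S)
  oct <- log2(stimuli$pt_frequency[is_pt])
  K[is_pt, is_pt] <- exp(-abs(outer(oct, oct, `-`)) / ell)
  K[!is_pt, !is_pt] <- cs_cor
  diag(K) <- 1
  eg <- eigen(K, symmetric = TRUE)
  lam <- pmax(eg$values, 1e-8)
  Kp <- eg$vectors %*% (lam * t(eg$vectors))
  d <- sqrt(diag(Kp))
  Kp <- Kp / outer(d, d)
  eg <- eigen(Kp, symmetric = TRUE)
  A <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  list(K = Kp, A = A)
}

# Tuning curve from latent: positive affine map so Pearson correlations
# between days equal correlations of the latents, and the peak equals the
# neuron's amplitude scale. rows = neurons.
latent_to_curves <- function(z, offset, amp) {
  zz <- sweep(z, 1, offset, `+`)
  mx <- apply(zz, 1, max)
  mx[mx <= 0] <- 1  # degenerate latent; curve stays on the amp scale
  amp * zz / mx
}

#' Simulate a synthetic cohort dataset
#'
#' Generates a full `cohort_dataset` (trial tensors, presence masks, neuron
#' records, stimulus set) with ground truth attached for
#' [export_truth()] and parameter-recovery tests. Trial amplitudes are
#' `tuning + Gaussian noise`; pre-stimulus baselines are zero-mean noise with
#' the same s.d. All randomness derives from `params$seed` through named
#' sub-streams per mouse/FOV/day.
#'
#' @param params a [sim_params()] list.
#' @param cohort cohort label applied to all simulated mice.
#' @return A `cohort_dataset` with a ground-truth attribute.
#' @export
simulate_cohort <- function(params = sim_params(), cohort = "control") {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_mice < 1 || params$n_fov_per_mouse < 1 ||
      params$n_neurons_range[1] < 1) {
    dm_stop("driftmap_invalid_argument",
            "simulate_cohort: need at least one mouse, FOV and neuron")
  }
  days <- default_days()
  nd <- length(days)
  stimuli <- build_stimulus_set()
  S <- nrow(stimuli); Tt <- 10L
  kern <- stimulus_similarity_kernel(stimuli)
  neuron_tabs <- list(); tensors <- list(); present <- list(); truth_fov <- list()

  for (mi in seq_len(params$n_mice)) {
    mouse <- sprintf("m%02d", mi)
    for (fi in seq_len(params$n_fov_per_mouse)) {
      fov <- sprintf("%s_f%d", mouse, fi)
      fseed <- seed_stream(params$seed, "fov", fov)
      fovsim <- with_seed(fseed, simulate_fov(params, fov, mouse, cohort,
                                              days, S, Tt, kern$A))
      neuron_tabs[[fov]] <- fovsim$neurons
      tensors[[fov]] <- fovsim$tensor
      present[[fov]] <- fovsim$present
      truth_fov[[fov]] <- fovsim$truth
    }
  }
  neurons <- do.call(rbind, neuron_tabs)
  rownames(neurons) <- NULL
  class(neurons) <- c("neuron_records", "data.frame")
  ds <- cohort_dataset(neurons = neurons, tensors = tensors, present = present)
  attr(ds, "truth") <- list(seed = params$seed, params = params,
                            effects = NULL, fov = truth_fov)
  ds
}

# One FOV: latent evolution, states, curves, trial tensors. Runs under the
# FOV's own RNG stream. `KA` is the factor of the stimulus-similarity kernel.
simulate_fov <- function(params, fov, mouse, cohort, days, S, Tt, KA) {
  nd <- length(days)
  N <- if (params$n_neurons_range[1] == params$n_neurons_range[2]) {
    params$n_neurons_range[1]
  } else {
    sample(params$n_neurons_range[1]:params$n_neurons_range[2], 1)
  }
  ids <- sprintf("%s_n%03d", fov, seq_len(N))
  inhib <- stats::runif(N) < params$p_inhibitory
  offset <- params$tuning_offset *
    ifelse(inhib, params$inhibitory_width_factor, 1)
  amp <- stats::rlnorm(N, params$amp_meanlog, params$amp_sdlog)
  # positions in a 367 x 367 x 200 um slab
  pos <- cbind(x = stats::runif(N, 0, 367), y = stats::runif(N, 0, 367),
               z = stats::runif(N, 0, 200))

  k <- params$k_latent; w <- params$latent_weight
  sw <- params$stim_structure_weight
  # nonnegative factor loadings: locally shared tuning raises the similarity
  # matrix off-diagonal within a FOV, which the FOV-shuffle null removes
  L <- if (k > 0) matrix(abs(stats::rnorm(S * k)), S, k) else NULL

  # AR(1) evolution of three latent components: stimulus-structured (through
  # the kernel factor KA), FOV-shared loadings b (k-dim) and private e
  # (S-dim); steps scale with the day gap (drift_rho is per 2 days).
  z <- array(NA_real_, c(N, S, nd))
  lm0 <- params$latent_loading_mean
  b <- if (k > 0) matrix(stats::rnorm(N * k), N, k) + lm0 else NULL
  e <- matrix(stats::rnorm(N * S), N, S)
  u <- matrix(stats::rnorm(N * S), N, S)
  mix <- function(b, e, u) {
    shared <- if (k > 0) tcrossprod(b, L) / sqrt(k) else 0
    sqrt(sw) * tcrossprod(u, KA) + sqrt(w) * shared + sqrt(1 - w - sw) * e
  }
  z[, , 1] <- mix(b, e, u)
  for (j in 2:nd) {
    rho <- params$drift_rho^((days[j] - days[j - 1]) / 2)
    if (k > 0) {
      b <- lm0 + rho * (b - lm0) +
        sqrt(1 - rho^2) * matrix(stats::rnorm(N * k), N, k)
    }
    e <- rho * e + sqrt(1 - rho^2) * matrix(stats::rnorm(N * S), N, S)
    u <- rho * u + sqrt(1 - rho^2) * matrix(stats::rnorm(N * S), N, S)
    z[, , j] <- mix(b, e, u)
  }

  # responsiveness Markov chain, started at its stationary distribution
  states <- matrix(FALSE, N, nd)
  states[, 1] <- stats::runif(N) < params$p_responsive
  for (j in 2:nd) {
    u <- stats::runif(N)
    states[, j] <- ifelse(states[, j - 1],
                          u >= params$drop_rate,   # stays responsive
                          u < params$gain_rate)    # gains responsiveness
  }

  curves <- array(0, c(N, S, nd))
  for (j in seq_len(nd)) {
    cj <- latent_to_curves(z[, , j], offset, amp)
    cj[!states[, j], ] <- 0
    curves[, , j] <- cj
  }

  noise <- matrix(params$noise_sigma, N, nd)  # per-neuron per-day trial sd
  tensor <- list()
  for (j in seq_len(nd)) {
    day <- days[j]
    dseed <- seed_stream(params$seed, "trials", fov, day)
    arrs <- with_seed(dseed, {
      A <- array(stats::rnorm(N * S * Tt, sd = rep(noise[, j], S * Tt)),
                 c(N, S, Tt)) + as.vector(curves[, , j])
      pre <- array(stats::rnorm(N * S * Tt, sd = rep(noise[, j], S * Tt)),
                   c(N, S, Tt))
      list(A = A, pre = pre)
    })
    dimnames(arrs$A) <- dimnames(arrs$pre) <- list(ids, NULL, NULL)
    tensor[[as.character(day)]] <- trial_tensor(arrs$A, arrs$pre, fov, day)
  }

  pm <- matrix(TRUE, N, nd, dimnames = list(ids, as.character(days)))
  list(
    neurons = neuron_records(ids, fov, mouse, cohort,
                             pos[, 1], pos[, 2], pos[, 3], inhib),
    tensor = tensor,
    present = pm,
    truth = list(curves = curves, states = states, z = z, noise = noise,
                 amp = amp, offset = offset, ids = ids)
  )
}

#' Export the generator's ground truth
#'
#' Per neuron and day: true responsiveness state, true trial-noise s.d., true
#' signal-to-noise ratio (s.d. of the true tuning curve over trial noise) and
#' the true tuning curve (columns `s1..s34`). Only available for simulated
#' datasets.
#'
#' @param ds a simulated `cohort_dataset`.
#' @return A data.frame keyed by `neuron_id` and `day`.
#' @export
export_truth <- function(ds) {
  tr <- attr(ds, "truth")
  if (is.null(tr)) {
    dm_stop("driftmap_unsupported",
            "export_truth: dataset carries no ground truth (not simulated)")
  }
  days <- ds$days
  out <- list()
  for (fov in names(tr$fov)) {
    tf <- tr$fov[[fov]]
    N <- length(tf$ids)
    for (j in seq_along(days)) {
      cj <- tf$curves[, , j, drop = FALSE]
      dim(cj) <- c(N, dim(tf$curves)[2])
      sig <- apply(cj, 1, stats::sd)
      df <- data.frame(neuron_id = tf$ids, day = days[j],
                       responsive_state = tf$states[, j],
                       noise_sigma = tf$noise[, j],
                       snr = sig / tf$noise[, j],
                       stringsAsFactors = FALSE)
      colnames(cj) <- sprintf("s%d", seq_len(ncol(cj)))
      out[[paste(fov, j)]] <- cbind(df, cj)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
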