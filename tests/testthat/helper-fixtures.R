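# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small simulated cohort used by many tests.
sim_small <- function() {
  cached("sim_small", simulate_cohort(
    sim_params(n_mice = 1, n_fov_per_mouse = 2, n_neurons_range = c(60, 60),
               seed = 42L)))
}

resp_small <- function() {
  cached("resp_small", classify_responsiveness(sim_small()))
}

# Build a single-FOV cohort dataset from explicit per-day tuning curves.
# curves: list (one per day) of N x S matrices, or a single matrix reused for
# all days. Trial amplitudes are curve + noise_sigma * N(0,1); pre-stimulus
# values are pure noise. Positions on a grid spaced `spacing` um apart.
toy_dataset <- function(curves, noise_sigma = 0, n_trials = 10, seed = 1,
                        inhibitory = NULL, spacing = 50,
                        days = default_days()) {
  if (is.matrix(curves)) curves <- rep(list(curves), length(days))
  N <- nrow(curves[[1]]); S <- ncol(curves[[1]])
  stopifnot(length(curves) == length(days))
  ids <- sprintf("toy_n%03d", seq_len(N))
  if (is.null(inhibitory)) inhibitory <- rep(FALSE, N)
  grid <- expand.grid(x = seq(0, by = spacing, length.out = ceiling(sqrt(N))),
                      y = seq(0, by = spacing, length.out = ceiling(sqrt(N))))
  nr <- neuron_records(ids, "toy_f1", "toy_m1", "control",
                       grid$x[seq_len(N)], grid$y[seq_len(N)], rep(0, N),
                       inhibitory)
  set.seed(seed)
  tens <- list()
  for (j in seq_along(days)) {
    A <- array(rnorm(N * S * n_trials, sd = noise_sigma), c(N, S, n_trials)) +
      as.vector(curves[[j]])
    pre <- array(rnorm(N * S * n_trials, sd = noise_sigma), c(N, S, n_trials))
    dimnames(A) <- dimnames(pre) <- list(ids, NULL, NULL)
    tens[[as.character(days[j])]] <- trial_tensor(A, pre, "toy_f1", days[j])
  }
  pm <- matrix(TRUE, N, length(days), dimnames = list(ids, as.character(days)))
  stimuli <- if (S == 34) build_stimulus_set() else
    build_stimulus_set(n_pt = S, n_cs = 0)
  cohort_dataset(nr, list(toy_f1 = tens), list(toy_f1 = pm), stimuli = stimuli,
                 days = days)
}

# Exact two-sided signed-rank p-value by brute-force enumeration of all 2^n
# sign assignments (tie-free |d| assumed). Independent oracle for the exact
# test path.
enumerate_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  p_le <- mean(W_all <= W_obs)
  p_ge <- mean(W_all >= W_obs)
  min(1, 2 * min(p_le, p_ge))
}
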