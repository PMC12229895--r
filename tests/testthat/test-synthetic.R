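test_that("the generator is fully determined by its seed", {
  p <- sim_params(n_mice = 1, n_fov_per_mouse = 1,
                  n_neurons_range = c(30, 40), seed = 9L)
  d1 <- simulate_cohort(p)
  d2 <- simulate_cohort(p)
  fov <- fov_ids(d1)[1]
  for (day in c(1, 7, 15)) {
    expect_identical(get_tensor(d1, fov, day)$A, get_tensor(d2, fov, day)$A)
  }
  expect_identical(d1$neurons, d2$neurons)
  d3 <- simulate_cohort(sim_params(n_mice = 1, n_fov_per_mouse = 1,
                                   n_neurons_range = c(30, 40), seed = 10L))
  expect_false(identical(get_tensor(d1, fov, 1)$A, get_tensor(d3, fov, 1)$A))
  expect_error(simulate_cohort(sim_params(n_mice = 0)),
               class = "driftmap_invalid_argument")
})

test_that("frozen tuning (rho = 1, no noise) gives cross-day correlation 1", {
  p <- sim_params(n_mice = 1, n_fov_per_mouse = 1,
                  n_neurons_range = c(40, 40), drift_rho = 1, noise_sigma = 0,
                  drop_rate = 0, p_responsive = 0.5, seed = 11L)
  ds <- simulate_cohort(p)
  fov <- fov_ids(ds)[1]
  tr <- export_truth(ds)
  resp_ids <- unique(tr$neuron_id[tr$responsive_state & tr$day == 5])
  c1 <- tuning_curves(ds, fov, 1, neuron_ids = resp_ids)
  c15 <- tuning_curves(ds, fov, 15, neuron_ids = resp_ids)
  for (id in rownames(c1)) {
    expect_equal(cor(c1[id, ], c15[id, ]), 1, tolerance = 1e-9)
  }
})

test_that("truth export is bijective with the neuron records and reproduces
           the generator's state chain and noise schedule", {
  ds <- sim_small()
  tr <- export_truth(ds)
  expect_setequal(unique(tr$neuron_id), ds$neurons$neuron_id)
  expect_equal(nrow(tr), nrow(ds$neurons) * length(ds$days))
  p <- attr(ds, "truth")$params
  expect_true(all(tr$noise_sigma == p$noise_sigma))
  # states match the stored chain
  tf <- attr(ds, "truth")$fov[[fov_ids(ds)[1]]]
  sub <- tr[tr$neuron_id %in% tf$ids, ]
  for (j in seq_along(ds$days)) {
    expect_equal(sub$responsive_state[sub$day == ds$days[j]],
                 unname(tf$states[, j]))
  }
  # snr column = sd(true curve) / noise
  i <- which(tf$states[, 1])[1]
  expect_equal(sub$snr[sub$day == 1][i],
               sd(tf$curves[i, , 1]) / p$noise_sigma)
  # error on a dataset without ground truth
  ds2 <- ds; attr(ds2, "truth") <- NULL
  expect_error(export_truth(ds2), class = "driftmap_unsupported")
})

test_that("classified responsive fraction matches a Monte-Carlo-calibrated
           expectation at high SNR", {
  # at high SNR essentially every truly responsive neuron is detected, and
  # the per-neuron false-positive rate under BH is ~alpha; the expected
  # measured fraction is p + (1 - p) * fpr with both terms estimated from
  # the generator's own truth labels
  p <- sim_params(n_mice = 1, n_fov_per_mouse = 4,
                  n_neurons_range = c(120, 120), noise_sigma = 3,
                  seed = 13L)
  ds <- simulate_cohort(p)
  tr <- export_truth(ds)
  resp <- classify_responsiveness(ds, days = c(3, 5))
  m <- merge(resp, tr[, c("neuron_id", "day", "responsive_state")],
             by = c("neuron_id", "day"))
  sens <- mean(m$responsive[m$responsive_state])
  fpr <- mean(m$responsive[!m$responsive_state])
  expect_gt(sens, 0.95)       # high SNR: detection nearly certain
  expect_lt(fpr, 0.05 + 0.02) # BH family-wise error ~alpha under the null
  frac <- mean(m$responsive)
  expected <- 0.12 * sens + 0.88 * fpr
  n <- nrow(m)
  expect_lt(abs(frac - expected), 3 * sqrt(0.12 * 0.88 / n) + 0.02)
})

test_that("stationarity: per-day summaries are trend-free without ablation", {
  p <- sim_params(n_mice = 1, n_fov_per_mouse = 3,
                  n_neurons_range = c(100, 100), seed = 14L)
  ds <- simulate_cohort(p)
  tr <- export_truth(ds)
  # true responsive fraction per day has no trend (Markov chain stationary)
  frac <- tapply(tr$responsive_state, tr$day, mean)
  fit <- lm(frac ~ as.numeric(names(frac)))
  ci <- confint(fit)[2, ]
  expect_true(ci[1] < 0 && ci[2] > 0)
  # drift symmetry: cross-day tuning correlation depends only on the day gap
  tf <- attr(ds, "truth")$fov[[1]]
  mean_cor <- function(j1, j2) {
    mean(sapply(seq_len(nrow(tf$z)), function(i) {
      cor(tf$z[i, , j1], tf$z[i, , j2])
    }))
  }
  # day pairs (1,5) and (5,9): both 2 sessions apart, 4 days
  expect_equal(mean_cor(1, 3), mean_cor(3, 5), tolerance = 0.05)
  # larger gaps decorrelate more
  expect_gt(mean_cor(1, 2), mean_cor(1, 4))
})

test_that("amplitude-bin marginal puts roughly a quarter of responsive
           neurons in each printed bin", {
  p <- sim_params(n_mice = 2, n_fov_per_mouse = 3, seed = 15L)
  ds <- simulate_cohort(p)
  tr <- export_truth(ds)
  tr5 <- tr[tr$day == 5 & tr$responsive_state, ]
  best <- apply(as.matrix(tr5[, sprintf("s%d", 1:34)]), 1, max)
  occ <- table(cut(best, c(0, 15, 25, 55, Inf))) / length(best)
  # mirror the reported spread: each bin 25% within ~7 points
  expect_true(all(abs(occ - 0.25) < 0.08))
})

test_that("null-effect injection only masks targets, leaving spared data
           bit-identical", {
  ds <- sim_small()
  resp <- resp_small()
  plan <- suppressWarnings(select_targets(ds, resp, "responsive",
                                          n_per_fov = 4))
  ds2 <- inject_ablation(ds, plan, ablation_effects())
  fov <- fov_ids(ds)[1]
  expect_identical(get_tensor(ds2, fov, 7)$A, get_tensor(ds, fov, 7)$A)
  tids <- plan$targets$neuron_id[plan$targets$fov_id == fov]
  expect_true(all(!get_present(ds2, fov, 7)[tids]))
  expect_true(all(!get_present(ds2, fov, 15)[tids]))
  expect_true(all(get_present(ds2, fov, 5)[tids]))
  # unknown target -> classed error listing the id
  bad <- plan; bad$targets$neuron_id[1] <- "ghost"
  err <- tryCatch(inject_ablation(ds, bad, ablation_effects()),
                  error = function(e) e)
  expect_s3_class(err, "driftmap_invalid_argument")
  expect_match(conditionMessage(err), "ghost")
})

test_that("reliability dip lowers day-7 split-half reliability and recovers
           by day 11; pre-ablation days untouched", {
  p <- sim_params(n_mice = 1, n_fov_per_mouse = 3,
                  n_neurons_range = c(120, 120), seed = 16L)
  ds <- simulate_cohort(p, cohort = "responsive_ablation")
  resp <- classify_responsiveness(ds, days = c(3, 5))
  plan <- select_targets(ds, resp, "responsive", n_per_fov = 6)
  fx <- ablation_effects(reliability_dip = 0.6, recovery_tau = 2,
                         spatial_scale = 1e6)  # spatially uniform dip
  ds2 <- inject_ablation(ds, plan, fx)
  fov <- fov_ids(ds)[1]
  expect_identical(get_tensor(ds2, fov, 3)$A, get_tensor(ds, fov, 3)$A)

  spared <- setdiff(ds$neurons$neuron_id, plan$targets$neuron_id)
  respd <- classify_responsiveness(ds2)
  rel <- cohort_reliability(ds2, respd, spared_ids = spared)
  rel_day <- tapply(rel$r, rel$day, mean)
  base <- mean(rel_day[c("1", "3", "5")])
  # noise sd is divided by (1 - dip * exp(-(day - 7)/tau)): a clear day-7
  # dip that has decayed to ~8% extra noise by day 11
  expect_lt(rel_day["7"], base * 0.85)
  expect_gt(rel_day["11"], base * 0.93)  # recovered within tolerance
  expect_gt(rel_day["15"], base * 0.93)
})

test_that("tuning alignment of newly responsive neurons raises their
           correlation to the ablated reference tuning", {
  p <- sim_params(n_mice = 1, n_fov_per_mouse = 3,
                  n_neurons_range = c(120, 120), seed = 17L)
  ds <- simulate_cohort(p, cohort = "responsive_ablation")
  resp <- classify_responsiveness(ds, days = c(3, 5))
  plan <- select_targets(ds, resp, "responsive", n_per_fov = 6)
  mean_align <- function(alignment) {
    fx <- ablation_effects(gain_alignment = alignment, spatial_scale = 1e6)
    ds2 <- inject_ablation(ds, plan, fx)
    tru <- attr(ds2, "truth")
    vals <- c()
    for (fov in fov_ids(ds2)) {
      tf <- tru$fov[[fov]]
      abl <- match(plan$targets$neuron_id[plan$targets$fov_id == fov],
                   tf$ids)
      zref <- apply(tf$z[abl, , 3, drop = FALSE], 2, mean)
      newly <- !tf$states[, 3] & rowSums(tf$states[, 4:7, drop = FALSE]) > 0
      newly[abl] <- FALSE
      for (j in 4:7) {
        on <- which(newly & tf$states[, j])
        vals <- c(vals, apply(tf$curves[on, , j, drop = FALSE], 1,
                              function(v) cor(v, zref)))
      }
    }
    mean(vals)
  }
  expect_gt(mean_align(0.8), mean_align(0) + 0.2)
})
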