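# Toy responsiveness tables with controlled amplitudes for selection tests.
toy_resp <- function(amps3, amps5, responsive3, responsive5,
                     fov = "f1", mouse = "m1") {
  n <- length(amps3)
  ids <- sprintf("n%02d", seq_len(n))
  mk <- function(day, amp, rsp) {
    data.frame(neuron_id = ids, fov_id = fov, mouse_id = mouse, day = day,
               present = TRUE, responsive = rsp, n_sig = as.integer(rsp),
               best_stimulus = 1, best_amplitude = amp,
               amp_bin = amp_bin_of(abs(amp)), mean_sig_amp = amp,
               mean_amp_all = amp, min_q = ifelse(rsp, 0.01, 0.5),
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(3, amps3, responsive3), mk(5, amps5, responsive5))
  class(out) <- c("responsiveness_table", "data.frame")
  out
}

toy_ds_for <- function(resp, spacing = 100) {
  n <- length(unique(resp$neuron_id))
  ds <- toy_dataset(matrix(0, n, 34), spacing = spacing)
  ds$neurons$neuron_id <- unique(resp$neuron_id)
  ds$neurons$fov_id <- resp$fov_id[1]
  rownames(ds$present[[1]]) <- ds$neurons$neuron_id
  names(ds$tensors) <- names(ds$present) <- resp$fov_id[1]
  ds
}

test_that("responsive-mode selection merges the two baseline days, sorts by
           amplitude and deduplicates keeping the higher rank", {
  # n1 responsive both days (30, 25); n2 only day 3 (28); n3 only day 5 (27)
  amps3 <- c(30, 28, NA, 5); amps5 <- c(25, NA, 27, 6)
  r3 <- c(TRUE, TRUE, FALSE, FALSE); r5 <- c(TRUE, FALSE, TRUE, FALSE)
  resp <- toy_resp(amps3, amps5, r3, r5)
  ds <- toy_ds_for(resp)
  plan <- select_targets(ds, resp, "responsive", n_per_fov = 3)
  # merged distribution: n1@30, n2@28, n3@27, (n1@25 deduplicated away)
  expect_equal(plan$targets$neuron_id, c("n01", "n02", "n03"))
  expect_equal(plan$targets$amplitude, c(30, 28, 27))
  expect_equal(plan$targets$rank, 1:3)

  # brute-force merge oracle on random toys
  set.seed(17)
  for (rep in 1:5) {
    n <- 20
    a3 <- round(runif(n, 1, 60), 2); a5 <- round(runif(n, 1, 60), 2)
    r3 <- runif(n) < 0.5; r5 <- runif(n) < 0.5
    resp2 <- toy_resp(a3, a5, r3, r5)
    ds2 <- toy_ds_for(resp2)
    got <- suppressWarnings(select_targets(ds2, resp2, "responsive",
                                           n_per_fov = n))$candidates[[1]]
    # oracle: stack (id, amp) entries of both days for responsive neurons,
    # sort by amplitude descending, drop later duplicates
    ids <- sprintf("n%02d", 1:n)
    ent <- rbind(data.frame(id = ids[r3], amp = a3[r3]),
                 data.frame(id = ids[r5], amp = a5[r5]))
    ent <- ent[order(-ent$amp, ent$id), ]
    ent <- ent[!duplicated(ent$id), ]
    expect_equal(got$neuron_id, ent$id)
    expect_equal(got$amplitude, ent$amp)
    # dedup property: unique ids, length = |union of day lists|
    expect_false(anyDuplicated(got$neuron_id) > 0)
    expect_equal(nrow(got), length(union(ids[r3], ids[r5])))
  }
})

test_that("nonresponsive-mode selection averages the two per-day absolute
           amplitude ranks", {
  # nonresponsive on both days: n1..n4; |amp| day3 order n2<n1<n3<n4,
  # day5 order n1<n2<n3<n4
  amps3 <- c(2, -1, 5, 9, 40); amps5 <- c(0.5, 2, 4, 8, 45)
  r <- c(FALSE, FALSE, FALSE, FALSE, TRUE)
  resp <- toy_resp(amps3, amps5, r, r)
  ds <- toy_ds_for(resp)
  plan <- select_targets(ds, resp, "nonresponsive", n_per_fov = 3)
  # average ranks: n1 (2+1)/2 = 1.5, n2 (1+2)/2 = 1.5, n3 3, n4 4
  # tie n1/n2 breaks by id
  expect_equal(plan$targets$neuron_id, c("n01", "n02", "n03"))
  # all neurons responsive -> empty plan with a warning
  resp_all <- toy_resp(amps3, amps5, rep(TRUE, 5), rep(TRUE, 5))
  expect_warning(plan2 <- select_targets(toy_ds_for(resp_all), resp_all,
                                         "nonresponsive", n_per_fov = 3),
                 "no nonresponsive candidates")
  expect_equal(nrow(plan2$targets), 0)
})

test_that("inhibitory-mode selection takes responsive interneurons first and
           fills with apparent-responsive ones; n_per_fov honored", {
  amps3 <- c(30, 25, 20, 15, 10, 5)
  amps5 <- c(29, 24, 19, 14, 9, 4)
  rsp <- c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  resp <- toy_resp(amps3, amps5, rsp, rsp)
  ds <- toy_ds_for(resp)
  ds$neurons$inhibitory <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  plan <- select_targets(ds, resp, "inhibitory", n_per_fov = 3)
  # n1 (responsive interneuron) first, then apparent: n2 (24.5) over n4, n6
  expect_equal(plan$targets$neuron_id[1], "n01")
  expect_equal(plan$targets$neuron_id[2], "n02")
  expect_equal(nrow(plan$targets), 3)
  # a FOV without interneurons yields an empty plan with a warning
  ds$neurons$inhibitory <- rep(FALSE, 6)
  expect_warning(p2 <- select_targets(ds, resp, "inhibitory", n_per_fov = 3),
                 "no inhibitory candidates")
  expect_equal(nrow(p2$targets), 0)
  # 4-8 per FOV honored when requested
  rsp_all <- rep(TRUE, 6)
  resp3 <- toy_resp(amps3, amps5, rsp_all, rsp_all)
  ds3 <- toy_ds_for(resp3)
  p3 <- select_targets(ds3, resp3, "responsive", n_per_fov = 4)
  expect_equal(nrow(p3$targets), 4)
})

test_that("selection is deterministic and input-order invariant", {
  set.seed(18)
  n <- 15
  a3 <- round(runif(n, 1, 60), 3); a5 <- round(runif(n, 1, 60), 3)
  r3 <- runif(n) < 0.6; r5 <- runif(n) < 0.6
  resp <- toy_resp(a3, a5, r3, r5)
  ds <- toy_ds_for(resp)
  p1 <- select_targets(ds, resp, "responsive", n_per_fov = 5)
  perm <- sample(nrow(resp))
  p2 <- select_targets(ds, resp[perm, ], "responsive", n_per_fov = 5)
  expect_equal(p1$targets, p2$targets)
})

test_that("category sets: disjoint high/low, deterministic tie-break, and
           ablated interneurons never high-category", {
  amps3 <- c(50, 40, 40, 30, 20, 3, 2, 1)
  amps5 <- c(49, 39, 39, 29, 19, 2.5, 1.5, 0.5)
  rsp <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  resp <- toy_resp(amps3, amps5, rsp, rsp)
  ds <- toy_ds_for(resp)
  plan <- select_targets(ds, resp, "responsive", n_per_fov = 2)
  cats <- assign_categories(ds, resp, plan, "control", n_each = 3)
  expect_length(intersect(cats$high$neuron_id, cats$low$neuron_id), 0)
  expect_setequal(cats$exclude, c("high", "low"))
  # amplitude tie between n2 and n3 at 40: id order decides, stable
  expect_equal(cats$high$neuron_id, c("n01", "n02", "n03"))
  expect_equal(cats$low$neuron_id, c("n08", "n07", "n06"))

  # inhibitory cohort: ablated responsive interneuron excluded from high set
  ds$neurons$inhibitory <- c(TRUE, rep(FALSE, 7))
  plan_i <- select_targets(ds, resp, "inhibitory", n_per_fov = 1)
  expect_equal(plan_i$targets$neuron_id, "n01")
  cats_i <- assign_categories(ds, resp, plan_i, "inhibitory_ablation",
                              n_each = 3)
  expect_false("n01" %in% cats_i$high$neuron_id)
  expect_equal(cats_i$exclude, "high")
})

test_that("spared mask: radius boundary, failed targets, category exclusion
           and a brute-force distance oracle", {
  # geometry: ablated neuron at origin; probes at 14.9 and 15.1 um
  ids <- c("abl", "near", "far", "fail", "hi")
  nr <- neuron_records(ids, "f1", "m1", "control",
                       x = c(0, 14.9, 15.1, 200, 300),
                       y = 0, z = 0, inhibitory = FALSE)
  ds <- toy_dataset(matrix(0, 5, 34))
  ds$neurons <- nr
  rownames(ds$present[[1]]) <- ids
  names(ds$tensors) <- names(ds$present) <- "f1"
  plan <- structure(list(mode = "responsive",
                         targets = data.frame(fov_id = "f1",
                                              neuron_id = c("abl", "fail"),
                                              rank = 1:2, amplitude = c(9, 8),
                                              success = c(TRUE, FALSE)),
                         candidates = list(), warnings = character(0)),
                    class = "ablation_plan")
  cats <- structure(list(high = data.frame(fov_id = "f1", neuron_id = "hi"),
                         low = data.frame(fov_id = character(0),
                                          neuron_id = character(0)),
                         exclude = "high", shortfall = character(0)),
                    class = "category_sets")
  mask <- build_spared_mask(ds, plan, cats, radius = 15)
  got <- setNames(mask$reason, mask$neuron_id)
  expect_equal(unname(got["abl"]), "targeted")
  expect_equal(unname(got["fail"]), "targeted")  # failed target still excluded
  expect_equal(unname(got["near"]), "within_radius")  # 14.9 <= 15
  expect_true(mask$spared[mask$neuron_id == "far"])   # 15.1 spared
  expect_equal(unname(got["hi"]), "high_category")

  # brute-force oracle on a 300-neuron toy
  set.seed(19)
  n <- 300
  ids2 <- sprintf("n%03d", 1:n)
  nr2 <- neuron_records(ids2, "f1", "m1", "control",
                        x = runif(n, 0, 367), y = runif(n, 0, 367),
                        z = runif(n, 0, 200), inhibitory = FALSE)
  ds2 <- toy_dataset(matrix(0, n, 34))
  ds2$neurons <- nr2
  rownames(ds2$present[[1]]) <- ids2
  names(ds2$tensors) <- names(ds2$present) <- "f1"
  tgt <- sample(ids2, 6)
  plan2 <- structure(list(mode = "responsive",
                          targets = data.frame(fov_id = "f1", neuron_id = tgt,
                                               rank = 1:6, amplitude = 1,
                                               success = TRUE),
                          candidates = list(), warnings = character(0)),
                     class = "ablation_plan")
  cats2 <- structure(list(high = data.frame(fov_id = character(0),
                                            neuron_id = character(0)),
                          low = data.frame(fov_id = character(0),
                                           neuron_id = character(0)),
                          exclude = character(0), shortfall = character(0)),
                     class = "category_sets")
  mask2 <- build_spared_mask(ds2, plan2, cats2, radius = 15)
  P <- as.matrix(nr2[, c("x", "y", "z")])
  for (i in seq_len(n)) {
    if (ids2[i] %in% tgt) {
      expect_equal(mask2$reason[i], "targeted")
    } else {
      dmin <- min(sqrt(rowSums((P[match(tgt, ids2), , drop = FALSE] -
                                  matrix(P[i, ], 6, 3, byrow = TRUE))^2)))
      expect_equal(mask2$spared[i], dmin > 15)
    }
  }
})
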