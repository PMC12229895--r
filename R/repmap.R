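# Representational similarity matrices, summaries, embeddings, decoding.

#' Stimulus-pair similarity matrix from a trial tensor
#'
#' Population response vectors (one entry per neuron in the mask) are
#' correlated across stimuli. In `single_trial` mode, element (s1, s2) is the
#' mean Pearson correlation over all pairs of single-trial vectors of the two
#' stimuli, excluding identical-trial pairings on the diagonal (with 10
#' trials: 45 distinct trial pairs per diagonal element, 100 per
#' off-diagonal); the diagonal is the trial-to-trial reliability of the
#' population response. In `trial_averaged` mode, vectors are averaged across
#' trials first and the diagonal is exactly 1. Trial vectors with zero
#' variance have undefined correlations; those pairs are excluded from the
#' element average and counted.
#'
#' @param tt a [trial_tensor()].
#' @param mode `"single_trial"` or `"trial_averaged"`.
#' @param neuron_mask logical or integer selection of tensor rows (e.g.
#'   present & spared neurons). Default: all rows.
#' @return A list of class `similarity_matrix`: `M` (S x S), `mode`,
#'   `fov_id`, `day`, `n_neurons`, `n_excluded_pairs`.
#' @export
similarity_matrix <- function(tt, mode = c("single_trial", "trial_averaged"),
                              neuron_mask = NULL) {
  mode <- match.arg(mode)
  A <- tt$A
  if (!is.null(neuron_mask)) A <- A[neuron_mask, , , drop = FALSE]
  N <- dim(A)[1]; S <- dim(A)[2]; Tt <- dim(A)[3]
  if (N < 2) {
    dm_stop("driftmap_invalid_argument",
            "similarity_matrix: need at least 2 neurons in the mask")
  }
  n_excl <- 0L
  if (mode == "trial_averaged") {
    curves <- matrix(rowMeans(matrix(A, N * S), na.rm = TRUE), N, S)
    M <- suppressWarnings(stats::cor(curves))
    diag(M) <- 1
  } else {
    V <- matrix(A, nrow = N)  # column (s, t) sits at index (t - 1) * S + s
    C <- suppressWarnings(stats::cor(V))
    col_s <- rep(seq_len(S), times = Tt)
    col_t <- rep(seq_len(Tt), each = S)
    M <- matrix(NA_real_, S, S)
    for (s1 in seq_len(S)) {
      i1 <- which(col_s == s1)
      for (s2 in s1:S) {
        i2 <- which(col_s == s2)
        block <- C[i1, i2, drop = FALSE]
        if (s1 == s2) {
          vals <- block[upper.tri(block)]  # 45 distinct trial pairs for T=10
        } else {
          vals <- as.vector(block)         # all 100 trial pairings
        }
        n_excl <- n_excl + sum(is.na(vals))
        M[s1, s2] <- M[s2, s1] <- mean(vals, na.rm = TRUE)
      }
    }
  }
  structure(list(M = M, mode = mode, fov_id = tt$fov_id, day = tt$day,
                 n_neurons = N, n_excluded_pairs = n_excl),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %s, fov %s day %s, %d neurons; diag %.3f, offdiag %.3f\n",
              x$mode, x$fov_id %||% "grand", x$day, x$n_neurons,
              mean(diag(x$M)), offdiag_mean(x$M)))
  invisible(x)
}

#' Mean of the off-diagonal elements (each unordered pair counted once)
#' @param M square symmetric matrix.
#' @export
offdiag_mean <- function(M) mean(M[upper.tri(M)])

#' Grand-average similarity matrices and their day-course summary
#'
#' Averages similarity matrices elementwise across FOVs per day and reports
#' the mean of diagonal and off-diagonal elements, raw and normalized by the
#' mean over the baseline days.
#'
#' @param mats list of `similarity_matrix` objects (one mode only), any mix
#'   of FOVs and days.
#' @param baseline_days days used for ratio normalization, default
#'   `c(1, 3, 5)` (the pre-ablation sessions).
#' @return list: `summary` data.frame (day, n_fov, diag_mean, offdiag_mean,
#'   diag_norm, offdiag_norm), `grand` named list of day -> grand-average
#'   `similarity_matrix`.
#' @export
summarize_map <- function(mats, baseline_days = c(1, 3, 5)) {
  if (length(mats) == 0) {
    dm_stop("driftmap_invalid_argument", "summarize_map: empty FOV set")
  }
  modes <- unique(vapply(mats, `[[`, character(1), "mode"))
  if (length(modes) != 1) {
    dm_stop("driftmap_invalid_argument",
            "summarize_map: matrices mix modes (%s)", paste(modes, collapse = ", "))
  }
  days <- sort(unique(vapply(mats, function(m) m$day, numeric(1))))
  grand <- list()
  rows <- lapply(days, function(day) {
    sel <- Filter(function(m) m$day == day, mats)
    G <- Reduce(`+`, lapply(sel, `[[`, "M")) / length(sel)
    gm <- structure(list(M = G, mode = modes, fov_id = NULL, day = day,
                         n_neurons = sum(vapply(sel, `[[`, numeric(1),
                                                "n_neurons")),
                         n_excluded_pairs = NA),
                    class = "similarity_matrix")
    grand[[as.character(day)]] <<- gm
    data.frame(day = day, n_fov = length(sel),
               diag_mean = mean(diag(G)), offdiag_mean = offdiag_mean(G))
  })
  summary <- do.call(rbind, rows)
  base <- summary$day %in% baseline_days
  if (!any(base)) {
    dm_stop("driftmap_invalid_argument",
            "summarize_map: no baseline days among the matrices")
  }
  summary$diag_norm <- summary$diag_mean / mean(summary$diag_mean[base])
  summary$offdiag_norm <- summary$offdiag_mean / mean(summary$offdiag_mean[base])
  list(summary = summary, grand = grand)
}

#' Classical MDS embedding of a similarity matrix
#'
#' Converts correlations to dissimilarities (1 - r) and applies classical
#' (Torgerson) multidimensional scaling. Coordinates are defined up to
#' rotation/reflection; eigenvalues are returned so heavily non-Euclidean
#' inputs (negative eigenvalues) are visible to the caller.
#'
#' @param sm a `similarity_matrix`.
#' @param dims embedding dimension, default 2.
#' @return list: `coords` (S x dims), `eig` (all eigenvalues).
#' @export
mds_embed <- function(sm, dims = 2) {
  D <- 1 - sm$M
  diag(D) <- 0
  fit <- stats::cmdscale(stats::as.dist(D), k = dims, eig = TRUE)
  list(coords = fit$points, eig = fit$eig)
}

#' Pairwise stimulus decoding with a linear SVM
#'
#' Trains a linear maximum-margin classifier (cost fixed at `cost`) to
#' discriminate single-trial population vectors of each stimulus pair, with
#' stratified five-fold cross-validation so every trial is tested exactly
#' once. When `tt_test` is supplied, the model is trained on the training
#' day's folds and tested on the held-out fold of the test day
#' (fold-respecting cross-day protocol); the neuron mask is shared so
#' dimensionality matches.
#'
#' @param tt a [trial_tensor()] providing training trials.
#' @param pairs 2-column matrix of stimulus index pairs, or NULL for all
#'   pairs.
#' @param tt_test optional test-day tensor.
#' @param neuron_mask row selection applied to both tensors.
#' @param folds number of CV folds, default 5.
#' @param cost SVM regularization constant, default 1.
#' @param seed seed for fold assignment.
#' @return data.frame: `s1`, `s2`, `accuracy` (fraction of correctly
#'   classified test trials).
#' @export
pairwise_decode <- function(tt, pairs = NULL, tt_test = NULL,
                            neuron_mask = NULL, folds = 5, cost = 1,
                            seed = 1L) {
  A <- tt$A
  B <- if (is.null(tt_test)) A else tt_test$A
  if (!is.null(neuron_mask)) {
    A <- A[neuron_mask, , , drop = FALSE]
    B <- B[neuron_mask, , , drop = FALSE]
  }
  S <- dim(A)[2]; Tt <- dim(A)[3]
  if (Tt < folds) {
    dm_stop("driftmap_invalid_argument",
            "pairwise_decode: need at least %d trials per stimulus", folds)
  }
  if (is.null(pairs)) pairs <- t(utils::combn(S, 2))
  fold_of <- with_seed(seed_stream(seed, "decode", tt$fov_id, tt$day), {
    sample(rep_len(seq_len(folds), Tt))  # same stratified folds per stimulus
  })
  acc <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    s1 <- pairs[i, 1]; s2 <- pairs[i, 2]
    X1 <- t(A[, s1, , drop = TRUE]); X2 <- t(A[, s2, , drop = TRUE])
    Y1 <- t(B[, s1, , drop = TRUE]); Y2 <- t(B[, s2, , drop = TRUE])
    correct <- 0L; total <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_of != f; te <- !tr
      Xtr <- rbind(X1[tr, , drop = FALSE], X2[tr, , drop = FALSE])
      ytr <- factor(rep(c("a", "b"), c(sum(tr), sum(tr))))
      Xte <- rbind(Y1[te, , drop = FALSE], Y2[te, , drop = FALSE])
      yte <- factor(rep(c("a", "b"), c(sum(te), sum(te))))
      fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = cost,
                        scale = FALSE)
      pred <- stats::predict(fit, Xte)
      correct <- correct + sum(pred == yte)
      total <- total + length(yte)
    }
    acc[i] <- correct / total
  }
  data.frame(s1 = pairs[, 1], s2 = pairs[, 2], accuracy = acc)
}
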