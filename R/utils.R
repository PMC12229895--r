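# Internal helpers shared across modules.

#' Derive a reproducible child seed from a base seed and a character path
#'
#' All randomness in the package flows from one user-supplied base seed.
#' Sub-streams (per mouse, FOV, day, procedure) are derived by hashing the
#' stream labels together with the base seed, so regenerating any subset of a
#' cohort is reproducible without replaying the full stream.
#'
#' @param seed integer base seed.
#' @param ... character or numeric labels naming the sub-stream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
seed_stream <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  # 32-bit FNV-1a, kept in double precision (exact below 2^53)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% .Machine$integer.max)
}

#' Evaluate an expression under a local RNG state
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Pearson correlation that returns NA (no warning) for zero-variance input
#' @keywords internal
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Stop with a classed error
#' @keywords internal
dm_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "driftmap_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
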