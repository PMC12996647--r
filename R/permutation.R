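#' Paired sign-flip permutation test
#'
#' Two-sided test of paired differences: the null distribution is built by
#' independently flipping the sign of each paired difference, and the
#' p-value uses the add-one estimator
#' `p = (1 + #permutations with |T| >= |T_obs|) / (n_iter + 1)`, so it can
#' never be 0 and is bounded below by `1 / (n_iter + 1)`.
#'
#' @param x,y paired numeric samples of equal length >= 2 (no NA). `y` may
#'   be omitted to test differences `x` against 0.
#' @param n_iter number of permutations (default 10000).
#' @param statistic "median_diff" (default) or "mean_diff".
#' @param seed integer seed (mandatory: recorded in the result).
#' @return an object of class `permutation_result` with fields
#'   `statistic_name`, `observed`, `p_value`, `n_iter`, `seed`,
#'   `degenerate`.
#' @export
paired_permutation_test <- function(x, y = NULL, n_iter = 10000,
                                    statistic = c("median_diff", "mean_diff"),
                                    seed) {
  statistic <- match.arg(statistic)
  if (missing(seed)) stop("'seed' is required for reproducibility")
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (!is.null(y) && length(x) != length(y)) stop("unequal sample lengths")
  if (length(d) < 2L) stop("need at least 2 pairs")
  if (anyNA(d)) stop("NA in paired differences")
  stat_fun <- if (statistic == "median_diff") stats::median else mean
  observed <- stat_fun(d)
  if (all(d == 0)) {
    return(permutation_result(statistic, observed = 0, p_value = 1,
                              n_iter = n_iter, seed = seed,
                              degenerate = TRUE))
  }
  set.seed(as.integer(seed))
  n <- length(d)
  signs <- matrix(sample(c(-1, 1), n * n_iter, replace = TRUE), nrow = n)
  flipped <- signs * d
  perm <- if (statistic == "median_diff") {
    apply(flipped, 2, stats::median)
  } else {
    colMeans(flipped)
  }
  p <- (1 + sum(abs(perm) >= abs(observed))) / (n_iter + 1)
  permutation_result(statistic, observed, p, n_iter, seed)
}

permutation_result <- function(statistic_name, observed, p_value, n_iter,
                               seed, degenerate = FALSE,
                               alpha_corrected = NA_real_) {
  structure(list(statistic_name = statistic_name, observed = observed,
                 p_value = p_value, n_iter = as.integer(n_iter),
                 seed = as.integer(seed), degenerate = degenerate,
                 alpha_corrected = alpha_corrected),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> ", x$statistic_name, " = ",
      signif(x$observed, 4), ", p = ", signif(x$p_value, 4), " (",
      x$n_iter, " iterations, seed ", x$seed,
      if (x$degenerate) ", degenerate" else "", ")\n", sep = "")
  invisible(x)
}

#' Two-factor within-subject permutation tests
#'
#' For a complete subject x (2 x 2) design (e.g. algorithm x acquisition
#' day), sign-flip tests of: main effect of A (per-subject difference of
#' factor-B means between A levels), main effect of B (symmetrically), and
#' the interaction (the per-subject double difference
#' `(A1B1 - A1B2) - (A2B1 - A2B2)`).
#'
#' @param values numeric matrix or data.frame, one row per subject, columns
#'   `A1B1`, `A1B2`, `A2B1`, `A2B2` (cell means of the 2 x 2 design).
#' @param n_iter permutations per test (default 10000).
#' @param seed integer seed.
#' @param statistic see [paired_permutation_test()].
#' @return list of three `permutation_result`s: `main_A`, `main_B`,
#'   `interaction`.
#' @export
two_factor_permutation <- function(values, n_iter = 10000, seed,
                                   statistic = c("median_diff", "mean_diff")) {
  statistic <- match.arg(statistic)
  if (missing(seed)) stop("'seed' is required for reproducibility")
  values <- as.matrix(values)
  need <- c("A1B1", "A1B2", "A2B1", "A2B2")
  if (!all(need %in% colnames(values)))
    stop("'values' must have columns ", paste(need, collapse = ", "))
  if (anyNA(values)) stop("incomplete 2x2 table: NA cell(s)")
  v <- values[, need, drop = FALSE]
  d_A <- (v[, "A1B1"] + v[, "A1B2"]) / 2 - (v[, "A2B1"] + v[, "A2B2"]) / 2
  d_B <- (v[, "A1B1"] + v[, "A2B1"]) / 2 - (v[, "A1B2"] + v[, "A2B2"]) / 2
  d_int <- (v[, "A1B1"] - v[, "A1B2"]) - (v[, "A2B1"] - v[, "A2B2"])
  list(main_A = paired_permutation_test(d_A, n_iter = n_iter,
                                        statistic = statistic, seed = seed),
       main_B = paired_permutation_test(d_B, n_iter = n_iter,
                                        statistic = statistic,
                                        seed = seed + 1L),
       interaction = paired_permutation_test(d_int, n_iter = n_iter,
                                             statistic = statistic,
                                             seed = seed + 2L))
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m`: e.g. 0.05 over 3 comparisons gives 0.0166..., over 4 gives
#' 0.0125.
#'
#' @param alpha family-wise alpha.
#' @param m number of comparisons (>= 1).
#' @return corrected per-comparison threshold.
#' @export
bonferroni <- function(alpha, m) {
  m <- as.integer(m)
  if (m < 1L) stop("'m' must be >= 1")
  alpha / m
}
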