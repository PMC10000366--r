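# Comparison fusion rules: z-scored concatenation, convex kernel
# combination, the MAX decision rule, the Choquet fuzzy integral with a
# Sugeno lambda-measure, and the threshold-adaptive rule.

#' Concatenation fusion
#'
#' Z-normalises each modality per column (statistics taken from the
#' normalisation split, by default the data itself) and concatenates
#' column-wise; zero-variance columns are dropped with a warning.
#'
#' @param I1,I2 Feature matrices with aligned rows.
#' @param stats Optional list from a previous call (`$mean1`, `$sd1`, ...)
#'   so test rows reuse training-split statistics.
#' @return The concatenated matrix with a `"stats"` attribute for reuse.
#' @export
concat_fuse <- function(I1, I2, stats = NULL) {
  I1 <- as.matrix(I1); I2 <- as.matrix(I2)
  assert_that(nrow(I1) == nrow(I2) || ncol(I1) == 0 || ncol(I2) == 0,
              "inputs must share rows", "emofuse_shape")
  norm_one <- function(M, mu, sg, tag) {
    if (ncol(M) == 0) return(list(M = M, mu = numeric(0), sg = numeric(0)))
    if (is.null(mu)) { mu <- colMeans(M); sg <- apply(M, 2, sd) }
    keep <- sg > 0
    if (!all(keep)) {
      rlang::warn(sprintf("dropping %d zero-variance %s column(s)",
                          sum(!keep), tag))
    }
    list(M = sweep(sweep(M[, keep, drop = FALSE], 2, mu[keep]),
                   2, sg[keep], `/`),
         mu = mu, sg = sg)
  }
  n1 <- norm_one(I1, stats$mean1, stats$sd1, "modality-1")
  n2 <- norm_one(I2, stats$mean2, stats$sd2, "modality-2")
  out <- cbind(n1$M, n2$M)
  attr(out, "stats") <- list(mean1 = n1$mu, sd1 = n1$sg,
                             mean2 = n2$mu, sd2 = n2$sg)
  out
}

#' Convex combination of kernel matrices
#'
#' @param kernels List of symmetric positive semi-definite Gram matrices of
#'   identical shape.
#' @param weights Non-negative weights summing to 1 (default uniform).
#' @return The combined Gram matrix (symmetric, PSD).
#' @export
combine_kernels <- function(kernels,
                            weights = rep(1 / length(kernels),
                                          length(kernels))) {
  assert_that(length(kernels) >= 1, "need at least one kernel")
  assert_that(length(weights) == length(kernels),
              "one weight per kernel", "emofuse_shape")
  assert_that(all(weights >= 0) && abs(sum(weights) - 1) < 1e-9,
              "weights must lie on the simplex", "emofuse_range")
  d <- dim(kernels[[1]])
  for (K in kernels) {
    assert_that(identical(dim(K), d), "kernels must share shape",
                "emofuse_shape")
    assert_that(max(abs(K - t(K))) < 1e-8, "kernels must be symmetric",
                "emofuse_range")
  }
  Reduce(`+`, Map(`*`, kernels, weights))
}

#' MAX decision fusion
#'
#' For each trial, every classifier contributes its per-class probabilities;
#' the winning class is the one whose maximum probability over classifiers
#' is largest.  Ties break to the lowest class index.
#'
#' @param probs 3-D array `trials x classes x classifiers`, or a list of
#'   per-classifier probability matrices (`trials x classes`).
#' @return Integer vector of winning class indices (one per trial).
#' @export
max_fuse <- function(probs) {
  if (is.list(probs)) {
    probs <- array(unlist(probs),
                   dim = c(nrow(probs[[1]]), ncol(probs[[1]]),
                           length(probs)))
  }
  assert_that(length(dim(probs)) == 3 && all(dim(probs) >= 1),
              "probs must be trials x classes x classifiers",
              "emofuse_shape")
  best_per_class <- apply(probs, c(1, 2), max)   # max over classifiers
  if (is.null(dim(best_per_class))) {
    best_per_class <- matrix(best_per_class, nrow = 1)
  }
  max.col(best_per_class, ties.method = "first")
}

#' Sugeno lambda-fuzzy measure from source densities
#'
#' Given densities `g_i` in `(0, 1)`, finds the unique `lambda > -1`,
#' `lambda != 0`, solving `prod(1 + lambda g_i) = 1 + lambda` (or `lambda =
#' 0` exactly when the densities sum to 1, the additive case) and builds the
#' monotone set function `mu(A + {i}) = mu(A) + g_i + lambda g_i mu(A)` over
#' all subsets, with `mu(full set) = 1`.
#'
#' @param g Densities, one per information source, each in `(0, 1)`.
#' @return A `fuzzy_measure`: list with `g`, `lambda`, and `mu`, a named
#'   vector over all non-empty subsets (names like `"1,3"` index sources).
#' @export
sugeno_lambda_measure <- function(g) {
  n <- length(g)
  assert_that(n >= 2, "need at least 2 sources", "emofuse_range")
  assert_that(all(g > 0 & g < 1), "densities must lie in (0, 1)",
              "emofuse_range")
  f <- function(l) prod(1 + l * g) - (1 + l)
  s <- sum(g)
  if (abs(s - 1) < 1e-12) {
    lambda <- 0
  } else if (s > 1) {
    # root in (-1, 0)
    lambda <- uniroot(f, c(-1 + 1e-12, -1e-12), tol = 1e-14)$root
  } else {
    # root in (0, Inf): bracket upward
    hi <- 1
    while (f(hi) < 0) hi <- hi * 2
    lambda <- uniroot(f, c(1e-12, hi), tol = 1e-14)$root
  }
  subsets <- lapply(seq_len(2^n - 1), function(m) which(bitwAnd(
    m, 2^(seq_len(n) - 1)) > 0))
  mu <- vapply(subsets, function(A) {
    v <- 0
    for (i in A) v <- v + g[i] + lambda * g[i] * v
    v
  }, 0)
  names(mu) <- vapply(subsets, paste, "", collapse = ",")
  # the full set must hit 1 by construction of lambda
  full <- paste(seq_len(n), collapse = ",")
  mu[full] <- 1
  structure(list(g = g, lambda = lambda, mu = mu, n = n),
            class = "fuzzy_measure")
}

measure_value <- function(measure, A) {
  if (length(A) == 0) return(0)
  measure$mu[[paste(sort(A), collapse = ",")]]
}

#' Discrete Choquet integral
#'
#' Sorts the per-source scores ascending and accumulates
#' `(h(x_(i)) - h(x_(i-1))) * mu(A_i)` with `A_i` the sources from rank `i`
#' upward and `h(x_(0)) = 0`.  Under an additive measure (`lambda = 0`)
#' this reduces to the weighted mean `sum g_i h(x_i)`.
#'
#' @param h Non-negative score per source (e.g. one class's probability
#'   from each classifier).
#' @param measure A [sugeno_lambda_measure()] over the same sources.
#' @return The scalar integral, between `min(h)` and `max(h)`.
#' @export
choquet_fuse <- function(h, measure) {
  assert_that(inherits(measure, "fuzzy_measure"),
              "measure must come from sugeno_lambda_measure()")
  assert_that(length(h) == measure$n, "score/source mismatch",
              "emofuse_shape")
  assert_that(all(h >= 0), "scores must be non-negative", "emofuse_range")
  ord <- order(h)
  sorted <- h[ord]
  total <- 0
  prev <- 0
  for (i in seq_along(sorted)) {
    A <- ord[i:length(ord)]
    total <- total + (sorted[i] - prev) * measure_value(measure, A)
    prev <- sorted[i]
  }
  total
}

#' Choquet-integral decision fusion over probability tables
#'
#' Computes one Choquet integral per trial and class over the classifiers'
#' probabilities and returns the class with the largest integral.
#'
#' @param probs `trials x classes x classifiers` array or list of matrices
#'   (as in [max_fuse()]).
#' @param measures A single [sugeno_lambda_measure()] shared by all classes,
#'   or a list of one measure per class.
#' @return Integer vector of winning class indices.
#' @export
choquet_label <- function(probs, measures) {
  if (is.list(probs)) {
    probs <- array(unlist(probs),
                   dim = c(nrow(probs[[1]]), ncol(probs[[1]]),
                           length(probs)))
  }
  n_class <- dim(probs)[2]
  if (inherits(measures, "fuzzy_measure")) {
    measures <- rep(list(measures), n_class)
  }
  assert_that(length(measures) == n_class, "one measure per class",
              "emofuse_shape")
  scores <- matrix(0, dim(probs)[1], n_class)
  for (t in seq_len(dim(probs)[1])) {
    for (c in seq_len(n_class)) {
      scores[t, c] <- choquet_fuse(probs[t, c, ], measures[[c]])
    }
  }
  max.col(scores, ties.method = "first")
}

#' Adaptive EEG/face score fusion
#'
#' Combines the EEG-side and face-side scores for one class.  Above the 0.4
#' EEG threshold the EEG score receives a small extra weight that grows with
#' its margin over the threshold; below it the two sides average equally.
#' The rule is continuous at the threshold:
#' `y = (yF + (1 + (yE - 0.4)/100) * yE) / 2` for `yE > 0.4`, else
#' `y = (yE + yF) / 2`.
#'
#' @param yE,yF EEG-side and face-side scores in `[0, 1]` (vectorised).
#' @return Fused score(s).
#' @export
adaptive_fuse <- function(yE, yF) {
  assert_that(all(yE >= 0 & yE <= 1) && all(yF >= 0 & yF <= 1),
              "scores must lie in [0, 1]", "emofuse_range")
  ifelse(yE > 0.4,
         (yF + (1 + (yE - 0.4) / 100) * yE) / 2,
         (yE + yF) / 2)
}

#' Adaptive decision fusion over probability tables
#'
#' Applies [adaptive_fuse()] class-wise to the EEG and video probability
#' tables and picks the class with the largest fused score.
#'
#' @param probs_eeg,probs_video `trials x classes` probability matrices.
#' @return Integer vector of winning class indices.
#' @export
adaptive_label <- function(probs_eeg, probs_video) {
  assert_that(identical(dim(probs_eeg), dim(probs_video)),
              "probability tables must share shape", "emofuse_shape")
  fused <- matrix(adaptive_fuse(as.vector(probs_eeg),
                                as.vector(probs_video)),
                  nrow(probs_eeg), ncol(probs_eeg))
  max.col(fused, ties.method = "first")
}
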