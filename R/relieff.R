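#' Multi-class ReliefF feature ranking
#'
#' Estimates the quality of each feature by how well it separates
#' neighbouring instances of different classes while staying similar
#' among neighbours of the same class (the multi-class ReliefF of
#' Robnik-Sikonja & Kononenko). For each sampled instance, the k nearest
#' hits (same class) decrease the weights of features on which they
#' differ, and the k nearest misses of every other class increase them,
#' weighted by the class prior `P(C) / (1 - P(class(Ri)))`. Feature
#' differences are `diff(f, a, b) = |a_f - b_f| / range_f`, and instance
#' distances are the sum of diffs over features. With `m = NULL` every
#' instance is used once in index order, making the ranking fully
#' deterministic (ties in distance are broken by instance index).
#'
#' @param x numeric matrix or data frame of features (rows = instances).
#' @param y class labels (e.g. ecotype), length `nrow(x)`, >= 2 classes.
#' @param k number of neighbours (default 10); reduced with a warning for
#'   classes with fewer than `k + 1` members.
#' @param m number of random instance draws, or `NULL` (default) to use
#'   every instance once.
#' @return an object of class `relieff_ranking`: list with `weights`
#'   (named, in input column order) and `ranking` (descriptor names,
#'   best first).
#' @examples
#' x <- cbind(sep = rep(c(0, 1), each = 10), noise = rep(0.5, 20))
#' relieff_rank(x, rep(c("a", "b"), each = 10), k = 3)$ranking
#' @export
relieff_rank <- function(x, y, k = 10L, m = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("features must be numeric")
  y <- as.character(y)
  n <- nrow(x)
  if (length(y) != n) stop("length(y) must match nrow(x)")
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]; y <- y[keep]; n <- nrow(x)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least 2 classes")
  counts <- table(y)
  if (any(counts < 2L)) stop("every class needs at least 2 members")
  if (any(counts - 1L < k)) {
    warning("k reduced for classes with fewer than k+1 members")
  }
  priors <- as.numeric(counts[classes]) / n

  # normalise features to [0, 1]; constant features contribute 0
  rng <- apply(x, 2L, function(v) diff(range(v)))
  xs <- x
  for (j in seq_len(ncol(x)))
    xs[, j] <- if (rng[j] > 0) (x[, j] - min(x[, j])) / rng[j] else 0

  sel <- if (is.null(m)) seq_len(n) else {
    if (m < 1L) stop("m must be >= 1")
    sample.int(n, size = m, replace = TRUE)
  }
  w <- numeric(ncol(x))
  mm <- length(sel)
  for (i in sel) {
    di <- rowSums(abs(xs - matrix(xs[i, ], n, ncol(xs), byrow = TRUE)))
    ord <- order(di, seq_len(n))  # ties broken by index
    ord <- ord[ord != i]
    for (cl in classes) {
      members <- ord[y[ord] == cl]
      kk <- min(k, length(members))
      if (kk == 0L) next
      nb <- members[seq_len(kk)]
      dif <- colSums(abs(xs[nb, , drop = FALSE] -
                           matrix(xs[i, ], kk, ncol(xs), byrow = TRUE))) / kk
      if (cl == y[i]) {
        w <- w - dif / mm
      } else {
        pc <- priors[match(cl, classes)] /
          (1 - priors[match(y[i], classes)])
        w <- w + pc * dif / mm
      }
    }
  }
  names(w) <- colnames(x)
  structure(list(weights = w,
                 ranking = names(sort(w, decreasing = TRUE)),
                 k = k, m = mm),
            class = "relieff_ranking")
}

#' @export
print.relieff_ranking <- function(x, ...) {
  cat(sprintf("<relieff_ranking> k = %d, m = %d\n", x$k, x$m))
  print(round(sort(x$weights, decreasing = TRUE), 4))
  invisible(x)
}
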