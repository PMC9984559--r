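## SMOTE: Synthetic Minority Oversampling TEchnique.  Balances the two
## classes by interpolating each synthetic point between a minority sample and
## one of its k nearest minority neighbours.  Applied to training data only —
## the pipeline never oversamples validation or test sets.

# k nearest neighbours within one matrix, chunked to bound memory.
knn_indices <- function(x, k, chunk = 512L) {
  n <- nrow(x)
  sq <- rowSums(x^2)
  out <- matrix(NA_integer_, n, k)
  for (start in seq(1, n, by = chunk)) {
    rows <- start:min(start + chunk - 1, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * x[rows, , drop = FALSE] %*% t(x)
    d2[cbind(seq_along(rows), rows)] <- Inf   # exclude self
    for (kk in seq_len(k)) {                  # k passes of argmin per row
      j <- max.col(-d2, ties.method = "first")
      out[rows, kk] <- j
      d2[cbind(seq_along(rows), j)] <- Inf
    }
  }
  out
}

#' SMOTE oversampling to balanced classes
#'
#' Adds synthetic minority points until the two classes have equal counts.
#' Each synthetic point is `x_i + u * (x_j - x_i)` with `u ~ U(0, 1)`, `x_i`
#' a random minority point and `x_j` one of its `k_neighbors` nearest
#' minority neighbours. Already-balanced input is returned unchanged.
#'
#' @param x Numeric matrix (rows = samples), e.g. latent representations.
#' @param labels Vector with exactly two distinct values.
#' @param k_neighbors Neighbourhood size (default 5); the minority class must
#'   have at least `k_neighbors + 1` members.
#' @param seed RNG seed.
#' @return List with the augmented `x`, `labels`, and logical `synthetic`
#'   marking the generated rows.
#' @export
smote_oversample <- function(x, labels, k_neighbors = 5, seed = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2) stop_dlrpmds("smote_oversample expects exactly 2 classes")
  counts <- table(factor(labels, levels = lv))
  if (counts[1] == counts[2])
    return(list(x = x, labels = labels, synthetic = rep(FALSE, nrow(x))))
  minority <- lv[which.min(counts)]
  need <- abs(diff(as.integer(counts)))
  min_rows <- which(labels == minority)
  if (length(min_rows) < k_neighbors + 1)
    stop_dlrpmds(paste0("minority class has %d members; needs >= k_neighbors + 1 = %d ",
                        "(use a smaller k_neighbors)"),
                 length(min_rows), k_neighbors + 1)
  xm <- x[min_rows, , drop = FALSE]
  nn <- knn_indices(xm, k_neighbors)
  with_seed(seed, {
    i <- sample.int(nrow(xm), need, replace = TRUE)
    j <- nn[cbind(i, sample.int(k_neighbors, need, replace = TRUE))]
    u <- stats::runif(need)
    synth <- xm[i, , drop = FALSE] + u * (xm[j, , drop = FALSE] - xm[i, , drop = FALSE])
    list(x = rbind(x, synth),
         labels = c(labels, rep(minority, need)),
         synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, need)))
  })
}
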