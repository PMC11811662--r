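#' Synthetic minority oversampling (SMOTE)
#'
#' Equalizes class counts by interpolating synthetic minority samples: a
#' minority instance `x_i` is drawn at random, one of its `k` nearest
#' minority neighbors `x_nn` (Euclidean distance after per-feature
#' standardization fit on this data) is drawn, and the synthetic sample is
#' `x_i + u (x_nn - x_i)` with `u ~ Uniform(0, 1)`. Original rows are
#' preserved verbatim; synthetic rows carry provenance `"smote"`. `k` is
#' reduced (with a message) when a class has fewer than `k + 1` members.
#'
#' @param X Numeric feature matrix.
#' @param y Class vector (2 or more classes, each with at least 2 members
#'   unless already at the majority count).
#' @param k_neighbors Number of minority neighbors to draw from (default 5).
#' @param seed Integer seed.
#' @return List with `X` (original rows then synthetic rows), `y`, and
#'   `provenance` (`"original"` / `"smote"` per row).
#' @export
smote_oversample <- function(X, y, k_neighbors = 5L, seed = 0L) {
  X <- as.matrix(X)
  y <- as.character(y)
  tab <- table(y)
  if (length(tab) < 2L) stop("SMOTE needs at least 2 classes")
  target <- max(tab)
  set.seed(seed)
  sc <- scale_fit(X)
  Xs <- scale_apply(X, sc)
  new_X <- list(); new_y <- character(0)
  for (cl in names(tab)) {
    need <- target - tab[[cl]]
    if (need == 0L) next
    idx <- which(y == cl)
    if (length(idx) < 2L) {
      stop(sprintf("class '%s' has %d instance(s); SMOTE needs at least 2",
                   cl, length(idx)))
    }
    k <- min(k_neighbors, length(idx) - 1L)
    if (k < k_neighbors) {
      message(sprintf("SMOTE: reducing k to %d for class '%s'", k, cl))
    }
    Xc <- X[idx, , drop = FALSE]
    Xcs <- Xs[idx, , drop = FALSE]
    D <- as.matrix(stats::dist(Xcs))
    diag(D) <- Inf
    nn_idx <- apply(D, 1L, function(r) order(r)[seq_len(k)])
    nn_idx <- matrix(nn_idx, nrow = k)
    base <- sample.int(length(idx), need, replace = TRUE)
    pick <- vapply(base, function(b) nn_idx[sample.int(k, 1L), b], integer(1))
    u <- stats::runif(need)
    synth <- Xc[base, , drop = FALSE] +
      u * (Xc[pick, , drop = FALSE] - Xc[base, , drop = FALSE])
    new_X[[cl]] <- synth
    new_y <- c(new_y, rep(cl, need))
  }
  Xout <- rbind(X, do.call(rbind, new_X))
  rownames(Xout) <- NULL
  list(X = Xout, y = c(y, new_y),
       provenance = c(rep("original", length(y)),
                      rep("smote", length(new_y))))
}
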