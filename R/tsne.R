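#' Exact t-SNE projection to two dimensions
#'
#' Classic (non-Barnes-Hut) t-distributed stochastic neighbor embedding:
#' per-point Gaussian bandwidths found by bisection to match the target
#' perplexity, symmetrized affinities, early exaggeration for the first
#' quarter of iterations, momentum gradient descent. O(n^2) per
#' iteration; intended for the corpus sizes this package embeds
#' (hundreds to a few thousand sequences). Deterministic given `seed`.
#'
#' @param x numeric matrix (n x d)
#' @param perplexity target perplexity (default 30); requires
#'   n > 3 * perplexity
#' @param n_iter gradient iterations (default 1000)
#' @param seed seed for the random initial layout (default 42)
#' @return n x 2 coordinate matrix (rownames preserved)
#' @export
project_tsne <- function(x, perplexity = 30, n_iter = 1000L, seed = 42L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= 3 * perplexity)
    config_error(sprintf(
      "n = %d too small for perplexity %g (need n > 3*perplexity); lower the perplexity",
      n, perplexity))
  D2 <- as.matrix(stats::dist(x))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(seed, {
    Y <- matrix(rnorm(n * 2L, 0, 1e-4), n, 2L)
    G <- matrix(0, n, 2L)
    exag <- 12; stop_exag <- max(50L, n_iter %/% 4L)
    momentum <- 0.5
    eta <- max(50, n / 12)
    for (it in seq_len(n_iter)) {
      Pe <- if (it <= stop_exag) P * exag else P
      num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (Pe - Q) * num
      grad <- 4 * (Y * rowSums(W) - W %*% Y)
      if (it == stop_exag + 1L) momentum <- 0.8
      G <- momentum * G - eta * grad
      Y <- Y + G
      Y <- sweep(Y, 2L, colMeans(Y))
    }
    rownames(Y) <- rownames(x)
    Y
  })
}

#' Silhouette and linear-probe separation of methylation classes
#'
#' Scores how well full-dimensional embeddings separate unmethylated
#' from highly methylated CGIs: the mean silhouette width over the two
#' classes (Euclidean) and a stratified k-fold cross-validated
#' linear-probe AUC (ridge-regularized linear scorer; Mann-Whitney AUC
#' on held-out folds). The "low" class is excluded from the binary score
#' and reported separately.
#'
#' @param embeddings numeric matrix, rows = sequences
#' @param classes character vector along rows ("unmethylated", "low",
#'   "high")
#' @param k_folds cross-validation folds (default 5)
#' @param min_class_size classes below this are skipped with a warning
#' @param seed fold-assignment seed
#' @return list: `silhouette`, `auc`, `n_per_class`, `excluded`
#' @export
class_separation <- function(embeddings, classes, k_folds = 5L,
                             min_class_size = 10L, seed = 1L) {
  keep_classes <- c("unmethylated", "high")
  n_per <- table(classes)
  usable <- names(n_per)[n_per >= min_class_size]
  binary <- intersect(keep_classes, usable)
  if (length(binary) < 2L) {
    warning("a class is below the minimum size; separation not computed")
    return(list(silhouette = NA_real_, auc = NA_real_,
                n_per_class = n_per, excluded = setdiff(classes, binary)))
  }
  sel <- classes %in% keep_classes
  X <- as.matrix(embeddings)[sel, , drop = FALSE]
  y <- as.integer(classes[sel] == "high")
  sil <- mean_silhouette(X, y)
  auc <- cv_linear_probe_auc(X, y, k_folds, seed)
  list(silhouette = sil, auc = auc, n_per_class = n_per,
       excluded = setdiff(unique(classes), keep_classes))
}

mean_silhouette <- function(X, y) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(y == y[i]); own <- setdiff(own, i)
    oth <- which(y != y[i])
    a <- if (length(own)) mean(D[i, own]) else 0
    b <- mean(D[i, oth])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# ridge least-squares linear probe, stratified k-fold, Mann-Whitney AUC
cv_linear_probe_auc <- function(X, y, k_folds = 5L, seed = 1L,
                                lambda = 1e-3) {
  n <- nrow(X)
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(y)) {
      i <- which(y == cl)
      folds[i] <- sample(rep_len(seq_len(k_folds), length(i)))
    }
  })
  scores <- numeric(n)
  for (f in seq_len(k_folds)) {
    tr <- folds != f; te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2L, sd)
    sdv[sdv < 1e-12] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu), 2L, sdv, `/`)
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2L, mu), 2L, sdv, `/`)
    yt <- y[tr] - mean(y[tr])
    w <- solve(crossprod(Xtr) + lambda * diag(ncol(X)), crossprod(Xtr, yt))
    scores[te] <- Xte %*% w
  }
  auc_mann_whitney(scores, y)
}

#' Mann-Whitney AUC of scores against binary labels
#' @param scores numeric vector
#' @param labels 0/1 vector
#' @return AUC in [0, 1]
#' @export
auc_mann_whitney <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
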