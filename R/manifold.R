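#' Population activity matrix from a session
#'
#' Extracts the N cells x T moving-frames matrix and the per-frame position
#' labels used by the manifold and decoding stages. Frames with an all-zero
#' population vector are dropped (the cosine distance is undefined at the
#' zero vector); their count is reported.
#'
#' @param session An [aligned_session()].
#' @param cells Cell indices to include.
#' @param max_frames Optional cap on T; frames are subsampled evenly.
#' @return List of class `population_matrix`: `X` (N x T), `theta_deg`,
#'   `radius_mm`, `frame_index`, `n_dropped_zero`.
#' @export
population_matrix <- function(session, cells = seq_len(session$n_cells),
                              max_frames = NULL) {
  use <- which(session$moving)
  X <- t(session$activity[use, cells, drop = FALSE])
  nz <- colSums(X) > 0
  n_dropped <- sum(!nz)
  X <- X[, nz, drop = FALSE]
  use <- use[nz]
  if (!is.null(max_frames) && ncol(X) > max_frames) {
    sel <- round(seq(1, ncol(X), length.out = max_frames))
    X <- X[, sel, drop = FALSE]
    use <- use[sel]
  }
  structure(list(X = X, theta_deg = session$theta_deg[use],
                 radius_mm = sqrt(session$x_mm[use]^2 + session$y_mm[use]^2),
                 frame_index = use, n_dropped_zero = n_dropped),
            class = "population_matrix")
}

#' Cosine-dissimilarity classical MDS embedding
#'
#' Computes the T x T pairwise cosine dissimilarity between population
#' vectors, double-centers the squared dissimilarities (B = -1/2 J D^2 J) and
#' eigendecomposes B. Component time courses are the leading eigenvectors
#' scaled by the square root of their eigenvalues; variance explained is
#' computed over the positive eigenvalues only (negative eigenvalues, which
#' arise when D is not Euclidean-embeddable, are retained for inspection but
#' excluded). A PCA backend over the same interface is available for
#' comparison.
#'
#' @param pop A [population_matrix()] (or a bare N x T matrix).
#' @param n_components Number of component time courses to keep (default:
#'   all positive-eigenvalue components).
#' @param method `"mds_cosine"` (default) or `"pca"`.
#' @return Object of class `mds_embedding`: `Y` (M x T), `eigenvalues`
#'   (non-increasing), `variance_explained` (cumulative fraction over the
#'   positive spectrum), `theta_deg`, `method`.
#' @export
embed_population <- function(pop, n_components = NULL,
                             method = c("mds_cosine", "pca")) {
  method <- match.arg(method)
  X <- if (is.matrix(pop)) pop else pop$X
  theta <- if (is.matrix(pop)) NULL else pop$theta_deg
  Tn <- ncol(X)
  if (Tn < 3L) stop("need at least 3 frames to embed", call. = FALSE)
  if (method == "mds_cosine") {
    D <- cosine_dissimilarity(X)
    emb <- classical_mds(D, n_components = n_components)
  } else {
    Xc <- X - rowMeans(X)
    B <- crossprod(Xc)          # T x T Gram; eigenvectors give PC scores
    emb <- embed_from_b(B, n_components)
  }
  emb$theta_deg <- theta
  emb$method <- method
  emb
}

#' Classical multidimensional scaling of a dissimilarity matrix
#'
#' Double-centers the squared dissimilarities, B = -1/2 J D^2 J, and
#' eigendecomposes B; coordinates are eigenvectors scaled by the square roots
#' of the eigenvalues. When D is Euclidean-consistent the embedding
#' reproduces the pairwise distances exactly in full dimension.
#'
#' @param D Symmetric T x T dissimilarity matrix, zero diagonal.
#' @param n_components Components to keep (default: all positive).
#' @return An `mds_embedding` (without position labels).
#' @export
classical_mds <- function(D, n_components = NULL) {
  if (nrow(D) != ncol(D)) stop("D must be square", call. = FALSE)
  embed_from_b(double_center(D^2), n_components)
}

embed_from_b <- function(B, n_components = NULL) {
  Tn <- ncol(B)
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  pos <- ev > max(ev[1], 0) * 1e-12
  n_pos <- sum(pos)
  if (n_pos == 0L)
    return(structure(list(Y = matrix(0, 0, Tn), eigenvalues = ev,
                          variance_explained = numeric(0), rank_zero = TRUE,
                          theta_deg = NULL, method = "mds"),
                     class = "mds_embedding"))
  M <- if (is.null(n_components)) n_pos else min(n_components, n_pos)
  Y <- t(e$vectors[, seq_len(M), drop = FALSE]) * sqrt(ev[seq_len(M)])
  ve <- cumsum(ev[seq_len(n_pos)]) / sum(ev[seq_len(n_pos)])
  structure(list(Y = Y, eigenvalues = ev, variance_explained = ve,
                 rank_zero = FALSE, theta_deg = NULL, method = "mds"),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat("<mds_embedding>", x$method, ":", nrow(x$Y), "components x",
      ncol(x$Y), "frames\n")
  if (length(x$variance_explained))
    cat(sprintf("  components for 90%% variance: %d\n",
                manifold_dimensionality(x, 0.9)))
  invisible(x)
}

#' Pairwise cosine dissimilarity
#'
#' D[s, t] = 1 - <x_s, x_t> / (|x_s| |x_t|); scale-invariant in the columns.
#' Columns must be nonzero.
#'
#' @param X N x T matrix of population vectors (columns).
#' @return T x T symmetric dissimilarity matrix with zero diagonal.
#' @export
cosine_dissimilarity <- function(X) {
  nrm <- sqrt(colSums(X^2))
  if (any(nrm == 0))
    stop("cosine distance undefined for all-zero population vectors",
         call. = FALSE)
  Xn <- sweep(X, 2, nrm, "/")
  D <- 1 - crossprod(Xn)
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

double_center <- function(D2) {
  rm <- rowMeans(D2)
  -0.5 * (D2 - outer(rm, rep(1, ncol(D2))) -
            outer(rep(1, nrow(D2)), colMeans(D2)) + mean(D2))
}

#' Manifold dimensionality at a variance threshold
#'
#' Smallest number of components whose cumulative variance (over the
#' positive spectrum) reaches the threshold.
#'
#' @param emb An `mds_embedding`.
#' @param threshold Cumulative-variance threshold (default 0.9).
#' @return Integer dimensionality.
#' @export
manifold_dimensionality <- function(emb, threshold = 0.9) {
  ve <- emb$variance_explained
  if (!length(ve)) stop("empty positive spectrum", call. = FALSE)
  which(ve >= threshold - 1e-12)[1L]
}

#' Dimensionality as a function of ensemble size
#'
#' For each ensemble size, draws random cell subsets, embeds each and
#' averages the dimensionality at the 90% threshold.
#'
#' @param session An [aligned_session()].
#' @param sizes Ensemble sizes (each <= number of cells).
#' @param n_draws Random subsets per size.
#' @param seed Integer seed.
#' @param threshold Variance threshold.
#' @param max_frames Frame cap passed to [population_matrix()].
#' @return Data frame with `size`, `mean_dimensionality`, `sd_dimensionality`.
#' @export
dimensionality_curve <- function(session, sizes, n_draws = 5, seed = 1L,
                                 threshold = 0.9, max_frames = 1000) {
  n_cells <- session$n_cells
  if (any(sizes > n_cells))
    stop("ensemble size exceeds number of cells", call. = FALSE)
  set.seed(derive_seed(seed, 7L))
  rows <- lapply(sizes, function(sz) {
    dims <- vapply(seq_len(if (sz == n_cells) 1L else n_draws), function(d) {
      cells <- if (sz == n_cells) seq_len(n_cells)
               else sort(sample.int(n_cells, sz))
      pop <- population_matrix(session, cells, max_frames = max_frames)
      manifold_dimensionality(embed_population(pop), threshold)
    }, 0L)
    data.frame(size = sz, mean_dimensionality = mean(dims),
               sd_dimensionality = stats::sd(dims))
  })
  do.call(rbind, rows)
}

#' Decode angular position with an optimal linear estimator
#'
#' Least-squares linear readout (with intercept) from the first `n_dims`
#' embedding components to the (cos, sin) representation of the angle, under
#' k-fold cross-validation. Folds are contiguous temporal blocks by default
#' to limit autocorrelation leakage; random-frame folds are available.
#' Performance is the mean Pearson correlation between predicted and true
#' cos and sin over held-out frames pooled across folds; the circular
#' correlation of predicted and true angles is also reported.
#'
#' @param emb An `mds_embedding` whose `theta_deg` labels are set, or supply
#'   `theta_deg`.
#' @param n_dims Number of leading components to use.
#' @param k_folds Number of folds (default 5).
#' @param theta_deg Angle labels (deg) if not carried by the embedding.
#' @param blocked Contiguous temporal blocks (default) or random frames.
#' @param seed Seed for random fold assignment.
#' @return Object of class `decoder_result`: `r` (mean componentwise Pearson
#'   correlation), `r_circular`, `predicted_deg`, `true_deg`, `fold`.
#' @export
decode_position_cv <- function(emb, n_dims, k_folds = 5, theta_deg = NULL,
                               blocked = TRUE, seed = 1L) {
  if (is.null(theta_deg)) theta_deg <- emb$theta_deg
  if (is.null(theta_deg)) stop("no angle labels available", call. = FALSE)
  Y <- emb$Y
  if (n_dims > nrow(Y))
    stop("n_dims exceeds available components", call. = FALSE)
  Tn <- ncol(Y)
  if (Tn < k_folds) stop("need T >= k_folds frames", call. = FALSE)
  Z <- t(Y[seq_len(n_dims), , drop = FALSE])
  th <- theta_deg * pi / 180
  targets <- cbind(cos(th), sin(th))
  fold <- if (blocked) {
    cut(seq_len(Tn), breaks = k_folds, labels = FALSE)
  } else {
    set.seed(derive_seed(seed, 11L))
    sample(rep_len(seq_len(k_folds), Tn))
  }
  pred <- matrix(NA_real_, Tn, 2)
  for (f in seq_len(k_folds)) {
    test <- fold == f
    if (sum(test) < 1L || sum(!test) < 2L)
      stop("fold with too few samples", call. = FALSE)
    A <- cbind(1, Z[!test, , drop = FALSE])
    W <- qr.solve(A, targets[!test, , drop = FALSE])
    pred[test, ] <- cbind(1, Z[test, , drop = FALSE]) %*% W
  }
  r_cos <- stats::cor(pred[, 1], targets[, 1])
  r_sin <- stats::cor(pred[, 2], targets[, 2])
  pred_deg <- wrap_deg(atan2(pred[, 2], pred[, 1]) * 180 / pi)
  structure(list(r = mean(c(r_cos, r_sin)), r_cos = r_cos, r_sin = r_sin,
                 r_circular = circular_correlation(pred_deg, theta_deg),
                 predicted_deg = pred_deg, true_deg = wrap_deg(theta_deg),
                 fold = fold, n_dims = n_dims, k_folds = k_folds),
            class = "decoder_result")
}

# Jammalamadaka-SenGupta circular correlation coefficient
circular_correlation <- function(a_deg, b_deg) {
  a <- a_deg * pi / 180; b <- b_deg * pi / 180
  am <- atan2(mean(sin(a)), mean(cos(a)))
  bm <- atan2(mean(sin(b)), mean(cos(b)))
  num <- sum(sin(a - am) * sin(b - bm))
  den <- sqrt(sum(sin(a - am)^2) * sum(sin(b - bm)^2))
  if (den == 0) return(NA_real_)
  num / den
}

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf("<decoder_result> %d dims, %d folds: r = %.3f (circular %.3f)\n",
              x$n_dims, x$k_folds, x$r, x$r_circular))
  invisible(x)
}
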