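#' PCA composite gene weights
#'
#' Principal component analysis of the samples x genes -ddCt matrix.
#' Treatment structure typically concentrates on components 2 and 3 (the
#' first component largely carries within-type expression magnitude), so
#' each gene's contribution to treatment clustering is summarized by the
#' composite weight `sqrt(loading_PC2^2 + loading_PC3^2)`. The composite is
#' invariant to the arbitrary sign of either component.
#'
#' Genes carrying any missing value in the analyzed subset are excluded
#' with a message (a QC-passing matrix is expected to be complete).
#'
#' @param expr [expression_matrix()] or matrix, >= 3 samples and >= 3
#'   complete genes of rank >= 3
#' @param standardize scale genes to unit variance before PCA (default
#'   TRUE, consistent with z-scored heat-map displays); FALSE gives
#'   covariance PCA
#' @return data.frame of class `composite_weights`: gene, pc2, pc3,
#'   composite, ranked by decreasing composite; fraction of variance
#'   explained per PC in attribute `var_explained`
#' @export
pca_composite_weights <- function(expr, standardize = TRUE) {
  x <- expr_values(expr)
  complete <- colSums(is.na(x)) == 0
  if (!all(complete))
    message("pca_composite_weights: excluded ", sum(!complete),
            " gene(s) with missing values: ",
            paste(colnames(x)[!complete], collapse = ", "))
  x <- x[, complete, drop = FALSE]
  if (nrow(x) < 3 || ncol(x) < 3) stop("need >= 3 samples and >= 3 complete genes")
  sds <- apply(x, 2, stats::sd)
  if (standardize && any(sds == 0))
    stop("zero-variance gene(s) cannot be standardized: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  if (ncol(pc$rotation) < 3) stop("matrix rank < 3; components 2 and 3 undefined")
  load2 <- pc$rotation[, 2]
  load3 <- pc$rotation[, 3]
  out <- data.frame(gene = colnames(x), pc2 = unname(load2), pc3 = unname(load3),
                    composite = unname(sqrt(load2^2 + load3^2)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$composite, out$gene), ]
  rownames(out) <- NULL
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  attr(out, "var_explained") <- ve
  attr(out, "rotation") <- pc$rotation
  class(out) <- c("composite_weights", "data.frame")
  out
}

#' Fisher linear discriminant projection
#'
#' Projects samples onto the `C - 1` Fisher discriminants maximizing
#' between-class over within-class scatter. The convention (stated because
#' centroid distances depend on it): `S_W` is the pooled within-class
#' covariance (denominator `N - C`), `S_B` the between-class covariance
#' weighted by class sizes; the generalized eigenproblem is solved by
#' symmetric whitening, and every discriminant is scaled to unit pooled
#' within-class variance (`a' S_W a = 1`). Signs are fixed by making each
#' discriminant's largest-magnitude gene loading positive. Genes with
#' missing values in the analyzed subset are excluded with a message.
#'
#' @param expr [expression_matrix()] or matrix
#' @param labels class (treatment) label per sample
#' @param regularization ridge added to `S_W` as a fraction of
#'   `mean(diag(S_W))` (default 1e-6) for numerical stability
#' @return samples x (C-1) coordinate matrix, with attributes `scaling`
#'   (gene loadings), `eigenvalues`, and `labels`
#' @export
lda_project <- function(expr, labels, regularization = 1e-6) {
  x <- expr_values(expr)
  complete <- colSums(is.na(x)) == 0
  if (!all(complete))
    message("lda_project: excluded ", sum(!complete), " gene(s) with missing values: ",
            paste(colnames(x)[!complete], collapse = ", "))
  x <- x[, complete, drop = FALSE]
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stop("one label per sample required")
  cls <- sort(unique(labels))
  if (length(cls) < 2) stop("need >= 2 classes")
  n <- nrow(x); p <- ncol(x); C <- length(cls)
  mu <- colMeans(x)
  sw <- matrix(0, p, p)
  sb <- matrix(0, p, p)
  for (cl in cls) {
    xi <- x[labels == cl, , drop = FALSE]
    ni <- nrow(xi)
    if (ni > 1) sw <- sw + (ni - 1) * stats::cov(xi)
    d <- colMeans(xi) - mu
    sb <- sb + ni * tcrossprod(d)
  }
  sw <- sw / (n - C)
  sb <- sb / n
  sw <- sw + regularization * mean(diag(sw)) * diag(p)
  es <- eigen(sw, symmetric = TRUE)
  if (min(es$values) <= 0)
    stop("within-class scatter singular; increase `regularization` (ridge)")
  w_half_inv <- es$vectors %*% diag(1 / sqrt(es$values), p) %*% t(es$vectors)
  m <- w_half_inv %*% sb %*% w_half_inv
  em <- eigen((m + t(m)) / 2, symmetric = TRUE)
  k <- min(C - 1, p)
  a <- w_half_inv %*% em$vectors[, seq_len(k), drop = FALSE]
  # unit pooled within-class variance along each discriminant (a' S_W a = 1
  # holds by construction up to the ridge; renormalize exactly)
  for (j in seq_len(k)) {
    s <- sqrt(drop(crossprod(a[, j], sw %*% a[, j])))
    a[, j] <- a[, j] / s
    i_max <- which.max(abs(a[, j]))
    if (a[i_max, j] < 0) a[, j] <- -a[, j]
  }
  coords <- sweep(x, 2, mu) %*% a
  colnames(coords) <- paste0("LD", seq_len(k))
  rownames(a) <- colnames(x)
  colnames(a) <- colnames(coords)
  attr(coords, "scaling") <- a
  attr(coords, "eigenvalues") <- em$values[seq_len(k)]
  attr(coords, "labels") <- labels
  coords
}

#' Class centroids and pairwise distances in discriminant space
#'
#' The centroid of each class is its mean coordinate in the full `C - 1`
#' dimensional discriminant space; separation between treatments is
#' quantified by pairwise Euclidean distances between centroids.
#'
#' @param coords sample coordinates (e.g. from [lda_project()])
#' @param labels class label per sample (defaults to the labels carried by
#'   `coords`)
#' @return list of class `centroid_table`: `centroids` (class x dimension
#'   matrix) and `distances` (symmetric matrix)
#' @export
centroid_distances <- function(coords, labels = attr(coords, "labels")) {
  if (is.null(labels)) stop("labels required")
  m <- as.matrix(coords)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  for (cl in cls) if (!any(labels == cl)) stop("empty class: ", cl)
  cen <- do.call(rbind, lapply(cls, function(cl)
    colMeans(m[labels == cl, , drop = FALSE])))
  rownames(cen) <- cls
  d <- as.matrix(stats::dist(cen))
  structure(list(centroids = cen, distances = d), class = "centroid_table")
}

#' @export
print.centroid_table <- function(x, ...) {
  cat("centroid_table (", nrow(x$centroids), " classes)\n", sep = "")
  print(round(x$distances, 3))
  invisible(x)
}
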