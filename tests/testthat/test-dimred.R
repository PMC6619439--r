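make_treatment_expr <- function(n_per = 12, seed = 31, gap = 3) {
  set.seed(seed)
  trts <- rep(c("Placebo", "Morphine", "Withdrawal"), each = n_per)
  n <- length(trts)
  x <- matrix(rnorm(n * 8, 0, 1), n, 8,
              dimnames = list(paste0("s", 1:n), paste0("g", 1:8)))
  # g1 carries the withdrawal axis
  x[trts == "Withdrawal", 1] <- x[trts == "Withdrawal", 1] + gap
  list(x = x, trts = trts)
}

test_that("composite weights follow the root-sum-square of PC2/PC3 loadings", {
  fx <- make_treatment_expr()
  w <- pca_composite_weights(fx$x)
  rot <- attr(w, "rotation")
  for (i in seq_len(nrow(w))) {
    g <- w$gene[i]
    expect_equal(w$composite[i], sqrt(rot[g, 2]^2 + rot[g, 3]^2))
    expect_equal(w$composite[i], sqrt(w$pc2[i]^2 + w$pc3[i]^2))
  }
  # loadings orthonormal; variance fractions sum to 1
  expect_equal(crossprod(rot), diag(ncol(rot)), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(sum(attr(w, "var_explained")), 1, tolerance = 1e-10)
  # 3-4-5 arithmetic of the formula itself
  expect_equal(sqrt(0.3^2 + 0.4^2), 0.5)
})

test_that("composite ranking is invariant to PC sign flips", {
  fx <- make_treatment_expr()
  w <- pca_composite_weights(fx$x)
  rot <- attr(w, "rotation")
  flipped <- sqrt((-rot[, 2])^2 + (-rot[, 3])^2)
  expect_equal(unname(flipped[w$gene]), w$composite)
})

test_that("a gene carrying the planted treatment axis ranks at the top", {
  # variation structure: PC1 = shared magnitude, treatment axis on g1
  set.seed(32)
  trts <- rep(c("Placebo", "Morphine", "Withdrawal"), each = 15)
  n <- length(trts)
  shared <- rnorm(n, 0, 3) # dominant common axis soaks up PC1
  x <- sapply(1:8, function(j) shared + rnorm(n, 0, 0.4))
  dimnames(x) <- list(paste0("s", 1:n), paste0("g", 1:8))
  x[trts == "Withdrawal", 1] <- x[trts == "Withdrawal", 1] + 4
  w <- pca_composite_weights(x, standardize = FALSE)
  expect_equal(w$gene[1], "g1")
})

test_that("rank-deficient input is rejected", {
  x <- matrix(rnorm(6), 2, 3, dimnames = list(c("a", "b"), c("g1", "g2", "g3")))
  expect_error(pca_composite_weights(x), ">= 3 samples")
})

test_that("LDA separates planted classes and collapses identical-mean classes", {
  set.seed(33)
  lab <- rep(c("a", "b"), each = 40)
  x0 <- matrix(rnorm(80 * 2), 80, 2, dimnames = list(paste0("s", 1:80), c("g1", "g2")))
  co0 <- lda_project(x0, lab)
  expect_lt(attr(co0, "eigenvalues")[1], 0.2) # no real separation

  x1 <- x0
  x1[lab == "b", 1] <- x1[lab == "b", 1] + 4 # 4 sigma gap
  co1 <- lda_project(x1, lab)
  # overlap along LD1 consistent with the Gaussian Bayes error at a
  # 4-sigma mean gap (pnorm(-2) ~ 2.3%)
  thr <- mean(c(mean(co1[lab == "a", 1]), mean(co1[lab == "b", 1])))
  mis <- mean(c(co1[lab == "a", 1] > thr, co1[lab == "b", 1] < thr))
  expect_lt(mis, 0.05)
})

test_that("LDA discriminants have unit pooled within-class variance", {
  fx <- make_treatment_expr()
  co <- lda_project(fx$x, fx$trts)
  # recompute pooled within-class variance along each discriminant
  for (j in seq_len(ncol(co))) {
    ssw <- 0
    for (cl in unique(fx$trts)) {
      v <- co[fx$trts == cl, j]
      ssw <- ssw + sum((v - mean(v))^2)
    }
    expect_equal(ssw / (nrow(co) - length(unique(fx$trts))), 1,
                 tolerance = 1e-4) # exact up to the default ridge
  }
})

test_that("sample coordinates are invariant to affine rescaling of one gene (up to sign)", {
  fx <- make_treatment_expr()
  co1 <- lda_project(fx$x, fx$trts)
  x2 <- fx$x
  x2[, 3] <- 5 * x2[, 3] - 7
  co2 <- lda_project(x2, fx$trts)
  for (j in seq_len(ncol(co1)))
    expect_true(isTRUE(all.equal(co1[, j], co2[, j], tolerance = 1e-4)) ||
                  isTRUE(all.equal(co1[, j], -co2[, j], tolerance = 1e-4)))
})

test_that("centroid distances are invariant under invertible linear maps of gene space", {
  fx <- make_treatment_expr()
  d1 <- centroid_distances(lda_project(fx$x, fx$trts))$distances
  set.seed(34)
  for (i in 1:5) {
    a <- matrix(rnorm(64), 8, 8)
    while (abs(det(a)) < 1e-3) a <- matrix(rnorm(64), 8, 8)
    xt <- fx$x %*% a
    colnames(xt) <- colnames(fx$x)
    d2 <- centroid_distances(lda_project(xt, fx$trts))$distances
    expect_equal(d2, d1, tolerance = 1e-2) # ridge breaks exact invariance

  }
})

test_that("centroid distances agree with the MASS::lda convention", {
  fx <- make_treatment_expr()
  d1 <- centroid_distances(lda_project(fx$x, fx$trts))$distances
  fit <- MASS::lda(fx$x, grouping = fx$trts)
  proj <- predict(fit)$x
  d2 <- centroid_distances(proj, fx$trts)$distances
  expect_equal(d1, d2[rownames(d1), colnames(d1)], tolerance = 1e-3)
})

test_that("centroid geometry: exact distances, symmetry, triangle inequality", {
  co <- matrix(c(0, 0, 0, 0, 3, 4, 3, 4), ncol = 2, byrow = TRUE,
               dimnames = list(paste0("s", 1:4), c("LD1", "LD2")))
  ctab <- centroid_distances(co, c("a", "a", "b", "b"))
  expect_equal(ctab$distances["a", "b"], 5)
  expect_equal(ctab$distances["a", "a"], 0)

  dup <- centroid_distances(co[c(1, 1), ], c("x", "y"))
  expect_equal(dup$distances["x", "y"], 0)

  fx <- make_treatment_expr()
  d <- centroid_distances(lda_project(fx$x, fx$trts))$distances
  expect_equal(d, t(d))
  cls <- rownames(d)
  for (i in cls) for (j in cls) for (k in cls)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})
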