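test_that("geNorm M is zero for a constant-ratio pair and matches a frozen hand example", {
  ct <- tiny_ct(cbind(c(20, 22, 24, 26), c(21, 23, 25, 27)),
                assays = c("hk1", "hk2"))
  gm <- genorm_m(ct, c("hk1", "hk2"))
  expect_equal(unname(gm$m), c(0, 0))

  # 3 candidates x 4 samples, small integers; expected values computed by
  # enumerating all pairwise SDs by hand
  ct3 <- tiny_ct(cbind(c(20, 21, 22, 23), c(20, 22, 21, 24), c(25, 24, 26, 25)),
                 assays = c("A", "B", "C"))
  gm3 <- genorm_m(ct3, c("A", "B", "C"))
  expect_equal(gm3$m, c(A = 1.1242108, B = 1.5094900, C = 1.6762736),
               tolerance = 1e-6)
  expect_equal(gm3$exclusion_order, "C") # least stable leaves first
})

test_that("geNorm M equals the brute-force pairwise-SD oracle on random instances", {
  set.seed(42)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    n <- sample(4:20, 1)
    x <- matrix(rnorm(n * k, 25, sample(1:3, 1)), n, k,
                dimnames = list(paste0("s", 1:n), paste0("hk", 1:k)))
    got <- genorm_m(ct_matrix(x), colnames(x))$m
    expect_equal(got, genorm_oracle(x, colnames(x)), tolerance = 1e-12)
  }
})

test_that("a planted high-noise candidate is excluded first", {
  set.seed(5)
  base <- rnorm(30, 25, 1.5) # shared input-amount variation
  x <- sapply(c(0.1, 0.12, 0.15, 0.11, 2), function(s) base + rnorm(30, 0, s))
  dimnames(x) <- list(paste0("s", 1:30), paste0("hk", 1:5))
  gm <- genorm_m(ct_matrix(x), colnames(x))
  expect_equal(gm$exclusion_order[1], "hk5")
})

test_that("reference selection minimizes combined rank with deterministic ties", {
  set.seed(8)
  base <- rnorm(40, 25, 1)
  x <- sapply(c(Ldha = 0.1, Actb = 0.12, Hprt1 = 0.6, B2m = 0.9),
              function(s) base + rnorm(40, 0, s))
  rownames(x) <- paste0("s", 1:40)
  rk <- hk_stability(ct_matrix(x), colnames(x))
  expect_setequal(select_reference_genes(rk, 2), c("Ldha", "Actb"))
  expect_setequal(select_reference_genes(rk, 4), colnames(x))
  expect_error(select_reference_genes(rk, 5), "exceeds")

  # exact tie in both measures: lower variance wins, then name
  rk2 <- data.frame(assay = c("b", "a"), variance = c(1, 1), m = c(0.5, 0.5),
                    combined_rank = c(1.5, 1.5))
  expect_equal(select_reference_genes(rk2, 1), "a")
})

test_that("designated controls are normalized but never selectable as reference", {
  set.seed(9)
  base <- rnorm(30, 25, 1)
  x <- sapply(c(Gapdh = 0.01, Ldha = 0.2, Actb = 0.25, B2m = 0.8),
              function(s) base + rnorm(30, 0, s))
  rownames(x) <- paste0("s", 1:30)
  rk <- hk_stability(ct_matrix(x), candidates = colnames(x), controls = "Gapdh")
  expect_false("Gapdh" %in% rk$assay) # most stable, yet not a candidate
  expect_setequal(select_reference_genes(rk, 2), c("Ldha", "Actb"))
})

test_that("-dCt follows the reference-mean arithmetic and the naive oracle", {
  ct <- tiny_ct(cbind(r1 = c(20, 20), r2 = c(22, 22), gene = c(25, 19)),
                assays = c("r1", "r2", "gene"))
  nd <- neg_delta_ct(ct, c("r1", "r2"))
  expect_equal(unname(nd[, "gene"]), c(-4, 2)) # 21 - 25, 21 - 19

  set.seed(10)
  x <- matrix(rnorm(8 * 6, 25, 2), 8, 6,
              dimnames = list(paste0("s", 1:8), paste0("g", 1:6)))
  x[2, 5] <- NA
  refs <- c("g1", "g2")
  nd2 <- neg_delta_ct(ct_matrix(x), refs)
  for (s in rownames(x)) for (g in setdiff(colnames(x), refs)) {
    want <- mean(c(x[s, "g1"], x[s, "g2"])) - x[s, g]
    expect_equal(unname(nd2[s, g]), want)
  }
})

test_that("samples with a reference non-detect are dropped with a message", {
  x <- matrix(rnorm(12, 25, 1), 4, 3,
              dimnames = list(paste0("s", 1:4), c("r1", "r2", "g")))
  x[3, "r1"] <- NA
  expect_message(nd <- neg_delta_ct(ct_matrix(x), c("r1", "r2")), "s3")
  expect_equal(rownames(nd), c("s1", "s2", "s4"))
})

test_that("-dCt is invariant to a constant per-sample Ct shift", {
  set.seed(12)
  x <- matrix(rnorm(60, 25, 2), 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("g", 1:6)))
  shift <- rnorm(10, 0, 3)
  nd0 <- neg_delta_ct(ct_matrix(x), c("g1", "g2"))
  nd1 <- neg_delta_ct(ct_matrix(x + shift), c("g1", "g2"))
  expect_equal(nd1, nd0, tolerance = 1e-12)
})

test_that("median centering zeroes each gene's median in scope, exactly", {
  set.seed(13)
  x <- matrix(rnorm(55, 0, 2), 11, 5,
              dimnames = list(paste0("s", 1:11), paste0("g", 1:5)))
  e <- median_center(x)
  meds <- apply(unclass(e), 2, median)
  expect_equal(unname(meds), rep(0, 5))
  # odd n: one sample sits exactly at 0 per gene
  expect_true(all(colSums(unclass(e) == 0) >= 1))
  # constant gene centers to all zeros
  xc <- x; xc[, 3] <- 7
  expect_equal(unname(unclass(median_center(xc))[, 3]), rep(0, 11))
  # per-group scope zeroes medians within each group
  grp <- rep(c("a", "b"), c(5, 6))
  eg <- median_center(x, scope = grp)
  for (g in c("a", "b"))
    expect_equal(unname(apply(unclass(eg)[grp == g, ], 2, median)), rep(0, 5))
})

test_that("z-scoring gives unit-variance genes and flags flat genes", {
  set.seed(14)
  x <- matrix(rnorm(50), 10, 5, dimnames = list(paste0("s", 1:10), paste0("g", 1:5)))
  x[, 4] <- 2.5
  z <- zscore_by_gene(x)
  for (j in c(1, 2, 3, 5)) {
    expect_equal(mean(z[, j]), 0, tolerance = 1e-12)
    expect_equal(sd(z[, j]), 1, tolerance = 1e-12)
    # naive two-pass oracle
    expect_equal(unname(z[, j]),
                 unname((x[, j] - mean(x[, j])) / sd(x[, j])))
  }
  expect_equal(unname(z[, 4]), rep(0, 10))
  expect_equal(attr(z, "zero_sd_genes"), "g4")
})

test_that("the planted most-stable pair is selected in >= 95% of replicates", {
  # sample size matches a per-cell-type panel (about 96 pools)
  set.seed(15)
  hit <- 0
  reps <- 100
  for (i in seq_len(reps)) {
    base <- rnorm(96, 25, 1)
    x <- sapply(c(Ldha = 0.15, Actb = 0.2, Hprt1 = 0.6, B2m = 0.8, Rpl13 = 0.7),
                function(s) base + rnorm(96, 0, s))
    rownames(x) <- paste0("s", 1:96)
    rk <- hk_stability(ct_matrix(x), colnames(x))
    if (setequal(select_reference_genes(rk, 2), c("Ldha", "Actb"))) hit <- hit + 1
  }
  expect_gte(hit / reps, 0.95)
})
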