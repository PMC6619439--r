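test_that("identical values give F = 0, p = 1", {
  fx <- nested_expr(c(Placebo = 0, Withdrawal = 0), animal_sd = 0, resid_sd = 0)
  fx$x[] <- 1.7
  res <- nested_anova(fx$x, fx$meta, "g1")
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
})

test_that("balanced toy F matches the brute-force sums-of-squares oracle", {
  set.seed(21)
  for (i in 1:10) {
    fx <- nested_expr(c(A = 0, B = 1, C = 0.5), n_animals = 4, n_pools = 5,
                      animal_sd = 0.5, resid_sd = 0.7)
    got <- nested_anova(fx$x, fx$meta, "g1")
    want <- nested_f_oracle(fx$d)
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(got$df1, 2L)
    expect_equal(got$df2, 9L)
    # balanced closed form agrees exactly with animal-mean collapse
    bal <- nested_anova(fx$x, fx$meta, "g1", method = "balanced")
    expect_equal(bal$F, got$F, tolerance = 1e-10)
  }
})

test_that("integer toy example is reproduced by hand computation", {
  # 2 treatments x 2 animals x 2 pools, integer data
  d <- data.frame(
    sample_id = paste0("s", 1:8),
    animal_id = rep(c("A1", "A2", "B1", "B2"), each = 2),
    treatment = rep(c("A", "B"), each = 4),
    cell_type = "neuron", batch_id = "b1")
  x <- matrix(c(1, 3, 2, 4, 5, 7, 6, 8), ncol = 1,
              dimnames = list(d$sample_id, "g"))
  # animal means 2, 3, 6, 7; treatment means 2.5, 6.5; grand 4.5
  # SSB = 2*(2-4.5)^2... on animal means: SSB = 2*(2.5-4.5)^2*... direct:
  # between SS = 2*(2.5-4.5)^2 + 2*(6.5-4.5)^2 = 16; within SS = 0.5+0.5 = 1
  # F = (16/1) / (1/2) = 32
  res <- nested_anova(x, sample_meta(d), "g")
  expect_equal(res$F, 32)
  expect_equal(res$df1, 1L)
  expect_equal(res$df2, 2L)
})

test_that("fewer than two animals per treatment is an error", {
  d <- data.frame(sample_id = paste0("s", 1:4),
                  animal_id = c("A1", "A1", "B1", "B2"),
                  treatment = rep(c("A", "B"), each = 2),
                  cell_type = "neuron", batch_id = "b1")
  x <- matrix(rnorm(4), ncol = 1, dimnames = list(d$sample_id, "g"))
  expect_error(nested_anova(x, sample_meta(d), "g"), "< 2 animals")
})

test_that("nested ANOVA holds its size under animal-level noise while pooled ANOVA inflates", {
  set.seed(22)
  reps <- 300
  nested_rej <- 0; pooled_rej <- 0
  for (i in seq_len(reps)) {
    fx <- nested_expr(c(P = 0, M = 0, N = 0, W = 0), n_animals = 4,
                      n_pools = 8, animal_sd = 0.5, resid_sd = 0.5)
    p_nested <- nested_anova(fx$x, fx$meta, "g1")$p
    p_pooled <- anova(lm(y ~ treatment, data = fx$d))$`Pr(>F)`[1]
    nested_rej <- nested_rej + (p_nested < 0.05)
    pooled_rej <- pooled_rej + (p_pooled < 0.05)
  }
  expect_lt(nested_rej / reps, 0.10)   # near nominal
  expect_gt(pooled_rej / reps, 0.15)   # grossly anticonservative
})

test_that("two-way abundance ANOVA: degenerate, planted, and hand-checked cases", {
  meta <- sample_meta(data.frame(
    sample_id = paste0("s", 1:16),
    animal_id = paste0("A", 1:16),
    treatment = rep(c("Placebo", "Morphine", "Naltrexone", "Withdrawal"), each = 4),
    cell_type = "cecal", batch_id = "b1"))

  # all-equal abundances -> p = 1
  flat <- matrix(2, 16, 2, dimnames = list(meta$sample_id, c("t1", "t2")))
  res <- two_way_anova(flat, meta)
  expect_equal(res$p, c(1, 1))

  # planted 2-unit Withdrawal shift is detected and the contrasts agree
  set.seed(23)
  x <- matrix(rnorm(32, 0, 0.5), 16, 2,
              dimnames = list(meta$sample_id, c("hit", "null")))
  x[meta$treatment == "Withdrawal", "hit"] <-
    x[meta$treatment == "Withdrawal", "hit"] + 2
  res2 <- two_way_anova(x, meta)
  hit <- res2[res2$taxon == "hit", ]
  expect_lt(hit$p, 0.05)
  expect_lt(hit$p_Withdrawal_vs_Morphine, 0.05)
  expect_lt(hit$p_Withdrawal_vs_Placebo, 0.05)
  expect_gt(res2[res2$taxon == "null", "p"], 0.05)

  # textbook check on a tiny 2-treatment table: one-way F by hand
  meta2 <- sample_meta(data.frame(
    sample_id = paste0("s", 1:6), animal_id = paste0("A", 1:6),
    treatment = rep(c("Placebo", "Withdrawal"), each = 3),
    cell_type = "cecal", batch_id = "b1"))
  y <- matrix(c(1, 2, 3, 5, 6, 7), ncol = 1, dimnames = list(meta2$sample_id, "t"))
  # means 2 and 6, grand 4; SSB = 3*4 + 3*4 = 24; SSW = 2 + 2 = 4
  # F = 24 / (4/4) = 24, df 1, 4
  res3 <- two_way_anova(y, meta2, model = "per_taxon",
                        contrast_pairs = list(c("Withdrawal", "Placebo")))
  expect_equal(res3$F, 24)
  expect_equal(res3$p, pf(24, 1, 4, lower.tail = FALSE))
})

test_that("a missing design cell is an error that names it", {
  meta <- sample_meta(data.frame(
    sample_id = paste0("s", 1:8), animal_id = paste0("A", 1:8),
    treatment = rep(c("Placebo", "Withdrawal"), each = 4),
    cell_type = "cecal", batch_id = "b1"))
  x <- matrix(rnorm(16), 8, 2, dimnames = list(meta$sample_id, c("t1", "t2")))
  x[meta$treatment == "Placebo", "t2"] <- NA
  expect_error(suppressMessages(two_way_anova(x, meta)), "Placebo x t2")
})

test_that("planted Withdrawal shifts reach contrast power >= 90%", {
  set.seed(24)
  reps <- 200
  meta <- sample_meta(data.frame(
    sample_id = paste0("s", 1:16), animal_id = paste0("A", 1:16),
    treatment = rep(c("Placebo", "Morphine", "Naltrexone", "Withdrawal"), each = 4),
    cell_type = "cecal", batch_id = "b1"))
  hits <- 0
  for (i in seq_len(reps)) {
    x <- matrix(rnorm(16, 0, 0.5), ncol = 1, dimnames = list(meta$sample_id, "t"))
    x[meta$treatment == "Withdrawal", 1] <- x[meta$treatment == "Withdrawal", 1] + 2
    res <- two_way_anova(x, meta, model = "per_taxon",
                         contrast_pairs = list(c("Withdrawal", "Placebo")))
    hits <- hits + (res$p_Withdrawal_vs_Placebo < 0.05)
  }
  expect_gte(hits / reps, 0.90)
})

test_that("BH adjustment matches hand computation and is permutation invariant", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(25)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15)) # monotone in p rank
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_message(qna <- bh_adjust(c(0.01, NaN, 0.5)), "excluded")
  expect_true(is.na(qna[2]))
})
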