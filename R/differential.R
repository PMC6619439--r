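#' Nested ANOVA for one gene
#'
#' Tests a fixed treatment effect with animals (the biological replicates,
#' n = 4 per treatment in the motivating design) as a random factor nested
#' in treatment, and replicate 10-cell pools nested in animals. Testing
#' treatment against the pooled-replicate error would treat pools as
#' independent and inflate the type-I error; here the F statistic is
#' `MS_treatment / MS_animal(treatment)`.
#'
#' Two equivalent routes are provided:
#' \describe{
#'   \item{`"collapse"` (default)}{pools are collapsed to unweighted animal
#'     means and a one-way ANOVA is run across animal means. Valid for
#'     unbalanced pool counts; identical to the closed form when balanced.}
#'   \item{`"balanced"`}{closed-form expected-mean-square decomposition on
#'     the pool-level data; requires equal pool counts per animal.}
#' }
#'
#' @param expr [expression_matrix()] or matrix (samples x genes)
#' @param meta sample annotations ([sample_meta()])
#' @param gene assay name to test
#' @param method `"collapse"` or `"balanced"`
#' @return one-row data.frame: gene, F, df1, df2, p, and per-treatment
#'   median -ddCt columns `median_<treatment>`
#' @export
nested_anova <- function(expr, meta, gene, method = c("collapse", "balanced")) {
  method <- match.arg(method)
  x <- expr_values(expr)
  if (!gene %in% colnames(x)) stop("gene not in matrix: ", gene)
  meta <- meta[match(rownames(x), meta$sample_id), , drop = FALSE]
  d <- data.frame(y = x[, gene], treatment = meta$treatment,
                  animal = meta$animal_id, stringsAsFactors = FALSE)
  d <- d[!is.na(d$y), , drop = FALSE]
  tr_n <- table(unique(d[, c("treatment", "animal")])$treatment)
  if (length(tr_n) < 2) stop("need >= 2 treatments with data for gene ", gene)
  if (any(tr_n < 2))
    stop("treatment(s) with < 2 animals for gene ", gene, ": ",
         paste(names(tr_n)[tr_n < 2], collapse = ", "))

  if (method == "balanced") {
    res <- nested_f_balanced(d)
  } else {
    am <- stats::aggregate(y ~ treatment + animal, data = d, FUN = mean)
    res <- oneway_f(am$y, am$treatment)
  }
  meds <- tapply(d$y, d$treatment, stats::median)
  out <- data.frame(gene = gene, F = res$F, df1 = res$df1, df2 = res$df2,
                    p = res$p, stringsAsFactors = FALSE)
  for (tr in names(meds)) out[[paste0("median_", tr)]] <- unname(meds[tr])
  out
}

# one-way ANOVA F with the degenerate cases pinned down:
# no between-group signal -> F = 0, p = 1; zero error MS with signal ->
# p = NaN with a warning (the caller excludes NaN p from BH).
oneway_f <- function(y, g) {
  g <- factor(g)
  n <- length(y)
  mu <- mean(y)
  gm <- tapply(y, g, mean)
  gn <- tapply(y, g, length)
  ss_b <- sum(gn * (gm - mu)^2)
  ss_w <- sum((y - gm[as.character(g)])^2)
  df1 <- nlevels(g) - 1L
  df2 <- n - nlevels(g)
  if (ss_b <= .Machine$double.eps * max(1, sum(y^2)))
    return(list(F = 0, df1 = df1, df2 = df2, p = 1))
  if (df2 < 1 || ss_w <= 0) {
    warning("zero denominator mean square; p reported as NaN")
    return(list(F = Inf, df1 = df1, df2 = df2, p = NaN))
  }
  f <- (ss_b / df1) / (ss_w / df2)
  list(F = f, df1 = df1, df2 = df2, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# closed-form nested decomposition for balanced pool counts:
# F = MS_treatment / MS_animal(treatment)
nested_f_balanced <- function(d) {
  pools <- table(d$treatment, d$animal)
  per_an <- pools[pools > 0]
  if (length(unique(per_an)) != 1)
    stop("balanced closed form requires equal pool counts per animal")
  mu <- mean(d$y)
  an_mean <- tapply(d$y, d$animal, mean)
  tr_mean <- tapply(d$y, d$treatment, mean)
  tr_of_animal <- tapply(d$treatment, d$animal, function(x) x[1])
  n_pool <- unique(per_an)
  t_lv <- names(tr_mean)
  a_per_t <- tapply(unique(d[, c("treatment", "animal")])$treatment,
                    unique(d[, c("treatment", "animal")])$treatment, length)
  ss_t <- sum(a_per_t[t_lv] * n_pool * (tr_mean - mu)^2)
  ss_a <- n_pool * sum((an_mean - tr_mean[tr_of_animal[names(an_mean)]])^2)
  df1 <- length(t_lv) - 1L
  df2 <- length(an_mean) - length(t_lv)
  if (ss_t <= .Machine$double.eps * max(1, sum(d$y^2)))
    return(list(F = 0, df1 = df1, df2 = df2, p = 1))
  if (ss_a <= 0) {
    warning("zero denominator mean square; p reported as NaN")
    return(list(F = Inf, df1 = df1, df2 = df2, p = NaN))
  }
  f <- (ss_t / df1) / (ss_a / df2)
  list(F = f, df1 = df1, df2 = df2, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Nested ANOVA across all genes with BH adjustment
#'
#' @inheritParams nested_anova
#' @param genes genes to test (default: all columns)
#' @return data.frame, one row per gene, with q values ([bh_adjust()]) and
#'   significance flags at the 0.05 / 0.01 / 0.0001 star conventions
#' @export
nested_anova_table <- function(expr, meta, genes = NULL,
                               method = c("collapse", "balanced")) {
  method <- match.arg(method)
  x <- expr_values(expr)
  if (is.null(genes)) genes <- colnames(x)
  rows <- lapply(genes, function(g) nested_anova(expr, meta, g, method = method))
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$signif <- signif_stars(out$p)
  out
}

signif_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 1e-4, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", ""))))
}

#' Two-way ANOVA for microbial abundance
#'
#' Differential abundance of taxa across treatments on animal-level data
#' (one cecal specimen per animal). The default model is the two-way
#' treatment x taxon linear model on the full panel; per-taxon treatment
#' F/p and the two reported contrasts (Withdrawal vs Morphine, Withdrawal
#' vs Placebo, the `*` / `#` legend symbols) are extracted via
#' estimated marginal means. `model = "per_taxon"` instead fits an
#' independent one-way treatment ANOVA per taxon.
#'
#' @param abund [expression_matrix()] of taxon -ddCt (samples x taxa)
#' @param meta sample annotations
#' @param taxa taxa to test (default all columns)
#' @param model `"treatment_x_taxon"` (default) or `"per_taxon"`
#' @param contrast_pairs list of 2-vectors `c(a, b)` tested as a - b
#' @return data.frame per taxon: F, df1, df2, p, q, contrast p values
#'   (`p_<a>_vs_<b>`), per-treatment medians
#' @export
two_way_anova <- function(abund, meta, taxa = NULL,
                          model = c("treatment_x_taxon", "per_taxon"),
                          contrast_pairs = list(c("Withdrawal", "Morphine"),
                                                c("Withdrawal", "Placebo"))) {
  model <- match.arg(model)
  x <- expr_values(abund)
  if (is.null(taxa)) taxa <- colnames(x)
  if (ncol(x) < 1) stop("no taxa to test")
  meta <- meta[match(rownames(x), meta$sample_id), , drop = FALSE]
  long <- do.call(rbind, lapply(taxa, function(tx)
    data.frame(y = x[, tx], treatment = meta$treatment, taxon = tx,
               stringsAsFactors = FALSE)))
  long <- long[!is.na(long$y), , drop = FALSE]
  cells <- table(long$treatment, long$taxon)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(sprintf("%s x %s", rownames(cells)[bad[, 1]],
                       colnames(cells)[bad[, 2]]), collapse = "; "))
  }
  contrast_pairs <- Filter(function(pr) all(pr %in% long$treatment), contrast_pairs)

  rows <- lapply(taxa, function(tx) {
    sub <- long[long$taxon == tx, ]
    res <- oneway_f(sub$y, sub$treatment)
    meds <- tapply(sub$y, sub$treatment, stats::median)
    out <- data.frame(taxon = tx, F = res$F, df1 = res$df1, df2 = res$df2,
                      p = res$p, stringsAsFactors = FALSE)
    for (tr in names(meds)) out[[paste0("median_", tr)]] <- unname(meds[tr])
    out
  })
  out <- do.call(rbind, rows)

  if (model == "treatment_x_taxon" && length(taxa) > 1) {
    fit <- stats::lm(y ~ treatment * taxon, data = long)
    # a zero-residual (degenerate) fit makes the contrast t tests
    # meaningless; their p values come out NaN, which is intended
    emm <- suppressWarnings(emmeans::emmeans(fit, ~ treatment | taxon))
    for (pr in contrast_pairs) {
      cname <- paste0("p_", pr[1], "_vs_", pr[2])
      ctr <- suppressWarnings(summary(emmeans::contrast(
        emm, method = contrast_list(pr, levels(factor(long$treatment))))))
      out[[cname]] <- ctr$p.value[match(out$taxon, ctr$taxon)]
    }
  } else {
    # per-taxon contrasts from the taxon's own one-way fit
    for (pr in contrast_pairs) {
      cname <- paste0("p_", pr[1], "_vs_", pr[2])
      out[[cname]] <- vapply(out$taxon, function(tx) {
        sub <- long[long$taxon == tx & long$treatment %in% pr, ]
        if (length(unique(sub$treatment)) < 2) return(NA_real_)
        stats::t.test(y ~ treatment, data = sub, var.equal = TRUE)$p.value
      }, 0)
    }
  }
  out$q <- bh_adjust(out$p)
  out
}

contrast_list <- function(pair, lev) {
  w <- as.numeric(lev == pair[1]) - as.numeric(lev == pair[2])
  stats::setNames(list(w), paste0(pair[1], " - ", pair[2]))
}

#' Benjamini-Hochberg q values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (delegates to [stats::p.adjust()]). `NA`/`NaN` p values are excluded
#' from the adjustment (their q is `NA`) and counted in a message.
#'
#' @param p numeric vector of p values in `[0, 1]`
#' @return q values, same length and order as `p`
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  bad <- !is.finite(p)
  if (any(bad))
    message("bh_adjust: ", sum(bad), " undefined p value(s) excluded from adjustment")
  q <- rep(NA_real_, length(p))
  q[!bad] <- stats::p.adjust(p[!bad], method = "BH")
  q
}
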