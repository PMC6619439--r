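#' Detect bimodal expression within a condition
#'
#' Some genes split a treatment group into high- and low-expressing
#' subphenotypes. Detection compares a one- against a two-component
#' Gaussian mixture (unequal variances, deterministic model-based
#' initialization, EM): the gene is called bimodal when the two-component
#' model is preferred by a BIC margin of at least `criterion_threshold`
#' (default 6, a conventional strong-evidence margin) AND both mixture
#' weights clear `min_group / n`, AND both resulting subgroups hold at
#' least `min_group` samples. The split point is the equal-posterior
#' boundary between the two component means.
#'
#' @param values numeric -ddCt vector for one gene in one condition
#' @param min_group minimum samples per subgroup (default 3)
#' @param criterion_threshold required BIC improvement of the 2-component
#'   model (on the -2 log-likelihood scale; larger = more conservative)
#' @param gene,condition labels carried into the result
#' @return object of class `bimodality_call`: `is_bimodal`, `split_point`,
#'   `means`, `sds`, `weights`, `score` (BIC improvement), `status`
#' @export
detect_bimodality <- function(values, min_group = 3, criterion_threshold = 6,
                              gene = NA_character_, condition = NA_character_) {
  x <- values[!is.na(values)]
  n <- length(x)
  call0 <- function(status) structure(
    list(gene = gene, condition = condition, is_bimodal = FALSE,
         split_point = NA_real_, means = NULL, sds = NULL, weights = NULL,
         score = NA_real_, n = n, status = status),
    class = "bimodality_call")
  if (n < 2 * min_group) return(call0("insufficient data"))
  if (stats::sd(x) == 0) return(call0("degenerate (constant values)"))

  f1 <- quiet_mclust(x, 1)
  f2 <- quiet_mclust(x, 2)
  if (is.null(f1) || is.null(f2)) return(call0("mixture fit failed"))
  # mclust BIC is on the 2*loglik - k*log(n) scale (larger = better), so
  # the improvement of the 2-component model is bic2 - bic1
  score <- as.numeric(f2$bic - f1$bic)
  mu <- as.numeric(f2$parameters$mean)
  w <- as.numeric(f2$parameters$pro)
  sd2 <- sqrt(as.numeric(f2$parameters$variance$sigmasq))
  if (length(sd2) == 1) sd2 <- rep(sd2, 2)
  ord <- order(mu)
  mu <- mu[ord]; w <- w[ord]; sd2 <- sd2[ord]
  split <- posterior_boundary(mu, sd2, w)
  lo <- sum(x <= split); hi <- sum(x > split)
  is_bi <- score > criterion_threshold &&
    all(w >= min_group / n) && lo >= min_group && hi >= min_group &&
    diff(mu) > .Machine$double.eps^0.5
  structure(list(gene = gene, condition = condition, is_bimodal = is_bi,
                 split_point = split, means = mu, sds = sd2, weights = w,
                 score = score, n = n, status = "ok"),
            class = "bimodality_call")
}

quiet_mclust <- function(x, g) {
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(x, G = g, modelNames = "V", verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$bic)) NULL else fit
}

# equal-posterior boundary between two component means: the point where
# w1 N(x | m1, s1) = w2 N(x | m2, s2), located inside (m1, m2)
posterior_boundary <- function(mu, sd, w) {
  f <- function(x) w[1] * stats::dnorm(x, mu[1], sd[1]) -
    w[2] * stats::dnorm(x, mu[2], sd[2])
  if (mu[2] - mu[1] < .Machine$double.eps^0.5) return(mean(mu))
  lo <- f(mu[1]); hi <- f(mu[2])
  if (is.finite(lo) && is.finite(hi) && sign(lo) != sign(hi))
    stats::uniroot(f, c(mu[1], mu[2]), tol = 1e-10)$root
  else
    mean(mu) # components too overlapped for a sign change; midpoint
}

#' @export
print.bimodality_call <- function(x, ...) {
  cat("bimodality_call [", x$gene, " / ", x$condition, "]: ",
      if (x$is_bimodal) "bimodal" else "unimodal",
      " (score ", round(x$score, 2), ", n ", x$n, ", ", x$status, ")\n", sep = "")
  invisible(x)
}

#' Bimodality calls for many genes in one condition
#'
#' @param expr [expression_matrix()] or matrix (one condition's samples)
#' @param condition label
#' @inheritParams detect_bimodality
#' @return data.frame: gene, condition, is_bimodal, split_point, component
#'   means/weights, score, n, status
#' @export
bimodality_table <- function(expr, condition = "condition", min_group = 3,
                             criterion_threshold = 6) {
  x <- expr_values(expr)
  rows <- lapply(colnames(x), function(g) {
    b <- detect_bimodality(x[, g], min_group = min_group,
                           criterion_threshold = criterion_threshold,
                           gene = g, condition = condition)
    data.frame(gene = g, condition = condition, is_bimodal = b$is_bimodal,
               split_point = b$split_point,
               mean_low = if (is.null(b$means)) NA_real_ else b$means[1],
               mean_high = if (is.null(b$means)) NA_real_ else b$means[2],
               weight_low = if (is.null(b$weights)) NA_real_ else b$weights[1],
               weight_high = if (is.null(b$weights)) NA_real_ else b$weights[2],
               score = b$score, n = b$n, status = b$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Split a condition by an anchor gene and profile the subgroups
#'
#' Partitions the condition's samples into low/high subgroups at the
#' anchor gene's split point and reports each subgroup's per-gene median
#' expression. When `placebo_reference` (per-gene mean expression of the
#' Placebo group) is supplied, profiles are reported relative to it.
#'
#' @param expr [expression_matrix()] or matrix for the condition
#' @param anchor_gene gene whose bimodal split defines the subgroups
#' @param call a [detect_bimodality()] result for the anchor gene with
#'   `is_bimodal = TRUE` (or a user-supplied split via `split_point`)
#' @param split_point explicit override of the split threshold
#' @param placebo_reference optional named per-gene vector of Placebo means
#' @param min_group minimum subgroup size
#' @return list of class `subgroup_profile`: `profiles` (genes x low/high
#'   medians), `samples` (list of low/high sample ids), `anchor_gene`,
#'   `split_point`
#' @export
split_and_profile <- function(expr, anchor_gene, call = NULL,
                              split_point = NULL, placebo_reference = NULL,
                              min_group = 3) {
  x <- expr_values(expr)
  if (!anchor_gene %in% colnames(x)) stop("anchor gene not in matrix: ", anchor_gene)
  if (is.null(split_point)) {
    if (is.null(call) || !isTRUE(call$is_bimodal))
      stop("anchor gene was not called bimodal; supply `split_point` to force a split")
    split_point <- call$split_point
  }
  a <- x[, anchor_gene]
  lo <- rownames(x)[!is.na(a) & a <= split_point]
  hi <- rownames(x)[!is.na(a) & a > split_point]
  if (length(lo) < min_group || length(hi) < min_group)
    stop("subgroup below the minimum size of ", min_group,
         " (low ", length(lo), ", high ", length(hi), ")")
  med <- function(rows) apply(x[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  prof <- cbind(low = med(lo), high = med(hi))
  if (!is.null(placebo_reference)) {
    ref <- placebo_reference[rownames(prof)]
    if (anyNA(ref)) stop("placebo_reference lacks gene(s): ",
                         paste(rownames(prof)[is.na(ref)], collapse = ", "))
    prof <- prof - ref
  }
  structure(list(profiles = prof, samples = list(low = lo, high = hi),
                 anchor_gene = anchor_gene, split_point = split_point),
            class = "subgroup_profile")
}
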