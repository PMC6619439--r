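#' geNorm stability M values with iterative exclusion
#'
#' For candidate reference genes j, k the pairwise variation
#' `V_jk = sd over samples of (Ct_j - Ct_k)` is computed on
#' pairwise-complete detected values (Ct is already log2-scale, so the
#' difference of Ct values is the log-ratio the original algorithm uses).
#' The stability measure `M_j` is the mean of `V_jk` over all other
#' candidates; lower M means more stable. Iterative exclusion repeatedly
#' removes the least-stable (highest-M) candidate and recomputes M until
#' two remain, recording the order.
#'
#' @param ct a [ct_matrix()] (or plain samples x assays matrix)
#' @param candidates character vector of candidate housekeeping assays
#'   (>= 2, each pair sharing >= `min_shared` detected samples)
#' @param min_shared minimum shared detected samples per candidate pair
#' @return list of class `genorm_result`: `m` (named M values, full
#'   candidate set), `rounds` (list of named M vectors per round),
#'   `exclusion_order` (assays in removal order, least stable first)
#' @export
genorm_m <- function(ct, candidates, min_shared = 3) {
  x <- expr_values(ct)
  miss <- setdiff(candidates, colnames(x))
  if (length(miss)) stop("candidate(s) not in matrix: ", paste(miss, collapse = ", "))
  if (length(candidates) < 2) stop("need >= 2 candidate reference genes")
  xc <- x[, candidates, drop = FALSE]
  m_of <- function(cols) {
    k <- length(cols)
    m <- numeric(k); names(m) <- cols
    for (j in seq_len(k)) {
      v <- vapply(setdiff(seq_len(k), j), function(l) {
        d <- xc[, cols[j]] - xc[, cols[l]]
        d <- d[!is.na(d)]
        if (length(d) < min_shared)
          stop("candidates ", cols[j], " and ", cols[l], " share only ",
               length(d), " detected samples (need >= ", min_shared, ")")
        stats::sd(d)
      }, 0)
      m[j] <- mean(v)
    }
    m
  }
  rounds <- list()
  order_out <- character()
  cur <- candidates
  m_full <- m_of(cur)
  repeat {
    m <- m_of(cur)
    rounds[[length(rounds) + 1L]] <- m
    if (length(cur) <= 2) break
    # drop highest M; ties broken by name for determinism
    worst <- cur[order(-m, cur)][1]
    order_out <- c(order_out, worst)
    cur <- setdiff(cur, worst)
  }
  structure(list(m = m_full, rounds = rounds, exclusion_order = order_out,
                 final_pair = cur),
            class = "genorm_result")
}

#' Housekeeping stability ranking (variance + geNorm)
#'
#' Stability is judged by two measures on the raw Ct values: per-assay
#' expression variance and the geNorm M value ([genorm_m()]). The combined
#' rank is the unweighted mean of the two measure ranks.
#'
#' @inheritParams genorm_m
#' @param controls assays normalized like any other gene but never
#'   selectable as reference (independent controls such as Gapdh); they are
#'   excluded from `candidates` if present.
#' @return data.frame of class `stability_ranking`: assay, variance, M,
#'   variance rank, M rank, combined rank; geNorm exclusion order attached
#'   as attribute `exclusion_order`.
#' @export
hk_stability <- function(ct, candidates, controls = character(), min_shared = 3) {
  candidates <- setdiff(candidates, controls)
  x <- expr_values(ct)
  gm <- genorm_m(ct, candidates, min_shared = min_shared)
  v <- apply(x[, candidates, drop = FALSE], 2, stats::var, na.rm = TRUE)
  rank_v <- rank(v, ties.method = "average")
  rank_m <- rank(gm$m, ties.method = "average")
  out <- data.frame(assay = candidates, variance = unname(v), m = unname(gm$m),
                    rank_variance = unname(rank_v), rank_m = unname(rank_m),
                    combined_rank = unname((rank_v + rank_m) / 2),
                    stringsAsFactors = FALSE)
  attr(out, "exclusion_order") <- gm$exclusion_order
  class(out) <- c("stability_ranking", "data.frame")
  out
}

#' Select the most stable reference genes
#'
#' Picks the `n_refs` candidates (default 2, as when Ldha and Actb emerge
#' as the brain panel's most stable pair) minimizing the combined rank;
#' ties are resolved in favor of the lower-variance assay, then by name.
#'
#' @param ranking a [hk_stability()] result
#' @param n_refs number of reference genes to select
#' @export
select_reference_genes <- function(ranking, n_refs = 2) {
  if (n_refs > nrow(ranking))
    stop("n_refs exceeds the number of candidates")
  ord <- order(ranking$combined_rank, ranking$variance, ranking$assay)
  ranking$assay[ord][seq_len(n_refs)]
}

#' Reference-normalized expression (-dCt)
#'
#' Subtracts each sample's reference signal from each gene:
#' `-dCt(s, g) = ref_mean(s) - Ct(s, g)` where `ref_mean(s)` is the
#' arithmetic mean of the reference genes' Ct in sample s. Because Ct is a
#' log2-scale quantity, the arithmetic mean of Ct is exactly the log of the
#' geometric mean of the linear-scale reference quantities — the geometric
#' mean prescribed for multi-reference normalization (taking the
#' arithmetic mean on the linear scale instead is a common mistake).
#' Higher -dCt means more expressed. Samples in which any reference is a
#' non-detect cannot be normalized and are dropped with a message.
#'
#' @param ct a [ct_matrix()]
#' @param refs reference assay names
#' @param drop_refs drop the reference columns from the output (default
#'   TRUE: references are excluded from downstream analyses)
#' @return samples x genes matrix of -dCt, attribute `reference_genes`
#' @export
neg_delta_ct <- function(ct, refs, drop_refs = TRUE) {
  x <- expr_values(ct)
  miss <- setdiff(refs, colnames(x))
  if (length(miss)) stop("reference assay(s) absent: ", paste(miss, collapse = ", "))
  ref_ct <- x[, refs, drop = FALSE]
  ok <- rowSums(is.na(ref_ct)) == 0
  if (!all(ok))
    message("neg_delta_ct: dropped ", sum(!ok),
            " sample(s) with reference non-detects: ",
            paste(rownames(x)[!ok], collapse = ", "))
  x <- x[ok, , drop = FALSE]
  ref_mean <- rowMeans(ref_ct[ok, , drop = FALSE])
  ndct <- ref_mean - x
  if (drop_refs) ndct <- ndct[, setdiff(colnames(ndct), refs), drop = FALSE]
  attr(ndct, "reference_genes") <- refs
  ndct
}

#' Median-center -dCt into -ddCt
#'
#' Second normalization step: each gene's -dCt values are centered on their
#' median over the centering scope, yielding -ddCt values comparable across
#' treatments and batches. Scope is global (all samples, the default) or
#' per group via a grouping factor.
#'
#' @param ndct samples x genes -dCt matrix from [neg_delta_ct()]
#' @param scope `"global"` or a factor/character vector of group labels per
#'   sample (e.g. cell type) for per-group centering
#' @return an [expression_matrix()]
#' @export
median_center <- function(ndct, scope = "global") {
  x <- as.matrix(ndct)
  if (identical(scope, "global")) {
    groups <- rep("all", nrow(x))
  } else {
    if (length(scope) != nrow(x))
      stop("`scope` must be \"global\" or one group label per sample")
    groups <- as.character(scope)
  }
  for (g in unique(groups)) {
    rows <- groups == g
    med <- apply(x[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    if (any(!is.finite(med)))
      stop("gene(s) with no detected value in centering group '", g, "': ",
           paste(colnames(x)[!is.finite(med)], collapse = ", "))
    x[rows, ] <- sweep(x[rows, , drop = FALSE], 2, med)
  }
  expression_matrix(x,
                    reference_genes = attr(ndct, "reference_genes"),
                    centering_scope = if (identical(scope, "global")) "global" else "per-group")
}

#' Normalized -ddCt expression matrix
#'
#' @param values samples x genes numeric matrix of -ddCt values (unitless
#'   log2-scale relative expression; higher = more expressed)
#' @param reference_genes assays used for reference normalization
#' @param centering_scope grouping used for median centering
#' @export
expression_matrix <- function(values, reference_genes = character(),
                              centering_scope = "global") {
  stopifnot(is.matrix(values), is.numeric(values))
  structure(values, reference_genes = reference_genes,
            centering_scope = centering_scope,
            class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix (-ddCt): ", nrow(x), " samples x ", ncol(x),
      " genes; refs: ", paste(attr(x, "reference_genes"), collapse = ", "),
      "; centering: ", attr(x, "centering_scope"), "\n", sep = "")
  invisible(x)
}

# accept expression_matrix / ct_matrix / plain matrix uniformly
expr_values <- function(x) {
  if (is.matrix(x)) {
    y <- unclass(x)
    attr(y, "reference_genes") <- NULL
    attr(y, "centering_scope") <- NULL
    attr(y, "ct_range") <- NULL
    return(y)
  }
  stop("expected a matrix-like object")
}

#' Full two-step normalization
#'
#' Convenience wrapper: stability ranking on the candidate housekeeping
#' genes, reference selection, -dCt, and median centering.
#'
#' @inheritParams neg_delta_ct
#' @inheritParams hk_stability
#' @inheritParams median_center
#' @param n_refs number of references to select
#' @return list: `expr` ([expression_matrix()]), `stability`
#'   ([hk_stability()] table), `refs`
#' @export
normalize_expression <- function(ct, candidates, controls = character(),
                                 n_refs = 2, scope = "global") {
  ranking <- hk_stability(ct, candidates, controls = controls)
  refs <- select_reference_genes(ranking, n_refs = n_refs)
  ndct <- neg_delta_ct(ct, refs)
  if (!identical(scope, "global")) {
    # samples may have been dropped for reference non-detects
    if (is.null(names(scope))) names(scope) <- rownames(expr_values(ct))
    scope <- scope[rownames(ndct)]
  }
  expr <- median_center(ndct, scope = scope)
  list(expr = expr, stability = ranking, refs = refs)
}

#' Per-gene z-scores for heat-map display
#'
#' `(x - mean) / sd` per gene on detected values. Genes with zero spread
#' are set to 0 and listed in attribute `zero_sd_genes`.
#'
#' @param expr an [expression_matrix()] or matrix
#' @export
zscore_by_gene <- function(expr) {
  x <- expr_values(expr)
  mu <- colMeans(x, na.rm = TRUE)
  sd <- apply(x, 2, stats::sd, na.rm = TRUE)
  flat <- !is.finite(sd) | sd == 0
  sd[flat] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sd, "/")
  z[, flat] <- 0
  attr(z, "zero_sd_genes") <- colnames(x)[flat]
  z
}
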