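#' Build a q-thresholded gene correlation network
#'
#' All-pairs Pearson correlations within one condition (a treatment x cell
#' type subset of samples), with two-sided p values from the t distribution
#' on `n - 2` degrees of freedom and BH adjustment over all tested pairs of
#' the condition. Gene pairs whose q value falls below `q_threshold`
#' (default 0.001) become undirected edges carrying the correlation `r`,
#' its absolute value as weight (edge thickness), and its sign (positive =
#' black, negative = green in the original renderings). Node attributes
#' store each gene's median -ddCt (node color). Pairs with fewer than
#' `min_pairs` complete observations are untested and logged; zero-variance
#' genes are excluded.
#'
#' @param expr [expression_matrix()] or matrix for one condition's samples
#' @param condition label for the network (e.g. "neuron:Withdrawal")
#' @param q_threshold FDR edge criterion (default 0.001)
#' @param min_pairs minimum complete observations per tested pair
#' @return object of class `correlation_network`: `condition`, `nodes`
#'   (gene, median), `edges` (gene1, gene2, r, p, q, n, sign, weight),
#'   `n_tested`
#' @export
build_network <- function(expr, condition = "condition", q_threshold = 0.001,
                          min_pairs = 5) {
  x <- expr_values(expr)
  if (ncol(x) < 2) stop("need >= 2 genes to build a network")
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  flat <- !is.finite(sds) | sds == 0
  if (any(flat))
    message("build_network [", condition, "]: excluded zero-variance gene(s): ",
            paste(colnames(x)[flat], collapse = ", "))
  x <- x[, !flat, drop = FALSE]
  genes <- colnames(x)
  p_genes <- length(genes)
  pr <- utils::combn(p_genes, 2)
  obs <- !is.na(x)
  n_shared <- crossprod(obs)
  r_mat <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  g1 <- pr[1, ]; g2 <- pr[2, ]
  n <- n_shared[cbind(g1, g2)]
  r <- r_mat[cbind(g1, g2)]
  testable <- n >= max(min_pairs, 3) & is.finite(r)
  if (any(!testable))
    message("build_network [", condition, "]: ", sum(!testable),
            " pair(s) below the observation floor left untested")
  df <- n - 2
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[abs(r) >= 1] <- 0
  p[!testable] <- NA
  q <- bh_adjust(p)
  keep <- testable & !is.na(q) & q < q_threshold
  edges <- data.frame(
    gene1 = genes[g1[keep]], gene2 = genes[g2[keep]],
    r = r[keep], p = p[keep], q = q[keep], n = n[keep],
    sign = ifelse(r[keep] >= 0, 1L, -1L), weight = abs(r[keep]),
    stringsAsFactors = FALSE)
  nodes <- data.frame(gene = genes,
                      median = apply(x, 2, stats::median, na.rm = TRUE),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(condition = condition, nodes = nodes, edges = edges,
                 n_tested = sum(testable), q_threshold = q_threshold),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("correlation_network [", x$condition, "]: ", nrow(x$nodes), " genes, ",
      nrow(x$edges), " edges at q < ", x$q_threshold, "\n", sep = "")
  invisible(x)
}

#' Convert a correlation network to an igraph object
#'
#' @param net a [build_network()] result
#' @return an undirected [igraph::graph_from_data_frame()] graph with edge
#'   attributes r/p/q/sign/weight and node attribute `median`
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "correlation_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Write a network edge list as TSV
#'
#' Edge-list export loadable by standard graph tools.
#'
#' @param net a [build_network()] result
#' @param path output file
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Summarize edge counts and per-gene degrees across conditions
#'
#' @param networks named list of [build_network()] results sharing one gene
#'   universe
#' @param delta_pairs list of 2-vectors of condition names; for each pair
#'   `c(a, b)` the per-gene degree difference `a - b` is reported. Defaults
#'   to Withdrawal minus Morphine and Withdrawal minus Placebo wherever the
#'   condition names contain those treatment labels within a cell type.
#' @return list: `edge_counts` (per condition), `degree` (gene x condition
#'   matrix), `degree_delta` (gene x pair matrix, if any pairs)
#' @export
edge_summary <- function(networks, delta_pairs = NULL) {
  if (is.null(names(networks)))
    names(networks) <- vapply(networks, `[[`, "", "condition")
  universes <- lapply(networks, function(n) sort(n$nodes$gene))
  ref <- universes[[1]]
  for (i in seq_along(universes))
    if (!identical(universes[[i]], ref))
      stop("networks do not share a gene universe; differences: ",
           paste(union(setdiff(universes[[i]], ref), setdiff(ref, universes[[i]])),
                 collapse = ", "))
  genes <- ref
  deg <- sapply(networks, function(n) {
    d <- stats::setNames(numeric(length(genes)), genes)
    tab <- table(c(n$edges$gene1, n$edges$gene2))
    d[names(tab)] <- as.numeric(tab)
    d
  })
  deg <- matrix(deg, nrow = length(genes),
                dimnames = list(genes, names(networks)))
  counts <- vapply(networks, function(n) nrow(n$edges), 0L)
  if (is.null(delta_pairs)) delta_pairs <- default_delta_pairs(names(networks))
  dd <- NULL
  if (length(delta_pairs)) {
    dd <- sapply(delta_pairs, function(pr) deg[, pr[1]] - deg[, pr[2]])
    dd <- matrix(dd, nrow = length(genes),
                 dimnames = list(genes, vapply(delta_pairs, function(pr)
                   paste0(pr[1], " - ", pr[2]), "")))
  }
  list(edge_counts = counts, degree = deg, degree_delta = dd)
}

# pair up "<celltype>:Withdrawal" with the matching Morphine/Placebo nets
default_delta_pairs <- function(nms) {
  prs <- list()
  for (w in grep("Withdrawal", nms, value = TRUE)) {
    for (base in c("Morphine", "Placebo")) {
      b <- sub("Withdrawal", base, w)
      if (b %in% nms) prs[[length(prs) + 1L]] <- c(w, b)
    }
  }
  prs
}
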