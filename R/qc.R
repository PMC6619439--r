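#' Quality-control report
#'
#' Bookkeeping record of QC exclusions. `n_datapoints_retained` counts the
#' detected (non-masked) cells of the surviving matrix exactly:
#' retained samples x retained assays minus masked non-detects.
#'
#' @param excluded_assays data.frame with columns `assay`, `reason`
#'   (and `batch` where a batch triggered the exclusion)
#' @param excluded_samples data.frame with columns `sample_id`, `reason`
#' @param ct the post-QC [ct_matrix()]
#' @export
qc_report <- function(excluded_assays, excluded_samples, ct) {
  structure(list(
    excluded_assays = excluded_assays,
    excluded_samples = excluded_samples,
    n_datapoints_retained = sum(detect_mask(ct))
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report: ", nrow(x$excluded_assays), " assay(s) and ",
      nrow(x$excluded_samples), " sample(s) excluded; ",
      x$n_datapoints_retained, " data points retained\n", sep = "")
  invisible(x)
}

empty_assay_exclusions <- function()
  data.frame(assay = character(), batch = character(), reason = character(),
             stringsAsFactors = FALSE)
empty_sample_exclusions <- function()
  data.frame(sample_id = character(), reason = character(), stringsAsFactors = FALSE)

#' Exclude assays that failed within any single batch
#'
#' A transcript measure that fails in one batch (poor signal quality or
#' assay contamination) is removed from the entire dataset — all batches —
#' so that every retained gene is analyzable across the whole design. The
#' failure rule is the within-batch non-detect fraction at or above
#' `failure_rule`; the default 1.0 requires complete failure of the assay
#' in a batch.
#'
#' @param ct a [ct_matrix()]
#' @param meta sample annotations ([sample_meta()]); `batch_id` required
#' @param failure_rule fraction in (0, 1]; an assay whose non-detect
#'   fraction within ANY batch is `>= failure_rule` is dropped everywhere.
#' @return `list(ct =, report =)` with the filtered matrix and a
#'   [qc_report()] naming the triggering batch for each removal.
#' @export
exclude_failed_assays <- function(ct, meta, failure_rule = 1.0) {
  stopifnot(failure_rule > 0, failure_rule <= 1)
  meta <- match_meta(ct, meta)
  nd <- is.na(unclass(ct))
  batches <- unique(meta$batch_id)
  excl <- empty_assay_exclusions()
  for (a in colnames(ct)) {
    for (b in batches) {
      in_b <- meta$batch_id == b
      frac <- mean(nd[in_b, a])
      if (frac >= failure_rule) {
        excl <- rbind(excl, data.frame(
          assay = a, batch = as.character(b),
          reason = sprintf("non-detect fraction %.2f >= %.2f in batch %s",
                           frac, failure_rule, b),
          stringsAsFactors = FALSE))
        break # one triggering batch is enough; removal is global
      }
    }
  }
  keep <- setdiff(colnames(ct), excl$assay)
  if (!length(keep)) stop("no assays survive QC")
  out <- ct_matrix(unclass(ct)[, keep, drop = FALSE], ct_range = attr(ct, "ct_range"))
  if (nrow(excl))
    message("exclude_failed_assays: removed ", nrow(excl), " assay(s): ",
            paste(excl$assay, collapse = ", "))
  list(ct = out, report = qc_report(excl, empty_sample_exclusions(), out))
}

#' Sample-level quality control
#'
#' Drops samples with too many non-detects or with any housekeeping Ct
#' outside the plausible working range (a sign of failed lysis, RT, or
#' loading). Thresholds are explicit configuration.
#'
#' @param ct a [ct_matrix()]
#' @param max_missing_frac maximum tolerated fraction of non-detect assays
#'   per sample (default 0.3)
#' @param hk_genes housekeeping assay names used for the Ct-range check
#'   (may be empty)
#' @param hk_ct_range admissible housekeeping Ct interval in cycles
#' @return `list(ct =, report =)`
#' @export
sample_qc <- function(ct, max_missing_frac = 0.3, hk_genes = character(),
                      hk_ct_range = c(5, 35)) {
  miss <- setdiff(hk_genes, colnames(ct))
  if (length(miss)) stop("housekeeping assay(s) not in matrix: ", paste(miss, collapse = ", "))
  v <- unclass(ct)
  excl <- empty_sample_exclusions()
  frac_nd <- rowMeans(is.na(v))
  bad_miss <- frac_nd > max_missing_frac
  for (s in rownames(ct)[bad_miss])
    excl <- rbind(excl, data.frame(
      sample_id = s,
      reason = sprintf("missing fraction %.2f > %.2f", frac_nd[s], max_missing_frac),
      stringsAsFactors = FALSE))
  if (length(hk_genes)) {
    hk <- v[, hk_genes, drop = FALSE]
    bad_hk <- apply(hk, 1, function(x)
      any(is.na(x)) || any(x < hk_ct_range[1] | x > hk_ct_range[2]))
    for (s in setdiff(rownames(ct)[bad_hk], excl$sample_id))
      excl <- rbind(excl, data.frame(
        sample_id = s,
        reason = sprintf("housekeeping Ct outside [%g, %g] or non-detect",
                         hk_ct_range[1], hk_ct_range[2]),
        stringsAsFactors = FALSE))
  }
  keep <- setdiff(rownames(ct), excl$sample_id)
  if (!length(keep)) stop("all samples dropped by sample QC")
  out <- ct_matrix(v[keep, , drop = FALSE], ct_range = attr(ct, "ct_range"))
  if (nrow(excl))
    message("sample_qc: dropped ", nrow(excl), " sample(s)")
  list(ct = out, report = qc_report(empty_assay_exclusions(), excl, out))
}

#' Validate cell-type identity via marker genes
#'
#' Collection purity is checked on normalized expression: for each cell
#' type, the median expression of its own marker (NeuN for neurons, Maf for
#' microglia, Gfap for astrocytes) must be strictly greater than the median
#' of every other cell type's marker within those samples.
#'
#' @param expr an [expression_matrix()] or plain samples x genes matrix
#' @param meta sample annotations
#' @param marker_map named character vector, `cell_type -> marker assay`
#' @return data.frame per cell type: own-marker median, best other-marker
#'   median, and `pass`
#' @export
validate_celltype_markers <- function(expr, meta, marker_map) {
  x <- expr_values(expr)
  miss <- setdiff(unname(marker_map), colnames(x))
  if (length(miss)) stop("marker assay(s) absent: ", paste(miss, collapse = ", "))
  meta <- meta[match(rownames(x), meta$sample_id), , drop = FALSE]
  res <- lapply(names(marker_map), function(ctype) {
    in_type <- meta$cell_type == ctype
    if (!any(in_type)) return(NULL)
    own <- stats::median(x[in_type, marker_map[[ctype]]], na.rm = TRUE)
    others <- vapply(marker_map[setdiff(names(marker_map), ctype)],
                     function(m) stats::median(x[in_type, m], na.rm = TRUE), 0)
    mo <- if (length(others)) max(others) else -Inf
    data.frame(cell_type = ctype, marker = marker_map[[ctype]],
               own_median = own, max_other_median = mo,
               pass = is.finite(own) && own > mo,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
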