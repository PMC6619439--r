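#' Microbial taxon panel annotations
#'
#' Describes a qPCR panel of bacterial assays: each non-control assay has a
#' taxonomic rank (phylum, class, genus, species, or subgroup) and a phylum
#' membership; at least one pan-bacterial control assay (Pan Bacteria /
#' Universal primers) must be present to serve as the reference for
#' normalization.
#'
#' @param df data.frame with columns `assay`, `rank`, `phylum`,
#'   `is_control` (logical)
#' @return validated data.frame of class `taxon_panel`
#' @export
taxon_panel <- function(df) {
  need <- c("assay", "rank", "phylum", "is_control")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("taxon panel lacks column(s): ", paste(miss, collapse = ", "))
  if (!any(df$is_control)) stop("taxon panel needs >= 1 control assay")
  noncon <- df[!df$is_control, ]
  bad <- is.na(noncon$rank) | noncon$rank == "" | is.na(noncon$phylum) | noncon$phylum == ""
  if (any(bad))
    stop("non-control taxa without rank/phylum annotation: ",
         paste(noncon$assay[bad], collapse = ", "))
  ranks <- c("phylum", "class", "genus", "species", "subgroup")
  unk <- setdiff(noncon$rank, ranks)
  if (length(unk)) stop("unknown rank(s): ", paste(unk, collapse = ", "))
  class(df) <- c("taxon_panel", "data.frame")
  df
}

#' Read a taxon annotation table
#'
#' @param path TSV with columns assay, rank, phylum, is_control
#' @export
read_taxon_panel <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$is_control <- as.logical(df$is_control)
  taxon_panel(df)
}

#' Normalize microbial abundances to pan-bacterial controls
#'
#' Runs the identical two-step machinery as the expression pipeline
#' ([neg_delta_ct()] then [median_center()]) with the panel's control
#' assays as the reference set: taxon Ct is normalized to the mean control
#' Ct within each specimen, then median-centered per taxon across samples.
#' Samples with a control non-detect cannot be normalized and are dropped
#' with a message.
#'
#' @param ct cecal [ct_matrix()] (samples x taxon assays)
#' @param panel a [taxon_panel()]
#' @param scope centering scope, as in [median_center()]
#' @return [expression_matrix()] of taxon -ddCt values
#' @export
normalize_abundance <- function(ct, panel, scope = "global") {
  controls <- panel$assay[panel$is_control]
  ndct <- neg_delta_ct(ct, refs = controls)
  median_center(ndct, scope = scope)
}

#' Firmicutes:Bacteroides ratio with normalization factor
#'
#' The dysbiosis summary: per treatment, `F` and `B` are the median -ddCt
#' of the phylum-level Firmicutes and Bacteroides assays across that
#' treatment's samples. Because -ddCt values are relative (log-scale,
#' median-centered), a normalization factor anchors the Firmicutes side at
#' 1: `NF = 1 - F`, and the ratio is displayed as
#' `(F + NF) : (B + NF) = 1 : r` with `r = B + NF`. `NF` is recomputed per
#' treatment (it is not a fixed constant), which makes `r` invariant to
#' adding a common constant to both medians. The right-hand side is
#' reported at full precision with a banker's-rounded (half-even)
#' two-decimal display value. A non-positive `B + NF` has no meaningful
#' ratio and is flagged as undefined, never clipped.
#'
#' @param expr [expression_matrix()] of taxon -ddCt ([normalize_abundance()])
#' @param panel a [taxon_panel()]; the phylum-level `Firmicutes` and
#'   `Bacteroides` assays are used (Table-style reports use the dedicated
#'   phylum assay, not an aggregate over member taxa)
#' @param meta sample annotations (treatment per sample)
#' @param nf explicit normalization-factor override (named by treatment),
#'   default `NULL` computes `NF = 1 - F`
#' @return data.frame of class `ratio_report`: treatment, F, B, NF,
#'   ratio_rhs, ratio_display, defined
#' @export
fb_ratio <- function(expr, panel, meta, nf = NULL) {
  x <- expr_values(expr)
  f_assay <- panel$assay[!panel$is_control & panel$rank == "phylum" &
                           panel$phylum == "Firmicutes"]
  b_assay <- panel$assay[!panel$is_control & panel$rank == "phylum" &
                           panel$phylum == "Bacteroides"]
  if (length(f_assay) != 1 || length(b_assay) != 1)
    stop("panel must contain exactly one phylum-level Firmicutes and one ",
         "phylum-level Bacteroides assay")
  if (!all(c(f_assay, b_assay) %in% colnames(x)))
    stop("phylum assay(s) missing from the matrix: ",
         paste(setdiff(c(f_assay, b_assay), colnames(x)), collapse = ", "))
  meta <- meta[match(rownames(x), meta$sample_id), , drop = FALSE]
  trts <- unique(meta$treatment)
  fmed <- vapply(trts, function(tr)
    stats::median(x[meta$treatment == tr, f_assay], na.rm = TRUE), 0)
  bmed <- vapply(trts, function(tr)
    stats::median(x[meta$treatment == tr, b_assay], na.rm = TRUE), 0)
  fb_ratio_from_medians(fmed, bmed, treatments = trts, nf = nf)
}

#' Firmicutes:Bacteroides ratio from group medians
#'
#' The ratio arithmetic on already-computed per-treatment medians (e.g. a
#' published summary table): `NF = 1 - F`, displayed ratio
#' `(F + NF) : (B + NF) = 1 : (B + 1 - F)`.
#'
#' @param f_median,b_median per-treatment median -ddCt of the Firmicutes
#'   and Bacteroides phylum assays
#' @param treatments treatment labels (defaults to names of `f_median`)
#' @param nf optional explicit NF override per treatment
#' @return data.frame of class `ratio_report`; `ratio_rhs` is the exact
#'   right-hand side, `ratio_display` its half-even 2-decimal rounding
#' @export
fb_ratio_from_medians <- function(f_median, b_median,
                                  treatments = names(f_median), nf = NULL) {
  if (length(f_median) != length(b_median))
    stop("F and B medians must have equal length")
  if (is.null(treatments)) treatments <- paste0("group", seq_along(f_median))
  if (is.null(nf)) nf <- 1 - f_median
  nf <- unname(nf)
  lhs <- unname(f_median) + nf
  rhs <- unname(b_median) + nf
  defined <- rhs > 0
  if (any(!defined))
    warning("non-positive B + NF for treatment(s): ",
            paste(treatments[!defined], collapse = ", "),
            "; ratio undefined there")
  out <- data.frame(treatment = treatments, F = unname(f_median),
                    B = unname(b_median), NF = nf,
                    lhs = lhs,
                    ratio_rhs = ifelse(defined, rhs, NA_real_),
                    ratio_display = ifelse(defined, round(rhs, 2), NA_real_),
                    defined = defined, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ratio_report", "data.frame")
  out
}

#' @export
print.ratio_report <- function(x, ...) {
  cat("Firmicutes : Bacteroides ratio (normalization-factor adjusted)\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-12s F %7.3f  B %7.3f  NF %6.3f  ratio 1 : %s\n",
                x$treatment[i], x$F[i], x$B[i], x$NF[i],
                ifelse(x$defined[i], format(x$ratio_display[i]), "undefined")))
  invisible(x)
}

#' Classify withdrawal-induced vs. -suppressed taxa
#'
#' Partitions taxa by the sign of `Withdrawal median - Placebo median`
#' (induced / suppressed / none for a zero shift) and attaches the tiered
#' significance symbols used in relative-abundance bar plots
#' (`#` p < 0.1, `*` p < 0.05, `**` p < 0.008, `***` p <= 0.0009), based on
#' the Withdrawal-vs-Placebo contrast when available, else the overall
#' treatment p.
#'
#' @param results per-taxon [two_way_anova()] table
#' @param expr [expression_matrix()] of taxon -ddCt
#' @param meta sample annotations
#' @param reference,target treatments compared (default Placebo vs
#'   Withdrawal)
#' @return data.frame: taxon, delta, direction, p, tier
#' @export
classify_direction <- function(results, expr, meta,
                               reference = "Placebo", target = "Withdrawal") {
  x <- expr_values(expr)
  meta <- meta[match(rownames(x), meta$sample_id), , drop = FALSE]
  taxa <- results$taxon
  delta <- vapply(taxa, function(tx)
    stats::median(x[meta$treatment == target, tx], na.rm = TRUE) -
      stats::median(x[meta$treatment == reference, tx], na.rm = TRUE), 0)
  pcol <- paste0("p_", target, "_vs_", reference)
  p <- if (pcol %in% names(results)) results[[pcol]] else results$p
  tier <- ifelse(is.na(p), "", ifelse(p <= 0.0009, "***", ifelse(p < 0.008, "**",
                ifelse(p < 0.05, "*", ifelse(p < 0.1, "#", "")))))
  direction <- ifelse(delta > 0, "induced", ifelse(delta < 0, "suppressed", "none"))
  data.frame(taxon = taxa, delta = unname(delta), direction = direction,
             p = p, tier = tier, stringsAsFactors = FALSE)
}
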