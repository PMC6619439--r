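#' Run the brain expression pipeline end-to-end
#'
#' Sequences the stages on either a synthetic dataset or user-supplied
#' files: assay/sample QC, housekeeping stability + reference selection,
#' two-step -ddCt normalization, marker validation, nested-ANOVA
#' differential table, PCA composite weights, LDA centroid distances,
#' per-(cell type x treatment) correlation networks, and bimodality calls.
#' Every artifact is written as TSV under `outdir` together with a JSON
#' manifest recording stage parameters and output file hashes; the same
#' config and seed reproduce the manifest exactly.
#'
#' @param config list. Either `simulate = sim_config(...)` or paths
#'   `ct_path` + `meta_path` (see [read_ct_matrix()], [read_sample_meta()]).
#'   Optional elements with defaults: `hk_candidates`, `hk_controls`,
#'   `n_refs` (2), `failure_rule` (1), `max_missing_frac` (0.3),
#'   `hk_ct_range` (c(5, 35)), `centering_scope` ("global" or
#'   "per-cell-type"), `q_threshold` (0.001), `min_pairs` (5), `networks`
#'   (TRUE), `subpheno_genes` (names of `bimodal` spec or NULL),
#'   `marker_map`.
#' @param outdir output directory (created if needed)
#' @return invisible list of all stage results (`expr`, `stability`,
#'   `refs`, `qc`, `differential`, `weights`, `centroids`, `networks`,
#'   `bimodality`, `manifest`)
#' @export
run_brain_pipeline <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  if (!is.null(cfg$simulate)) {
    sim <- generate_sc_qpcr(cfg$simulate)
    ct <- sim$ct; meta <- sim$meta
    if (is.null(cfg$hk_candidates)) cfg$hk_candidates <- names(cfg$simulate$hk_sd)
    if (is.null(cfg$hk_controls)) cfg$hk_controls <- cfg$simulate$hk_control
    if (is.null(cfg$marker_map)) cfg$marker_map <- cfg$simulate$markers
  } else {
    ct <- read_ct_matrix(cfg$ct_path)
    meta <- read_sample_meta(cfg$meta_path)
  }
  if (is.null(cfg$hk_candidates)) stop("config needs `hk_candidates`")
  cfg <- modifyList(list(n_refs = 2, failure_rule = 1, max_missing_frac = 0.3,
                         hk_ct_range = c(5, 35), centering_scope = "global",
                         q_threshold = 0.001, min_pairs = 5, networks = TRUE,
                         hk_controls = character(), marker_map = NULL,
                         subpheno_genes = NULL),
                    cfg)

  aq <- exclude_failed_assays(ct, meta, failure_rule = cfg$failure_rule)
  sq <- sample_qc(aq$ct, max_missing_frac = cfg$max_missing_frac,
                  hk_genes = intersect(cfg$hk_candidates, colnames(aq$ct)),
                  hk_ct_range = cfg$hk_ct_range)
  ct_qc <- sq$ct
  meta_qc <- meta[meta$sample_id %in% rownames(ct_qc), , drop = FALSE]

  scope <- if (identical(cfg$centering_scope, "per-cell-type"))
    stats::setNames(meta_qc$cell_type, meta_qc$sample_id) else "global"
  norm <- normalize_expression(ct_qc,
                               candidates = intersect(cfg$hk_candidates,
                                                      colnames(ct_qc)),
                               controls = cfg$hk_controls,
                               n_refs = cfg$n_refs, scope = scope)
  expr <- norm$expr
  meta_n <- meta_qc[match(rownames(expr), meta_qc$sample_id), , drop = FALSE]

  markers <- NULL
  if (!is.null(cfg$marker_map))
    markers <- validate_celltype_markers(expr, meta_n, cfg$marker_map)

  test_genes <- setdiff(colnames(expr), cfg$hk_controls)
  diff_tab <- nested_anova_table(expr, meta_n, genes = test_genes)

  weights <- pca_composite_weights(expr[, test_genes, drop = FALSE])
  coords <- lda_project(expr[, test_genes, drop = FALSE], meta_n$treatment)
  cents <- centroid_distances(coords)

  networks <- NULL
  if (isTRUE(cfg$networks)) {
    networks <- list()
    for (ctype in unique(meta_n$cell_type)) for (tr in unique(meta_n$treatment)) {
      rows <- meta_n$cell_type == ctype & meta_n$treatment == tr
      if (sum(rows) < 3) next
      nm <- paste0(ctype, ":", tr)
      networks[[nm]] <- build_network(
        expr[rows, test_genes, drop = FALSE], condition = nm,
        q_threshold = cfg$q_threshold, min_pairs = cfg$min_pairs)
    }
  }

  sub_genes <- cfg$subpheno_genes
  if (is.null(sub_genes) && !is.null(cfg$simulate) && !is.null(cfg$simulate$bimodal))
    sub_genes <- cfg$simulate$bimodal$gene
  bimod <- NULL
  if (!is.null(sub_genes)) {
    bimod <- list()
    for (ctype in unique(meta_n$cell_type)) for (tr in unique(meta_n$treatment)) {
      rows <- meta_n$cell_type == ctype & meta_n$treatment == tr
      nm <- paste0(ctype, ":", tr)
      bimod[[nm]] <- bimodality_table(
        expr[rows, intersect(sub_genes, colnames(expr)), drop = FALSE],
        condition = nm)
    }
    bimod <- do.call(rbind, bimod)
  }

  files <- c(
    write_tsv_artifact(as_table(expr, "sample_id"), file.path(outdir, "neg_ddct.tsv")),
    write_tsv_artifact(norm$stability, file.path(outdir, "stability_report.tsv")),
    write_tsv_artifact(diff_tab, file.path(outdir, "differential.tsv")),
    write_tsv_artifact(as_table(cents$distances, "class"),
                       file.path(outdir, "centroid_distances.tsv")),
    write_tsv_artifact(as.data.frame(weights), file.path(outdir, "composite_weights.tsv")),
    write_tsv_artifact(as_table(coords, "sample_id"),
                       file.path(outdir, "lda_coordinates.tsv")))
  if (!is.null(networks))
    for (nm in names(networks))
      files <- c(files, write_tsv_artifact(
        networks[[nm]]$edges,
        file.path(outdir, paste0("network_", gsub("[^A-Za-z0-9]", "_", nm), ".tsv"))))
  if (!is.null(bimod))
    files <- c(files, write_tsv_artifact(bimod, file.path(outdir, "bimodality_calls.tsv")))
  if (!is.null(markers))
    files <- c(files, write_tsv_artifact(markers, file.path(outdir, "marker_validation.tsv")))

  manifest <- write_manifest(outdir, "brain", cfg, files)
  invisible(list(expr = expr, stability = norm$stability, refs = norm$refs,
                 qc = list(assays = aq$report, samples = sq$report),
                 markers = markers, differential = diff_tab, weights = weights,
                 coords = coords, centroids = cents, networks = networks,
                 bimodality = bimod, manifest = manifest))
}

#' Run the gut microbiome pipeline end-to-end
#'
#' Control-referenced normalization, per-taxon differential abundance with
#' the two reported contrasts, induced/suppressed classification, and the
#' normalization-factor-adjusted Firmicutes:Bacteroides ratio table.
#'
#' @param config list: either `simulate = microbiome_config(...)` or
#'   `ct_path` + `meta_path` + `panel_path`; optional `centering_scope`
#' @param outdir output directory
#' @return invisible list (`abundance`, `differential`, `classification`,
#'   `ratio`, `manifest`)
#' @export
run_microbiome_pipeline <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  if (!is.null(cfg$simulate)) {
    sim <- generate_microbiome(cfg$simulate)
    ct <- sim$ct; meta <- sim$meta; panel <- sim$panel
  } else {
    ct <- read_ct_matrix(cfg$ct_path)
    meta <- read_sample_meta(cfg$meta_path)
    panel <- read_taxon_panel(cfg$panel_path)
  }
  abund <- normalize_abundance(ct, panel)
  meta_n <- meta[match(rownames(abund), meta$sample_id), , drop = FALSE]
  taxa <- setdiff(colnames(abund), panel$assay[panel$is_control])
  diff_tab <- two_way_anova(abund[, taxa, drop = FALSE], meta_n)
  classes <- classify_direction(diff_tab, abund, meta_n)
  ratio <- fb_ratio(abund, panel, meta_n)
  files <- c(
    write_tsv_artifact(as_table(abund, "sample_id"), file.path(outdir, "abundance_neg_ddct.tsv")),
    write_tsv_artifact(diff_tab, file.path(outdir, "differential_abundance.tsv")),
    write_tsv_artifact(classes, file.path(outdir, "induced_suppressed.tsv")),
    write_tsv_artifact(as.data.frame(ratio), file.path(outdir, "fb_ratio.tsv")))
  manifest <- write_manifest(outdir, "microbiome", cfg, files)
  invisible(list(abundance = abund, differential = diff_tab,
                 classification = classes, ratio = ratio, manifest = manifest))
}

as_table <- function(m, id_col) {
  df <- as.data.frame(unclass(m))
  df <- cbind(stats::setNames(data.frame(rownames(m), stringsAsFactors = FALSE),
                              id_col), df)
  rownames(df) <- NULL
  df
}

write_tsv_artifact <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_manifest <- function(outdir, pipeline, cfg, files) {
  manifest <- list(
    pipeline = pipeline,
    parameters = cfg[setdiff(names(cfg), c("simulate"))],
    seed = if (!is.null(cfg$simulate)) cfg$simulate$seed else NULL,
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
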