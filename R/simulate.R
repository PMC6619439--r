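#' Simulation configuration for pooled single-cell qPCR data
#'
#' Defines the generative model the analysis assumes: a fixed treatment
#' effect per gene (planted on the -ddCt / log2 scale and mapped to Ct by
#' sign inversion), an animal-level random effect nested in treatment,
#' residual pool-to-pool noise, graded-stability housekeeping candidates,
#' cell-type marker elevation, an optional bimodal subpopulation within one
#' condition, and a Ct-dependent logistic dropout (non-detect) curve.
#'
#' Defaults emulate the motivating design: 4 treatments (Placebo, Morphine,
#' Naltrexone, Withdrawal) x 4 animals x 8 ten-cell pools per animal per
#' cell type, 46 measured genes plus housekeeping candidates, residual SD
#' 0.5 Ct, animal SD 0.3 Ct, and a withdrawal-dominated effect map in
#' which Morphine stays near Placebo and astrocytes shift most.
#'
#' @param treatments treatment labels
#' @param n_animals animals per treatment
#' @param n_pools pools per animal per cell type
#' @param cell_types assayed cell types
#' @param n_genes total measured genes (named effect/marker genes are
#'   completed with filler genes up to this count)
#' @param hk_sd named vector: housekeeping candidate -> noise SD (Ct);
#'   graded stability. `hk_control` names candidates treated as independent
#'   controls (normalized, never selectable as reference).
#' @param hk_control independent-control housekeeping assays
#' @param effects named list: gene -> named vector of per-treatment -ddCt
#'   shifts (unlisted treatments shift 0)
#' @param celltype_gain named multiplier on treatment effects per cell type
#'   (astrocytes most responsive by default)
#' @param markers named vector cell_type -> marker gene
#' @param marker_shift -ddCt elevation of a marker in its own cell type
#' @param animal_sd,resid_sd random-effect and residual SDs (Ct units)
#' @param bimodal `NULL` or list(gene, treatment, cell_type, gap, weight):
#'   within that condition, a `weight` fraction of samples shifts the gene
#'   by `gap` -ddCt units (the high mode)
#' @param dropout_ct50,dropout_slope logistic non-detect curve: a reaction
#'   with true Ct `c` fails with probability `plogis((c - ct50)/slope)`
#' @param baseline_range uniform range of per-gene baseline Ct
#' @param n_batches batches per cell type (samples split evenly)
#' @param seed mandatory integer seed; generation is deterministic given it
#' @return list of class `sim_config`
#' @export
sim_config <- function(
    treatments = c("Placebo", "Morphine", "Naltrexone", "Withdrawal"),
    n_animals = 4, n_pools = 8,
    cell_types = c("neuron", "microglia", "astrocyte"),
    n_genes = 46,
    hk_sd = c(Ldha = 0.15, Actb = 0.2, Gapdh = 0.35, Hprt1 = 0.6, B2m = 0.8),
    hk_control = "Gapdh",
    effects = list(
      Tnf    = c(Withdrawal = 1.5),
      cFos   = c(Withdrawal = 1.2),
      Nos3   = c(Withdrawal = 1.0),
      Ptges3 = c(Withdrawal = -1.8),
      Mapk1  = c(Withdrawal = -1.0)),
    celltype_gain = c(neuron = 1, microglia = 1, astrocyte = 1.3),
    markers = c(neuron = "NeuN", microglia = "Maf", astrocyte = "Gfap"),
    marker_shift = 4,
    animal_sd = 0.3, resid_sd = 0.5,
    bimodal = list(gene = "Mapk1", treatment = "Withdrawal",
                   cell_type = "astrocyte", gap = 4, weight = 0.5),
    dropout_ct50 = 36, dropout_slope = 1.5,
    baseline_range = c(18, 30),
    n_batches = 2,
    seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("`seed` is mandatory (no silent nondeterminism)")
  stopifnot(n_animals >= 1, n_pools >= 1, n_genes >= 1,
            animal_sd >= 0, resid_sd >= 0, all(hk_sd >= 0))
  if (!is.null(bimodal))
    stopifnot(bimodal$weight > 0, bimodal$weight < 1)
  named <- unique(c(names(effects), unname(markers)))
  if (length(named) > n_genes)
    stop("more named genes than n_genes")
  fill <- paste0("Gene", seq_len(max(0, n_genes - length(named))))
  genes <- c(named, fill)
  structure(list(
    treatments = treatments, n_animals = n_animals, n_pools = n_pools,
    cell_types = cell_types, genes = genes, hk_sd = hk_sd,
    hk_control = hk_control, effects = effects,
    celltype_gain = celltype_gain, markers = markers,
    marker_shift = marker_shift, animal_sd = animal_sd, resid_sd = resid_sd,
    bimodal = bimodal, dropout_ct50 = dropout_ct50,
    dropout_slope = dropout_slope, baseline_range = baseline_range,
    n_batches = n_batches, seed = as.integer(seed)),
    class = "sim_config")
}

#' Generate a pooled single-cell qPCR dataset with ground truth
#'
#' Ct is built as `baseline_g - signal + noise`: the planted -ddCt signal
#' (treatment effect x cell-type gain + animal effect + bimodal component
#' shift + marker elevation) lowers Ct because more template crosses
#' threshold earlier. Housekeeping candidates receive only their own
#' graded noise. Non-detects are drawn from the logistic dropout curve on
#' the true Ct.
#'
#' @param config a [sim_config()]
#' @return list: `ct` ([ct_matrix()]), `meta` ([sample_meta()]), `truth`
#'   (list recording every planted quantity: effects, animal effects,
#'   bimodal high-mode samples, stable reference identity, baselines)
#' @export
generate_sc_qpcr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  hk <- names(cfg$hk_sd)
  assays <- c(cfg$genes, hk)
  baseline <- stats::setNames(
    stats::runif(length(assays), cfg$baseline_range[1], cfg$baseline_range[2]),
    assays)

  meta <- list(); k <- 0
  for (ctype in cfg$cell_types) {
    for (ti in seq_along(cfg$treatments)) {
      tr <- cfg$treatments[ti]
      for (ai in seq_len(cfg$n_animals)) {
        animal <- sprintf("%s_A%d", tr, ai)
        for (pi in seq_len(cfg$n_pools)) {
          k <- k + 1
          meta[[k]] <- data.frame(
            sample_id = sprintf("%s_%s_P%d", ctype, animal, pi),
            animal_id = animal, treatment = tr, cell_type = ctype,
            batch_id = sprintf("%s_b%d", ctype,
                               ((ai - 1) %% cfg$n_batches) + 1L),
            pool_size = 10L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  meta <- sample_meta(do.call(rbind, meta))

  animals <- unique(meta$animal_id)
  # one random intercept per animal per cell type panel (separate arrays)
  an_eff <- array(stats::rnorm(length(animals) * length(cfg$cell_types),
                               0, cfg$animal_sd),
                  dim = c(length(animals), length(cfg$cell_types)),
                  dimnames = list(animals, cfg$cell_types))

  n <- nrow(meta)
  signal <- matrix(0, n, length(assays), dimnames = list(meta$sample_id, assays))
  for (g in names(cfg$effects)) {
    sh <- cfg$effects[[g]]
    for (tr in names(sh)) {
      rows <- meta$treatment == tr
      gain <- cfg$celltype_gain[meta$cell_type[rows]]
      signal[rows, g] <- signal[rows, g] + sh[[tr]] * unname(gain)
    }
  }
  for (ctype in names(cfg$markers))
    signal[meta$cell_type == ctype, cfg$markers[[ctype]]] <-
      signal[meta$cell_type == ctype, cfg$markers[[ctype]]] + cfg$marker_shift
  signal[, cfg$genes] <- signal[, cfg$genes] +
    an_eff[cbind(meta$animal_id, meta$cell_type)]

  high_mode <- character()
  if (!is.null(cfg$bimodal)) {
    bi <- cfg$bimodal
    rows <- which(meta$treatment == bi$treatment & meta$cell_type == bi$cell_type)
    hi <- rows[stats::runif(length(rows)) < bi$weight]
    signal[hi, bi$gene] <- signal[hi, bi$gene] + bi$gap
    high_mode <- meta$sample_id[hi]
  }

  noise <- matrix(stats::rnorm(n * length(cfg$genes), 0, cfg$resid_sd),
                  n, length(cfg$genes))
  hk_noise <- vapply(hk, function(h) stats::rnorm(n, 0, cfg$hk_sd[[h]]),
                     numeric(n))
  ct <- matrix(NA_real_, n, length(assays), dimnames = list(meta$sample_id, assays))
  ct[, cfg$genes] <- rep(baseline[cfg$genes], each = n) -
    signal[, cfg$genes] + noise
  ct[, hk] <- rep(baseline[hk], each = n) + hk_noise

  drop_p <- stats::plogis((ct - cfg$dropout_ct50) / cfg$dropout_slope)
  dropped <- matrix(stats::runif(length(ct)) < drop_p, nrow = n)
  ct[dropped] <- NA_real_

  truth <- list(
    baseline = baseline,
    effects = cfg$effects,
    celltype_gain = cfg$celltype_gain,
    animal_effects = an_eff,
    markers = cfg$markers,
    marker_shift = cfg$marker_shift,
    bimodal = cfg$bimodal,
    bimodal_high_samples = high_mode,
    hk_sd = cfg$hk_sd,
    stable_pair = names(sort(cfg$hk_sd[setdiff(hk, cfg$hk_control)]))[1:2],
    control = cfg$hk_control,
    dropout = c(ct50 = cfg$dropout_ct50, slope = cfg$dropout_slope))
  list(ct = ct_matrix(ct, ct_range = c(0, 40)), meta = meta, truth = truth)
}

#' Simulation configuration for the microbial panel
#'
#' @param treatments treatment labels
#' @param n_animals animals (cecal specimens) per treatment
#' @param taxa data.frame (assay, rank, phylum) of non-control assays;
#'   default panel mirrors a dysbiosis study: phylum-level Firmicutes and
#'   Bacteroides assays, their subgroups, and anti-inflammatory genera
#' @param shifts named list: assay -> named per-treatment -ddCt shift;
#'   default plants the Withdrawal Firmicutes-down / Bacteroides-up pattern
#'   with subgroups shifting in the same direction as their phylum
#' @param control_sd SD of the pan-bacterial control assays
#' @param resid_sd residual SD per taxon measurement
#' @param baseline_range uniform range of per-assay baseline Ct
#' @param seed mandatory seed
#' @export
microbiome_config <- function(
    treatments = c("Placebo", "Morphine", "Naltrexone", "Withdrawal"),
    n_animals = 4,
    taxa = default_taxa(),
    shifts = default_taxon_shifts(),
    control_sd = 0.2, resid_sd = 0.5,
    baseline_range = c(15, 25),
    seed) {
  if (missing(seed) || !is.numeric(seed)) stop("`seed` is mandatory")
  unknown <- setdiff(names(shifts), taxa$assay)
  if (length(unknown)) stop("shift(s) for unknown taxa: ", paste(unknown, collapse = ", "))
  structure(list(treatments = treatments, n_animals = n_animals, taxa = taxa,
                 shifts = shifts, control_sd = control_sd, resid_sd = resid_sd,
                 baseline_range = baseline_range, seed = as.integer(seed)),
            class = "microbiome_config")
}

default_taxa <- function() {
  data.frame(
    assay = c("Firmicutes", "Bacteroides",
              "Clostridium_coccoides", "Clostridium_leptum",
              "Butyricicoccus", "Butyricicoccus_pullicaecorum",
              "Bacteroides_fragilis", "Bacteroides_vulgatus",
              "Bacteroides_thetaiotaomicron",
              "Bifidobacterium", "Faecalibacterium_prausnitzii",
              "Enterococcus_faecalis", "Enterococcus_gallinarum"),
    rank = c("phylum", "phylum", "subgroup", "subgroup", "genus", "species",
             "species", "species", "species", "genus", "species",
             "species", "species"),
    phylum = c("Firmicutes", "Bacteroides", "Firmicutes", "Firmicutes",
               "Firmicutes", "Firmicutes", "Bacteroides", "Bacteroides",
               "Bacteroides", "other", "Firmicutes", "Firmicutes",
               "Firmicutes"),
    stringsAsFactors = FALSE)
}

# Withdrawal lowers the Firmicutes side and raises the Bacteroides side;
# subgroup shifts track their phylum. Phylum-level magnitudes follow the
# per-treatment median pattern of the motivating dysbiosis study
# (Firmicutes mildly up under morphine, down in withdrawal; Bacteroides
# strongly up in withdrawal).
default_taxon_shifts <- function() {
  list(
    Firmicutes = c(Placebo = -0.487, Morphine = 0.359, Naltrexone = 0.151,
                   Withdrawal = -0.726),
    Bacteroides = c(Placebo = -0.741, Morphine = 0.391, Naltrexone = -0.424,
                    Withdrawal = 2.943),
    Clostridium_coccoides = c(Withdrawal = -0.8),
    Clostridium_leptum = c(Withdrawal = -0.7),
    Butyricicoccus = c(Withdrawal = -0.6),
    Butyricicoccus_pullicaecorum = c(Withdrawal = -0.6),
    Bifidobacterium = c(Withdrawal = -0.8),
    Faecalibacterium_prausnitzii = c(Withdrawal = -0.7),
    Bacteroides_fragilis = c(Withdrawal = 2.0),
    Bacteroides_vulgatus = c(Withdrawal = 2.2),
    Bacteroides_thetaiotaomicron = c(Withdrawal = 1.8),
    Enterococcus_faecalis = c(Withdrawal = 1.5),
    Enterococcus_gallinarum = c(Withdrawal = 1.2))
}

#' Generate a microbial qPCR panel dataset with ground truth
#'
#' Control assays are stable (their own small noise only); taxon Ct is
#' shifted per treatment by the planted -ddCt shifts (sign-inverted on the
#' Ct scale).
#'
#' @param config a [microbiome_config()]
#' @return list: `ct`, `meta`, `panel` ([taxon_panel()]), `truth`
#' @export
generate_microbiome <- function(config) {
  stopifnot(inherits(config, "microbiome_config"))
  set.seed(config$seed)
  cfg <- config
  controls <- c("PanBacteria", "Universal")
  assays <- c(cfg$taxa$assay, controls)
  baseline <- stats::setNames(
    stats::runif(length(assays), cfg$baseline_range[1], cfg$baseline_range[2]),
    assays)
  meta <- do.call(rbind, lapply(cfg$treatments, function(tr)
    data.frame(sample_id = sprintf("cecal_%s_A%d", tr, seq_len(cfg$n_animals)),
               animal_id = sprintf("%s_A%d", tr, seq_len(cfg$n_animals)),
               treatment = tr, cell_type = "cecal", batch_id = "cecal_b1",
               pool_size = 1L, stringsAsFactors = FALSE)))
  meta <- sample_meta(meta)
  n <- nrow(meta)
  ct <- matrix(NA_real_, n, length(assays),
               dimnames = list(meta$sample_id, assays))
  for (a in cfg$taxa$assay) {
    shift <- numeric(n)
    sh <- cfg$shifts[[a]]
    if (!is.null(sh))
      for (tr in names(sh)) shift[meta$treatment == tr] <- sh[[tr]]
    ct[, a] <- baseline[a] - shift + stats::rnorm(n, 0, cfg$resid_sd)
  }
  for (a in controls)
    ct[, a] <- baseline[a] + stats::rnorm(n, 0, cfg$control_sd)
  panel <- taxon_panel(data.frame(
    assay = assays,
    rank = c(cfg$taxa$rank, NA, NA),
    phylum = c(cfg$taxa$phylum, NA, NA),
    is_control = c(rep(FALSE, nrow(cfg$taxa)), TRUE, TRUE),
    stringsAsFactors = FALSE))
  truth <- list(baseline = baseline, shifts = cfg$shifts,
                controls = controls)
  list(ct = ct_matrix(ct), meta = meta, panel = panel, truth = truth)
}
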