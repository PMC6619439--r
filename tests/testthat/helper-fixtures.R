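# small in-code fixtures shared across tests

# a tiny named Ct matrix
tiny_ct <- function(values, samples = NULL, assays = NULL) {
  m <- as.matrix(values)
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(m)))
  if (is.null(assays)) assays <- paste0("g", seq_len(ncol(m)))
  dimnames(m) <- list(samples, assays)
  ct_matrix(m)
}

# annotations for a flat design: one animal per `per_animal` samples
flat_meta <- function(ct, treatment = "Placebo", cell_type = "neuron",
                      batch = "b1", per_animal = 2) {
  n <- nrow(ct)
  sample_meta(data.frame(
    sample_id = rownames(ct),
    animal_id = paste0(treatment, "_A", ceiling(seq_len(n) / per_animal)),
    treatment = treatment, cell_type = cell_type, batch_id = batch,
    stringsAsFactors = FALSE))
}

# nested design data: t treatments x a animals x p pools, with effects
nested_data <- function(trt_means, n_animals, n_pools, animal_sd, resid_sd) {
  trts <- names(trt_means)
  rows <- expand.grid(pool = seq_len(n_pools), animal = seq_len(n_animals),
                      treatment = trts, stringsAsFactors = FALSE)
  rows$animal_id <- paste0(rows$treatment, "_A", rows$animal)
  an_eff <- stats::rnorm(n_animals * length(trts), 0, animal_sd)
  names(an_eff) <- unique(rows$animal_id)
  rows$y <- trt_means[rows$treatment] + an_eff[rows$animal_id] +
    stats::rnorm(nrow(rows), 0, resid_sd)
  rows$sample_id <- paste0(rows$animal_id, "_P", rows$pool)
  rows
}

# matrix + meta wrapper around nested_data for one gene
nested_expr <- function(trt_means, n_animals = 4, n_pools = 4,
                        animal_sd = 0.3, resid_sd = 0.5, gene = "g1") {
  d <- nested_data(trt_means, n_animals, n_pools, animal_sd, resid_sd)
  x <- matrix(d$y, ncol = 1, dimnames = list(d$sample_id, gene))
  meta <- sample_meta(data.frame(
    sample_id = d$sample_id, animal_id = d$animal_id,
    treatment = d$treatment, cell_type = "neuron", batch_id = "b1",
    stringsAsFactors = FALSE))
  list(x = x, meta = meta, d = d)
}

# independent brute-force geNorm oracle: explicit double loop over pairs
genorm_oracle <- function(x, candidates) {
  m <- numeric(length(candidates))
  names(m) <- candidates
  for (j in candidates) {
    vs <- c()
    for (k in setdiff(candidates, j)) {
      d <- x[, j] - x[, k]
      vs <- c(vs, stats::sd(d[!is.na(d)]))
    }
    m[j] <- mean(vs)
  }
  m
}

# independent brute-force one-way/nested F oracle on animal means
nested_f_oracle <- function(d) {
  am <- aggregate(y ~ treatment + animal_id, data = d, FUN = mean)
  k <- length(unique(am$treatment))
  n <- nrow(am)
  grand <- mean(am$y)
  ssb <- 0; ssw <- 0
  for (tr in unique(am$treatment)) {
    yi <- am$y[am$treatment == tr]
    ssb <- ssb + length(yi) * (mean(yi) - grand)^2
    ssw <- ssw + sum((yi - mean(yi))^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}
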