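#' Raw qPCR cycle-threshold matrix
#'
#' A `ct_matrix` holds raw Ct values for a set of samples (10-cell pools, or
#' cecal specimens for microbial panels) measured across a set of assays.
#' Non-detects (reactions with no amplification signal) are stored as `NA`
#' and tracked through all downstream steps as missing values; they are
#' never imputed, because substituting a ceiling Ct (e.g. 40) would bias the
#' relative-quantification arithmetic.
#'
#' @param values numeric matrix, samples in rows, assays in columns, with
#'   `NA` marking non-detects. Must carry unique row and column names.
#' @param ct_range plausible Ct range in PCR cycles; detected values outside
#'   it trigger a warning (they are retained — use [sample_qc()] to drop).
#' @return an object of class `ct_matrix`: the value matrix with the
#'   `ct_range` attribute attached and its invariants checked.
#' @seealso [read_ct_matrix()], [detect_mask()]
#' @export
ct_matrix <- function(values, ct_range = c(0, 40)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x assays)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample row names and assay column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate assay id(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  det <- !is.na(values)
  if (any(det & !is.finite(values)))
    stop("non-finite Ct value in a detected cell")
  out_of_range <- det & (values < ct_range[1] | values > ct_range[2])
  if (any(out_of_range))
    warning(sum(out_of_range), " detected Ct value(s) outside the plausible range [",
            ct_range[1], ", ", ct_range[2], "] cycles")
  structure(values, ct_range = ct_range, class = c("ct_matrix", "matrix", "array"))
}

#' @rdname ct_matrix
#' @param x a `ct_matrix`
#' @export
is_ct_matrix <- function(x) inherits(x, "ct_matrix")

#' Detection mask of a Ct matrix
#'
#' @param x a `ct_matrix` (or any matrix with `NA` non-detects)
#' @return logical matrix, `TRUE` where the reaction was detected
#' @export
detect_mask <- function(x) !is.na(unclass(x))

#' @export
print.ct_matrix <- function(x, ...) {
  cat("ct_matrix: ", nrow(x), " samples x ", ncol(x), " assays (",
      sum(is.na(x)), " non-detects)\n", sep = "")
  invisible(x)
}

sample_ids <- function(x) rownames(x)
assay_ids <- function(x) colnames(x)

#' Read a raw Ct table from a delimited text file
#'
#' Ingests wide-format Ct tables in either orientation. Cells equal to one
#' of `nondetect_tokens` are mapped to `NA` (non-detect); any other
#' non-numeric cell is a hard error naming its row and column.
#'
#' @param path path to a TSV/CSV file; the delimiter is inferred from the
#'   extension (`.csv` = comma, otherwise tab) unless `sep` is given.
#' @param layout `"samples-in-rows"` (default) or `"samples-in-columns"`.
#'   The two layouts of the same data yield identical objects.
#' @param nondetect_tokens character vector of cell values denoting a failed
#'   reaction. Defaults cover the common "999" flag, "NA", and empty cells.
#' @param sep field separator override.
#' @param ct_range passed to [ct_matrix()].
#' @return a [ct_matrix()]
#' @export
read_ct_matrix <- function(path,
                           layout = c("samples-in-rows", "samples-in-columns"),
                           nondetect_tokens = c("999", "NA", ""),
                           sep = NULL, ct_range = c(0, 40)) {
  layout <- match.arg(layout)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "\"", comment.char = "")
  m <- as.matrix(raw)
  vals <- parse_ct_cells(m, nondetect_tokens)
  if (layout == "samples-in-columns") vals <- t(vals)
  ct_matrix(vals, ct_range = ct_range)
}

parse_ct_cells <- function(m, nondetect_tokens) {
  v <- trimws(m)
  nd <- v %in% nondetect_tokens
  num <- suppressWarnings(as.numeric(v))
  bad <- !nd & is.na(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = FALSE)[1]
    rc <- arrayInd(idx, dim(m))
    stop("non-numeric Ct value \"", m[idx], "\" at row '", rownames(m)[rc[1]],
         "', column '", colnames(m)[rc[2]], "'")
  }
  num[nd] <- NA_real_
  dim(num) <- dim(m)
  dimnames(num) <- dimnames(m)
  num
}

#' Read sample annotations defining the nested design
#'
#' @param path TSV/CSV with columns `sample_id`, `animal_id`, `treatment`,
#'   `cell_type`, `batch_id` and optionally `pool_size` (default 10 cells).
#' @param sep field separator override (inferred from extension otherwise).
#' @return a validated `data.frame` of class `sample_meta`
#' @export
read_sample_meta <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  sample_meta(df)
}

#' Construct/validate sample annotations
#'
#' Each sample (pool) maps to one animal, each animal to exactly one
#' treatment; the animal is the biological replicate of the design.
#'
#' @param df data.frame with columns `sample_id`, `animal_id`, `treatment`,
#'   `cell_type`, `batch_id`, optional `pool_size`.
#' @export
sample_meta <- function(df) {
  need <- c("sample_id", "animal_id", "treatment", "cell_type", "batch_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in annotations: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (is.null(df$pool_size)) df$pool_size <- 10L
  tab <- unique(df[, c("animal_id", "treatment")])
  dup <- tab$animal_id[duplicated(tab$animal_id)]
  if (length(dup))
    stop("animal(s) assigned to more than one treatment: ", paste(dup, collapse = ", "))
  class(df) <- c("sample_meta", "data.frame")
  df
}

# align annotations to a ct_matrix, erroring on samples without metadata
match_meta <- function(ct, meta) {
  miss <- setdiff(rownames(ct), meta$sample_id)
  if (length(miss))
    stop("sample(s) missing from annotations: ", paste(miss, collapse = ", "))
  meta[match(rownames(ct), meta$sample_id), , drop = FALSE]
}
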