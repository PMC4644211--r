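#' Construct an expression atlas
#'
#' An `ExpressionAtlas` bundles a dense genes x samples expression matrix with
#' per-sample metadata (donor, age, sex, brain region, developmental stage) and
#' a scale flag tracking where the values sit in the preprocessing pipeline
#' (`"rpkm"` raw, `"quantile_norm"` after quantile normalization, `"log2"`
#' after the log transform). The matrix orientation is fixed as genes in rows
#' and samples in columns throughout the package.
#'
#' @param values numeric matrix, genes x samples. Row names are taken as gene
#'   identifiers if `genes` is missing; column names as sample ids.
#' @param samples data.frame of sample metadata with columns `sample_id`,
#'   `donor_id`, `age` (signed days relative to birth; negative = prenatal),
#'   `sex` (`"M"`, `"F"` or `"unknown"`), `region` (acronym). Optional columns
#'   `stage` (integer, `NA` before stage assignment) and `imputed` (logical)
#'   are added when absent.
#' @param genes character vector of gene symbols, one per matrix row.
#' @param scale one of `"rpkm"`, `"quantile_norm"`, `"log2"`.
#'
#' @return an object of class `ExpressionAtlas`: a list with elements
#'   `values`, `samples`, `genes`, `scale`.
#' @export
expression_atlas <- function(values, samples, genes = rownames(values),
                             scale = c("rpkm", "quantile_norm", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(genes)) {
    stop("gene identifiers are required (row names or `genes`)")
  }
  genes <- as.character(genes)
  if (length(genes) != nrow(values)) {
    stop("`genes` has ", length(genes), " entries but the matrix has ",
         nrow(values), " rows")
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  required <- c("sample_id", "donor_id", "age", "sex", "region")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("sample metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(samples) != ncol(values)) {
    stop("metadata describes ", nrow(samples), " samples but the matrix has ",
         ncol(values), " columns")
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample ids")
  }
  key <- paste(samples$donor_id, samples$region, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (donor, region) combinations in sample metadata")
  }
  if (!"stage" %in% names(samples)) samples$stage <- NA_integer_
  if (!"imputed" %in% names(samples)) samples$imputed <- FALSE
  samples$age <- as.numeric(samples$age)
  samples$sex <- ifelse(samples$sex %in% c("M", "F"), samples$sex, "unknown")
  rownames(values) <- genes
  colnames(values) <- samples$sample_id
  rownames(samples) <- NULL
  structure(
    list(values = values, samples = samples, genes = genes, scale = scale),
    class = "ExpressionAtlas"
  )
}

#' @export
print.ExpressionAtlas <- function(x, ...) {
  cat("ExpressionAtlas:", length(x$genes), "genes x", nrow(x$samples),
      "samples\n")
  cat("  donors:", length(unique(x$samples$donor_id)),
      " regions:", length(unique(x$samples$region)),
      " scale:", x$scale, "\n")
  if (!all(is.na(x$samples$stage))) {
    cat("  stages:", paste(sort(unique(x$samples$stage)), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionAtlas <- function(x) dim(x$values)

#' Number of donors in an atlas
#' @param atlas an `ExpressionAtlas`.
#' @return integer count of distinct donors.
#' @export
n_donors <- function(atlas) length(unique(atlas$samples$donor_id))

#' Subset an atlas by genes and/or samples
#'
#' @param atlas an `ExpressionAtlas`.
#' @param genes character vector of gene symbols to keep (order preserved as
#'   given); `NULL` keeps all.
#' @param sample_idx integer or logical index into the sample columns; `NULL`
#'   keeps all.
#' @return the subset `ExpressionAtlas`.
#' @export
subset_atlas <- function(atlas, genes = NULL, sample_idx = NULL) {
  values <- atlas$values
  samples <- atlas$samples
  if (!is.null(genes)) {
    missing <- setdiff(genes, atlas$genes)
    if (length(missing)) {
      stop("genes absent from atlas: ", paste(utils::head(missing, 5), collapse = ", "))
    }
    values <- values[genes, , drop = FALSE]
  }
  if (!is.null(sample_idx)) {
    values <- values[, sample_idx, drop = FALSE]
    samples <- samples[sample_idx, , drop = FALSE]
  }
  expression_atlas(values, samples, genes = rownames(values), scale = atlas$scale)
}

#' Construct a gene set
#'
#' @param genes character vector of gene symbols.
#' @param name set name.
#' @param case_normalize upper-case symbols (the package-wide convention)?
#' @return a `GeneSet`: list with `name` and the deduplicated `genes`.
#' @export
gene_set <- function(genes, name = "gene_set", case_normalize = TRUE) {
  genes <- as.character(genes)
  if (case_normalize) genes <- toupper(genes)
  genes <- genes[nzchar(genes)]
  n_dup <- sum(duplicated(genes))
  if (n_dup > 0) {
    message("gene set '", name, "': dropped ", n_dup, " duplicate symbol(s)")
  }
  structure(list(name = name, genes = unique(genes)), class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat("GeneSet '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' @export
length.GeneSet <- function(x) length(x$genes)

as_gene_vector <- function(x) {
  if (inherits(x, "GeneSet")) x$genes else as.character(x)
}
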