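#' Parse donor ages to signed days relative to birth
#'
#' Ages given in post-conception weeks map to negative (prenatal) days with
#' birth fixed at 40 PCW: `days = (pcw - 40) * 7`. Postnatal ages map as
#' `months * 365 / 12` and `years * 365`. Bare numbers are taken as days.
#' Parsing is monotone within each unit: a larger PCW/month/year always yields
#' a larger day value.
#'
#' @param age character vector, e.g. `"8 pcw"`, `"4 mos"`, `"21 yrs"`, or a
#'   numeric day count.
#' @param sample_id optional ids used in error messages.
#' @return numeric vector of ages in days (negative = prenatal).
#' @export
parse_age_days <- function(age, sample_id = NULL) {
  if (is.numeric(age)) return(as.numeric(age))
  age_chr <- trimws(tolower(as.character(age)))
  out <- rep(NA_real_, length(age_chr))
  m <- regmatches(age_chr, regexec("^(-?[0-9.]+)\\s*([a-z]*)\\.?$", age_chr))
  for (i in seq_along(age_chr)) {
    parts <- m[[i]]
    if (length(parts) == 3) {
      num <- suppressWarnings(as.numeric(parts[2]))
      unit <- parts[3]
      if (!is.na(num)) {
        out[i] <- if (unit == "") num else switch(
          unit,
          "pcw" = (num - 40) * 7,
          "mos" = , "mo" = , "months" = , "month" = num * 365 / 12,
          "yrs" = , "yr" = , "years" = , "year" = , "y" = num * 365,
          "d" = , "days" = , "day" = num,
          NA_real_
        )
      }
    }
    if (is.na(out[i])) {
      id <- if (!is.null(sample_id)) sample_id[i] else paste0("entry ", i)
      stop("unparseable age '", age[i], "' for sample ", id)
    }
  }
  out
}

#' Read an expression atlas from disk
#'
#' Two on-disk dialects are supported. The three-file dialect mirrors the
#' BrainSpan distribution: a header-less `expression_matrix.csv` (one row per
#' gene; an optional leading integer index column is detected and dropped), a
#' `columns_metadata.csv` with header columns `donor_id`, `age`, `sex` (or
#' `gender`), `region` (or `structure_acronym`), and a `rows_metadata.csv`
#' with a `gene_symbol` (or `gene`/`symbol`) column. Passing only `expr_path`
#' and `samples_path` reads the single-TSV dialect (first column gene id,
#' header = sample ids) used for synthetic atlases.
#'
#' @param expr_path path to the expression matrix file.
#' @param samples_path path to the sample (column) metadata CSV/TSV.
#' @param genes_path path to the gene (row) metadata CSV, or `NULL` for the
#'   single-TSV dialect.
#' @return an [expression_atlas()] with `scale = "rpkm"` and ages parsed to
#'   signed days.
#' @export
read_atlas <- function(expr_path, samples_path, genes_path = NULL) {
  for (p in c(expr_path, samples_path, genes_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE,
                             sep = guess_sep(samples_path))
  names(samples) <- sub("^structure_acronym$", "region", names(samples))
  names(samples) <- sub("^gender$", "sex", names(samples))
  required <- c("donor_id", "age", "sex", "region")
  miss <- setdiff(required, names(samples))
  if (length(miss)) {
    stop("columns metadata ", samples_path, " lacks: ", paste(miss, collapse = ", "))
  }
  if (!"sample_id" %in% names(samples)) {
    samples$sample_id <- paste(samples$donor_id, samples$region, sep = "_")
  }
  samples$age <- parse_age_days(samples$age, samples$sample_id)

  if (is.null(genes_path)) {
    tab <- utils::read.delim(expr_path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    genes <- as.character(tab[[1]])
    values <- as.matrix(tab[, -1, drop = FALSE])
    if (ncol(values) != nrow(samples)) {
      stop("dimension mismatch: ", expr_path, " has ", ncol(values),
           " sample columns but ", samples_path, " describes ", nrow(samples))
    }
  } else {
    genes_meta <- utils::read.csv(genes_path, stringsAsFactors = FALSE,
                                  sep = guess_sep(genes_path))
    sym_col <- intersect(c("gene_symbol", "gene", "symbol"), names(genes_meta))
    if (!length(sym_col)) {
      stop("rows metadata ", genes_path, " lacks a gene symbol column")
    }
    genes <- as.character(genes_meta[[sym_col[1]]])
    values <- as.matrix(utils::read.csv(expr_path, header = FALSE))
    # BrainSpan ships a leading row-number column; detect and drop it
    if (ncol(values) == nrow(samples) + 1 &&
        all(values[, 1] == seq_len(nrow(values)))) {
      values <- values[, -1, drop = FALSE]
    }
    if (nrow(values) != length(genes)) {
      stop("dimension mismatch: ", expr_path, " has ", nrow(values),
           " gene rows but ", genes_path, " describes ", length(genes))
    }
    if (ncol(values) != nrow(samples)) {
      stop("dimension mismatch: ", expr_path, " has ", ncol(values),
           " sample columns but ", samples_path, " describes ", nrow(samples))
    }
  }
  expression_atlas(values, samples, genes = toupper(genes), scale = "rpkm")
}

guess_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Write an expression atlas in the three-file CSV dialect
#'
#' @param atlas an `ExpressionAtlas`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths written.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_path <- file.path(dir, "expression_matrix.csv")
  cols_path <- file.path(dir, "columns_metadata.csv")
  rows_path <- file.path(dir, "rows_metadata.csv")
  utils::write.table(cbind(seq_along(atlas$genes), signif(atlas$values, 9)),
                     expr_path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.csv(atlas$samples, cols_path, row.names = FALSE)
  utils::write.csv(data.frame(row_num = seq_along(atlas$genes),
                              gene_symbol = atlas$genes),
                   rows_path, row.names = FALSE)
  invisible(c(expr_path, cols_path, rows_path))
}

#' Read a gene set from a plain list file
#'
#' One symbol per line; blank lines ignored; duplicates dropped with a
#' message; symbols upper-cased unless `case_normalize = FALSE`.
#'
#' @param path file path.
#' @param name set name (defaults to the file stem).
#' @param case_normalize upper-case symbols?
#' @return a [gene_set()].
#' @export
read_gene_set <- function(path, name = NULL,
                          case_normalize = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("gene set file is empty: ", path)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  gene_set(lines, name = name, case_normalize = case_normalize)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: per line, set name, description, then member symbols, all
#' tab-separated.
#'
#' @param path GMT file path.
#' @param case_normalize upper-case symbols?
#' @return a list of [gene_set()] objects, named by set name.
#' @export
read_gmt <- function(path, case_normalize = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("GMT file is empty: ", path)
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
    gene_set(f[-(1:2)], name = f[1], case_normalize = case_normalize)
  })
  names(sets) <- vapply(sets, function(s) s$name, character(1))
  sets
}

#' Write a tabular result as TSV
#'
#' All result tables in the package are written with a header line, floats at
#' 6 significant digits, and the row order of the input (each producer sorts
#' deterministically before returning).
#'
#' @param rows data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  for (j in seq_along(rows)) {
    if (is.double(rows[[j]])) rows[[j]] <- signif(rows[[j]], 6)
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a pair-trajectory matrix as TSV
#'
#' Columns: `gene_a`, `gene_b`, `rho_stage1..S`, `n_stage1..S`.
#'
#' @param traj a `PairTrajectoryMatrix` from [stage_pair_trajectories()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trajectories <- function(traj, path) {
  S <- length(traj$stages)
  rho <- traj$rho
  n <- traj$n_donors_used
  colnames(rho) <- paste0("rho_stage", seq_len(S))
  colnames(n) <- paste0("n_stage", seq_len(S))
  write_table(cbind(traj$pairs, rho, n), path)
}

#' Read a pair-trajectory matrix written by [write_trajectories()]
#' @param path TSV path.
#' @return a `PairTrajectoryMatrix`.
#' @export
read_trajectories <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  rho_cols <- grep("^rho_stage", names(tab))
  n_cols <- grep("^n_stage", names(tab))
  new_pair_trajectories(
    pairs = tab[, c("gene_a", "gene_b")],
    rho = as.matrix(tab[, rho_cols, drop = FALSE]),
    n_donors_used = as.matrix(tab[, n_cols, drop = FALSE]),
    stages = seq_along(rho_cols)
  )
}
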