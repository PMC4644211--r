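#' Preprocessing configuration
#'
#' Defaults follow the atlas-preparation conventions for developmental brain
#' expression data: donors missing more than six of the required regions are
#' excluded, genes must reach 5 RPKM in at least one sample, and log2 uses a
#' +1 offset because quantile-normalized RPKM can be 0.
#'
#' @param max_missing_regions donors missing strictly more than this many
#'   required regions are excluded.
#' @param min_rpkm a gene is retained iff its maximum over samples is `>=`
#'   this value.
#' @param regions_required region acronyms every donor must (after
#'   imputation) contribute.
#' @param log_offset value added before log2.
#' @return a `PreprocessConfig` list.
#' @export
preprocess_config <- function(max_missing_regions = 6, min_rpkm = 5,
                              regions_required = default_regions(),
                              log_offset = 1) {
  stopifnot(max_missing_regions >= 0, min_rpkm >= 0,
            length(regions_required) >= 1, log_offset >= 0)
  structure(list(max_missing_regions = as.integer(max_missing_regions),
                 min_rpkm = min_rpkm,
                 regions_required = regions_required,
                 log_offset = log_offset),
            class = "PreprocessConfig")
}

#' Exclude donors with too many missing regions
#'
#' A donor is dropped iff it lacks strictly more than
#' `cfg$max_missing_regions` of `cfg$regions_required` (a donor missing
#' exactly the threshold count is retained). Samples from regions outside
#' `regions_required` are also dropped, so downstream steps see a fixed
#' region panel.
#'
#' @param atlas an `ExpressionAtlas`.
#' @param cfg a [preprocess_config()].
#' @return the filtered atlas.
#' @export
filter_donors <- function(atlas, cfg = preprocess_config()) {
  req <- cfg$regions_required
  s <- atlas$samples
  keep_region <- s$region %in% req
  donors <- unique(s$donor_id)
  n_missing <- vapply(donors, function(d) {
    length(setdiff(req, s$region[s$donor_id == d]))
  }, integer(1))
  keep_donors <- donors[n_missing <= cfg$max_missing_regions]
  if (!length(keep_donors)) stop("no donor retains enough required regions")
  dropped <- setdiff(donors, keep_donors)
  if (length(dropped)) {
    message("filter_donors: dropped ", length(dropped), " donor(s): ",
            paste(dropped, collapse = ", "))
  }
  subset_atlas(atlas, sample_idx = which(keep_region & s$donor_id %in% keep_donors))
}

#' Impute missing donor regions from the age-nearest donor
#'
#' Each missing (donor, region) column is filled with that region's column
#' from the donor with minimal absolute age difference among donors observed
#' (not themselves imputed) for the region; ties go to the younger donor.
#' Imputed columns are flagged `imputed = TRUE` in the sample metadata;
#' observed values are untouched. Columns are re-sorted by (donor, region)
#' for a deterministic layout.
#'
#' @param atlas an `ExpressionAtlas` (after [filter_donors()]).
#' @param cfg a [preprocess_config()].
#' @return the completed atlas: every donor has every required region.
#' @export
impute_missing <- function(atlas, cfg = preprocess_config()) {
  req <- cfg$regions_required
  s <- atlas$samples
  donors <- unique(s$donor_id)
  donor_age <- vapply(donors, function(d) s$age[s$donor_id == d][1], numeric(1))
  new_cols <- list()
  new_meta <- list()
  for (d in donors) {
    have <- s$region[s$donor_id == d]
    miss <- setdiff(req, have)
    if (length(miss) > cfg$max_missing_regions) {
      stop("donor ", d, " misses ", length(miss),
           " required regions; run filter_donors first")
    }
    for (r in miss) {
      cand_idx <- which(s$region == r & !s$imputed)
      if (!length(cand_idx)) stop("region ", r, " is absent from every donor")
      cand_donor <- s$donor_id[cand_idx]
      cand_age <- s$age[cand_idx]
      delta <- abs(cand_age - donor_age[[d]])
      best <- cand_idx[order(delta, cand_age)][1]  # tie -> younger donor
      new_cols[[length(new_cols) + 1L]] <- atlas$values[, best]
      new_meta[[length(new_meta) + 1L]] <- data.frame(
        sample_id = paste(d, r, sep = "_"), donor_id = d,
        age = donor_age[[d]], sex = s$sex[s$donor_id == d][1],
        region = r, stage = s$stage[s$donor_id == d][1], imputed = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  if (length(new_cols)) {
    message("impute_missing: imputed ", length(new_cols), " donor-region column(s)")
    values <- cbind(atlas$values, do.call(cbind, new_cols))
    samples <- rbind(s[, c("sample_id", "donor_id", "age", "sex", "region",
                           "stage", "imputed")],
                     do.call(rbind, new_meta))
    colnames(values) <- samples$sample_id
  } else {
    values <- atlas$values
    samples <- s
  }
  ord <- order(samples$donor_id, samples$region)
  expression_atlas(values[, ord, drop = FALSE], samples[ord, ],
                   genes = atlas$genes, scale = atlas$scale)
}

#' Filter genes on a minimum-expression rule
#'
#' A gene is retained iff its maximum RPKM over all samples is greater than
#' or equal to `cfg$min_rpkm`; genes never reaching the floor are treated as
#' noise and removed.
#'
#' @param atlas an `ExpressionAtlas` at scale `"rpkm"`.
#' @param cfg a [preprocess_config()].
#' @return the filtered atlas.
#' @export
filter_genes <- function(atlas, cfg = preprocess_config()) {
  if (atlas$scale != "rpkm") stop("filter_genes expects scale 'rpkm'")
  keep <- apply(atlas$values, 1, max) >= cfg$min_rpkm
  if (!any(keep)) stop("no gene passes the expression filter")
  message("filter_genes: retained ", sum(keep), " of ", length(keep), " genes")
  subset_atlas(atlas, genes = atlas$genes[keep])
}

#' Quantile-normalize an expression matrix across samples
#'
#' Classic quantile normalization: every sample's values are replaced by the
#' across-sample mean of order statistics at the sample's own ranks, so all
#' samples end with an identical sorted value distribution (exactly so in the
#' absence of within-sample ties; tied values receive the mean of the
#' reference values at the tied ranks). Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param atlas an `ExpressionAtlas` at scale `"rpkm"`.
#' @return the atlas at scale `"quantile_norm"`.
#' @export
quantile_normalize <- function(atlas) {
  if (atlas$scale != "rpkm") stop("quantile_normalize expects scale 'rpkm'")
  if (ncol(atlas$values) < 2) stop("quantile normalization needs >= 2 samples")
  values <- limma::normalizeQuantiles(atlas$values, ties = TRUE)
  dimnames(values) <- dimnames(atlas$values)
  out <- expression_atlas(values, atlas$samples, genes = atlas$genes,
                          scale = "rpkm")
  out$scale <- "quantile_norm"
  out
}

#' Log2-transform normalized expression values
#'
#' @param atlas an `ExpressionAtlas` at scale `"quantile_norm"`.
#' @param cfg a [preprocess_config()]; `log_offset` is added before log2.
#' @return the atlas at scale `"log2"`.
#' @export
log_transform <- function(atlas, cfg = preprocess_config()) {
  if (atlas$scale != "quantile_norm") {
    stop("log_transform expects scale 'quantile_norm'")
  }
  if (any(atlas$values < 0)) stop("negative expression value before log2")
  out <- atlas
  out$values <- log2(atlas$values + cfg$log_offset)
  out$scale <- "log2"
  out
}

#' Assign developmental stages to all samples from donor age
#'
#' @param atlas an `ExpressionAtlas`.
#' @param stage_map stage-map data.frame (half-open `[lo, hi)` day intervals).
#' @return the atlas with `samples$stage` filled.
#' @export
assign_stages <- function(atlas, stage_map = default_stage_map()) {
  st <- stage_of_age(atlas$samples$age, stage_map)
  if (anyNA(st)) {
    bad <- unique(atlas$samples$donor_id[is.na(st)])
    stop("donor age not covered by the stage map: ", paste(bad, collapse = ", "))
  }
  out <- atlas
  out$samples$stage <- st
  out
}

#' Run the full preprocessing pipeline
#'
#' Fixed order: donor exclusion, nearest-neighbour imputation of missing
#' regions, minimum-expression gene filtering, quantile normalization, log2
#' transform, stage assignment.
#'
#' @param atlas an `ExpressionAtlas` at scale `"rpkm"`.
#' @param cfg a [preprocess_config()].
#' @param stage_map stage-map data.frame.
#' @return the preprocessed atlas at scale `"log2"` with stages assigned.
#' @export
preprocess_atlas <- function(atlas, cfg = preprocess_config(),
                             stage_map = default_stage_map()) {
  atlas |>
    filter_donors(cfg) |>
    impute_missing(cfg) |>
    filter_genes(cfg) |>
    quantile_normalize() |>
    log_transform(cfg) |>
    assign_stages(stage_map)
}
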