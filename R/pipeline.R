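#' Configuration for an end-to-end run
#'
#' Nested blocks mirror the pipeline stages; every default can be overridden
#' by passing a partial list, which is merged over the defaults. The whole
#' config is serialized verbatim into the run manifest.
#'
#' @param ... named blocks (`preprocess`, `stagecorr`, `pairmodules`,
#'   `genomemodules`, `enrichment`, `permutation`, `hubs`) whose entries
#'   override the defaults.
#' @return a `RunConfig` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    preprocess = list(max_missing_regions = 6, min_rpkm = 5, log_offset = 1),
    stagecorr = list(min_abs_rho = 0.8),
    pairmodules = list(k = 3),
    genomemodules = list(k = 32, distance = "one_minus_rho"),
    enrichment = list(alpha = 0.001),
    permutation = list(enabled = FALSE, R = 10000, seed = 1),
    hubs = list(threshold = 0.9, top_n = 10)
  )
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  for (blk in names(override)) {
    defaults[[blk]][names(override[[blk]])] <- override[[blk]]
  }
  structure(defaults, class = "RunConfig")
}

#' Run the full co-expression pipeline
#'
#' Executes preprocessing, stage-resolved pair trajectories for the query
#' list, trajectory thresholding and temporal-module clustering,
#' transcriptome-wide module detection, gene-set enrichment (query plus any
#' marker sets) and hub-gene ranking, optionally with the pair-survival
#' permutation test. Every intermediate table is written as TSV under
#' `out_dir` with fixed names, and a JSON manifest records the config, seeds,
#' per-stage row counts and MD5 hashes of all outputs. Any stage error aborts
#' with the stage name; tables already written are preserved.
#'
#' @param atlas an `ExpressionAtlas` at scale `"rpkm"` (or a path to an atlas
#'   directory readable by [read_atlas()]).
#' @param query a `GeneSet`: the candidate gene list whose pair trajectories
#'   are analysed.
#' @param marker_sets optional named list of `GeneSet`s for enrichment.
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @param stage_map stage-map data.frame.
#' @return invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_all <- function(atlas, query, marker_sets = list(), out_dir,
                    config = run_config(), stage_map = default_stage_map()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(atlas)) {
    atlas <- read_atlas(file.path(atlas, "expression_matrix.csv"),
                        file.path(atlas, "columns_metadata.csv"),
                        file.path(atlas, "rows_metadata.csv"))
  }
  manifest <- list(package = "devcoexpr",
                   version = as.character(utils::packageVersion("devcoexpr")),
                   config = unclass(config), stages = character())
  outputs <- character()
  stage <- function(name, expr) {
    message("[", name, "] running")
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages <<- c(manifest$stages, name)
    res
  }
  emit <- function(tab, file) {
    path <- file.path(out_dir, file)
    write_table(tab, path)
    outputs <<- c(outputs, path)
  }

  pp <- config$preprocess
  atlas <- stage("preprocess", {
    cfg <- preprocess_config(max_missing_regions = pp$max_missing_regions,
                             min_rpkm = pp$min_rpkm,
                             log_offset = pp$log_offset)
    preprocess_atlas(atlas, cfg, stage_map)
  })
  manifest$n_samples <- nrow(atlas$samples)
  manifest$n_genes <- length(atlas$genes)

  traj <- stage("stage_coexpression", stage_pair_trajectories(atlas, query))
  surv <- threshold_pairs(traj, config$stagecorr$min_abs_rho)
  write_trajectories(traj, file.path(out_dir, "traj.tsv"))
  outputs <- c(outputs, file.path(out_dir, "traj.tsv"))
  manifest$n_pairs <- nrow(traj$pairs)
  manifest$n_pairs_surviving <- nrow(surv$pairs)

  part_pairs <- stage("trajectory_modules", {
    cluster_trajectories(surv, k = config$pairmodules$k)
  })
  summ <- summarize_modules(surv, part_pairs)
  emit(partition_table(part_pairs), "pair_modules.tsv")
  emit(data.frame(module = seq_len(part_pairs$k),
                  n_pairs = summ$module_sizes,
                  stats::setNames(as.data.frame(summ$mean_trajectory),
                                  paste0("rho_stage", surv$stages))),
       "pair_module_summary.tsv")
  emit(data.frame(
    module = rep(seq_along(summ$module_genes),
                 lengths(summ$module_genes)),
    gene = unlist(summ$module_genes)), "pair_module_genes.tsv")

  part_tx <- stage("transcriptome_modules", {
    cluster_transcriptome(atlas, k = config$genomemodules$k,
                          distance = config$genomemodules$distance)
  })
  emit(partition_table(part_tx), "genome_modules.tsv")
  emit(module_expression_profiles(atlas, part_tx), "module_profiles.tsv")
  manifest$transcriptome_module_sizes <- part_tx$module_sizes

  enr <- stage("enrichment", {
    enrich_modules(part_tx, c(list(query), marker_sets),
                   alpha = config$enrichment$alpha)
  })
  emit(enr, "enrichment.tsv")

  if (isTRUE(config$permutation$enabled)) {
    perm <- stage("permutation", {
      permutation_pair_survival(atlas, query, R = config$permutation$R,
                                min_abs_rho = config$stagecorr$min_abs_rho,
                                seed = config$permutation$seed)
    })
    emit(data.frame(observed_pairs = perm$observed_pairs, R = perm$R,
                    p_empirical = perm$p_empirical, seed = perm$seed),
         "permutation.tsv")
    emit(data.frame(table(null_count = perm$null_counts)),
         "permutation_null_histogram.tsv")
  }

  hubs <- stage("hub_analysis", {
    hub_report(atlas, part_tx, threshold = config$hubs$threshold,
               top_n = config$hubs$top_n)
  })
  emit(as.data.frame(hubs), "hubs.tsv")

  manifest$outputs <- as.list(tools::md5sum(sort(outputs)))
  names(manifest$outputs) <- basename(sort(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
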