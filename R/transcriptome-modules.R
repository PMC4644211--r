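#' Spearman correlation matrix of genes across samples
#'
#' @param atlas an `ExpressionAtlas`.
#' @param genes gene symbols (default all).
#' @return gene x gene Spearman correlation matrix.
#' @export
gene_cor_matrix <- function(atlas, genes = atlas$genes) {
  stats::cor(t(atlas$values[genes, , drop = FALSE]), method = "spearman")
}

#' Transcriptome-wide co-expression modules
#'
#' All (non-constant) genes are hierarchically clustered on the correlation
#' distance `d(g1, g2) = 1 - rho(g1, g2)` — Spearman over all samples — with
#' complete linkage, and the dendrogram cut into `k` flat modules. The signed
#' transform places strongly anti-correlated genes far apart so that each
#' module has a coherent average expression pattern; set
#' `distance = "one_minus_abs_rho"` to group by correlation magnitude
#' instead. Genes constant across all samples are excluded with a warning
#' before clustering.
#'
#' @param atlas an `ExpressionAtlas` at scale `"log2"`.
#' @param k number of modules (default 32).
#' @param distance `"one_minus_rho"` (default) or `"one_minus_abs_rho"`.
#' @return a `ModulePartition` over genes.
#' @export
cluster_transcriptome <- function(atlas, k = 32,
                                  distance = c("one_minus_rho",
                                               "one_minus_abs_rho")) {
  distance <- match.arg(distance)
  if (atlas$scale != "log2") stop("cluster_transcriptome expects scale 'log2'")
  const <- apply(atlas$values, 1, function(v) stats::sd(v) == 0)
  genes <- atlas$genes[!const]
  if (any(const)) {
    warning("excluding ", sum(const), " constant gene(s) from clustering")
  }
  if (k > length(genes)) {
    stop("k = ", k, " exceeds the number of usable genes (", length(genes), ")")
  }
  rho <- gene_cor_matrix(atlas, genes)
  d <- if (distance == "one_minus_rho") 1 - rho else 1 - abs(rho)
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  labels <- stats::cutree(hc, k = k)
  new_module_partition(genes, labels, "complete", distance)
}

#' Average regional expression profiles per module
#'
#' For every module, brain region and developmental stage, the mean log2
#' expression over the module's member genes and the matching samples.
#'
#' @param atlas a staged `ExpressionAtlas`.
#' @param part a gene-level `ModulePartition` (item ids = gene symbols).
#' @return data.frame with columns `module`, `region`, `stage`, `mean_expr`,
#'   sorted by (module, region, stage).
#' @export
module_expression_profiles <- function(atlas, part) {
  if (!all(part$item_ids %in% atlas$genes)) {
    stop("partition contains genes absent from the atlas")
  }
  s <- atlas$samples
  if (all(is.na(s$stage))) stop("atlas has no stage assignment")
  cell <- interaction(s$region, s$stage, drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(seq_len(part$k), function(m) {
    g <- part$item_ids[part$labels == m]
    v <- colMeans(atlas$values[g, , drop = FALSE])
    agg <- tapply(v, cell, mean)
    key <- do.call(rbind, strsplit(names(agg), ".", fixed = TRUE))
    data.frame(module = m, region = key[, 1],
               stage = as.integer(key[, 2]), mean_expr = as.numeric(agg),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$module, out$region, out$stage), , drop = FALSE]
  rownames(out) <- NULL
  out
}
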