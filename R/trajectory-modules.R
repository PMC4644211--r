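new_module_partition <- function(item_ids, labels, linkage_method,
                                 distance_metric, pairs = NULL) {
  k <- max(labels)
  structure(list(item_ids = item_ids, labels = as.integer(labels), k = k,
                 linkage_method = linkage_method,
                 distance_metric = distance_metric,
                 module_sizes = as.integer(table(factor(labels, levels = 1:k))),
                 pairs = pairs),
            class = "ModulePartition")
}

#' @export
print.ModulePartition <- function(x, ...) {
  cat("ModulePartition:", length(x$item_ids), "items in", x$k, "modules (",
      x$linkage_method, "linkage,", x$distance_metric, "distance )\n")
  cat("  sizes:", paste(x$module_sizes, collapse = " "), "\n")
  invisible(x)
}

#' Cluster gene-pair trajectories into temporal modules
#'
#' Agglomerative hierarchical clustering with complete linkage on the
#' Euclidean distance between the stage-length correlation trajectories; the
#' dendrogram is cut into exactly `k` flat modules. `NA` trajectory entries
#' are imputed to the pair's own mean over its defined stages before the
#' distance is computed (logged); a pair with no defined stage at all is
#' rejected. Results are deterministic given the input order.
#'
#' @param traj a `PairTrajectoryMatrix`, usually after [threshold_pairs()].
#' @param k number of modules (default 3).
#' @return a `ModulePartition` over the pairs (item ids `"geneA|geneB"`).
#' @export
cluster_trajectories <- function(traj, k = 3) {
  n <- nrow(traj$pairs)
  if (n == 0) stop("no gene pairs to cluster")
  if (k > n) stop("k = ", k, " exceeds the number of pairs (", n, ")")
  x <- traj$rho
  if (anyNA(x)) {
    if (any(rowSums(!is.na(x)) == 0)) {
      stop("pair(s) with no defined trajectory entry cannot be clustered")
    }
    message("cluster_trajectories: imputing ", sum(is.na(x)),
            " missing entries to per-pair stage means")
    rm_ <- rowMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- rm_[idx[, 1]]
  }
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "complete")
  labels <- stats::cutree(hc, k = k)
  ids <- paste(traj$pairs$gene_a, traj$pairs$gene_b, sep = "|")
  new_module_partition(ids, labels, "complete", "euclidean",
                       pairs = traj$pairs)
}

#' Summarize temporal modules by their mean trajectory
#'
#' Each module's correlation pattern is the per-stage arithmetic mean over
#' its member pairs' trajectories; the member gene list of a module is the
#' union of genes appearing in its member pairs.
#'
#' @param traj the `PairTrajectoryMatrix` that was clustered.
#' @param part the `ModulePartition` from [cluster_trajectories()].
#' @return a `ModuleSummary`: list with `mean_trajectory` (k x stages
#'   matrix), `module_sizes`, and `module_genes` (list of character vectors).
#' @export
summarize_modules <- function(traj, part) {
  if (nrow(traj$pairs) != length(part$item_ids)) {
    stop("partition does not cover the trajectory pairs")
  }
  k <- part$k
  if (any(part$module_sizes == 0)) stop("empty module in partition")
  mt <- t(vapply(seq_len(k), function(m) {
    colMeans(traj$rho[part$labels == m, , drop = FALSE], na.rm = TRUE)
  }, numeric(length(traj$stages))))
  rownames(mt) <- paste0("module", seq_len(k))
  genes <- lapply(seq_len(k), function(m) {
    sel <- part$labels == m
    sort(unique(c(traj$pairs$gene_a[sel], traj$pairs$gene_b[sel])))
  })
  structure(list(mean_trajectory = mt, module_sizes = part$module_sizes,
                 module_genes = genes),
            class = "ModuleSummary")
}

#' @export
print.ModuleSummary <- function(x, ...) {
  cat("ModuleSummary:", nrow(x$mean_trajectory), "modules\n")
  print(round(x$mean_trajectory, 3))
  invisible(x)
}

#' Tabulate a partition for writing
#'
#' @param part a `ModulePartition`.
#' @return data.frame `item_id`, `module` (sorted by module then item id).
#' @export
partition_table <- function(part) {
  out <- data.frame(item_id = part$item_ids, module = part$labels,
                    stringsAsFactors = FALSE)
  out[order(out$module, out$item_id), , drop = FALSE]
}
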