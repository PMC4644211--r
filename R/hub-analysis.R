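#' Correlation graph of one co-expression module
#'
#' Nodes are the module's genes; an undirected edge joins two genes whose
#' Spearman correlation over all samples reaches `threshold`. The default is
#' the signed rule (`rho >= threshold`); `rule = "absolute"` uses
#' `|rho| >= threshold`. The edge statistic is the same one the transcriptome
#' clustering used, recomputed over the full sample panel.
#'
#' @param atlas an `ExpressionAtlas`.
#' @param part a gene-level `ModulePartition`.
#' @param module_id module to extract.
#' @param threshold edge threshold in `[0, 1]` (default 0.9).
#' @param rule `"signed"` (default) or `"absolute"`.
#' @return data.frame `gene_a`, `gene_b`, `rho` (gene_a < gene_b, sorted);
#'   empty with a warning for modules of size < 2.
#' @export
module_graph <- function(atlas, part, module_id, threshold = 0.9,
                         rule = c("signed", "absolute")) {
  rule <- match.arg(rule)
  stopifnot(threshold >= 0, threshold <= 1)
  if (!module_id %in% seq_len(part$k)) stop("no module ", module_id)
  genes <- sort(part$item_ids[part$labels == module_id])
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      rho = numeric(), stringsAsFactors = FALSE)
  if (length(genes) < 2) {
    warning("module ", module_id, " has fewer than 2 genes")
    return(empty)
  }
  rho <- gene_cor_matrix(atlas, genes)
  stat <- if (rule == "signed") rho else abs(rho)
  sel <- which(upper.tri(stat) & stat >= threshold, arr.ind = TRUE)
  if (!nrow(sel)) return(empty)
  out <- data.frame(gene_a = genes[sel[, 1]], gene_b = genes[sel[, 2]],
                    rho = rho[sel], stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top hub genes of a module graph
#'
#' Genes ranked by degree (number of above-threshold edges), descending,
#' alphabetical within ties; ranks are dense and tied genes share a rank.
#' All genes tied with the `n`-th entry are included and flagged
#' (`boundary_tie`) rather than arbitrarily truncated.
#'
#' @param edges edge list from [module_graph()].
#' @param n number of top hubs requested (default 10).
#' @param module_id optional module id to stamp on the rows.
#' @return data.frame `module`, `gene`, `degree`, `rank`, `boundary_tie`.
#' @export
top_hubs <- function(edges, n = 10, module_id = NA_integer_) {
  stopifnot(n >= 1)
  empty <- data.frame(module = integer(), gene = character(),
                      degree = integer(), rank = integer(),
                      boundary_tie = logical(), stringsAsFactors = FALSE)
  if (!nrow(edges)) return(empty)
  deg <- table(c(edges$gene_a, edges$gene_b))
  genes <- names(deg)
  ord <- order(-as.integer(deg), genes)
  deg <- as.integer(deg)[ord]
  genes <- genes[ord]
  rank <- match(deg, sort(unique(deg), decreasing = TRUE))  # dense, shared
  if (length(genes) > n) {
    cutoff <- deg[n]
    keep <- deg >= cutoff
    # all genes tied at the boundary degree are kept; flag them when they
    # overflow the requested n
    overflow <- sum(deg > cutoff) + sum(deg == cutoff) > n
    boundary <- (deg == cutoff) & overflow
  } else {
    keep <- rep(TRUE, length(genes))
    boundary <- rep(FALSE, length(genes))
  }
  out <- data.frame(module = module_id, gene = genes[keep],
                    degree = deg[keep], rank = rank[keep],
                    boundary_tie = boundary[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Hub report over several modules
#'
#' @param atlas an `ExpressionAtlas`.
#' @param part a gene-level `ModulePartition`.
#' @param modules integer ids or `"all"`.
#' @param threshold edge threshold (default 0.9).
#' @param top_n hubs per module (default 10).
#' @param rule `"signed"` or `"absolute"` edge rule.
#' @return a `HubReport` data.frame (rows as in [top_hubs()]).
#' @export
hub_report <- function(atlas, part, modules = "all", threshold = 0.9,
                       top_n = 10, rule = "signed") {
  if (identical(modules, "all")) modules <- seq_len(part$k)
  out <- do.call(rbind, lapply(modules, function(m) {
    top_hubs(module_graph(atlas, part, m, threshold, rule), n = top_n,
             module_id = m)
  }))
  if (is.null(out)) {
    out <- top_hubs(data.frame(gene_a = character(), gene_b = character()))
  }
  attr(out, "edge_threshold") <- threshold
  class(out) <- c("HubReport", "data.frame")
  out
}

#' Write an edge list as GraphML for external network viewers
#'
#' @param edges edge list from [module_graph()].
#' @param path output `.graphml` path.
#' @return invisibly, `path`.
#' @export
write_graphml <- function(edges, path) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
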