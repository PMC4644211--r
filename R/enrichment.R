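#' Hypergeometric over-representation probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, m)`: the probability that a
#' module of `m` genes drawn without replacement from a universe of `N` genes
#' containing `K` query genes overlaps the query in at least `k` genes. Set
#' `mode = "pmf"` for the point probability `P(X = k)` (of archaeological
#' interest only; over-representation testing uses the upper tail).
#'
#' @param N universe size.
#' @param K query genes in the universe.
#' @param m module size.
#' @param k observed overlap.
#' @param mode `"upper_tail"` (default) or `"pmf"`.
#' @return a probability.
#' @export
hypergeom_upper_tail <- function(N, K, m, k, mode = c("upper_tail", "pmf")) {
  mode <- match.arg(mode)
  if (!(k >= 0 && k <= m && m <= N && K >= 0 && K <= N && k <= K)) {
    if (k > K || k > m) {
      if (k > min(K, m)) stop("k exceeds min(K, m)")
    } else {
      stop("invalid hypergeometric arguments")
    }
  }
  if (mode == "pmf") return(stats::dhyper(k, K, N - K, m))
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvals numeric vector of p values in `[0, 1]`.
#' @return BH step-up adjusted p values (monotone in rank, `<= 1`).
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Gene-set over-representation in co-expression modules
#'
#' One hypergeometric upper-tail test per (module, query set), with the
#' clustered genes as the universe. BH-FDR is applied within each query set
#' across modules (`fdr_scope = "per_query"`) or over all rows at once
#' (`"global"`). A query with empty intersection with the universe yields
#' rows with `K = 0`, `p = 1` and a warning.
#'
#' @param part a gene-level `ModulePartition`.
#' @param queries a `GeneSet` or list of `GeneSet`s.
#' @param universe a `GeneSet`/character vector; defaults to the clustered
#'   genes. Queries are intersected with the universe before counting.
#' @param alpha significance level on the FDR-adjusted p (default 0.001).
#' @param fdr_scope `"per_query"` (default) or `"global"`.
#' @return an `EnrichmentTable` data.frame: `module`, `query`, `N`, `K`,
#'   `m`, `k`, `p_hyper`, `p_fdr`, `significant`; sorted by (query, module).
#' @export
enrich_modules <- function(part, queries, universe = NULL, alpha = 0.001,
                           fdr_scope = c("per_query", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  if (inherits(queries, "GeneSet")) queries <- list(queries)
  uni <- if (is.null(universe)) part$item_ids else
    intersect(as_gene_vector(universe), part$item_ids)
  N <- length(uni)
  in_uni <- part$item_ids %in% uni
  rows <- do.call(rbind, lapply(queries, function(q) {
    qg <- intersect(as_gene_vector(q), uni)
    K <- length(qg)
    if (K == 0) {
      warning("query '", q$name, "' has no gene in the universe")
    }
    do.call(rbind, lapply(seq_len(part$k), function(mod) {
      members <- part$item_ids[part$labels == mod & in_uni]
      m <- length(members)
      k <- length(intersect(members, qg))
      data.frame(module = mod, query = q$name, N = N, K = K, m = m, k = k,
                 p_hyper = if (K == 0) 1 else hypergeom_upper_tail(N, K, m, k),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (fdr_scope == "per_query") {
    rows$p_fdr <- stats::ave(rows$p_hyper, rows$query, FUN = bh_fdr)
  } else {
    rows$p_fdr <- bh_fdr(rows$p_hyper)
  }
  rows$significant <- rows$p_fdr < alpha
  rows <- rows[order(rows$query, rows$module), , drop = FALSE]
  rownames(rows) <- NULL
  class(rows) <- c("EnrichmentTable", "data.frame")
  rows
}

#' Permutation null for the number of strongly co-expressed pairs
#'
#' Counts the gene pairs of `query` whose stage trajectory exceeds
#' `min_abs_rho` in absolute value at some stage, then repeats the count for
#' `R` uniformly drawn random gene sets of the same size from the atlas
#' genes. The empirical p value uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (1 + R)`, so it is never exactly 0.
#'
#' @param atlas a staged `ExpressionAtlas`.
#' @param query a `GeneSet` or character vector (>= 2 genes in the atlas).
#' @param R number of random sets (default 10000).
#' @param min_abs_rho survival threshold (default 0.8, strict).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param max_draws guard on `R * set size` (default 5e7) to catch infeasible
#'   requests early.
#' @return a `PermutationResult`: `observed_pairs`, `null_counts` (length
#'   `R`), `p_empirical`, `R`, `seed`.
#' @export
permutation_pair_survival <- function(atlas, query, R = 10000,
                                      min_abs_rho = 0.8, seed,
                                      max_draws = 5e7) {
  stopifnot(R >= 1)
  if (missing(seed)) stop("a seed is required")
  qg <- sort(intersect(as_gene_vector(query), atlas$genes))
  if (length(qg) < 2) stop("query must share at least 2 genes with the atlas")
  if (as.double(R) * length(qg) > max_draws) {
    stop("R x set size exceeds the feasibility cap; reduce R")
  }
  all_genes <- sort(atlas$genes)
  prof <- donor_rank_profiles(atlas, all_genes)
  stages <- seq_len(max(atlas$samples$stage))

  count_surviving <- function(idx) {
    agg <- stage_mean_rho(prof, idx = idx, stages = stages)
    layers <- lapply(seq_along(stages), function(s) abs(agg$mean[, , s]))
    mx <- do.call(pmax, c(layers, list(na.rm = TRUE)))
    sum(mx[upper.tri(mx)] > min_abs_rho, na.rm = TRUE)
  }

  observed <- count_surviving(match(qg, all_genes))
  set.seed(seed)
  null_counts <- vapply(seq_len(R), function(r) {
    count_surviving(sample.int(length(all_genes), length(qg)))
  }, numeric(1))
  structure(list(observed_pairs = observed, null_counts = null_counts,
                 p_empirical = (1 + sum(null_counts >= observed)) / (1 + R),
                 R = R, seed = seed),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat("PermutationResult: observed =", x$observed_pairs,
      "surviving pairs; R =", x$R, "\n")
  cat("  null mean =", round(mean(x$null_counts), 2),
      " max =", max(x$null_counts),
      " p =", format(x$p_empirical, digits = 4), "\n")
  invisible(x)
}
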