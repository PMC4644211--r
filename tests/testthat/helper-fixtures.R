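# Shared fixtures, built in code. The default simulated scenario is cached so
# the suite pays for generation and preprocessing once.

sim_default <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42)
      sim <- simulate_atlas(cfg)
      sim$cfg <- cfg
      sim$pre <- suppressMessages(preprocess_atlas(sim$atlas))
      cache <<- sim
    }
    cache
  }
})

# a planted partition over the expression-module genes, from ground truth
truth_expr_partition <- function(truth) {
  g <- truth$genes
  sel <- !is.na(g$expr_module)
  devcoexpr:::new_module_partition(g$gene[sel], g$expr_module[sel],
                                   "planted", "planted")
}

# hand-built atlas: values chosen directly, one donor per age, stages set
tiny_atlas <- function(values, ages, regions = NULL, scale = "log2",
                       stage = NULL) {
  n <- ncol(values)
  n_donors <- length(ages)
  stopifnot(n %% n_donors == 0)
  per <- n / n_donors
  if (is.null(regions)) regions <- paste0("R", seq_len(per))
  samples <- data.frame(
    sample_id = paste0("s", seq_len(n)),
    donor_id = rep(paste0("d", seq_len(n_donors)), each = per),
    age = rep(ages, each = per), sex = "M",
    region = rep(regions, n_donors), stringsAsFactors = FALSE)
  if (!is.null(stage)) samples$stage <- rep(stage, each = per)
  a <- expression_atlas(values, samples,
                        genes = rownames(values) %||%
                          sprintf("G%03d", seq_len(nrow(values))),
                        scale = "rpkm")
  a$scale <- scale
  a
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent Spearman oracle: mid-ranks by counting, then textbook Pearson
spearman_oracle <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# independent hypergeometric oracle: enumerate all m-subsets of 1..N, where
# the query is 1..K, and count overlaps
hyper_tail_oracle <- function(N, K, m, k) {
  if (m == 0) return(as.numeric(k == 0))
  subsets <- utils::combn(N, m)
  overlaps <- colSums(subsets <= K)
  mean(overlaps >= k)
}

# independent BH oracle: literal step-up definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
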