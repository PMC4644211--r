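#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of mid-ranks (ties receive average ranks). When either
#' vector is constant the rank correlation is undefined and `NA` is returned
#' rather than an error, so callers can decide how to treat undefined donors.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return a number in `[-1, 1]`, or `NA` if undefined.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

new_pair_trajectories <- function(pairs, rho, n_donors_used, stages) {
  rownames(rho) <- rownames(n_donors_used) <- NULL
  structure(list(pairs = pairs, rho = rho, n_donors_used = n_donors_used,
                 stages = stages),
            class = "PairTrajectoryMatrix")
}

#' @export
print.PairTrajectoryMatrix <- function(x, ...) {
  cat("PairTrajectoryMatrix:", nrow(x$pairs), "gene pairs x",
      length(x$stages), "stages\n")
  invisible(x)
}

# Per-donor gene profiles as centred, unit-norm mid-ranks across that donor's
# regions, so that tcrossprod() of two rows is their Spearman correlation.
# Constant genes get an all-NA row. Returns list(donors, stage, mats).
donor_rank_profiles <- function(atlas, genes) {
  s <- atlas$samples
  if (all(is.na(s$stage))) stop("atlas has no stage assignment; run assign_stages")
  donors <- unique(s$donor_id)
  stage <- vapply(donors, function(d) s$stage[s$donor_id == d][1], integer(1))
  mats <- lapply(donors, function(d) {
    cols <- which(s$donor_id == d)
    m <- atlas$values[genes, cols, drop = FALSE]
    # vectorized row-wise mid-ranks: rank = #less + (#equal + 1) / 2
    r <- m
    for (j in seq_len(ncol(m))) {
      r[, j] <- rowSums(m < m[, j]) + (rowSums(m == m[, j]) + 1) / 2
    }
    r <- r - rowMeans(r)
    nrm <- sqrt(rowSums(r^2))
    bad <- nrm == 0
    r <- r / ifelse(bad, 1, nrm)
    r[bad, ] <- NA_real_
    r
  })
  list(donors = donors, stage = stage, mats = mats)
}

# Stage-wise mean Spearman matrices from donor rank profiles, optionally for
# a gene subset (integer index into the profile rows). Donors where a gene is
# constant are skipped for that gene's pairs; the divisor is returned in $n.
stage_mean_rho <- function(prof, idx = NULL, stages = NULL) {
  if (is.null(stages)) stages <- seq_len(max(prof$stage))
  g <- if (is.null(idx)) nrow(prof$mats[[1]]) else length(idx)
  sums <- counts <- array(0, dim = c(g, g, length(stages)))
  for (k in seq_along(prof$donors)) {
    st <- match(prof$stage[k], stages)
    if (is.na(st)) next
    m <- prof$mats[[k]]
    if (!is.null(idx)) m <- m[idx, , drop = FALSE]
    rho <- tcrossprod(m)
    if (anyNA(rho)) {
      ok <- !is.na(rho)
      rho[!ok] <- 0
      sums[, , st] <- sums[, , st] + rho
      counts[, , st] <- counts[, , st] + ok
    } else {
      sums[, , st] <- sums[, , st] + rho
      counts[, , st] <- counts[, , st] + 1
    }
  }
  mean <- sums / counts
  mean[counts == 0] <- NA_real_
  list(mean = mean, n = counts, stages = stages)
}

#' Stage-resolved co-expression trajectories for all gene pairs
#'
#' For every unordered pair of query genes present in the atlas, the Spearman
#' correlation across brain regions is computed separately within each donor,
#' then averaged (arithmetic mean) over the donors of each developmental
#' stage. The resulting trajectory — one correlation per stage — is the
#' central statistic of the package. Donors where either gene is constant
#' across regions contribute nothing to that pair's average for their stage;
#' if every donor of a stage is skipped the entry is `NA`.
#'
#' @param atlas a staged `ExpressionAtlas` (typically at scale `"log2"`).
#' @param genes a `GeneSet` or character vector; `NULL` uses all atlas genes.
#' @return a `PairTrajectoryMatrix`: `pairs` (data.frame `gene_a` < `gene_b`
#'   lexicographically), `rho` (pairs x stages), `n_donors_used` (pairs x
#'   stages), `stages`.
#' @export
stage_pair_trajectories <- function(atlas, genes = NULL) {
  g <- if (is.null(genes)) atlas$genes else
    intersect(as_gene_vector(genes), atlas$genes)
  g <- sort(unique(g))
  if (length(g) < 2) stop("need at least 2 query genes present in the atlas")
  s <- atlas$samples
  if (all(is.na(s$stage))) stop("atlas has no stage assignment; run assign_stages")
  stages <- seq_len(max(s$stage))
  donors_per_stage <- table(factor(
    s$stage[!duplicated(s$donor_id)], levels = stages))
  if (any(donors_per_stage == 0)) {
    stop("stage(s) without donors: ",
         paste(stages[donors_per_stage == 0], collapse = ", "))
  }
  prof <- donor_rank_profiles(atlas, g)
  agg <- stage_mean_rho(prof, stages = stages)
  ut <- which(upper.tri(matrix(nrow = length(g), ncol = length(g))),
              arr.ind = TRUE)
  ut <- ut[order(ut[, "row"], ut[, "col"]), , drop = FALSE]
  flat <- function(a) {
    out <- vapply(seq_along(stages),
                  function(st) a[, , st][ut], numeric(nrow(ut)))
    matrix(out, nrow = nrow(ut))
  }
  rho <- flat(agg$mean)
  n <- flat(agg$n)
  # clamp tiny fp excursions outside [-1, 1]
  rho[!is.na(rho) & rho > 1] <- 1
  rho[!is.na(rho) & rho < -1] <- -1
  pairs <- data.frame(gene_a = g[ut[, "row"]], gene_b = g[ut[, "col"]],
                      stringsAsFactors = FALSE)
  new_pair_trajectories(pairs, rho, n, stages)
}

#' Retain strongly co-expressed gene pairs
#'
#' Keeps pairs whose trajectory reaches an absolute correlation strictly
#' greater than `min_abs_rho` in at least one developmental stage; `NA`
#' entries are ignored in the maximum. Pair order is preserved.
#'
#' @param traj a `PairTrajectoryMatrix`.
#' @param min_abs_rho threshold in `[0, 1]` (default 0.8).
#' @return the filtered `PairTrajectoryMatrix` (possibly with zero rows).
#' @export
threshold_pairs <- function(traj, min_abs_rho = 0.8) {
  stopifnot(min_abs_rho >= 0, min_abs_rho <= 1)
  mx <- apply(abs(traj$rho), 1, function(v) {
    if (all(is.na(v))) -Inf else max(v, na.rm = TRUE)
  })
  keep <- mx > min_abs_rho
  new_pair_trajectories(traj$pairs[keep, , drop = FALSE],
                        traj$rho[keep, , drop = FALSE],
                        traj$n_donors_used[keep, , drop = FALSE],
                        traj$stages)
}
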