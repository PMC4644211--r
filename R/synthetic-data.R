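#' Configuration for the synthetic atlas generator
#'
#' The defaults emulate the geometry of a developmental brain expression
#' atlas: 30 donors across 16 brain regions, grouped into 7 developmental
#' stages, with a small fraction of donor-region samples missing. Planted
#' pair-modules share a per-donor regional latent factor whose loading is
#' scheduled over stages so that member-pair Spearman correlation follows a
#' target trajectory shape; planted expression modules share a deterministic
#' region x stage profile with per-gene loadings (one optional hub gene at
#' doubled loading). Remaining genes are independent noise around their
#' baseline.
#'
#' @param n_donors number of donors (default 30).
#' @param regions region acronyms (default the 16-region panel).
#' @param stage_map stage-map data.frame; its row count sets the stage count.
#' @param donors_per_stage integer allocation summing to `n_donors`.
#' @param n_genes total genes (default 400).
#' @param planted_pair_modules list of `list(size, trajectory_shape, rho_target)`
#'   with shape one of `"prenatal_high"`, `"postnatal_high"`, `"flat_noise"`.
#' @param planted_expr_modules list of `list(size, regional_sd, temporal_sd,
#'   factor_sd, noise_sd, hub)`; `regional_sd`/`temporal_sd` scale the region
#'   and stage components of the shared log2 profile, `factor_sd` the
#'   per-sample shared latent factor, `noise_sd` optionally overrides the
#'   global noise level for member genes (tightly co-regulated genes are less
#'   noisy than the transcriptome at large), and `hub = TRUE` plants one gene
#'   at doubled loading.
#' @param noise_sd per-value Gaussian noise on the log2 scale (default 0.1).
#' @param missing_region_rate probability a donor-region sample is missing
#'   (default 0.05; capped at 6 missing regions per donor).
#' @param marker_overlap_fraction fraction of each simulated gene list drawn
#'   from its aligned planted module (default 0.8).
#' @param query_size,marker_size sizes of the simulated query and marker
#'   lists (defaults 80 and 60).
#' @param seed RNG seed (mandatory).
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n_donors = 30,
                       regions = default_regions(),
                       stage_map = default_stage_map(),
                       donors_per_stage = c(5, 5, 4, 4, 4, 4, 4),
                       n_genes = 400,
                       planted_pair_modules = list(
                         list(size = 40, trajectory_shape = "prenatal_high",
                              rho_target = 0.9),
                         list(size = 40, trajectory_shape = "postnatal_high",
                              rho_target = 0.9),
                         list(size = 40, trajectory_shape = "flat_noise",
                              rho_target = 0)),
                       planted_expr_modules = list(
                         list(size = 50, regional_sd = 0.037,
                              temporal_sd = 0.15, factor_sd = 0.15,
                              noise_sd = 0.06, hub = TRUE),
                         list(size = 50, regional_sd = 0.037,
                              temporal_sd = 0.15, factor_sd = 0.15,
                              noise_sd = 0.06, hub = TRUE),
                         list(size = 50, regional_sd = 0.037,
                              temporal_sd = 0.15, factor_sd = 0.15,
                              noise_sd = 0.06, hub = TRUE)),
                       noise_sd = 0.1,
                       missing_region_rate = 0.05,
                       marker_overlap_fraction = 0.8,
                       query_size = 80, marker_size = 60,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  validate_stage_map(stage_map)
  n_stages <- nrow(stage_map)
  if (length(donors_per_stage) != n_stages) {
    stop("donors_per_stage must have one entry per stage")
  }
  if (sum(donors_per_stage) != n_donors) {
    stop("donors_per_stage must sum to n_donors")
  }
  planted <- sum(vapply(planted_pair_modules, function(m) m$size, numeric(1)),
                 vapply(planted_expr_modules, function(m) m$size, numeric(1)))
  if (planted > n_genes) stop("planted module sizes exceed n_genes")
  stopifnot(noise_sd >= 0, missing_region_rate >= 0, missing_region_rate < 1,
            marker_overlap_fraction >= 0, marker_overlap_fraction <= 1)
  shapes <- vapply(planted_pair_modules, function(m) m$trajectory_shape,
                   character(1))
  if (!all(shapes %in% c("prenatal_high", "postnatal_high", "flat_noise"))) {
    stop("unknown trajectory_shape")
  }
  structure(list(n_donors = n_donors, regions = regions,
                 stage_map = stage_map, n_stages = n_stages,
                 donors_per_stage = as.integer(donors_per_stage),
                 n_genes = n_genes,
                 planted_pair_modules = planted_pair_modules,
                 planted_expr_modules = planted_expr_modules,
                 noise_sd = noise_sd,
                 missing_region_rate = missing_region_rate,
                 marker_overlap_fraction = marker_overlap_fraction,
                 query_size = query_size, marker_size = marker_size,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# Target member-pair Spearman correlation per stage for a planted pair-module
pair_module_rho_schedule <- function(shape, rho_target, stage_map) {
  S <- nrow(stage_map)
  prenatal <- stage_map$hi <= 0
  switch(shape,
         prenatal_high = ifelse(prenatal, rho_target, 0),
         postnatal_high = rho_target * (seq_len(S) - 1) / (S - 1),
         flat_noise = rep(0, S))
}

#' Simulate a developmental expression atlas with planted structure
#'
#' Values are built on the log2 scale as
#' `baseline + pair-module factor signal + expression-module profile + noise`
#' and exponentiated to an RPKM-like positive scale. For a pair-module with
#' stage correlation target `rho_s`, the factor loading is
#' `0.1 * sqrt(rho_s / (1 - rho_s))` — calibrated so that at the default
#' noise level (`noise_sd = 0.1`) the expected pairwise Pearson correlation
#' of member genes across regions equals `rho_s` (Spearman is marginally
#' below this for Gaussian data). Raising `noise_sd` above the reference
#' level therefore degrades planted correlations, as real measurement noise
#' would. The regional factor is redrawn per donor. Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `atlas` (an `ExpressionAtlas` at scale `"rpkm"`, stages
#'   unset) and `truth` (a `SimTruth`: per-gene planted labels and loadings,
#'   the per-module stage correlation schedule, planted hub genes, and the
#'   donor table).
#' @export
simulate_atlas <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  S <- cfg$n_stages
  R <- length(cfg$regions)

  # donors: stage allocation, then uniform age within the stage interval
  donor_stage <- rep(seq_len(S), cfg$donors_per_stage)
  donor_age <- stats::runif(cfg$n_donors,
                            cfg$stage_map$lo[donor_stage],
                            cfg$stage_map$hi[donor_stage])
  donor_id <- sprintf("d%02d", seq_len(cfg$n_donors))
  donor_sex <- sample(c("M", "F"), cfg$n_donors, replace = TRUE)

  # gene blocks: pair modules first, then expression modules, then background
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  pair_label <- expr_label <- rep(NA_integer_, cfg$n_genes)
  loading <- rep(1, cfg$n_genes)
  is_hub <- rep(FALSE, cfg$n_genes)
  at <- 0L
  for (j in seq_along(cfg$planted_pair_modules)) {
    sz <- cfg$planted_pair_modules[[j]]$size
    pair_label[at + seq_len(sz)] <- j
    at <- at + sz
  }
  for (j in seq_along(cfg$planted_expr_modules)) {
    mod <- cfg$planted_expr_modules[[j]]
    idx <- at + seq_len(mod$size)
    expr_label[idx] <- j
    loading[idx] <- stats::runif(mod$size, 0.85, 1.15)
    if (isTRUE(mod$hub)) {
      loading[idx[1]] <- 2
      is_hub[idx[1]] <- TRUE
    }
    at <- at + mod$size
  }
  baseline <- stats::runif(cfg$n_genes, 3, 8)

  rho_sched <- lapply(cfg$planted_pair_modules, function(m) {
    pair_module_rho_schedule(m$trajectory_shape, m$rho_target, cfg$stage_map)
  })
  # loadings calibrated at the reference noise level (0.1) so that noise_sd
  # acts as a degradation dial rather than being compensated away
  lam_sched <- lapply(rho_sched, function(r) 0.1 * sqrt(r / (1 - r)))

  # shared region x stage profiles for expression modules; each component is
  # rescaled to its exact target sd so module correlation strength does not
  # swing with the luck of a handful of draws
  scale_to_sd <- function(v, target) {
    v <- v - mean(v)
    s <- stats::sd(v)
    if (length(v) < 2 || target == 0 || s == 0) return(rep(0, length(v)))
    v * target / s
  }
  expr_profiles <- lapply(cfg$planted_expr_modules, function(m) {
    list(region = scale_to_sd(stats::rnorm(R), m$regional_sd),
         stage = scale_to_sd(stats::rnorm(S), m$temporal_sd),
         factor_sd = if (is.null(m$factor_sd)) 0 else m$factor_sd,
         noise_sd = if (is.null(m$noise_sd)) cfg$noise_sd else m$noise_sd)
  })

  values <- matrix(NA_real_, cfg$n_genes, cfg$n_donors * R)
  meta <- vector("list", cfg$n_donors)
  for (d in seq_len(cfg$n_donors)) {
    st <- donor_stage[d]
    noise <- matrix(stats::rnorm(cfg$n_genes * R, 0, cfg$noise_sd),
                    cfg$n_genes, R)
    z <- noise + baseline
    for (j in seq_along(cfg$planted_pair_modules)) {
      lam <- lam_sched[[j]][st]
      if (lam > 0) {
        f <- stats::rnorm(R)  # one regional factor per donor and module
        sel <- which(pair_label == j)
        z[sel, ] <- z[sel, ] + loading[sel] %o% (lam * f)
      }
    }
    for (j in seq_along(cfg$planted_expr_modules)) {
      ep <- expr_profiles[[j]]
      p <- ep$region + ep$stage[st] + stats::rnorm(R, 0, ep$factor_sd)
      sel <- which(expr_label == j)
      z[sel, ] <- z[sel, ] + loading[sel] %o% p
      if (ep$noise_sd != cfg$noise_sd) {
        # per-module noise override: replace the global noise for members
        z[sel, ] <- z[sel, ] - noise[sel, ] +
          matrix(stats::rnorm(length(sel) * R, 0, ep$noise_sd),
                 length(sel), R)
      }
    }
    values[, (d - 1) * R + seq_len(R)] <- 2^z
    meta[[d]] <- data.frame(
      sample_id = paste(donor_id[d], cfg$regions, sep = "_"),
      donor_id = donor_id[d], age = donor_age[d], sex = donor_sex[d],
      region = cfg$regions, stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, meta)

  # mask missing donor-region samples (at most 6 per donor; every region
  # must stay observed in at least one donor)
  drop <- rep(FALSE, nrow(samples))
  if (cfg$missing_region_rate > 0) {
    for (d in seq_len(cfg$n_donors)) {
      idx <- which(samples$donor_id == donor_id[d])
      m <- which(stats::runif(R) < cfg$missing_region_rate)
      if (length(m) > 6) m <- m[seq_len(6)]
      drop[idx[m]] <- TRUE
    }
    for (r in cfg$regions) {
      ridx <- which(samples$region == r)
      if (all(drop[ridx])) drop[ridx[1]] <- FALSE
    }
  }

  atlas <- expression_atlas(values[, !drop, drop = FALSE],
                            samples[!drop, , drop = FALSE],
                            genes = genes, scale = "rpkm")
  truth <- structure(list(
    genes = data.frame(gene = genes, pair_module = pair_label,
                       expr_module = expr_label, loading = loading,
                       is_hub = is_hub, stringsAsFactors = FALSE),
    rho_schedule = do.call(rbind, rho_sched),
    hub_genes = genes[is_hub],
    donors = data.frame(donor_id = donor_id, age = donor_age,
                        stage = donor_stage, stringsAsFactors = FALSE),
    config = cfg), class = "SimTruth")
  list(atlas = atlas, truth = truth)
}

#' Planted labels for gene pairs
#'
#' Maps each row of a pair table to its planted pair-module: a pair is
#' labelled `j` iff both genes belong to planted pair-module `j`, `NA`
#' otherwise. Used as the clustering oracle in parameter-recovery tests.
#'
#' @param truth a `SimTruth`.
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @return integer vector of module labels (`NA` for unplanted pairs).
#' @export
planted_pair_labels <- function(truth, pairs) {
  lab <- truth$genes$pair_module[match(pairs$gene_a, truth$genes$gene)]
  lab_b <- truth$genes$pair_module[match(pairs$gene_b, truth$genes$gene)]
  ifelse(!is.na(lab) & !is.na(lab_b) & lab == lab_b, lab, NA_integer_)
}

#' Simulate query and cell-type marker gene lists
#'
#' Produces one query list overlapping the planted pair-modules at
#' `cfg$marker_overlap_fraction` (filler genes drawn from the unplanted
#' background) and one marker list per planted expression module, each
#' overlapping its module at the same fraction — the roles of a candidate
#' gene list and of neuron/astrocyte/oligodendrocyte marker panels.
#'
#' @param truth a `SimTruth` from [simulate_atlas()].
#' @param cfg the same [sim_config()].
#' @param seed RNG seed for the list composition (default `cfg$seed + 1`).
#' @return named list of `GeneSet`s: `query`, then `marker1..n`.
#' @export
simulate_gene_sets <- function(truth, cfg, seed = cfg$seed + 1) {
  set.seed(seed)
  g <- truth$genes
  background <- g$gene[is.na(g$pair_module) & is.na(g$expr_module)]
  draw <- function(pool, n) {
    if (n > length(pool)) stop("gene pool too small for requested list size")
    sample(pool, n)
  }
  mk <- function(aligned_pool, size, name) {
    n_in <- round(cfg$marker_overlap_fraction * size)
    gene_set(c(draw(aligned_pool, n_in), draw(background, size - n_in)),
             name = name)
  }
  out <- list(query = mk(g$gene[!is.na(g$pair_module)], cfg$query_size,
                         "query"))
  for (j in seq_along(cfg$planted_expr_modules)) {
    out[[paste0("marker", j)]] <-
      mk(g$gene[g$expr_module %in% j], cfg$marker_size, paste0("marker", j))
  }
  out
}
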