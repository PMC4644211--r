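# helper: an RPKM atlas where donor d has the given regions
regions_atlas <- function(donor_regions, ages = NULL) {
  donors <- names(donor_regions)
  if (is.null(ages)) ages <- stats::setNames(seq_along(donors) * 100, donors)
  samples <- do.call(rbind, lapply(donors, function(d) {
    data.frame(sample_id = paste(d, donor_regions[[d]], sep = "_"),
               donor_id = d, age = ages[[d]], sex = "M",
               region = donor_regions[[d]], stringsAsFactors = FALSE)
  }))
  set.seed(99)
  values <- matrix(stats::runif(3 * nrow(samples), 1, 100), 3,
                   dimnames = list(c("A", "B", "C"), samples$sample_id))
  expression_atlas(values, samples, genes = c("A", "B", "C"))
}

test_that("donors are excluded only when missing strictly more than the cap", {
  req <- default_regions()
  atl <- regions_atlas(list(
    full = req,
    six_missing = req[1:10],    # misses exactly 6 -> retained
    seven_missing = req[1:9]))  # misses 7 -> dropped
  out <- suppressMessages(filter_donors(atl, preprocess_config()))
  expect_setequal(unique(out$samples$donor_id), c("full", "six_missing"))
  # all donors complete -> identity
  atl2 <- regions_atlas(list(d1 = req, d2 = req))
  out2 <- filter_donors(atl2, preprocess_config())
  expect_identical(out2$values, atl2$values)
  expect_error(
    suppressMessages(filter_donors(regions_atlas(list(bad = req[1:2])))),
    "no donor")
})

test_that("imputation copies the age-nearest donor's region, tie to younger", {
  req <- c("AMY", "HIP", "STR")
  cfg <- preprocess_config(regions_required = req, max_missing_regions = 2)
  atl <- regions_atlas(
    list(A = c("AMY", "STR"), B = req, C = req),
    ages = c(A = 100, B = 90, C = 200))
  out <- suppressMessages(impute_missing(atl, cfg))
  expect_equal(sort(out$samples$region[out$samples$donor_id == "A"]), sort(req))
  # A (100 d) missing HIP; B at 90 d is nearer than C at 200 d
  expect_identical(unname(out$values[, "A_HIP"]), unname(atl$values[, "B_HIP"]))
  expect_true(out$samples$imputed[out$samples$sample_id == "A_HIP"])
  # observed columns bit-identical
  for (sid in atl$samples$sample_id) {
    expect_identical(out$values[, sid], atl$values[, sid])
  }
  # equidistant donors at +/- 50 d: the younger donor wins
  atl2 <- regions_atlas(
    list(A = c("AMY", "STR"), B = req, C = req),
    ages = c(A = 100, B = 50, C = 150))
  out2 <- suppressMessages(impute_missing(atl2, cfg))
  expect_identical(unname(out2$values[, "A_HIP"]), unname(atl2$values[, "B_HIP"]))
  # no missing regions -> identity, zero flags
  atl3 <- regions_atlas(list(A = req, B = req))
  out3 <- impute_missing(atl3, cfg)
  expect_equal(sum(out3$samples$imputed), 0)
  expect_identical(out3$values[, order(colnames(out3$values))],
                   atl3$values[, order(colnames(atl3$values))])
  # a region absent from every donor cannot be imputed
  atl4 <- regions_atlas(list(A = c("AMY", "HIP"), B = c("AMY", "HIP")))
  expect_error(impute_missing(atl4, cfg), "STR")
})

test_that("gene filter keeps genes reaching the RPKM floor and is idempotent", {
  values <- rbind(LOW = rep(4.9, 4), EDGE = c(5, 0, 0, 0),
                  HIGH = c(10, 20, 30, 40))
  atl <- tiny_atlas(values, ages = c(10, 20), scale = "rpkm")
  out <- suppressMessages(filter_genes(atl, preprocess_config()))
  expect_setequal(out$genes, c("EDGE", "HIGH"))
  out2 <- suppressMessages(filter_genes(out, preprocess_config()))
  expect_identical(out2$values, out$values)
  # vacuous threshold keeps everything
  out0 <- suppressMessages(filter_genes(atl, preprocess_config(min_rpkm = 0)))
  expect_length(out0$genes, 3)
  expect_error(
    suppressMessages(filter_genes(atl, preprocess_config(min_rpkm = 1e6))),
    "no gene")
})

test_that("quantile normalization equalizes sample distributions", {
  atl <- tiny_atlas(rbind(c(1, 4), c(2, 5), c(3, 6)), ages = c(10, 20),
                    scale = "rpkm")
  out <- quantile_normalize(atl)
  expect_equal(unname(out$values), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  expect_identical(out$scale, "quantile_norm")
  # random continuous matrix: all sorted columns become identical, exactly
  set.seed(3)
  atl2 <- tiny_atlas(matrix(stats::rexp(200, 1 / 50), 20), ages = 1:10,
                     regions = "R1", scale = "rpkm")
  qn <- quantile_normalize(atl2)
  sorted <- apply(qn$values, 2, sort)
  expect_true(all(sorted == sorted[, 1]))
  # idempotence and fixed point on already-identical samples
  qn_again <- qn
  qn_again$scale <- "rpkm"
  qn2 <- quantile_normalize(qn_again)
  expect_equal(qn2$values, qn$values)
  one <- tiny_atlas(matrix(1:3, 3, 1), ages = 1, scale = "rpkm")
  expect_error(quantile_normalize(one), "2 samples")
})

test_that("log transform applies log2(x + offset) and guards its domain", {
  atl <- tiny_atlas(rbind(c(3, 0), c(1, 7)), ages = c(10, 20), scale = "rpkm")
  atl$scale <- "quantile_norm"
  out <- log_transform(atl, preprocess_config())
  expect_equal(unname(out$values), rbind(c(2, 0), c(1, 3)))
  expect_identical(out$scale, "log2")
  expect_error(log_transform(out), "quantile_norm")
  neg <- atl; neg$values[1] <- -1
  expect_error(log_transform(neg, preprocess_config()), "negative")
})

test_that("stage assignment follows the half-open interval convention", {
  sm <- default_stage_map()
  expect_equal(nrow(sm), 7)
  expect_equal(stage_of_age(-224, sm), 1L)
  expect_equal(stage_of_age(sm$lo, sm), 1:7)     # lo boundary is inclusive
  expect_equal(stage_of_age(sm$hi[1] - 1e-9, sm), 1L)
  atl <- tiny_atlas(matrix(1:4, 2), ages = c(-224, 730))
  staged <- assign_stages(atl, sm)
  expect_equal(staged$samples$stage, c(1L, 4L))
  old <- tiny_atlas(matrix(1:4, 2), ages = c(100, 99 * 365))
  expect_error(assign_stages(old, sm), "d2")
})

test_that("stage maps load from YAML and reject overlapping intervals", {
  path <- withr::local_tempfile(lines = c(
    "stages:",
    "  - {label: fetal, lo: -224, hi: 0}",
    "  - {label: postnatal, lo: 0, hi: 18250}"))
  sm <- read_stage_map(path)
  expect_equal(sm$stage, 1:2)
  expect_equal(sm$hi, c(0, 18250))
  bad <- withr::local_tempfile(lines = c(
    "stages:",
    "  - {label: a, lo: 0, hi: 10}",
    "  - {label: b, lo: 5, hi: 20}"))
  expect_error(read_stage_map(bad), "overlap")
})

test_that("full pipeline completes the sample grid and ends on log2 scale", {
  sim <- sim_default()
  pre <- sim$pre
  expect_identical(pre$scale, "log2")
  expect_equal(nrow(pre$samples), 30 * 16)
  expect_equal(length(unique(pre$samples$donor_id)), 30)
  expect_false(anyNA(pre$samples$stage))
  # per-donor stage consistency
  by_donor <- tapply(pre$samples$stage, pre$samples$donor_id,
                     function(s) length(unique(s)))
  expect_true(all(by_donor == 1))
})
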