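test_that("age parsing maps PCW, months and years onto one signed-day axis", {
  expect_equal(parse_age_days("8 pcw"), (8 - 40) * 7)   # -224, prenatal
  expect_equal(parse_age_days("40 pcw"), 0)
  expect_equal(parse_age_days("2 yrs"), 730)
  expect_equal(parse_age_days("6 mos"), 182.5)
  expect_equal(parse_age_days(100), 100)
  # monotone within each unit
  pcw <- parse_age_days(paste(8:38, "pcw"))
  expect_true(all(diff(pcw) > 0))
  yrs <- parse_age_days(paste(1:40, "yrs"))
  expect_true(all(diff(yrs) > 0))
  expect_lt(max(pcw), min(yrs))
  expect_error(parse_age_days("eleventy", sample_id = "s9"), "s9")
})

test_that("three-file atlas round-trips values and metadata", {
  values <- matrix(c(1.5, 2, 3, 4.25, 5, 6, 7, 8, 9.125, 10, 11, 12), 3, 4)
  samples <- data.frame(
    sample_id = paste0("s", 1:4),
    donor_id = c("d1", "d1", "d2", "d2"),
    age = c(-224, -224, 730, 730), sex = c("M", "M", "F", "F"),
    region = c("AMY", "HIP", "AMY", "HIP"), stringsAsFactors = FALSE)
  atlas <- expression_atlas(values, samples, genes = c("FMR1", "MECP2", "TSC1"))
  dir <- withr::local_tempdir()
  write_atlas(atlas, dir)
  back <- read_atlas(file.path(dir, "expression_matrix.csv"),
                     file.path(dir, "columns_metadata.csv"),
                     file.path(dir, "rows_metadata.csv"))
  expect_equal(back$genes, atlas$genes)
  expect_equal(back$values, atlas$values, tolerance = 1e-6)
  expect_identical(back$samples$donor_id, atlas$samples$donor_id)
  expect_identical(back$samples$region, atlas$samples$region)
  expect_equal(back$samples$age, atlas$samples$age)
  expect_identical(back$scale, "rpkm")
})

test_that("textual BrainSpan-style ages are converted on read", {
  dir <- withr::local_tempdir()
  writeLines(c("donor_id,age,gender,structure_acronym",
               "donor1,8 pcw,M,AMY", "donor2,2 yrs,F,AMY"),
             file.path(dir, "columns_metadata.csv"))
  writeLines(c("1,1.0,2.0", "2,3.0,4.0"),
             file.path(dir, "expression_matrix.csv"))
  writeLines(c("row_num,gene_symbol", "1,FMR1", "2,MECP2"),
             file.path(dir, "rows_metadata.csv"))
  atlas <- read_atlas(file.path(dir, "expression_matrix.csv"),
                      file.path(dir, "columns_metadata.csv"),
                      file.path(dir, "rows_metadata.csv"))
  expect_equal(atlas$samples$age, c(-224, 730))
  expect_identical(atlas$samples$sex, c("M", "F"))
})

test_that("dimension mismatches raise errors naming the offending file", {
  dir <- withr::local_tempdir()
  writeLines(c("donor_id,age,sex,region", "d1,100,M,AMY", "d1,100,M,HIP"),
             file.path(dir, "columns_metadata.csv"))
  writeLines(c("1,1.0,2.0", "2,3.0,4.0", "3,5.0,6.0"),
             file.path(dir, "expression_matrix.csv"))
  writeLines(c("row_num,gene_symbol", "1,A", "2,B", "3,C", "4,D"),
             file.path(dir, "rows_metadata.csv"))
  expect_error(
    read_atlas(file.path(dir, "expression_matrix.csv"),
               file.path(dir, "columns_metadata.csv"),
               file.path(dir, "rows_metadata.csv")),
    "rows_metadata.csv")
})

test_that("gene lists deduplicate, upper-case, and reject empty files", {
  path <- withr::local_tempfile(lines = c("FMR1", "Mecp2", "FMR1", ""))
  expect_message(gs <- read_gene_set(path, "asd"), "1 duplicate")
  expect_setequal(gs$genes, c("FMR1", "MECP2"))
  expect_identical(gs$name, "asd")
  empty <- withr::local_tempfile(lines = character())
  expect_error(read_gene_set(empty), "empty")
})

test_that("GMT lines parse into named gene sets", {
  path <- withr::local_tempfile(
    lines = c("setA\tdesc\tG1\tG2", "setB\tother\tG3\tG4\tG5"))
  sets <- read_gmt(path)
  expect_named(sets, c("setA", "setB"))
  expect_setequal(sets$setA$genes, c("G1", "G2"))
  expect_length(sets$setB, 3)
  bad <- withr::local_tempfile(lines = "lonely")
  expect_error(read_gmt(bad), "malformed")
})

test_that("tables write as TSV with headers, including degenerate inputs", {
  path <- withr::local_tempfile()
  write_table(data.frame(module = 1:2, p = c(0.123456789, 1e-7)), path)
  lines <- readLines(path)
  expect_length(lines, 3)
  expect_identical(lines[1], "module\tp")
  expect_identical(lines[2], "1\t0.123457")  # 6 significant digits
  empty <- data.frame(module = integer(), gene = character(),
                      degree = integer())
  path2 <- withr::local_tempfile()
  write_table(empty, path2)
  expect_length(readLines(path2), 1)  # header only
})

test_that("pair-trajectory matrices survive a write/read cycle", {
  sim <- sim_default()
  g <- sim$truth$genes$gene[sim$truth$genes$pair_module %in% 1][1:8]
  traj <- stage_pair_trajectories(sim$pre, g)
  path <- withr::local_tempfile()
  write_trajectories(traj, path)
  back <- read_trajectories(path)
  expect_identical(back$pairs$gene_a, traj$pairs$gene_a)
  expect_identical(back$pairs$gene_b, traj$pairs$gene_b)
  expect_equal(back$rho, traj$rho, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$n_donors_used, traj$n_donors_used, ignore_attr = TRUE)
})
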