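test_that("platform weights are proportional to sample size within a level", {
  expect_equal(platform_weights(c(600, 400, 200)), c(0.5, 1/3, 1/6))
  expect_equal(platform_weights(30), 1)
  expect_equal(platform_weights(c(50, 50)), c(0.5, 0.5))
  expect_equal(platform_weights(c(600, 200)), c(0.75, 0.25))
  expect_error(platform_weights(numeric(0)), "no sample sizes")
  expect_error(platform_weights(c(10, 0)), ">= 1")
})

test_that("feature normalization centers and scales with the sample-sd convention", {
  X <- cbind(a = c(1, 2, 3), b = c(2, 0, 1))
  Z <- normalize_features(X)
  expect_equal(unname(Z[, "a"]), c(-1, 0, 1))  # sample sd of (1,2,3) is 1
  expect_equal(colMeans(Z), c(a = 0, b = 0))
  expect_equal(apply(Z, 2, sd), c(a = 1, b = 1))
  # idempotence
  Z2 <- normalize_features(Z)
  expect_lt(max(abs(Z2 - Z)), 1e-12)
  # constant column rejected by name
  expect_error(normalize_features(cbind(ok = 1:3, flat = rep(2, 3))), "flat")
  expect_error(normalize_features(cbind(z = rep(0, 4))), "constant")
})

test_that("omics_dataset validates its invariants", {
  X <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("f", 1:4)))
  ds <- omics_dataset(X, rnorm(5), "d1", "snp")
  expect_equal(ds$n, 5)
  expect_equal(ds$d, 4)
  expect_lt(max(abs(colMeans(ds$X))), 1e-12)
  expect_error(omics_dataset(X, rnorm(4), "d1", "snp"), "length\\(Y\\)")
  X2 <- X; X2[1, 1] <- NA
  expect_error(omics_dataset(X2, rnorm(5), "d1", "snp"), "missing values")
  colnames(X2) <- c("f1", "f1", "f3", "f4")
  expect_error(omics_dataset(X, rnorm(5), "d1", "snp",
                             feature_ids = c("a", "a", "b", "c")), "duplicate")
})

test_that("study_collection computes level structure and delta weights", {
  mk <- function(id, level, n, d = 3) {
    X <- matrix(rnorm(n * d), n, d,
                dimnames = list(NULL, paste0(id, "_f", 1:d)))
    omics_dataset(X, rnorm(n), id, level)
  }
  coll <- study_collection(list(mk("s1", "snp", 600), mk("s2", "snp", 400),
                                mk("s3", "snp", 200), mk("e1", "expr", 70),
                                mk("e2", "expr", 50), mk("e3", "expr", 30)))
  expect_equal(coll$T, 6)
  expect_equal(coll$K, 2)
  expect_equal(coll$delta[1:3], c(0.5, 1/3, 1/6))
  for (k in seq_len(coll$K))
    expect_equal(sum(coll$delta[coll$level_index == k]), 1, tolerance = 1e-12)
  expect_equal(coll$omega, rep(1, 6))
  # degenerate single-dataset collection
  solo <- study_collection(list(mk("only", "snp", 25)))
  expect_equal(solo$T, 1)
  expect_equal(solo$K, 1)
  expect_equal(solo$delta, 1)
  expect_equal(solo$omega, 1)
  # omega override must cover every level
  expect_error(study_collection(list(mk("a", "snp", 10)), omega = c(expr = 1)),
               "every level")
})

test_that("gene index is a covering, non-overlapping partition", {
  rc <- rand_collection(seed = 4, Tn = 3, Q = 6)
  idx <- rc$groups
  total <- sum(vapply(rc$collection$datasets, `[[`, 0L, "d"))
  expect_equal(idx$dim, total)
  expect_equal(sum(lengths(idx$slices)), total)
  expect_equal(sort(unlist(idx$slices, use.names = FALSE)), seq_len(total))
  expect_equal(length(idx$gene_ids), idx$Q)
  # membership positions match the stacked slices
  for (q in seq_len(idx$Q)) {
    rebuilt <- unlist(lapply(seq_along(idx$task_dims), function(i)
      idx$task_offsets[i] + idx$membership[[q]][[i]]), use.names = FALSE)
    expect_equal(sort(unname(rebuilt)), sort(unname(idx$slices[[q]])))
  }
})

test_that("gene index rejects unannotated features and duplicate annotation rows", {
  rc <- rand_collection(seed = 5, Tn = 2)
  ann <- collection_annotation(rc$collection, rc$groups)
  expect_error(build_gene_index(rc$collection, ann[-1, ]), "missing from annotation")
  expect_error(build_gene_index(rc$collection, rbind(ann, ann[1, ])),
               "duplicate")
})

test_that("write/load round-trip is the identity on matrices and structure", {
  rc <- rand_collection(seed = 6, Tn = 3)
  dir <- withr::local_tempdir()
  write_study_collection(rc$collection, rc$groups, dir)
  re <- load_study_collection(file.path(dir, "manifest.yaml"),
                              file.path(dir, "annotation.tsv"))
  expect_equal(re$collection$T, rc$collection$T)
  expect_equal(re$collection$delta, rc$collection$delta)
  expect_equal(re$groups$stacked, rc$groups$stacked)
  for (i in seq_along(rc$collection$datasets)) {
    a <- rc$collection$datasets[[i]]; b <- re$collection$datasets[[i]]
    expect_lt(max(abs(a$X - b$X)), 1e-12)
    expect_lt(max(abs(a$Y - b$Y)), 1e-12)
  }
})

test_that("loader drops unannotated features with a warning and fails on missing files", {
  rc <- rand_collection(seed = 7, Tn = 2)
  dir <- withr::local_tempdir()
  write_study_collection(rc$collection, rc$groups, dir)
  ann <- read.delim(file.path(dir, "annotation.tsv"))
  write.table(ann[-1, ], file.path(dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_warning(
    re <- load_study_collection(file.path(dir, "manifest.yaml"),
                                file.path(dir, "annotation.tsv")),
    "unannotated")
  expect_equal(re$collection$datasets[[1]]$d,
               rc$collection$datasets[[1]]$d - 1L)
  expect_error(load_study_collection(file.path(dir, "nope.yaml"),
                                     file.path(dir, "annotation.tsv")),
               "not found")
})

test_that("level subsetting keeps the right tasks and rebuilds the gene index", {
  sim <- build_scenario_collection(tiny_scenario(), seed = 2)
  sub <- subset_collection(sim$collection, sim$groups, "expression")
  expect_equal(sub$collection$T, 2)
  expect_true(all(vapply(sub$collection$datasets, `[[`, "", "level") ==
                    "expression"))
  expect_equal(sub$groups$Q, sim$groups$Q)  # every gene has expression
  expect_equal(sum(sub$collection$delta), 1)
  expect_error(subset_collection(sim$collection, sim$groups, "proteome"),
               "no dataset")
})

test_that("stacked coefficient vector splits into per-task views", {
  rc <- rand_collection(seed = 8, Tn = 3)
  C <- rnorm(rc$groups$dim)
  blocks <- split_tasks(C, rc$groups)
  expect_equal(lengths(blocks), unname(rc$groups$task_dims))
  expect_equal(unlist(blocks), C)
})
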