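test_that("data splits form a disjoint 60/20/20 cover, deterministically", {
  tab <- planted_table(100, seed = 3)
  sp <- split_data(tab, seed = 5)
  expect_equal(nrow(sp$train), 60)
  expect_equal(nrow(sp$validation), 20)
  expect_equal(nrow(sp$test), 20)
  all_rows <- rbind(sp$train, sp$validation, sp$test)
  expect_equal(nrow(all_rows), 100)
  expect_equal(sort(as.integer(rownames(all_rows))),
               sort(as.integer(rownames(tab))))
  sp2 <- split_data(tab, seed = 5)
  expect_identical(lapply(sp, rownames), lapply(sp2, rownames))
  sp3 <- split_data(tab, seed = 6)
  expect_false(identical(rownames(sp$train), rownames(sp3$train)))
})

test_that("test-set balancing equalizes the two classes", {
  tab <- planted_table(200, seed = 4)
  sp <- split_data(tab, seed = 2, balance_test = "unstable")
  cls <- table(sp$test$unstable)
  expect_equal(unname(cls[1]), unname(cls[2]))
})

test_that("group-aware splits never straddle an alignment", {
  tab <- planted_table(200, seed = 9)
  sp <- split_data(tab, seed = 2, group = "alignment")
  groups <- lapply(sp, function(d) unique(d$alignment))
  expect_length(intersect(groups$train, groups$test), 0)
  expect_length(intersect(groups$train, groups$validation), 0)
  expect_length(intersect(groups$validation, groups$test), 0)
})

test_that("balanced batches satisfy the without-replacement contract", {
  labels <- c(rep(1, 10), rep(0, 72))
  batches <- balanced_batches(labels, seed = 1)
  expect_length(batches, 7L)
  expect_true(all(lengths(batches) == 20L))
  minority <- which(labels == 1)
  majority_used <- lapply(batches, setdiff, y = minority)
  for (b in batches) expect_true(all(minority %in% b))
  expect_equal(anyDuplicated(unlist(majority_used)), 0L)
  even <- balanced_batches(rep(c(0, 1), each = 15), seed = 1)
  expect_length(even, 1L)
  expect_length(even[[1]], 30L)
  expect_error(balanced_batches(rep(1, 10)), "nonempty")
})

test_that("sampled hyperparameters stay inside the declared bounds", {
  space <- hyperparam_space("classify_tii")
  expect_equal(space$trials, 200L)
  set.seed(8)
  for (i in 1:50) {
    hp <- taxonstab:::sample_hyperparams(space)
    expect_true(hp$n_trees >= 10 && hp$n_trees <= 1000)
    expect_true(hp$max_depth >= 10 && hp$max_depth <= 1000)
    expect_true(hp$min_split_fraction >= 1e-5 && hp$min_split_fraction <= 1)
    expect_true(hp$min_leaf_fraction >= 1e-5 && hp$min_leaf_fraction <= 1)
    expect_true(hp$max_features %in% c("all", "log2"))
    expect_true(hp$criterion %in% space$criterion)
  }
})

test_that("tuned ensembles learn a planted rule and predict consistently", {
  tab <- planted_table(300, seed = 11)
  ## force several balanced batches by thinning the positive class
  pos <- which(tab$unstable == 1)
  drop <- pos[-seq_len(floor(length(pos) / 3))]
  tab <- tab[setdiff(seq_len(nrow(tab)), drop), , drop = FALSE]
  mod <- tune_and_train(tab, "classify_tii",
                        space = hyperparam_space("classify_tii",
                                                 trials = 15),
                        seed = 3)
  expect_gt(length(mod$batches), 1L)
  for (b in mod$batches) {
    lab <- mod$splits$train$unstable[b]
    expect_equal(sum(lab == 1), sum(lab == 0))
  }
  expect_gt(mod$test_score, 0.8)
  pr <- ensemble_predict(mod, mod$splits$test)
  expect_length(pr$labels, nrow(mod$splits$test))
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  ## averaged probability equals the mean of per-forest probabilities
  per_forest <- vapply(mod$forests, function(f) {
    stats::predict(f, data = mod$splits$test[, mod$features, drop = FALSE],
                   num.threads = 1)$predictions[, "1"]
  }, numeric(nrow(mod$splits$test)))
  expect_equal(pr$prob, rowMeans(per_forest), tolerance = 1e-12)
  ## single-batch ensemble equals its one forest
  one <- mod
  one$forests <- mod$forests[1]
  pr1 <- ensemble_predict(one, mod$splits$test)
  expect_equal(pr1$prob, per_forest[, 1], tolerance = 1e-12)
  expect_equal(pr1$labels, as.integer(per_forest[, 1] >= 0.5))
})

test_that("rows with missing mandatory features are skipped on predict", {
  tab <- planted_table(120, seed = 13)
  mod <- tune_and_train(tab, "classify_tii",
                        space = hyperparam_space("classify_tii",
                                                 trials = 5),
                        seed = 2)
  rows <- mod$splits$test
  rows$lwr[1] <- NA
  pr <- suppressMessages(ensemble_predict(mod, rows))
  expect_equal(pr$skipped, 1L)
  expect_length(pr$labels, nrow(rows) - 1L)
})

test_that("regression ensembles average predictions and score with R2", {
  tab <- planted_table(200, seed = 17)
  tab$tii_norm <- pmin(1, pmax(0, 0.6 * tab$distance_ratio_sd +
                                 0.3 * (1 - tab$dist_low_bootstrap_edge) +
                                 rnorm(nrow(tab), 0, 0.02)))
  mod <- tune_and_train(tab, "regress_tii",
                        space = hyperparam_space("regress_tii",
                                                 trials = 15),
                        seed = 4)
  expect_gt(mod$test_score, 0.5)
  pr <- ensemble_predict(mod, mod$splits$test)
  expect_length(pr$predictions, nrow(mod$splits$test))
})

test_that("permutation importances are normalized, seeded, and ignore noise", {
  tab <- planted_table(300, seed = 19)
  mod <- tune_and_train(tab, "classify_tii",
                        space = hyperparam_space("classify_tii",
                                                 trials = 10),
                        seed = 5)
  imp <- feature_importances(mod, seed = 2)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_true(all(imp >= 0))
  expect_identical(imp, feature_importances(mod, seed = 2))
  ## a pure-noise feature should sit below the median importance
  below_median <- 0L
  for (seed in 1:5) {
    tabn <- planted_table(300, seed = 20 + seed)
    tabn$nj_tii <- runif(nrow(tabn))   # overwrite with target-free noise
    m <- tune_and_train(tabn, "classify_tii",
                        space = hyperparam_space("classify_tii",
                                                 trials = 5),
                        seed = seed)
    im <- feature_importances(m, seed = seed)
    below_median <- below_median +
      (im["nj_tii"] <= stats::median(im))
  }
  expect_gte(below_median, 4L)
})
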