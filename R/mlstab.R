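## Random-forest prediction of stability: class-balanced batched
## ensembles for classification (TII zero vs non-zero; significant
## instability) and single-forest models for regression (normalized TII;
## disruption radius), with randomized hyperparameter search, majority
## voting / averaged probabilities, and permutation feature importances.

feature_columns <- c(
  "insertion_dist_mean", "insertion_dist_sd", "lwr",
  "n_insertion_locations", "insertion_branch_length",
  "norm_dist_nearest_node", "pendant_length", "dist_low_bootstrap_edge",
  "bootstrap_mean", "bootstrap_sd", "distance_ratio_mean",
  "distance_ratio_sd", "ratio_diff_closest_mean", "ratio_diff_closest_sd",
  "dist_diff_insertion_sibling", "insertion_height", "nj_tii",
  "pythia_difficulty"
)

task_target <- function(task) {
  switch(task,
         classify_tii = "unstable",
         classify_significant = "significant",
         regress_tii = "tii_norm",
         regress_radius = "disruption_radius",
         stop("unknown task: ", task))
}

is_classification <- function(task) startsWith(task, "classify")

#' Hyperparameter search space for the stability forests
#'
#' Number of trees in `[10, 1000]`; maximum depth in `[10, 1000]` and the
#' minimum samples-per-split and samples-per-leaf fractions in
#' `[1e-5, 1]`, all three sampled from the log domain; the number of
#' features considered per split is either all features or `log2` of
#' them. Split criteria are drawn from the sets the ranger backend
#' offers: `gini`/`extratrees` for classification and
#' `variance`/`extratrees`/`maxstat` for regression.
#'
#' @param task one of `classify_tii`, `classify_significant`,
#'   `regress_tii`, `regress_radius`.
#' @param trials number of hyperparameter-search trials (default 200).
#' @return a `hyperparam_space` list.
#' @export
hyperparam_space <- function(task, trials = 200L) {
  structure(list(
    task = task,
    n_trees = c(10L, 1000L),
    max_depth = c(10L, 1000L),
    min_split_fraction = c(1e-5, 1),
    min_leaf_fraction = c(1e-5, 1),
    max_features = c("all", "log2"),
    criterion = if (is_classification(task)) c("gini", "extratrees")
                else c("variance", "extratrees", "maxstat"),
    trials = as.integer(trials)
  ), class = "hyperparam_space")
}

## one random configuration from the space (log-domain where declared)
sample_hyperparams <- function(space) {
  loguni <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  list(
    n_trees = as.integer(round(runif(1, space$n_trees[1], space$n_trees[2]))),
    max_depth = as.integer(round(loguni(space$max_depth[1],
                                        space$max_depth[2]))),
    min_split_fraction = loguni(space$min_split_fraction[1],
                                space$min_split_fraction[2]),
    min_leaf_fraction = loguni(space$min_leaf_fraction[1],
                               space$min_leaf_fraction[2]),
    max_features = sample(space$max_features, 1),
    criterion = sample(space$criterion, 1)
  )
}

#' Split a labelled table into train/validation/test sets
#'
#' Disjoint 60/20/20 cover (fractions within one row per stratum),
#' deterministic given the seed; when `check_class` is given the split is
#' stratified on that class. With `balance_test`, the larger class of that binary
#' target is randomly subsampled in the test set so both classes have
#' equal size there. With `group`, rows sharing a group key (source
#' alignment) never straddle two sets.
#'
#' @param table labelled feature table (>= 10 rows).
#' @param seed integer seed.
#' @param balance_test optional binary target column to balance the test
#'   set on.
#' @param group optional grouping column name for group-aware splitting.
#' @param check_class optional binary column that must be represented in
#'   every split (error suggesting a different seed otherwise).
#' @return list with `train`, `validation`, `test` data frames.
#' @export
split_data <- function(table, seed = 1L, balance_test = NULL, group = NULL,
                       check_class = balance_test) {
  stopifnot(nrow(table) >= 10L)
  set.seed(seed)
  n <- nrow(table)
  if (is.null(group)) {
    split_idx <- function(idx) {
      idx <- sample(idx)
      k <- length(idx)
      n_train <- round(0.6 * k)
      n_val <- round(0.2 * k)
      list(train = idx[seq_len(n_train)],
           validation = idx[n_train + seq_len(n_val)],
           test = idx[setdiff(seq_len(k), seq_len(n_train + n_val))])
    }
    if (is.null(check_class)) {
      parts <- split_idx(seq_len(n))
    } else {
      ## stratified on the checked class so both classes reach every split
      by_class <- lapply(split(seq_len(n), table[[check_class]]), split_idx)
      parts <- lapply(c(train = "train", validation = "validation",
                        test = "test"),
                      function(p) unlist(lapply(by_class, `[[`, p),
                                         use.names = FALSE))
    }
  } else {
    gs <- sample(unique(table[[group]]))
    sizes <- table(table[[group]])[gs]
    cum <- cumsum(as.numeric(sizes)) / n
    g_assign <- ifelse(cum <= 0.6, "train", ifelse(cum <= 0.8, "validation",
                                                   "test"))
    parts <- lapply(c(train = "train", validation = "validation",
                      test = "test"),
                    function(p) which(table[[group]] %in% gs[g_assign == p]))
  }
  out <- lapply(parts, function(ii) table[ii, , drop = FALSE])
  if (!is.null(check_class)) {
    for (p in names(out)) {
      if (length(unique(out[[p]][[check_class]])) < 2L) {
        stop("class of '", check_class, "' absent from the ", p,
             " split; try a different stratification seed")
      }
    }
  }
  if (!is.null(balance_test)) {
    y <- out$test[[balance_test]]
    tabs <- table(y)
    small <- min(tabs)
    keep <- unlist(lapply(names(tabs), function(lv) {
      ii <- which(y == lv)
      if (length(ii) > small) sample(ii, small) else ii
    }))
    out$test <- out$test[sort(keep), , drop = FALSE]
  }
  out
}

#' Class-balanced training batches
#'
#' `floor(majority/minority)` batches; every batch contains all minority
#' samples plus an equal number of majority samples drawn without
#' replacement across batches (leftover majority samples unused).
#'
#' @param labels binary vector (0/1), both classes nonempty.
#' @param seed integer seed.
#' @return list of integer index vectors into `labels`.
#' @export
balanced_batches <- function(labels, seed = 1L) {
  tab <- table(labels)
  if (length(tab) < 2L || any(tab == 0)) stop("both classes must be nonempty")
  minority_lv <- names(tab)[which.min(tab)]
  minority <- which(labels == minority_lv)
  majority <- which(labels != minority_lv)
  nb <- floor(length(majority) / length(minority))
  set.seed(seed)
  shuffled <- sample(majority)
  lapply(seq_len(nb), function(b) {
    c(minority, shuffled[(b - 1L) * length(minority) + seq_along(minority)])
  })
}

## fit one ranger forest with a sampled configuration
fit_forest <- function(data, task, hp, feats, seed) {
  n <- nrow(data)
  y <- data[[task_target(task)]]
  if (is_classification(task)) y <- factor(y, levels = c(0, 1))
  ranger::ranger(
    x = data[, feats, drop = FALSE], y = y,
    num.trees = hp$n_trees,
    max.depth = hp$max_depth,
    min.node.size = max(2L, ceiling(hp$min_split_fraction * n)),
    min.bucket = max(1L, ceiling(hp$min_leaf_fraction * n)),
    mtry = if (hp$max_features == "all") length(feats)
           else max(1L, floor(log2(length(feats)))),
    splitrule = hp$criterion,
    probability = is_classification(task),
    seed = seed, num.threads = 1
  )
}

ensemble_raw_predict <- function(forests, task, rows, feats) {
  if (is_classification(task)) {
    probs <- vapply(forests, function(f) {
      stats::predict(f, data = rows[, feats, drop = FALSE],
                     num.threads = 1)$predictions[, "1"]
    }, numeric(nrow(rows)))
    probs <- matrix(probs, nrow = nrow(rows))
    votes <- rowSums(probs >= 0.5)
    ## majority vote; ties go to the positive (unstable) class
    labels <- as.integer(votes >= length(forests) / 2)
    list(labels = labels, prob = rowMeans(probs))
  } else {
    preds <- vapply(forests, function(f) {
      stats::predict(f, data = rows[, feats, drop = FALSE],
                     num.threads = 1)$predictions
    }, numeric(nrow(rows)))
    preds <- matrix(preds, nrow = nrow(rows))
    list(predictions = rowMeans(preds))
  }
}

score_rows <- function(forests, task, rows, feats) {
  y <- rows[[task_target(task)]]
  pr <- ensemble_raw_predict(forests, task, rows, feats)
  if (is_classification(task)) {
    if (length(unique(y)) < 2L) return(NA_real_)
    as.numeric(pROC::auc(response = y, predictor = pr$prob,
                         levels = c(0, 1), direction = "<", quiet = TRUE))
  } else {
    1 - sum((y - pr$predictions)^2) / sum((y - mean(y))^2)
  }
}

#' Tune and train a class-balanced stability forest ensemble
#'
#' Randomized search (`trials` draws from [hyperparam_space()]) maximizing
#' validation AUROC (classification) or R-squared (regression); the final
#' ensemble is retrained on the training batches with the best
#' configuration and evaluated on the held-out test set. For
#' `classify_tii` the training set is split into class-balanced batches
#' (one forest per batch) and the test set is class-balanced by
#' subsampling; `classify_significant` and the regressions use a single
#' forest on the full training set.
#'
#' @param table labelled feature table (needs the target columns
#'   `unstable`, `significant`, `tii_norm`, `disruption_radius` and an
#'   `alignment` group key).
#' @param task one of `classify_tii`, `classify_significant`,
#'   `regress_tii`, `regress_radius`.
#' @param space a [hyperparam_space] (defaults to the task's space).
#' @param feature_config `"full"`, `"no_difficulty"` (drops the Pythia
#'   difficulty), or `"no_difficulty_no_bootstrap"` (also drops bootstrap
#'   mean/SD).
#' @param seed integer seed; fixes the split, search and forests.
#' @param group_aware split by source alignment instead of by row.
#' @return a `balanced_ensemble` object with fitted forests, batch
#'   composition, splits, best configuration and validation/test scores.
#' @export
tune_and_train <- function(table, task, space = hyperparam_space(task),
                           feature_config = c("full", "no_difficulty",
                                              "no_difficulty_no_bootstrap"),
                           seed = 1L, group_aware = FALSE) {
  feature_config <- match.arg(feature_config)
  feats <- feature_columns
  if (feature_config != "full") feats <- setdiff(feats, "pythia_difficulty")
  if (feature_config == "no_difficulty_no_bootstrap") {
    feats <- setdiff(feats, c("bootstrap_mean", "bootstrap_sd"))
  }
  feats <- intersect(feats, colnames(table))
  ## drop entirely-missing feature columns, then incomplete rows
  feats <- feats[vapply(feats, function(f) !all(is.na(table[[f]])),
                        logical(1))]
  target <- task_target(task)
  keep <- stats::complete.cases(table[, c(feats, target)])
  if (any(!keep)) {
    message(sum(!keep), " row(s) with missing values skipped")
  }
  table <- table[keep, , drop = FALSE]

  balance <- task == "classify_tii"
  splits <- split_data(table, seed = seed,
                       balance_test = if (balance) target,
                       group = if (group_aware) "alignment",
                       check_class = if (is_classification(task)) target)
  batches <- if (balance) {
    balanced_batches(splits$train[[target]], seed = seed)
  } else {
    list(seq_len(nrow(splits$train)))
  }

  set.seed(seed)
  best <- NULL
  best_score <- -Inf
  trial_log <- character(0)
  for (trial in seq_len(space$trials)) {
    hp <- sample_hyperparams(space)
    forests <- tryCatch(
      lapply(seq_along(batches), function(b) {
        fit_forest(splits$train[batches[[b]], , drop = FALSE], task, hp,
                   feats, seed = seed + 1000L * trial + b)
      }),
      error = function(e) conditionMessage(e))
    if (is.character(forests)) {
      trial_log <- c(trial_log, paste0("trial ", trial, ": ", forests))
      next
    }
    sc <- score_rows(forests, task, splits$validation, feats)
    if (!is.na(sc) && sc > best_score) {
      best_score <- sc
      best <- hp
    }
  }
  if (is.null(best)) {
    stop("all hyperparameter trials failed:\n",
         paste(trial_log, collapse = "\n"))
  }
  forests <- lapply(seq_along(batches), function(b) {
    fit_forest(splits$train[batches[[b]], , drop = FALSE], task, best,
               feats, seed = seed + b)
  })
  model <- structure(list(
    forests = forests, task = task, features = feats,
    feature_config = feature_config, batches = batches,
    best_params = best, validation_score = best_score,
    splits = splits, seed = seed
  ), class = "balanced_ensemble")
  model$test_score <- score_rows(forests, task, splits$test, feats)
  model
}

#' Predict with a balanced ensemble
#'
#' Classification: per-forest class votes with majority rule (ties to
#' the positive, unstable class) and probabilities averaged across
#' forests; regression: mean prediction across forests. Rows with
#' missing mandatory features are skipped (reported in `skipped`).
#'
#' @param model a `balanced_ensemble`.
#' @param rows data frame with the training feature columns.
#' @return list with `labels` and `prob` (classification) or
#'   `predictions` (regression), plus `kept`/`skipped` row indices.
#' @export
ensemble_predict <- function(model, rows) {
  ok <- stats::complete.cases(rows[, model$features, drop = FALSE])
  if (any(!ok)) {
    message(sum(!ok), " row(s) with missing features skipped")
  }
  out <- ensemble_raw_predict(model$forests, model$task,
                              rows[ok, , drop = FALSE], model$features)
  out$kept <- which(ok)
  out$skipped <- which(!ok)
  out
}

#' Permutation feature importances of a balanced ensemble
#'
#' Per forest, each feature column is shuffled `n_shuffles` times and the
#' mean drop of the forest's test metric (AUROC or R-squared) recorded;
#' importances are averaged across forests, negative values floored at
#' 0, and normalized to sum to one.
#'
#' @param model a `balanced_ensemble`.
#' @param rows evaluation rows (default: the model's test split).
#' @param seed integer seed for the shuffles.
#' @param n_shuffles shuffles per feature (default 10).
#' @return named numeric vector summing to 1.
#' @export
feature_importances <- function(model, rows = model$splits$test, seed = 1L,
                                n_shuffles = 10L) {
  stopifnot(nrow(rows) > 0L)
  feats <- model$features
  rows <- rows[stats::complete.cases(rows[, feats, drop = FALSE]), ,
               drop = FALSE]
  set.seed(seed)
  imp_per_forest <- vapply(model$forests, function(f) {
    base <- score_rows(list(f), model$task, rows, feats)
    vapply(feats, function(fc) {
      drops <- vapply(seq_len(n_shuffles), function(k) {
        shuffled <- rows
        shuffled[[fc]] <- sample(shuffled[[fc]])
        base - score_rows(list(f), model$task, shuffled, feats)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  }, numeric(length(feats)))
  imp <- rowMeans(matrix(imp_per_forest, nrow = length(feats),
                         dimnames = list(feats, NULL)))
  imp[is.na(imp)] <- 0
  imp[imp < 0] <- 0
  if (sum(imp) == 0) return(setNames(rep(1 / length(imp), length(imp)),
                                     feats))
  imp / sum(imp)
}
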