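# small deterministic feature fixture: one separating feature + noise
toy_features <- function(n_per_class = 10, n_noise = 50, seed = 1) {
  set.seed(seed)
  labels <- rep(c("A", "B"), each = n_per_class)
  sep <- c(rnorm(n_per_class, 0, 0.3), rnorm(n_per_class, 5, 0.3))
  noise <- matrix(rnorm(2 * n_per_class * n_noise), ncol = n_noise)
  colnames(noise) <- paste0("noise", seq_len(n_noise))
  list(
    features = dplyr::bind_cols(tibble::tibble(sep = sep),
                                tibble::as_tibble(noise)),
    labels = labels
  )
}

test_that("shadow selection keeps the separating feature and drops noise", {
  kept_sep <- 0
  noise_rates <- numeric(0)
  for (seed in 1:5) {
    toy <- toy_features(seed = seed)
    sel <- select_features(toy$features, toy$labels, n_rounds = 10,
                           num_trees = 200, seed = seed)
    if ("sep" %in% sel) kept_sep <- kept_sep + 1
    noise_rates <- c(noise_rates,
                     mean(grepl("^noise", sel)) * length(sel) / 50)
  }
  expect_equal(kept_sep, 5)
  expect_true(all(noise_rates <= 0.1))   # >= 90% of noise features rejected
})

test_that("a duplicated informative feature survives selection", {
  toy <- toy_features(seed = 2)
  toy$features$sep_copy <- toy$features$sep
  sel <- select_features(toy$features, toy$labels, n_rounds = 10,
                         num_trees = 200, seed = 2)
  expect_true(any(c("sep", "sep_copy") %in% sel))
})

test_that("shuffled labels trigger the fallback path", {
  toy <- toy_features(seed = 3)
  set.seed(99)
  shuffled <- sample(toy$labels)
  expect_warning(
    sel <- select_features(toy$features, shuffled, n_rounds = 10,
                           num_trees = 200, seed = 3),
    "falling back"
  )
  expect_true(attr(sel, "fallback"))
  expect_lte(length(sel), 10)
})

test_that("the classifier separates synthetic individuals and is deterministic", {
  pop <- small_pop()
  ft <- call_feature_table(pop)
  f1 <- train_individual_classifier(ft, pop$individual_id, seed = 5)
  f2 <- train_individual_classifier(ft, pop$individual_id, seed = 5)
  expect_gte(f1$accuracy, 95)
  expect_identical(f1$accuracy, f2$accuracy)
  expect_identical(f1$balanced_accuracy, f2$balanced_accuracy)
  expect_true(all(f1$accuracy_ci >= 0 & f1$accuracy_ci <= 100))
  expect_true(all(f1$balanced_accuracy$balanced_accuracy >= 0 &
                    f1$balanced_accuracy$balanced_accuracy <= 100))

  # permuted labels collapse to chance
  set.seed(7)
  perm <- sample(pop$individual_id)
  fp <- train_individual_classifier(ft, perm, seed = 5)
  expect_lt(fp$accuracy, 50)

  expect_error(train_individual_classifier(ft, rep("X", nrow(ft))),
               "at least 2")
  expect_error(
    train_individual_classifier(ft[1:5, ],
                                c("A", "A", "B", "B", "C")[1:5]),
    "at least 2 calls"
  )
})

test_that("proximity equals per-tree leaf co-occurrence bookkeeping", {
  toy <- toy_features(n_per_class = 6, n_noise = 3, seed = 4)
  fit <- train_individual_classifier(toy$features, toy$labels,
                                     num_trees = 3, seed = 9)
  prox <- proximity_matrix(fit, toy$features)
  nodes <- predict(fit$model,
                   data = as.data.frame(toy$features),
                   type = "terminalNodes")$predictions
  # independent bookkeeping: count shared leaves pair by pair
  n <- nrow(nodes)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      expect_equal(unclass(prox)[i, j], mean(nodes[i, ] == nodes[j, ]))
    }
  }
  expect_equal(unname(diag(unclass(prox))), rep(1, n))
})

test_that("identical feature rows have proximity 1", {
  toy <- toy_features(n_per_class = 6, n_noise = 3, seed = 6)
  ft <- dplyr::bind_rows(toy$features, toy$features[1, ])
  fit <- train_individual_classifier(toy$features, toy$labels, seed = 2)
  prox <- proximity_matrix(fit, ft)
  expect_equal(unclass(prox)[1, nrow(ft)], 1)
  # missing features are refused
  expect_error(proximity_matrix(fit, toy$features[, 1:2]), "lacks")
})

test_that("holdout clustering recovers planted individuals and rejects leakage", {
  pop <- small_pop()
  ft <- call_feature_table(pop)
  inds <- unique(pop$individual_id)
  tr <- pop$individual_id %in% inds[1:3]
  fit <- train_individual_classifier(ft[tr, ], pop$individual_id[tr],
                                     seed = 3)
  prox <- proximity_matrix(fit, ft[!tr, ])
  v <- suppressWarnings(
    validate_by_clustering(prox, pop$individual_id[!tr],
                           training_ids = inds[1:3], seed = 3)
  )
  expect_gte(v$ari, 0.5)
  expect_equal(nrow(v$clusters), sum(!tr))
  expect_error(
    validate_by_clustering(prox, pop$individual_id[!tr],
                           training_ids = unique(pop$individual_id[!tr])),
    "overlap"
  )
  expect_error(validate_by_clustering(prox, rep("Z", sum(!tr))),
               "at least 2")
})

test_that("identical holdout calls report ARI 0 with a warning", {
  ids <- paste0("c", 1:6)
  m <- similarity_matrix(matrix(1, 6, 6), method = "RF-proximity",
                         call_ids = ids)
  expect_warning(
    v <- validate_by_clustering(m, rep(c("A", "B"), each = 3)),
    "identical"
  )
  expect_equal(v$ari, 0)
  expect_equal(v$n_components, 1L)
})

test_that("shuffled holdout labels give near-zero ARI", {
  pop <- small_pop()
  ft <- call_feature_table(pop)
  inds <- unique(pop$individual_id)
  tr <- pop$individual_id %in% inds[1:3]
  fit <- train_individual_classifier(ft[tr, ], pop$individual_id[tr],
                                     seed = 3)
  prox <- proximity_matrix(fit, ft[!tr, ])
  set.seed(10)
  aris <- replicate(20, {
    suppressWarnings(
      validate_by_clustering(prox, sample(pop$individual_id[!tr]),
                             seed = 3)$ari
    )
  })
  expect_lt(abs(mean(aris)), 0.15)
})
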