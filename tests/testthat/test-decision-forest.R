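test_that("best_split finds the entropy-optimal midpoint threshold", {
  s <- best_split(c(1, 2, 3, 4), c(0, 0, 1, 1), min_leaf = 1L)
  expect_equal(s$threshold, 2.5)
  expect_equal(s$gain, 1)  # pure children from a 50/50 prior: 1 bit

  expect_null(best_split(c(1, 2, 3), c(1, 1, 1)))          # pure labels
  expect_null(best_split(c(2, 2, 2, 2), c(0, 1, 0, 1)))    # no threshold
  expect_null(best_split(c(1, 1, 2, 2), c(0, 1, 0, 1)))    # zero best gain
  # min_leaf leaves only the zero-gain middle threshold admissible
  expect_null(best_split(c(1, 2, 3, 4), c(0, 1, 0, 1), min_leaf = 2L))
  expect_error(best_split(c(1, 2), c(0, 1, 0)), "length")
})

test_that("best_split matches exhaustive enumeration on random instances", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(4:40, 1L)
    vals <- round(stats::rnorm(n), sample(0:2, 1L))  # force ties sometimes
    labs <- stats::rbinom(n, 1L, 0.5)
    ml <- sample(1:3, 1L)
    got <- best_split(vals, labs, min_leaf = ml)
    want <- oracle_best_split(vals, labs, min_leaf = ml)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$gain, want$gain, tolerance = 1e-12)
    }
  }
})

test_that("build_tree grows greedy trees with the expected shape", {
  sep <- make_separable_dataset()
  cfg <- forest_config(min_leaf = 1L)
  tree <- build_tree(sep, config = cfg)
  expect_false(tree$leaf)
  expect_identical(tree$descriptor, "sep")
  expect_true(tree$left$leaf && tree$right$leaf)  # depth-1 suffices
  p <- erbforest:::predict_tree(tree, sep$x)
  expect_equal(mean(classify(p) == as.character(sep$y)), 1)  # train acc 1.0

  one_class <- labeled_dataset(sep$x, rep("binder", nrow(sep$x)))
  leaf <- build_tree(one_class, config = cfg)
  expect_true(leaf$leaf)
  expect_equal(leaf$binder_fraction, 1)

  expect_error(build_tree(sep, pool = character(0)), "pool")
  expect_error(build_tree(sep, pool = "absent"), "absent")
})

test_that("build_tree agrees with a naive reference grower", {
  gen <- generate_dataset(synth_config(
    n_binders = 40L, n_nonbinders = 20L, n_descriptors = 8L,
    n_informative = 3L, effect_size = 2, fraction_constant = 0, seed = 5L))
  ds <- gen$dataset
  for (cfg in list(forest_config(min_leaf = 5L),
                   forest_config(min_leaf = 2L, max_depth = 3L),
                   forest_config(min_leaf = 3L, split_alpha = NULL))) {
    got <- build_tree(ds, config = cfg)
    want <- oracle_grow_tree(as.data.frame(ds$x),
                             as.integer(ds$y == "binder"),
                             colnames(ds$x), cfg$min_leaf, cfg$max_depth,
                             cfg$split_alpha)
    expect_equal(got, want)
  }
})

test_that("train_forest keeps descriptor sets disjoint and consensus sound", {
  ds <- make_signal_dataset()
  model <- train_forest(ds, forest_config(max_trees = 5L, min_leaf = 2L))
  expect_s3_class(model, "decision_forest")
  expect_gte(length(model$trees), 1L)
  sets <- model$descriptor_sets
  if (length(sets) > 1L)
    for (i in seq_along(sets)[-1])
      for (j in seq_len(i - 1L))
        expect_length(intersect(sets[[i]], sets[[j]]), 0L)
  # consensus training balanced accuracy never falls below the first tree
  expect_true(all(diff(model$training_balanced_accuracy) >= 0))
  expect_gte(model$training_balanced_accuracy[length(model$trees)],
             model$training_balanced_accuracy[1L])

  single <- train_forest(ds, forest_config(max_trees = 1L, min_leaf = 2L))
  expect_equal(single$trees[[1L]],
               build_tree(ds, config = forest_config(max_trees = 1L,
                                                     min_leaf = 2L)))

  one_class <- labeled_dataset(ds$x, rep("binder", nrow(ds$x)))
  expect_error(train_forest(one_class), "both classes")
})

test_that("training is deterministic for identical inputs", {
  ds <- make_signal_dataset()
  m1 <- train_forest(ds)
  m2 <- train_forest(ds)
  expect_identical(m1, m2)
})

test_that("consensus probability is the unweighted mean of leaf fractions", {
  leaf_tree <- function(f) list(leaf = TRUE, binder_fraction = f,
                                n_train = 10L)
  model <- structure(
    list(trees = list(leaf_tree(1), leaf_tree(0.5)),
         descriptor_sets = list(character(0), character(0)),
         config = forest_config(), kept_names = c("D1", "D2"),
         n_train = 10L, class_counts = c(binder = 8L, non_binder = 2L),
         training_balanced_accuracy = c(0.5, 0.5)),
    class = "decision_forest")
  x <- matrix(stats::rnorm(4), 2L, 2L,
              dimnames = list(c("a", "b"), c("D1", "D2")))
  expect_equal(predict(model, x, type = "prob"), c(a = 0.75, b = 0.75),
               ignore_attr = TRUE)
  full <- predict(model, x, type = "full")
  expect_identical(full$label, c("binder", "binder"))
  expect_equal(full$confidence, c(0.5, 0.5))

  model$trees <- list(leaf_tree(0))
  expect_equal(unname(predict(model, x, type = "prob")), c(0, 0))

  expect_error(predict(model, x[, "D1", drop = FALSE]), "D2")

  # mean is bounded by the per-tree extremes
  ds <- make_signal_dataset()
  m <- train_forest(ds, forest_config(min_leaf = 2L))
  per_tree <- vapply(m$trees, erbforest:::predict_tree, numeric(nrow(ds$x)),
                     x = ds$x)
  per_tree <- matrix(per_tree, nrow = nrow(ds$x))
  p <- predict(m, ds$x, type = "prob")
  expect_true(all(p >= apply(per_tree, 1L, min) - 1e-12))
  expect_true(all(p <= apply(per_tree, 1L, max) + 1e-12))
})

test_that("classification boundary is inclusive at P = 0.5", {
  expect_identical(classify(c(0.5, 0.49, 1, 0)),
                   c("binder", "non_binder", "binder", "non_binder"))
  expect_error(classify(1.2), "\\[0, 1\\]")
  expect_error(classify(-0.1), "\\[0, 1\\]")
})
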