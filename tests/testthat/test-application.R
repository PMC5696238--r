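constant_model <- function(fraction, kept = c("D1", "D2")) {
  structure(
    list(trees = list(list(leaf = TRUE, binder_fraction = fraction,
                           n_train = 10L)),
         descriptor_sets = list(character(0)),
         config = forest_config(), kept_names = kept, n_train = 10L,
         class_counts = c(binder = 9L, non_binder = 1L),
         training_balanced_accuracy = 0.5),
    class = "decision_forest")
}

assay_frame <- function(ids, outcomes)
  data.frame(compound_id = ids, outcome = outcomes,
             stringsAsFactors = FALSE)

test_that("an all-binder predictor yields the closed-form metrics", {
  x <- matrix(stats::rnorm(20), 10L, 2L,
              dimnames = list(sprintf("C%02d", 1:10), c("D1", "D2")))
  assay <- assay_frame(rownames(x), rep(c("active", "inactive"), c(6L, 4L)))
  res <- apply_model(constant_model(1), x, assay)
  expect_equal(res$metrics$sensitivity, 1)
  expect_equal(res$metrics$specificity, 0)
  expect_equal(res$metrics$accuracy, 0.6)
  expect_identical(res$confusion$tp, 6L)
  expect_identical(res$confusion$fp, 4L)
})

test_that("not_determined compounds are excluded and counted", {
  x <- matrix(stats::rnorm(12), 6L, 2L,
              dimnames = list(sprintf("C%02d", 1:6), c("D1", "D2")))
  assay <- assay_frame(rownames(x),
                       c("active", "not_determined", "inactive", "active",
                         "not_determined", "inactive"))
  res <- suppressMessages(apply_model(constant_model(0.9), x, assay))
  expect_identical(res$n_not_determined, 2L)
  expect_identical(nrow(res$predictions), 4L)

  expect_error(apply_model(constant_model(1), x,
                           assay_frame("C99", "active")), "C99")
  expect_error(
    apply_model(constant_model(1), x,
                assay_frame(rownames(x), rep("not_determined", 6L))),
    "determined")
  expect_error(apply_model(constant_model(1, kept = c("D1", "D9")), x,
                           assay_frame("C01", "active")), "D9")
})

test_that("confidence strata partition the overall confusion matrix", {
  gen <- generate_dataset(synth_config(
    n_binders = 90L, n_nonbinders = 10L, n_descriptors = 5L,
    n_informative = 2L, effect_size = 2, fraction_constant = 0, seed = 13L))
  model <- train_forest(gen$dataset, forest_config(min_leaf = 2L))
  outcomes <- ifelse(as.character(gen$dataset$y) == "binder",
                     "active", "inactive")
  res <- apply_model(model, gen$dataset$x,
                     assay_frame(rownames(gen$dataset$x), outcomes),
                     confidence_cut = 0.5)
  total <- function(cm) if (is.null(cm)) c(0L, 0L, 0L, 0L)
           else c(cm$tp, cm$fp, cm$fn, cm$tn)
  expect_identical(total(res$confusion),
                   total(res$confusion_high) + total(res$confusion_low))
})

test_that("concordance of the shared compounds matches the published 2x2s", {
  tabs <- load_assay_summaries()
  pct <- function(v) round_half_up(100 * v, 1L)

  c480 <- tabs[["OT_ER_ERbERb_0480"]]$concordance
  res480 <- compare_label_sets(c480$binding, c480$assay)
  expect_equal(pct(res480$metrics$accuracy), 71.4)
  expect_identical(res480$confusion$tp, 15L)
  expect_identical(res480$confusion$fp, 6L)
  # every shared compound is predicted binder, so specificity collapses to 0
  # and the MCC denominator is degenerate (flagged, reported as 0)
  expect_equal(res480$metrics$specificity, 0)
  expect_true(res480$metrics$mcc_undefined)
  expect_equal(res480$metrics$mcc, 0)

  c1440 <- tabs[["OT_ER_ERbERb_1440"]]$concordance
  expect_equal(pct(compare_label_sets(c1440$binding,
                                      c1440$assay)$metrics$accuracy), 85.7)
})

test_that("concordance degenerates and errors sensibly", {
  a <- stats::setNames(rep("binder", 4L), paste0("C", 1:4))
  b <- stats::setNames(c("active", "active", "inactive", "active"),
                       paste0("C", 1:4))
  self <- compare_label_sets(a, ifelse(a == "binder", "active", "inactive"))
  expect_identical(self$confusion$fp + self$confusion$fn, 0L)
  expect_equal(self$metrics$accuracy, 1)

  # named vectors are matched by compound, not position
  shuffled <- compare_label_sets(a, b[c(3L, 1L, 4L, 2L)])
  expect_identical(shuffled$confusion, compare_label_sets(a, b)$confusion)

  names(b)[4L] <- "C9"
  expect_error(compare_label_sets(a, b), "different")
  expect_error(compare_label_sets(unname(a), b[1:3]), "length")
})

test_that("identical two-class label sets give perfect agreement and MCC 1", {
  a <- stats::setNames(c(rep("binder", 3L), "non_binder"), paste0("K", 1:4))
  b <- stats::setNames(c(rep("active", 3L), "inactive"), paste0("K", 1:4))
  res <- compare_label_sets(a, b)
  expect_equal(res$metrics$accuracy, 1)
  expect_equal(res$metrics$mcc, 1)
})
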