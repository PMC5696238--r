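test_that("confusion counts actual-vs-predicted with binder positive", {
  cm <- confusion(c("binder", "binder", "non_binder"),
                  c("binder", "non_binder", "non_binder"))
  expect_identical(cm[c("tp", "fn", "tn", "fp")],
                   list(tp = 1L, fn = 1L, tn = 1L, fp = 0L))

  same <- confusion(rep(c("binder", "non_binder"), 3:2),
                    rep(c("binder", "non_binder"), 3:2))
  expect_identical(same$fp + same$fn, 0L)

  # swapping every prediction exchanges tp<->fn and tn<->fp
  actual <- c("binder", "binder", "non_binder", "binder", "non_binder")
  pred <- c("binder", "non_binder", "binder", "binder", "non_binder")
  flip <- ifelse(pred == "binder", "non_binder", "binder")
  a <- confusion(actual, pred)
  b <- confusion(actual, flip)
  expect_identical(b$tp, a$fn)
  expect_identical(b$fn, a$tp)
  expect_identical(b$tn, a$fp)
  expect_identical(b$fp, a$tn)

  expect_error(confusion(c("binder"), c("binder", "binder")), "length")
  expect_error(confusion_matrix(-1, 0, 0, 0), "non-negative")
})

test_that("metrics reproduce the published dimerization application tables", {
  pct <- function(v) round_half_up(100 * v, 1L)
  m480 <- compute_metrics(confusion_matrix(tp = 162, fp = 1280,
                                           fn = 13, tn = 350))
  expect_equal(pct(m480$sensitivity), 92.6)
  expect_equal(pct(m480$accuracy), 28.4)
  expect_equal(pct(m480$specificity), 21.5)

  m1440 <- compute_metrics(confusion_matrix(tp = 135, fp = 1304,
                                            fn = 15, tn = 346))
  expect_equal(pct(m1440$sensitivity), 90.0)
  expect_equal(pct(m1440$accuracy), 26.7)
  expect_equal(pct(m1440$specificity), 21.0)
})

test_that("closed-form extremes behave", {
  perfect <- compute_metrics(confusion_matrix(tp = 7, fp = 0, fn = 0,
                                              tn = 3))
  for (m in c("accuracy", "sensitivity", "specificity",
              "balanced_accuracy", "mcc"))
    expect_equal(perfect[[m]], 1)

  all_pos <- compute_metrics(confusion_matrix(tp = 9, fp = 4, fn = 0,
                                              tn = 0))
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  expect_equal(all_pos$balanced_accuracy, 0.5)
  expect_equal(all_pos$mcc, 0)       # zero denominator factor
  expect_true(all_pos$mcc_undefined)

  no_neg <- compute_metrics(confusion_matrix(tp = 5, fp = 0, fn = 1,
                                             tn = 0))
  expect_true(is.na(no_neg$specificity))
  expect_true(is.na(no_neg$balanced_accuracy))
  expect_error(compute_metrics(confusion_matrix(0, 0, 0, 0)), "empty")
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(23)
  for (i in 1:200) {
    k <- sample(0:40, 4L, replace = TRUE)
    if (sum(k) == 0L) k[1L] <- 1L
    cm <- confusion_matrix(k[1L], k[2L], k[3L], k[4L])
    m <- compute_metrics(cm)
    n_pos <- cm$tp + cm$fn
    n_neg <- cm$tn + cm$fp
    if (!is.na(m$sensitivity) && !is.na(m$specificity)) {
      expect_equal(m$accuracy,
                   (m$sensitivity * n_pos + m$specificity * n_neg) /
                     (n_pos + n_neg))
      expect_equal(m$balanced_accuracy,
                   (m$sensitivity + m$specificity) / 2)
    }
    # MCC invariant under simultaneous class swap
    swapped <- compute_metrics(confusion_matrix(cm$tn, cm$fn, cm$fp, cm$tp))
    expect_equal(swapped$mcc, m$mcc)
    for (f in c("accuracy", "sensitivity", "specificity",
                "balanced_accuracy"))
      if (!is.na(m[[f]])) expect_true(m[[f]] >= 0 && m[[f]] <= 1)
    expect_true(m$mcc >= -1 && m$mcc <= 1)
  }
})

test_that("percentages round half away from zero", {
  expect_equal(round_half_up(92.55), 92.6)
  expect_equal(round_half_up(20.9697), 21.0)
  expect_equal(round_half_up(-2.45, 1), -2.5)
  expect_equal(round_half_up(2.5, 0), 3)
})
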