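test_that("consensus averages close annotations and invalidates the rest", {
  c1 <- build_consensus(c(10.00), c(10.10))
  expect_equal(c1$onsets, 10.05)
  expect_equal(nrow(c1$invalid), 0)

  # over 250 ms apart: both invalid
  c2 <- build_consensus(c(10.00), c(10.40))
  expect_equal(length(c2$onsets), 0)
  expect_equal(nrow(c2$invalid), 2)

  # unpaired singleton invalid
  c3 <- build_consensus(c(10.00, 20.00), c(10.10))
  expect_equal(c3$onsets, 10.05)
  expect_equal(c3$invalid$onset, 20.00)
  expect_equal(c3$invalid$annotator, "expert1")

  # boundary: exactly 250 ms apart is retained
  c4 <- build_consensus(c(10.00), c(10.25))
  expect_equal(c4$onsets, 10.125)
})

test_that("consensus pairing agrees with the exhaustive small-case oracle", {
  set.seed(51)
  for (rep in 1:100) {
    n1 <- sample(0:5, 1); n2 <- sample(0:5, 1)
    t1 <- sort(stats::runif(n1, 0, 6))
    t2 <- sort(stats::runif(n2, 0, 6))
    got <- build_consensus(t1, t2)
    want <- oracle_consensus(t1, t2)
    expect_equal(got$onsets, want$onsets)
    expect_equal(nrow(got$invalid), want$n_invalid)
  }
})

test_that("detection matching mirrors the TP/FP/FN definitions", {
  ref <- make_efforts(c(1, 4, 7), c(2, 5, 8))
  m <- match_detections(ref, ref)
  expect_equal(c(m$tp, m$fp, m$fn), c(3, 0, 0))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$ppv, 1)
  expect_equal(m$onset_bias, 0)

  shifted <- make_efforts(c(1.05, 4.05, 7.05), c(2.05, 5.05, 8.05))
  m2 <- match_detections(shifted, ref)
  expect_equal(m2$tp, 3)
  expect_equal(m2$onset_bias, 0.05)

  # one dropped, one inserted
  det <- make_efforts(c(1, 7, 10), c(2, 8, 11))
  m3 <- match_detections(det, ref)
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(2, 1, 1))
  # identities: tp + fn = |ref|, tp + fp = |detected|
  expect_equal(m3$tp + m3$fn, 3)
  expect_equal(m3$tp + m3$fp, 3)

  # surplus detections on one reference count as false positives
  det2 <- make_efforts(c(0.9, 1.6), c(1.5, 2.2))
  m4 <- match_detections(det2, make_efforts(1, 2))
  expect_equal(c(m4$tp, m4$fp, m4$fn), c(1, 1, 0))
})

test_that("random drop/insert scenarios match an exhaustive count oracle", {
  set.seed(52)
  for (rep in 1:50) {
    ref <- random_stream(10)
    keep <- stats::runif(10) > 0.2
    det_on <- ref$on[keep] + stats::runif(sum(keep), -0.05, 0.05)
    det_off <- ref$off[keep]
    ins <- stats::runif(2, 0, max(ref$off)) + 30   # clear insertions
    det <- make_efforts(c(det_on, ins), c(det_off, ins + 0.5))
    m <- match_detections(det, make_efforts(ref$on, ref$off))
    expect_equal(m$tp, sum(keep))
    expect_equal(m$fp, 2)
    expect_equal(m$fn, 10 - sum(keep))
  }
})

test_that("confusion tabulation aligns by shared support and effort overlap", {
  eff <- make_efforts(c(1, 5), c(2, 6))
  sup <- make_supports(c(1.1, 5.1), c(2.2, 6.2))
  ref <- classify(eff, sup)
  # identical prediction -> diagonal
  ct <- tabulate_confusion(ref, ref)
  expect_equal(sum(ct), 2)
  expect_equal(ct["synchronous", "synchronous"], 2)

  # reference ineffective effort undetected -> (ineffective, not_detected)
  ref2 <- classify(make_efforts(c(1, 9), c(2, 10)), sup[1, ])
  pred2 <- classify(make_efforts(1, 2), sup[1, ])
  ct2 <- tabulate_confusion(pred2, ref2)
  expect_equal(ct2["ineffective", "not_detected"], 1)
  expect_equal(ct2["synchronous", "synchronous"], 1)

  # prediction with no reference counterpart -> (not_detected, label)
  pred3 <- classify(make_efforts(c(1, 9), c(2, 10)), sup[1, ])
  ct3 <- tabulate_confusion(pred3, classify(make_efforts(1, 2), sup[1, ]))
  expect_equal(ct3["not_detected", "ineffective"], 1)

  # scripted mismatch: sync reclassified as delayed on shared support
  predd <- ref
  predd$label[1] <- "delayed"
  ct4 <- tabulate_confusion(predd, ref)
  expect_equal(ct4["synchronous", "delayed"], 1)
  expect_equal(ct4["synchronous", "synchronous"], 1)
})

test_that("class metrics reproduce hand arithmetic and identity tables", {
  lv <- c("synchronous", "delayed", "auto_trigger", "ineffective",
          "double_trigger", "double_effort", "not_detected")
  ident <- diag(c(10, 8, 6, 4, 3, 2, 0))
  dimnames(ident) <- list(lv, lv)
  cm <- class_metrics(ident)
  expect_true(all(cm$per_class$sensitivity == 1))
  expect_true(all(cm$per_class$ppv == 1))
  expect_equal(unname(cm$total_macro["sensitivity"]), 1)
  expect_equal(unname(cm$total_weighted["ppv"]), 1)

  # permutation invariance of the aggregate metrics
  perm <- sample(7)
  cmp <- class_metrics(ident[perm, perm])
  expect_equal(cmp$total_macro, cm$total_macro)

  # empty class row excluded with flag
  empty <- ident
  empty["double_effort", "double_effort"] <- 0
  cme <- class_metrics(empty)
  expect_true("double_effort" %in% cme$undefined)
})

test_that("repeated-measures Bland-Altman recovers bias and variance", {
  # a == b -> zero bias, zero-width limits
  a <- stats::rnorm(20)
  subj <- rep(1:4, each = 5)
  ba0 <- bland_altman_rm(a, a, subj)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)

  # constant offset: bias = offset, sd 0 regardless of grouping
  ba1 <- bland_altman_rm(a + 0.06, a, subj)
  expect_equal(ba1$bias, 0.06)
  expect_equal(ba1$sd_total, 0)

  # single subject falls back with a warning
  expect_warning(ba2 <- bland_altman_rm(a + 0.1, a, rep(1, 20)),
                 "single subject")
  expect_equal(ba2$bias, 0.1)

  # one pair per subject reduces to the classic computation
  set.seed(53)
  d <- stats::rnorm(40, 0.2, 0.3)
  ba3 <- bland_altman_rm(d, rep(0, 40), seq_len(40))
  expect_equal(ba3$bias, mean(d))
  expect_equal(ba3$sd_total, stats::sd(d), tolerance = 1e-6)

  # Monte-Carlo recovery: 30 subjects x 20 pairs
  set.seed(54)
  nsub <- 30; npair <- 20
  subj <- rep(seq_len(nsub), each = npair)
  bsub <- rep(stats::rnorm(nsub, 0, 0.1), each = npair)
  dmc <- 0.05 + bsub + stats::rnorm(nsub * npair, 0, 0.05)
  ba4 <- bland_altman_rm(dmc, rep(0, length(dmc)), subj)
  expect_equal(ba4$bias, 0.05, tolerance = 0.01 / 0.05)
  expect_equal(ba4$sd_total, sqrt(0.1^2 + 0.05^2), tolerance = 0.10)
})
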