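#' Build the expert consensus annotation
#'
#' Onset annotations from two experts are paired greedily by nearest time
#' (each annotation used at most once). Pairs differing by at most `tol_s`
#' are averaged into a consensus onset; pairs over tolerance and unpaired
#' annotations are invalid and discarded.
#'
#' @param expert1,expert2 [annotation_table()]s (or numeric onset vectors)
#'   from the same recording.
#' @param tol_s Agreement tolerance in s (default 0.250).
#' @return List of class `vent_consensus`: `onsets` (sorted consensus
#'   times) and `invalid` (data.frame of discarded annotations with their
#'   annotator).
#' @export
build_consensus <- function(expert1, expert2, tol_s = 0.250) {
  t1 <- if (is.data.frame(expert1)) expert1$onset else as.numeric(expert1)
  t2 <- if (is.data.frame(expert2)) expert2$onset else as.numeric(expert2)
  t1 <- sort(t1); t2 <- sort(t2)
  pairs <- greedy_pair(t1, t2, tol_s)
  onsets <- sort((t1[pairs[, 1]] + t2[pairs[, 2]]) / 2)
  inv1 <- setdiff(seq_along(t1), pairs[, 1])
  inv2 <- setdiff(seq_along(t2), pairs[, 2])
  invalid <- rbind(
    data.frame(annotator = rep("expert1", length(inv1)), onset = t1[inv1]),
    data.frame(annotator = rep("expert2", length(inv2)), onset = t2[inv2]))
  structure(list(onsets = onsets, invalid = invalid),
            class = "vent_consensus")
}

# greedy one-to-one pairing by nearest time within tol; returns matrix of
# index pairs (i in a, j in b)
greedy_pair <- function(a, b, tol) {
  if (length(a) == 0 || length(b) == 0)
    return(matrix(integer(0), ncol = 2))
  d <- abs(outer(a, b, "-"))
  d[d > tol] <- NA
  pairs <- matrix(integer(0), ncol = 2)
  while (any(!is.na(d))) {
    ij <- which(d == min(d, na.rm = TRUE), arr.ind = TRUE)[1, , drop = FALSE]
    pairs <- rbind(pairs, ij)
    d[ij[1], ] <- NA
    d[, ij[2]] <- NA
  }
  pairs
}

#' Match detected efforts against a reference segmentation
#'
#' A detected effort overlapping a reference effort is a true positive
#' (greedy one-to-one assignment by onset proximity; surplus detections on
#' an already-matched reference count as false positives), a detection
#' overlapping no reference is a false positive, and unmatched reference
#' efforts are false negatives. Onset bias and SD are computed over the
#' matched pairs as `t_detected - t_reference`.
#'
#' @param detected,reference [effort_events()] tables (reference offsets
#'   present, e.g. via [effort_end_pmus()]).
#' @return List of class `vent_detmetrics`: `tp`, `fp`, `fn`,
#'   `sensitivity`, `ppv`, `onset_bias`, `onset_sd`, `pairs`.
#' @export
match_detections <- function(detected, reference) {
  nd <- nrow(detected); nr <- nrow(reference)
  matched_d <- integer(0); matched_r <- integer(0)
  if (nd > 0 && nr > 0) {
    ov <- matrix(FALSE, nd, nr)
    for (i in seq_len(nd)) ov[i, ] <-
      pmin(detected$offset[i], reference$offset) -
      pmax(detected$onset[i], reference$onset) > 0
    d <- abs(outer(detected$onset, reference$onset, "-"))
    d[!ov] <- NA
    while (any(!is.na(d))) {
      ij <- which(d == min(d, na.rm = TRUE), arr.ind = TRUE)[1, ]
      matched_d <- c(matched_d, ij[1]); matched_r <- c(matched_r, ij[2])
      d[ij[1], ] <- NA
      d[, ij[2]] <- NA
    }
  }
  tp <- length(matched_d)
  fp <- nd - tp
  fn <- nr - tp
  diffs <- detected$onset[matched_d] - reference$onset[matched_r]
  structure(list(
    tp = tp, fp = fp, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    onset_bias = if (tp > 0) mean(diffs) else NA_real_,
    onset_sd = if (tp > 1) stats::sd(diffs) else NA_real_,
    pairs = data.frame(detected = matched_d, reference = matched_r,
                       diff = diffs)),
    class = "vent_detmetrics")
}

PVI_CLASSES <- c("synchronous", "delayed", "auto_trigger", "ineffective",
                 "double_trigger", "double_effort")

#' Tabulate a classification confusion table
#'
#' Cross-tabulates reference breath records (rows) against predicted ones
#' (columns) over the six interaction classes plus a `not_detected`
#' margin. Records are aligned via their shared support segmentation
#' (same support interval) or, for unsupported records, by effort
#' overlap. Reference events without a predicted counterpart land in the
#' `not_detected` column; predictions without a reference in the
#' `not_detected` row.
#'
#' @param predicted,reference `vent_breaths` tables built on the same
#'   support segmentation.
#' @return 7x7 integer matrix of class `vent_confusion`, reference on
#'   rows.
#' @export
tabulate_confusion <- function(predicted, reference) {
  lv <- c(PVI_CLASSES, "not_detected")
  ct <- matrix(0L, 7, 7, dimnames = list(reference = lv, predicted = lv))
  used_p <- rep(FALSE, nrow(predicted))
  key <- function(df, i) {
    if (!is.na(df$support_on[i])) c(df$support_on[i], df$support_off[i])
    else NULL
  }
  for (i in seq_len(nrow(reference))) {
    hit <- NA_integer_
    for (j in seq_len(nrow(predicted))) {
      if (used_p[j]) next
      same_support <- !is.na(reference$support_on[i]) &&
        !is.na(predicted$support_on[j]) &&
        abs(reference$support_on[i] - predicted$support_on[j]) < 1e-6
      effort_overlap <- !is.na(reference$effort_on[i]) &&
        !is.na(predicted$effort_on[j]) &&
        (min(reference$effort_off[i], predicted$effort_off[j]) -
           max(reference$effort_on[i], predicted$effort_on[j]) > 0)
      if (same_support || effort_overlap) { hit <- j; break }
    }
    if (is.na(hit)) {
      ct[reference$label[i], "not_detected"] <-
        ct[reference$label[i], "not_detected"] + 1L
    } else {
      used_p[hit] <- TRUE
      ct[reference$label[i], predicted$label[hit]] <-
        ct[reference$label[i], predicted$label[hit]] + 1L
    }
  }
  for (j in which(!used_p)) {
    ct["not_detected", predicted$label[j]] <-
      ct["not_detected", predicted$label[j]] + 1L
  }
  class(ct) <- c("vent_confusion", class(ct))
  ct
}

#' Per-class and aggregate classification metrics
#'
#' For each interaction class, one-vs-rest sensitivity
#' (`diagonal / row sum`), positive predictive value
#' (`diagonal / column sum`) and specificity (`TN / (TN + FP)` after
#' collapsing all other classes). Aggregates are the arithmetic (macro)
#' mean and the class-frequency-weighted mean over classes with defined
#' metrics.
#'
#' @param ct A [tabulate_confusion()] matrix (or any square matrix whose
#'   first rows/columns are the six classes; a `not_detected` margin is
#'   included in the totals).
#' @return List of class `vent_classmetrics`: `per_class` data.frame,
#'   `total_macro`, `total_weighted`, `undefined` (classes excluded for
#'   empty rows/columns).
#' @export
class_metrics <- function(ct) {
  classes <- intersect(PVI_CLASSES, rownames(ct))
  total <- sum(ct)
  per <- data.frame(class = classes, n = NA_real_, sensitivity = NA_real_,
                    ppv = NA_real_, specificity = NA_real_)
  for (k in seq_along(classes)) {
    cl <- classes[k]
    tp <- ct[cl, cl]
    rs <- sum(ct[cl, ]); cs <- sum(ct[, cl])
    fp <- cs - tp
    tn <- total - rs - cs + tp
    per$n[k] <- rs
    per$sensitivity[k] <- if (rs > 0) tp / rs else NA_real_
    per$ppv[k] <- if (cs > 0) tp / cs else NA_real_
    per$specificity[k] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  }
  agg <- function(w) {
    ok <- !is.na(per$sensitivity) & !is.na(per$ppv) & !is.na(per$specificity)
    if (!any(ok)) return(c(sensitivity = NA, ppv = NA, specificity = NA))
    wts <- if (is.null(w)) rep(1, sum(ok)) else w[ok]
    c(sensitivity = sum(per$sensitivity[ok] * wts) / sum(wts),
      ppv = sum(per$ppv[ok] * wts) / sum(wts),
      specificity = sum(per$specificity[ok] * wts) / sum(wts))
  }
  structure(list(per_class = per,
                 total_macro = agg(NULL),
                 total_weighted = agg(per$n),
                 undefined = per$class[is.na(per$sensitivity) |
                                         is.na(per$ppv)]),
            class = "vent_classmetrics")
}

#' Bland-Altman limits of agreement for repeated measurements
#'
#' Limits of agreement between two methods when each subject contributes
#' several paired measurements: the differences `d = a - b` are
#' decomposed by a one-way random-effects model (subject as the random
#' factor, unequal group sizes handled by the usual n0 correction), so
#' that `sd_total^2` is the between-subject plus within-subject variance
#' of a single difference. Limits are `bias +/- 1.96 * sd_total`. With a
#' single subject the classic Bland-Altman computation is used (with a
#' warning).
#'
#' @param value_a,value_b Paired measurements.
#' @param subject Subject/recording identifier per pair.
#' @return List of class `vent_ba`: `bias`, `sd_total`, `loa_low`,
#'   `loa_high`, `var_between`, `var_within`, `n_subjects`, `n_pairs`.
#' @export
bland_altman_rm <- function(value_a, value_b, subject) {
  stopifnot(length(value_a) == length(value_b),
            length(value_a) == length(subject))
  d <- value_a - value_b
  subject <- as.character(subject)
  groups <- split(d, subject)
  k <- length(groups)
  N <- length(d)
  bias <- mean(d)
  if (k < 2) {
    warning("single subject: falling back to simple Bland-Altman")
    s2 <- if (N > 1) stats::var(d) else 0
    vb <- 0; vw <- s2
  } else {
    ni <- lengths(groups)
    gm <- vapply(groups, mean, numeric(1))
    ssb <- sum(ni * (gm - bias)^2)
    ssw <- sum(vapply(groups, function(g)
      sum((g - mean(g))^2), numeric(1)))
    msb <- ssb / (k - 1)
    msw <- if (N - k > 0) ssw / (N - k) else 0
    n0 <- (N - sum(ni^2) / N) / (k - 1)
    vb <- max((msb - msw) / n0, 0)
    vw <- msw
  }
  sd_total <- sqrt(vb + vw)
  structure(list(bias = bias, sd_total = sd_total,
                 loa_low = bias - 1.96 * sd_total,
                 loa_high = bias + 1.96 * sd_total,
                 var_between = vb, var_within = vw,
                 n_subjects = k, n_pairs = N),
            class = "vent_ba")
}

#' @export
print.vent_ba <- function(x, ...) {
  cat(sprintf("<vent_ba> bias %.4f, LoA [%.4f, %.4f] (sd %.4f; %d subjects, %d pairs)\n",
              x$bias, x$loa_low, x$loa_high, x$sd_total,
              x$n_subjects, x$n_pairs))
  invisible(x)
}
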