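#' Classify patient-ventilator interaction breath by breath
#'
#' Pairs detected patient efforts with segmented ventilator supports by
#' positive-duration interval overlap and assigns the six interaction
#' classes. For an overlapping pair the trigger delay is
#' `delta_t = t_Paw - t_patient` (support start minus effort onset). A
#' one-to-one overlap is `synchronous` when `delta_t <= sync_threshold_s`
#' (inclusive; negative delays count as synchronous) and `delayed`
#' otherwise. An effort overlapping no support is an `ineffective` trigger;
#' a support with no effort is an `auto_trigger`. When one effort overlaps
#' two (or more) supports the first support is classified by its delay and
#' the remaining ones are `double_trigger`s; two (or more) efforts under a
#' single support make the later ones `double_effort`s. Components of the
#' overlap graph with several efforts and supports generalize this: the
#' earliest effort pairs with the earliest support, surplus supports are
#' double triggers and surplus efforts double efforts.
#'
#' @param efforts [effort_events()] table (sorted, non-overlapping).
#' @param supports `vent_supports` table from [segment_supports()].
#' @param sync_threshold_s Synchronous/delayed boundary in s (default
#'   0.250).
#' @return data.frame of class `vent_breaths`: one row per breath record
#'   with `effort_on`, `effort_off`, `support_on`, `support_off`, `label`,
#'   `delay`. Every effort and support appears in exactly one row.
#' @export
classify <- function(efforts, supports, sync_threshold_s = 0.250) {
  ne <- if (is.null(efforts)) 0L else nrow(efforts)
  ns <- if (is.null(supports)) 0L else nrow(supports)
  check_sorted <- function(on, off, what) {
    if (length(on) > 1 && any(on[-1] < off[-length(off)]))
      stop("overlapping intervals within the ", what, " list")
  }
  eon <- if (ne) efforts$onset else numeric(0)
  eoff <- if (ne) efforts$offset else numeric(0)
  son <- if (ns) supports$t_start else numeric(0)
  soff <- if (ns) supports$t_end else numeric(0)
  o_e <- order(eon); eon <- eon[o_e]; eoff <- eoff[o_e]
  o_s <- order(son); son <- son[o_s]; soff <- soff[o_s]
  check_sorted(eon, eoff, "effort")
  check_sorted(son, soff, "support")

  # overlap graph: effort i ~ support j iff intersection has positive length
  adj_s <- lapply(seq_len(ne), function(i) which(
    pmin(eoff[i], soff) - pmax(eon[i], son) > 0))
  # union-find
  parent <- seq_len(ne + ns)
  find <- function(v) { while (parent[v] != v) v <- parent[v]; v }
  for (i in seq_len(ne)) for (j in adj_s[[i]]) {
    ri <- find(i); rj <- find(ne + j)
    if (ri != rj) parent[ri] <- rj
  }
  roots_e <- if (ne) vapply(seq_len(ne), find, integer(1)) else integer(0)
  roots_s <- if (ns) vapply(seq_len(ns), function(j) find(ne + j), integer(1)) else integer(0)

  rows <- list()
  add <- function(ei, sj, label, delay) {
    rows[[length(rows) + 1L]] <<- data.frame(
      effort_on = if (is.na(ei)) NA_real_ else eon[ei],
      effort_off = if (is.na(ei)) NA_real_ else eoff[ei],
      support_on = if (is.na(sj)) NA_real_ else son[sj],
      support_off = if (is.na(sj)) NA_real_ else soff[sj],
      label = label, delay = delay)
  }
  for (root in unique(c(roots_e, roots_s))) {
    es <- which(roots_e == root)
    ss <- which(roots_s == root)
    if (length(es) >= 1 && length(ss) >= 1) {
      e1 <- es[1]; s1 <- ss[1]          # earliest of each (lists sorted)
      d <- son[s1] - eon[e1]
      add(e1, s1, if (d <= sync_threshold_s) "synchronous" else "delayed", d)
      for (sj in ss[-1]) add(NA, sj, "double_trigger", NA_real_)
      for (ei in es[-1]) add(ei, NA, "double_effort", NA_real_)
    } else if (length(es) >= 1) {
      for (ei in es) add(ei, NA, "ineffective", NA_real_)
    } else {
      for (sj in ss) add(NA, sj, "auto_trigger", NA_real_)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(effort_on = numeric(0), effort_off = numeric(0),
               support_on = numeric(0), support_off = numeric(0),
               label = character(0), delay = numeric(0))
  key <- ifelse(is.na(out$effort_on), out$support_on,
                pmin(out$effort_on, out$support_on, na.rm = TRUE))
  out <- out[order(key), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("vent_breaths", "data.frame")
  out
}

#' Asynchrony index
#'
#' Number of major asynchronous events (ineffective, auto- and double
#' triggers, and double efforts) divided by the total number of breaths,
#' where breaths are counted as ventilator insufflations plus ineffective
#' (unsupported) patient efforts.
#'
#' @param records `vent_breaths` table from [classify()].
#' @param denominator `"supports_plus_ineffective"` (default, the
#'   convention above) or `"supports_plus_unsupported"` which also counts
#'   double efforts in the denominator.
#' @return List of class `vent_ai`: `ai` in `[0, 1]` (NA with a flag when
#'   no breaths), per-class `counts`, `n_breaths`.
#' @export
asynchrony_index <- function(records,
                             denominator = c("supports_plus_ineffective",
                                             "supports_plus_unsupported")) {
  denominator <- match.arg(denominator)
  classes <- c("synchronous", "delayed", "auto_trigger", "ineffective",
               "double_trigger", "double_effort")
  counts <- vapply(classes, function(cl) sum(records$label == cl), integer(1))
  n_supports <- sum(!is.na(records$support_on))
  extra <- if (denominator == "supports_plus_ineffective")
    counts[["ineffective"]]
  else counts[["ineffective"]] + counts[["double_effort"]]
  n_breaths <- n_supports + extra
  major <- counts[["ineffective"]] + counts[["auto_trigger"]] +
    counts[["double_trigger"]] + counts[["double_effort"]]
  if (n_breaths == 0)
    return(structure(list(ai = NA_real_, counts = counts, n_breaths = 0L,
                          undefined = TRUE), class = "vent_ai"))
  structure(list(ai = major / n_breaths, counts = counts,
                 n_breaths = n_breaths, undefined = FALSE),
            class = "vent_ai")
}

#' @export
print.vent_ai <- function(x, ...) {
  if (x$undefined) cat("<vent_ai> undefined (no breaths)\n")
  else cat(sprintf("<vent_ai> AI = %.3f over %d breaths (%s)\n", x$ai,
                   x$n_breaths,
                   paste(names(x$counts), x$counts, sep = "=", collapse = ", ")))
  invisible(x)
}
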