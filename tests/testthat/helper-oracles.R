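# Independent brute-force oracles and small fixture builders.

# --- brute-force interaction classifier ------------------------------
# Enumerates the overlap constellation of every event by explicit BFS on
# the bipartite overlap graph; labels follow the stated rules. Written
# independently of ventsync::classify (O(n^2) matrix + BFS).
oracle_classify <- function(eff, sup, thr = 0.25) {
  ne <- nrow(eff); ns <- nrow(sup)
  ov <- matrix(FALSE, max(ne, 1), max(ns, 1))
  if (ne > 0 && ns > 0) {
    for (i in 1:ne) for (j in 1:ns) {
      lo <- max(eff$onset[i], sup$t_start[j])
      hi <- min(eff$offset[i], sup$t_end[j])
      ov[i, j] <- (hi - lo) > 0
    }
  }
  seen_e <- rep(FALSE, ne); seen_s <- rep(FALSE, ns)
  out <- list()
  emit <- function(ei, sj, label, delay) {
    out[[length(out) + 1L]] <<- data.frame(
      effort_on = if (is.na(ei)) NA_real_ else eff$onset[ei],
      support_on = if (is.na(sj)) NA_real_ else sup$t_start[sj],
      label = label, delay = delay)
  }
  for (start in seq_len(ne)) {
    if (seen_e[start]) next
    # BFS component
    qe <- start; comp_e <- integer(0); comp_s <- integer(0)
    seen_e[start] <- TRUE
    while (length(qe)) {
      i <- qe[1]; qe <- qe[-1]
      comp_e <- c(comp_e, i)
      for (j in seq_len(ns)) if (ov[i, j] && !seen_s[j]) {
        seen_s[j] <- TRUE
        comp_s <- c(comp_s, j)
        for (i2 in seq_len(ne)) if (ov[i2, j] && !seen_e[i2]) {
          seen_e[i2] <- TRUE; qe <- c(qe, i2)
        }
      }
    }
    comp_e <- sort(comp_e); comp_s <- sort(comp_s)
    if (length(comp_s) == 0) {
      for (i in comp_e) emit(i, NA, "ineffective", NA_real_)
    } else {
      d <- sup$t_start[comp_s[1]] - eff$onset[comp_e[1]]
      emit(comp_e[1], comp_s[1],
           if (d <= thr) "synchronous" else "delayed", d)
      if (length(comp_s) > 1)
        for (j in comp_s[-1]) emit(NA, j, "double_trigger", NA_real_)
      if (length(comp_e) > 1)
        for (i in comp_e[-1]) emit(i, NA, "double_effort", NA_real_)
    }
  }
  for (j in seq_len(ns)) if (!seen_s[j]) emit(NA, j, "auto_trigger", NA_real_)
  do.call(rbind, out)
}

# random sorted non-overlapping interval stream
random_stream <- function(n, gap_max = 2, dur_max = 1.5) {
  t <- 0; on <- numeric(n); off <- numeric(n)
  for (i in seq_len(n)) {
    t <- t + stats::runif(1, 0.05, gap_max)
    on[i] <- t
    t <- t + stats::runif(1, 0.1, dur_max)
    off[i] <- t
  }
  data.frame(on = on, off = off)
}

make_efforts <- function(on = numeric(0), off = numeric(0))
  effort_events(on, off)

make_supports <- function(on = numeric(0), off = numeric(0)) {
  df <- data.frame(t_start = on, t_end = off,
                   peep = rep(5, length(on)), peak_paw = rep(13, length(on)))
  class(df) <- c("vent_supports", "data.frame")
  df
}

# normalized label table for comparing classify() against the oracle
label_key <- function(df) {
  k <- df[, c("effort_on", "support_on", "label")]
  k <- k[order(ifelse(is.na(k$effort_on), k$support_on,
                      pmin(k$effort_on, k$support_on, na.rm = TRUE)),
               k$label), ]
  rownames(k) <- NULL
  k
}

# --- brute-force 70% offset scan -------------------------------------
oracle_offset_scan <- function(samples, rate, t0, onset, bound, baseline,
                               fraction = 0.7) {
  i0 <- round((onset - t0) * rate) + 1
  i1 <- round((bound - t0) * rate) + 1
  seg <- samples[i0:i1]
  ip <- which.max(seg)
  for (i in seq(ip, length(seg))) {
    if (seg[i] - baseline < fraction * (seg[ip] - baseline))
      return(t0 + (i0 - 1 + i - 1) / rate)
  }
  bound
}

# --- recursive greedy-nearest pairing oracle (consensus rule) --------
oracle_consensus <- function(t1, t2, tol = 0.25) {
  t1 <- sort(t1); t2 <- sort(t2)
  pairs <- list()
  i_left <- seq_along(t1); j_left <- seq_along(t2)
  repeat {
    best <- NULL; bd <- Inf
    for (i in i_left) for (j in j_left) {
      d <- abs(t1[i] - t2[j])
      if (d <= tol && d < bd) { bd <- d; best <- c(i, j) }
    }
    if (is.null(best)) break
    pairs[[length(pairs) + 1L]] <- best
    i_left <- setdiff(i_left, best[1])
    j_left <- setdiff(j_left, best[2])
  }
  onsets <- sort(vapply(pairs, function(p) (t1[p[1]] + t2[p[2]]) / 2,
                        numeric(1)))
  list(onsets = onsets,
       n_invalid = length(i_left) + length(j_left))
}
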