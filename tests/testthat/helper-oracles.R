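# Independent oracles the implementation is checked against. These take the
# definitional route (multiset intersection, naive recursion, exhaustive
# bottom-up tabulation) rather than the implementation's.

# strict one-to-one matching as multiset intersection of (start,end,type)
oracle_counts <- function(gold, pred) {
  gk <- if (nrow(gold)) paste(gold$start, gold$end, gold$type) else character(0)
  pk <- if (nrow(pred)) paste(pred$start, pred$end, pred$type) else character(0)
  tp <- 0L
  for (k in unique(c(gk, pk))) {
    tp <- tp + min(sum(gk == k), sum(pk == k))
  }
  c(tp = tp, fp = length(pk) - tp, fn = length(gk) - tp)
}

oracle_prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

# brute-force corpus scorer: overall and per-type counts and metrics
oracle_score <- function(gold, pred) {
  types <- sort(unique(unlist(c(
    purrr::map(gold$entities, "type"), purrr::map(pred$entities, "type")))))
  per_type <- purrr::map(types, function(tt) {
    tot <- c(tp = 0L, fp = 0L, fn = 0L)
    for (i in seq_len(nrow(gold))) {
      g <- gold$entities[[i]]; p <- pred$entities[[i]]
      tot <- tot + oracle_counts(g[g$type == tt, , drop = FALSE],
                                 p[p$type == tt, , drop = FALSE])
    }
    c(tot, oracle_prf(tot[["tp"]], tot[["fp"]], tot[["fn"]]))
  })
  names(per_type) <- types
  overall <- c(tp = 0L, fp = 0L, fn = 0L)
  for (tt in types) overall <- overall + per_type[[tt]][c("tp", "fp", "fn")]
  list(overall = c(overall, oracle_prf(overall[["tp"]], overall[["fp"]],
                                       overall[["fn"]])),
       by_type = per_type)
}

# per-stratum brute force: TP/FN take the gold entity's stratum, FP the
# prediction's own training frequency stratum
oracle_stratum_score <- function(gold, pred, train, threshold = 5L) {
  ents <- purrr::list_rbind(purrr::map(train$entities, tibble::as_tibble))
  freq_of <- function(surface, type) {
    if (nrow(ents) == 0L) return(0L)
    sum(ents$surface == surface & ents$type == type)
  }
  stratum_of <- function(f) {
    if (f == 0L) "unknown" else if (f < threshold) "low" else "high"
  }
  acc <- list(unknown = c(tp = 0L, fp = 0L, fn = 0L),
              low = c(tp = 0L, fp = 0L, fn = 0L),
              high = c(tp = 0L, fp = 0L, fn = 0L))
  for (i in seq_len(nrow(gold))) {
    g <- gold$entities[[i]]; p <- pred$entities[[i]]
    gk <- if (nrow(g)) paste(g$start, g$end, g$type) else character(0)
    pk <- if (nrow(p)) paste(p$start, p$end, p$type) else character(0)
    matched <- intersect(gk, pk)  # keys unique within a valid sentence
    for (j in seq_len(nrow(g))) {
      s <- stratum_of(freq_of(g$surface[j], g$type[j]))
      w <- if (gk[j] %in% matched) "tp" else "fn"
      acc[[s]][[w]] <- acc[[s]][[w]] + 1L
    }
    for (j in seq_len(nrow(p))) {
      if (pk[j] %in% matched) next
      s <- stratum_of(freq_of(p$surface[j], p$type[j]))
      acc[[s]][["fp"]] <- acc[[s]][["fp"]] + 1L
    }
  }
  acc
}

# textbook naive recursion for the edit distance (exponential; tiny inputs)
lev_rec <- function(a, b) {
  if (!nzchar(a)) return(nchar(b))
  if (!nzchar(b)) return(nchar(a))
  sub_cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
  min(lev_rec(substring(a, 2), b) + 1L,
      lev_rec(a, substring(b, 2)) + 1L,
      lev_rec(substring(a, 2), substring(b, 2)) + sub_cost)
}

# all strings over `alphabet` up to `max_len`, with the defining recursion
# d(ax, by) = min(d(a, by) + 1, d(ax, b) + 1, d(a, b) + [x != y])
# evaluated exhaustively bottom-up over the whole universe of pairs
oracle_lev_universe <- function(alphabet, max_len) {
  strs <- list("")
  parent <- list(integer(0))
  lastch <- list(integer(0))
  for (l in seq_len(max_len)) {
    prev <- strs[[l]]
    strs[[l + 1]] <- paste0(rep(prev, each = length(alphabet)), alphabet)
    parent[[l + 1]] <- rep(seq_along(prev), each = length(alphabet))
    lastch[[l + 1]] <- rep(seq_along(alphabet), times = length(prev))
  }
  offs <- cumsum(c(0L, lengths(strs)))
  N <- offs[length(offs)]
  D <- matrix(0L, N, N)
  for (l in 0:max_len) {
    rows <- offs[l + 1] + seq_along(strs[[l + 1]])
    D[rows, 1] <- l
    D[1, rows] <- l
  }
  for (l1 in seq_len(max_len)) {
    rows <- offs[l1 + 1] + seq_along(strs[[l1 + 1]])
    prow <- offs[l1] + parent[[l1 + 1]]
    xrow <- lastch[[l1 + 1]]
    for (l2 in seq_len(max_len)) {
      cols <- offs[l2 + 1] + seq_along(strs[[l2 + 1]])
      pcol <- offs[l2] + parent[[l2 + 1]]
      ycol <- lastch[[l2 + 1]]
      neq <- outer(xrow, ycol, "!=")
      D[rows, cols] <- pmin(D[prow, cols] + 1L, D[rows, pcol] + 1L,
                            D[prow, pcol] + neq)
    }
  }
  list(strings = unlist(strs), D = D)
}
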