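# Independent brute-force oracles: plain double loops over all pairs,
# written without reference to the package implementations.

brute_cindex <- function(times, events, scores) {
  n <- length(times)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      comparable <- (times[i] < times[j] && events[i] == 1) ||
        (times[i] == times[j] && events[i] == 1 && events[j] == 0)
      if (!comparable) next
      den <- den + 1
      if (scores[j] > scores[i]) num <- num + 1
      else if (scores[j] == scores[i]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  num <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) num <- num + 1
      else if (p == q) num <- num + 0.5
    }
  }
  num / (length(pos) * length(neg))
}

# Step-by-step enrichment walk, independent of the vectorized version.
brute_walk <- function(x, in_set, exponent = 1) {
  G <- length(x)
  ord <- order(x, decreasing = TRUE)
  r <- rank(x, ties.method = "average")
  wsum <- sum(abs(r[in_set])^exponent)
  level <- 0
  walk <- numeric(G)
  for (k in seq_len(G)) {
    g <- ord[k]
    if (in_set[g]) level <- level + abs(r[g])^exponent / wsum
    else level <- level - 1 / (G - sum(in_set))
    walk[k] <- level
  }
  max(c(walk, 0)) + min(c(walk, 0))
}

# Hand-coded Kaplan-Meier table for a handful of observations.
brute_km_survival <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (k in seq_along(ut)) {
    at_risk <- sum(times >= ut[k])
    d <- sum(times == ut[k] & events == 1)
    s <- s * (1 - d / at_risk)
    out$surv[k] <- s
  }
  out
}
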