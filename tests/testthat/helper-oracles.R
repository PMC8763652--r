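## Independent oracles the production code is checked against. These stay
## deliberately naive: brute force, enumeration, hand formulas.

## Quadratic all-pairs UMI grouping: union-find over identical keys.
naive_group_families <- function(reads) {
  n <- nrow(reads)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j >= i) break
      same <- reads$chrom[i] == reads$chrom[j] &&
        reads$start[i] == reads$start[j] && reads$umi[i] == reads$umi[j]
      if (same) parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  ## canonical partition: sorted read ids per group, groups sorted
  grp <- split(reads$read_id, roots)
  unname(lapply(grp[order(vapply(grp, function(g) min(sort(g)), ""))], sort))
}

partition_of <- function(grouped) {
  grp <- split(grouped$read_id, grouped$family_id)
  unname(lapply(grp[order(vapply(grp, function(g) min(sort(g)), ""))], sort))
}

## Hand product-limit estimator.
hand_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ts <- sort(unique(time[event]))
  surv <- numeric(length(ts))
  s <- 1
  for (k in seq_along(ts)) {
    at_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  data.frame(time = ts, surv = surv)
}

## Exact two-sided Fisher p by hypergeometric enumeration on a 2x2 table.
enumerate_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c; nn <- b + d; k <- a + b
  lo <- max(0, k - nn); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, nn, k)
  p_obs <- dhyper(a, m, nn, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Monte-Carlo permutation p for the log-rank statistic.
permutation_logrank_p <- function(groupA, groupB, n_perm = 2000, seed = 1) {
  df <- rbind(cbind(groupA, g = "A"), cbind(groupB, g = "B"))
  obs <- logrank_test(groupA, groupB)$chi2
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    g <- sample(df$g)
    ch <- logrank_test(df[g == "A", c("time", "event")],
                       df[g == "B", c("time", "event")])$chi2
    if (!is.na(ch) && ch >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}
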