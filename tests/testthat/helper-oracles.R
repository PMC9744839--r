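## Independent brute-force oracles, kept deliberately naive.

## BH step-up by the definition: q_(i) = min_{j >= i} min(1, m * p_(j) / j)
bh_brute <- function(p) {
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  o <- order(pv)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cands <- vapply(i:m, function(j) min(1, m * pv[o[j]] / j), numeric(1))
    q_sorted[i] <- min(cands)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  out <- rep(NA_real_, length(p))
  out[ok] <- q
  out
}

## two-sided Fisher exact p by hypergeometric enumeration
## (probability-ordering definition, as in stats::fisher.test)
fisher_brute <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) dhyper(x, m, n, k), numeric(1))
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## all-pairs interval overlap on 0-based half-open coordinates
overlap_brute <- function(track, exons, min_overlap_bp = 1) {
  out <- setNames(vector("list", nrow(exons)), exons$name)
  for (i in seq_len(nrow(exons))) {
    hits <- character(0)
    for (j in seq_len(nrow(track))) {
      if (exons$chrom[i] != track$chrom[j]) next
      ov <- min(exons$end[i], track$end[j]) - max(exons$start[i], track$start[j])
      if (ov >= min_overlap_bp) hits <- union(hits, track$name[j])
    }
    out[[i]] <- hits
  }
  out
}

## per-event/per-sample PSI by scalar loops
psi_brute <- function(tpm, events, min_total_tpm = 1) {
  out <- matrix(NA_real_, nrow(events), ncol(tpm),
                dimnames = list(events$event_id, colnames(tpm)))
  for (i in seq_len(nrow(events))) {
    for (s in seq_len(ncol(tpm))) {
      inc <- sum(vapply(events$inclusion[[i]], function(tx) tpm[tx, s],
                        numeric(1)))
      tot <- sum(vapply(events$total[[i]], function(tx) tpm[tx, s],
                        numeric(1)))
      if (tot >= min_total_tpm && tot > 0) out[i, s] <- inc / tot
    }
  }
  out
}

## rank-based AUROC of a score for a positive set
auroc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
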