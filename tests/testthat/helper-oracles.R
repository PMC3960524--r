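# Independent oracles kept deliberately naive: direct formula transcriptions,
# no shared code with the implementation paths they check.

# Upper-tail hypergeometric probability by direct term-by-term summation of
# binomial-coefficient products.
oracle_hypergeom <- function(N, M, n, m) {
  if (m == 0) return(1)
  i <- m:min(n, M)
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up, written out longhand: sort ascending, take
# running minima of p * K / rank from the largest rank down, un-sort.
oracle_bh <- function(p) {
  K <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(K)
  running <- 1
  for (i in K:1) {
    running <- min(running, ps[i] * K / i)
    q[i] <- running
  }
  q[order(ord)]
}

# All-pairs overlap scan on half-open intervals.
oracle_targets <- function(peaks, regions) {
  hit <- character(0)
  for (i in seq_len(nrow(peaks))) {
    same <- regions$chrom == peaks$chrom[i]
    ov <- same &
      pmax(regions$start, peaks$start[i]) < pmin(regions$end, peaks$end[i])
    hit <- c(hit, regions$feature_id[ov])
  }
  sort(unique(hit))
}
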