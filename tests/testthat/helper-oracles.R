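## Independent brute-force oracles used to pin the statistical kernels and
## the caller. These deliberately avoid the code paths they check.

## Exact two-sided Mann-Whitney p by full arrangement enumeration.
mw_exact_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

## Exact two-sided Wilcoxon signed-rank p by enumeration of all sign patterns.
wsr_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(!anyDuplicated(abs(d)), n <= 16)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  vs <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  p <- 2 * min(mean(vs <= v_obs), mean(vs >= v_obs))
  min(1, p)
}

## Hypergeometric upper tail by explicit pmf summation with choose().
hyper_tail_oracle <- function(k, K, n, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## Exact permutation p-value for Pearson correlation (all n! orderings).
perm_cor_oracle <- function(x, y) {
  stopifnot(length(y) <= 7)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  r_obs <- abs(cor(x, y))
  rs <- vapply(perms(y), function(p) abs(cor(x, p)), 1)
  mean(rs >= r_obs - 1e-12)
}

## Naive per-row re-count of the caller's decision rule.
brute_force_call <- function(pileup, min_coverage = 10, min_frequency = 0.10,
                             min_quality = 25, min_alt_reads = 2) {
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (i in seq_len(nrow(pileup))) {
    row <- pileup[i, ]
    counts <- c(row$nA, row$nC, row$nG, row$nT)
    quals <- c(row$qA, row$qC, row$qG, row$qT)
    counts[is.na(quals) | quals < min_quality] <- 0
    depth <- sum(counts)
    best <- 0; alt <- NA
    for (b in bases) {          # lexicographic: strict > keeps the first max
      if (b == row$ref) next
      cnt <- counts[match(b, bases)]
      if (cnt > best) { best <- cnt; alt <- b }
    }
    if (is.na(alt)) next
    if (depth >= min_coverage && best >= min_alt_reads &&
        best / depth >= min_frequency) {
      out[[length(out) + 1]] <- data.frame(
        contig = row$contig, pos = row$pos, ref = row$ref, alt = alt,
        depth_retained = depth, alt_count = best,
        editing_frequency = best / depth, sample = row$sample,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

## Sliding-window identity scan: counts genome offsets where the window
## matches with identity above the threshold (independent of seed-and-extend).
sliding_identity_oracle <- function(window_chars, genome_chars, min_identity = 0.90) {
  L <- length(genome_chars); w <- length(window_chars)
  hits <- 0L
  for (s in seq_len(L - w + 1)) {
    if (mean(genome_chars[s:(s + w - 1)] == window_chars) > min_identity)
      hits <- hits + 1L
  }
  hits
}
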