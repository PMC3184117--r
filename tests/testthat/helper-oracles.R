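# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the package implementation.

# Exhaustive ungapped offset-sliding alignment oracle: for every
# relative shift (diagonal), count mismatches over the full overlap,
# take the genuine end offsets as overhangs, and score the diagonal by
# its best contiguous +1/-1 sub-segment. Diagonals are ranked by score,
# then fewest mismatches, then smallest total overhang.
oracle_align_ungapped <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av)
  m <- length(bv)
  cands <- list()
  for (d in (-(m - 1L)):(n - 1L)) {
    i1 <- max(1L, 1L + d)
    i2 <- min(n, m + d)
    if (i2 < i1) next
    seg_a <- av[i1:i2]
    seg_b <- bv[(i1 - d):(i2 - d)]
    match <- seg_a == seg_b & seg_a != "N"
    sc <- ifelse(match, 1, -1)
    run <- 0
    best_win <- 0
    for (v in sc) {
      run <- max(0, run + v)
      best_win <- max(best_win, run)
    }
    la <- i1 - 1L
    lb <- i1 - d - 1L
    ra <- n - i2
    rb <- m - (i2 - d)
    cands[[length(cands) + 1L]] <- list(
      score = best_win, mismatches = sum(!match),
      overhang_left = abs(la - lb), overhang_right = abs(ra - rb),
      aligned_length = length(seg_a))
  }
  scores <- vapply(cands, `[[`, 0, "score")
  best_score <- max(scores)
  if (best_score <= 0) {
    mn <- min(n, m)
    return(list(best = list(score = 0, mismatches = mn,
                            overhang_left = 0,
                            overhang_right = abs(n - m),
                            aligned_length = mn),
                tied = list()))
  }
  top <- cands[scores == best_score]
  mms <- vapply(top, `[[`, 0, "mismatches")
  top <- top[mms == min(mms)]
  ohs <- vapply(top, function(c) c$overhang_left + c$overhang_right, 0)
  top <- top[ohs == min(ohs)]
  list(best = top[[1L]], tied = top)
}

# Two-sided Fisher p by direct hypergeometric enumeration with the
# "tables as or less probable" convention (same relative slack as the
# reference implementation).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  N <- a + b + c + d
  if (N == 0) return(1)
  lo <- max(0, c1 - (N - r1))
  hi <- min(r1, c1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, c1, N - c1, r1)
  p_obs <- stats::dhyper(a, c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sided Mann-Whitney p by full enumeration of rank assignments
# (no ties allowed).
oracle_mw_p <- function(x, y) {
  n <- length(x)
  m <- length(y)
  pooled <- c(x, y)
  stopifnot(anyDuplicated(pooled) == 0L)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  us <- colSums(matrix(seq_len(n + m)[combs], nrow = n)) -
    n * (n + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Upper tails by direct summation.
oracle_pois_tail <- function(k, lambda) {
  if (k == 0) return(1)
  1 - sum(stats::dpois(0:(k - 1), lambda))
}
oracle_binom_tail <- function(k, n, p) {
  if (k == 0) return(1)
  sum(stats::dbinom(k:n, n, p))
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
        collapse = "")
}

substitute_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1L]]
  ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1L)
  paste(ch, collapse = "")
}
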