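# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the alignment oracle enumerates every global
# alignment, the hypergeometric oracle enumerates every draw, the Welch
# oracle is the textbook formula.

# exhaustive enumeration of all global alignments of a and b under affine gap
# costs (gap of length L costs open + L*ext); with end_gaps = FALSE the first
# and last gap runs of the alignment are free. Returns the optimal score.
oracle_align_score <- function(a, b, S, open = 10, ext = 0.5,
                               end_gaps = FALSE) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  best <- -Inf
  refund <- function(type, len) {
    if (!end_gaps && type != "M") open + len * ext else 0
  }
  # carry the first and current runs so terminal refunds are O(1) at the leaf
  rec <- function(i, j, score, first_type, first_len, last_type, last_len,
                  nruns) {
    if (i > n && j > m) {
      total <- score
      if (nruns == 1) {
        total <- total + refund(first_type, first_len)
      } else {
        total <- total + refund(first_type, first_len) +
          refund(last_type, last_len)
      }
      if (total > best) best <<- total
      return(invisible())
    }
    step <- function(type, ds) {
      new_run <- !identical(type, last_type)
      cost <- if (type == "M") ds else (ext + if (new_run) open else 0)
      sc <- if (type == "M") score + cost else score - cost
      ft <- if (nruns == 0) type else first_type
      fl <- if (nruns == 0) 1L else if (nruns == 1 && !new_run) first_len + 1L else first_len
      lt <- type
      ll <- if (new_run) 1L else last_len + 1L
      nr <- nruns + as.integer(new_run || nruns == 0)
      rec(i + (type != "X"), j + (type != "Y"), sc, ft, fl, lt, ll, nr)
    }
    if (i <= n && j <= m) step("M", S[A[i], B[j]])
    if (j <= m) step("X", 0)
    if (i <= n) step("Y", 0)
  }
  rec(1L, 1L, 0, NA_character_, 0L, NA_character_, 0L, 0L)
  best
}

# upper-tail hypergeometric by complete enumeration of all C(N, n) draws
oracle_hyper_upper <- function(k, K, n, N) {
  stopifnot(N <= 12)
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- colSums(matrix(draws %in% marked, nrow = n))
  mean(hits >= k)
}

# textbook Welch statistic with Satterthwaite degrees of freedom
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# max-T permutation approximation of Tukey family-wise pairwise p-values on a
# balanced one-way layout
oracle_tukey_perm <- function(values, groups, n_perm = 1e4, seed = 1) {
  set.seed(seed)
  groups <- as.factor(groups)
  g <- nlevels(groups)
  q_pairs <- function(v) {
    mns <- tapply(v, groups, mean)
    ns <- tapply(v, groups, length)
    msw <- sum(tapply(v, groups, function(z) sum((z - mean(z))^2))) /
      (length(v) - g)
    pr <- utils::combn(g, 2)
    abs(mns[pr[1, ]] - mns[pr[2, ]]) /
      sqrt(msw / 2 * (1 / ns[pr[1, ]] + 1 / ns[pr[2, ]]))
  }
  obs <- q_pairs(values)
  exceed <- matrix(0, n_perm, length(obs))
  for (p in seq_len(n_perm)) {
    exceed[p, ] <- max(q_pairs(sample(values))) >= obs
  }
  colMeans(exceed)
}
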