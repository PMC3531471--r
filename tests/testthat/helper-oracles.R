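# Independent oracles used across the suite. These deliberately avoid the
# package's fast paths: the subsequence relation is the literal recursive
# definition, optima come from plain level-by-level enumeration, and
# probabilities from Monte-Carlo simulation.

# literal recursion: t embeds s
embeds_rec <- function(t, s) {
  if (nchar(s) == 0) return(TRUE)
  if (nchar(t) == 0) return(FALSE)
  if (substr(t, 1, 1) == substr(s, 1, 1))
    embeds_rec(substr(t, 2, nchar(t)), substr(s, 2, nchar(s)))
  else
    embeds_rec(substr(t, 2, nchar(t)), s)
}

rand_string <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# exhaustive enumeration: smallest L such that some string of length L over
# the instance alphabet is a supersequence of every instance string
enum_scs_optimum <- function(inst, max_len = 12, row_cap = 1.5e6) {
  q <- length(inst$alphabet)
  for (L in max(inst$lengths):max_len) {
    if (q^L > row_cap) stop("enumeration too large at L = ", L)
    M <- as.matrix(expand.grid(rep(list(seq_len(q)), L)))
    ok <- rep(TRUE, nrow(M))
    for (e in inst$enc) {
      n <- length(e)
      k <- integer(nrow(M))
      for (col in seq_len(L)) {
        adv <- (k < n) & (M[, col] == e[pmin(k + 1L, n)])
        k[adv] <- k[adv] + 1L
      }
      ok <- ok & (k == n)
      if (!any(ok)) break
    }
    if (any(ok)) return(L)
  }
  stop("no supersequence found up to max_len")
}

# Monte-Carlo embedding frequencies: for a fixed string of length i over a
# q-ary alphabet, the fraction of `trials` random strings of length jmax
# that embed it within their first j symbols, for j = 1..jmax.
# Vectorised greedy matching across trials.
mc_embed_freq <- function(q, i, jmax, trials) {
  s <- sample.int(q, i, replace = TRUE)
  Y <- matrix(sample.int(q, trials * jmax, replace = TRUE), nrow = trials)
  k <- integer(trials)
  freq <- numeric(jmax)
  for (j in seq_len(jmax)) {
    adv <- (k < i) & (Y[, j] == s[pmin(k + 1L, i)])
    k[adv] <- k[adv] + 1L
    freq[j] <- mean(k == i)
  }
  freq
}

# small random instance for oracle comparisons
tiny_instance <- function(seed, m_range = 2:4, len_range = 1:8, q_range = 2:4) {
  set.seed(seed)
  q <- sample(q_range, 1)
  m <- sample(m_range, 1)
  lens <- sample(len_range, m, replace = TRUE)
  generate_random_instance(q, lengths = lens, seed = seed + 1000L,
                           id = paste0("tiny-", seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
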