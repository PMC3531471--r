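#' Majority Merge heuristic
#'
#' Greedy construction: repeatedly append the symbol found at the front of
#' the most remaining string parts and advance those fronts, until every
#' string is embedded. Ties are broken by alphabet order by default, or
#' uniformly at random (`tie_break = "random"`, seeded by the caller) for
#' the stochastic variant used in the literature.
#'
#' @param inst an [scs_instance()].
#' @param tie_break `"alphabet"` or `"random"`.
#' @return a valid supersequence; its length is at most the total instance
#'   length, since every step embeds at least one symbol.
#' @examples
#' majority_merge(scs_instance(c("ab", "ba")))  # "aba"
#' @export
majority_merge <- function(inst, tie_break = c("alphabet", "random")) {
  tie_break <- match.arg(tie_break)
  .front_greedy(inst, weight_by_length = FALSE, tie_break = tie_break)
}

#' Weighted Majority Merge heuristic
#'
#' Like [majority_merge()], but each front occurrence of a symbol scores
#' the remaining length of its string, so longer strings are shortened
#' first; the symbol with the highest total weight is appended. The weight
#' is linear in the remaining length.
#'
#' @inheritParams majority_merge
#' @return a valid supersequence.
#' @examples
#' weighted_majority_merge(scs_instance(c("ab", "b")))  # "ab"
#' @export
weighted_majority_merge <- function(inst, tie_break = c("alphabet", "random")) {
  tie_break <- match.arg(tie_break)
  .front_greedy(inst, weight_by_length = TRUE, tie_break = tie_break)
}

.front_greedy <- function(inst, weight_by_length, tie_break) {
  stopifnot(inherits(inst, "scs_instance"))
  q <- length(inst$alphabet)
  lam <- integer(length(inst$strings))
  lens <- inst$lengths
  enc <- inst$enc
  out <- integer(0)
  while (any(lam < lens)) {
    w <- numeric(q)
    for (i in seq_along(lam)) {
      if (lam[i] < lens[i]) {
        a <- enc[[i]][lam[i] + 1L]
        w[a] <- w[a] + if (weight_by_length) lens[i] - lam[i] else 1
      }
    }
    top <- which(w == max(w))
    a <- if (length(top) == 1L || tie_break == "alphabet") top[1L]
         else top[sample.int(length(top), 1L)]
    out[length(out) + 1L] <- a
    for (i in seq_along(lam)) {
      if (lam[i] < lens[i] && enc[[i]][lam[i] + 1L] == a) lam[i] <- lam[i] + 1L
    }
  }
  paste(inst$alphabet[out], collapse = "")
}

#' Alphabet Leftmost heuristic
#'
#' Cycles through a fixed permutation of the alphabet, appending each
#' symbol only when it occurs at the front of at least one remaining string
#' part (unproductive steps are skipped), until all strings are embedded.
#'
#' @param inst an [scs_instance()].
#' @param perm permutation of the instance alphabet; defaults to alphabet
#'   order.
#' @return a valid supersequence.
#' @examples
#' alphabet_leftmost(scs_instance(c("ab", "ba")))  # "aba"
#' @export
alphabet_leftmost <- function(inst, perm = inst$alphabet) {
  stopifnot(inherits(inst, "scs_instance"))
  if (!setequal(perm, inst$alphabet) || length(perm) != length(inst$alphabet))
    stop("perm must be a permutation of the alphabet")
  pe <- match(perm, inst$alphabet)
  lam <- integer(length(inst$strings))
  lens <- inst$lengths
  enc <- inst$enc
  out <- integer(0)
  while (any(lam < lens)) {
    for (a in pe) {
      hit <- FALSE
      for (i in seq_along(lam)) {
        if (lam[i] < lens[i] && enc[[i]][lam[i] + 1L] == a) {
          lam[i] <- lam[i] + 1L
          hit <- TRUE
        }
      }
      if (hit) out[length(out) + 1L] <- a
      if (all(lam >= lens)) break
    }
  }
  paste(inst$alphabet[out], collapse = "")
}

#' Length of the longest common subsequence of two strings
#'
#' Classical quadratic dynamic programme; used by the exact-solver tests
#' through the two-string identity
#' `|SCS(x, y)| = |x| + |y| - |LCS(x, y)|`.
#'
#' @param x,y plain strings.
#' @return integer LCS length.
#' @examples
#' lcs_length("ab", "ba")  # 1
#' @export
lcs_length <- function(x, y) {
  xs <- strsplit(x, "", fixed = TRUE)[[1]]
  ys <- strsplit(y, "", fixed = TRUE)[[1]]
  n <- length(xs); m <- length(ys)
  if (n == 0L || m == 0L) return(0L)
  prev <- integer(m + 1L)
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    for (j in seq_len(m)) {
      cur[j + 1L] <- if (xs[i] == ys[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Exact shortest common supersequence (small instances)
#'
#' Breadth-first shortest-path search over the product state space whose
#' states are vectors of embedded-prefix lengths and whose edges append one
#' alphabet symbol advancing at least one coordinate. Returns a provably
#' optimal supersequence; ties are broken by alphabet order, so the result
#' is deterministic. Memory grows with the product of `(|s_i| + 1)`, which
#' must not exceed `state_limit`.
#'
#' @param inst an [scs_instance()].
#' @param state_limit maximum admissible number of product states.
#' @return an optimal supersequence (character scalar).
#' @examples
#' nchar(exact_scs(scs_instance(c("ab", "ba"))))  # 3
#' @export
exact_scs <- function(inst, state_limit = 2e6) {
  stopifnot(inherits(inst, "scs_instance"))
  res <- exact_scs_cpp(.enc0(inst), length(inst$alphabet), state_limit)
  out <- .dec(res$seq, inst$alphabet)
  stopifnot(is_supersequence_of_all(out, inst))
  out
}
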