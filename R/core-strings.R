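#' Embedding test (subsequence relation)
#'
#' `embeds(t, s)` is `TRUE` iff `s` is a subsequence of `t`: all symbols of
#' `s` occur in `t` in the same order, not necessarily contiguously. A
#' single left-to-right greedy scan decides the relation; the empty string
#' is embedded in anything.
#'
#' @param t,s plain strings over a common alphabet (may be empty).
#' @return logical scalar.
#' @examples
#' embeds("acbcb", "abb")  # TRUE
#' embeds("ab", "ba")      # FALSE
#' @export
embeds <- function(t, s) lambda_prefix(t, s) == nchar(s)

#' Length of the longest embedded prefix
#'
#' The progress function of supersequence construction: the length of the
#' longest prefix of `s` that is a subsequence of `y`. Greedy left-to-right
#' matching attains it.
#'
#' @param y,s plain strings.
#' @return integer in `0..nchar(s)`.
#' @examples
#' lambda_prefix("ba", "ab")  # 1
#' @export
lambda_prefix <- function(y, s) {
  n <- nchar(s)
  if (n == 0L || nchar(y) == 0L) return(0L)
  ss <- strsplit(s, "", fixed = TRUE)[[1]]
  k <- 0L
  for (ch in strsplit(y, "", fixed = TRUE)[[1]]) {
    if (ch == ss[k + 1L]) {
      k <- k + 1L
      if (k == n) break
    }
  }
  k
}

#' Part of a string not yet embedded
#'
#' Drops from `s` the longest prefix embedded by `y`; the embedded prefix
#' concatenated with the result reconstitutes `s`.
#'
#' @inheritParams lambda_prefix
#' @return character scalar (possibly empty).
#' @examples
#' remaining("ba", "ab")  # "b"
#' @export
remaining <- function(y, s) substr(s, lambda_prefix(y, s) + 1L, nchar(s))

#' Prefix of a string outside its longest embeddable suffix
#'
#' Returns `s[1..k]` where `s[(k+1)..]` is the longest suffix of `s` that is
#' a subsequence of `y`, found by a right-to-left greedy scan. Used by the
#' reduction local search: the returned prefix is what a replacement prefix
#' of the solution must still cover.
#'
#' @param s the input string to split.
#' @param y the fixed solution suffix the split is measured against.
#' @return character scalar; concatenated with the dropped suffix it
#'   equals `s`.
#' @examples
#' longest_embedded_suffix_split("abcab", "cb")  # "abca"
#' @export
longest_embedded_suffix_split <- function(s, y) {
  k <- nchar(s)
  if (k == 0L) return("")
  ss <- strsplit(s, "", fixed = TRUE)[[1]]
  if (nchar(y) > 0L) {
    for (ch in rev(strsplit(y, "", fixed = TRUE)[[1]])) {
      if (k > 0L && ch == ss[k]) k <- k - 1L
      if (k == 0L) break
    }
  }
  substr(s, 1L, k)
}

#' Create the empty candidate solution for an instance
#'
#' A candidate solution couples the sequence constructed so far with, per
#' input string, the length of its longest prefix embedded by that sequence
#' (the lambda vector). The candidate is complete when every lambda equals
#' its string length.
#'
#' @param inst an [scs_instance()].
#' @return An object of class `scs_candidate` with fields `seq` (character)
#'   and `lambdas` (integer vector).
#' @export
new_candidate <- function(inst) {
  stopifnot(inherits(inst, "scs_instance"))
  structure(list(seq = "", lambdas = integer(length(inst$strings))),
            class = "scs_candidate")
}

#' @export
print.scs_candidate <- function(x, ...) {
  cat("candidate: |seq| =", nchar(x$seq),
      " lambdas =", paste(x$lambdas, collapse = ","), "\n")
  invisible(x)
}

#' Extend a candidate by one symbol
#'
#' Appends symbol `a` and updates the lambda vector incrementally: each
#' string whose next unembedded symbol equals `a` advances by exactly one.
#' The result is identical to recomputing [lambda_prefix()] from scratch on
#' the extended sequence.
#'
#' @param cand an `scs_candidate` for `inst`.
#' @param a single character, must belong to the instance alphabet.
#' @param inst the [scs_instance()] the candidate refers to.
#' @return the extended `scs_candidate`.
#' @export
advance <- function(cand, a, inst) {
  stopifnot(inherits(cand, "scs_candidate"), inherits(inst, "scs_instance"))
  if (!(a %in% inst$alphabet)) stop("symbol '", a, "' not in alphabet")
  lam <- cand$lambdas
  for (i in seq_along(lam)) {
    if (lam[i] < inst$lengths[i] && inst$chars[[i]][lam[i] + 1L] == a)
      lam[i] <- lam[i] + 1L
  }
  structure(list(seq = paste0(cand$seq, a), lambdas = lam),
            class = "scs_candidate")
}

#' Is a candidate complete?
#'
#' @inheritParams advance
#' @return `TRUE` iff every input string is fully embedded.
#' @export
is_complete <- function(cand, inst) all(cand$lambdas == inst$lengths)

#' Validity check: supersequence of every instance string
#'
#' @param t plain string.
#' @param inst an [scs_instance()].
#' @return `TRUE` iff `embeds(t, s)` for every instance string `s`
#'   (vacuously `TRUE` for an instance with zero strings).
#' @export
is_supersequence_of_all <- function(t, inst) {
  stopifnot(inherits(inst, "scs_instance"))
  all(vapply(inst$strings, function(s) embeds(t, s), logical(1)))
}
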