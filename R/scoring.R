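#' Table of embedding probabilities
#'
#' `P[i, j]` (0-based indices carried as dimnames) is the probability that a
#' fixed string of length `i` is a subsequence of a uniform random string of
#' length `j` over an alphabet of `q` symbols. It satisfies the recurrence
#' \deqn{P(i, j) = \frac{1}{q} P(i-1, j-1) + \left(1 - \frac{1}{q}\right) P(i, j-1)}
#' with `P(0, j) = 1` and `P(i, j) = 0` for `i > j`. The probability does
#' not depend on which fixed string of length `i` is considered, because
#' each random symbol matches any given symbol with probability `1/q`.
#' The `i = 1` row has the closed form `1 - (1 - 1/q)^j`.
#'
#' @param q alphabet size (>= 1).
#' @param imax,jmax table bounds (lengths of the fixed and the random
#'   string, respectively).
#' @return An object of class `scs_prob_table`: list with `q`, `imax`,
#'   `jmax`, the `(imax+1) x (jmax+1)` matrix `P` (dimnames are the 0-based
#'   lengths) and its elementwise natural log `logP`.
#' @examples
#' tab <- build_probability_table(2, 3, 5)
#' tab$P["1", "2"]  # 0.75
#' @export
build_probability_table <- function(q, imax, jmax = imax) {
  if (q < 1) stop("alphabet size q must be >= 1")
  P <- prob_table_cpp(as.integer(q), as.integer(imax), as.integer(jmax))
  dimnames(P) <- list(0:imax, 0:jmax)
  structure(list(q = as.integer(q), imax = as.integer(imax),
                 jmax = as.integer(jmax), P = P, logP = log(P)),
            class = "scs_prob_table")
}

#' @export
print.scs_prob_table <- function(x, ...) {
  cat("embedding-probability table: q =", x$q,
      " i <=", x$imax, " j <=", x$jmax, "\n")
  invisible(x)
}

#' Heuristic value of a partial solution
#'
#' The probability, under the assumption that the input strings are
#' independent, that one common random string of length `j` embeds every
#' remaining (not yet embedded) part of the instance strings:
#' \deqn{h(c) = \prod_i P(r_i, j), \qquad r_i = |s_i| - \lambda_i.}
#' With `length_mode = "max_remaining"` (default) `j` is the largest
#' remaining length of the candidate being evaluated, which keeps the
#' product well-defined per candidate without a global horizon estimate;
#' `length_mode = "fixed"` uses the user-supplied `j`. Beam selection ranks
#' by the log form (`log = TRUE`) to avoid underflow of products over many
#' strings.
#'
#' @param cand an `scs_candidate`.
#' @param inst the corresponding [scs_instance()].
#' @param tab an `scs_prob_table` built with the instance's alphabet size;
#'   its bounds must cover the remaining lengths and the chosen `j`.
#' @param length_mode `"max_remaining"` or `"fixed"`.
#' @param j reference random-string length, required for `"fixed"`.
#' @param log return the log value (sum of log probabilities).
#' @return numeric scalar in `[0, 1]` (or its log); equals 1 iff the
#'   candidate is complete.
#' @export
heuristic_value <- function(cand, inst, tab,
                            length_mode = c("max_remaining", "fixed"),
                            j = NULL, log = FALSE) {
  length_mode <- match.arg(length_mode)
  stopifnot(inherits(cand, "scs_candidate"), inherits(tab, "scs_prob_table"))
  r <- inst$lengths - cand$lambdas
  jj <- if (length_mode == "max_remaining") {
    if (length(r) == 0) 0L else max(r)
  } else {
    if (is.null(j)) stop("length_mode = 'fixed' requires j")
    as.integer(j)
  }
  if (max(r, 0L) > tab$imax || jj > tab$jmax)
    stop("probability table bounds exceeded (need i <= ", max(r, 0L),
         ", j <= ", jj, ")")
  idx <- cbind(r + 1L, jj + 1L)
  if (log) sum(tab$logP[idx]) else prod(tab$P[idx])
}

#' Dominance between candidates at the same beam level
#'
#' Candidate `a` dominates candidate `b` (so `b` can be discarded when `a`
#' is a dominator) iff, at equal constructed length, every embedded-prefix
#' length of `a` is at least that of `b`. The relation is reflexive and
#' transitive; non-strict comparison means exact duplicates of a dominator
#' are pruned too.
#'
#' @param a,b `scs_candidate` objects with `nchar(a$seq) == nchar(b$seq)`.
#' @return logical scalar.
#' @export
dominates <- function(a, b) {
  stopifnot(inherits(a, "scs_candidate"), inherits(b, "scs_candidate"))
  if (nchar(a$seq) != nchar(b$seq))
    stop("dominance is only defined between candidates at the same level")
  all(a$lambdas >= b$lambdas)
}
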