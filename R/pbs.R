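#' Configuration for probabilistic beam search
#'
#' @param kw beam width: maximum number of partial solutions kept per level.
#' @param kb number of dominators: the top-`kb` ranked children enter the
#'   beam unconditionally and serve as references for dominance pruning.
#'   `kb = kw` gives plain deterministic beam search. Defaults to 11,
#'   capped at `kw`.
#' @param mu randomness of selection in `[0, 1]`: with probability `mu` the
#'   next beam member is drawn by linear-ranking sampling over the remaining
#'   pool, otherwise the pool's best is taken. `mu = 0` is purely greedy.
#' @param length_mode,j reference length for the heuristic product; see
#'   [heuristic_value()].
#' @param max_levels safety cap on construction levels; `0` means
#'   "total instance length + 1", which always suffices.
#' @param seed optional integer seed applied at the start of [pbs_solve()];
#'   `NULL` leaves the current RNG state untouched.
#' @return a list of class `pbs_config`.
#' @details Defaults follow the settings that the sensitivity analysis of
#'   the method singles out as robust: a beam width of 100 and 11
#'   dominators; the selection randomness defaults to 0.1 and is ramped by
#'   the perturbation schedule where applicable.
#' @export
pbs_config <- function(kw = 100L, kb = min(11L, kw), mu = 0.1,
                       length_mode = c("max_remaining", "fixed"), j = NULL,
                       max_levels = 0L, seed = NULL) {
  length_mode <- match.arg(length_mode)
  stopifnot(kw >= 1, kb >= 0, kb <= kw, mu >= 0, mu <= 1)
  if (length_mode == "fixed" && is.null(j))
    stop("length_mode = 'fixed' requires j")
  structure(list(kw = as.integer(kw), kb = as.integer(kb), mu = mu,
                 length_mode = length_mode, j = j,
                 max_levels = as.integer(max_levels), seed = seed),
            class = "pbs_config")
}

.jmode <- function(cfg) if (cfg$length_mode == "fixed") as.integer(cfg$j) else -1L

#' Does a symbol contribute to a candidate?
#'
#' A symbol contributes iff appending it embeds a new symbol of at least one
#' input string, i.e. it equals the next unembedded symbol of some string.
#' Beam construction only generates contributing extensions.
#'
#' @inheritParams advance
#' @return logical scalar.
#' @export
contributes <- function(cand, a, inst) {
  stopifnot(inherits(cand, "scs_candidate"))
  for (i in seq_along(cand$lambdas)) {
    li <- cand$lambdas[i]
    if (li < inst$lengths[i] && inst$chars[[i]][li + 1L] == a) return(TRUE)
  }
  FALSE
}

#' Extend every beam member with every contributing symbol
#'
#' Produces the auxiliary child set of one beam level: for each member (in
#' beam order) and each alphabet symbol (in alphabet order) with
#' [contributes()] true, the advanced candidate. If a child is complete it
#' is reported immediately; by construction it is the first complete child
#' in generation order.
#'
#' @param members list of `scs_candidate`s, all of equal constructed length.
#' @param inst the [scs_instance()].
#' @return list with `children` (list of candidates, insertion order
#'   preserved) and `complete` (the first complete child, or `NULL`).
#' @export
extend_beam <- function(members, inst) {
  children <- list()
  for (c in members) {
    for (a in inst$alphabet) {
      if (!contributes(c, a, inst)) next
      ch <- advance(c, a, inst)
      if (is_complete(ch, inst)) return(list(children = children, complete = ch))
      children[[length(children) + 1L]] <- ch
    }
  }
  list(children = children, complete = NULL)
}

#' Draw one candidate by linear-ranking selection
#'
#' Baker-style linear ranking: in a pool of `N` candidates sorted best
#' first, the element at rank `r` is chosen with probability proportional
#' to `N - r + 1`.
#'
#' @param ranked nonempty list (or vector) sorted by decreasing quality.
#' @return one element of `ranked`.
#' @seealso [linear_rank_index()] for the bare rank draw.
#' @export
linear_rank_sample <- function(ranked) {
  if (length(ranked) == 0) stop("empty pool")
  ranked[[linear_rank_index(length(ranked))]]
}

#' @rdname linear_rank_sample
#' @param n pool size.
#' @return [linear_rank_index()]: an integer rank in `1..n` (1 = best).
#' @export
linear_rank_index <- function(n) lr_sample_cpp(as.integer(n))

# rank children: log-heuristic desc, then total progress desc, then
# insertion order (stable sort)
.rank_children <- function(children, inst, tab, cfg) {
  h <- vapply(children, heuristic_value, numeric(1), inst = inst, tab = tab,
              length_mode = cfg$length_mode, j = cfg$j, log = TRUE)
  slam <- vapply(children, function(c) sum(c$lambdas), numeric(1))
  order(-h, -slam)
}

#' Select the next beam from a child set
#'
#' Reference implementation of one beam-selection step: children are ranked
#' by log heuristic value (ties: larger total progress first, then
#' insertion order); the best `min(kb, N)` become dominators and enter the
#' beam; then, until the beam holds `kw` members or the pool is exhausted,
#' the next member is taken greedily or — with probability `mu` — by
#' linear-ranking sampling, and discarded instead of added if a dominator
#' dominates it. Selection is without replacement; a discarded candidate
#' consumes a draw but not a beam slot.
#'
#' @param children nonempty list of `scs_candidate`s at one level.
#' @param cfg a [pbs_config()].
#' @param inst the [scs_instance()].
#' @param tab an `scs_prob_table` covering the instance lengths.
#' @return list of selected `scs_candidate`s (the new beam, size <= `kw`).
#' @export
select_beam <- function(children, cfg, inst, tab) {
  stopifnot(length(children) >= 1)
  ord <- .rank_children(children, inst, tab, cfg)
  N <- length(ord)
  d <- min(cfg$kb, N)
  beam <- children[ord[seq_len(d)]]
  dominators <- beam
  pool <- ord[setdiff(seq_len(N), seq_len(d))]
  while (length(beam) < cfg$kw && length(pool) > 0) {
    pos <- if (cfg$mu > 0 && runif(1) < cfg$mu) linear_rank_index(length(pool)) else 1L
    ci <- pool[pos]
    pool <- pool[-pos]
    cand <- children[[ci]]
    dominated <- any(vapply(dominators, dominates, logical(1), b = cand))
    if (!dominated) beam[[length(beam) + 1L]] <- cand
  }
  if (length(beam) == 0) beam <- children[ord[1]]  # liveness guard
  beam
}

#' Solve an instance by probabilistic beam search
#'
#' Level-synchronous construction: starting from the empty candidate, every
#' beam member is extended with every contributing symbol; the first child
#' that embeds all strings is returned; otherwise [select_beam()] keeps up
#' to `kw` children and the next level starts. With `mu = 0` and `kb = kw`
#' the algorithm degenerates to deterministic beam search and its output is
#' seed-independent.
#'
#' @param inst an [scs_instance()].
#' @param cfg a [pbs_config()].
#' @param seed integer seed (overrides `cfg$seed`); `NULL` leaves the RNG
#'   state untouched.
#' @param engine `"cpp"` (default, fast path) or `"r"` (reference stepping
#'   through [extend_beam()] / [select_beam()]; intended for testing). The
#'   two engines produce identical output in deterministic mode (`mu = 0`).
#' @return the constructed supersequence (character scalar); it always
#'   satisfies [is_supersequence_of_all()].
#' @examples
#' inst <- scs_instance(c("ab", "ba"))
#' pbs_solve(inst, pbs_config(kw = 2, kb = 2, mu = 0))
#' @export
pbs_solve <- function(inst, cfg = pbs_config(), seed = cfg$seed,
                      engine = c("cpp", "r")) {
  stopifnot(inherits(inst, "scs_instance"), inherits(cfg, "pbs_config"))
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (engine == "cpp") {
    res <- pbs_solve_cpp(.enc0(inst), length(inst$alphabet), cfg$kw, cfg$kb,
                         cfg$mu, .jmode(cfg), cfg$max_levels)
    if (!res$ok) stop("beam search exceeded max_levels")
    out <- .dec(res$seq, inst$alphabet)
  } else {
    imax <- max(inst$lengths)
    jmax <- max(imax, if (cfg$length_mode == "fixed") cfg$j else 0L)
    tab <- build_probability_table(length(inst$alphabet), imax, jmax)
    beam <- list(new_candidate(inst))
    maxlev <- if (cfg$max_levels > 0) cfg$max_levels else sum(inst$lengths) + 1L
    out <- NULL
    for (level in seq_len(maxlev)) {
      ext <- extend_beam(beam, inst)
      if (!is.null(ext$complete)) { out <- ext$complete$seq; break }
      if (length(ext$children) == 0) stop("no contributing extension found")
      beam <- select_beam(ext$children, cfg, inst, tab)
    }
    if (is.null(out)) stop("beam search exceeded max_levels")
  }
  stopifnot(is_supersequence_of_all(out, inst))
  out
}
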