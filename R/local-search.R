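#' Linear randomness schedule for the perturbation local search
#'
#' The repair beam search used inside [pbs_perturbation()] starts fully
#' greedy and becomes progressively more explorative: its selection
#' randomness grows linearly from `mu_start` in the first iteration to
#' `mu_end` in the last one (defaults 0 and 0.65), so that early rounds
#' search close to the incumbent and later rounds reach dissimilar regions.
#'
#' @param iterations number of perturbation rounds (>= 1).
#' @param mu_start,mu_end randomness at the first and last round.
#' @return a list of class `perturbation_schedule`.
#' @export
perturbation_schedule <- function(iterations = 100L, mu_start = 0.0,
                                  mu_end = 0.65) {
  stopifnot(iterations >= 1, mu_start >= 0, mu_start <= mu_end, mu_end <= 1)
  structure(list(iterations = as.integer(iterations), mu_start = mu_start,
                 mu_end = mu_end),
            class = "perturbation_schedule")
}

#' @rdname perturbation_schedule
#' @param sched a `perturbation_schedule`.
#' @param k 1-based round index.
#' @return `mu_at()`: the randomness used at round `k`.
#' @export
mu_at <- function(sched, k) {
  stopifnot(k >= 1, k <= sched$iterations)
  sched$mu_start + (k - 1) * (sched$mu_end - sched$mu_start) /
    max(1L, sched$iterations - 1L)
}

#' Shorten a supersequence by split-and-resolve reduction
#'
#' For every split point `p` (scanned ascending from 1 to `nchar(z) - 1`)
#' the suffix `z[(p+1)..]` is kept fixed; for each input string the prefix
#' not covered by that suffix ([longest_embedded_suffix_split()]) forms a
#' sub-instance, which beam search re-solves. If the re-solved prefix is
#' strictly shorter than `p`, it replaces the original prefix and the scan
#' restarts from the improved solution. Split points whose sub-instance
#' provably cannot beat `p` (some uncovered prefix is already `>= p` long)
#' are skipped without consuming RNG draws.
#'
#' @param inst an [scs_instance()].
#' @param z a valid supersequence of `inst` (checked).
#' @param cfg [pbs_config()] for the inner beam search; the default runs it
#'   deterministically (`mu = 0`), keeping the many sub-solves cheap.
#' @param seed optional integer seed set before the scan.
#' @param time_budget wall-clock budget in seconds (`Inf` = none); on
#'   expiry the current sub-instance finishes and the incumbent is
#'   returned.
#' @return a valid supersequence with `nchar(result) <= nchar(z)`.
#' @examples
#' inst <- scs_instance(c("ab", "ba"))
#' pbs_reduction(inst, "abab")  # length 3
#' @export
pbs_reduction <- function(inst, z, cfg = pbs_config(mu = 0), seed = NULL,
                          time_budget = Inf) {
  stopifnot(inherits(inst, "scs_instance"))
  if (!is_supersequence_of_all(z, inst))
    stop("z is not a supersequence of the instance")
  if (!is.null(seed)) set.seed(as.integer(seed))
  z0 <- match(strsplit(z, "", fixed = TRUE)[[1]], inst$alphabet) - 1L
  if (anyNA(z0)) stop("z contains characters outside the instance alphabet")
  res <- reduction_cpp(.enc0(inst), length(inst$alphabet), z0, cfg$kw, cfg$kb,
                       cfg$mu, .jmode(cfg),
                       if (is.finite(time_budget)) time_budget else -1)
  out <- .dec(res, inst$alphabet)
  stopifnot(nchar(out) <= nchar(z), is_supersequence_of_all(out, inst))
  out
}

#' Shorten a supersequence by perturb-and-repair local search
#'
#' Each round replaces one uniformly chosen symbol of the incumbent by a
#' different uniformly chosen symbol, keeps the mutated prefix up to and
#' including that position, and repairs feasibility by beam-search solving
#' the sub-instance of string parts not embedded by the prefix. The
#' repaired solution replaces the incumbent only if strictly shorter. The
#' repair randomness follows `sched` (see [perturbation_schedule()]).
#'
#' @inheritParams pbs_reduction
#' @param sched a [perturbation_schedule()].
#' @param cfg [pbs_config()] for the repair beam search; its `mu` is
#'   overridden by the schedule.
#' @return a valid supersequence with `nchar(result) <= nchar(z)`. With a
#'   one-symbol alphabet no mutation exists and `z` is returned unchanged
#'   with a warning.
#' @export
pbs_perturbation <- function(inst, z, sched = perturbation_schedule(),
                             cfg = pbs_config(), seed = NULL,
                             time_budget = Inf) {
  stopifnot(inherits(inst, "scs_instance"),
            inherits(sched, "perturbation_schedule"))
  if (!is_supersequence_of_all(z, inst))
    stop("z is not a supersequence of the instance")
  if (length(inst$alphabet) < 2) {
    warning("alphabet of size 1: no replacement symbol exists; z returned unchanged")
    return(z)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  z0 <- match(strsplit(z, "", fixed = TRUE)[[1]], inst$alphabet) - 1L
  if (anyNA(z0)) stop("z contains characters outside the instance alphabet")
  res <- perturbation_cpp(.enc0(inst), length(inst$alphabet), z0,
                          sched$iterations, sched$mu_start, sched$mu_end,
                          cfg$kw, cfg$kb, .jmode(cfg),
                          if (is.finite(time_budget)) time_budget else -1)
  out <- .dec(res, inst$alphabet)
  stopifnot(nchar(out) <= nchar(z), is_supersequence_of_all(out, inst))
  out
}
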