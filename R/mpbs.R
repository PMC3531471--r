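#' Configuration for the multilevel anytime driver
#'
#' @param time_budget wall-clock budget in seconds (> 0). The deadline is
#'   checked between sub-instance solves; a phase in progress finishes its
#'   current sub-instance before the loop exits, so overshoot is bounded by
#'   one sub-solve.
#' @param initial_runs number of seeded beam-search constructions whose
#'   shortest result seeds the local-search loop.
#' @param construction_cfg,reduction_cfg,perturbation_cfg [pbs_config()]s
#'   for the three roles of beam search. Construction defaults to the
#'   stochastic setting (`mu = 0.1`), reduction to the deterministic one
#'   (`mu = 0`); the perturbation `mu` is governed by the schedule.
#' @param schedule a [perturbation_schedule()] for the perturbation phase.
#' @param seed integer base seed; every phase derives its own seed from it
#'   and the round index, so a run is reproducible and each round's
#'   randomness does not depend on how many rounds fit in the budget.
#' @param max_rounds optional cap on reduction+perturbation rounds
#'   (`Inf` = budget-only); with a non-binding budget it makes runs fully
#'   deterministic end to end.
#' @param target_length optional early-stop bound: the driver returns as
#'   soon as the incumbent reaches this length (e.g. a known optimum or
#'   lower bound). Independently, the driver always stops at the universal
#'   lower bound `max(nchar(strings))`, which certifies optimality.
#' @return a list of class `mpbs_config`.
#' @export
mpbs_config <- function(time_budget = 30, initial_runs = 5L,
                        construction_cfg = pbs_config(),
                        reduction_cfg = pbs_config(mu = 0),
                        perturbation_cfg = pbs_config(),
                        schedule = perturbation_schedule(),
                        seed = 1L, max_rounds = Inf, target_length = NULL) {
  stopifnot(time_budget > 0, initial_runs >= 1)
  structure(list(time_budget = time_budget,
                 initial_runs = as.integer(initial_runs),
                 construction_cfg = construction_cfg,
                 reduction_cfg = reduction_cfg,
                 perturbation_cfg = perturbation_cfg,
                 schedule = schedule,
                 seed = as.integer(seed), max_rounds = max_rounds,
                 target_length = target_length),
            class = "mpbs_config")
}

# per-phase seed derivation; kept below 2^31 - 1
.derive_seed <- function(base, round, phase) {
  as.integer((as.double(base) + 10007 * round + 5003 * phase) %% 2147483647)
}

#' Multilevel probabilistic beam search (anytime)
#'
#' Runs `initial_runs` seeded beam-search constructions and keeps the
#' shortest result; then alternates the reduction and perturbation local
#' searches on the incumbent until the wall-clock budget (or `max_rounds`,
#' or `target_length`) is reached, recording every improvement. The
#' incumbent never worsens, so the algorithm can be stopped at any time.
#'
#' @param inst an [scs_instance()].
#' @param cfg an [mpbs_config()].
#' @return list of class `mpbs_result` with elements `solution` (a valid
#'   supersequence), `length`, and `trace`: a data frame with columns
#'   `elapsed_sec`, `best_length`, `phase` (one row per improvement;
#'   `best_length` is nonincreasing and its last entry equals
#'   `nchar(solution)`).
#' @examples
#' inst <- scs_instance(c("ab", "ba"))
#' mpbs_solve(inst, mpbs_config(time_budget = 1, seed = 7))$length
#' @export
mpbs_solve <- function(inst, cfg = mpbs_config()) {
  stopifnot(inherits(inst, "scs_instance"), inherits(cfg, "mpbs_config"))
  t0 <- proc.time()[["elapsed"]]
  elapsed <- function() proc.time()[["elapsed"]] - t0
  deadline <- cfg$time_budget
  lb <- max(inst$lengths)
  target <- max(lb, if (is.null(cfg$target_length)) lb else cfg$target_length)

  events <- list()
  note <- function(len, phase) {
    events[[length(events) + 1L]] <<-
      data.frame(elapsed_sec = elapsed(), best_length = len, phase = phase)
  }

  best <- NULL
  for (k in seq_len(cfg$initial_runs)) {
    z <- pbs_solve(inst, cfg$construction_cfg, seed = .derive_seed(cfg$seed, k, 0L))
    if (is.null(best) || nchar(z) < nchar(best)) {
      best <- z
      note(nchar(best), "construction")
    }
    if (nchar(best) <= target || elapsed() >= deadline) break
  }

  round <- 0L
  while (nchar(best) > target && elapsed() < deadline &&
         round < cfg$max_rounds) {
    round <- round + 1L
    z <- pbs_reduction(inst, best, cfg$reduction_cfg,
                       seed = .derive_seed(cfg$seed, round, 1L),
                       time_budget = max(deadline - elapsed(), 0.001))
    if (nchar(z) < nchar(best)) { best <- z; note(nchar(best), "reduction") }
    if (nchar(best) <= target || elapsed() >= deadline) break
    z <- pbs_perturbation(inst, best, cfg$schedule,
                          cfg$perturbation_cfg,
                          seed = .derive_seed(cfg$seed, round, 2L),
                          time_budget = max(deadline - elapsed(), 0.001))
    if (nchar(z) < nchar(best)) { best <- z; note(nchar(best), "perturbation") }
  }

  trace <- do.call(rbind, events)
  structure(list(solution = best, length = nchar(best), trace = trace),
            class = "mpbs_result")
}

#' @export
print.mpbs_result <- function(x, ...) {
  cat("MPBS result: length", x$length, "after", nrow(x$trace),
      "improvement(s)\n")
  invisible(x)
}

#' Relative percentage difference from a best-known length
#'
#' `100 * (length - best_known) / best_known`; negative when a new best is
#' found.
#'
#' @param length attained supersequence length.
#' @param best_known positive reference length.
#' @return numeric scalar (a percentage).
#' @examples
#' rpd(103, 100)  # 3
#' @export
rpd <- function(length, best_known) {
  if (any(best_known <= 0)) stop("best_known must be positive")
  100 * (length - best_known) / best_known
}

#' Export an anytime trace as CSV
#'
#' Writes the improvement log with header `elapsed_sec,best_length,phase`.
#'
#' @param result an `mpbs_result` (or a data frame shaped like its trace).
#' @param path destination file.
#' @return invisibly, `path`.
#' @export
write_trace_csv <- function(result, path) {
  tr <- if (inherits(result, "mpbs_result")) result$trace else result
  stopifnot(all(c("elapsed_sec", "best_length", "phase") %in% names(tr)))
  write.csv(tr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a solution sequence
#'
#' Writes a single-record FASTA file when `path` ends in `.fa`/`.fasta`,
#' otherwise one plain-text line.
#'
#' @param solution character scalar.
#' @param path destination file.
#' @param id record identifier for FASTA output.
#' @return invisibly, `path`.
#' @export
write_solution <- function(solution, path, id = "scs") {
  if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE)) {
    writeLines(c(paste0(">", id), solution), path)
  } else {
    writeLines(solution, path)
  }
  invisible(path)
}
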