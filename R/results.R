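#' Summarise benchmark runs as mean and sd of RPD
#'
#' Takes per-run records and a best-known length per instance and reports,
#' per algorithm (and per `group` column if present, e.g. alphabet size),
#' the mean and standard deviation of the relative percentage difference
#' ([rpd()]) from best-known. When no best-known table is supplied, the
#' best length observed in `results` for each instance is used as its
#' reference, so the best algorithm scores 0.
#'
#' @param results data frame with columns `instance_id`, `algorithm`,
#'   `length` (and optionally `group`); typically read from the JSON
#'   records written by the command-line front end.
#' @param best_known optional data frame with columns `instance_id`,
#'   `length`. Every `instance_id` in `results` must be present; missing
#'   ids are an error listing the ids.
#' @return data frame with columns (`group`,) `algorithm`, `n`,
#'   `mean_rpd`, `sd_rpd`.
#' @export
evaluate_results <- function(results, best_known = NULL) {
  stopifnot(all(c("instance_id", "algorithm", "length") %in% names(results)))
  if (is.null(best_known)) {
    best <- tapply(results$length, results$instance_id, min)
  } else {
    stopifnot(all(c("instance_id", "length") %in% names(best_known)))
    best <- stats::setNames(best_known$length, best_known$instance_id)
    missing <- setdiff(unique(results$instance_id), names(best))
    if (length(missing) > 0)
      stop("instance_id(s) missing from best-known table: ",
           paste(missing, collapse = ", "))
  }
  results$rpd <- rpd(results$length, as.numeric(best[as.character(results$instance_id)]))
  keys <- if ("group" %in% names(results)) c("group", "algorithm") else "algorithm"
  agg <- stats::aggregate(results["rpd"], results[keys], function(v) {
    c(n = length(v), mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0)
  })
  out <- cbind(agg[keys],
               n = agg$rpd[, "n"],
               mean_rpd = agg$rpd[, "mean"],
               sd_rpd = agg$rpd[, "sd"])
  out[do.call(order, out[keys]), , drop = FALSE]
}
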