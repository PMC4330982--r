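#' Configuration of the scoring-sufficiency analysis
#'
#' The analysis asks how many cells must be scored before an individual's
#' mean foci rate stabilises: at every `checkpoint` cells the running mean is
#' compared to the final (reference) mean as a percentage, 100% meaning
#' exact agreement, and an individual's value counts as stable when it lies
#' within `tolerance` of 100%.
#'
#' @param checkpoint Checkpoint interval, cells (default 200).
#' @param tolerance Relative tolerance band around exact agreement
#'   (default 0.15, i.e. +/- 15%).
#' @param reference Reference cell count the final mean is computed over
#'   (default 1000); individuals with fewer cells use all available cells.
#' @param required_fraction Fraction of individuals that must sit inside the
#'   band for a checkpoint to qualify as sufficient (default 0.75).
#' @return An object of class `sufficiency_config`.
#' @export
sufficiency_config <- function(checkpoint = 200, tolerance = 0.15,
                               reference = 1000, required_fraction = 0.75) {
  stopifnot(checkpoint >= 1, tolerance > 0, tolerance < 1,
            reference >= checkpoint,
            required_fraction > 0, required_fraction <= 1)
  structure(list(checkpoint = as.integer(checkpoint), tolerance = tolerance,
                 reference = as.integer(reference),
                 required_fraction = required_fraction),
            class = "sufficiency_config")
}

#' Cumulative-mean agreement curve for one individual and condition
#'
#' Cells are taken in their original scoring order. At each checkpoint `n`
#' the agreement is `100 * mean(first n counts) / mean(first N counts)`,
#' where `N = min(reference, cells available)`; the final checkpoint uses
#' all `N` cells and therefore equals exactly 100%. An all-zero reference
#' mean leaves the agreement undefined: the curve is flagged invalid and is
#' skipped by [fraction_within_tolerance()].
#'
#' @param counts Integer vector of per-cell foci counts in scoring order.
#' @param config A [sufficiency_config()].
#' @param individual_id,condition Optional labels carried on the curve.
#' @return An object of class `sufficiency_curve`: list with `checkpoints`
#'   (data frame `n_cells`, `agreement_pct`), `n_reference`, `valid` and the
#'   labels.
#' @examples
#' cumulative_agreement(c(1, 0, 2, 0, 1, 2),
#'                      sufficiency_config(checkpoint = 2, reference = 6))
#' @export
cumulative_agreement <- function(counts, config = sufficiency_config(),
                                 individual_id = NA_character_,
                                 condition = NA_character_) {
  stopifnot(is.numeric(counts), length(counts) >= 1, all(counts >= 0))
  N <- min(config$reference, length(counts))
  if (N < config$checkpoint) {
    stop("fewer cells than one checkpoint interval", call. = FALSE)
  }
  ns <- seq(config$checkpoint, N, by = config$checkpoint)
  if (ns[length(ns)] != N) ns <- c(ns, N)
  cum <- cumsum(counts[seq_len(N)])
  final_mean <- cum[N] / N
  valid <- final_mean > 0
  agreement <- if (valid) 100 * (cum[ns] / ns) / final_mean else
    rep(NA_real_, length(ns))
  # the self-ratio at n = N is identically 1; keep it exact
  if (valid) agreement[ns == N] <- 100
  structure(list(
    individual_id = individual_id, condition = condition,
    checkpoints = data.frame(n_cells = as.integer(ns),
                             agreement_pct = agreement),
    n_reference = as.integer(N), valid = valid
  ), class = "sufficiency_curve")
}

#' Agreement curves for a whole cohort
#'
#' Splits a per-cell record table by individual and condition and computes
#' one [cumulative_agreement()] curve per combination.
#'
#' @param records Per-cell count table (shared schema; see
#'   [generate_cohort()]).
#' @param config A [sufficiency_config()].
#' @return List of `sufficiency_curve` objects.
#' @export
cohort_sufficiency <- function(records, config = sufficiency_config()) {
  check_records(records)
  split_f <- interaction(records$individual_id, records$condition, drop = TRUE)
  lapply(split(records, split_f), function(d) {
    d <- d[order(d$cell_index), ]
    cumulative_agreement(d$foci_count, config,
                         individual_id = d$individual_id[1],
                         condition = d$condition[1])
  })
}

#' Fraction of individuals inside the tolerance band per checkpoint
#'
#' @param curves List of `sufficiency_curve` objects (invalid curves -- with
#'   an all-zero reference mean -- are excluded with a warning).
#' @param config A [sufficiency_config()].
#' @return Data frame `n_cells`, `pct_within` (percentage of individuals
#'   with `|agreement - 100| <= 100 * tolerance`) and `n_curves`.
#' @export
fraction_within_tolerance <- function(curves, config = sufficiency_config()) {
  if (length(curves) == 0) stop("empty cohort", call. = FALSE)
  invalid <- !vapply(curves, function(cv) cv$valid, logical(1))
  if (any(invalid)) {
    warning(sum(invalid), " curve(s) with zero reference mean excluded")
    curves <- curves[!invalid]
  }
  if (length(curves) == 0) stop("no valid curves", call. = FALSE)
  cp <- do.call(rbind, lapply(curves, function(cv) cv$checkpoints))
  band <- 100 * config$tolerance
  within <- abs(cp$agreement_pct - 100) <= band
  ns <- sort(unique(cp$n_cells))
  data.frame(
    n_cells = ns,
    pct_within = vapply(ns, function(n) 100 * mean(within[cp$n_cells == n]),
                        numeric(1)),
    n_curves = vapply(ns, function(n) sum(cp$n_cells == n), numeric(1))
  )
}

#' Smallest sufficient cell count
#'
#' @param tolerance_table Output of [fraction_within_tolerance()].
#' @param required_fraction Required fraction of individuals inside the
#'   band.
#' @return The smallest checkpoint `n_cells` whose `pct_within` reaches the
#'   requirement, or `NA_integer_` (sentinel) if none does.
#' @export
minimum_cells <- function(tolerance_table, required_fraction = 0.75) {
  stopifnot(nrow(tolerance_table) > 0)
  ok <- tolerance_table$pct_within >= 100 * required_fraction
  if (!any(ok)) return(NA_integer_)
  as.integer(min(tolerance_table$n_cells[ok]))
}
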