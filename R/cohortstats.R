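#' Per-individual mean foci rates
#'
#' Computes the arithmetic mean foci count per cell for every individual and
#' condition, together with the number of cells it is based on. Individuals
#' scored on fewer than `min_cells` cells are flagged (`sufficient = FALSE`)
#' but retained; the caller decides whether to drop them.
#'
#' @param records Per-cell count table (shared schema).
#' @param min_cells Minimum cells for a reliable rate (default 600, the
#'   sufficiency analysis' working minimum).
#' @return Data frame `individual_id`, `group`, `condition`, `mean_foci`,
#'   `n_cells`, `sufficient`.
#' @export
summarize_individuals <- function(records, min_cells = 600) {
  check_records(records)
  if (nrow(records) == 0) {
    warning("empty record table")
    return(data.frame(individual_id = character(0), group = character(0),
                      condition = character(0), mean_foci = numeric(0),
                      n_cells = integer(0), sufficient = logical(0)))
  }
  f <- interaction(records$individual_id, records$group, records$condition,
                   drop = TRUE, sep = "\r")
  tot <- rowsum(as.numeric(records$foci_count), f)
  n <- as.vector(table(f)[rownames(tot)])
  parts <- do.call(rbind, strsplit(rownames(tot), "\r", fixed = TRUE))
  out <- data.frame(
    individual_id = parts[, 1], group = parts[, 2], condition = parts[, 3],
    mean_foci = as.vector(tot) / n, n_cells = as.integer(n),
    sufficient = n >= min_cells, stringsAsFactors = FALSE
  )
  out <- out[order(out$group, out$individual_id, out$condition), ]
  rownames(out) <- NULL
  out
}

#' Fit a Gaussian to per-individual foci rates
#'
#' Two fit methods are provided. `"moment"` (default) takes the sample mean
#' and sample SD (denominator `n - 1`) -- deterministic and the reference
#' choice. `"binned"` reproduces the histogram procedure: rates are binned
#' at `bin_width` (default: Freedman-Diaconis) and a three-parameter
#' Gaussian `A * exp(-(x - mu)^2 / (2 sigma^2))` is least-squares fitted to
#' the bin counts; because far-out bins hold few counts this fit is robust
#' to a contaminating outlier subpopulation.
#'
#' @param values Numeric vector of per-individual mean foci rates (n >= 3).
#' @param method `"moment"` or `"binned"`.
#' @param bin_width Bin width (foci/cell) for the binned fit; `NULL` chooses
#'   the Freedman-Diaconis width.
#' @param group,condition Optional labels recorded with the fit.
#' @return An object of class `cohort_fit`: list with `mu`, `sigma`, `n`,
#'   `method`, `bin_width`, `group`, `condition`.
#' @examples
#' fit_cohort_distribution(c(1, 2, 3))  # mu = 2, sigma = 1
#' @export
fit_cohort_distribution <- function(values,
                                    method = c("moment", "binned"),
                                    bin_width = NULL,
                                    group = NA_character_,
                                    condition = NA_character_) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  if (sd(values) == 0) stop("zero variance: Gaussian fit undefined",
                            call. = FALSE)
  if (method == "moment") {
    fit <- list(mu = mean(values), sigma = sd(values), n = length(values),
                method = "moment", bin_width = NA_real_)
  } else {
    if (is.null(bin_width)) {
      bin_width <- 2 * IQR(values) / length(values)^(1 / 3)
      if (bin_width <= 0) bin_width <- diff(range(values)) / 10
    }
    lo <- floor(min(values) / bin_width) * bin_width
    breaks <- seq(lo, max(values) + bin_width, by = bin_width)
    hg <- graphics::hist(values, breaks = breaks, plot = FALSE)
    df <- data.frame(x = hg$mids, y = hg$counts)
    start <- list(A = max(df$y), mu = median(values),
                  sigma = max(mad(values), bin_width))
    nfit <- minpack.lm::nlsLM(
      y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)), data = df, start = start,
      lower = c(A = 0, mu = -Inf, sigma = bin_width / 10),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(nfit)
    fit <- list(mu = unname(cf["mu"]), sigma = abs(unname(cf["sigma"])),
                n = length(values), method = "binned-least-squares",
                bin_width = bin_width)
  }
  fit$group <- group; fit$condition <- condition
  structure(fit, class = "cohort_fit")
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat(sprintf("Gaussian fit (%s): mu = %.3f, sigma = %.3f foci/cell, n = %d\n",
              x$method, x$mu, x$sigma, x$n))
  invisible(x)
}

# Lilliefors statistic: KS distance of the sample against a Gaussian with
# estimated mean and SD
lilliefors_stat <- function(x) {
  n <- length(x)
  z <- pnorm(sort(x), mean(x), sd(x))
  i <- seq_len(n)
  max(i / n - z, z - (i - 1) / n)
}

#' Monte-Carlo null distribution of the Lilliefors statistic
#'
#' Simulates the distribution of the Kolmogorov-Smirnov distance with
#' estimated parameters under Gaussian sampling; used as the reference for
#' the Lilliefors p-value. Computing the bank once and reusing it across
#' many tests of the same sample size is both faster and exactly
#' reproducible.
#'
#' @param n Sample size.
#' @param reps Number of null replicates (default 10000).
#' @param seed Optional seed.
#' @return Numeric vector of `reps` null statistics.
#' @export
lilliefors_null_bank <- function(n, reps = 10000, seed = NULL) {
  stopifnot(n >= 5, reps >= 100)
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(reps), function(i) lilliefors_stat(rnorm(n)), numeric(1))
}

#' Normality tests for per-individual foci rates
#'
#' Applies the Kolmogorov-Smirnov test against the fitted Gaussian and the
#' Lilliefors test (KS with estimated parameters) whose p-value is obtained
#' from a seeded Monte-Carlo null of the statistic rather than a table
#' approximation.
#'
#' @param values Numeric vector, n >= 5, not all equal.
#' @param reps Monte-Carlo replicates for the Lilliefors null.
#' @param seed Seed for the Monte-Carlo null.
#' @param null_bank Optional precomputed [lilliefors_null_bank()] for
#'   `length(values)`; overrides `reps`/`seed`.
#' @return List with `ks_p`, `lilliefors_p` and the observed statistic
#'   `lilliefors_d`.
#' @export
test_normality <- function(values, reps = 10000, seed = NULL,
                           null_bank = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 5) stop("need at least 5 values", call. = FALSE)
  if (sd(values) == 0) stop("all values tied: normality test undefined",
                            call. = FALSE)
  ks_p <- suppressWarnings(
    ks.test(values, "pnorm", mean(values), sd(values))$p.value)
  d <- lilliefors_stat(values)
  if (is.null(null_bank)) {
    null_bank <- lilliefors_null_bank(length(values), reps, seed)
  }
  lf_p <- (1 + sum(null_bank >= d)) / (length(null_bank) + 1)
  list(ks_p = ks_p, lilliefors_p = lf_p, lilliefors_d = d)
}

#' Compare the foci rates of two groups
#'
#' Two-sided two-sample t-test of the per-individual mean rates plus the
#' relative increase of the patient mean over the healthy mean, reported at
#' one decimal as a percentage.
#'
#' @param hi_values Per-individual rates of the healthy group.
#' @param rc_values Per-individual rates of the patient group.
#' @param var_equal Passed to [stats::t.test()] (default Welch).
#' @return List with `t`, `df`, `p`, `mean_hi`, `mean_rc` and
#'   `relative_increase_pct` (`NA` with a warning if the healthy mean is 0).
#' @examples
#' compare_groups(c(0.48, 0.49, 0.50), c(0.58, 0.59, 0.60))
#' @export
compare_groups <- function(hi_values, rc_values, var_equal = FALSE) {
  stopifnot(length(hi_values) >= 2, length(rc_values) >= 2)
  tt <- t.test(rc_values, hi_values, var.equal = var_equal)
  m_hi <- mean(hi_values); m_rc <- mean(rc_values)
  rel <- if (m_hi == 0) {
    warning("healthy-group mean is zero: relative increase undefined")
    NA_real_
  } else {
    round(100 * (m_rc - m_hi) / m_hi, 1)
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_hi = m_hi, mean_rc = m_rc,
       relative_increase_pct = rel)
}

#' Standard-deviation exceedance calls against a reference distribution
#'
#' For each individual the call `k` is the largest `j` in 1..3 with
#' `value > mu + j * sigma` of the reference Gaussian, else 0. Calls are
#' one-sided above the mean: radiosensitivity outliers are individuals with
#' increased foci rates, and the 2 and 3 SD cut-offs correspond to the
#' upper tails of the 95% and 99% intervals.
#'
#' @param summaries Summary table from [summarize_individuals()].
#' @param reference A `cohort_fit` used as the reference distribution.
#' @param condition Condition to classify on.
#' @return Data frame `individual_id`, `group`, `condition`,
#'   `reference_group`, `value`, `k`, `direction`.
#' @export
classify_outliers <- function(summaries, reference, condition) {
  stopifnot(inherits(reference, "cohort_fit"))
  condition <- check_condition(condition)
  s <- summaries[summaries$condition == condition, , drop = FALSE]
  k <- integer(nrow(s))
  for (j in 1:3) k[s$mean_foci > reference$mu + j * reference$sigma] <- j
  data.frame(
    individual_id = s$individual_id, group = s$group, condition = condition,
    reference_group = reference$group, value = s$mean_foci, k = k,
    direction = "above", stringsAsFactors = FALSE
  )
}

#' Exceedance percentage matrix
#'
#' Percentage of each evaluated group falling more than 1, 2 and 3 reference
#' SDs above the reference mean, for every requested combination of
#' evaluated group, reference distribution and condition -- the cohort-level
#' outlier summary. An empty group/condition intersection yields a row with
#' `n = 0` and `NA` percentages rather than an error.
#'
#' @param summaries Summary table from [summarize_individuals()].
#' @param fits Named list of `cohort_fit` objects, names `"<group>.<condition>"`.
#' @param groups Groups to evaluate.
#' @param references Reference groups whose fits are used.
#' @param conditions Conditions to tabulate.
#' @return Data frame `group`, `reference`, `condition`, `n`,
#'   `pct_gt_1sd`, `pct_gt_2sd`, `pct_gt_3sd`.
#' @export
exceedance_table <- function(summaries, fits,
                             groups = group_labels(),
                             references = group_labels(),
                             conditions = c("preexisting", "remaining")) {
  rows <- list()
  for (g in groups) for (ref in references) for (cond in conditions) {
    s <- summaries[summaries$group == g & summaries$condition == cond, ,
                   drop = FALSE]
    key <- paste(ref, cond, sep = ".")
    if (!key %in% names(fits)) stop("missing fit for ", key, call. = FALSE)
    if (nrow(s) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        group = g, reference = ref, condition = cond, n = 0L,
        pct_gt_1sd = NA_real_, pct_gt_2sd = NA_real_, pct_gt_3sd = NA_real_)
      next
    }
    calls <- classify_outliers(s, fits[[key]], cond)
    rows[[length(rows) + 1]] <- data.frame(
      group = g, reference = ref, condition = cond, n = nrow(calls),
      pct_gt_1sd = 100 * mean(calls$k >= 1),
      pct_gt_2sd = 100 * mean(calls$k >= 2),
      pct_gt_3sd = 100 * mean(calls$k >= 3))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Three-class outlier taxonomy
#'
#' Combines the exceedance calls of the unirradiated (preexisting) and the
#' 2 Gy / 24 h (remaining) conditions into the four-way partition: `both`
#' when the call reaches the threshold in both conditions, `preexisting_only`
#' / `remaining_only` when in exactly one, `none` otherwise. Individuals
#' with only elevated preexisting damage point to DNA-damaging exposure;
#' elevation in both, or only in residual damage, points to an impaired
#' DNA damage response.
#'
#' @param calls_preexisting,calls_remaining Call tables from
#'   [classify_outliers()] covering the same individuals.
#' @param k_threshold SD multiple that defines an outlier (default 2).
#' @return Data frame `individual_id`, `group`, `k_preexisting`,
#'   `k_remaining`, `class`, `k_threshold`.
#' @export
outlier_taxonomy <- function(calls_preexisting, calls_remaining,
                             k_threshold = 2) {
  a <- calls_preexisting[order(calls_preexisting$individual_id), ]
  b <- calls_remaining[order(calls_remaining$individual_id), ]
  if (!identical(a$individual_id, b$individual_id)) {
    stop("call sets cover different individuals", call. = FALSE)
  }
  pre <- a$k >= k_threshold
  rem <- b$k >= k_threshold
  cls <- ifelse(pre & rem, "both",
         ifelse(pre, "preexisting_only",
         ifelse(rem, "remaining_only", "none")))
  data.frame(
    individual_id = a$individual_id, group = a$group,
    k_preexisting = a$k, k_remaining = b$k,
    class = cls, k_threshold = k_threshold, stringsAsFactors = FALSE
  )
}
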