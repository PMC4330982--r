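#' Parameters of the synthetic gamma-H2AX cohort
#'
#' Defines a two-group cohort (healthy individuals `HI`, patients `RC`) whose
#' per-individual true foci rates are drawn, per exposure condition, from a
#' positive-truncated Gaussian and whose per-cell counts are Poisson or
#' negative-binomial around the individual rate. A fraction of one group can
#' be planted as radiosensitivity outliers whose rate is multiplied by
#' `outlier_effect` on the conditions its class affects.
#'
#' Default calibration: group sizes 59/136; preexisting means 0.49 (HI) and
#' 0.59 (RC) foci/cell and remaining means 2.63/2.97 foci/cell. The initial
#' condition (0.5 Gy, 30 min) has no published mean; its default of 5.0
#' foci/cell is a plausible induction level and is documented as
#' uncalibrated. Between-individual SDs and the within-individual dispersion
#' are likewise uncalibrated defaults (see the methods vignette).
#'
#' @param n_individuals Named integer vector `c(HI = ..., RC = ...)`.
#' @param baseline_mean 3 x 2 matrix of mean foci/cell, rows
#'   `preexisting`/`initial`/`remaining`, columns `HI`/`RC`. All entries must
#'   be positive.
#' @param between_sd Named numeric vector of between-individual SDs
#'   (foci/cell) per condition.
#' @param dispersion Within-individual overdispersion `phi` >= 0 of the
#'   per-cell counts: variance = lambda + phi * lambda^2. `phi = 0` gives
#'   Poisson counts.
#' @param outlier_fraction Probability that an individual of `outlier_group`
#'   is a planted outlier, in `[0, 1]`.
#' @param outlier_effect Multiplicative shift applied to the true rate on the
#'   conditions affected by the planted class (> 1 for elevated rates).
#' @param outlier_classes Named weights over the planted classes
#'   `preexisting_only`, `both`, `remaining_only`; normalised to sum to 1.
#' @param outlier_group Group receiving planted outliers (default `"RC"`).
#' @param cells_per_individual Cells scored per individual and condition.
#' @param rate_floor Positive truncation floor for the rate draw (foci/cell).
#' @param seed Integer seed; fixed seed gives bit-identical cohorts.
#' @return An object of class `cohort_params` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_params <- function(n_individuals = c(HI = 59, RC = 136),
                          baseline_mean = matrix(
                            c(0.49, 0.59,
                              5.00, 5.00,
                              2.63, 2.97),
                            nrow = 3, byrow = TRUE,
                            dimnames = list(condition_labels(), group_labels())
                          ),
                          between_sd = c(preexisting = 0.12,
                                         initial = 0.90,
                                         remaining = 0.55),
                          dispersion = 0.15,
                          outlier_fraction = 0.12,
                          outlier_effect = 5,
                          outlier_classes = c(preexisting_only = 1/3,
                                              both = 1/3,
                                              remaining_only = 1/3),
                          outlier_group = "RC",
                          cells_per_individual = 1000,
                          rate_floor = 0.02,
                          seed = NULL) {
  p <- list(
    n_individuals = n_individuals, baseline_mean = baseline_mean,
    between_sd = between_sd, dispersion = dispersion,
    outlier_fraction = outlier_fraction, outlier_effect = outlier_effect,
    outlier_classes = outlier_classes, outlier_group = outlier_group,
    cells_per_individual = cells_per_individual, rate_floor = rate_floor,
    seed = seed
  )
  validate_cohort_params(p)
}

validate_cohort_params <- function(p) {
  stopifnot(is.numeric(p$n_individuals), length(p$n_individuals) >= 1)
  if (is.null(names(p$n_individuals)) ||
      !all(names(p$n_individuals) %in% group_labels())) {
    stop("n_individuals must be named with groups among ",
         paste(group_labels(), collapse = "/"), call. = FALSE)
  }
  if (any(p$n_individuals < 0)) stop("group sizes must be >= 0", call. = FALSE)
  bm <- p$baseline_mean
  if (!is.matrix(bm) || !all(condition_labels() %in% rownames(bm)) ||
      !all(names(p$n_individuals) %in% colnames(bm))) {
    stop("baseline_mean must be a condition x group matrix", call. = FALSE)
  }
  if (any(!is.finite(bm)) || any(bm <= 0)) {
    stop("all baseline means must be positive", call. = FALSE)
  }
  if (!all(condition_labels() %in% names(p$between_sd))) {
    stop("between_sd must be named per condition", call. = FALSE)
  }
  if (any(p$between_sd < 0)) stop("between_sd must be >= 0", call. = FALSE)
  if (p$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (p$outlier_fraction < 0 || p$outlier_fraction > 1) {
    stop("outlier_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (p$outlier_effect <= 0) stop("outlier_effect must be > 0", call. = FALSE)
  w <- p$outlier_classes
  cls <- c("preexisting_only", "both", "remaining_only")
  if (!all(names(w) %in% cls) || any(w < 0) || sum(w) <= 0) {
    stop("outlier_classes must be non-negative weights over ",
         paste(cls, collapse = "/"), call. = FALSE)
  }
  p$outlier_classes <- w / sum(w)
  if (p$cells_per_individual < 1) {
    stop("cells_per_individual must be >= 1", call. = FALSE)
  }
  if (p$rate_floor <= 0) stop("rate_floor must be > 0", call. = FALSE)
  structure(p, class = "cohort_params")
}

# Gaussian truncated below at `floor`, by rejection (vectorised refill).
rtrunc_norm <- function(n, mean, sd, floor) {
  if (sd == 0) return(rep(max(mean, floor), n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < floor)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < floor]
  }
  x
}

#' Generate a synthetic cohort of per-cell foci counts
#'
#' Draws, for every individual and exposure condition, a true mean foci rate
#' from a positive-truncated Gaussian (multiplied by the planted outlier
#' effect where applicable) and then i.i.d. per-cell counts from a Poisson
#' (`dispersion = 0`) or negative-binomial distribution with that mean.
#'
#' The planted truth (true rates and outlier class per individual) is
#' returned alongside the records; downstream analysis functions never read
#' it -- it exists for validation only.
#'
#' @param params A [cohort_params()] object.
#' @return A list with elements
#'   \describe{
#'     \item{records}{data frame `individual_id`, `group`, `condition`,
#'       `cell_index`, `foci_count` -- one row per scored cell.}
#'     \item{truth}{data frame `individual_id`, `group`, `condition`,
#'       `true_rate`, `outlier_class`.}
#'   }
#' @examples
#' cohort <- generate_cohort(cohort_params(
#'   n_individuals = c(HI = 4, RC = 6),
#'   cells_per_individual = 50, seed = 1))
#' head(cohort$records)
#' @export
generate_cohort <- function(params = cohort_params()) {
  if (!inherits(params, "cohort_params")) params <- validate_cohort_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  m <- params$cells_per_individual
  recs <- list()
  truths <- list()
  for (g in names(params$n_individuals)) {
    n <- params$n_individuals[[g]]
    if (n == 0) next
    ids <- sprintf("%s_%03d", g, seq_len(n))
    cls <- rep("none", n)
    if (identical(g, params$outlier_group) && params$outlier_fraction > 0) {
      planted <- runif(n) < params$outlier_fraction
      if (any(planted)) {
        cls[planted] <- sample(names(params$outlier_classes), sum(planted),
                               replace = TRUE, prob = params$outlier_classes)
      }
    }
    for (cond in condition_labels()) {
      lam <- rtrunc_norm(n, params$baseline_mean[cond, g],
                         params$between_sd[[cond]], params$rate_floor)
      affected <- (cls == "both" & cond != "initial") |
        (cls == "preexisting_only" & cond == "preexisting") |
        (cls == "remaining_only" & cond == "remaining")
      lam[affected] <- lam[affected] * params$outlier_effect
      lam_cells <- rep(lam, each = m)
      counts <- if (params$dispersion > 0) {
        rnbinom(n * m, mu = lam_cells, size = 1 / params$dispersion)
      } else {
        rpois(n * m, lam_cells)
      }
      key <- paste(g, cond, sep = ".")
      recs[[key]] <- data.frame(
        individual_id = rep(ids, each = m),
        group = g,
        condition = cond,
        cell_index = rep.int(seq_len(m), n),
        foci_count = as.integer(counts),
        stringsAsFactors = FALSE
      )
      truths[[key]] <- data.frame(
        individual_id = ids, group = g, condition = cond,
        true_rate = lam, outlier_class = cls,
        stringsAsFactors = FALSE
      )
    }
  }
  records <- do.call(rbind, unname(recs))
  truth <- do.call(rbind, unname(truths))
  rownames(records) <- rownames(truth) <- NULL
  list(records = records, truth = truth)
}
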