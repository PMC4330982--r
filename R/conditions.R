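#' Exposure conditions of the gamma-H2AX assay
#'
#' The assay scores each individual's lymphocytes under three fixed exposure
#' conditions: `preexisting` (unirradiated, spontaneous damage), `initial`
#' (0.5 Gy ex vivo X-rays, 30 min incubation; damage induction) and
#' `remaining` (2 Gy, 24 h; residual unrepaired damage). The label-to-dose
#' mapping is fixed and bijective.
#'
#' @return A data frame with columns `condition`, `dose_gy` and
#'   `incubation_min`, one row per condition in assay order.
#' @examples
#' exposure_conditions()
#' @export
exposure_conditions <- function() {
  data.frame(
    condition = c("preexisting", "initial", "remaining"),
    dose_gy = c(0, 0.5, 2),
    incubation_min = c(0, 30, 1440),
    stringsAsFactors = FALSE
  )
}

condition_labels <- function() c("preexisting", "initial", "remaining")

group_labels <- function() c("HI", "RC")

check_condition <- function(condition) {
  condition <- as.character(condition)
  bad <- setdiff(unique(condition), condition_labels())
  if (length(bad) > 0) {
    stop("unknown exposure condition(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  condition
}
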