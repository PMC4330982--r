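#' Pipeline configuration
#'
#' One validated configuration object drives the whole analysis. Exactly one
#' input mode is active: `"simulate"` (generate a synthetic cohort),
#' `"counts"` (read a per-cell count CSV) or `"images"` (quantify z-stacks
#' listed in a manifest CSV with columns `prefix`, `individual_id`, `group`,
#' `condition`). The seed is recorded in every output.
#'
#' @param mode Input mode.
#' @param input Input path (count CSV or image manifest CSV); ignored for
#'   `"simulate"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed used for every stochastic stage.
#' @param cohort Named list of [cohort_params()] overrides (simulate mode).
#' @param foci A [foci_config()] (images mode).
#' @param sufficiency A [sufficiency_config()].
#' @param fit_method Gaussian fit method, `"moment"` or `"binned"`.
#' @param k_threshold SD multiple defining an outlier.
#' @param taxonomy_reference Reference group for the taxonomy (default RC).
#' @param min_cells Minimum cells per individual for the summaries.
#' @param normality_reps Monte-Carlo replicates of the Lilliefors null.
#' @param log_file Optional log file (messages always go to stderr too).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "counts", "images"),
                            input = NULL,
                            out_dir = tempfile("foci_run_"),
                            seed = 1L,
                            cohort = list(),
                            foci = foci_config(),
                            sufficiency = sufficiency_config(),
                            fit_method = "moment",
                            k_threshold = 2,
                            taxonomy_reference = "RC",
                            min_cells = 600,
                            normality_reps = 10000,
                            log_file = NULL) {
  mode <- match.arg(mode)
  if (mode != "simulate" && (is.null(input) || !file.exists(input))) {
    stop("mode '", mode, "' needs an existing input file", call. = FALSE)
  }
  stopifnot(fit_method %in% c("moment", "binned"),
            k_threshold %in% 1:3,
            taxonomy_reference %in% group_labels())
  structure(list(
    mode = mode, input = input, out_dir = out_dir, seed = as.integer(seed),
    cohort = cohort, foci = foci, sufficiency = sufficiency,
    fit_method = fit_method, k_threshold = k_threshold,
    taxonomy_reference = taxonomy_reference, min_cells = min_cells,
    normality_reps = normality_reps, log_file = log_file
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Every key is optional and falls back to the [pipeline_config()] default;
#' nested sections `cohort`, `foci` and `sufficiency` override the
#' corresponding stage parameters.
#'
#' @param path YAML file.
#' @param ... Overrides applied after the file (e.g. `seed`, `out_dir`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  dots <- list(...)
  y[names(dots)] <- dots
  args <- list()
  for (key in c("mode", "input", "out_dir", "seed", "fit_method",
                "k_threshold", "taxonomy_reference", "min_cells",
                "normality_reps", "log_file", "cohort")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$foci)) args$foci <- do.call(foci_config, y$foci)
  if (!is.null(y$sufficiency)) {
    args$sufficiency <- do.call(sufficiency_config, y$sufficiency)
  }
  do.call(pipeline_config, args)
}

pipeline_log <- function(config, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(...))
  message(msg)
  if (!is.null(config$log_file)) cat(msg, "\n", file = config$log_file,
                                     append = TRUE)
  invisible(NULL)
}

#' Run the full screening pipeline
#'
#' Executes simulate/ingest, (for images) quantification, per-individual
#' summaries, the scoring-sufficiency analysis and the cohort statistics,
#' and writes all tables plus a run manifest (seed, configuration, config
#' hash, package version) to the output directory. Statistical outputs are
#' byte-identical across reruns with the same configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @param stages Stages to run after ingest; subset of
#'   `c("sufficiency", "stats")`.
#' @return Invisibly, a list with the in-memory results (`records`,
#'   `summaries`, `tolerance`, `fits`, `comparisons`, `exceedance`,
#'   `taxonomy`, `paths`).
#' @export
run_pipeline <- function(config, stages = c("sufficiency", "stats")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(stages) > 0) stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  paths <- character(0)
  res <- list()

  pipeline_log(config, "mode=", config$mode, " seed=", config$seed)
  if (config$mode == "simulate") {
    params <- do.call(cohort_params, c(config$cohort, list(seed = config$seed)))
    cohort <- generate_cohort(params)
    records <- cohort$records
    write_truth(cohort$truth, out("cohort.truth.csv"))
    paths <- c(paths, truth = out("cohort.truth.csv"))
  } else if (config$mode == "counts") {
    records <- read_counts(config$input)
  } else {
    manifest <- read.csv(config$input, stringsAsFactors = FALSE)
    need <- c("prefix", "individual_id", "group", "condition")
    missing_cols <- setdiff(need, names(manifest))
    if (length(missing_cols) > 0) {
      stop("image manifest is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    recs <- list()
    for (i in seq_len(nrow(manifest))) {
      stk <- read_zstack(manifest$prefix[i])
      q <- quantify_field(stk, config$foci,
                          individual_id = manifest$individual_id[i],
                          group = manifest$group[i],
                          condition = manifest$condition[i])
      recs[[i]] <- q$records[, counts_schema()]
    }
    records <- do.call(rbind, recs)
    # re-index cells within individual x condition in acquisition order
    f <- interaction(records$individual_id, records$condition, drop = TRUE)
    records$cell_index <- stats::ave(seq_len(nrow(records)), f,
                                     FUN = seq_along)
  }
  check_records(records)
  write_counts(records, out("counts.csv"))
  paths <- c(paths, counts = out("counts.csv"))
  res$records <- records
  pipeline_log(config, nrow(records), " cell records ingested")

  summaries <- summarize_individuals(records, config$min_cells)
  write.csv(summaries, out("summaries.csv"), row.names = FALSE)
  paths <- c(paths, summaries = out("summaries.csv"))
  res$summaries <- summaries

  if ("sufficiency" %in% stages) {
    curves <- cohort_sufficiency(records, config$sufficiency)
    curve_df <- do.call(rbind, lapply(curves, function(cv) {
      cbind(individual_id = cv$individual_id, condition = cv$condition,
            cv$checkpoints)
    }))
    rownames(curve_df) <- NULL
    write.csv(curve_df, out("sufficiency_curves.csv"), row.names = FALSE)
    tol <- fraction_within_tolerance(curves, config$sufficiency)
    tol$minimum_sufficient <- minimum_cells(
      tol, config$sufficiency$required_fraction)
    write.csv(tol, out("sufficiency_tolerance.csv"), row.names = FALSE)
    paths <- c(paths, sufficiency_curves = out("sufficiency_curves.csv"),
               sufficiency_tolerance = out("sufficiency_tolerance.csv"))
    res$tolerance <- tol
    pipeline_log(config, "sufficiency: minimum sufficient n = ",
                 tol$minimum_sufficient[1])
  }

  if ("stats" %in% stages) {
    fits <- list(); normality <- list()
    for (g in intersect(group_labels(), unique(summaries$group))) {
      for (cond in intersect(condition_labels(), unique(summaries$condition))) {
        v <- summaries$mean_foci[summaries$group == g &
                                   summaries$condition == cond]
        if (length(v) < 3) next
        key <- paste(g, cond, sep = ".")
        fits[[key]] <- fit_cohort_distribution(v, config$fit_method,
                                               group = g, condition = cond)
        if (length(v) >= 5 && sd(v) > 0) {
          normality[[key]] <- test_normality(v, reps = config$normality_reps,
                                             seed = config$seed)
        }
      }
    }
    res$fits <- fits
    jsonlite::write_json(
      list(fits = lapply(fits, unclass), normality = normality),
      out("fits.json"), auto_unbox = TRUE, digits = 10)
    paths <- c(paths, fits = out("fits.json"))

    comparisons <- list()
    for (cond in intersect(condition_labels(), unique(summaries$condition))) {
      hi <- summaries$mean_foci[summaries$group == "HI" &
                                  summaries$condition == cond]
      rc <- summaries$mean_foci[summaries$group == "RC" &
                                  summaries$condition == cond]
      if (length(hi) >= 2 && length(rc) >= 2) {
        comparisons[[cond]] <- compare_groups(hi, rc)
      }
    }
    res$comparisons <- comparisons
    jsonlite::write_json(comparisons, out("comparisons.json"),
                         auto_unbox = TRUE, digits = 10)
    paths <- c(paths, comparisons = out("comparisons.json"))

    have <- function(key) key %in% names(fits)
    if (any(grepl("^HI\\.", names(fits))) || any(grepl("^RC\\.", names(fits)))) {
      refs <- intersect(group_labels(),
                        unique(sub("\\..*$", "", names(fits))))
      conds <- intersect(c("preexisting", "remaining"),
                         unique(sub("^.*\\.", "", names(fits))))
      if (length(conds) > 0 && length(refs) > 0) {
        exc <- exceedance_table(summaries, fits,
                                groups = intersect(group_labels(),
                                                   unique(summaries$group)),
                                references = refs, conditions = conds)
        write.csv(exc, out("exceedance.csv"), row.names = FALSE)
        paths <- c(paths, exceedance = out("exceedance.csv"))
        res$exceedance <- exc
      }
      ref <- config$taxonomy_reference
      if (have(paste0(ref, ".preexisting")) && have(paste0(ref, ".remaining"))) {
        tax <- outlier_taxonomy(
          classify_outliers(summaries, fits[[paste0(ref, ".preexisting")]],
                            "preexisting"),
          classify_outliers(summaries, fits[[paste0(ref, ".remaining")]],
                            "remaining"),
          k_threshold = config$k_threshold)
        write.csv(tax, out("taxonomy.csv"), row.names = FALSE)
        paths <- c(paths, taxonomy = out("taxonomy.csv"))
        res$taxonomy <- tax
        pipeline_log(config, "taxonomy: ",
                     sum(tax$class != "none"), "/", nrow(tax), " outliers")
      }
    }
  }

  cfg_yaml <- out("config.yaml")
  yaml::write_yaml(serialize_config(config), cfg_yaml)
  manifest <- list(
    seed = config$seed,
    mode = config$mode,
    config_file = basename(cfg_yaml),
    config_md5 = unname(tools::md5sum(cfg_yaml)),
    package = "fociscreen",
    package_version = as.character(packageVersion("fociscreen")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(paths)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  paths <- c(paths, config = cfg_yaml, manifest = out("manifest.json"))
  res$paths <- paths
  pipeline_log(config, "run complete: ", config$out_dir)
  invisible(res)
}

serialize_config <- function(config) {
  x <- unclass(config)
  x$foci <- unclass(x$foci)
  x$sufficiency <- unclass(x$sufficiency)
  x$out_dir <- NULL  # location-independent hash
  x
}
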