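make_summaries <- function(values, group = "RC", condition = "preexisting") {
  data.frame(individual_id = sprintf("%s_%04d", group, seq_along(values)),
             group = group, condition = condition, mean_foci = values,
             n_cells = 1000L, sufficient = TRUE, stringsAsFactors = FALSE)
}

test_that("per-individual summaries are arithmetic means with cell counts", {
  rec <- data.frame(individual_id = "A", group = "HI",
                    condition = "preexisting", cell_index = 1:3,
                    foci_count = c(0L, 1L, 2L))
  s <- summarize_individuals(rec, min_cells = 600)
  expect_equal(s$mean_foci, 1)
  expect_equal(s$n_cells, 3L)
  expect_false(s$sufficient)
  s2 <- summarize_individuals(rec, min_cells = 3)
  expect_true(s2$sufficient)
})

test_that("summary means track the generator's true rates", {
  p <- cohort_params(n_individuals = c(HI = 10, RC = 10),
                     outlier_fraction = 0, cells_per_individual = 500,
                     seed = 71)
  co <- generate_cohort(p)
  s <- summarize_individuals(co$records, min_cells = 500)
  m <- merge(s, co$truth, by = c("individual_id", "group", "condition"))
  se <- sqrt((m$true_rate + p$dispersion * m$true_rate^2) / m$n_cells)
  expect_true(all(abs(m$mean_foci - m$true_rate) < 4 * se))
})

test_that("the moment fit is the sample mean and SD", {
  f <- fit_cohort_distribution(c(1, 2, 3))
  expect_equal(f$mu, 2)
  expect_equal(f$sigma, 1)
  expect_equal(f$method, "moment")
  expect_error(fit_cohort_distribution(c(1, 1, 1)), "variance")
  expect_error(fit_cohort_distribution(c(1, 2)), "3 values")
})

test_that("the binned fit recovers Gaussian parameters and tracks the moment fit", {
  set.seed(72)
  v <- rnorm(1e4, 0.59, 0.1)
  f <- fit_cohort_distribution(v, "binned")
  expect_lt(abs(f$mu - 0.59), 0.01)
  expect_lt(abs(f$sigma - 0.1), 0.01)
  expect_match(f$method, "binned")
  expect_gt(f$bin_width, 0)

  # large cohorts: the two estimators agree per cohort
  for (s in 73:75) {
    set.seed(s)
    v <- rnorm(1e4, 0.59, 0.12)
    fm <- fit_cohort_distribution(v, "moment")
    fb <- fit_cohort_distribution(v, "binned")
    expect_lt(abs(fm$mu - fb$mu), 0.05 * fm$sigma)
  }
  # study-sized cohorts (n = 136): agreement holds at the median over seeds
  d <- vapply(1:20, function(s) {
    set.seed(100 + s)
    v <- rnorm(136, 0.59, 0.12)
    fm <- fit_cohort_distribution(v, "moment")
    fb <- fit_cohort_distribution(v, "binned")
    abs(fm$mu - fb$mu) / fm$sigma
  }, numeric(1))
  expect_lt(median(d), 0.05)
})

test_that("the Lilliefors statistic equals the reference implementation", {
  skip_if_not_installed("nortest")
  set.seed(76)
  for (i in 1:5) {
    x <- rnorm(50 + 10 * i)
    expect_equal(unname(test_normality(x, reps = 200, seed = 1)$lilliefors_d),
                 unname(nortest::lillie.test(x)$statistic), tolerance = 1e-12)
  }
})

test_that("normality tests accept Gaussian samples and reject exponential ones", {
  bank <- lilliefors_null_bank(500, reps = 1000, seed = 77)
  ok <- vapply(1:20, function(s) {
    set.seed(200 + s)
    r <- test_normality(rnorm(500, 0.59, 0.12), null_bank = bank)
    r$ks_p > 0.05 && r$lilliefors_p > 0.05
  }, logical(1))
  expect_gte(sum(ok), 18)

  rej <- vapply(1:10, function(s) {
    set.seed(300 + s)
    test_normality(rexp(500), null_bank = bank)$lilliefors_p < 0.05
  }, logical(1))
  expect_true(all(rej))

  expect_error(test_normality(rep(1, 10)), "tied")
  expect_error(test_normality(rnorm(3)), "at least 5")
})

test_that("group comparison reports t statistics and relative increases", {
  r <- compare_groups(c(0.48, 0.49, 0.50), c(0.58, 0.59, 0.60))
  expect_equal(r$relative_increase_pct, 20.4)
  expect_gt(r$t, 0)

  same <- c(1.1, 1.3, 1.5, 1.2)
  r2 <- compare_groups(same, same)
  expect_equal(r2$t, 0)
  expect_equal(r2$relative_increase_pct, 0)
  expect_lt(abs(r2$p - 1), 1e-12)

  expect_warning(r3 <- compare_groups(c(0, 0, 0), c(1, 2, 3)), "zero")
  expect_true(is.na(r3$relative_increase_pct))
})

test_that("SD-exceedance calls follow the one-sided rule", {
  ref <- fit_cohort_distribution(c(0.4, 0.5, 0.6), group = "HI",
                                 condition = "preexisting")
  mu <- ref$mu; s <- ref$sigma
  vals <- c(mu, mu + 0.5 * s, mu + 1.5 * s, mu + 2.5 * s, mu + 3.5 * s,
            mu - 5 * s)
  calls <- classify_outliers(make_summaries(vals), ref, "preexisting")
  expect_equal(calls$k, c(0L, 0L, 1L, 2L, 3L, 0L))
  expect_true(all(calls$direction == "above"))
})

test_that("exceedance against a lower-mean reference never decreases the call", {
  set.seed(78)
  vals <- rnorm(200, 1, 0.2)
  hi_ref <- structure(list(mu = 0.9, sigma = 0.2, n = 100, method = "moment",
                           bin_width = NA_real_, group = "HI",
                           condition = "preexisting"), class = "cohort_fit")
  rc_ref <- structure(list(mu = 1.1, sigma = 0.2, n = 100, method = "moment",
                           bin_width = NA_real_, group = "RC",
                           condition = "preexisting"), class = "cohort_fit")
  k_lo <- classify_outliers(make_summaries(vals), hi_ref, "preexisting")$k
  k_hi <- classify_outliers(make_summaries(vals), rc_ref, "preexisting")$k
  expect_true(all(k_lo >= k_hi))
})

test_that("the taxonomy applies the two-condition rule and partitions the cohort", {
  ref <- structure(list(mu = 1, sigma = 0.1, n = 50, method = "moment",
                        bin_width = NA_real_, group = "RC",
                        condition = "preexisting"), class = "cohort_fit")
  vals_pre <- c(1.35, 1.25, 1.0, 0.9)   # k = 3, 2, 0, 0
  vals_rem <- c(1.0, 1.25, 1.25, 0.9)   # k = 0, 2, 2, 0
  tax <- outlier_taxonomy(
    classify_outliers(make_summaries(vals_pre), ref, "preexisting"),
    classify_outliers(make_summaries(vals_rem, condition = "remaining"),
                      ref, "remaining"))
  expect_equal(tax$class,
               c("preexisting_only", "both", "remaining_only", "none"))
  expect_equal(sum(table(tax$class)), nrow(tax))

  mismatch <- classify_outliers(make_summaries(vals_rem[1:3],
                                               condition = "remaining"),
                                ref, "remaining")
  expect_error(outlier_taxonomy(
    classify_outliers(make_summaries(vals_pre), ref, "preexisting"),
    mismatch), "different individuals")
})

test_that("the exceedance table mirrors groups x references and tolerates empties", {
  set.seed(79)
  s <- rbind(make_summaries(rnorm(50, 0.5, 0.1), group = "HI"),
             make_summaries(rnorm(80, 0.6, 0.12), group = "RC"))
  fits <- list(
    "HI.preexisting" = fit_cohort_distribution(
      s$mean_foci[s$group == "HI"], group = "HI", condition = "preexisting"),
    "RC.preexisting" = fit_cohort_distribution(
      s$mean_foci[s$group == "RC"], group = "RC", condition = "preexisting"))
  tab <- exceedance_table(s, fits, conditions = "preexisting")
  expect_equal(nrow(tab), 4)  # 2 groups x 2 references
  expect_true(all(tab$n[tab$group == "HI"] == 50))
  # RC against the lower HI reference exceeds more than against its own
  rc_self <- tab$pct_gt_1sd[tab$group == "RC" & tab$reference == "RC"]
  rc_hi <- tab$pct_gt_1sd[tab$group == "RC" & tab$reference == "HI"]
  expect_gte(rc_hi, rc_self)

  s_hi_only <- s[s$group == "HI", ]
  tab2 <- exceedance_table(s_hi_only, fits, groups = c("HI", "RC"),
                           references = "HI", conditions = "preexisting")
  empty <- tab2[tab2$group == "RC", ]
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$pct_gt_2sd))
})
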