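test_that("cohort generation is bit-identical under a fixed seed", {
  p <- cohort_params(n_individuals = c(HI = 4, RC = 6),
                     cells_per_individual = 80, seed = 11)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a, b)
  c <- generate_cohort(cohort_params(n_individuals = c(HI = 4, RC = 6),
                                     cells_per_individual = 80, seed = 12))
  expect_false(identical(a$records$foci_count, c$records$foci_count))
})

test_that("invalid cohort parameters are rejected", {
  bad_mean <- matrix(c(0.49, -1, 5, 5, 2.63, 2.97), nrow = 3, byrow = TRUE,
                     dimnames = list(condition_labels(), group_labels()))
  expect_error(cohort_params(baseline_mean = bad_mean), "positive")
  expect_error(cohort_params(outlier_fraction = 1.2), "outlier_fraction")
  expect_error(cohort_params(dispersion = -1), "dispersion")
  expect_error(cohort_params(cells_per_individual = 0), "cells_per_individual")
})

test_that("zero dispersion and zero spread give Poisson counts", {
  mu <- matrix(1, 3, 2, dimnames = list(condition_labels(), group_labels()))
  p <- cohort_params(n_individuals = c(HI = 1, RC = 0), baseline_mean = mu,
                     between_sd = c(preexisting = 0, initial = 0, remaining = 0),
                     dispersion = 0, outlier_fraction = 0,
                     cells_per_individual = 3e5, seed = 21)
  x <- generate_cohort(p)$records
  x <- x$foci_count[x$condition == "preexisting"]
  # Poisson(1): mean = variance = 1; 3 standard errors
  expect_lt(abs(mean(x) - 1), 3 / sqrt(length(x)))
  expect_lt(abs(var(x) - 1), 3 * sqrt(3) / sqrt(length(x)))
})

test_that("negative-binomial dispersion inflates the variance as specified", {
  mu <- matrix(2, 3, 2, dimnames = list(condition_labels(), group_labels()))
  p <- cohort_params(n_individuals = c(HI = 1, RC = 0), baseline_mean = mu,
                     between_sd = c(preexisting = 0, initial = 0, remaining = 0),
                     dispersion = 0.5, outlier_fraction = 0,
                     cells_per_individual = 2e5, seed = 22)
  x <- generate_cohort(p)$records
  x <- x$foci_count[x$condition == "remaining"]
  expect_lt(abs(mean(x) - 2), 0.03)
  # var = mu + phi mu^2 = 4
  expect_lt(abs(var(x) - 4), 0.15)
})

test_that("grand means of an outlier-free healthy cohort match the calibration", {
  p <- cohort_params(outlier_fraction = 0, seed = 23)
  rec <- generate_cohort(p)$records
  hi <- rec[rec$group == "HI", ]
  m_pre <- mean(hi$foci_count[hi$condition == "preexisting"])
  m_rem <- mean(hi$foci_count[hi$condition == "remaining"])
  # 3 SE with between-individual spread dominating (tau / sqrt(59))
  expect_lt(abs(m_pre - 0.49), 3 * 0.12 / sqrt(59) + 0.01)
  expect_lt(abs(m_rem - 2.63), 3 * 0.55 / sqrt(59) + 0.02)
})

test_that("planted-outlier count matches a direct binomial oracle", {
  n_rep <- 150
  planted <- vapply(seq_len(n_rep), function(r) {
    co <- generate_cohort(cohort_params(cells_per_individual = 5,
                                        seed = 3000 + r))
    tr <- co$truth[co$truth$condition == "preexisting" & co$truth$group == "RC", ]
    sum(tr$outlier_class != "none")
  }, numeric(1))
  set.seed(77)
  oracle <- rbinom(20000, 136, 0.12)
  se <- sqrt(var(planted) / n_rep + var(oracle) / length(oracle))
  expect_lt(abs(mean(planted) - mean(oracle)), 3 * se)
  # binomial expectation 136 * 0.12 = 16.32
  expect_lt(abs(mean(planted) - 16.32), 3 * se + 0.1)
  # HI group never receives planted outliers by default
  co <- generate_cohort(cohort_params(cells_per_individual = 5, seed = 1))
  expect_true(all(co$truth$outlier_class[co$truth$group == "HI"] == "none"))
})

test_that("true rates respect the positive floor and the planted effect", {
  p <- cohort_params(outlier_fraction = 0.5, outlier_effect = 5,
                     cells_per_individual = 5, seed = 31)
  tr <- generate_cohort(p)$truth
  expect_true(all(tr$true_rate >= p$rate_floor))
  # initial condition is never affected by a planted class
  ini <- tr[tr$condition == "initial" & tr$group == "RC", ]
  expect_true(all(ini$true_rate < 5 + 6 * 0.9))
})

test_that("Poisson counts pass a chi-square goodness-of-fit test across seeds", {
  mu0 <- 2.63
  mu <- matrix(mu0, 3, 2, dimnames = list(condition_labels(), group_labels()))
  pass <- vapply(1:40, function(s) {
    p <- cohort_params(n_individuals = c(HI = 1, RC = 0), baseline_mean = mu,
                       between_sd = c(preexisting = 0, initial = 0,
                                      remaining = 0),
                       dispersion = 0, outlier_fraction = 0,
                       cells_per_individual = 2000, seed = 4000 + s)
    x <- generate_cohort(p)$records
    x <- x$foci_count[x$condition == "remaining"]
    # pool the upper tail so every expected count is >= 5
    kmax <- max(x)
    probs <- dpois(0:kmax, mu0)
    probs <- c(probs, 1 - sum(probs))
    obs <- tabulate(x + 1, nbins = kmax + 1)
    obs <- c(obs, 0)
    while (length(probs) > 2 && probs[length(probs)] * length(x) < 5) {
      k <- length(probs)
      probs[k - 1] <- probs[k - 1] + probs[k]
      obs[k - 1] <- obs[k - 1] + obs[k]
      probs <- probs[-k]; obs <- obs[-k]
    }
    stat <- sum((obs - length(x) * probs)^2 / (length(x) * probs))
    pchisq(stat, df = length(probs) - 1, lower.tail = FALSE) >= 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("a focus-free truth renders pure background in the foci channel", {
  tr <- simulate_image_truth(n_nuclei = 3, image_size = c(256, 256),
                             mean_foci = 0, seed = 41)
  st <- generate_zstack(tr)
  o <- tr$optics
  expect_lt(max(st$foci), o$background + 6.5 * o$noise_sd)
  q <- quantify_field(st)
  expect_equal(nrow(q$records), 3)
  expect_true(all(q$records$foci_count == 0))
})

test_that("stack geometry carries five planes 0.75 um apart and renders deterministically", {
  tr <- simulate_image_truth(n_nuclei = 4, image_size = c(256, 256), seed = 42)
  expect_equal(tr$geometry$n_planes, 5)
  expect_equal(tr$geometry$plane_spacing, 0.75)
  a <- generate_zstack(tr)
  b <- generate_zstack(tr)
  expect_identical(a$nucleus, b$nucleus)
  expect_identical(a$foci, b$foci)
  expect_equal(a$n_planes, 5)
  expect_equal(a$plane_spacing, 0.75)
  expect_true(all(a$foci >= 0 & a$foci <= 2^16 - 1))
  expect_true(all(a$foci == round(a$foci)))
})

test_that("foci outside the image or their nucleus are rejected", {
  tr <- simulate_image_truth(n_nuclei = 3, image_size = c(256, 256),
                             mean_foci = 3, seed = 43)
  bad <- tr
  bad$foci$y[1] <- 1e4
  expect_error(generate_zstack(bad), "bounds")
  bad2 <- tr
  bad2$foci$x[1] <- tr$nuclei$cx[tr$foci$nucleus_id[1]] +
    2 * tr$nuclei$radius_px[tr$foci$nucleus_id[1]]
  expect_error(generate_zstack(bad2), "nucleus|bounds")
})

test_that("z-stacks round-trip through TIFF plus sidecar unchanged", {
  tr <- simulate_image_truth(n_nuclei = 3, image_size = c(256, 256), seed = 44)
  st <- generate_zstack(tr)
  pfx <- tempfile("stack_")
  write_zstack(st, pfx)
  st2 <- read_zstack(pfx)
  expect_identical(st$nucleus, st2$nucleus)
  expect_identical(st$foci, st2$foci)
  expect_equal(st2$plane_spacing, 0.75)
  expect_equal(st2$pixel_size, st$pixel_size)
})
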