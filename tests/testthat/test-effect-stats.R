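make_pair_fixture <- function(n_pairs, tissues = c("t1", "t2", "t3", "t4", "t5"),
                              replicates = 2, pm_fun, mm_fun) {
  pm_ids <- sprintf("pm%03d", seq_len(n_pairs))
  mm_ids <- sprintf("mm%03d", seq_len(n_pairs))
  n_arr <- length(tissues) * replicates
  pm <- make_intensity(pm_ids, "A", tissues, replicates, pm_fun(n_pairs, n_arr))
  mm <- make_intensity(mm_ids, "B", tissues, replicates, mm_fun(n_pairs, n_arr))
  pairs <- tibble::tibble(
    pair_id = mm_ids, pm_probe_id = pm_ids, mm_probe_id = mm_ids,
    position = sample.int(25, n_pairs, replace = TRUE),
    mismatch_type = sample(mismatch_types(), n_pairs, replace = TRUE)
  )
  list(pairs = pairs, pm = pm, mm = mm)
}

test_that("log-ratio estimates are exact for constant-ratio intensities", {
  set.seed(51)
  base <- matrix(2^rnorm(20 * 10, 8), 20, 10)
  fx <- make_pair_fixture(20,
    pm_fun = function(n, a) base, mm_fun = function(n, a) base
  )
  est0 <- estimate_log_ratios(fx$pairs, fx$pm, fx$mm)
  expect_equal(est0$estimate, rep(0, 20))

  fx2 <- make_pair_fixture(20,
    pm_fun = function(n, a) 2 * base, mm_fun = function(n, a) base
  )
  est1 <- estimate_log_ratios(fx2$pairs, fx2$pm, fx2$mm)
  expect_equal(est1$estimate, rep(1, 20), tolerance = 1e-12)

  # the estimate equals the mean of its per-tissue components
  per_tissue_means <- vapply(
    est1$per_tissue, function(d) mean(d$ratio), numeric(1)
  )
  expect_equal(est1$estimate, per_tissue_means)
})

test_that("closed-form chip effect equals an independent lm() fit", {
  set.seed(52)
  tissues <- c("t1", "t2", "t3", "t4", "t5")
  fx <- make_pair_fixture(50,
    tissues = tissues,
    pm_fun = function(n, a) matrix(2^rnorm(n * a, 8, 1), n, a),
    mm_fun = function(n, a) matrix(2^rnorm(n * a, 7, 1), n, a)
  )
  est <- estimate_log_ratios(fx$pairs, fx$pm, fx$mm)
  pm_m <- log2(as.matrix(fx$pm$values[-1]))
  mm_m <- log2(as.matrix(fx$mm$values[-1]))
  for (i in c(1, 17, 50)) {
    cells <- dplyr::bind_rows(lapply(tissues, function(t) {
      pm_cols <- fx$pm$metadata$array_id[fx$pm$metadata$tissue == t]
      mm_cols <- fx$mm$metadata$array_id[fx$mm$metadata$tissue == t]
      tibble::tibble(
        y = c(mean(pm_m[i, pm_cols]), mean(mm_m[i, mm_cols])),
        tissue = t, chip = c("PM", "MM")
      )
    }))
    cells$chip <- factor(cells$chip, levels = c("MM", "PM"))
    fit <- lm(y ~ tissue + chip, data = cells)
    expect_equal(est$estimate[i], unname(coef(fit)[["chipPM"]]),
      tolerance = 1e-10
    )
  }
})

test_that("missing probes and unbalanced designs are rejected", {
  set.seed(53)
  fx <- make_pair_fixture(5,
    pm_fun = function(n, a) matrix(2^rnorm(n * a, 8), n, a),
    mm_fun = function(n, a) matrix(2^rnorm(n * a, 8), n, a)
  )
  bad_pairs <- fx$pairs
  bad_pairs$pm_probe_id[2] <- "ghost"
  err <- expect_error(
    estimate_log_ratios(bad_pairs, fx$pm, fx$mm),
    class = "xsmm_validation_error"
  )
  expect_match(conditionMessage(err), "ghost")

  lopsided <- fx$mm
  lopsided$metadata <- lopsided$metadata[-1, ]
  lopsided$values <- lopsided$values[, c("probe_id", lopsided$metadata$array_id)]
  expect_error(
    estimate_log_ratios(fx$pairs, fx$pm, lopsided),
    class = "xsmm_validation_error"
  )
})

test_that("position profile reports robust summaries with fixed conventions", {
  est <- tibble::tibble(position = c(13, 13, 13), estimate = c(1, 1, 1))
  prof <- position_profile(est)
  expect_equal(nrow(prof), 25L)
  row13 <- prof[prof$position == 13, ]
  expect_equal(row13$n, 3L)
  expect_equal(row13$mean, 1)
  expect_equal(row13$median, 1)
  expect_equal(row13$mad, 0)
  expect_equal(row13$iqr, 0)
  expect_true(all(prof$n[prof$position != 13] == 0L))
  expect_true(all(is.na(prof$median[prof$position != 13])))

  # oracle-computed under the declared conventions (raw MAD, type-7 IQR):
  # values {0,1,2,4}: median 1.5; |dev| {1.5,.5,.5,2.5} -> MAD 1.0;
  # Q3 - Q1 = 2.5 - 0.75 = 1.75
  est2 <- tibble::tibble(position = rep(5, 4), estimate = c(0, 1, 2, 4))
  row5 <- position_profile(est2)[5, ]
  expect_equal(row5$median, 1.5)
  expect_equal(row5$mad, 1.0)
  expect_equal(row5$iqr, 1.75)

  expect_error(
    position_profile(tibble::tibble(position = integer(0), estimate = numeric(0))),
    class = "xsmm_validation_error"
  )
})

test_that("spread regression matches collinear and constant edge cases", {
  prof <- tibble::tibble(
    position = 1:25, n = 10L,
    median = seq(0.2, 1.2, length.out = 25)
  )
  prof$mad <- 0.5 * prof$median + 0.1
  prof$mean <- prof$median
  prof$iqr <- prof$mad
  fit <- spread_regression(prof)
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  flat <- prof
  flat$mad <- 0.3
  flat_fit <- spread_regression(flat)
  expect_equal(flat_fit$slope, 0)
  expect_equal(flat_fit$r_squared, 0)

  expect_error(
    spread_regression(prof[1:2, ]),
    class = "xsmm_validation_error"
  )
})

test_that("spread regression equals the normal-equations oracle", {
  set.seed(54)
  prof <- tibble::tibble(
    position = 1:25, n = 10L,
    median = rnorm(25, 0.8, 0.2), mad = rnorm(25, 0.3, 0.05)
  )
  fit <- spread_regression(prof)
  x <- cbind(1, prof$median)
  beta <- solve(t(x) %*% x, t(x) %*% prof$mad)
  expect_equal(fit$intercept, beta[1, 1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2, 1], tolerance = 1e-10)
  expect_equal(fit$r_squared, cor(prof$median, prof$mad)^2, tolerance = 1e-12)

  # r_squared is invariant under affine rescaling of both axes
  scaled <- prof
  scaled$median <- 3 * prof$median - 5
  scaled$mad <- -0.5 * prof$mad + 2
  expect_equal(spread_regression(scaled)$r_squared, fit$r_squared, tolerance = 1e-12)

  # tidy/glance expose the fit in broom shape
  td <- tidy(fit)
  expect_equal(td$estimate, c(fit$intercept, fit$slope))
  expect_equal(glance(fit)$r.squared, fit$r_squared)
})

test_that("type/group summary bins, counts and tests as specified", {
  # one type with center {1,2,3} vs 5' {2,3,4}: pooled t = -1.2247, p = 0.2879
  est <- tibble::tibble(
    position = c(10, 11, 12, 1, 2, 3, 20, 21),
    mismatch_type = "C-A",
    estimate = c(1, 2, 3, 2, 3, 4, 2.5, 2.5)
  )
  summ <- suppressMessages(type_group_summary(est))
  expect_equal(nrow(summ), 12L)
  row <- summ[summ$mismatch_type == "C-A", ]
  expect_equal(row$frequency, 8L)
  expect_equal(row$mean_center, 2)
  expect_equal(row$mean_five_prime, 3)
  expect_equal(row$p_center_vs_five, 0.2878641, tolerance = 1e-6)
  expect_equal(sum(summ$frequency), nrow(est))
  expect_equal(row$pair_class, "CG_pair")

  # undersized cells yield NA p-values and are logged
  tiny <- tibble::tibble(position = c(1, 10), mismatch_type = "A-C", estimate = c(1, 2))
  tiny_summ <- suppressMessages(type_group_summary(tiny))
  expect_true(is.na(tiny_summ$p_center_vs_five[tiny_summ$mismatch_type == "A-C"]))
  expect_true("A-C:center_vs_five" %in% attr(tiny_summ, "skipped"))

  agg <- summarize_type_table(summ)
  expect_equal(agg$total_frequency, 8L)
})

test_that("percent contrasts follow both declared conventions", {
  expect_equal(contrast_percent(1.2, 1.2, "ratio"), 0)
  expect_equal(contrast_percent(1.2, 1.2, "log2"), 0)
  expect_equal(contrast_percent(1, 0, "ratio"), 50) # one log2 unit down
  expect_equal(contrast_percent(1.0, 1.13, "log2"), 13, tolerance = 1e-9)
  expect_error(contrast_percent(0, 1, "log2"), class = "xsmm_validation_error")
  expect_error(contrast_percent(NA, 1), class = "xsmm_validation_error")
})

test_that("control comparison is overwhelming for separated samples", {
  set.seed(55)
  est <- tibble::tibble(
    position = rep(13, 500), estimate = rnorm(500, 1, 0.1)
  )
  ctrl <- rnorm(500, 0, 0.1)
  res <- compare_to_controls(est, ctrl)
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$n_mismatch, 500L)

  # a position with a single estimate is skipped and logged
  est2 <- dplyr::bind_rows(est, tibble::tibble(position = 7, estimate = 1))
  res2 <- suppressMessages(compare_to_controls(est2, ctrl))
  expect_false(7 %in% res2$position)
  expect_equal(attr(res2, "skipped"), 7L)
})
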