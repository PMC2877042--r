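# Per-pair log2(PM/MM) estimation and the positional / mismatch-type
# summaries built on it.

#' Estimate per-pair log2(PM/MM) from probe-level intensities
#'
#' For every pair, replicate log2 intensities are averaged within each
#' (tissue, chip) cell; the per-tissue ratio is mean log2 PM minus mean
#' log2 MM, and the pair's estimate is the chip-effect coefficient of the
#' additive two-factor (tissue + chip) linear model on those cell means.
#' Under the balanced design this coefficient equals the across-tissue mean
#' of the per-tissue ratios; both routes are computed and their equality
#' asserted to 1e-8.
#'
#' @param pairs Tibble with columns `pair_id`, `pm_probe_id`, `mm_probe_id`
#'   and optionally `position`, `mismatch_type`, `probeset_id` (carried
#'   through). Works for mismatch pairs and for identical-probe control
#'   pairs alike.
#' @param pm,mm Intensity objects (lists with `values` and `metadata`, as
#'   from [simulate_intensities()] or [read_intensity_matrix()]) holding the
#'   PM-design and the query-design arrays. Both must cover the same
#'   tissues with the same replicate counts and are expected to be
#'   quantile-normalized.
#' @return A tibble with the carried-through pair columns, the `estimate`
#'   (log2 units) and a nested `per_tissue` list-column of tibbles
#'   (`tissue`, `ratio`).
#' @export
estimate_log_ratios <- function(pairs, pm, mm) {
  assert_data_frame(pairs, "pairs", c("pair_id", "pm_probe_id", "mm_probe_id"))
  pm_chk <- validate_intensity(pm$values, pm$metadata)
  mm_chk <- validate_intensity(mm$values, mm$metadata)
  check_design_balance(pm_chk$metadata, mm_chk$metadata)
  tissues <- sort(unique(pm_chk$metadata$tissue))

  pm_log <- cell_means(pairs$pm_probe_id, pm_chk, tissues, pairs$pair_id)
  mm_log <- cell_means(pairs$mm_probe_id, mm_chk, tissues, pairs$pair_id)
  d <- pm_log - mm_log # pairs x tissues matrix of per-tissue ratios
  closed_form <- rowMeans(d)

  # Independent route: chip-effect coefficient of the additive linear model
  # on the 2T cell means, solved by least squares with a fixed design matrix.
  n_t <- length(tissues)
  chip <- rep(c(1, 0), each = n_t) # PM = 1, MM = 0
  tissue_f <- factor(rep(tissues, 2L))
  x <- stats::model.matrix(~ tissue_f + chip)
  y <- rbind(t(pm_log), t(mm_log)) # 2T x pairs
  beta <- solve(crossprod(x), crossprod(x, y))
  lm_route <- beta["chip", ]
  gap <- max(abs(lm_route - closed_form))
  if (is.na(gap) || gap > 1e-8) {
    abort(sprintf(
      "closed-form and linear-model chip effects disagree (max |diff| = %.3g)",
      gap
    ), class = c("xsmm_internal_error", "xsmm_error"))
  }

  per_tissue <- tibble(
    pair_id = rep(pairs$pair_id, each = n_t),
    tissue = rep(tissues, nrow(pairs)),
    ratio = as.vector(t(d))
  ) %>%
    tidyr::nest(per_tissue = c("tissue", "ratio"))
  keep <- intersect(
    c("pair_id", "probeset_id", "position", "mismatch_type"), names(pairs)
  )
  dplyr::bind_cols(
    as_tibble(pairs)[keep],
    tibble(estimate = unname(closed_form)),
    per_tissue["per_tissue"]
  )
}

# Per-(probe, tissue) means of replicate log2 intensities; errors name the
# first missing pair/tissue cell.
cell_means <- function(probe_ids, intensity, tissues, pair_ids) {
  m <- intensity_as_matrix(intensity$values)
  missing <- setdiff(probe_ids, rownames(m))
  if (length(missing) > 0L) {
    first <- which(probe_ids %in% missing)[1L]
    abort_validation(sprintf(
      "pair %s: probe %s absent from the intensity matrix",
      pair_ids[first], probe_ids[first]
    ))
  }
  lg <- log2(m[probe_ids, , drop = FALSE])
  meta <- intensity$metadata
  out <- matrix(NA_real_, length(probe_ids), length(tissues),
    dimnames = list(NULL, tissues)
  )
  for (t in tissues) {
    cols <- meta$array_id[meta$tissue == t]
    out[, t] <- rowMeans(lg[, cols, drop = FALSE])
  }
  out
}

check_design_balance <- function(meta_pm, meta_mm) {
  tab_pm <- dplyr::count(meta_pm, .data$tissue)
  tab_mm <- dplyr::count(meta_mm, .data$tissue)
  merged <- dplyr::full_join(tab_pm, tab_mm, by = "tissue")
  bad <- merged[is.na(merged$n.x) | is.na(merged$n.y) | merged$n.x != merged$n.y, ]
  if (nrow(bad) > 0L) {
    abort_validation(sprintf(
      "tissue %s is not covered with equal replicate counts on both platforms",
      bad$tissue[1L]
    ))
  }
  invisible(TRUE)
}

#' Per-position profile of log2(PM/MM) estimates
#'
#' Summarises the estimates at each of the 25 probe positions: pair count
#' `n`, mean, median, raw median absolute deviation (no consistency
#' constant) and interquartile range (type-7 quartiles). Positions with no
#' pairs carry `n = 0` and `NA` summaries.
#'
#' @param estimates Tibble with columns `position` and `estimate`, as from
#'   [estimate_log_ratios()].
#' @return A 25-row tibble: `position`, `n`, `mean`, `median`, `mad`, `iqr`.
#' @export
position_profile <- function(estimates) {
  assert_data_frame(estimates, "estimates", c("position", "estimate"))
  if (nrow(estimates) == 0L) {
    abort_validation("`estimates` is empty")
  }
  summary <- estimates %>%
    dplyr::filter(!is.na(.data$position)) %>%
    dplyr::group_by(position = as.integer(.data$position)) %>%
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$estimate),
      median = median(.data$estimate),
      mad = stats::mad(.data$estimate, constant = 1),
      iqr = unname(diff(quantile(.data$estimate, c(0.25, 0.75), type = 7))),
      .groups = "drop"
    )
  tibble(position = seq_len(PROBE_LENGTH)) %>%
    dplyr::left_join(summary, by = "position") %>%
    dplyr::mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
}

#' Regress positional spread on positional location
#'
#' Ordinary least squares of the per-position MAD (response) on the
#' per-position median (predictor) across the 25 mismatch positions,
#' quantifying how the variability of log2(PM/MM) grows with its typical
#' size.
#'
#' @param profile A [position_profile()] tibble; at least 3 positions must
#'   have defined median and MAD.
#' @return An object of class `xsmm_spread_fit` with elements `slope`,
#'   `intercept`, `r_squared`, `n_positions`, the underlying `lm` fit and
#'   the points used. Supports [tidy()], [glance()] and [autoplot()].
#' @export
spread_regression <- function(profile) {
  assert_data_frame(profile, "profile", c("position", "median", "mad"))
  pts <- profile %>%
    dplyr::filter(is.finite(.data$median), is.finite(.data$mad))
  if (nrow(pts) < 3L) {
    abort_validation(sprintf(
      "spread regression needs >= 3 positions with defined median and MAD (got %d)",
      nrow(pts)
    ))
  }
  fit <- lm(mad ~ median, data = pts)
  r2 <- if (sd(pts$mad) == 0 || sd(pts$median) == 0) {
    0
  } else {
    cor(pts$median, pts$mad)^2
  }
  structure(
    list(
      slope = unname(coef(fit)[["median"]]),
      intercept = unname(coef(fit)[["(Intercept)"]]),
      r_squared = r2,
      n_positions = nrow(pts),
      fit = fit,
      data = pts
    ),
    class = "xsmm_spread_fit"
  )
}

#' @export
print.xsmm_spread_fit <- function(x, ...) {
  cat("<xsmm_spread_fit>  MAD ~ median across mismatch positions\n")
  cat(sprintf(
    "  slope %.4f, intercept %.4f, R^2 %.3f (n = %d positions)\n",
    x$slope, x$intercept, x$r_squared, x$n_positions
  ))
  invisible(x)
}

#' Mismatch-type by position-group summary with pooled t-tests
#'
#' Bins positions into the 5' / center / 3' groups, reports the mean
#' log2(PM/MM) per (type, group) cell and the per-type pair frequency, and
#' tests the three group contrasts (center vs 5', center vs 3', 5' vs 3')
#' per type with two-sided two-sample Student's t-tests. Pooled-variance
#' tests are the default; no multiple-testing correction is applied. A
#' contrast whose cells hold fewer than 2 estimates gets an `NA` p-value and
#' is recorded in the `skipped` attribute.
#'
#' @param estimates Tibble with `position`, `mismatch_type`, `estimate`.
#' @param var_equal Use the pooled-variance Student's t-test (default);
#'   `FALSE` switches to Welch.
#' @return A 12-row tibble: `mismatch_type`, `pair_class`, `frequency`, the
#'   three group means (`mean_five_prime`, `mean_center`,
#'   `mean_three_prime`) and p-values `p_center_vs_five`,
#'   `p_center_vs_three`, `p_five_vs_three`.
#' @export
type_group_summary <- function(estimates, var_equal = TRUE) {
  assert_data_frame(estimates, "estimates", c("position", "mismatch_type", "estimate"))
  est <- estimates %>%
    dplyr::filter(!is.na(.data$position), !is.na(.data$mismatch_type))
  check_mismatch_types(est$mismatch_type)
  est$group <- position_group(est$position)
  skipped <- character(0)
  one_type <- function(type) {
    sub <- est[est$mismatch_type == type, ]
    vals <- split(sub$estimate, sub$group)
    grp_mean <- vapply(
      position_group_levels(),
      function(g) if (length(vals[[g]]) > 0L) mean(vals[[g]]) else NA_real_,
      numeric(1)
    )
    contrast <- function(a, b, label) {
      if (length(vals[[a]]) < 2L || length(vals[[b]]) < 2L) {
        skipped <<- c(skipped, sprintf("%s:%s", type, label))
        return(NA_real_)
      }
      stats::t.test(vals[[a]], vals[[b]], var.equal = var_equal)$p.value
    }
    tibble(
      mismatch_type = type,
      pair_class = consolidate_pair_class(type),
      frequency = nrow(sub),
      mean_five_prime = grp_mean[["five_prime"]],
      mean_center = grp_mean[["center"]],
      mean_three_prime = grp_mean[["three_prime"]],
      p_center_vs_five = contrast("center", "five_prime", "center_vs_five"),
      p_center_vs_three = contrast("center", "three_prime", "center_vs_three"),
      p_five_vs_three = contrast("five_prime", "three_prime", "five_vs_three")
    )
  }
  out <- dplyr::bind_rows(lapply(mismatch_types(), one_type))
  if (length(skipped) > 0L) {
    inform(sprintf(
      "contrasts skipped for undersized cells: %s", paste(skipped, collapse = ", ")
    ))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Count p-values above a threshold and total frequency of a type table
#'
#' Aggregates a [type_group_summary()]-shaped table: the total pair
#' frequency and, per contrast column, how many of the 12 p-values exceed
#' `alpha`.
#'
#' @param summary A tibble with `frequency` and `p_*` contrast columns.
#' @param alpha Threshold (default 0.05).
#' @return A list with `total_frequency` and a named integer vector
#'   `n_above` per contrast column.
#' @export
summarize_type_table <- function(summary, alpha = 0.05) {
  assert_data_frame(summary, "summary", "frequency")
  p_cols <- grep("^p_", names(summary), value = TRUE)
  list(
    total_frequency = sum(summary$frequency),
    n_above = vapply(
      summary[p_cols],
      function(p) sum(p > alpha, na.rm = TRUE), integer(1)
    )
  )
}

#' Percent contrasts between two mean log2(PM/MM) values
#'
#' Two conventions are exposed. `scale = "ratio"` reports the relative
#' change of the geometric-mean PM/MM ratio,
#' `100 * (1 - 2^(mean_other - mean_ref))` — positive when `mean_other` is
#' smaller, i.e. a percent decrease. `scale = "log2"` reports how much
#' higher `mean_other` is on the log2 scale,
#' `100 * (mean_other / mean_ref - 1)`.
#'
#' @param mean_ref,mean_other Finite mean log2(PM/MM) values.
#' @param scale `"ratio"` or `"log2"`.
#' @return Percent value(s).
#' @export
#' @examples
#' contrast_percent(1, 0, scale = "ratio") # one log2 unit: 50% decrease
#' contrast_percent(1, 1.13, scale = "log2") # 13% higher
contrast_percent <- function(mean_ref, mean_other, scale = c("ratio", "log2")) {
  scale <- match.arg(scale)
  if (any(!is.finite(mean_ref)) || any(!is.finite(mean_other))) {
    abort_validation("inputs must be finite")
  }
  if (scale == "ratio") {
    100 * (1 - 2^(mean_other - mean_ref))
  } else {
    if (any(mean_ref == 0)) {
      abort_validation("`mean_ref` must be non-zero on the log2 scale form")
    }
    100 * (mean_other / mean_ref - 1)
  }
}

#' Test mismatch-pair estimates against identical-probe controls
#'
#' Per mismatch position, a two-sided two-sample Student's t-test compares
#' the log2(PM/MM) estimates at that position with the cross-design signal
#' differences of identical probe pairs (which carry no mismatch effect).
#' Positions where either sample has fewer than 2 values are skipped and
#' logged.
#'
#' @param estimates Tibble with `position` and `estimate` for mismatch
#'   pairs.
#' @param control_differences Numeric vector (or tibble with an `estimate`
#'   column) of per-pair log2 differences for identical probes.
#' @param var_equal Pooled-variance test (default) or Welch.
#' @return Tibble `position`, `n_mismatch`, `n_control`, `statistic`,
#'   `p_value` for tested positions; skipped positions appear in the
#'   `skipped` attribute.
#' @export
compare_to_controls <- function(estimates, control_differences, var_equal = TRUE) {
  assert_data_frame(estimates, "estimates", c("position", "estimate"))
  if (is.data.frame(control_differences)) {
    assert_data_frame(control_differences, "control_differences", "estimate")
    control_differences <- control_differences$estimate
  }
  ctrl <- control_differences[is.finite(control_differences)]
  est <- estimates %>% dplyr::filter(!is.na(.data$position))
  positions <- sort(unique(as.integer(est$position)))
  skipped <- integer(0)
  rows <- lapply(positions, function(p) {
    x <- est$estimate[est$position == p]
    if (length(x) < 2L || length(ctrl) < 2L) {
      skipped <<- c(skipped, p)
      return(NULL)
    }
    tt <- stats::t.test(x, ctrl, var.equal = var_equal)
    tibble(
      position = p, n_mismatch = length(x), n_control = length(ctrl),
      statistic = unname(tt$statistic), p_value = tt$p.value
    )
  })
  if (length(skipped) > 0L) {
    inform(sprintf(
      "positions skipped for undersized samples: %s",
      paste(skipped, collapse = ", ")
    ))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}
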