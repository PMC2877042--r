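# Cross-study comparison of mismatch-type effects: notation conversion,
# rank vectors, correlation matrices and Watson-Crick outlier flagging.

check_direction <- function(direction, arg = "direction") {
  if (!all(direction %in% c("stability", "discrimination"))) {
    abort_validation(sprintf(
      '`%s` must be "stability" or "discrimination"', arg
    ))
  }
  direction
}

validate_effect_vector <- function(vec, arg = "vector") {
  assert_data_frame(vec, arg, c("mismatch_type", "value"))
  vec <- as_tibble(vec)
  check_mismatch_types(vec$mismatch_type)
  missing <- setdiff(mismatch_types(), vec$mismatch_type)
  if (length(missing) > 0L) {
    abort_validation(sprintf(
      "%s is missing mismatch type(s): %s", arg, paste(missing, collapse = ", ")
    ))
  }
  if (nrow(vec) != 12L || anyDuplicated(vec$mismatch_type)) {
    abort_validation(sprintf("%s must hold exactly one value per type", arg))
  }
  if (any(!is.finite(vec$value))) {
    abort_validation(sprintf("%s contains missing values", arg))
  }
  vec
}

#' Convert between PM->MM and duplex (probe/target) notation
#'
#' In duplex notation the mismatched base pair is written as (probe base,
#' target base): the probe provides the MM base and the target provides the
#' Watson-Crick complement of the PM base (U replacing T when the target
#' chemistry is RNA). `convert_notation()` maps PM->MM types to duplex
#' notation; `duplex_to_type()` inverts it, and the two round-trip over all
#' 12 types.
#'
#' @param types Character vector of PM->MM mismatch types (e.g. `"A-C"`).
#' @param chemistry Target chemistry, `"RNA"` (default) or `"DNA"`.
#' @return `convert_notation()`: tibble `mismatch_type`, `probe_base`,
#'   `target_base`, `duplex` (e.g. `"C/U"`). `duplex_to_type()`: character
#'   vector of PM->MM types.
#' @export
#' @examples
#' convert_notation("A-C") # probe C, target U
#' duplex_to_type("C/U") # "A-C"
convert_notation <- function(types, chemistry = c("RNA", "DNA")) {
  chemistry <- match.arg(chemistry)
  types <- check_mismatch_types(types)
  probe <- mm_base(types)
  target <- unname(DNA_COMPLEMENT[pm_base(types)])
  if (chemistry == "RNA") {
    target[target == "T"] <- "U"
  }
  tibble(
    mismatch_type = types, probe_base = probe, target_base = target,
    duplex = paste0(probe, "/", target)
  )
}

#' @rdname convert_notation
#' @param duplex Character vector like `"C/U"` (probe base / target base).
#' @export
duplex_to_type <- function(duplex, chemistry = c("RNA", "DNA")) {
  chemistry <- match.arg(chemistry)
  parts <- stringr::str_match(duplex, "^([ACGTU])/([ACGTU])$")
  if (any(is.na(parts[, 1L]))) {
    abort_validation(sprintf(
      "invalid duplex notation: %s", duplex[which(is.na(parts[, 1L]))[1L]]
    ))
  }
  probe <- parts[, 2L]
  target <- parts[, 3L]
  target[target == "U"] <- "T"
  pm <- unname(DNA_COMPLEMENT[target])
  out <- paste0(pm, "-", probe)
  check_mismatch_types(out, arg = "duplex (maps to an identical-base pair)")
  out
}

#' Rank a 12-type effect vector
#'
#' Converts a study's mismatch-type effect vector to ranks 1..12 with
#' average tie handling, in the requested direction. A vector already in
#' the output direction is ranked ascending (rank 1 = smallest value); when
#' the input and output directions differ (a discrimination measure such as
#' log2(PM/MM) is the reverse of a stability measure) the ranking is
#' flipped.
#'
#' @param vec Tibble with columns `mismatch_type` (all 12 types) and
#'   `value`; no missing values.
#' @param direction Direction of `value`: `"discrimination"` (larger =
#'   less stable duplex, the log2(PM/MM) convention) or `"stability"`
#'   (larger = more stable).
#' @param output_direction Direction of the returned ranks.
#' @return Tibble `mismatch_type`, `rank`.
#' @export
rank_types <- function(vec, direction, output_direction = direction) {
  vec <- validate_effect_vector(vec)
  direction <- check_direction(direction)
  output_direction <- check_direction(output_direction, "output_direction")
  v <- if (direction == output_direction) vec$value else -vec$value
  tibble(
    mismatch_type = vec$mismatch_type,
    rank = rank(v, ties.method = "average")
  )
}

#' Positions on the stability list
#'
#' Converts an effect vector into stability-list positions, where position 1
#' is the MOST stable mismatch type (the usual way stability orders are
#' printed, and the orientation [flag_wc_outliers()] expects). For a
#' discrimination-direction vector this is simply the ascending rank (the
#' least discriminating type is the most stable); for a stability-direction
#' vector the ranking is descending.
#'
#' @inheritParams rank_types
#' @return Tibble `mismatch_type`, `stability_position` (1 = most stable).
#' @export
stability_positions <- function(vec, direction) {
  direction <- check_direction(direction)
  ranks <- rank_types(vec, direction, output_direction = "discrimination")
  tibble(
    mismatch_type = ranks$mismatch_type,
    stability_position = ranks$rank
  )
}

#' Flag Watson-Crick outliers in a stability ranking
#'
#' On a complete stability list of the 12 types (position 1 = most stable),
#' Watson-Crick base-pairing predicts the six AT_pair-class types (mismatch
#' disrupting an A-T pair) at positions 1-6 and the six CG_pair-class types
#' at positions 7-12. A type is flagged iff it is AT_pair-class ranked in
#' positions 7-12 or CG_pair-class ranked in positions 1-6. By pigeonhole
#' the two flag counts are equal on any complete ranking.
#'
#' @param ranking Tibble with `mismatch_type` (all 12) and
#'   `stability_position` (1 = most stable), as from
#'   [stability_positions()].
#' @return Tibble of flagged types: `mismatch_type`, `pair_class`,
#'   `stability_position`, `expected` (`"1-6"` / `"7-12"`).
#' @export
flag_wc_outliers <- function(ranking) {
  assert_data_frame(ranking, "ranking", c("mismatch_type", "stability_position"))
  ranking <- as_tibble(ranking)
  check_mismatch_types(ranking$mismatch_type)
  if (!setequal(ranking$mismatch_type, mismatch_types()) ||
    nrow(ranking) != 12L) {
    abort_validation("`ranking` must cover all 12 mismatch types exactly once")
  }
  pos <- ranking$stability_position
  if (any(!is.finite(pos))) {
    abort_validation("`ranking` has missing stability positions")
  }
  if (sum(pos <= 6.5) != 6L) {
    abort_validation(
      "ties straddle the position-6/7 boundary; the block rule is ambiguous"
    )
  }
  ranking %>%
    dplyr::mutate(
      pair_class = consolidate_pair_class(.data$mismatch_type),
      top_half = .data$stability_position <= 6.5,
      expected = ifelse(.data$pair_class == "AT_pair", "1-6", "7-12")
    ) %>%
    dplyr::filter(
      (.data$pair_class == "AT_pair" & !.data$top_half) |
        (.data$pair_class == "CG_pair" & .data$top_half)
    ) %>%
    dplyr::select("mismatch_type", "pair_class", "stability_position", "expected")
}

# Two-sided p for a correlation coefficient via the t approximation.
cor_p_t_approx <- function(r, n) {
  if (abs(r) >= 1) {
    return(0)
  }
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t_stat), df = n - 2)
}

#' Correlate mismatch-type effect vectors across studies
#'
#' Harmonizes every study vector to the stability direction (discrimination
#' measures are negated), then computes all pairwise Spearman rank
#' correlations and Pearson correlations with two-sided p-values under the
#' null of zero correlation at N = 12. Spearman p-values use the
#' t-approximation by default (`spearman_p = "approx"`); an exact
#' permutation p is available for untied ranks (`spearman_p = "exact"`).
#' Because the question of whether Pearson should see raw values or
#' ranks-as-values is convention-dependent, both are reported
#' (`pearson_*` on values, `pearson_rank_*` on ranks).
#'
#' @param vectors Long tibble with columns `study_id`, `mismatch_type`,
#'   `value`, `direction`; each study must cover all 12 types.
#' @param spearman_p `"approx"` (t approximation) or `"exact"`.
#' @return Tibble with one row per ordered study pair (the full symmetric
#'   grid, diagonal included): `study_a`, `study_b`, `n`, `spearman_rho`,
#'   `spearman_p`, `pearson_r`, `pearson_p`, `pearson_rank_r`,
#'   `pearson_rank_p`.
#' @export
correlate_studies <- function(vectors, spearman_p = c("approx", "exact")) {
  spearman_p <- match.arg(spearman_p)
  assert_data_frame(vectors, "vectors", c("study_id", "mismatch_type", "value", "direction"))
  studies <- unique(vectors$study_id)
  if (length(studies) < 2L) {
    abort_validation("need at least two studies to correlate")
  }
  harmonized <- lapply(studies, function(s) {
    sub <- vectors[vectors$study_id == s, ]
    dir <- unique(check_direction(sub$direction))
    if (length(dir) != 1L) {
      abort_validation(sprintf("study %s declares conflicting directions", s))
    }
    vec <- validate_effect_vector(sub, arg = sprintf("study %s", s))
    vec <- vec[match(mismatch_types(), vec$mismatch_type), ]
    if (dir == "stability") vec$value else -vec$value
  })
  names(harmonized) <- studies
  grid <- tidyr::expand_grid(study_a = studies, study_b = studies)
  res <- purrr::pmap(grid, function(study_a, study_b) {
    x <- harmonized[[study_a]]
    y <- harmonized[[study_b]]
    n <- length(x)
    rx <- rank(x)
    ry <- rank(y)
    rho <- cor(rx, ry)
    sp_p <- if (spearman_p == "exact") {
      suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
      )
    } else {
      cor_p_t_approx(rho, n)
    }
    pe <- stats::cor.test(x, y, method = "pearson")
    pr <- cor(rx, ry) # pearson on ranks equals spearman rho
    tibble(
      study_a = study_a, study_b = study_b, n = n,
      spearman_rho = rho, spearman_p = sp_p,
      pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
      pearson_rank_r = pr, pearson_rank_p = cor_p_t_approx(pr, n)
    )
  })
  dplyr::bind_rows(res)
}

#' Read a study's 12-type effect vector from TSV
#'
#' The file must hold columns `mismatch_type` and `value`, one row per
#' mismatch type in PM->MM notation.
#'
#' @param path TSV path.
#' @param study_id Study label to attach.
#' @param direction Direction of the values (`"stability"` or
#'   `"discrimination"`).
#' @return Tibble `study_id`, `mismatch_type`, `value`, `direction`.
#' @export
read_study_vector <- function(path, study_id, direction) {
  direction <- check_direction(direction)
  if (!file.exists(path)) {
    abort_validation(sprintf("study vector not found: %s", path))
  }
  vec <- readr::read_tsv(path, col_types = readr::cols(
    mismatch_type = readr::col_character(), value = readr::col_double()
  ))
  vec <- validate_effect_vector(vec, arg = path)
  tibble(
    study_id = study_id, mismatch_type = vec$mismatch_type,
    value = vec$value, direction = direction
  )
}
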