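# The five-step discovery procedure around the aligner: probeset-level
# filtering, single-mismatch pair calling against the PM design, and
# identical-probe control identification.

#' Filter probesets on sequential, complete alignments
#'
#' A probeset is kept iff (a) alignment start coordinates are strictly
#' increasing in probe `order_index` ("sequential") and (b) every probe is
#' fully aligned with no gaps ("complete"). The discard log names the first
#' violated criterion per probeset, checking (a) before (b).
#'
#' @param alignments Tibble from [align_probes()] (must carry
#'   `probeset_id`, `order_index`, `start`, `gap_count`,
#'   `probe_fully_aligned`).
#' @return A list with `kept` (alignment rows of surviving probesets) and
#'   `discarded` (tibble `probeset_id`, `reason` with reasons
#'   `"non-sequential"` / `"incomplete"`).
#' @export
filter_probesets <- function(alignments) {
  assert_data_frame(alignments, "alignments", c(
    "probeset_id", "order_index", "start", "gap_count", "probe_fully_aligned"
  ))
  dup <- alignments %>%
    dplyr::count(.data$probeset_id, .data$order_index) %>%
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort_validation(sprintf(
      "probeset %s has duplicated order_index values", dup$probeset_id[1L]
    ))
  }
  verdict <- alignments %>%
    dplyr::group_by(.data$probeset_id) %>%
    dplyr::arrange(.data$order_index, .by_group = TRUE) %>%
    dplyr::summarise(
      sequential = all(diff(.data$start) > 0),
      complete = all(.data$probe_fully_aligned & .data$gap_count == 0L),
      .groups = "drop"
    ) %>%
    dplyr::mutate(reason = dplyr::case_when(
      !.data$sequential ~ "non-sequential",
      !.data$complete ~ "incomplete",
      TRUE ~ NA_character_
    ))
  discarded <- verdict %>%
    dplyr::filter(!is.na(.data$reason)) %>%
    dplyr::select("probeset_id", "reason")
  kept <- alignments %>%
    dplyr::filter(!.data$probeset_id %in% discarded$probeset_id)
  list(kept = kept, discarded = discarded)
}

#' Call single-mismatch PM/MM probe pairs
#'
#' From the filtered alignments of the query design, a pair is emitted iff
#' the query probe shows exactly one mismatch to the consensus and the PM
#' design contains a probe whose sequence equals the aligned consensus
#' window exactly. The mismatch position is the probe coordinate (1..25) and
#' the type is `<consensus base>-<probe base>` (PM->MM notation, since the
#' PM probe matches the consensus window). Query probes with zero mismatches
#' and an identical PM-design probe are routed to the control set; probes
#' with two or more mismatches are dropped.
#'
#' A PM window match is preferred within the query probe's own probeset;
#' matches confined to several other probesets raise an ambiguity error.
#'
#' @param alignments The `kept` alignments from [filter_probesets()] for the
#'   query design.
#' @param pm_probes Probe table of the PM design.
#' @param consensus Consensus tibble (`id`, `sequence`).
#' @return A list with tibbles `pairs` (`pair_id`, `probeset_id`,
#'   `pm_probe_id`, `mm_probe_id`, `position`, `mismatch_type`,
#'   `consensus_id`, `start`, `end`), `controls` (zero-mismatch query probes
#'   with their identical PM probe) and `dropped` (probe id + reason).
#' @export
call_mismatch_pairs <- function(alignments, pm_probes, consensus) {
  assert_data_frame(alignments, "alignments", c(
    "probeset_id", "probe_id", "consensus_id", "start", "end",
    "gap_count", "probe_fully_aligned", "n_mismatch",
    "mismatch_positions", "mismatch_pairs"
  ))
  pm_probes <- validate_probe_table(pm_probes)
  assert_data_frame(consensus, "consensus", c("id", "sequence"))
  cons_seq <- setNames(consensus$sequence, consensus$id)

  usable <- alignments %>%
    dplyr::filter(.data$probe_fully_aligned, .data$gap_count == 0L)
  dropped <- alignments %>%
    dplyr::filter(!.data$probe_id %in% usable$probe_id) %>%
    dplyr::transmute(probe_id = .data$probe_id, reason = "gapped_or_partial")
  multi <- usable %>%
    dplyr::filter(.data$n_mismatch >= 2L) %>%
    dplyr::transmute(probe_id = .data$probe_id, reason = "multiple_mismatches")
  usable <- usable %>% dplyr::filter(.data$n_mismatch <= 1L)

  window <- substr(
    cons_seq[usable$consensus_id], usable$start, usable$end
  )
  pm_match <- match_pm_window(window, usable$probeset_id, pm_probes)
  unmatched <- usable %>%
    dplyr::filter(is.na(pm_match)) %>%
    dplyr::transmute(probe_id = .data$probe_id, reason = "no_pm_window_probe")

  hit <- !is.na(pm_match)
  res <- usable[hit, ]
  res$pm_probe_id <- pm_probes$probe_id[pm_match[hit]]
  pairs <- res %>%
    dplyr::filter(.data$n_mismatch == 1L) %>%
    dplyr::mutate(
      position = purrr::map_int(.data$mismatch_positions, 1L),
      mismatch_type = purrr::map_chr(.data$mismatch_pairs, 1L)
    ) %>%
    dplyr::transmute(
      pair_id = .data$probe_id, probeset_id = .data$probeset_id,
      pm_probe_id = .data$pm_probe_id, mm_probe_id = .data$probe_id,
      position = .data$position, mismatch_type = .data$mismatch_type,
      consensus_id = .data$consensus_id, start = .data$start, end = .data$end
    )
  check_mismatch_types(pairs$mismatch_type)
  controls <- res %>%
    dplyr::filter(.data$n_mismatch == 0L) %>%
    dplyr::transmute(
      pair_id = .data$probe_id, probeset_id = .data$probeset_id,
      pm_probe_id = .data$pm_probe_id, mm_probe_id = .data$probe_id,
      consensus_id = .data$consensus_id, start = .data$start, end = .data$end
    )
  list(
    pairs = dplyr::arrange(pairs, .data$pair_id),
    controls = dplyr::arrange(controls, .data$pair_id),
    dropped = dplyr::bind_rows(dropped, multi, unmatched)
  )
}

# Match consensus windows to PM-design probe sequences: same-probeset match
# preferred; a unique other-probeset match is accepted; several matches on
# conflicting probesets raise an ambiguity error.
match_pm_window <- function(window, probeset_id, pm_probes) {
  same_key <- paste(probeset_id, window)
  pm_key <- paste(pm_probes$probeset_id, pm_probes$sequence)
  hit <- match(same_key, pm_key)
  need <- which(is.na(hit))
  if (length(need) > 0L) {
    by_seq <- split(seq_len(nrow(pm_probes)), pm_probes$sequence)
    for (i in need) {
      cand <- by_seq[[window[i]]]
      if (is.null(cand)) next
      if (length(unique(pm_probes$probeset_id[cand])) > 1L) {
        abort_ambiguity(sprintf(
          "consensus window for probe in probeset %s matches PM probes on conflicting probesets: %s",
          probeset_id[i],
          paste(pm_probes$probe_id[cand], collapse = ", ")
        ))
      }
      hit[i] <- cand[1L]
    }
  }
  hit
}

#' Find identical probes between two designs
#'
#' Pairs probes with bitwise-equal 25-mer sequences by an exact sequence
#' join. Each design-B probe is matched to at most one design-A probe:
#' first by shared `probeset_id`, otherwise to the lexicographically
#' smallest matching `probe_id` (such fallbacks are recorded in the
#' `tie_broken` attribute).
#'
#' @param design_a,design_b Probe tables of the two designs.
#' @return Tibble with one row per matched design-B probe: `probe_id_a`,
#'   `probe_id_b`, `probeset_id_a`, `probeset_id_b`, `sequence`.
#' @export
find_identical_probes <- function(design_a, design_b) {
  design_a <- validate_probe_table(design_a)
  design_b <- validate_probe_table(design_b)
  key_a <- paste(design_a$probeset_id, design_a$sequence)
  key_b <- paste(design_b$probeset_id, design_b$sequence)
  hit <- match(key_b, key_a)
  tie_broken <- character(0)
  need <- which(is.na(hit))
  if (length(need) > 0L) {
    a_sorted <- order(design_a$probe_id)
    first_by_seq <- tapply(a_sorted, design_a$sequence[a_sorted], `[`, 1L)
    fallback <- first_by_seq[design_b$sequence[need]]
    found <- !is.na(fallback)
    hit[need[found]] <- fallback[found]
    tie_broken <- design_b$probe_id[need[found]]
  }
  keep <- which(!is.na(hit))
  out <- tibble(
    probe_id_a = design_a$probe_id[hit[keep]],
    probe_id_b = design_b$probe_id[keep],
    probeset_id_a = design_a$probeset_id[hit[keep]],
    probeset_id_b = design_b$probeset_id[keep],
    sequence = design_b$sequence[keep]
  ) %>%
    dplyr::arrange(.data$probe_id_b)
  attr(out, "tie_broken") <- tie_broken
  out
}
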