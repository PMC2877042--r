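# Synthetic data generator: consensus sequences, two probe designs differing
# by controlled single-base substitutions, and probe-level intensities under
# a generative model with known positional/type mismatch penalties.

#' Default mismatch penalty surface
#'
#' Returns the default table of per-(position, type) signal-loss penalties
#' delta (log2-intensity units) used by the generator:
#' `delta(i, type) = type_effect(type) * w(i)`, where `w` is a unimodal
#' positional weight peaking at position 12 with a slightly stronger falloff
#' toward the 3' flank, and the 12 type effects separate the pair classes
#' (mismatches disrupting C-G pairs penalized more than A-T pairs, with C-A,
#' G-A and C-G strongest and A-C, A-G, A-T weakest). The default scale puts
#' the peak positional mean near one log2 unit and reproduces, in
#' expectation, a 24%/29% decrease of the PM/MM ratio from position 12 to
#' positions 1/25 and a 13%/17% excess of the center position group over the
#' 5'/3' groups.
#'
#' @param type_effects Named numeric vector of per-type effect sizes (log2
#'   units at the positional peak); names must be the 12 PM->MM types.
#' @param position_weights Optional numeric vector of length 25 replacing the
#'   default positional weight curve.
#' @return A tibble with columns `position` (1..25), `mismatch_type` (12
#'   types) and `delta`, 300 rows.
#' @export
#' @examples
#' surf <- default_delta_surface()
#' surf[which.max(surf$delta), ]
default_delta_surface <- function(type_effects = NULL, position_weights = NULL) {
  if (is.null(type_effects)) {
    type_effects <- c(
      "A-C" = 0.70, "A-G" = 0.72, "A-T" = 0.75,
      "T-A" = 0.80, "T-C" = 0.85, "T-G" = 0.82,
      "C-A" = 1.25, "C-G" = 1.20, "C-T" = 1.05,
      "G-A" = 1.22, "G-C" = 1.10, "G-T" = 1.08
    )
  }
  if (!setequal(names(type_effects), mismatch_types()) ||
    length(type_effects) != 12L) {
    abort_validation("`type_effects` must be named by the 12 mismatch types")
  }
  if (is.null(position_weights)) {
    position_weights <- default_position_weights()
  }
  if (length(position_weights) != PROBE_LENGTH || any(position_weights < 0)) {
    abort_validation("`position_weights` must be 25 non-negative values")
  }
  tidyr::expand_grid(
    position = seq_len(PROBE_LENGTH),
    mismatch_type = mismatch_types()
  ) %>%
    dplyr::mutate(delta = unname(type_effects[.data$mismatch_type]) *
      position_weights[.data$position])
}

# Two-sided power falloff from position 12 plus a small Gaussian bump that
# keeps the peak identifiable over the otherwise steady center; constants
# solved once against the target contrasts documented in the vignette.
default_position_weights <- function() {
  i <- seq_len(PROBE_LENGTH)
  a_left <- 0.3646478
  a_right <- 0.4749093
  p_left <- 7.245963
  p_right <- 8.157814
  bump <- 0.08
  f <- ifelse(i <= 12,
    1 - a_left * ((12 - i) / 11)^p_left,
    1 - a_right * ((i - 12) / 13)^p_right
  )
  g <- exp(-(i - 12)^2 / (2 * 1.5^2))
  (f + bump * g) / (1 + bump)
}

#' Ground-truth parameters for the synthetic generator
#'
#' Bundles every knob of the generative model: the penalty surface `delta`,
#' per-tissue log2 abundance offsets, the spread of per-probe baseline
#' affinities, per-measurement noise, and the composition of the second
#' design (fractions of identical-control and multi-mismatch probes).
#'
#' @param delta Penalty table as from [default_delta_surface()]: one `delta`
#'   value (log2 units) per (position 1..25, mismatch type) cell, 300 rows.
#' @param tissue_effects Named numeric vector of per-tissue log2 abundance
#'   offsets; the default emulates five RNA sources.
#' @param probe_affinity_sd Standard deviation (log2 units) of per-probe
#'   baseline affinities shared by paired probes across designs.
#' @param noise_sd Standard deviation (log2 units) of independent
#'   per-measurement noise.
#' @param control_fraction Proportion of probes copied unchanged into the
#'   second design (identical-probe controls).
#' @param multi_mismatch_fraction Proportion of probes given exactly two
#'   substitutions (exercises the exclusion filter); the remainder get one.
#' @param baseline_log2 Mean baseline log2 intensity of a probe.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `xsmm_truth`.
#' @export
simulation_truth <- function(delta = default_delta_surface(),
                             tissue_effects = c(
                               fibroblast = 0, cortex = 0.6, pancreas = -0.4,
                               testes = 1.1, thymus = -0.8
                             ),
                             probe_affinity_sd = 1.0,
                             noise_sd = 0.3,
                             control_fraction = 0.6,
                             multi_mismatch_fraction = 0.1,
                             baseline_log2 = 8,
                             seed = 1L) {
  assert_data_frame(delta, "delta", c("position", "mismatch_type", "delta"))
  delta <- as_tibble(delta)
  cells <- paste(delta$position, delta$mismatch_type)
  want <- paste(
    rep(seq_len(PROBE_LENGTH), each = 12L),
    rep(mismatch_types(), PROBE_LENGTH)
  )
  if (nrow(delta) != 300L || !setequal(cells, want) || anyDuplicated(cells)) {
    abort_validation("`delta` must have exactly one row per (position 1..25, mismatch type) cell")
  }
  if (is.null(names(tissue_effects)) || length(tissue_effects) < 2L) {
    abort_validation("`tissue_effects` must be a named vector with >= 2 tissues")
  }
  for (f in c(control_fraction, multi_mismatch_fraction)) {
    if (!is.numeric(f) || f < 0 || f > 1) {
      abort_validation("fractions must lie in [0, 1]")
    }
  }
  if (control_fraction + multi_mismatch_fraction > 1) {
    abort_validation("control_fraction + multi_mismatch_fraction must be <= 1")
  }
  if (noise_sd < 0 || probe_affinity_sd < 0) {
    abort_validation("standard deviations must be >= 0")
  }
  structure(
    list(
      delta = delta,
      tissue_effects = tissue_effects,
      probe_affinity_sd = probe_affinity_sd,
      noise_sd = noise_sd,
      control_fraction = control_fraction,
      multi_mismatch_fraction = multi_mismatch_fraction,
      baseline_log2 = baseline_log2,
      seed = as.integer(seed)
    ),
    class = "xsmm_truth"
  )
}

#' @export
print.xsmm_truth <- function(x, ...) {
  cat("<xsmm_truth>\n")
  cat(sprintf(
    "  tissues: %s\n", paste(names(x$tissue_effects), collapse = ", ")
  ))
  cat(sprintf(
    "  fractions: control %.2f, multi-mismatch %.2f, single %.2f\n",
    x$control_fraction, x$multi_mismatch_fraction,
    1 - x$control_fraction - x$multi_mismatch_fraction
  ))
  cat(sprintf(
    "  probe_affinity_sd %.2f, noise_sd %.2f, seed %d\n",
    x$probe_affinity_sd, x$noise_sd, x$seed
  ))
  invisible(x)
}

normalize_weights <- function(w, n, names = NULL, arg = "weights") {
  if (is.null(w)) {
    w <- rep(1, n)
  }
  if (!is.null(names) && !is.null(names(w))) {
    w <- w[names]
  }
  if (length(w) != n || any(is.na(w)) || any(w < 0) || sum(w) == 0) {
    abort_validation(sprintf(
      "`%s` must be %d non-negative weights with positive sum", arg, n
    ))
  }
  w / sum(w)
}

#' Generate paired probe designs over shared consensus sequences
#'
#' Builds `n_probesets` random consensus sequences, tiles `probes_per_set`
#' non-overlapping 25-mer windows left-to-right across each (so probe order
#' follows consensus coordinate), and derives two designs: the PM design
#' copies each window exactly; the second (query) design copies it unchanged
#' (controls), with one substitution at a drawn (position, type) — the
#' consensus base at that offset is set to the type's PM base first, so the
#' type is realized exactly — or with two substitutions at distinct positions
#' (multi-mismatch fodder). Category draws use the fractions in `truth`;
#' position and type draws use `position_weights`/`type_weights` (default
#' uniform over 25 positions x 12 types).
#'
#' @param truth An [simulation_truth()] object.
#' @param n_probesets,probes_per_set Number of probesets and probes per set.
#' @param consensus_length Consensus length in bases; defaults to a tiling
#'   with small inter-probe gaps. Must leave room for non-overlapping
#'   windows.
#' @param position_weights Optional length-25 sampling weights for the
#'   substituted position.
#' @param type_weights Optional sampling weights for the 12 mismatch types
#'   (named or in [mismatch_types()] order).
#' @return A list of class `xsmm_designs` with elements `consensus` (tibble
#'   id/sequence), `pm_probes`, `query_probes` (probe-table tibbles) and
#'   `ledger` (one row per query probe: `probe_id`, `pm_probe_id`,
#'   `category`, `position`, `mismatch_type`, `consensus_id`, `start`, `end`,
#'   `true_penalty`).
#' @export
#' @examples
#' truth <- simulation_truth(seed = 42)
#' d <- generate_designs(truth, n_probesets = 3, probes_per_set = 4)
#' d$ledger
generate_designs <- function(truth, n_probesets = 100L, probes_per_set = 11L,
                             consensus_length = NULL,
                             position_weights = NULL, type_weights = NULL) {
  stopifnot(inherits(truth, "xsmm_truth"))
  n_probesets <- assert_scalar_count(n_probesets, "n_probesets")
  probes_per_set <- assert_scalar_count(probes_per_set, "probes_per_set")
  gap <- 5L
  if (is.null(consensus_length)) {
    consensus_length <- probes_per_set * (PROBE_LENGTH + gap) + 15L
  }
  consensus_length <- assert_scalar_count(consensus_length, "consensus_length")
  min_len <- probes_per_set * PROBE_LENGTH
  if (consensus_length < min_len) {
    abort_sizing(sprintf(
      "consensus_length %d too short for %d non-overlapping 25-mer probes (need >= %d)",
      consensus_length, probes_per_set, min_len
    ))
  }
  pos_w <- normalize_weights(position_weights, PROBE_LENGTH, arg = "position_weights")
  type_w <- normalize_weights(type_weights, 12L, mismatch_types(), "type_weights")

  delta_lookup <- setNames(
    truth$delta$delta,
    paste0(truth$delta$position, ":", truth$delta$mismatch_type)
  )
  slack <- consensus_length - min_len
  n_total <- n_probesets * probes_per_set

  withr::with_seed(truth$seed, {
    ps_ids <- sprintf("PS%05d", seq_len(n_probesets))
    # category per probe
    cats <- sample(
      c("control", "multi_mismatch", "single_mismatch"), n_total,
      replace = TRUE,
      prob = c(
        truth$control_fraction, truth$multi_mismatch_fraction,
        1 - truth$control_fraction - truth$multi_mismatch_fraction
      )
    )
    consensus <- character(n_probesets)
    rows_pm <- vector("list", n_probesets)
    rows_q <- vector("list", n_probesets)
    rows_led <- vector("list", n_probesets)
    k <- 0L
    for (s in seq_len(n_probesets)) {
      cons <- sample(DNA_BASES, consensus_length, replace = TRUE)
      # left-to-right tiling with random non-negative gaps summing to `slack`
      gaps <- if (slack > 0L) {
        tabulate(sample.int(probes_per_set + 1L, slack, replace = TRUE),
          nbins = probes_per_set + 1L
        )
      } else {
        integer(probes_per_set + 1L)
      }
      starts <- cumsum(c(1L, rep(PROBE_LENGTH, probes_per_set - 1L))) +
        cumsum(gaps[seq_len(probes_per_set)])
      cat_s <- cats[k + seq_len(probes_per_set)]
      pos <- rep(NA_integer_, probes_per_set)
      typ <- rep(NA_character_, probes_per_set)
      penalty <- numeric(probes_per_set)
      single <- which(cat_s == "single_mismatch")
      if (length(single) > 0L) {
        pos[single] <- sample.int(PROBE_LENGTH, length(single),
          replace = TRUE, prob = pos_w
        )
        typ[single] <- sample(mismatch_types(), length(single),
          replace = TRUE, prob = type_w
        )
        # plant the PM base on the consensus so the drawn type is realized
        cons[starts[single] + pos[single] - 1L] <- pm_base(typ[single])
        penalty[single] <- unname(delta_lookup[paste0(pos[single], ":", typ[single])])
      }
      pm_seqs <- vapply(
        starts,
        function(st) paste(cons[st:(st + PROBE_LENGTH - 1L)], collapse = ""),
        character(1)
      )
      q_seqs <- pm_seqs
      if (length(single) > 0L) {
        substr(q_seqs[single], pos[single], pos[single]) <- mm_base(typ[single])
      }
      for (j in which(cat_s == "multi_mismatch")) {
        p2 <- sort(sample.int(PROBE_LENGTH, 2L))
        chars <- strsplit(q_seqs[j], "")[[1L]]
        pen <- 0
        for (p in p2) {
          new_base <- sample(setdiff(DNA_BASES, chars[p]), 1L)
          pen <- pen + unname(delta_lookup[paste0(p, ":", chars[p], "-", new_base)])
          chars[p] <- new_base
        }
        q_seqs[j] <- paste(chars, collapse = "")
        penalty[j] <- pen
      }
      consensus[s] <- paste(cons, collapse = "")
      base_id <- sprintf("%s_%02d", ps_ids[s], seq_len(probes_per_set))
      rows_pm[[s]] <- tibble(
        probeset_id = ps_ids[s], probe_id = paste0(base_id, "_A"),
        order_index = seq_len(probes_per_set), sequence = pm_seqs,
        design_id = "arrayA"
      )
      rows_q[[s]] <- tibble(
        probeset_id = ps_ids[s], probe_id = paste0(base_id, "_B"),
        order_index = seq_len(probes_per_set), sequence = q_seqs,
        design_id = "arrayB"
      )
      rows_led[[s]] <- tibble(
        probe_id = paste0(base_id, "_B"),
        pm_probe_id = paste0(base_id, "_A"),
        category = cat_s, position = pos, mismatch_type = typ,
        consensus_id = ps_ids[s], start = starts,
        end = starts + PROBE_LENGTH - 1L, true_penalty = penalty
      )
      k <- k + probes_per_set
    }
    out <- list(
      consensus = tibble(id = ps_ids, sequence = consensus),
      pm_probes = dplyr::bind_rows(rows_pm),
      query_probes = dplyr::bind_rows(rows_q),
      ledger = dplyr::bind_rows(rows_led)
    )
  })
  structure(out, class = "xsmm_designs")
}

#' Simulate probe-level intensities for both designs
#'
#' Log2 intensity of a probe on an array is
#' `affinity + tissue_effect - penalty + noise`, where the per-probe baseline
#' affinity is shared between the paired PM-design and query-design probes,
#' `penalty` is the ledger's true penalty (0 for PM-design probes and
#' identical-control copies; `delta(i, type)` for a single-mismatch copy; the
#' sum of its two substitution penalties for multi-mismatch fodder), and the
#' noise is independent Gaussian with `truth$noise_sd`. Intensities are
#' returned on the linear scale, clipped below at `2^-10`, with one array per
#' (platform, tissue, replicate).
#'
#' @param truth An [simulation_truth()] object.
#' @param designs Result of [generate_designs()].
#' @param tissues Number of tissues to simulate (>= 2); uses the first
#'   `tissues` entries of `truth$tissue_effects`.
#' @param replicates Replicate arrays per (platform, tissue), >= 2.
#' @return A list with elements `pm` and `query`, each a list with `values`
#'   (wide tibble, `probe_id` plus one column per array) and `metadata`.
#' @export
simulate_intensities <- function(truth, designs,
                                 tissues = length(truth$tissue_effects),
                                 replicates = 2L) {
  stopifnot(inherits(truth, "xsmm_truth"), inherits(designs, "xsmm_designs"))
  tissues <- assert_scalar_count(tissues, "tissues", min = 2L)
  replicates <- assert_scalar_count(replicates, "replicates", min = 2L)
  if (tissues > length(truth$tissue_effects)) {
    abort_validation("more tissues requested than defined in `truth$tissue_effects`")
  }
  ledger <- designs$ledger
  bad <- setdiff(
    unique(ledger$category),
    c("control", "single_mismatch", "multi_mismatch")
  )
  if (length(bad) > 0L) {
    abort(sprintf("unknown ledger category: %s", paste(bad, collapse = ", ")),
      class = c("xsmm_internal_error", "xsmm_error")
    )
  }
  t_eff <- truth$tissue_effects[seq_len(tissues)]
  n_probes <- nrow(ledger)

  withr::with_seed(stage_seed(truth$seed, 1L), {
    affinity <- rnorm(n_probes, truth$baseline_log2, truth$probe_affinity_sd)
    one_platform <- function(platform, probe_ids, penalty) {
      meta <- tidyr::expand_grid(
        tissue = names(t_eff), replicate = seq_len(replicates)
      ) %>%
        dplyr::mutate(
          platform = platform,
          array_id = sprintf("%s_%s_r%d", platform, .data$tissue, .data$replicate)
        ) %>%
        dplyr::select("array_id", "platform", "tissue", "replicate")
      vals <- matrix(NA_real_, n_probes, nrow(meta),
        dimnames = list(probe_ids, meta$array_id)
      )
      for (a in seq_len(nrow(meta))) {
        mu <- affinity + t_eff[[meta$tissue[a]]] - penalty
        vals[, a] <- mu + rnorm(n_probes, 0, truth$noise_sd)
      }
      list(
        values = matrix_as_intensity(pmax(2^vals, 2^-10)),
        metadata = meta
      )
    }
    out <- list(
      pm = one_platform("arrayA", ledger$pm_probe_id, 0),
      query = one_platform("arrayB", ledger$probe_id, ledger$true_penalty)
    )
  })
  out
}

#' Write every artifact of a synthetic run to a directory
#'
#' Writes the consensus FASTA, both probe tables, the ground-truth ledger and
#' the two intensity matrices (values + metadata TSVs) using the package's
#' deterministic writers.
#'
#' @param designs Result of [generate_designs()].
#' @param intensities Result of [simulate_intensities()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_run <- function(designs, intensities, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(designs$consensus, file.path(dir, "consensus.fa"))
  write_probe_table(designs$pm_probes, file.path(dir, "pm_probes.tsv"))
  write_probe_table(designs$query_probes, file.path(dir, "query_probes.tsv"))
  ledger <- dplyr::arrange(designs$ledger, .data$probe_id)
  readr::write_tsv(ledger, file.path(dir, "ledger.tsv"))
  write_intensity_matrix(
    intensities$pm,
    file.path(dir, "pm_values.tsv"), file.path(dir, "pm_metadata.tsv")
  )
  write_intensity_matrix(
    intensities$query,
    file.path(dir, "query_values.tsv"), file.path(dir, "query_metadata.tsv")
  )
  invisible(dir)
}
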