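# Semi-global probe-to-consensus alignment: the probe aligns end-to-end,
# consensus end gaps are free. A sliding-window Hamming scan serves as a
# provably optimal fast path whenever the best ungapped window's score meets
# the upper bound achievable by any gapped alignment; otherwise a full
# affine-gap dynamic program runs.

#' Alignment scoring parameters
#'
#' Scores for the semi-global probe-to-consensus alignment. The default
#' scale (match +1, mismatch -1, gap open 5, gap extend 0.5) is chosen so
#' that for a 25-mer a single substitution always outscores any gapped
#' alternative; a one-base gap costs `gap_open + gap_extend = 5.5` while two
#' substitutions cost 4.
#'
#' @param match_score,mismatch_score Per-base scores; `match_score` must
#'   exceed `mismatch_score`.
#' @param gap_open_penalty,gap_extend_penalty Non-negative affine gap costs;
#'   a gap of length L costs `gap_open_penalty + L * gap_extend_penalty`.
#' @return An object of class `xsmm_alignment_params`.
#' @export
alignment_params <- function(match_score = 1, mismatch_score = -1,
                             gap_open_penalty = 5, gap_extend_penalty = 0.5) {
  if (gap_open_penalty < 0 || gap_extend_penalty < 0) {
    abort_validation("gap penalties must be >= 0")
  }
  if (match_score <= mismatch_score) {
    abort_validation("`match_score` must exceed `mismatch_score`")
  }
  structure(
    list(
      match_score = match_score, mismatch_score = mismatch_score,
      gap_open_penalty = gap_open_penalty,
      gap_extend_penalty = gap_extend_penalty
    ),
    class = "xsmm_alignment_params"
  )
}

# 25 x W matrix of consensus windows as raw bytes; reused across the probes
# of one probeset.
consensus_window_matrix <- function(cons_raw) {
  n <- length(cons_raw)
  w <- n - PROBE_LENGTH + 1L
  idx <- outer(0:(PROBE_LENGTH - 1L), seq_len(w), "+")
  matrix(cons_raw[idx], nrow = PROBE_LENGTH)
}

#' Align one probe to a consensus sequence
#'
#' Semi-global alignment maximizing the affine-gap score: the probe is
#' aligned end-to-end while consensus overhangs are free. Ties are broken
#' deterministically (leftmost window for ungapped optima, then fewest
#' gaps). Coordinates are 1-based inclusive on the consensus; mismatch
#' positions are probe coordinates (1 = the 5'-most base of the probe as
#' written).
#'
#' @param sequence Probe sequence (25-mer character scalar).
#' @param consensus Consensus sequence (character scalar, length >= 25).
#' @param params An [alignment_params()] object.
#' @return One-row tibble with columns `start`, `end`, `score`, `gap_count`
#'   (gapped columns in the alignment), `probe_fully_aligned` (no probe base
#'   opposite a gap), `n_mismatch`, and list-columns `mismatch_positions`
#'   (integer probe coordinates, ascending) and `mismatch_pairs` (strings
#'   `"<consensus base>-<probe base>"`).
#' @export
#' @examples
#' align_probe("ACGTACGTACGTACGTACGTACGTA", paste0(
#'   "GGGGG", "ACGTACGTACGTACGTACGTACGTA", "TTTTT"
#' ))
align_probe <- function(sequence, consensus, params = alignment_params()) {
  stopifnot(inherits(params, "xsmm_alignment_params"))
  if (nchar(sequence) != PROBE_LENGTH) {
    abort_validation(sprintf(
      "probe sequence must be %d bases, got %d", PROBE_LENGTH, nchar(sequence)
    ))
  }
  if (nchar(consensus) < PROBE_LENGTH) {
    abort_sizing(sprintf(
      "consensus (%d bases) shorter than the probe (%d bases)",
      nchar(consensus), PROBE_LENGTH
    ))
  }
  cons_raw <- charToRaw(consensus)
  res <- align_core(
    charToRaw(sequence), cons_raw,
    consensus_window_matrix(cons_raw), params
  )
  alignment_tibble(list(res))
}

# Core alignment returning a plain list (tibble assembly is deferred so
# bulk drivers stay fast).
align_core <- function(probe_raw, cons_raw, cons_mat, params) {
  counts <- .colSums(
    cons_mat != probe_raw, PROBE_LENGTH, ncol(cons_mat)
  )
  k <- min(counts)
  j <- which.min(counts) # leftmost best window
  s0 <- (PROBE_LENGTH - k) * params$match_score + k * params$mismatch_score
  gapped_bound <- PROBE_LENGTH * params$match_score -
    (params$gap_open_penalty + params$gap_extend_penalty)
  if (s0 >= gapped_bound) {
    mm <- which(cons_mat[, j] != probe_raw)
    return(list(
      start = j, end = j + PROBE_LENGTH - 1L, score = s0,
      gap_count = 0L, probe_fully_aligned = TRUE,
      mismatch_positions = as.integer(mm),
      mismatch_pairs = paste0(
        rawToChar(cons_mat[mm, j], multiple = TRUE), "-",
        rawToChar(probe_raw[mm], multiple = TRUE)
      )
    ))
  }
  align_dp(probe_raw, cons_raw, params)
}

alignment_tibble <- function(results) {
  tibble(
    start = vapply(results, function(r) as.integer(r$start), integer(1)),
    end = vapply(results, function(r) as.integer(r$end), integer(1)),
    score = vapply(results, `[[`, numeric(1), "score"),
    gap_count = vapply(results, `[[`, integer(1), "gap_count"),
    probe_fully_aligned = vapply(results, `[[`, logical(1), "probe_fully_aligned"),
    n_mismatch = vapply(results, function(r) length(r$mismatch_positions), integer(1)),
    mismatch_positions = lapply(results, `[[`, "mismatch_positions"),
    mismatch_pairs = lapply(results, `[[`, "mismatch_pairs")
  )
}

# Full affine-gap semi-global dynamic program with traceback. Row-vectorized;
# the horizontal (consensus-gap) recurrence uses a running-max trick.
align_dp <- function(probe_raw, cons_raw, params) {
  m <- PROBE_LENGTH
  n <- length(cons_raw)
  open <- params$gap_open_penalty
  ext <- params$gap_extend_penalty
  NEG <- -1e18
  M <- matrix(NEG, m + 1L, n + 1L)
  X <- matrix(NEG, m + 1L, n + 1L) # probe base opposite a gap
  Y <- matrix(NEG, m + 1L, n + 1L) # consensus base opposite a gap
  M[1L, ] <- 0 # free consensus prefix
  jj <- seq_len(n)
  for (i in seq_len(m)) {
    s <- ifelse(cons_raw == probe_raw[i], params$match_score, params$mismatch_score)
    prev_best <- pmax(M[i, jj], X[i, jj], Y[i, jj])
    M[i + 1L, jj + 1L] <- s + prev_best
    X[i + 1L, ] <- pmax(M[i, ] - open - ext, X[i, ] - ext)
    a <- M[i + 1L, jj + 1L] + jj * ext
    run <- cummax(c(M[i + 1L, 1L], a[-n]))
    Y[i + 1L, jj + 1L] <- run - open - jj * ext
  }
  final <- pmax(M[m + 1L, ], X[m + 1L, ])
  best <- max(final)
  end_col <- which(final >= best - 1e-9)[1L] # leftmost end among ties
  state <- if (M[m + 1L, end_col] >= X[m + 1L, end_col]) "M" else "X"
  i <- m
  jc <- end_col - 1L
  tol <- 1e-9
  aligned_cons <- integer(0)
  mm_pos <- integer(0)
  mm_cons <- character(0)
  mm_probe <- character(0)
  n_gap <- 0L
  fully <- TRUE
  while (i > 0L) {
    if (state == "M") {
      aligned_cons <- c(aligned_cons, jc)
      if (cons_raw[jc] != probe_raw[i]) {
        mm_pos <- c(mm_pos, i)
        mm_cons <- c(mm_cons, rawToChar(cons_raw[jc]))
        mm_probe <- c(mm_probe, rawToChar(probe_raw[i]))
      }
      val <- M[i + 1L, jc + 1L] -
        ifelse(cons_raw[jc] == probe_raw[i], params$match_score, params$mismatch_score)
      state <- if (abs(M[i, jc] - val) < tol) {
        "M"
      } else if (abs(X[i, jc] - val) < tol) {
        "X"
      } else {
        "Y"
      }
      i <- i - 1L
      jc <- jc - 1L
    } else if (state == "X") {
      n_gap <- n_gap + 1L
      fully <- FALSE
      val <- X[i + 1L, jc + 1L]
      state <- if (abs(M[i, jc + 1L] - open - ext - val) < tol) "M" else "X"
      i <- i - 1L
    } else { # Y
      n_gap <- n_gap + 1L
      aligned_cons <- c(aligned_cons, jc)
      val <- Y[i + 1L, jc + 1L]
      state <- if (abs(M[i + 1L, jc] - open - ext - val) < tol) "M" else "Y"
      jc <- jc - 1L
    }
  }
  ord <- order(mm_pos)
  list(
    start = if (length(aligned_cons) > 0L) min(aligned_cons) else NA_integer_,
    end = if (length(aligned_cons) > 0L) max(aligned_cons) else NA_integer_,
    score = best, gap_count = n_gap, probe_fully_aligned = fully,
    mismatch_positions = as.integer(mm_pos[ord]),
    mismatch_pairs = paste0(mm_cons[ord], "-", mm_probe[ord])
  )
}

#' Align a probe table against its consensus set
#'
#' Vectorized driver for [align_probe()]: each probe is aligned to the
#' consensus of its probeset. Unless the probe table carries an explicit
#' `consensus_id` column, the consensus id is taken to equal `probeset_id`.
#'
#' @param probes Probe-table tibble (see [read_probe_table()]).
#' @param consensus Consensus tibble with columns `id`, `sequence`.
#' @param params An [alignment_params()] object.
#' @return Tibble with one row per probe: the probe-table keys plus the
#'   [align_probe()] columns and `consensus_id`.
#' @export
align_probes <- function(probes, consensus, params = alignment_params()) {
  probes <- validate_probe_table(probes)
  assert_data_frame(consensus, "consensus", c("id", "sequence"))
  cons_id <- if ("consensus_id" %in% names(probes)) {
    probes$consensus_id
  } else {
    probes$probeset_id
  }
  missing_cons <- setdiff(unique(cons_id), consensus$id)
  if (length(missing_cons) > 0L) {
    abort_validation(sprintf(
      "no consensus sequence for: %s",
      paste(utils::head(missing_cons, 5L), collapse = ", ")
    ))
  }
  too_short <- nchar(consensus$sequence) < PROBE_LENGTH
  if (any(too_short)) {
    abort_sizing(sprintf(
      "consensus %s is shorter than a probe", consensus$id[which(too_short)[1L]]
    ))
  }
  cons_seq <- setNames(consensus$sequence, consensus$id)
  row_order <- order(match(cons_id, unique(cons_id)))
  results <- vector("list", nrow(probes))
  pos <- 1L
  for (cid in unique(cons_id)) {
    rows <- which(cons_id == cid)
    cons_raw <- charToRaw(cons_seq[[cid]])
    cons_mat <- consensus_window_matrix(cons_raw)
    for (r in rows) {
      results[[pos]] <- align_core(
        charToRaw(probes$sequence[r]), cons_raw, cons_mat, params
      )
      pos <- pos + 1L
    }
  }
  dplyr::bind_cols(
    probes[row_order, c("probeset_id", "probe_id", "order_index")],
    tibble(consensus_id = cons_id[row_order]),
    alignment_tibble(results)
  )
}
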