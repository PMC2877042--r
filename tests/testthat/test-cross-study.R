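vec12 <- function(values, study = "s", direction = "discrimination") {
  tibble::tibble(
    study_id = study, mismatch_type = mismatch_types(),
    value = values, direction = direction
  )
}

test_that("notation conversion matches the duplex convention and round-trips", {
  # A->C: probe provides the MM base C, target the complement of PM base A
  ac <- convert_notation("A-C", chemistry = "RNA")
  expect_equal(ac$probe_base, "C")
  expect_equal(ac$target_base, "U")
  expect_equal(ac$duplex, "C/U")

  gt <- convert_notation("G-T", chemistry = "RNA")
  expect_equal(gt$probe_base, "T")
  expect_equal(gt$target_base, "C")

  dna <- convert_notation("A-C", chemistry = "DNA")
  expect_equal(dna$target_base, "T")

  for (chem in c("RNA", "DNA")) {
    conv <- convert_notation(mismatch_types(), chemistry = chem)
    expect_equal(
      duplex_to_type(conv$duplex, chemistry = chem),
      mismatch_types()
    )
  }
  expect_error(duplex_to_type("A/X"), class = "xsmm_validation_error")
  # a self-pair is not a mismatch
  expect_error(duplex_to_type("T/A"), class = "xsmm_validation_error")
  expect_error(convert_notation("A-A"), class = "xsmm_validation_error")
})

test_that("pair-class consolidation splits the 12 types six and six", {
  expect_equal(consolidate_pair_class("A-G"), "AT_pair")
  expect_equal(consolidate_pair_class("C-A"), "CG_pair")
  classes <- consolidate_pair_class(mismatch_types())
  expect_equal(sum(classes == "AT_pair"), 6L)
  expect_equal(sum(classes == "CG_pair"), 6L)
})

test_that("rank vectors follow direction semantics with average ties", {
  inc <- vec12(seq(0.1, 1.2, by = 0.1))
  same <- rank_types(inc, "discrimination", "discrimination")
  expect_equal(same$rank, as.numeric(1:12))
  flipped <- rank_types(inc, "discrimination", "stability")
  expect_equal(flipped$rank, as.numeric(12:1))

  tied <- vec12(c(0.5, 0.5, seq(1, 10)))
  tr <- rank_types(tied, "stability")
  expect_equal(tr$rank[1:2], c(1.5, 1.5))

  incomplete <- vec12(seq(0.1, 1.2, by = 0.1))[-3, ]
  expect_error(
    rank_types(incomplete, "stability"),
    regexp = "A-T", class = "xsmm_validation_error"
  )
})

test_that("study correlations: self, reversal, and the rank-difference oracle", {
  set.seed(61)
  v <- sample(seq(0.1, 1.2, by = 0.1))
  studies <- dplyr::bind_rows(
    vec12(v, "self_a"),
    vec12(v, "self_b"),
    vec12(rev(sort(v))[rank(v)], "reversed") # value order exactly reversed
  )
  rep <- correlate_studies(studies)
  self_row <- rep[rep$study_a == "self_a" & rep$study_b == "self_b", ]
  expect_equal(self_row$spearman_rho, 1)
  expect_equal(self_row$pearson_r, 1)
  rev_row <- rep[rep$study_a == "self_a" & rep$study_b == "reversed", ]
  expect_equal(rev_row$spearman_rho, -1)

  # symmetric with unit diagonal
  diag_rows <- rep[rep$study_a == rep$study_b, ]
  expect_true(all(diag_rows$spearman_rho == 1))
  ab <- rep[rep$study_a == "self_a" & rep$study_b == "reversed", ]
  ba <- rep[rep$study_a == "reversed" & rep$study_b == "self_a", ]
  expect_equal(ab$pearson_r, ba$pearson_r)

  # independent oracle: rho = 1 - 6 sum(d^2) / (n(n^2-1)) on untied ranks
  set.seed(62)
  x <- rnorm(12)
  y <- rnorm(12)
  two <- correlate_studies(dplyr::bind_rows(vec12(x, "x"), vec12(y, "y")))
  d2 <- sum((rank(x) - rank(y))^2)
  rho_oracle <- 1 - 6 * d2 / (12 * (12^2 - 1))
  xy <- two[two$study_a == "x" & two$study_b == "y", ]
  expect_equal(xy$spearman_rho, rho_oracle, tolerance = 1e-12)
  # t-approximation p-value oracle
  t_stat <- rho_oracle * sqrt(10 / (1 - rho_oracle^2))
  expect_equal(xy$spearman_p, 2 * pt(-abs(t_stat), 10), tolerance = 1e-12)
  # pearson against cor.test
  ct <- cor.test(-x, -y) # harmonized to stability by negation
  expect_equal(xy$pearson_r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(xy$pearson_p, ct$p.value, tolerance = 1e-12)
})

test_that("spearman is invariant under monotone transforms; exact p available", {
  set.seed(63)
  x <- rnorm(12)
  y <- rnorm(12)
  base <- correlate_studies(dplyr::bind_rows(vec12(x, "x"), vec12(y, "y")))
  warped <- correlate_studies(dplyr::bind_rows(
    vec12(exp(x), "x"), vec12(y^3 + 10 * y, "y")
  ))
  get <- function(r) r[r$study_a == "x" & r$study_b == "y", ]
  expect_equal(get(warped)$spearman_rho, get(base)$spearman_rho, tolerance = 1e-12)

  ex <- correlate_studies(
    dplyr::bind_rows(vec12(x, "x"), vec12(y, "y")),
    spearman_p = "exact"
  )
  ct <- suppressWarnings(cor.test(-x, -y, method = "spearman", exact = TRUE))
  expect_equal(get(ex)$spearman_p, ct$p.value, tolerance = 1e-12)

  # mixed directions are harmonized before correlating
  mixed <- correlate_studies(dplyr::bind_rows(
    vec12(x, "disc", "discrimination"), vec12(-x, "stab", "stability")
  ))
  expect_equal(
    mixed$spearman_rho[mixed$study_a == "disc" & mixed$study_b == "stab"], 1
  )
})

test_that("Watson-Crick outlier flagging implements the block rule", {
  at_types <- mismatch_types()[consolidate_pair_class(mismatch_types()) == "AT_pair"]
  cg_types <- setdiff(mismatch_types(), at_types)

  block <- tibble::tibble(
    mismatch_type = c(at_types, cg_types),
    stability_position = 1:12
  )
  expect_equal(nrow(flag_wc_outliers(block)), 0L)

  # an AT-class type at stability position 9 is flagged
  swapped <- block
  swapped$stability_position[swapped$mismatch_type == at_types[1]] <- 9
  swapped$stability_position[swapped$mismatch_type == cg_types[3]] <- 1
  flags <- flag_wc_outliers(swapped)
  expect_setequal(flags$mismatch_type, c(at_types[1], cg_types[3]))
  expect_equal(
    flags$expected[flags$mismatch_type == at_types[1]], "1-6"
  )

  # flag counts are symmetric on any permutation (pigeonhole)
  set.seed(64)
  for (i in 1:20) {
    perm <- tibble::tibble(
      mismatch_type = mismatch_types(),
      stability_position = sample.int(12)
    )
    fl <- flag_wc_outliers(perm)
    expect_equal(
      sum(fl$pair_class == "AT_pair"), sum(fl$pair_class == "CG_pair")
    )
  }

  expect_error(flag_wc_outliers(block[-1, ]), class = "xsmm_validation_error")
})

test_that("stability positions orient rank 1 at the most stable type", {
  # discrimination values: smallest log2(PM/MM) = most stable = position 1
  set.seed(65)
  v <- vec12(runif(12))
  sp <- stability_positions(v, "discrimination")
  expect_equal(
    sp$mismatch_type[sp$stability_position == 1],
    v$mismatch_type[which.min(v$value)]
  )
  # for stability-direction values the largest value takes position 1
  sv <- vec12(runif(12), direction = "stability")
  sp2 <- stability_positions(sv, "stability")
  expect_equal(
    sp2$mismatch_type[sp2$stability_position == 1],
    sv$mismatch_type[which.max(sv$value)]
  )
})

test_that("bundled synthetic study vectors load and correlate", {
  a <- read_study_vector(
    system.file("extdata", "study_vector_synthetic_A.tsv", package = "xsmm"),
    "synthA", "discrimination"
  )
  b <- read_study_vector(
    system.file("extdata", "study_vector_synthetic_B.tsv", package = "xsmm"),
    "synthB", "stability"
  )
  rep <- correlate_studies(dplyr::bind_rows(a, b))
  expect_equal(nrow(rep), 4L)
  expect_true(all(abs(rep$spearman_rho) <= 1))
})
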