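#' The 12 single-base mismatch types
#'
#' A mismatch type is written in PM->MM notation: the first letter is the base
#' on the perfect-match (PM) probe — which equals the consensus base at the
#' aligned offset — and the second letter is the base substituted on the
#' mismatch (MM) probe. Twelve ordered pairs exist over the DNA alphabet.
#'
#' @return Character vector of the 12 types, e.g. `"A-C"`, in the canonical
#'   order used throughout the package (PM base A, T, C, G; MM base
#'   alphabetical within each).
#' @export
#' @examples
#' mismatch_types()
mismatch_types <- function() {
  c(
    "A-C", "A-G", "A-T",
    "T-A", "T-C", "T-G",
    "C-A", "C-G", "C-T",
    "G-A", "G-C", "G-T"
  )
}

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

check_mismatch_types <- function(types, arg = "mismatch_type") {
  types <- as.character(types)
  bad <- setdiff(unique(types), mismatch_types())
  if (length(bad) > 0L) {
    abort_validation(sprintf(
      "invalid %s value(s): %s (expected one of the 12 PM->MM types)",
      arg, paste(bad, collapse = ", ")
    ))
  }
  types
}

#' Split a mismatch type into its PM and MM bases
#'
#' @param types Character vector of PM->MM mismatch types (e.g. `"C-A"`).
#' @return For `pm_base()`/`mm_base()`, a character vector of single bases.
#' @export
#' @examples
#' pm_base("C-A") # "C"
#' mm_base("C-A") # "A"
pm_base <- function(types) {
  substr(check_mismatch_types(types), 1L, 1L)
}

#' @rdname pm_base
#' @export
mm_base <- function(types) {
  substr(check_mismatch_types(types), 3L, 3L)
}

#' Consolidate mismatch types into Watson-Crick pair classes
#'
#' Each mismatch disrupts the Watson-Crick pair the PM base would have formed
#' with the target: types whose PM base is A or T disrupt an A-T pair
#' (`"AT_pair"`), those with PM base C or G disrupt a C-G pair (`"CG_pair"`).
#' Six types fall in each class.
#'
#' @param types Character vector of PM->MM mismatch types.
#' @return Character vector of `"AT_pair"` / `"CG_pair"`.
#' @export
#' @examples
#' consolidate_pair_class(c("A-G", "C-A"))
consolidate_pair_class <- function(types) {
  ifelse(pm_base(types) %in% c("A", "T"), "AT_pair", "CG_pair")
}

#' Bin probe positions into 5' / center / 3' groups
#'
#' Positions 1-8 form the 5' end group (position 1 is the 5'-most base of the
#' probe as written), 9-17 the center, and 18-25 the 3' end (the end attached
#' to the array surface).
#'
#' @param positions Integer vector of probe positions in 1..25.
#' @return Factor with levels `five_prime`, `center`, `three_prime`.
#' @export
#' @examples
#' position_group(c(1, 13, 25))
position_group <- function(positions) {
  positions <- as.integer(positions)
  if (any(is.na(positions) | positions < 1L | positions > PROBE_LENGTH)) {
    abort_validation("`positions` must be integers in 1..25")
  }
  cut(positions,
    breaks = c(0, 8, 17, 25),
    labels = c("five_prime", "center", "three_prime")
  )
}

position_group_levels <- function() c("five_prime", "center", "three_prime")
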