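# The 15-bp chromosome breakage sequence (Cbs) family: consensus, degeneracy
# pattern, and variant-label arithmetic. The consensus C-rich strand sequence
# is TAAACCAACCTCTTT; family degeneracy is restricted to positions 1, 11, 13,
# 14 and 15 (W, Y, N, H, W respectively).

CBS_CONSENSUS <- "TAAACCAACCTCTTT"
CBS_LENGTH <- 15L

# perl-compatible regex for the family on the C-rich strand; the letter N in
# input sequence never matches because character classes enumerate ACGT only.
CBS_FAMILY_REGEX <- "[AT]AAACCAACC[CT]C[ACGT][ACT][AT]"

#' Classify a 15-mer against the Cbs consensus
#'
#' Compares a candidate chromosome breakage sequence (C-rich strand) with the
#' consensus `TAAACCAACCTCTTT` and labels it by its substitutions, e.g.
#' `"11C"` or `"1A,15A"`; the consensus itself is labelled `"canonical"`.
#' Sequences with more than two substitutions are labelled the same way but
#' flagged non-functional, matching the empirical observation that no
#' functional family member carries more than two substitutions.
#'
#' @param sequence character, a single 15-base sequence (C-rich strand).
#' @return list with `variant` (label), `n_substitutions`, and `functional`
#'   (TRUE iff at most two substitutions).
#' @examples
#' classify_variant("TAAACCAACCCCTTT")  # "11C"
#' @export
classify_variant <- function(sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) != CBS_LENGTH)
    stop("Cbs variant classification requires a 15-base sequence, got ",
         nchar(sequence), " bases")
  s <- strsplit(sequence, "")[[1]]
  k <- strsplit(CBS_CONSENSUS, "")[[1]]
  mm <- which(s != k)
  if (length(mm) == 0L)
    return(list(variant = "canonical", n_substitutions = 0L, functional = TRUE))
  list(variant = paste0(mm, s[mm], collapse = ","),
       n_substitutions = length(mm),
       functional = length(mm) <= 2L)
}

# inverse of classify_variant: build the 15-mer for a variant label
variant_to_sequence <- function(variant) {
  vapply(variant, function(v) {
    if (v == "canonical") return(CBS_CONSENSUS)
    s <- strsplit(CBS_CONSENSUS, "")[[1]]
    for (sub in strsplit(v, ",")[[1]]) {
      pos <- as.integer(sub("([0-9]+)[ACGT]$", "\\1", sub))
      base <- sub("^[0-9]+", "", sub)
      if (is.na(pos) || pos < 1L || pos > CBS_LENGTH || !(base %in% DNA_BASES))
        stop("malformed Cbs variant label: ", v)
      s[pos] <- base
    }
    paste(s, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Published Cbs variant spectrum
#'
#' Returns the per-variant counts of the 225 mapped chromosome breakage
#' sequences of the *T. thermophila* germline assembly, as distributed with
#' the package (`inst/extdata/cbs_variant_table.tsv`): 109 canonical copies,
#' 93 single-substitution and 23 double-substitution variants.
#'
#' @return data.frame with columns `variant`, `count`, `sequence`,
#'   `n_substitutions`.
#' @export
cbs_variant_counts <- function() {
  path <- system.file("extdata", "cbs_variant_table.tsv", package = "micmac")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$sequence <- variant_to_sequence(tab$variant)
  tab$n_substitutions <- vapply(tab$sequence,
                                function(s) classify_variant(s)$n_substitutions,
                                integer(1), USE.NAMES = FALSE)
  tab
}

#' Published micronuclear centromere interval table
#'
#' Per-chromosome locations (Mb) of the most centromere-proximal chromosome
#' breakage sequence on each arm, chromosome lengths, and derived centromere
#' spans, as distributed with the package
#' (`inst/extdata/centromere_table.tsv`).
#'
#' @return data.frame with columns `chromosome`, `l_cbs_mb`, `r_cbs_mb`,
#'   `length_mb`.
#' @export
centromere_intervals <- function() {
  path <- system.file("extdata", "centromere_table.tsv", package = "micmac")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# expand the variant table into one sequence per Cbs copy
expand_variant_counts <- function(tab = cbs_variant_counts()) {
  rep(tab$sequence, tab$count)
}
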