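#' Fixed label vocabularies
#'
#' The three label axes of the property theory of Chinese materia medica as
#' recorded in pharmacopoeia monographs: five properties (natures), seven
#' flavors, and twelve meridian tropisms. The vector order is the canonical
#' order used throughout the package: triplets are sorted lexicographically by
#' (property, flavor, meridian) position in these vectors, which fixes the row
#' order of the triplet measurement matrix.
#'
#' @return A character vector of labels.
#' @examples
#' length(pccmm_properties()) * length(pccmm_flavors()) * length(pccmm_meridians())
#' @export
pccmm_properties <- function() {
  c("cold", "warm", "even", "cool", "hot")
}

#' @rdname pccmm_properties
#' @export
pccmm_flavors <- function() {
  c("bitter", "pungent", "sweet", "sour", "astringent", "salty", "bland")
}

#' @rdname pccmm_properties
#' @export
pccmm_meridians <- function() {
  c(
    "liver", "lung", "spleen", "stomach", "kidney", "heart",
    "large-intestine", "small-intestine", "sanjiao", "bladder",
    "pericardium", "gallbladder"
  )
}

#' Current label vocabulary (overridable)
#'
#' Internal accessor that returns the three vocabularies as a list. Alternate
#' property systems (other ethnopharmacological traditions use different but
#' structurally identical label tuples) can be supplied to the parsing
#' functions via their `vocab` argument in this same list shape.
#'
#' @keywords internal
#' @noRd
default_vocab <- function() {
  list(
    properties = pccmm_properties(),
    flavors = pccmm_flavors(),
    meridians = pccmm_meridians()
  )
}

check_vocab <- function(vocab) {
  stopifnot(
    is.list(vocab),
    all(c("properties", "flavors", "meridians") %in% names(vocab))
  )
  for (axis in c("properties", "flavors", "meridians")) {
    v <- vocab[[axis]]
    if (!is.character(v) || anyDuplicated(v) || any(!nzchar(v))) {
      stop("invalid vocabulary for axis '", axis, "'", call. = FALSE)
    }
  }
  vocab
}

#' Normalize a label token
#'
#' Lower-cases, trims, and collapses internal whitespace/underscores to
#' hyphens, so "Large Intestine", "large_intestine" and "large-intestine" all
#' resolve to the same token.
#'
#' @keywords internal
#' @noRd
normalize_label <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]_]+", "-", x)
}

# Dense triplet index over the full vocabulary product, 1-based:
# tid = (p-1) * n_f * n_m + (f-1) * n_m + m. Canonical (lexicographic) triplet
# order is increasing tid.
triplet_id <- function(p_idx, f_idx, m_idx, vocab = default_vocab()) {
  nf <- length(vocab$flavors)
  nm <- length(vocab$meridians)
  (p_idx - 1L) * nf * nm + (f_idx - 1L) * nm + m_idx
}

triplet_from_id <- function(tid, vocab = default_vocab()) {
  nf <- length(vocab$flavors)
  nm <- length(vocab$meridians)
  tid0 <- tid - 1L
  data.frame(
    property = vocab$properties[tid0 %/% (nf * nm) + 1L],
    flavor = vocab$flavors[(tid0 %/% nm) %% nf + 1L],
    meridian = vocab$meridians[tid0 %% nm + 1L],
    stringsAsFactors = FALSE
  )
}

triplet_label <- function(tid, vocab = default_vocab()) {
  tf <- triplet_from_id(tid, vocab)
  paste(tf$property, tf$flavor, tf$meridian, sep = "|")
}

#' Enumerate the full triplet space
#'
#' All property x flavor x meridian triplets over a vocabulary, in canonical
#' order. With the default vocabularies this yields 5 * 7 * 12 = 420 triplets,
#' of which only a minority are observed in any real pharmacopoeia.
#'
#' @param vocab Vocabulary list (`properties`, `flavors`, `meridians`).
#' @return A data frame with columns `property`, `flavor`, `meridian`, `tid`
#'   (the dense triplet index) and `label`.
#' @examples
#' nrow(full_triplet_space())  # 420
#' @export
full_triplet_space <- function(vocab = default_vocab()) {
  vocab <- check_vocab(vocab)
  n <- length(vocab$properties) * length(vocab$flavors) * length(vocab$meridians)
  tids <- seq_len(n)
  out <- triplet_from_id(tids, vocab)
  out$tid <- tids
  out$label <- paste(out$property, out$flavor, out$meridian, sep = "|")
  out
}
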