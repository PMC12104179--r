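#' Build the Boolean triplet measurement matrix
#'
#' Column j of the m x N matrix P is the 0-1 indicator, over the observed
#' triplet space, of the triplet set of the j-th materia medica: P[k, j] = 1
#' iff triplet k belongs to the expansion of record j. The matrix is stored
#' sparse (compressed columns); with pharmacopoeia-scale input the density is
#' well under 2 percent.
#'
#' @param records A `pcmm_table`.
#' @param spaces The `pccmm_spaces` built from the same records.
#' @return A `dgCMatrix` with rownames = triplet labels, colnames = CMM ids.
#' @export
build_pccmm_matrix <- function(records, spaces) {
  stopifnot(inherits(records, "pcmm_table"), inherits(spaces, "pccmm_spaces"))
  complete <- records[records$complete, , drop = FALSE]
  if (!identical(complete$cmm_id, spaces$cmm$ids)) {
    stop("spaces were not built from these records (CMM id mismatch)", call. = FALSE)
  }
  vocab <- spaces$vocab
  tid_sets <- record_tids(complete, vocab)
  rows <- spaces$pccmm$index[as.character(unlist(tid_sets))]
  if (anyNA(rows)) {
    stop("record expands to a triplet outside the space; rebuild the spaces", call. = FALSE)
  }
  cols <- rep.int(seq_along(tid_sets), lengths(tid_sets))
  P <- Matrix::sparseMatrix(
    i = as.integer(rows), j = cols, x = 1,
    dims = c(spaces$m, spaces$N),
    dimnames = list(spaces$pccmm$labels, spaces$cmm$ids)
  )
  methods::as(P, "CsparseMatrix")
}

#' Encode a formula as a 0-1 membership vector
#'
#' @param cmm_ids Character vector of member ids (distinct).
#' @param space A `pccmm_spaces` object.
#' @return Named integer 0/1 vector of length N with support at the members.
#' @export
encode_formula <- function(cmm_ids, space) {
  stopifnot(inherits(space, "pccmm_spaces"))
  if (anyDuplicated(cmm_ids)) {
    stop("duplicate ids in formula: ", paste(unique(cmm_ids[duplicated(cmm_ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  x <- setNames(integer(space$N), space$cmm$ids)
  if (length(cmm_ids)) {
    idx <- space$cmm$index[cmm_ids]
    if (anyNA(idx)) {
      stop("unresolvable id(s): ", paste(cmm_ids[is.na(idx)], collapse = ", "),
        call. = FALSE
      )
    }
    x[idx] <- 1L
  }
  x
}

#' Forward measurement: formula vector to triplet-set vector
#'
#' The weighted measurement is the exact integer count y_w = P x (how many of
#' the formula's members carry each triplet); the unweighted measurement is
#' its entrywise cap y = min(P x, 1), the 0-1 indicator of the union of the
#' members' triplet sets. Both share the same support.
#'
#' @param P The measurement matrix from [build_pccmm_matrix()].
#' @param x A 0-1 formula vector of length `ncol(P)`.
#' @param weighted If `TRUE` return the integer count vector, else the 0-1
#'   capped vector.
#' @return Named integer vector of length `nrow(P)`.
#' @export
measure <- function(P, x, weighted = FALSE) {
  if (length(x) != ncol(P)) stop("length(x) != ncol(P)", call. = FALSE)
  if (!all(x %in% c(0L, 1L))) stop("x must be a 0-1 vector", call. = FALSE)
  yw <- as.integer(round(as.numeric(P %*% x)))
  out <- if (weighted) yw else pmin(yw, 1L)
  setNames(out, rownames(P))
}

#' Jaccard similarity of two 0-1 vectors
#'
#' |supp intersection| / |supp union|; the set Jaccard coefficient expressed
#' on indicator vectors via entrywise min and max. Undefined (an error) when
#' both vectors are zero.
#'
#' @param x1,x2 0-1 vectors of equal length.
#' @return A number in [0, 1].
#' @examples
#' jaccard(c(1, 1, 1, 0), c(0, 1, 1, 1)) # 0.5
#' @export
jaccard <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("vectors differ in length", call. = FALSE)
  if (!all(x1 %in% c(0, 1)) || !all(x2 %in% c(0, 1))) {
    stop("jaccard() is defined for 0-1 vectors", call. = FALSE)
  }
  u <- sum(pmax(x1, x2))
  if (u == 0) stop("Jaccard similarity undefined for two empty supports", call. = FALSE)
  sum(pmin(x1, x2)) / u
}

#' Cosine similarity of two vectors
#'
#' @param x1,x2 Numeric vectors of equal length, neither all-zero.
#' @return dot(x1, x2) / (||x1|| ||x2||).
#' @export
cosine <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("vectors differ in length", call. = FALSE)
  n1 <- sqrt(sum(x1^2))
  n2 <- sqrt(sum(x2^2))
  if (n1 == 0 || n2 == 0) stop("cosine similarity undefined for a zero vector", call. = FALSE)
  sum(x1 * x2) / (n1 * n2)
}

#' Export / import the measurement matrix in Matrix Market format
#'
#' MTX coordinate format (1-based) is the interchange standard for sparse
#' matrices; dimnames are written to sibling `.rows`/`.cols` text files so the
#' triplet labels and CMM ids survive the round trip.
#'
#' @param P Sparse matrix.
#' @param path Output `.mtx` path.
#' @export
write_pccmm_matrix <- function(P, path) {
  Matrix::writeMM(methods::as(P, "CsparseMatrix"), path)
  writeLines(rownames(P), paste0(path, ".rows"))
  writeLines(colnames(P), paste0(path, ".cols"))
  invisible(path)
}

#' @rdname write_pccmm_matrix
#' @export
read_pccmm_matrix <- function(path) {
  P <- methods::as(Matrix::readMM(path) * 1, "CsparseMatrix")
  rfile <- paste0(path, ".rows")
  cfile <- paste0(path, ".cols")
  dimnames(P) <- list(
    if (file.exists(rfile)) readLines(rfile) else NULL,
    if (file.exists(cfile)) readLines(cfile) else NULL
  )
  P
}
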