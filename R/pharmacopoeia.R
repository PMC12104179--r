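#' @importFrom stats setNames
NULL

new_pcmm_table <- function(df) {
  structure(df, class = c("pcmm_table", "data.frame"))
}

split_labels <- function(cell, sep) {
  if (is.na(cell) || !nzchar(trimws(cell))) {
    return(character(0))
  }
  toks <- normalize_label(strsplit(cell, sep, fixed = TRUE)[[1]])
  toks[nzchar(toks)]
}

validate_labels <- function(labels, axis, vocab, row_id) {
  bad <- setdiff(labels, vocab[[axis]])
  if (length(bad)) {
    stop(
      "unknown ", axis, " label(s) for record '", row_id, "': ",
      paste(sQuote(bad), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(labels)) {
    stop("duplicated ", axis, " label within record '", row_id, "'", call. = FALSE)
  }
  labels
}

#' Construct a materia-medica table from label sets
#'
#' In-memory constructor for the record table that [parse_cmm_table()] reads
#' from disk. Each record carries the three label sets of one materia medica
#' (CMM); a record is "complete" when all three sets are non-empty, and only
#' complete records are admitted to the CMM/triplet spaces.
#'
#' @param cmm_id Character vector of unique external identifiers.
#' @param properties,flavors,meridians Lists of character vectors, one label
#'   set per record.
#' @param pinyin_name,latin_name Optional name columns.
#' @param vocab Vocabulary list; labels outside it are a hard error.
#' @return A `pcmm_table` data frame with list-columns `properties`,
#'   `flavors`, `meridians` and a logical `complete` column.
#' @export
pcmm_table <- function(cmm_id, properties, flavors, meridians,
                       pinyin_name = cmm_id, latin_name = cmm_id,
                       vocab = default_vocab()) {
  vocab <- check_vocab(vocab)
  n <- length(cmm_id)
  stopifnot(
    length(properties) == n, length(flavors) == n, length(meridians) == n,
    length(pinyin_name) == n, length(latin_name) == n
  )
  if (anyDuplicated(cmm_id)) {
    stop("duplicate cmm_id: ", paste(unique(cmm_id[duplicated(cmm_id)]), collapse = ", "),
      call. = FALSE
    )
  }
  properties <- lapply(seq_len(n), function(i) {
    validate_labels(normalize_label(properties[[i]]), "properties", vocab, cmm_id[i])
  })
  flavors <- lapply(seq_len(n), function(i) {
    validate_labels(normalize_label(flavors[[i]]), "flavors", vocab, cmm_id[i])
  })
  meridians <- lapply(seq_len(n), function(i) {
    validate_labels(normalize_label(meridians[[i]]), "meridians", vocab, cmm_id[i])
  })
  df <- data.frame(
    cmm_id = as.character(cmm_id),
    pinyin_name = as.character(pinyin_name),
    latin_name = as.character(latin_name),
    stringsAsFactors = FALSE
  )
  df$properties <- properties
  df$flavors <- flavors
  df$meridians <- meridians
  df$complete <- lengths(properties) > 0 & lengths(flavors) > 0 & lengths(meridians) > 0
  attr(df, "vocab") <- vocab
  new_pcmm_table(df)
}

#' Parse a delimited materia-medica table
#'
#' Reads one record per row with columns `cmm_id`, `pinyin_name`,
#' `latin_name`, `properties`, `flavors`, `meridians`. Multi-label cells are
#' split on `label_sep` (default `";"`). Label strings are normalized
#' (case/whitespace) and validated against the vocabulary; an unknown token is
#' a hard error naming the record and the token. Records with any empty label
#' set are flagged incomplete (kept in the table, excluded from spaces).
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator (default `,`; use `"\t"` for TSV).
#' @param label_sep Separator inside multi-label cells.
#' @param vocab Vocabulary list.
#' @param quiet Suppress the parse report message.
#' @return A `pcmm_table`; see [pcmm_table()].
#' @export
parse_cmm_table <- function(path, sep = ",", label_sep = ";",
                            vocab = default_vocab(), quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path,
    header = TRUE, sep = sep, quote = "\"",
    stringsAsFactors = FALSE, comment.char = "", strip.white = TRUE,
    colClasses = "character"
  )
  names(raw) <- tolower(trimws(names(raw)))
  needed <- c("cmm_id", "properties", "flavors", "meridians")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"pinyin_name" %in% names(raw)) raw$pinyin_name <- raw$cmm_id
  if (!"latin_name" %in% names(raw)) raw$latin_name <- raw$cmm_id
  tab <- pcmm_table(
    cmm_id = trimws(raw$cmm_id),
    properties = lapply(raw$properties, split_labels, sep = label_sep),
    flavors = lapply(raw$flavors, split_labels, sep = label_sep),
    meridians = lapply(raw$meridians, split_labels, sep = label_sep),
    pinyin_name = trimws(raw$pinyin_name),
    latin_name = trimws(raw$latin_name),
    vocab = vocab
  )
  if (!quiet) {
    message(
      "parsed ", nrow(tab), " records from ", path, ": ",
      sum(tab$complete), " complete, ", sum(!tab$complete), " incomplete"
    )
  }
  tab
}

#' Expand a record's label sets into its triplet set
#'
#' The triplet ("PCCMM") set of a materia medica is the Cartesian product of
#' its property, flavor and meridian label sets: a record with n1 properties,
#' n2 flavors and n3 meridians expands to exactly n1 * n2 * n3 triplets.
#'
#' @param properties,flavors,meridians Character vectors of labels, or pass a
#'   single-row `pcmm_table` as `properties` to expand that record.
#' @param vocab Vocabulary list.
#' @return Data frame of triplets in canonical order with columns `property`,
#'   `flavor`, `meridian`, `tid`, `label`.
#' @examples
#' mahuang <- expand_triplets("warm", c("bitter", "pungent"), c("lung", "bladder"))
#' nrow(mahuang) # 4
#' @export
expand_triplets <- function(properties, flavors = NULL, meridians = NULL,
                            vocab = default_vocab()) {
  if (inherits(properties, "pcmm_table")) {
    rec <- properties
    if (nrow(rec) != 1L) stop("pass exactly one record", call. = FALSE)
    vocab <- attr(rec, "vocab") %||% vocab
    flavors <- rec$flavors[[1L]]
    meridians <- rec$meridians[[1L]]
    properties <- rec$properties[[1L]]
  }
  vocab <- check_vocab(vocab)
  if (!length(properties) || !length(flavors) || !length(meridians)) {
    stop("incomplete record: all three label sets must be non-empty", call. = FALSE)
  }
  p_idx <- match(normalize_label(properties), vocab$properties)
  f_idx <- match(normalize_label(flavors), vocab$flavors)
  m_idx <- match(normalize_label(meridians), vocab$meridians)
  if (anyNA(p_idx) || anyNA(f_idx) || anyNA(m_idx)) {
    stop("label outside vocabulary in expand_triplets()", call. = FALSE)
  }
  grid <- expand.grid(p = p_idx, f = f_idx, m = m_idx, KEEP.OUT.ATTRS = FALSE)
  tids <- sort(unique(triplet_id(grid$p, grid$f, grid$m, vocab)))
  out <- triplet_from_id(tids, vocab)
  out$tid <- tids
  out$label <- paste(out$property, out$flavor, out$meridian, sep = "|")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

record_tids <- function(records, vocab) {
  lapply(seq_len(nrow(records)), function(i) {
    if (!records$complete[i]) {
      return(integer(0))
    }
    expand_triplets(records$properties[[i]], records$flavors[[i]],
      records$meridians[[i]],
      vocab = vocab
    )$tid
  })
}

#' Build the CMM and triplet spaces from a record table
#'
#' The CMM space is the ordered list of complete records (input order); the
#' triplet space is the union of the records' expanded triplet sets in
#' canonical order — only observed triplets enter the space, not the full
#' 420-element vocabulary product. Both spaces are deterministic given the
#' input, and permuting input rows permutes CMM indices identically while
#' leaving the triplet space unchanged as a set.
#'
#' @param records A `pcmm_table`.
#' @return An object of class `pccmm_spaces`: a list with elements `cmm`
#'   (list: `ids`, named `index`) and `pccmm` (list: `tids`, `labels`,
#'   `table`, named `index`), plus `N` and `m`.
#' @export
build_spaces <- function(records) {
  stopifnot(inherits(records, "pcmm_table"))
  vocab <- attr(records, "vocab") %||% default_vocab()
  complete <- records[records$complete, , drop = FALSE]
  if (nrow(complete) == 0L) stop("no complete records: cannot build spaces", call. = FALSE)
  ids <- complete$cmm_id
  tid_sets <- record_tids(complete, vocab)
  tids <- sort(unique(unlist(tid_sets)))
  tab <- triplet_from_id(tids, vocab)
  tab$tid <- tids
  tab$label <- paste(tab$property, tab$flavor, tab$meridian, sep = "|")
  structure(
    list(
      cmm = list(ids = ids, index = setNames(seq_along(ids), ids)),
      pccmm = list(
        tids = tids, labels = tab$label, table = tab,
        index = setNames(seq_along(tids), as.character(tids))
      ),
      N = length(ids), m = length(tids), vocab = vocab
    ),
    class = "pccmm_spaces"
  )
}

#' @exportS3Method base::print
print.pccmm_spaces <- function(x, ...) {
  cat(
    "<pccmm_spaces> N =", x$N, "materia medica, m =", x$m,
    "observed triplets\n"
  )
  invisible(x)
}

#' Load incompatible (contraindicated) herb pairs
#'
#' Reads a two-column id table of unordered contraindicated pairs (the
#' "eighteen incompatible medicaments" tradition). Pairs are deduplicated
#' ignoring order; self-pairs are an error; pairs naming an id outside the
#' CMM space are dropped with a warning, since reconstruction only ranges
#' over the space.
#'
#' @param path Delimited text file with columns `cmm_id_1`, `cmm_id_2`, or a
#'   two-column data frame / character matrix.
#' @param space A `pccmm_spaces` object (or its `$cmm` component).
#' @param sep Field separator for file input.
#' @param quiet Suppress the count message.
#' @return An `incompatible_pairs` object: a two-column character matrix of
#'   resolved pairs with an `index_pairs` attribute (two-column integer
#'   matrix of 1-based CMM indices).
#' @export
load_incompatible_pairs <- function(path, space, sep = ",", quiet = FALSE) {
  if (is.character(path) && length(path) == 1L && !is.matrix(path)) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    df <- utils::read.table(path,
      header = TRUE, sep = sep, stringsAsFactors = FALSE,
      strip.white = TRUE, colClasses = "character"
    )
  } else {
    df <- as.data.frame(path, stringsAsFactors = FALSE)
  }
  if (ncol(df) < 2L) stop("pair table needs two id columns", call. = FALSE)
  a <- trimws(as.character(df[[1L]]))
  b <- trimws(as.character(df[[2L]]))
  incompatible_pairs(a, b, space, quiet = quiet)
}

#' @rdname load_incompatible_pairs
#' @param a,b Character vectors of the two pair members.
#' @export
incompatible_pairs <- function(a, b, space, quiet = FALSE) {
  cmm <- if (inherits(space, "pccmm_spaces")) space$cmm else space
  stopifnot(length(a) == length(b))
  if (any(a == b)) stop("self-pair in incompatible pair table", call. = FALSE)
  ia <- cmm$index[a]
  ib <- cmm$index[b]
  unresolved <- is.na(ia) | is.na(ib)
  if (any(unresolved)) {
    warning(
      sum(unresolved), " incompatible pair(s) reference ids outside the CMM space; dropped",
      call. = FALSE
    )
    a <- a[!unresolved]
    b <- b[!unresolved]
    ia <- ia[!unresolved]
    ib <- ib[!unresolved]
  }
  lo <- pmin(ia, ib)
  hi <- pmax(ia, ib)
  keep <- !duplicated(paste(lo, hi))
  idx <- cbind(lo[keep], hi[keep])
  ids <- cbind(cmm$ids[idx[, 1L]], cmm$ids[idx[, 2L]])
  colnames(ids) <- c("cmm_id_1", "cmm_id_2")
  if (!quiet) message("loaded ", nrow(ids), " incompatible pair(s)")
  structure(ids, index_pairs = idx, class = c("incompatible_pairs", class(ids)))
}

#' An empty incompatible-pair set
#' @param space A `pccmm_spaces` object.
#' @export
no_pairs <- function(space) {
  incompatible_pairs(character(0), character(0), space, quiet = TRUE)
}

#' Parse a formula catalog
#'
#' One formula per row with columns `formula_id`, `cmm_ids` (`label_sep`-
#' joined member ids) and optional `batch` and `syndrome` columns. Every
#' member id must resolve in the CMM space and members must be distinct
#' within a formula.
#'
#' @param path Delimited text file, or a data frame in the same shape.
#' @param space A `pccmm_spaces` object.
#' @param sep,label_sep Field and in-cell separators.
#' @return A `formula_catalog` data frame with list-column `cmm_ids`.
#' @export
parse_formula_catalog <- function(path, space, sep = ",", label_sep = ";") {
  if (is.character(path) && length(path) == 1L) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    df <- utils::read.table(path,
      header = TRUE, sep = sep, stringsAsFactors = FALSE,
      strip.white = TRUE, colClasses = "character"
    )
  } else {
    df <- as.data.frame(path, stringsAsFactors = FALSE)
  }
  names(df) <- tolower(trimws(names(df)))
  if (!all(c("formula_id", "cmm_ids") %in% names(df))) {
    stop("formula catalog needs columns formula_id and cmm_ids", call. = FALSE)
  }
  members <- lapply(df$cmm_ids, function(cell) {
    toks <- trimws(strsplit(cell, label_sep, fixed = TRUE)[[1L]])
    toks[nzchar(toks)]
  })
  formula_catalog(
    formula_id = trimws(df$formula_id),
    cmm_ids = members,
    batch = if ("batch" %in% names(df)) trimws(df$batch) else NA_character_,
    syndrome = if ("syndrome" %in% names(df)) trimws(df$syndrome) else NA_character_,
    space = space
  )
}

#' @rdname parse_formula_catalog
#' @param formula_id Character vector of formula ids.
#' @param cmm_ids List of character vectors of member ids.
#' @param batch,syndrome Optional per-formula tags.
#' @export
formula_catalog <- function(formula_id, cmm_ids, batch = NA_character_,
                            syndrome = NA_character_, space = NULL) {
  n <- length(formula_id)
  stopifnot(length(cmm_ids) == n)
  if (anyDuplicated(formula_id)) stop("duplicate formula_id", call. = FALSE)
  batch <- rep_len(as.character(batch), n)
  syndrome <- rep_len(as.character(syndrome), n)
  for (i in seq_len(n)) {
    mem <- cmm_ids[[i]]
    if (anyDuplicated(mem)) {
      stop("duplicate member ids in formula '", formula_id[i], "'", call. = FALSE)
    }
    if (!is.null(space)) {
      bad <- mem[is.na(space$cmm$index[mem])]
      if (length(bad)) {
        stop(
          "formula '", formula_id[i], "' references unknown id(s): ",
          paste(bad, collapse = ", "),
          call. = FALSE
        )
      }
    }
  }
  df <- data.frame(
    formula_id = as.character(formula_id), batch = batch,
    syndrome = syndrome, stringsAsFactors = FALSE
  )
  df$cmm_ids <- cmm_ids
  structure(df, class = c("formula_catalog", "data.frame"))
}

#' Write a formula catalog back to delimited text
#' @param catalog A `formula_catalog`.
#' @param path Output path.
#' @param sep,label_sep Field and in-cell separators.
#' @export
write_formula_catalog <- function(catalog, path, sep = ",", label_sep = ";") {
  df <- data.frame(
    formula_id = catalog$formula_id,
    batch = catalog$batch,
    cmm_ids = vapply(catalog$cmm_ids, paste, "", collapse = label_sep),
    syndrome = catalog$syndrome,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path,
    sep = sep, row.names = FALSE, quote = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Write a materia-medica table to delimited text
#' @param records A `pcmm_table`.
#' @param path Output path.
#' @param sep,label_sep Field and in-cell separators.
#' @export
write_cmm_table <- function(records, path, sep = ",", label_sep = ";") {
  df <- data.frame(
    cmm_id = records$cmm_id,
    pinyin_name = records$pinyin_name,
    latin_name = records$latin_name,
    properties = vapply(records$properties, paste, "", collapse = label_sep),
    flavors = vapply(records$flavors, paste, "", collapse = label_sep),
    meridians = vapply(records$meridians, paste, "", collapse = label_sep),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path,
    sep = sep, row.names = FALSE, quote = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Write incompatible pairs to delimited text
#' @param pairs An `incompatible_pairs` object.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_incompatible_pairs <- function(pairs, path, sep = ",") {
  df <- data.frame(
    cmm_id_1 = pairs[, 1L], cmm_id_2 = pairs[, 2L],
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
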