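#' Transaction encodings of a formula catalog
#'
#' One transaction per formula. At the CMM level the items are the formula's
#' member ids; at the triplet (PCCMM) level the items are the labels of the
#' union of the members' triplet sets (deduplicated within the formula, set
#' semantics).
#'
#' @param catalog A `formula_catalog`.
#' @param level `"cmm"` or `"pccmm"`.
#' @param P Measurement matrix (required for `level = "pccmm"`).
#' @param spaces Matching `pccmm_spaces` (required for `level = "pccmm"`).
#' @return A `transaction_set`: list with `items` (list of character
#'   vectors), `universe` (sorted item vocabulary), `level`.
#' @export
catalog_transactions <- function(catalog, level = c("cmm", "pccmm"),
                                 P = NULL, spaces = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(catalog, "formula_catalog"))
  items <- if (level == "cmm") {
    catalog$cmm_ids
  } else {
    if (is.null(P) || is.null(spaces)) {
      stop("level = \"pccmm\" needs P and spaces", call. = FALSE)
    }
    lapply(catalog$cmm_ids, function(ids) {
      y <- measure(P, encode_formula(ids, spaces), weighted = FALSE)
      names(y)[y == 1L]
    })
  }
  transaction_set(items, level = level, ids = catalog$formula_id)
}

#' @rdname catalog_transactions
#' @param items List of character item vectors (distinct within each
#'   transaction).
#' @param ids Optional transaction ids.
#' @export
transaction_set <- function(items, level = "custom", ids = NULL) {
  stopifnot(is.list(items))
  for (i in seq_along(items)) {
    if (anyDuplicated(items[[i]])) {
      stop("duplicate item within transaction ", i, call. = FALSE)
    }
  }
  structure(
    list(
      items = items, universe = sort(unique(unlist(items))),
      level = level, ids = ids
    ),
    class = "transaction_set"
  )
}

#' Write / read transactions in basket format
#'
#' One transaction per line, items joined by `label_sep`.
#' @param tx A `transaction_set`.
#' @param path File path.
#' @param label_sep In-line item separator.
#' @export
write_transactions <- function(tx, path, label_sep = ";") {
  writeLines(vapply(tx$items, paste, "", collapse = label_sep), path)
  invisible(path)
}

#' @rdname write_transactions
#' @export
read_transactions <- function(path, label_sep = ";") {
  lines <- readLines(path)
  items <- lapply(strsplit(lines, label_sep, fixed = TRUE), function(v) v[nzchar(v)])
  transaction_set(items)
}

tx_matrix <- function(tx, items = tx$universe) {
  M <- matrix(FALSE, nrow = length(tx$items), ncol = length(items),
    dimnames = list(tx$ids, items)
  )
  for (i in seq_along(tx$items)) {
    hit <- match(tx$items[[i]], items)
    M[i, hit[!is.na(hit)]] <- TRUE
  }
  M
}

#' Item frequency table
#'
#' Exact occurrence counts of every item across the transactions, each
#' item's share of the total occurrences, and the cumulative share under the
#' decreasing-count ranking (ties broken by item name).
#'
#' @param tx A `transaction_set`.
#' @return A data frame with columns `item`, `count`, `proportion`,
#'   `cumulative`, sorted by decreasing count.
#' @export
item_frequency <- function(tx) {
  stopifnot(inherits(tx, "transaction_set"))
  if (!length(tx$items)) stop("empty transaction set", call. = FALSE)
  counts <- table(unlist(tx$items))
  df <- data.frame(
    item = names(counts), count = as.integer(counts),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$count, df$item), , drop = FALSE]
  total <- sum(df$count)
  df$proportion <- df$count / total
  df$cumulative <- cumsum(df$proportion)
  rownames(df) <- NULL
  attr(df, "n_transactions") <- length(tx$items)
  attr(df, "total_occurrences") <- total
  df
}

#' Select high-frequency items
#'
#' Items whose occurrence count reaches `min_count`, together with the share
#' of all item occurrences they account for. There is no universal
#' high-frequency threshold in the field; the cutoff is a parameter.
#'
#' @param freq An [item_frequency()] table.
#' @param min_count Minimum occurrence count (>= 1).
#' @return List with `items`, `table` (the selected rows) and
#'   `cumulative_proportion`.
#' @export
high_frequency_items <- function(freq, min_count) {
  stopifnot(min_count >= 1)
  sel <- freq[freq$count >= min_count, , drop = FALSE]
  list(
    items = sel$item, table = sel,
    cumulative_proportion = sum(sel$count) / sum(freq$count)
  )
}

#' Aggregate an item frequency table by category
#'
#' Sums counts over a user-supplied item-to-category mapping (for example a
#' functional classification of herbs); items missing from the mapping fall
#' into an explicit `"unclassified"` bucket. Proportions are relative to the
#' selected items' total.
#'
#' @param freq An [item_frequency()] table (or its high-frequency subset).
#' @param mapping Named character vector (`item -> category`) or a data frame
#'   with columns `item`, `category`.
#' @return Data frame with `category`, `count`, `proportion`, sorted by
#'   decreasing count.
#' @export
aggregate_by_category <- function(freq, mapping) {
  if (is.data.frame(mapping)) {
    mapping <- setNames(as.character(mapping$category), mapping$item)
  }
  cat <- unname(mapping[freq$item])
  cat[is.na(cat)] <- "unclassified"
  agg <- stats::aggregate(list(count = freq$count), by = list(category = cat), FUN = sum)
  agg <- agg[order(-agg$count, agg$category), , drop = FALSE]
  agg$proportion <- agg$count / sum(agg$count)
  rownames(agg) <- NULL
  agg
}

# Levelwise apriori frequent-itemset search. Itemsets are kept as sorted
# integer index vectors into `items`; support counting goes through the
# logical transaction matrix.
frequent_itemsets <- function(M, min_support, max_len) {
  n_tx <- nrow(M)
  min_count <- ceiling(min_support * n_tx - 1e-9)
  supp1 <- colSums(M)
  frequent <- list()
  current <- lapply(which(supp1 >= min_count), function(j) j)
  current_supp <- supp1[supp1 >= min_count]
  k <- 1L
  while (length(current) && k <= max_len) {
    frequent[[k]] <- list(sets = current, support = current_supp / n_tx)
    if (k == max_len) break
    keys <- vapply(current, paste, "", collapse = ",")
    # join step: combine itemsets sharing the first k-1 elements
    prefixes <- vapply(current, function(s) paste(s[-length(s)], collapse = ","), "")
    cand <- list()
    for (pf in unique(prefixes)) {
      group <- current[prefixes == pf]
      if (length(group) < 2L) next
      lasts <- sort(vapply(group, function(s) s[length(s)], 0L))
      base <- group[[1L]][-length(group[[1L]])]
      combs <- utils::combn(lasts, 2L)
      for (c_i in seq_len(ncol(combs))) {
        cand[[length(cand) + 1L]] <- c(base, combs[, c_i])
      }
    }
    if (!length(cand)) break
    # prune: all k-subsets must be frequent
    keyset <- new.env(hash = TRUE, parent = emptyenv())
    for (key in keys) assign(key, TRUE, envir = keyset)
    keep <- vapply(cand, function(s) {
      all(vapply(seq_along(s), function(drop) {
        exists(paste(s[-drop], collapse = ","), envir = keyset)
      }, TRUE))
    }, TRUE)
    cand <- cand[keep]
    if (!length(cand)) break
    counts <- vapply(cand, function(s) sum(rowSums(M[, s, drop = FALSE]) == length(s)), 0)
    ok <- counts >= min_count
    current <- cand[ok]
    current_supp <- counts[ok]
    k <- k + 1L
  }
  frequent
}

#' Mine association rules (apriori)
#'
#' Levelwise apriori over the transactions followed by rule generation with
#' single-item consequents: for every frequent itemset L of size >= 2 and
#' every item c in L, the rule (L \ c) -> c is emitted when support(L) >=
#' `min_support`, confidence = support(L)/support(L \ c) >= `min_confidence`,
#' and lift = confidence/support(c) > `min_lift` (the lift filter is strict).
#'
#' @param tx A `transaction_set`.
#' @param min_support Minimum rule support (fraction of transactions).
#' @param min_confidence Minimum confidence.
#' @param min_lift Strict lower bound on lift.
#' @param max_len Maximum total rule length (antecedent + consequent).
#' @return Data frame with columns `lhs` (";"-joined), `rhs`, `support`,
#'   `confidence`, `lift`, `count`; zero rows when nothing passes.
#' @export
mine_rules <- function(tx, min_support = 0.1, min_confidence = 0.8,
                       min_lift = 1, max_len = 10L) {
  stopifnot(inherits(tx, "transaction_set"))
  if (min_support <= 0 || min_support > 1) stop("min_support must be in (0, 1]", call. = FALSE)
  if (min_confidence < 0 || min_confidence > 1) stop("min_confidence must be in [0, 1]", call. = FALSE)
  M <- tx_matrix(tx)
  items <- colnames(M)
  n_tx <- nrow(M)
  levels <- frequent_itemsets(M, min_support, max_len)
  empty <- data.frame(
    lhs = character(0), rhs = character(0), support = numeric(0),
    confidence = numeric(0), lift = numeric(0), count = integer(0),
    stringsAsFactors = FALSE
  )
  if (length(levels) < 2L) return(empty)
  supp_env <- new.env(hash = TRUE, parent = emptyenv())
  for (lev in levels) {
    for (i in seq_along(lev$sets)) {
      assign(paste(lev$sets[[i]], collapse = ","), lev$support[i], envir = supp_env)
    }
  }
  rows <- list()
  for (k in 2:length(levels)) {
    lev <- levels[[k]]
    for (i in seq_along(lev$sets)) {
      s <- lev$sets[[i]]
      supp <- lev$support[i]
      for (drop in seq_along(s)) {
        lhs <- s[-drop]
        rhs <- s[drop]
        supp_lhs <- get(paste(lhs, collapse = ","), envir = supp_env)
        conf <- supp / supp_lhs
        if (conf < min_confidence - 1e-12) next
        supp_rhs <- get(as.character(rhs), envir = supp_env)
        lift <- conf / supp_rhs
        if (lift <= min_lift + 1e-12) next
        rows[[length(rows) + 1L]] <- data.frame(
          lhs = paste(items[lhs], collapse = ";"), rhs = items[rhs],
          support = supp, confidence = conf, lift = lift,
          count = as.integer(round(supp * n_tx)), stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(-out$support, -out$confidence, out$lhs, out$rhs), , drop = FALSE]
}

item_contingency <- function(tx, items) {
  M <- tx_matrix(tx, items)
  absent <- items[colSums(M) == 0L]
  if (length(absent)) {
    stop("item(s) absent from all transactions: ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  M
}

#' Pairwise binary distances between items
#'
#' Asymmetric binary (Jaccard) distance over the transactions each item
#' occurs in: d(a, b) = (n10 + n01) / (n11 + n10 + n01), i.e. joint absences
#' are ignored; equals 1 minus the Jaccard similarity of the items'
#' transaction sets. A symmetric Hamming variant
#' ((n10 + n01) / n) is available via `method`.
#'
#' @param tx A `transaction_set`.
#' @param items Items to include (default all in the universe).
#' @param method `"binary"` (asymmetric, default) or `"hamming"`.
#' @return Symmetric matrix with zero diagonal, entries in [0, 1].
#' @export
binary_distance_matrix <- function(tx, items = tx$universe,
                                   method = c("binary", "hamming")) {
  method <- match.arg(method)
  M <- item_contingency(tx, items)
  n11 <- crossprod(M)
  tot <- nrow(M)
  ci <- colSums(M)
  union <- outer(ci, ci, "+") - n11
  D <- if (method == "binary") {
    as.matrix(1 - n11 / union)
  } else {
    as.matrix((union - n11) / tot)
  }
  diag(D) <- 0
  dimnames(D) <- list(items, items)
  D
}

#' Pairwise phi (Pearson-on-binary) correlations between items
#'
#' Pearson correlation of the items' 0/1 indicator columns, identical to the
#' phi coefficient computed from each pair's 2x2 contingency table. Items
#' occurring in every transaction or none (zero variance) are an error.
#'
#' @inheritParams binary_distance_matrix
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
phi_correlation_matrix <- function(tx, items = tx$universe) {
  M <- item_contingency(tx, items)
  const <- items[colSums(M) == nrow(M) | colSums(M) == 0L]
  if (length(const)) {
    stop("constant indicator column(s): ", paste(const, collapse = ", "),
      call. = FALSE
    )
  }
  R <- stats::cor(M * 1L)
  dimnames(R) <- list(items, items)
  R
}

#' Write association rules to delimited text
#' @param rules A [mine_rules()] data frame.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_rules <- function(rules, path, sep = ",") {
  utils::write.table(rules, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
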