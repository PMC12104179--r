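# Brute-force rule enumerator: all itemsets up to max_len, all single-item
# consequents, metrics straight from transaction counts.
brute_rules <- function(tx, min_support, min_confidence, min_lift, max_len = 10L) {
  items <- tx$universe
  n_tx <- length(tx$items)
  supp_of <- function(set) {
    mean(vapply(tx$items, function(t) all(set %in% t), TRUE))
  }
  rows <- list()
  for (k in 2:min(max_len, length(items))) {
    sets <- utils::combn(items, k, simplify = FALSE)
    for (s in sets) {
      supp <- supp_of(s)
      if (supp < min_support - 1e-12) next
      for (c_i in seq_along(s)) {
        lhs <- s[-c_i]
        rhs <- s[c_i]
        conf <- supp / supp_of(lhs)
        lift <- conf / supp_of(rhs)
        if (conf >= min_confidence - 1e-12 && lift > min_lift + 1e-12) {
          rows[[length(rows) + 1L]] <- data.frame(
            lhs = paste(sort(lhs), collapse = ";"), rhs = rhs,
            support = supp, confidence = conf, lift = lift,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(
      lhs = character(0), rhs = character(0),
      support = numeric(0), confidence = numeric(0), lift = numeric(0)
    ))
  }
  out <- do.call(rbind, rows)
  out[order(out$lhs, out$rhs), , drop = FALSE]
}

rule_key <- function(df) {
  if (!nrow(df)) {
    return(character(0))
  }
  canon_lhs <- vapply(strsplit(df$lhs, ";"), function(v) paste(sort(v), collapse = ";"), "")
  sort(sprintf(
    "%s=>%s|%.10f|%.10f|%.10f", canon_lhs, df$rhs,
    df$support, df$confidence, df$lift
  ))
}

test_that("item frequencies count exact occurrences with coherent proportions", {
  tx <- transaction_set(list(c("A", "B"), "A", c("A", "C")))
  fr <- item_frequency(tx)
  expect_equal(fr$count[fr$item == "A"], 3L)
  expect_equal(fr$count[fr$item == "B"], 1L)
  expect_equal(fr$count[fr$item == "C"], 1L)
  expect_equal(sum(fr$proportion), 1)
  expect_equal(fr$cumulative[nrow(fr)], 1)
  expect_equal(attr(fr, "total_occurrences"), 5L)
  # single transaction: every item counted once
  fr1 <- item_frequency(transaction_set(list(c("X", "Y", "Z"))))
  expect_true(all(fr1$count == 1L))
  expect_error(item_frequency(transaction_set(list())), "empty")
  expect_error(transaction_set(list(c("A", "A"))), "duplicate")
})

test_that("high-frequency selection returns the right items and occurrence share", {
  tx <- transaction_set(list(
    c("A", "B", "C"), c("A", "B"), c("A", "D"), "A", c("B", "D")
  ))
  fr <- item_frequency(tx)
  hf <- high_frequency_items(fr, 3L)
  expect_setequal(hf$items, c("A", "B"))
  # counts: A 4, B 3, C 1, D 2 -> selected 7 of 10 occurrences
  expect_equal(hf$cumulative_proportion, 7 / 10)
  all_items <- high_frequency_items(fr, 1L)
  expect_equal(all_items$cumulative_proportion, 1)
  expect_setequal(all_items$items, fr$item)
})

test_that("category aggregation sums counts with an explicit unclassified bucket", {
  fr <- item_frequency(transaction_set(list(c("A", "B"), c("A", "C"), "A")))
  agg <- aggregate_by_category(fr, c(A = "tonic", B = "tonic"))
  expect_equal(agg$count[agg$category == "tonic"], 4L)
  expect_equal(agg$count[agg$category == "unclassified"], 1L)
  expect_equal(sum(agg$proportion), 1)
  # identity mapping preserves the counts
  ident <- aggregate_by_category(fr, setNames(fr$item, fr$item))
  expect_equal(sort(ident$count), sort(fr$count))
  # all one category -> single full-mass row
  one <- aggregate_by_category(fr, setNames(rep("all", nrow(fr)), fr$item))
  expect_equal(nrow(one), 1L)
  expect_equal(one$proportion, 1)
})

test_that("the toy rule example computes the published metric identities", {
  tx <- transaction_set(list(c("A", "B"), c("A", "B"), "A", "B"))
  # lift > 1 filters out both candidate rules
  expect_equal(nrow(mine_rules(tx, 0.5, 0.5, min_lift = 1)), 0L)
  rules <- mine_rules(tx, 0.5, 0.5, min_lift = 0)
  expect_equal(nrow(rules), 2L)
  ab <- rules[rules$lhs == "A", ]
  expect_equal(ab$support, 0.5)
  expect_equal(ab$confidence, 2 / 3)
  expect_equal(ab$lift, 8 / 9)
})

test_that("mined rules equal brute-force enumeration on random small universes", {
  withr::local_seed(71)
  for (trial in 1:8) {
    n_items <- sample(4:7, 1)
    n_tx <- sample(6:12, 1)
    items <- LETTERS[seq_len(n_items)]
    tx <- transaction_set(lapply(seq_len(n_tx), function(i) {
      k <- sample.int(n_items, 1)
      sort(sample(items, k))
    }))
    min_s <- sample(c(0.1, 0.2, 0.3), 1)
    min_c <- sample(c(0.5, 0.7), 1)
    min_l <- sample(c(0, 1), 1)
    mined <- mine_rules(tx, min_s, min_c, min_lift = min_l, max_len = n_items)
    brute <- brute_rules(tx, min_s, min_c, min_lift = min_l, max_len = n_items)
    expect_identical(rule_key(mined), rule_key(brute))
  }
})

test_that("rule metrics satisfy their defining identities when recomputed from raw transactions", {
  withr::local_seed(83)
  tx <- transaction_set(lapply(1:15, function(i) {
    sort(sample(LETTERS[1:6], sample(2:4, 1)))
  }))
  rules <- mine_rules(tx, 0.1, 0.3, min_lift = 0, max_len = 4)
  expect_gt(nrow(rules), 0)
  n_tx <- length(tx$items)
  supp_of <- function(set) mean(vapply(tx$items, function(t) all(set %in% t), TRUE))
  for (r in seq_len(nrow(rules))) {
    lhs <- strsplit(rules$lhs[r], ";")[[1]]
    rhs <- rules$rhs[r]
    expect_equal(rules$support[r], supp_of(c(lhs, rhs)))
    expect_equal(rules$confidence[r], supp_of(c(lhs, rhs)) / supp_of(lhs))
    expect_equal(rules$lift[r], rules$confidence[r] / supp_of(rhs))
    expect_lte(rules$support[r], min(supp_of(lhs), supp_of(rhs)) + 1e-12)
    expect_false(rhs %in% lhs)
  }
})

test_that("binary distance is the complement of transaction-set Jaccard similarity", {
  tx <- transaction_set(list(
    c("A", "B"), c("A", "B"), c("A", "B", "C"), "B", "C"
  ))
  D <- binary_distance_matrix(tx)
  # direct count: A in {1,2,3}, B in {1,2,3,4} -> d = (0 + 1)/(3 + 0 + 1)
  expect_equal(D["A", "B"], 1 / 4)
  # cross-check with the measurement-module jaccard on indicator vectors
  M <- 1 * t(vapply(tx$items, function(t) tx$universe %in% t, logical(3)))
  colnames(M) <- tx$universe
  for (a in tx$universe) {
    for (b in tx$universe) {
      if (a == b) next
      expect_equal(D[a, b], 1 - jaccard(M[, a], M[, b]))
    }
  }
  # identical transaction sets -> 0; never co-occurring -> 1
  tx2 <- transaction_set(list(c("X", "Y"), c("X", "Y"), "Z"))
  D2 <- binary_distance_matrix(tx2)
  expect_equal(D2["X", "Y"], 0)
  expect_equal(D2["X", "Z"], 1)
  expect_error(binary_distance_matrix(tx2, c("X", "Q")), "absent")
  # symmetric hamming variant counts joint absences in the denominator
  H <- binary_distance_matrix(tx, method = "hamming")
  expect_equal(H["A", "B"], 1 / 5)
})

test_that("phi correlations equal Pearson on indicators and the 2x2-table formula", {
  withr::local_seed(97)
  tx <- transaction_set(lapply(1:30, function(i) {
    sort(sample(LETTERS[1:5], sample(1:4, 1)))
  }))
  R <- phi_correlation_matrix(tx)
  expect_true(isSymmetric(R))
  expect_equal(diag(R), rep(1, ncol(R)), ignore_attr = TRUE)
  M <- 1 * t(vapply(tx$items, function(t) tx$universe %in% t, logical(5)))
  colnames(M) <- tx$universe
  n <- nrow(M)
  for (a in 1:4) {
    for (b in (a + 1):5) {
      # Pearson on the 0/1 indicator columns
      expect_equal(R[a, b], stats::cor(M[, a], M[, b]), tolerance = 1e-12)
      # phi from the 2x2 contingency table
      n11 <- sum(M[, a] & M[, b])
      n10 <- sum(M[, a] & !M[, b])
      n01 <- sum(!M[, a] & M[, b])
      n00 <- n - n11 - n10 - n01
      phi <- (n11 * n00 - n10 * n01) /
        sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
      expect_equal(R[a, b], phi, tolerance = 1e-12)
    }
  }
  # constant indicator columns are an error naming the item
  tx_const <- transaction_set(list(c("A", "B"), c("A", "C")))
  expect_error(phi_correlation_matrix(tx_const), "A")
})

test_that("catalog transactions deduplicate triplets within a formula", {
  fx <- mahuang_fixture()
  catalog <- formula_catalog("MHD", list(fx$formula_ids), space = fx$spaces)
  tx_cmm <- catalog_transactions(catalog, "cmm")
  expect_equal(tx_cmm$items[[1]], fx$formula_ids)
  tx_p <- catalog_transactions(catalog, "pccmm", P = fx$P, spaces = fx$spaces)
  # 16 triplet slots collapse to 13 distinct triplets
  expect_equal(length(tx_p$items[[1]]), 13L)
  expect_false(anyDuplicated(tx_p$items[[1]]) > 0)
  # basket files round-trip
  path <- withr::local_tempfile(fileext = ".txt")
  write_transactions(tx_p, path)
  tx_back <- read_transactions(path)
  expect_equal(tx_back$items[[1]], tx_p$items[[1]])
})
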