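# Shared fixtures: tiny record tables and random small reconstruction
# instances, all generated in code.

tiny_records <- function() {
  pcmm_table(
    cmm_id = c("CMM-1", "CMM-2", "CMM-3"),
    pinyin_name = c("one", "two", "three"),
    properties = list("warm", c("cold", "hot"), "even"),
    flavors = list(c("bitter", "pungent"), "sweet", "bland"),
    meridians = list(c("lung", "bladder"), "liver", c("heart", "kidney", "spleen"))
  )
}

random_label_set <- function(labels, max_k) {
  sort(sample(labels, sample.int(min(max_k, length(labels)), 1L)))
}

random_records <- function(n, prefix = "CMM") {
  pcmm_table(
    cmm_id = sprintf("%s-%d", prefix, seq_len(n)),
    properties = replicate(n, random_label_set(pccmm_properties(), 2L), simplify = FALSE),
    flavors = replicate(n, random_label_set(pccmm_flavors(), 3L), simplify = FALSE),
    meridians = replicate(n, random_label_set(pccmm_meridians(), 4L), simplify = FALSE)
  )
}

# A random small reconstruction instance whose target derives from a real
# formula (hence always feasible). Returns everything needed for both the
# package solver and the brute-force oracle.
random_instance <- function(n_cmm = NULL, n_pairs = NULL, formula_size = NULL) {
  if (is.null(n_cmm)) n_cmm <- sample(6:12, 1L)
  records <- random_records(n_cmm)
  spaces <- build_spaces(records)
  P <- build_pccmm_matrix(records, spaces)
  if (is.null(n_pairs)) n_pairs <- sample(0:2, 1L)
  pairs <- NULL
  if (n_pairs > 0L) {
    cand <- t(utils::combn(spaces$cmm$ids, 2L))
    take <- sample.int(nrow(cand), n_pairs)
    pairs <- incompatible_pairs(cand[take, 1L], cand[take, 2L], spaces, quiet = TRUE)
  }
  if (is.null(formula_size)) formula_size <- sample(2:4, 1L)
  # draw a formula respecting the pairs so its own target is feasible
  idx_pairs <- if (is.null(pairs)) matrix(integer(0), ncol = 2L) else attr(pairs, "index_pairs")
  repeat {
    members <- sort(sample.int(n_cmm, formula_size))
    ok <- TRUE
    if (nrow(idx_pairs)) {
      for (r in seq_len(nrow(idx_pairs))) {
        if (all(idx_pairs[r, ] %in% members)) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) break
  }
  x <- integer(n_cmm)
  x[members] <- 1L
  list(records = records, spaces = spaces, P = P, pairs = pairs, x = x)
}

pool_support_set <- function(pool) {
  sort(vapply(pool$solutions, function(s) paste(sort(s), collapse = ","), ""))
}
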