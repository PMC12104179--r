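#' Default synthetic-pharmacopoeia configuration
#'
#' Label-count distributions chosen to emulate pharmacopoeia-scale structure:
#' records carry 1-2 properties, 1-3 flavors and 1-6 meridians, with weights
#' tuned so the expected triplet-set size per record is about 3.9 (real
#' monograph tables sit near 3.7 triplets per record, i.e. a measurement
#' matrix density well under 2 percent). Label identities are drawn with
#' mildly skewed weights so common labels (warm/cold, sweet/bitter/pungent,
#' liver/lung/spleen/stomach) dominate, as they do in real monographs.
#'
#' @param n_cmm Number of records.
#' @param n_formulas Catalog size.
#' @param sparsity Mean members per formula (the catalog-wide average in the
#'   motivating data is 6.55).
#' @param n_pairs Number of incompatible pairs to draw.
#' @param seed Master seed; all child generators derive from it by fixed
#'   offsets.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_cmm = 120L, n_formulas = 60L, sparsity = 6.55,
                         n_pairs = 10L, seed = 1L) {
  stopifnot(n_cmm >= 1L, n_formulas >= 0L, sparsity > 0, sparsity < n_cmm, n_pairs >= 0L)
  structure(
    list(
      n_cmm = as.integer(n_cmm), n_formulas = as.integer(n_formulas),
      sparsity = sparsity, n_pairs = as.integer(n_pairs),
      seed = as.integer(seed),
      prop_count_weights = c(`1` = 0.95, `2` = 0.05),
      flavor_count_weights = c(`1` = 0.50, `2` = 0.40, `3` = 0.10),
      meridian_count_weights = c(
        `1` = 0.30, `2` = 0.35, `3` = 0.20,
        `4` = 0.07, `5` = 0.05, `6` = 0.03
      ),
      prop_label_weights = c(cold = 0.30, warm = 0.30, even = 0.20, cool = 0.12, hot = 0.08),
      flavor_label_weights = c(
        bitter = 0.28, pungent = 0.22, sweet = 0.28, sour = 0.08,
        astringent = 0.06, salty = 0.05, bland = 0.03
      ),
      meridian_label_weights = c(
        liver = 0.18, lung = 0.16, spleen = 0.14, stomach = 0.14,
        kidney = 0.10, heart = 0.10, `large-intestine` = 0.05,
        `small-intestine` = 0.03, sanjiao = 0.02, bladder = 0.04,
        pericardium = 0.02, gallbladder = 0.02
      )
    ),
    class = "synth_config"
  )
}

sample_label_set <- function(labels, count_weights, label_weights) {
  k <- sample(as.integer(names(count_weights)), 1L, prob = count_weights)
  sort(sample(labels, k, prob = label_weights[labels]))
}

#' Generate a synthetic pharmacopoeia
#'
#' Draws `n_cmm` complete records with label sets sampled per the
#' configuration. Deterministic under the config seed.
#'
#' @param config A [synth_config()].
#' @return A `pcmm_table`.
#' @export
generate_pharmacopoeia <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  vocab <- default_vocab()
  withr::with_seed(config$seed, {
    props <- replicate(config$n_cmm,
      sample_label_set(vocab$properties, config$prop_count_weights, config$prop_label_weights),
      simplify = FALSE
    )
    flavs <- replicate(config$n_cmm,
      sample_label_set(vocab$flavors, config$flavor_count_weights, config$flavor_label_weights),
      simplify = FALSE
    )
    merids <- replicate(config$n_cmm,
      sample_label_set(vocab$meridians, config$meridian_count_weights, config$meridian_label_weights),
      simplify = FALSE
    )
    ids <- sprintf("CMM-%03d", seq_len(config$n_cmm))
    pcmm_table(
      cmm_id = ids, properties = props, flavors = flavs, meridians = merids,
      pinyin_name = sprintf("synth-%03d", seq_len(config$n_cmm)),
      latin_name = sprintf("Synthetica herba %03d", seq_len(config$n_cmm))
    )
  })
}

#' Generate a synthetic formula catalog
#'
#' Formula sizes are Binomial(N, sparsity/N) conditioned on being at least 1;
#' members are drawn uniformly without replacement, re-drawing members that
#' would violate an incompatible pair, so generated catalogs never contain a
#' contraindicated pair. Deterministic under `seed`.
#'
#' @param spaces A `pccmm_spaces`.
#' @param count Number of formulas.
#' @param sparsity Mean formula size s (0 < s < N).
#' @param pairs An `incompatible_pairs` object or `NULL`.
#' @param seed Integer seed.
#' @param batches Batch tags cycled over the formulas (default two batches).
#' @return A `formula_catalog`.
#' @export
generate_catalog <- function(spaces, count, sparsity, pairs = NULL, seed = 1L,
                             batches = c("1", "2")) {
  stopifnot(inherits(spaces, "pccmm_spaces"), sparsity > 0, sparsity < spaces$N)
  N <- spaces$N
  forbidden <- if (is.null(pairs)) {
    matrix(integer(0), ncol = 2L)
  } else {
    attr(pairs, "index_pairs")
  }
  conflict_list <- vector("list", N)
  if (nrow(forbidden)) {
    for (r in seq_len(nrow(forbidden))) {
      a <- forbidden[r, 1L]
      b <- forbidden[r, 2L]
      conflict_list[[a]] <- c(conflict_list[[a]], b)
      conflict_list[[b]] <- c(conflict_list[[b]], a)
    }
  }
  withr::with_seed(as.integer(seed), {
    members <- lapply(seq_len(count), function(i) {
      size <- 0L
      while (size == 0L) size <- stats::rbinom(1L, N, sparsity / N)
      chosen <- integer(0)
      blocked <- logical(N)
      for (k in seq_len(size)) {
        pool <- which(!blocked)
        pool <- setdiff(pool, chosen)
        if (!length(pool)) break
        pick <- pool[sample.int(length(pool), 1L)]
        chosen <- c(chosen, pick)
        blocked[conflict_list[[pick]]] <- TRUE
      }
      sort(chosen)
    })
    formula_catalog(
      formula_id = sprintf("SYN-%03d", seq_len(count)),
      cmm_ids = lapply(members, function(ix) spaces$cmm$ids[ix]),
      batch = rep_len(batches, count),
      space = spaces
    )
  })
}

#' The Mahuang Decoction worked-example fixture
#'
#' A four-herb decoction used as the package's in-source worked example. The
#' Mahuang (Ephedrae Herba) label set -- warm; bitter, pungent; lung, bladder
#' -- is the canonical monograph record; the other three records are
#' transcribed from the 2020 pharmacopoeia monographs:
#'
#' * Guizhi (Cinnamomi Ramulus): warm; pungent, sweet; heart, lung, bladder.
#' * Gancao (Glycyrrhizae Radix et Rhizoma): even; sweet; heart, lung,
#'   spleen, stomach.
#' * Kuxingren (Armeniacae Semen Amarum): warm (monograph "slightly warm");
#'   bitter; lung, large-intestine.
#'
#' Expected measurement facts (all recomputable from the bundle): Mahuang
#' expands to 4 triplets; the formula's 16 triplet slots collapse to 13
#' distinct triplets; exactly 3 triplets have weighted multiplicity 2
#' (warm|bitter|lung shared by Mahuang and Kuxingren; warm|pungent|lung and
#' warm|pungent|bladder shared by Mahuang and Guizhi); min(y_w, 1) = y.
#'
#' @return A list with `records` (`pcmm_table`), `formula_ids`, `spaces`,
#'   `P`, `x`, and `expected` (list of the facts above).
#' @export
mahuang_fixture <- function() {
  records <- pcmm_table(
    cmm_id = c("CMM-144", "CMM-173", "CMM-269", "CMM-307"),
    pinyin_name = c("Gancao", "Guizhi", "Kuxingren", "Mahuang"),
    latin_name = c(
      "Glycyrrhizae Radix et Rhizoma", "Cinnamomi Ramulus",
      "Armeniacae Semen Amarum", "Ephedrae Herba"
    ),
    properties = list("even", "warm", "warm", "warm"),
    flavors = list("sweet", c("pungent", "sweet"), "bitter", c("bitter", "pungent")),
    meridians = list(
      c("heart", "lung", "spleen", "stomach"),
      c("heart", "lung", "bladder"),
      c("lung", "large-intestine"),
      c("lung", "bladder")
    )
  )
  spaces <- build_spaces(records)
  P <- build_pccmm_matrix(records, spaces)
  x <- encode_formula(records$cmm_id, spaces)
  list(
    records = records,
    formula_ids = records$cmm_id,
    spaces = spaces,
    P = P,
    x = x,
    expected = list(
      mahuang_triplets = 4L,
      support_size = 13L,
      multiplicity_two = 3L,
      multiplicity_two_labels = c(
        "warm|bitter|lung", "warm|pungent|lung", "warm|pungent|bladder"
      )
    )
  )
}

#' End-to-end synthetic recovery experiment
#'
#' Generates a pharmacopoeia and catalog per the config, measures every
#' formula, reconstructs it from its own measurement, and reports max-Jaccard
#' recovery per mode and omega1. Full provenance (config and seeds) is
#' embedded in the report.
#'
#' @param config A [synth_config()].
#' @param omega1_grid,modes,cap,tol,backend Passed to [rebuild_catalog()].
#' @return A `rebuild_report` with an extra `provenance` element.
#' @export
recovery_experiment <- function(config = synth_config(),
                                omega1_grid = c(0.1, 0.5, 0.9),
                                modes = c("weighted", "unweighted"),
                                cap = 15000L, tol = 1e-6,
                                backend = c("highs", "exhaustive")) {
  backend <- match.arg(backend)
  records <- generate_pharmacopoeia(config)
  spaces <- build_spaces(records)
  P <- build_pccmm_matrix(records, spaces)
  pairs <- if (config$n_pairs > 0L) {
    withr::with_seed(config$seed + 1L, {
      cand <- t(utils::combn(spaces$cmm$ids, 2L))
      take <- sample.int(nrow(cand), min(config$n_pairs, nrow(cand)))
      incompatible_pairs(cand[take, 1L], cand[take, 2L], spaces, quiet = TRUE)
    })
  } else {
    NULL
  }
  catalog <- generate_catalog(spaces, config$n_formulas, config$sparsity,
    pairs = pairs, seed = config$seed + 2L
  )
  report <- rebuild_catalog(catalog, P, spaces,
    pairs = pairs,
    omega1_grid = omega1_grid, modes = modes, cap = cap, tol = tol,
    backend = backend
  )
  report$provenance <- list(
    config = unclass(config), omega1_grid = omega1_grid, modes = modes,
    n_cmm = spaces$N, m = spaces$m, nnz = Matrix::nnzero(P)
  )
  report$inputs <- list(records = records, spaces = spaces, P = P, pairs = pairs, catalog = catalog)
  report
}

#' Write the synthetic bundle to a directory
#'
#' Emits the CMM table, incompatible pairs, catalog, measurement matrix and
#' an expected-facts JSON so external harnesses can replay the data.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_synthetic_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records <- generate_pharmacopoeia(config)
  spaces <- build_spaces(records)
  P <- build_pccmm_matrix(records, spaces)
  pairs <- if (config$n_pairs > 0L) {
    withr::with_seed(config$seed + 1L, {
      cand <- t(utils::combn(spaces$cmm$ids, 2L))
      take <- sample.int(nrow(cand), min(config$n_pairs, nrow(cand)))
      incompatible_pairs(cand[take, 1L], cand[take, 2L], spaces, quiet = TRUE)
    })
  } else {
    no_pairs(spaces)
  }
  catalog <- generate_catalog(spaces, config$n_formulas, config$sparsity,
    pairs = pairs, seed = config$seed + 2L
  )
  write_cmm_table(records, file.path(dir, "cmm_table.csv"))
  write_incompatible_pairs(pairs, file.path(dir, "incompatible_pairs.csv"))
  write_formula_catalog(catalog, file.path(dir, "formula_catalog.csv"))
  write_pccmm_matrix(P, file.path(dir, "pccmm_matrix.mtx"))
  jsonlite::write_json(
    list(
      config = unclass(config), N = spaces$N, m = spaces$m,
      nnz = Matrix::nnzero(P),
      mean_triplets_per_cmm = Matrix::nnzero(P) / spaces$N,
      mean_formula_size = mean(lengths(catalog$cmm_ids))
    ),
    file.path(dir, "expected_facts.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
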