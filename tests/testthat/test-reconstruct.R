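# Identity-matrix instance used for direct structural checks: three "herbs"
# each carrying exactly one private triplet.
identity_instance <- function() {
  recs <- pcmm_table(
    cmm_id = c("A", "B", "C"),
    properties = list("cold", "warm", "hot"),
    flavors = list("sour", "sour", "sour"),
    meridians = list("liver", "liver", "liver")
  )
  spaces <- build_spaces(recs)
  list(recs = recs, spaces = spaces, P = build_pccmm_matrix(recs, spaces))
}

test_that("build_milp produces the expected structure on an identity matrix", {
  inst <- identity_instance()
  # target covering the private triplets of herbs A and C
  y <- integer(3)
  y[which(as.matrix(inst$P)[, "A"] == 1)] <- 1L
  y[which(as.matrix(inst$P)[, "C"] == 1)] <- 1L
  enc_u <- build_milp(reconstruction_problem(y, inst$P, omega1 = 0.5, mode = "unweighted"))
  expect_equal(enc_u$n_z, 3L)
  expect_equal(enc_u$n_u, 1L) # one off-target row
  expect_equal(enc_u$obj, c(0.5, 0.5, 0.5, 0.5))
  enc_w <- build_milp(reconstruction_problem(y, inst$P, omega1 = 0.5, mode = "weighted"))
  expect_equal(enc_w$n_u, 0L)
  # weighted objective coefficients are omega1 + (1 - omega1) * colsum
  expect_equal(enc_w$obj, 0.5 + 0.5 * Matrix::colSums(inst$P), ignore_attr = TRUE)
  expect_error(
    reconstruction_problem(y, inst$P, omega1 = 1, mode = "weighted"),
    "omega1"
  )
  expect_error(
    reconstruction_problem(c(2L, 0L, 0L), inst$P, mode = "unweighted"),
    "0-1"
  )
})

test_that("solve_pool finds the unique optimum on the identity instance (both backends)", {
  inst <- identity_instance()
  y <- integer(3)
  y[which(as.matrix(inst$P)[, "A"] == 1)] <- 1L
  y[which(as.matrix(inst$P)[, "C"] == 1)] <- 1L
  for (backend in c("exhaustive", "highs")) {
    pool <- solve_pool(
      reconstruction_problem(y, inst$P, omega1 = 0.5, mode = "unweighted"),
      backend = backend
    )
    expect_equal(pool$status, "optimal")
    expect_equal(pool$optimum, 1.0)
    expect_equal(length(pool$solutions), 1L)
    expect_setequal(colnames(inst$P)[pool$solutions[[1]]], c("A", "C"))
  }
})

test_that("duplicate-column herbs yield exchangeable single-herb optima, not their union", {
  recs <- pcmm_table(
    cmm_id = c("X", "Y"),
    properties = list("warm", "warm"),
    flavors = list("pungent", "pungent"),
    meridians = list(c("lung", "spleen"), c("lung", "spleen"))
  )
  spaces <- build_spaces(recs)
  P <- build_pccmm_matrix(recs, spaces)
  y <- measure(P, c(1L, 0L), weighted = TRUE)
  for (backend in c("exhaustive", "highs")) {
    pool <- solve_pool(
      reconstruction_problem(y, P, omega1 = 0.5, mode = "weighted"),
      backend = backend
    )
    expect_equal(length(pool$solutions), 2L)
    expect_setequal(pool_support_set(pool), c("1", "2"))
  }
})

test_that("uncoverable targets are reported infeasible by both backends", {
  inst <- identity_instance()
  y <- rep(1L, 3)
  # forbid every pair: no two herbs can combine, so covering all three rows
  # is impossible
  pr <- incompatible_pairs(
    c("A", "A", "B"), c("B", "C", "C"), inst$spaces,
    quiet = TRUE
  )
  prob <- reconstruction_problem(y, inst$P, pairs = pr, omega1 = 0.5, mode = "unweighted")
  for (backend in c("exhaustive", "highs")) {
    pool <- solve_pool(prob, backend = backend)
    expect_equal(pool$status, "infeasible")
  }
  expect_error(reconstruct_formula(prob), "no covering formula")
})

test_that("MILP pools equal brute-force enumeration of the verbatim objective", {
  withr::local_seed(101)
  n_instances <- 12
  encodings <- list()
  keys <- list()
  oracle_sets <- list()
  oracle_opt <- numeric(0)
  for (i in seq_len(n_instances)) {
    inst <- random_instance()
    for (mode in c("weighted", "unweighted")) {
      target <- measure(inst$P, inst$x, weighted = (mode == "weighted"))
      for (w1 in c(0.1, 0.5, 0.9)) {
        orc <- oracle_pool(inst$P, target, inst$pairs, omega1 = w1, mode = mode)
        prob <- reconstruction_problem(target, inst$P,
          pairs = inst$pairs,
          omega1 = w1, mode = mode
        )
        encodings[[length(encodings) + 1L]] <- build_milp(prob)
        oracle_sets[[length(oracle_sets) + 1L]] <- oracle_support_set(orc)
        oracle_opt <- c(oracle_opt, orc$optimum)
      }
    }
  }
  pools <- solve_pool_batch(encodings, backend = "highs")
  for (k in seq_along(pools)) {
    expect_equal(pool_support_set(pools[[k]]), oracle_sets[[k]])
    expect_equal(pools[[k]]$optimum, oracle_opt[k], tolerance = 1e-6)
  }
  # exhaustive backend agrees on a subsample
  for (k in seq(1, length(encodings), by = 11)) {
    pe <- solve_pool(encodings[[k]], backend = "exhaustive")
    expect_equal(pool_support_set(pe), oracle_sets[[k]])
  }
})

test_that("every pool member is feasible and its verbatim objective equals the reported optimum", {
  withr::local_seed(33)
  for (i in 1:6) {
    inst <- random_instance()
    mode <- if (i %% 2 == 0) "weighted" else "unweighted"
    target <- measure(inst$P, inst$x, weighted = (mode == "weighted"))
    pool <- solve_pool(
      reconstruction_problem(target, inst$P,
        pairs = inst$pairs, omega1 = 0.3,
        mode = mode
      ),
      backend = "highs"
    )
    idx_pairs <- if (is.null(inst$pairs)) {
      matrix(integer(0), ncol = 2)
    } else {
      attr(inst$pairs, "index_pairs")
    }
    Pm <- as.matrix(inst$P)
    for (s in pool$solutions) {
      z <- integer(ncol(Pm))
      z[s] <- 1L
      Pz <- as.numeric(Pm %*% z)
      expect_true(all(Pz >= target)) # covering constraint
      if (nrow(idx_pairs)) {
        expect_true(all(z[idx_pairs[, 1]] + z[idx_pairs[, 2]] <= 1))
      }
      pen <- if (mode == "unweighted") {
        sum(abs(pmin(Pz, 1) - target))
      } else {
        sum(abs(Pz - target))
      }
      expect_equal(0.3 * sum(z) + 0.7 * pen, pool$optimum, tolerance = 1e-6)
    }
    # feasibility of the true formula bounds the optimum from above
    Pz_true <- as.numeric(Pm %*% inst$x)
    pen_true <- if (mode == "unweighted") {
      sum(abs(pmin(Pz_true, 1) - target))
    } else {
      sum(abs(Pz_true - target))
    }
    expect_lte(pool$optimum, 0.3 * sum(inst$x) + 0.7 * pen_true + 1e-9)
  }
})

test_that("the pool cap truncates and flags large pools", {
  # ten herbs with identical columns: any single one is optimal, pool size 10
  recs <- pcmm_table(
    cmm_id = sprintf("H-%d", 1:10),
    properties = replicate(10, "warm", simplify = FALSE),
    flavors = replicate(10, "sweet", simplify = FALSE),
    meridians = replicate(10, "spleen", simplify = FALSE)
  )
  spaces <- build_spaces(recs)
  P <- build_pccmm_matrix(recs, spaces)
  y <- measure(P, c(1L, rep(0L, 9)), weighted = TRUE)
  prob <- reconstruction_problem(y, P, omega1 = 0.5, mode = "weighted")
  full <- solve_pool(prob, backend = "highs")
  expect_equal(length(full$solutions), 10L)
  expect_false(full$capped)
  capped <- solve_pool(prob, cap = 4L, backend = "highs")
  expect_equal(length(capped$solutions), 4L)
  expect_true(capped$capped)
})

test_that("rebuild_catalog recovers orthogonal designs exactly and reports batch averages", {
  # orthogonal design: each herb has a private (property, flavor) pair so no
  # column is contained in another -> every formula is uniquely identifiable
  recs <- pcmm_table(
    cmm_id = sprintf("O-%d", 1:10),
    properties = as.list(rep(pccmm_properties(), 2))[1:10],
    flavors = as.list(rep(pccmm_flavors()[1:5], each = 2))[1:10],
    meridians = replicate(10, c("liver", "lung"), simplify = FALSE)
  )
  spaces <- build_spaces(recs)
  P <- build_pccmm_matrix(recs, spaces)
  withr::local_seed(13)
  catalog <- generate_catalog(spaces, 8, 3.5, seed = 13, batches = c("1", "2"))
  report <- rebuild_catalog(catalog, P, spaces,
    omega1_grid = c(0.3, 0.5),
    modes = "weighted", backend = "highs"
  )
  expect_true(all(report$per_formula$max_jaccard == 1))
  expect_true(all(report$summary$avg_max_jaccard == 1))
  expect_setequal(unique(report$per_formula$omega1), c(0.3, 0.5))
  # serialization smoke check
  path <- withr::local_tempfile(fileext = ".json")
  write_rebuild_report(report, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".weighted.tsv")))
})

test_that("average recovery does not improve as omega1 grows beyond 0.5", {
  cfg <- synth_config(n_cmm = 60, n_formulas = 25, n_pairs = 5, seed = 77)
  report <- recovery_experiment(cfg, omega1_grid = c(0.5, 0.7, 0.9), modes = "weighted")
  s <- report$summary
  trend <- vapply(c(0.5, 0.7, 0.9), function(w) {
    mean(s$avg_max_jaccard[abs(s$omega1 - w) < 1e-9])
  }, 0)
  expect_true(all(diff(trend) <= 1e-9))
})

test_that("weighted targets recover at least as well as unweighted ones on average", {
  withr::local_seed(55)
  encodings <- list()
  meta <- list()
  xs <- list()
  for (i in 1:40) {
    inst <- random_instance(n_cmm = 10, formula_size = 3)
    for (mode in c("weighted", "unweighted")) {
      target <- measure(inst$P, inst$x, weighted = (mode == "weighted"))
      encodings[[length(encodings) + 1L]] <- build_milp(
        reconstruction_problem(target, inst$P,
          pairs = inst$pairs, omega1 = 0.5,
          mode = mode
        )
      )
      meta[[length(meta) + 1L]] <- mode
      xs[[length(xs) + 1L]] <- inst$x
    }
  }
  pools <- solve_pool_batch(encodings, backend = "highs")
  maxj <- vapply(seq_along(pools), function(k) {
    max(vapply(pools[[k]]$solutions, function(s) {
      z <- integer(length(xs[[k]]))
      z[s] <- 1L
      jaccard(xs[[k]], z)
    }, 0))
  }, 0)
  mw <- mean(maxj[unlist(meta) == "weighted"])
  mu <- mean(maxj[unlist(meta) == "unweighted"])
  expect_gte(mw, mu)
})
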