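#' Define a formula-reconstruction problem
#'
#' The backward problem: given a target triplet vector measured from an
#' unknown formula, find 0-1 candidate formula vectors z minimizing
#'
#' * unweighted mode: `omega1 * ||z||_1 + (1 - omega1) * ||min(Pz, 1) - y||_1`
#'   subject to `Pz >= y` and the incompatible-pair constraints
#'   `z_a + z_b <= 1`;
#' * weighted mode: `omega1 * ||z||_1 + (1 - omega1) * ||Pz - y_w||_1`
#'   subject to `Pz >= y_w` and the pair constraints.
#'
#' The two objective terms trade off formula parsimony against off-target
#' triplet coverage; `omega1` in (0, 1) balances them (0.5 is the
#' conventional default).
#'
#' @param target Integer target vector of length `nrow(P)`: 0-1 for
#'   `mode = "unweighted"`, nonnegative counts for `mode = "weighted"`.
#' @param P Measurement matrix ([build_pccmm_matrix()]).
#' @param pairs An `incompatible_pairs` object (or `NULL` for none).
#' @param omega1 Sparsity weight, strictly between 0 and 1.
#' @param mode `"weighted"` or `"unweighted"`.
#' @return A `reconstruction_problem` object.
#' @export
reconstruction_problem <- function(target, P, pairs = NULL, omega1 = 0.5,
                                   mode = c("weighted", "unweighted")) {
  mode <- match.arg(mode)
  if (!is.numeric(omega1) || length(omega1) != 1L || omega1 <= 0 || omega1 >= 1) {
    stop("omega1 must lie strictly between 0 and 1", call. = FALSE)
  }
  if (length(target) != nrow(P)) stop("target length != nrow(P)", call. = FALSE)
  target <- as.integer(round(target))
  if (any(target < 0)) stop("target entries must be nonnegative", call. = FALSE)
  if (mode == "unweighted" && any(target > 1L)) {
    stop("unweighted targets must be 0-1; use mode = \"weighted\" for counts",
      call. = FALSE
    )
  }
  idx_pairs <- if (is.null(pairs)) {
    matrix(integer(0), ncol = 2L)
  } else {
    attr(pairs, "index_pairs")
  }
  structure(
    list(
      target = target, P = methods::as(P, "CsparseMatrix"),
      pairs = idx_pairs, omega1 = omega1, mode = mode
    ),
    class = "reconstruction_problem"
  )
}

#' Encode a reconstruction problem as a mixed-integer linear program
#'
#' In unweighted mode the nonlinear penalty `||min(Pz,1) - y||_1` is
#' linearized with one auxiliary binary u_k per off-target row k (rows with
#' y_k = 0) and big-M constants M_k equal to the row sums of P (the tightest
#' valid constants): minimize
#' `omega1 * sum(z) + (1 - omega1) * sum(u)` subject to `(Pz)_k >= 1` on
#' target rows, `(Pz)_k <= M_k u_k` on off-target rows, and the pair
#' constraints. Under `Pz >= y` the penalty equals the number of covered
#' off-target rows, so the encoding's optimal value equals the original
#' objective (unit tests re-evaluate the verbatim objective on every pool
#' member).
#'
#' In weighted mode the constraint `Pz >= y_w` makes the penalty linear:
#' `||Pz - y_w||_1 = sum_j colsum_j(P) z_j - ||y_w||_1`, so the model needs
#' no auxiliaries; the constant `-(1 - omega1) * ||y_w||_1` is dropped
#' internally and added back to reported objective values.
#'
#' @param problem A `reconstruction_problem`.
#' @return A `milp_encoding` list: objective `obj`, sparse constraint rows
#'   (`A`, `row_lower`, `row_upper`), variable counts (`n_z`, `n_u`), the
#'   objective `constant`, and bookkeeping needed to decode solutions.
#' @export
build_milp <- function(problem) {
  stopifnot(inherits(problem, "reconstruction_problem"))
  P <- problem$P
  y <- problem$target
  w1 <- problem$omega1
  m <- nrow(P)
  N <- ncol(P)
  Tm <- methods::as(P, "TsparseMatrix")
  pi <- Tm@i + 1L # rows of nonzeros
  pj <- Tm@j + 1L # cols of nonzeros
  px <- Tm@x
  target_rows <- which(y >= 1L)

  if (problem$mode == "weighted") {
    colsum <- Matrix::colSums(P)
    obj <- w1 + (1 - w1) * colsum
    n_u <- 0L
    # covering rows only (off-target rows are trivially satisfied, y_k = 0,
    # but keeping them costs nothing and keeps row indexing transparent)
    keep <- pi %in% target_rows
    Ai <- match(pi[keep], target_rows)
    Aj <- pj[keep]
    Ax <- px[keep]
    n_rows <- length(target_rows)
    row_lower <- as.numeric(y[target_rows])
    row_upper <- rep(Inf, n_rows)
    constant <- -(1 - w1) * sum(y)
  } else {
    off_rows <- setdiff(seq_len(m), target_rows)
    M <- Matrix::rowSums(P)
    n_u <- length(off_rows)
    obj <- c(rep(w1, N), rep(1 - w1, n_u))
    # covering rows: (Pz)_k >= 1, k in supp(y)
    keep_t <- pi %in% target_rows
    Ai1 <- match(pi[keep_t], target_rows)
    Aj1 <- pj[keep_t]
    Ax1 <- px[keep_t]
    n1 <- length(target_rows)
    # off-target rows: (Pz)_k - M_k u_k <= 0
    keep_o <- pi %in% off_rows
    Ai2 <- n1 + match(pi[keep_o], off_rows)
    Aj2 <- pj[keep_o]
    Ax2 <- px[keep_o]
    Ai2u <- n1 + seq_len(n_u)
    Aj2u <- N + seq_len(n_u)
    Ax2u <- -M[off_rows]
    Ai <- c(Ai1, Ai2, Ai2u)
    Aj <- c(Aj1, Aj2, Aj2u)
    Ax <- c(Ax1, Ax2, Ax2u)
    n_rows <- n1 + n_u
    row_lower <- c(rep(1, n1), rep(-Inf, n_u))
    row_upper <- c(rep(Inf, n1), rep(0, n_u))
    constant <- 0
  }

  # incompatible pairs: z_a + z_b <= 1
  q <- nrow(problem$pairs)
  if (q > 0L) {
    Ai <- c(Ai, rep(n_rows + seq_len(q), each = 2L))
    Aj <- c(Aj, as.integer(t(problem$pairs)))
    Ax <- c(Ax, rep(1, 2L * q))
    row_lower <- c(row_lower, rep(-Inf, q))
    row_upper <- c(row_upper, rep(1, q))
    n_rows <- n_rows + q
  }

  structure(
    list(
      obj = as.numeric(obj),
      A = list(i = as.integer(Ai), j = as.integer(Aj), x = as.numeric(Ax)),
      n_rows = n_rows, n_vars = N + n_u,
      row_lower = row_lower, row_upper = row_upper,
      n_z = N, n_u = n_u, constant = constant,
      mode = problem$mode, omega1 = w1,
      cmm_ids = colnames(P)
    ),
    class = "milp_encoding"
  )
}

#' Enumerate the optimal solution pool of an encoded problem
#'
#' Finds the optimum and all distinct optimal candidate-formula vectors (a
#' zero pool gap: only solutions whose objective ties the optimum within
#' `tol` are admitted), up to `cap` solutions. The default backend solves the
#' MILP with HiGHS (via the bundled scipy helper) and enumerates alternates
#' with no-good cuts `sum_{i in supp(z*)} (1 - z_i) + sum_{i notin supp} z_i
#' >= 1`; the `"exhaustive"` backend enumerates all 2^N candidate vectors and
#' is available for small spaces. Pools are sets: no order is promised.
#'
#' @param encoding A `milp_encoding`, or a `reconstruction_problem` (encoded
#'   on the fly).
#' @param cap Maximum pool size; pools that hit the cap are flagged `capped`
#'   (reported maxima may then be underestimates).
#' @param tol Objective tie tolerance.
#' @param backend `"highs"` or `"exhaustive"`.
#' @return A `solution_pool`: list with `optimum` (reported on the original
#'   objective scale, constant included), `solutions` (list of integer
#'   support index vectors over the CMM space), `objectives`, `capped`,
#'   `status`.
#' @export
solve_pool <- function(encoding, cap = 15000L, tol = 1e-6,
                       backend = c("highs", "exhaustive")) {
  backend <- match.arg(backend)
  if (inherits(encoding, "reconstruction_problem")) encoding <- build_milp(encoding)
  solve_pool_batch(list(encoding), cap = cap, tol = tol, backend = backend)[[1L]]
}

#' @rdname solve_pool
#' @param encodings A list of `milp_encoding` objects solved in one backend
#'   call (one subprocess for the HiGHS backend).
#' @export
solve_pool_batch <- function(encodings, cap = 15000L, tol = 1e-6,
                             backend = c("highs", "exhaustive")) {
  backend <- match.arg(backend)
  encodings <- lapply(encodings, function(e) {
    if (inherits(e, "reconstruction_problem")) build_milp(e) else e
  })
  stopifnot(all(vapply(encodings, inherits, TRUE, "milp_encoding")))
  raw <- if (backend == "highs") {
    milp_pool_highs(encodings, cap = cap, tol = tol)
  } else {
    lapply(encodings, milp_pool_exhaustive, cap = cap, tol = tol)
  }
  Map(function(res, enc) {
    if (identical(res$status, "infeasible")) {
      return(structure(
        list(
          status = "infeasible", optimum = NA_real_, solutions = list(),
          objectives = numeric(0), capped = FALSE, mode = enc$mode,
          omega1 = enc$omega1, cmm_ids = enc$cmm_ids
        ),
        class = "solution_pool"
      ))
    }
    structure(
      list(
        status = "optimal",
        optimum = res$optimum + enc$constant,
        solutions = res$solutions,
        objectives = res$objectives + enc$constant,
        capped = isTRUE(res$capped),
        mode = enc$mode, omega1 = enc$omega1, cmm_ids = enc$cmm_ids
      ),
      class = "solution_pool"
    )
  }, raw, encodings)
}

#' @exportS3Method base::print
print.solution_pool <- function(x, ...) {
  if (identical(x$status, "infeasible")) {
    cat("<solution_pool> infeasible: no covering formula exists\n")
  } else {
    cat(
      "<solution_pool>", length(x$solutions), "optimal solution(s), objective",
      format(x$optimum, digits = 6),
      if (x$capped) "(pool capped)" else "", "\n"
    )
  }
  invisible(x)
}

#' Reconstruct a target and stop on infeasibility
#'
#' Convenience wrapper: measure nothing, just solve; raises a distinct error
#' when no candidate formula can cover the target.
#'
#' @inheritParams solve_pool
#' @param problem A `reconstruction_problem`.
#' @export
reconstruct_formula <- function(problem, cap = 15000L, tol = 1e-6,
                                backend = c("highs", "exhaustive")) {
  pool <- solve_pool(build_milp(problem), cap = cap, tol = tol, backend = backend)
  if (identical(pool$status, "infeasible")) {
    stop("no covering formula exists for this target", call. = FALSE)
  }
  pool
}

#' Rebuild every formula of a catalog from its own measurement
#'
#' The self-reconstruction experiment: for each formula, encode its vector
#' x, measure y (or y_w), solve the reconstruction problem, and score the
#' best pool member by Jaccard similarity against x. Batch averages of the
#' per-formula maxima summarize identifiability per mode and omega1.
#'
#' @param catalog A `formula_catalog`.
#' @param P Measurement matrix.
#' @param spaces The `pccmm_spaces` P was built over.
#' @param pairs An `incompatible_pairs` object or `NULL`.
#' @param omega1_grid Numeric vector of omega1 values (default the 0.1..0.9
#'   sweep).
#' @param modes Character subset of `c("weighted", "unweighted")`.
#' @param cap,tol,backend Passed to [solve_pool_batch()].
#' @return A `rebuild_report`: list with `per_formula` (one row per formula x
#'   mode x omega1: pool size, capped flag, objective, max Jaccard) and
#'   `summary` (mean max Jaccard per batch x mode x omega1).
#' @export
rebuild_catalog <- function(catalog, P, spaces, pairs = NULL,
                            omega1_grid = seq(0.1, 0.9, by = 0.1),
                            modes = c("weighted", "unweighted"),
                            cap = 15000L, tol = 1e-6,
                            backend = c("highs", "exhaustive")) {
  backend <- match.arg(backend)
  modes <- match.arg(modes, c("weighted", "unweighted"), several.ok = TRUE)
  stopifnot(inherits(catalog, "formula_catalog"))
  xs <- lapply(catalog$cmm_ids, encode_formula, space = spaces)
  grid <- expand.grid(
    f = seq_len(nrow(catalog)), mode = modes, omega1 = omega1_grid,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  encodings <- lapply(seq_len(nrow(grid)), function(r) {
    i <- grid$f[r]
    mode <- grid$mode[r]
    y <- measure(P, xs[[i]], weighted = (mode == "weighted"))
    build_milp(reconstruction_problem(y, P,
      pairs = pairs,
      omega1 = grid$omega1[r], mode = mode
    ))
  })
  pools <- solve_pool_batch(encodings, cap = cap, tol = tol, backend = backend)
  per <- do.call(rbind, lapply(seq_len(nrow(grid)), function(r) {
    i <- grid$f[r]
    pool <- pools[[r]]
    x <- xs[[i]]
    maxj <- if (length(pool$solutions)) {
      max(vapply(pool$solutions, function(s) {
        z <- integer(length(x))
        z[s] <- 1L
        jaccard(x, z)
      }, 0))
    } else {
      NA_real_
    }
    data.frame(
      formula_id = catalog$formula_id[i], batch = catalog$batch[i],
      mode = grid$mode[r], omega1 = grid$omega1[r],
      status = pool$status, pool_size = length(pool$solutions),
      capped = pool$capped, objective = pool$optimum,
      max_jaccard = maxj, stringsAsFactors = FALSE
    )
  }))
  per$batch[is.na(per$batch)] <- "(none)"
  ok <- per$status == "optimal"
  summary <- stats::aggregate(
    max_jaccard ~ batch + mode + omega1,
    data = per[ok, , drop = FALSE], FUN = mean
  )
  names(summary)[names(summary) == "max_jaccard"] <- "avg_max_jaccard"
  structure(
    list(per_formula = per, summary = summary, cap = cap, backend = backend),
    class = "rebuild_report"
  )
}

#' @exportS3Method base::print
print.rebuild_report <- function(x, ...) {
  cat("<rebuild_report>", nrow(x$per_formula), "formula solves\n")
  print(x$summary)
  invisible(x)
}

#' Serialize a rebuild report
#'
#' JSON for the per-formula rows plus a wide delimited table (formula x
#' omega1, one file per mode) of max-Jaccard values.
#'
#' @param report A `rebuild_report`.
#' @param path Output JSON path; the wide tables are written alongside it as
#'   `<path>.<mode>.tsv`.
#' @export
write_rebuild_report <- function(report, path) {
  jsonlite::write_json(
    list(per_formula = report$per_formula, summary = report$summary),
    path,
    dataframe = "rows", digits = NA, auto_unbox = TRUE
  )
  for (mode in unique(report$per_formula$mode)) {
    sub <- report$per_formula[report$per_formula$mode == mode, ]
    wide <- stats::reshape(
      sub[, c("formula_id", "omega1", "max_jaccard")],
      idvar = "formula_id", timevar = "omega1", direction = "wide"
    )
    names(wide) <- sub("^max_jaccard\\.", "omega1_", names(wide))
    utils::write.table(wide, paste0(path, ".", mode, ".tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  invisible(path)
}
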