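# Solver backends for milp_encoding objects.
#
# "highs": serializes a batch of encodings to JSON and runs the bundled
# scipy/HiGHS helper (inst/python/milp_pool.py) once for the whole batch;
# the helper performs the no-good-cut pool enumeration.
#
# "exhaustive": pure-R enumeration of all 2^n_z candidate vectors against the
# encoding's constraint rows; intended for small spaces (n_z <= 22).

python_binary <- function() {
  bin <- Sys.getenv("PCCMM_PYTHON", unset = "python")
  path <- Sys.which(bin)
  if (!nzchar(path)) {
    stop(
      "python interpreter '", bin, "' not found on PATH; the \"highs\" MILP ",
      "backend needs python with scipy >= 1.9 (set PCCMM_PYTHON to override), ",
      "or use backend = \"exhaustive\" for small problems",
      call. = FALSE
    )
  }
  path
}

milp_helper_path <- function() {
  path <- system.file("python", "milp_pool.py", package = "pccmm")
  if (!nzchar(path)) stop("bundled MILP helper not found", call. = FALSE)
  path
}

encoding_to_payload <- function(enc, cap, tol) {
  list(
    obj = I(enc$obj),
    # 0-based triplet coordinates for the helper
    ai = I(enc$A$i - 1L), aj = I(enc$A$j - 1L), ax = I(enc$A$x),
    n_rows = enc$n_rows, n_vars = enc$n_vars, n_z = enc$n_z,
    row_lower = I(unname(ifelse(is.finite(enc$row_lower), enc$row_lower, -1e30))),
    row_upper = I(unname(ifelse(is.finite(enc$row_upper), enc$row_upper, 1e30))),
    cap = as.integer(cap), tol = tol
  )
}

milp_pool_highs <- function(encodings, cap, tol) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  payload <- list(problems = lapply(encodings, encoding_to_payload, cap = cap, tol = tol))
  jsonlite::write_json(payload, infile, digits = NA, auto_unbox = TRUE)
  status <- system2(python_binary(), c(milp_helper_path(), infile, outfile),
    stdout = FALSE, stderr = ""
  )
  if (!identical(status, 0L) || !file.exists(outfile)) {
    stop("MILP helper failed (exit status ", status, ")", call. = FALSE)
  }
  res <- jsonlite::read_json(outfile, simplifyVector = FALSE)
  lapply(res$results, function(r) {
    if (identical(r$status, "infeasible")) {
      return(list(status = "infeasible"))
    }
    list(
      status = "optimal",
      optimum = as.numeric(r$optimum),
      solutions = lapply(r$solutions, function(s) as.integer(unlist(s)) + 1L),
      objectives = as.numeric(unlist(r$objectives)),
      capped = isTRUE(r$capped)
    )
  })
}

milp_pool_exhaustive <- function(enc, cap, tol) {
  n <- enc$n_z
  if (n > 22L) {
    stop("exhaustive backend limited to 22 decision variables (got ", n, ")",
      call. = FALSE
    )
  }
  A <- Matrix::sparseMatrix(
    i = enc$A$i, j = enc$A$j, x = enc$A$x,
    dims = c(enc$n_rows, enc$n_vars)
  )
  Az <- A[, seq_len(n), drop = FALSE]
  # Auxiliary binaries (unweighted mode) appear in exactly one row each, with
  # coefficient -M_k; at a minimum they take their smallest feasible value,
  # so u_k is determined by z: u_k = 1 iff the row's z-part is positive.
  aux <- enc$A$j > n
  u_rows <- enc$A$i[aux][order(enc$A$j[aux])]
  Mk <- -enc$A$x[aux][order(enc$A$j[aux])]
  u_cols <- n + seq_len(enc$n_u)
  total <- 2^n
  best <- Inf
  sols <- list()
  objs <- numeric(0)
  chunk <- 65536L
  for (start in seq(0, total - 1, by = chunk)) {
    codes <- start:min(start + chunk - 1, total - 1)
    Z <- matrix(0L, nrow = length(codes), ncol = n)
    for (b in seq_len(n)) Z[, b] <- bitwAnd(codes %/% 2^(b - 1L), 1L)
    AzT <- as.matrix(Az %*% t(Z)) # n_rows x n_codes
    for (ci in seq_along(codes)) {
      z <- Z[ci, ]
      lhs <- AzT[, ci]
      if (enc$n_u == 0L) {
        feasible <- all(lhs >= enc$row_lower - 1e-9) &&
          all(lhs <= enc$row_upper + 1e-9)
        if (!feasible) next
        obj <- sum(enc$obj[seq_len(n)] * z)
      } else {
        u <- as.numeric(lhs[u_rows] > 1e-9)
        if (any(u > 0 & Mk <= 0)) next
        lhs[u_rows] <- lhs[u_rows] - Mk * u
        feasible <- all(lhs >= enc$row_lower - 1e-9) &&
          all(lhs <= enc$row_upper + 1e-9)
        if (!feasible) next
        obj <- sum(enc$obj[seq_len(n)] * z) + sum(enc$obj[u_cols] * u)
      }
      if (obj < best - tol) {
        best <- obj
        sols <- list(which(z == 1L))
        objs <- obj
      } else if (obj <= best + tol) {
        sols[[length(sols) + 1L]] <- which(z == 1L)
        objs <- c(objs, obj)
      }
    }
  }
  if (!is.finite(best)) {
    return(list(status = "infeasible"))
  }
  keep <- objs <= best + tol
  sols <- sols[keep]
  objs <- objs[keep]
  capped <- length(sols) > cap
  if (capped) {
    sols <- sols[seq_len(cap)]
    objs <- objs[seq_len(cap)]
  }
  list(
    status = "optimal", optimum = best, solutions = sols,
    objectives = objs, capped = capped
  )
}
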