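# Independent brute-force oracle for the reconstruction problem: enumerates
# every candidate 0-1 vector and evaluates the published objective verbatim
# (including the nonlinear min(Pz, 1) penalty), with no reference to the MILP
# encoding. Usable up to ~14 decision variables.

enumerate_binary <- function(N) {
  codes <- 0:(2^N - 1)
  Z <- matrix(0L, nrow = length(codes), ncol = N)
  for (b in seq_len(N)) Z[, b] <- bitwAnd(codes %/% 2^(b - 1L), 1L)
  Z
}

# objective of the published models, evaluated directly on a candidate matrix
verbatim_objective <- function(ZP, Z, target, omega1, mode) {
  tgt <- matrix(target, nrow = nrow(ZP), ncol = length(target), byrow = TRUE)
  pen <- if (mode == "unweighted") {
    rowSums(abs(pmin(ZP, 1) - tgt))
  } else {
    rowSums(abs(ZP - tgt))
  }
  omega1 * rowSums(Z) + (1 - omega1) * pen
}

oracle_pool <- function(P, target, pairs = NULL, omega1 = 0.5,
                        mode = c("weighted", "unweighted"), tol = 1e-6) {
  mode <- match.arg(mode)
  N <- ncol(P)
  stopifnot(N <= 14)
  Z <- enumerate_binary(N)
  ZP <- Z %*% t(as.matrix(P))
  tgt <- matrix(target, nrow = nrow(ZP), ncol = length(target), byrow = TRUE)
  feasible <- rowSums(ZP < tgt) == 0L
  idx_pairs <- if (is.null(pairs)) matrix(integer(0), ncol = 2L) else attr(pairs, "index_pairs")
  if (nrow(idx_pairs)) {
    for (r in seq_len(nrow(idx_pairs))) {
      feasible <- feasible & (Z[, idx_pairs[r, 1L]] + Z[, idx_pairs[r, 2L]] <= 1L)
    }
  }
  if (!any(feasible)) {
    return(list(status = "infeasible", optimum = NA_real_, solutions = list()))
  }
  obj <- verbatim_objective(ZP, Z, target, omega1, mode)
  obj[!feasible] <- Inf
  best <- min(obj)
  hit <- which(obj <= best + tol)
  list(
    status = "optimal", optimum = best,
    solutions = lapply(hit, function(r) which(Z[r, ] == 1L))
  )
}

oracle_support_set <- function(oracle) {
  sort(vapply(oracle$solutions, function(s) paste(sort(s), collapse = ","), ""))
}
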