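#' Sample random pseudo-formulas
#'
#' Draws n independent 0-1 vectors of length N with i.i.d. Bernoulli(s/N)
#' entries, so the expected number of members per pseudo-formula is s and the
#' member count follows Binomial(N, s/N). All-zero draws are rejected and
#' resampled (an empty "formula" has no triplet image and breaks every
#' downstream operation); this is the only deviation from raw Bernoulli
#' sampling and is noted here deliberately.
#'
#' @param n Number of pseudo-formulas.
#' @param N Dimension (size of the CMM space).
#' @param s Target sparsity (expected member count), 0 < s < N.
#' @param seed Integer seed; batches are reproducible.
#' @return A `pseudo_formula_batch`: integer n x N 0/1 matrix with attributes
#'   `s`, `p`, `seed`.
#' @export
sample_pseudo_formulas <- function(n, N, s, seed) {
  if (!is.numeric(s) || s <= 0 || s >= N) {
    stop("sparsity s must satisfy 0 < s < N", call. = FALSE)
  }
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  p <- s / N
  X <- withr::with_seed(as.integer(seed), {
    X <- matrix(stats::rbinom(n * N, 1L, p), nrow = n, ncol = N)
    for (i in seq_len(n)) {
      while (sum(X[i, ]) == 0L) {
        X[i, ] <- stats::rbinom(N, 1L, p)
      }
    }
    X
  })
  rownames(X) <- sprintf("pseudo-%d", seq_len(n))
  structure(X, s = s, p = p, seed = as.integer(seed), class = c("pseudo_formula_batch", class(X)))
}

#' Bootstrap nearest-class-mean classification
#'
#' Repeated random train/test splits: each trial draws `train_per_class`
#' members per class uniformly without replacement, predicts every remaining
#' vector's class as the one whose training members have the smallest mean
#' l1 distance, and records the accuracy. With `preembed = TRUE` (the
#' default) vectors are first projected to 2-D by t-SNE (Hamming distance)
#' and the l1 distances are computed in the embedded plane; with `FALSE`
#' distances are computed in the original vector space. Argmin ties go to the
#' class earliest in the factor level order.
#'
#' @param vectors Numeric matrix, one vector per row.
#' @param labels Class label per row (factor or character; factor level order
#'   fixes tie-breaking).
#' @param trials Number of bootstrap trials.
#' @param train_per_class Training cases drawn per class; every class must
#'   have strictly more members than this.
#' @param preembed Embed to 2-D before computing distances.
#' @param seed Integer seed covering both the embedding and the resampling.
#' @param perplexity,learning_rate Passed to [embed_2d()] when preembedding.
#' @return A `bootstrap_result`: list with `accuracies` (length `trials`),
#'   `mean`, `quantiles`, `trials`, `train_per_class`, `preembed`.
#' @export
bootstrap_classify <- function(vectors, labels, trials = 5000L,
                               train_per_class = 16L, preembed = TRUE, seed,
                               perplexity = 30, learning_rate = 500) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  labels <- as.factor(labels)
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != length(labels)) stop("one label per vector required", call. = FALSE)
  sizes <- table(labels)
  small <- names(sizes)[sizes <= train_per_class]
  if (length(small)) {
    stop(
      "class(es) too small for train_per_class = ", train_per_class, ": ",
      paste(small, collapse = ", "),
      call. = FALSE
    )
  }
  data <- if (preembed) {
    embed_2d(vectors,
      metric = "hamming", perplexity = perplexity,
      learning_rate = learning_rate, seed = seed
    )
  } else {
    vectors
  }
  # full pairwise l1 distances once; trials only index into it
  D <- as.matrix(stats::dist(data, method = "manhattan"))
  classes <- levels(labels)
  idx_by_class <- lapply(classes, function(cl) which(labels == cl))
  accuracies <- withr::with_seed(as.integer(seed) + 1L, {
    vapply(seq_len(trials), function(t) {
      train <- lapply(idx_by_class, function(ix) sort(sample(ix, train_per_class)))
      test <- setdiff(seq_along(labels), unlist(train))
      means <- vapply(train, function(ix) {
        rowMeans(D[test, ix, drop = FALSE])
      }, numeric(length(test)))
      if (length(test) == 1L) means <- matrix(means, nrow = 1L)
      pred <- classes[max.col(-means, ties.method = "first")]
      mean(pred == as.character(labels[test]))
    }, 0)
  })
  structure(
    list(
      accuracies = accuracies, mean = mean(accuracies),
      quantiles = stats::quantile(accuracies, c(0.025, 0.25, 0.5, 0.75, 0.975)),
      trials = trials, train_per_class = train_per_class, preembed = preembed
    ),
    class = "bootstrap_result"
  )
}

#' @exportS3Method base::print
print.bootstrap_result <- function(x, ...) {
  cat(
    "<bootstrap_result>", x$trials, "trials, mean accuracy",
    format(x$mean, digits = 4), "\n"
  )
  print(x$quantiles)
  invisible(x)
}

#' Mixed real/pseudo-formula separation dataset
#'
#' Builds the matrices used for the separation experiment: the catalog's
#' formula vectors (CMM level) stacked over `pseudo_n` random pseudo-formulas
#' at the catalog's average sparsity, plus the corresponding weighted
#' triplet-set vectors, with cluster labels.
#'
#' @param catalog A `formula_catalog`.
#' @param P Measurement matrix.
#' @param spaces Matching `pccmm_spaces`.
#' @param pseudo_n Number of pseudo-formulas to mix in.
#' @param s Sparsity of the pseudo-formulas; defaults to the catalog's mean
#'   formula size.
#' @param seed Integer seed.
#' @return List with matrices `cmm` (formula vectors) and `pccmm` (weighted
#'   triplet vectors), and `labels` (batch tags for real formulas,
#'   `"random"` for pseudo-formulas).
#' @export
separation_dataset <- function(catalog, P, spaces, pseudo_n = 150L, s = NULL, seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  xs <- t(vapply(
    catalog$cmm_ids, function(ids) encode_formula(ids, spaces),
    integer(spaces$N)
  ))
  rownames(xs) <- catalog$formula_id
  if (is.null(s)) s <- mean(lengths(catalog$cmm_ids))
  pseudo <- sample_pseudo_formulas(pseudo_n, spaces$N, s, seed = seed)
  X <- rbind(xs, unclass(pseudo))
  YW <- t(apply(X, 1L, function(x) measure(P, x, weighted = TRUE)))
  labels <- c(
    ifelse(is.na(catalog$batch), "formula", paste0("batch-", catalog$batch)),
    rep("random", pseudo_n)
  )
  list(cmm = X, pccmm = YW, labels = labels, s = s, seed = as.integer(seed))
}
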