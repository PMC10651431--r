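#' Regression metrics: Pearson r, RMSE, MAE
#'
#' Standard definitions. The correlation is reported as `NaN` with a
#' warning when either vector is constant (rather than a silent zero,
#' which would corrupt comparisons); RMSE and MAE are always defined.
#'
#' @param predictions,targets Equal-length numeric vectors (length >= 2
#'   for a correlation).
#' @return List with `r`, `rmse`, `mae`, `n`.
#' @export
eval_metrics <- function(predictions, targets) {
  abort_if(length(predictions) != length(targets),
           "length mismatch: %d predictions vs %d targets",
           length(predictions), length(targets))
  n <- length(predictions)
  rmse <- sqrt(mean((predictions - targets)^2))
  mae <- mean(abs(predictions - targets))
  r <- if (n < 2) {
    NaN
  } else if (sd(predictions) == 0 || sd(targets) == 0) {
    warning("constant predictions or targets: Pearson r undefined")
    NaN
  } else {
    cor(predictions, targets)
  }
  list(r = r, rmse = rmse, mae = mae, n = n)
}

#' Reverse a set of variant pairs
#'
#' Swaps wild-type and mutant sequences and negates the target: the true
#' ddG of a reverse mutation is the negation of the direct value. The
#' construction is an involution — applying it twice restores the
#' original set.
#'
#' @param pairs Data frame with `wt_seq`, `mt_seq`, `position`, `ddg`.
#' @return The reversed pairs, same columns.
#' @export
reverse_pairs <- function(pairs) {
  out <- pairs
  out$wt_seq <- pairs$mt_seq
  out$mt_seq <- pairs$wt_seq
  out$ddg <- -pairs$ddg
  out
}

#' Symmetric (direct/reverse) evaluation
#'
#' Constructs the reversed counterpart of every test pair, scores both
#' sides with the model, and returns paired metrics mirroring the
#' direct/reverse column structure of symmetric benchmarks (r_dir,
#' r_rev, RMSE, MAE per side). A perfectly antisymmetric model yields
#' identical metrics on the two sides.
#'
#' @param model A trained head/ensemble, or a function
#'   `(pairs) -> predictions`.
#' @param pairs Direct test pairs with `ddg` targets.
#' @param backbone Backbone (ignored when `model` is a function).
#' @param allow_untrained Permit untrained heads.
#' @return A `protstab_eval` list: `r_dir`, `r_rev`, `rmse_dir`,
#'   `rmse_rev`, `mae_dir`, `mae_rev`, `n_dir`, `n_rev`.
#' @export
evaluate_symmetric <- function(model, pairs, backbone = NULL,
                               allow_untrained = FALSE) {
  predict_fun <- if (is.function(model)) model
  else function(p) predict_pairs(model, p, backbone,
                                 allow_untrained = allow_untrained)
  rev <- reverse_pairs(pairs)
  m_dir <- eval_metrics(predict_fun(pairs), pairs$ddg)
  m_rev <- eval_metrics(predict_fun(rev), rev$ddg)
  structure(list(r_dir = m_dir$r, r_rev = m_rev$r,
                 rmse_dir = m_dir$rmse, rmse_rev = m_rev$rmse,
                 mae_dir = m_dir$mae, mae_rev = m_rev$mae,
                 n_dir = m_dir$n, n_rev = m_rev$n),
            class = "protstab_eval")
}

#' @export
print.protstab_eval <- function(x, ...) {
  cat(sprintf("          %8s %8s\n", "direct", "reverse"))
  cat(sprintf("Pearson r %8.3f %8.3f\n", x$r_dir, x$r_rev))
  cat(sprintf("RMSE      %8.3f %8.3f\n", x$rmse_dir, x$rmse_rev))
  cat(sprintf("MAE       %8.3f %8.3f\n", x$mae_dir, x$mae_rev))
  cat(sprintf("n         %8d %8d\n", x$n_dir, x$n_rev))
  invisible(x)
}

# single-linkage clusters over the homology graph: an edge joins two
# sequences when identity > threshold and E-value < threshold
sequence_clusters <- function(sequences, backend, identity_threshold = 30,
                              evalue_threshold = 0.05) {
  n <- length(sequences)
  nm <- names(sequences) %||% as.character(seq_len(n))
  comp <- seq_len(n)
  find <- function(i) {
    while (comp[i] != i) i <- comp[i]
    i
  }
  if (n > 1) {
    hits <- backend(setNames(sequences, nm), setNames(sequences, nm))
    edges <- hits[hits$query != hits$subject &
                    hits$identity > identity_threshold &
                    hits$evalue < evalue_threshold, , drop = FALSE]
    for (k in seq_len(nrow(edges))) {
      a <- find(match(edges$query[k], nm))
      b <- find(match(edges$subject[k], nm))
      if (a != b) comp[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  setNames(match(roots, unique(roots)), nm)
}

#' Cluster-aware cross-validation folds
#'
#' Sequences are clustered by single linkage on the homology graph
#' (identity above the threshold with a qualifying E-value), and whole
#' clusters are assigned to folds — never split — so that test folds
#' contain no protein homologous to the training folds. Clusters are
#' placed greedily, largest first, onto the currently lightest fold,
#' balancing by record count when weights are supplied. Deterministic
#' for a fixed seed.
#'
#' @param sequences Named character vector of wild-type sequences.
#' @param k Number of folds (>= 2).
#' @param backend Identity backend, e.g. [identity_backend_naive()].
#' @param seed Seed (used only to break exact ties in cluster order).
#' @param weights Optional per-sequence record counts used for
#'   balancing; default 1 each.
#' @param identity_threshold,evalue_threshold Homology-edge thresholds.
#' @return A `fold_assignment`: list with `fold` (named integer vector,
#'   per sequence), `cluster` (named integer vector), `k`.
#' @export
make_cluster_folds <- function(sequences, k,
                               backend = identity_backend_naive(
                                 identity_threshold),
                               seed = 1L, weights = NULL,
                               identity_threshold = 30,
                               evalue_threshold = 0.05) {
  abort_if(k < 2, "k must be >= 2")
  nm <- names(sequences) %||% as.character(seq_along(sequences))
  names(sequences) <- nm
  weights <- weights %||% setNames(rep(1, length(sequences)), nm)
  cl <- sequence_clusters(sequences, backend, identity_threshold,
                          evalue_threshold)
  ncl <- max(cl)
  abort_if(ncl < k, "only %d cluster(s) for %d folds", ncl, k)
  cl_weight <- vapply(seq_len(ncl), function(ci)
    sum(weights[nm[cl == ci]]), 0)
  order_cl <- with_seed(seed, {
    jitter_rank <- sample.int(ncl)  # deterministic tie-break
    order(-cl_weight, jitter_rank)
  })
  fold_of_cluster <- integer(ncl)
  load <- rep(0, k)
  for (ci in order_cl) {
    f <- which.min(load)
    fold_of_cluster[ci] <- f
    load[f] <- load[f] + cl_weight[ci]
  }
  structure(list(fold = setNames(fold_of_cluster[cl], nm),
                 cluster = cl, k = as.integer(k)),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("fold_assignment: %d sequence(s), %d cluster(s), k = %d\n",
              length(x$fold), max(x$cluster), x$k))
  print(table(fold = x$fold))
  invisible(x)
}
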