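#' Clustering evaluation metrics
#'
#' Permutation-invariant agreement measures between a predicted clustering
#' and gold class labels: optimal-mapping accuracy (ACC), normalized mutual
#' information (NMI), adjusted Rand index (ARI) and two F1 variants. Labels
#' are treated as opaque categories; neither vector needs contiguous or
#' matching label sets.
#'
#' @name clustering-metrics
NULL

check_labels <- function(gold, pred, min_n = 1L) {
  if (length(gold) != length(pred)) {
    abort(sprintf("label vectors differ in length: %d vs %d",
                  length(gold), length(pred)))
  }
  if (length(gold) < min_n) abort(sprintf("need at least %d samples", min_n))
  invisible(TRUE)
}

contingency <- function(gold, pred) {
  table(pred = as.character(pred), gold = as.character(gold))
}

# Hungarian algorithm (shortest augmenting path with potentials) for the
# square min-cost assignment problem. Returns the column assigned to each
# row. O(n^3).
hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost))
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)      # p[j + 1]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) assignment[p[j + 1]] <- j
  assignment
}

# Optimal one-to-one mapping of predicted clusters (rows) to gold classes
# (columns) maximizing mapped mass; rectangular tables are zero-padded.
optimal_mapping <- function(tab) {
  n <- max(dim(tab))
  m <- matrix(0, n, n)
  m[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  hungarian(max(m) - m)
}

#' @describeIn clustering-metrics Best accuracy over one-to-one mappings of
#'   predicted clusters to gold classes, found by optimal assignment on the
#'   contingency table.
#' @param gold,pred Equal-length label vectors.
#' @export
clustering_accuracy <- function(gold, pred) {
  check_labels(gold, pred)
  tab <- contingency(gold, pred)
  assign <- optimal_mapping(tab)
  matched <- 0
  for (i in seq_len(nrow(tab))) {
    j <- assign[i]
    if (j <= ncol(tab)) matched <- matched + tab[i, j]
  }
  matched / length(gold)
}

entropy_nat <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' @describeIn clustering-metrics Mutual information of the contingency
#'   table normalized by the arithmetic mean of the two label entropies.
#'   Two identical single-cluster partitions score 1; a zero-entropy
#'   partition against a non-degenerate one scores 0.
#' @export
nmi <- function(gold, pred) {
  check_labels(gold, pred)
  tab <- as.matrix(contingency(gold, pred))
  n <- sum(tab)
  hg <- entropy_nat(colSums(tab))
  hp <- entropy_nat(rowSums(tab))
  if (hg == 0 && hp == 0) return(1)
  if (hg == 0 || hp == 0) return(0)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      if (tab[i, j] > 0) {
        mi <- mi + tab[i, j] / n *
          log(tab[i, j] * n / (sum(tab[i, ]) * sum(tab[, j])))
      }
    }
  }
  mi / ((hg + hp) / 2)
}

#' @describeIn clustering-metrics Adjusted Rand index from pair counts:
#'   `(Index - E[Index]) / (Max - E[Index])`; 1 for identical partitions,
#'   about 0 for independent random ones.
#' @export
ari <- function(gold, pred) {
  check_labels(gold, pred, min_n = 2L)
  tab <- as.matrix(contingency(gold, pred))
  n <- sum(tab)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(ifelse(sum_ij == maximum, 1, 0))
  (sum_ij - expected) / (maximum - expected)
}

#' @describeIn clustering-metrics F1 of the clustering. The `"macro"`
#'   variant (default) pairs predicted clusters one-to-one with gold
#'   classes by the assignment maximizing the summed per-class F1 and
#'   reports the unweighted mean over gold classes (optimizing the F1 sum
#'   itself, rather than reusing the accuracy-optimal mapping, keeps the
#'   score well defined when several mappings tie on accuracy); the
#'   `"pairwise"` variant computes precision and recall over same-cluster
#'   sample pairs.
#' @param variant `"macro"` or `"pairwise"`.
#' @export
clustering_f1 <- function(gold, pred, variant = c("macro", "pairwise")) {
  variant <- match.arg(variant)
  check_labels(gold, pred)
  if (variant == "pairwise") {
    tab <- as.matrix(contingency(gold, pred))
    choose2 <- function(x) x * (x - 1) / 2
    tp <- sum(choose2(tab))
    pred_pairs <- sum(choose2(rowSums(tab)))
    gold_pairs <- sum(choose2(colSums(tab)))
    if (pred_pairs == 0 && gold_pairs == 0) return(1)
    if (pred_pairs == 0 || gold_pairs == 0) return(0)
    prec <- tp / pred_pairs
    rec <- tp / gold_pairs
    if (prec + rec == 0) return(0)
    return(2 * prec * rec / (prec + rec))
  }
  tab <- as.matrix(contingency(gold, pred))
  n <- max(dim(tab))
  f1_pair <- matrix(0, n, n)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      denom <- rs[i] + cs[j]
      if (denom > 0) f1_pair[i, j] <- 2 * tab[i, j] / denom
    }
  }
  assign <- hungarian(max(f1_pair) - f1_pair)
  total <- sum(f1_pair[cbind(seq_len(n), assign)])
  total / ncol(tab)
}

#' Full metrics report
#'
#' Computes all clustering indicators at once.
#'
#' @param gold,pred Equal-length label vectors.
#' @return A one-row tibble with columns `acc`, `nmi`, `ari`, `f1_macro`,
#'   `f1_pairwise`, `n`, carrying the predicted-by-gold contingency table
#'   as attribute `contingency`.
#' @examples
#' evaluate_clustering(c(1, 1, 2, 2), c(2, 2, 1, 1))
#' @export
evaluate_clustering <- function(gold, pred) {
  check_labels(gold, pred)
  out <- tibble(
    acc = clustering_accuracy(gold, pred),
    nmi = nmi(gold, pred),
    ari = if (length(gold) >= 2) ari(gold, pred) else NA_real_,
    f1_macro = clustering_f1(gold, pred, "macro"),
    f1_pairwise = clustering_f1(gold, pred, "pairwise"),
    n = length(gold)
  )
  attr(out, "contingency") <- contingency(gold, pred)
  out
}
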