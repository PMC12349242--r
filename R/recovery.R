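# Sample-size simulation: how reliably does k-means recover known cluster
# labels at a given n and centroid separation?

# k vertices of a regular simplex with edge length `edge`, embedded in p
# dimensions (p >= k - 1) under a seeded random rotation
simplex_centroids <- function(k, p, edge) {
  V <- diag(k)
  V <- scale(V, scale = FALSE)          # centered; pairwise distance sqrt(2)
  V <- V * edge / sqrt(2)
  M <- matrix(0, k, p)
  M[, seq_len(k)] <- V[, seq_len(min(k, p))]
  Q <- qr.Q(qr(matrix(rnorm(p * p), p)))
  M %*% Q
}

#' Draw one Gaussian-mixture feature cohort with known cluster labels
#'
#' `n` subjects from a `k`-component spherical Gaussian mixture over `p`
#' variables. Centroids sit on a randomly rotated regular simplex whose
#' coordinates differ by `separation` within-cluster SDs per variable on
#' average (edge length `separation * sqrt(p)`), and the columns are then
#' z-scored — the standardized-variable setting of the sample-size
#' analysis.
#'
#' @param n Subjects.
#' @param k True clusters.
#' @param p Variables.
#' @param separation Per-variable centroid difference, in SD units.
#' @param seed Integer seed.
#' @return Tibble with `subject`, true `label`, and variables `f1..fp`.
#' @export
simulate_cluster_cohort <- function(n = 200, k = 5, p = 5, separation = 1.5,
                                    seed = 1L) {
  withr::with_seed(seed, {
    C <- simplex_centroids(k, p, separation * sqrt(p))
    label <- sample(rep(seq_len(k), length.out = n))
    X <- C[label, , drop = FALSE] + matrix(rnorm(n * p), n, p)
  })
  X <- scale(X)
  out <- as_tibble(setNames(as.data.frame(X), paste0("f", seq_len(p))))
  bind_cols(tibble(subject = sprintf("S%04d", seq_len(n)), label = label), out)
}

#' Label-recovery accuracy after optimal permutation
#'
#' Fraction of subjects whose estimated cluster matches the true label
#' under the best one-to-one label matching (Hungarian assignment on the
#' confusion matrix).
#'
#' @param truth,estimate Integer label vectors of equal length.
#' @return Accuracy in \[0, 1\].
#' @export
label_recovery_accuracy <- function(truth, estimate) {
  if (length(truth) != length(estimate)) abort("label vectors differ in length.")
  tab <- table(factor(truth), factor(estimate))
  m <- max(dim(tab))
  sq <- matrix(0, m, m)
  sq[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  perm <- clue::solve_LSAP(sq, maximum = TRUE)
  sum(sq[cbind(seq_len(m), perm)]) / length(truth)
}

#' Monte-Carlo assessment of k-means label recovery
#'
#' For each replicate, a fresh mixture cohort is drawn (per-variable
#' centroid separation sampled uniformly over `separation_range`), k-means
#' with `n_init` restarts is fit at the true k, and recovery accuracy after
#' optimal label permutation is recorded.
#'
#' @inheritParams simulate_cluster_cohort
#' @param separation_range Range the per-variable separation is drawn from.
#' @param replicates Number of Monte-Carlo replicates.
#' @param n_init k-means restarts.
#' @param seed Integer root seed.
#' @return List with `mean_accuracy_pct` and per-replicate tibble `detail`
#'   (`replicate`, `separation`, `accuracy`).
#' @export
assess_cluster_recovery <- function(n = 200, k = 5, p = 5,
                                    separation_range = c(1, 2),
                                    replicates = 100, n_init = 100,
                                    seed = 20250725L) {
  detail <- lapply(seq_len(replicates), function(r) {
    s <- child_seed(seed, r)
    sep <- withr::with_seed(child_seed(s, 1L),
                            runif(1, separation_range[1], separation_range[2]))
    coh <- simulate_cluster_cohort(n, k, p, separation = sep,
                                   seed = child_seed(s, 2L))
    X <- as.matrix(coh[, paste0("f", seq_len(p))])
    km <- withr::with_seed(child_seed(s, 3L),
                           kmeans(X, k, nstart = n_init, iter.max = 100))
    tibble(replicate = r, separation = sep,
           accuracy = label_recovery_accuracy(coh$label, km$cluster))
  }) |> list_rbind()
  list(mean_accuracy_pct = 100 * mean(detail$accuracy), detail = detail)
}
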