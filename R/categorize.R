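# Standardization, sign-aligned PCA, the k-means scan with its cluster-count
# diagnostics (elbow / silhouette / gap), and model-fit adjudication via
# MANOVA-style variance explained and AIC.

#' Z-score a feature table on a variable set
#'
#' Complete-case rows on the chosen set are z-scored column-wise; the
#' per-variable (mean, SD) scaler is retained so new subjects can be
#' projected later.
#'
#' @param features Per-subject feature tibble (must contain a `subject`
#'   column and the set's variables).
#' @param set Character vector of variable names, e.g. one element of
#'   [variable_sets()].
#' @return Object of class `ul_zmatrix`: list with `z` (matrix), `subjects`,
#'   `variables`, `scaler`, `n_dropped`.
#' @export
standardize_features <- function(features, set = variable_sets()$v5) {
  missing_vars <- setdiff(set, names(features))
  if (length(missing_vars) > 0) {
    abort(paste0("features table lacks variables: ",
                 paste(missing_vars, collapse = ", ")))
  }
  X <- as.matrix(features[, set])
  keep <- complete.cases(X)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warn(sprintf("dropping %d subject(s) with missing values on this variable set.",
                 n_dropped))
  }
  X <- X[keep, , drop = FALSE]
  if (nrow(X) < 2) abort("need >= 2 complete-case subjects to standardize.")
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  if (any(sdev == 0)) {
    abort(paste0("zero-variance variable(s): ",
                 paste(set[sdev == 0], collapse = ", ")))
  }
  z <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  rownames(z) <- if ("subject" %in% names(features)) {
    features$subject[keep]
  } else as.character(which(keep))
  structure(
    list(z = z, subjects = rownames(z), variables = set,
         scaler = tibble(variable = set, mean = mu, sd = sdev),
         n_dropped = n_dropped),
    class = "ul_zmatrix"
  )
}

#' Principal component analysis of the standardized variables
#'
#' PCA on the z-scored matrix (equivalently, of the correlation structure),
#' components ordered by explained variance and sign-aligned so every
#' component loads non-negatively on the anchor variable (preferred time by
#' default) — the sign of a PC is arbitrary, and anchoring makes loadings
#' comparable across variable sets.
#'
#' @param zmat An `ul_zmatrix` from [standardize_features()].
#' @param anchor Anchoring variable for [align_signs()].
#' @return Object of class `ul_pca`: list with `loadings`,
#'   `explained_variance_pct`, `scores`, `sign_aligned`.
#' @export
run_pca <- function(zmat, anchor = "preferred_time") {
  stopifnot(inherits(zmat, "ul_zmatrix"))
  if (nrow(zmat$z) < length(zmat$variables)) {
    warn("fewer subjects than variables; PCA proceeds with min(n, p) components.")
  }
  pc <- prcomp(zmat$z, center = FALSE, scale. = FALSE)
  expl <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  out <- structure(
    list(loadings = pc$rotation, explained_variance_pct = expl,
         scores = pc$x, sign_aligned = FALSE, variables = zmat$variables),
    class = "ul_pca"
  )
  align_signs(out, anchor = anchor)
}

#' Align principal component signs on an anchor variable
#'
#' For every component whose loading on the anchor is negative, both the
#' loadings and the scores of that component are multiplied by −1. The
#' internal structure of the loadings is unchanged.
#'
#' @param pca An `ul_pca`.
#' @param anchor Variable name; absent anchors make this a no-op with a
#'   warning.
#' @return The sign-aligned `ul_pca`.
#' @export
align_signs <- function(pca, anchor = "preferred_time") {
  stopifnot(inherits(pca, "ul_pca"))
  if (!anchor %in% rownames(pca$loadings)) {
    warn(sprintf("anchor variable '%s' not present; signs left unchanged.", anchor))
    return(pca)
  }
  flip <- pca$loadings[anchor, ] < 0
  if (any(flip)) {
    pca$loadings[, flip] <- -pca$loadings[, flip, drop = FALSE]
    pca$scores[, flip] <- -pca$scores[, flip, drop = FALSE]
  }
  pca$sign_aligned <- TRUE
  pca
}

#' MANOVA-style percentage of total variance explained by clusters
#'
#' Treating cluster membership as a categorical factor, the trace-based
#' effect size 100·(1 − WSS/TSS), where TSS sums squared deviations from
#' the grand centroid over all variables.
#'
#' @param z Numeric matrix (subjects × variables).
#' @param assignments Integer cluster labels.
#' @return Percentage in \[0, 100\].
#' @export
cluster_variance_explained <- function(z, assignments) {
  tss <- sum(sweep(z, 2, colMeans(z))^2)
  if (tss == 0) abort("total sum of squares is zero.")
  100 * (1 - cluster_wss(z, assignments) / tss)
}

cluster_wss <- function(z, assignments) {
  sum(vapply(split(seq_len(nrow(z)), assignments), function(idx) {
    zi <- z[idx, , drop = FALSE]
    sum(sweep(zi, 2, colMeans(zi))^2)
  }, numeric(1)))
}

#' AIC of a k-means solution under a spherical Gaussian within-cluster model
#'
#' −2·logLik + 2·k·p with logLik of an isotropic Gaussian around each
#' centroid and common variance WSS/(n·p):
#' AIC = n·p·(log(2π·WSS/(n·p)) + 1) + 2·k·p. The additive constant is part
#' of the package's convention so within-grid comparisons are exact;
#' absolute values are not comparable across datasets. WSS = 0 (k = n) is
#' reported as undefined.
#'
#' @inheritParams cluster_variance_explained
#' @return AIC value (NA when WSS = 0).
#' @export
cluster_aic <- function(z, assignments) {
  n <- nrow(z); p <- ncol(z); k <- length(unique(assignments))
  wss <- cluster_wss(z, assignments)
  if (wss <= 0) return(NA_real_)
  n * p * (log(2 * pi * wss / (n * p)) + 1) + 2 * k * p
}

#' Mean silhouette width of a clustering
#'
#' @inheritParams cluster_variance_explained
#' @return Mean silhouette over subjects (Euclidean distance), in \[−1, 1\].
#' @export
silhouette_statistic <- function(z, assignments) {
  if (length(unique(assignments)) < 2) abort("silhouette requires k >= 2.")
  if (length(unique(assignments)) == length(assignments)) {
    return(0)  # all-singleton clustering: widths are 0 by convention
  }
  mean(cluster::silhouette(assignments, stats::dist(z))[, "sil_width"])
}

# one seeded k-means fit with canonical label order (ascending first-PC
# centroid projection) so reports are stable across runs
fit_kmeans <- function(z, k, seed, n_init = 25, max_iter = 300) {
  if (k == nrow(z)) {
    # every point its own cluster; stats::kmeans declines this boundary
    km <- list(cluster = seq_len(k), centers = z, tot.withinss = 0,
               totss = sum(sweep(z, 2, colMeans(z))^2))
  } else {
    km <- withr::with_seed(seed, {
      if (k == 1) {
        kmeans(z, centers = 1, iter.max = max_iter)
      } else {
        kmeans(z, centers = k, nstart = n_init, iter.max = max_iter)
      }
    })
  }
  pc1 <- prcomp(z, center = FALSE)$rotation[, 1]
  proj <- as.vector(km$centers %*% pc1)
  relabel <- order(order(proj))
  assignments <- relabel[km$cluster]
  centers <- km$centers[order(proj), , drop = FALSE]
  rownames(centers) <- seq_len(k)
  list(assignments = assignments, centers = centers,
       wss = km$tot.withinss, tss = km$totss)
}

#' Scan k-means solutions over a range of cluster counts
#'
#' Best-of-`n_init` Lloyd's k-means for every k, with WSS, silhouette,
#' MANOVA variance explained and AIC per solution. Deterministic given
#' `seed`; labels are canonically ordered by ascending PC1 centroid.
#'
#' @param zmat An `ul_zmatrix`.
#' @param k_range Integer vector of cluster counts (default 1:10).
#' @param seed Integer seed.
#' @param n_init Random restarts per k.
#' @return Object of class `ul_kmeans_scan`: tibble with one row per k
#'   (columns `k`, `wss`, `variance_explained_pct`, `silhouette`, `aic`)
#'   plus an `assignments` list-column; the z-matrix is attached.
#' @export
kmeans_scan <- function(zmat, k_range = 1:10, seed = 20250725L, n_init = 25) {
  stopifnot(inherits(zmat, "ul_zmatrix"))
  z <- zmat$z
  if (max(k_range) > nrow(z)) abort("max(k_range) exceeds the number of subjects.")
  rows <- lapply(k_range, function(k) {
    fit <- fit_kmeans(z, k, seed = child_seed(seed, k), n_init = n_init)
    tibble(
      k = k,
      wss = fit$wss,
      variance_explained_pct = cluster_variance_explained(z, fit$assignments),
      silhouette = if (k >= 2) silhouette_statistic(z, fit$assignments) else NA_real_,
      aic = cluster_aic(z, fit$assignments),
      assignments = list(fit$assignments),
      centers = list(fit$centers)
    )
  })
  out <- list_rbind(rows)
  attr(out, "zmat") <- zmat
  attr(out, "seed") <- seed
  attr(out, "n_init") <- n_init
  class(out) <- c("ul_kmeans_scan", class(out))
  out
}

#' Within-cluster sum of squares (elbow) curve
#'
#' @param scan An `ul_kmeans_scan`.
#' @return Tibble with `k` and `wss`, verified non-increasing in k.
#' @export
elbow_curve <- function(scan) {
  stopifnot(inherits(scan, "ul_kmeans_scan"))
  out <- scan[order(scan$k), c("k", "wss")]
  if (any(diff(out$wss) > 1e-8 * out$wss[1])) {
    warn("WSS is not non-increasing in k; consider more restarts.")
  }
  as_tibble(out)
}

#' Gap statistic over a k-means scan
#'
#' Tibshirani's gap statistic with the PCA-aligned uniform-box reference
#' (`spaceH0 = "scaledPCA"`) on squared distances, with the √(1 + 1/B)
#' standard-error factor. The suggested k is the smallest k with
#' Gap(k) ≥ Gap(k+1) − SE(k+1).
#'
#' @param zmat An `ul_zmatrix`.
#' @param k_max Largest k evaluated.
#' @param B Number of reference datasets (>= 10).
#' @param seed Integer seed.
#' @param n_init Restarts per k-means fit.
#' @return List with `table` (tibble: k, gap, se) and `suggested_k`.
#' @export
gap_statistic <- function(zmat, k_max = 10, B = 100, seed = 20250725L, n_init = 25) {
  stopifnot(inherits(zmat, "ul_zmatrix"))
  if (B < 10) abort("`B` must be >= 10.")
  gap <- withr::with_seed(seed, {
    cluster::clusGap(
      zmat$z,
      FUNcluster = function(x, k) {
        list(cluster = if (k == 1) rep(1L, nrow(x)) else
          kmeans(x, k, nstart = n_init, iter.max = 300)$cluster)
      },
      K.max = k_max, B = B, d.power = 2, spaceH0 = "scaledPCA", verbose = FALSE
    )
  })
  tab <- as_tibble(gap$Tab)[, c("gap", "SE.sim")]
  names(tab) <- c("gap", "se")
  tab <- bind_cols(tibble(k = seq_len(k_max)), tab)
  k_hat <- cluster::maxSE(tab$gap, tab$se, method = "Tibs2001SEmax")
  list(table = tab, suggested_k = k_hat)
}

#' Adjudicate cluster count and variable set by model fit
#'
#' Builds the full grid of (variable set × candidate k) solutions: for each
#' set the features are z-scored, PCA is run (sign-aligned), k-means is fit
#' for every candidate k, and MANOVA variance explained plus AIC are
#' recorded. The chosen model is the grid cell with the lowest AIC, ties
#' broken toward smaller k and then fewer variables.
#'
#' @param features Per-subject feature tibble.
#' @param sets Named list of variable sets (default [variable_sets()]).
#' @param k_candidates Candidate cluster counts (default 2:5).
#' @param seed Integer seed.
#' @param n_init Restarts per k-means fit.
#' @return Object of class `ul_adjudication`: list with `grid` (tibble:
#'   set, n_vars, pc1_pct, pc2_pct, k, variance_explained_pct, aic),
#'   `chosen`, and per-set `pca`, `scans`, `zmats`.
#' @export
adjudicate_clusters <- function(features, sets = variable_sets(),
                                k_candidates = 2:5, seed = 20250725L,
                                n_init = 25) {
  zmats <- lapply(sets, function(s) standardize_features(features, s))
  pcas <- lapply(zmats, run_pca)
  scans <- imap(zmats, function(zm, nm) {
    kmeans_scan(zm, k_range = k_candidates,
                seed = child_seed(seed, 10L + match(nm, names(sets))),
                n_init = n_init)
  })
  grid <- imap(scans, function(sc, nm) {
    ev <- pcas[[nm]]$explained_variance_pct
    tibble(
      set = nm,
      n_vars = length(sets[[nm]]),
      pc1_pct = ev[1],
      pc2_pct = if (length(ev) >= 2) ev[2] else NA_real_,
      k = sc$k,
      variance_explained_pct = sc$variance_explained_pct,
      aic = sc$aic
    )
  }) |> list_rbind()
  ord <- order(grid$aic, grid$k, grid$n_vars)
  chosen <- grid[ord[1], c("set", "k")]
  structure(
    list(grid = grid, chosen = chosen, pca = pcas, scans = scans,
         zmats = zmats, seed = seed),
    class = "ul_adjudication"
  )
}

#' Cluster assignments of the chosen (or any) grid model
#'
#' @param adj An `ul_adjudication`.
#' @param set,k Variable set name and cluster count (default: the chosen
#'   cell).
#' @return Tibble with `subject` and `cluster`.
#' @export
cluster_assignments <- function(adj, set = NULL, k = NULL) {
  stopifnot(inherits(adj, "ul_adjudication"))
  set <- set %||% adj$chosen$set
  k <- k %||% adj$chosen$k
  sc <- adj$scans[[set]]
  row <- which(sc$k == k)
  if (length(row) != 1) abort("requested k not in the adjudicated grid.")
  tibble(subject = adj$zmats[[set]]$subjects,
         cluster = sc$assignments[[row]])
}
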