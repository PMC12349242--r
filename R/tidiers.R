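#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy PCA loadings
#'
#' @param x An `ul_pca`.
#' @param ... Unused.
#' @return Long tibble: `variable`, `component`, `loading`.
#' @method tidy ul_pca
#' @export
tidy.ul_pca <- function(x, ...) {
  L <- x$loadings
  tibble(
    variable = rep(rownames(L), times = ncol(L)),
    component = rep(colnames(L), each = nrow(L)),
    loading = as.vector(L)
  )
}

#' One-row PCA summary
#'
#' @param x An `ul_pca`.
#' @param ... Unused.
#' @return Tibble with `n_components`, `pc1_pct`, `pc2_pct`,
#'   `pc12_cumulative_pct`, `sign_aligned`.
#' @method glance ul_pca
#' @export
glance.ul_pca <- function(x, ...) {
  ev <- x$explained_variance_pct
  tibble(
    n_components = length(ev),
    pc1_pct = ev[1],
    pc2_pct = if (length(ev) >= 2) ev[2] else NA_real_,
    pc12_cumulative_pct = sum(ev[seq_len(min(2, length(ev)))]),
    sign_aligned = x$sign_aligned
  )
}

#' Tidy a k-means scan
#'
#' @param x An `ul_kmeans_scan`.
#' @param ... Unused.
#' @return Tibble with one row per k: `k`, `wss`,
#'   `variance_explained_pct`, `silhouette`, `aic`.
#' @method tidy ul_kmeans_scan
#' @export
tidy.ul_kmeans_scan <- function(x, ...) {
  as_tibble(x[, c("k", "wss", "variance_explained_pct", "silhouette", "aic")])
}

#' Tidy an adjudication grid
#'
#' @param x An `ul_adjudication`.
#' @param ... Unused.
#' @return The full set-by-k grid tibble.
#' @method tidy ul_adjudication
#' @export
tidy.ul_adjudication <- function(x, ...) x$grid

#' One-row adjudication summary
#'
#' @param x An `ul_adjudication`.
#' @param ... Unused.
#' @return Tibble with the chosen set and k plus their fit statistics.
#' @method glance ul_adjudication
#' @export
glance.ul_adjudication <- function(x, ...) {
  ch <- x$chosen
  cell <- x$grid[x$grid$set == ch$set & x$grid$k == ch$k, ]
  tibble(
    chosen_set = ch$set, chosen_k = ch$k,
    variance_explained_pct = cell$variance_explained_pct,
    aic = cell$aic,
    pc1_pct = cell$pc1_pct, pc2_pct = cell$pc2_pct
  )
}

#' @export
print.ul_adjudication <- function(x, ...) {
  cat("Cluster-count adjudication over", length(unique(x$grid$set)),
      "variable sets and k in {", paste(sort(unique(x$grid$k)), collapse = ", "),
      "}\n")
  cat("Chosen by minimum AIC:", x$chosen$set, "set, k =", x$chosen$k, "\n\n")
  print(x$grid, n = nrow(x$grid))
  invisible(x)
}
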