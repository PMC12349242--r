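#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point facet_wrap
#'   labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Elbow and silhouette diagnostics of a k-means scan
#'
#' @param object An `ul_kmeans_scan`.
#' @param ... Unused.
#' @return A ggplot: WSS (elbow) and mean silhouette against k.
#' @method autoplot ul_kmeans_scan
#' @export
autoplot.ul_kmeans_scan <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("wss", "silhouette"), names_to = "statistic",
                        values_to = "value") |>
    filter(!is.na(.data$value))
  ggplot(d, aes(x = .data$k, y = .data$value)) +
    geom_line() + geom_point() +
    facet_wrap(~statistic, scales = "free_y") +
    labs(x = "Number of clusters k", y = NULL,
         title = "Cluster-count diagnostics") +
    theme_minimal()
}

#' AIC adjudication curves per variable set
#'
#' @param object An `ul_adjudication`.
#' @param ... Unused.
#' @return A ggplot of AIC against k, one line per variable set.
#' @method autoplot ul_adjudication
#' @export
autoplot.ul_adjudication <- function(object, ...) {
  ggplot(object$grid, aes(x = .data$k, y = .data$aic, colour = .data$set)) +
    geom_line() + geom_point() +
    labs(x = "Number of clusters k", y = "AIC",
         colour = "Variable set",
         title = "Model-fit adjudication (lower AIC is better)") +
    theme_minimal()
}

#' Cluster solution rendered in two-dimensional PC space
#'
#' @param adj An `ul_adjudication`.
#' @param set,k Grid cell to display (default: the chosen one).
#' @return A ggplot of subjects on PC1 (overall activity) vs PC2
#'   (preferred-limb use), colored by cluster.
#' @export
plot_pc_space <- function(adj, set = NULL, k = NULL) {
  stopifnot(inherits(adj, "ul_adjudication"))
  set <- set %||% adj$chosen$set
  k <- k %||% adj$chosen$k
  pca <- adj$pca[[set]]
  assign <- cluster_assignments(adj, set, k)
  d <- tibble(subject = rownames(pca$scores),
              PC1 = pca$scores[, 1], PC2 = pca$scores[, 2]) |>
    inner_join(assign, by = "subject")
  ggplot(d, aes(x = .data$PC1, y = .data$PC2,
                colour = factor(.data$cluster))) +
    geom_point(alpha = 0.7) +
    labs(colour = "Cluster",
         x = "PC1 (overall UL activity)",
         y = "PC2 (preferred-limb use)",
         title = sprintf("%s set, k = %d", set, k)) +
    theme_minimal()
}

#' Density plots of the performance variables by diagnosis
#'
#' @param features Feature tibble with a `diagnosis` column.
#' @param vars Variables to display (default the v12 set).
#' @return A ggplot of per-variable densities stratified by diagnosis.
#' @export
plot_feature_densities <- function(features, vars = variable_sets()$v12) {
  d <- features |>
    select("diagnosis", all_of(intersect(vars, names(features)))) |>
    tidyr::pivot_longer(-"diagnosis", names_to = "variable",
                        values_to = "value") |>
    filter(!is.na(.data$value))
  ggplot(d, aes(x = .data$value, colour = .data$diagnosis)) +
    ggplot2::geom_density() +
    facet_wrap(~variable, scales = "free") +
    labs(x = NULL, y = "Density", colour = "Diagnosis") +
    theme_minimal()
}
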