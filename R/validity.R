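# Convergent and divergent validity: R-squared of each self-report outcome
# regressed on cluster indicators, the two PC scores, or each single
# accelerometry variable.

#' R-squared of an ordinary least-squares regression
#'
#' Categorical predictors are expanded to indicator contrasts; the
#' significance flag comes from the overall F test. Complete cases only;
#' the n actually used is reported.
#'
#' @param data Data frame holding outcome and predictors.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names.
#' @return One-row tibble: `r_squared`, `adj_r_squared`, `p_value`, `n`.
#' @export
regress_r2 <- function(data, outcome, predictors) {
  keep <- complete.cases(data[, c(outcome, predictors)])
  d <- data[keep, , drop = FALSE]
  n <- nrow(d)
  if (n == 0 || var(d[[outcome]]) == 0) {
    return(tibble(r_squared = NA_real_, adj_r_squared = NA_real_,
                  p_value = NA_real_, n = n))
  }
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- lm(fml, data = d)
  s <- summary(fit)
  pval <- if (is.null(s$fstatistic)) NA_real_ else {
    unname(pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3], lower.tail = FALSE))
  }
  tibble(r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
         p_value = pval, n = n)
}

validity_outcomes <- function() {
  c("promis_ue", "mal_aou", "dash", "acs_global", "acs_iadl",
    "euroqol_selfcare", "euroqol_usual", "cesd")
}

#' Build the convergent/divergent validity table
#'
#' For every outcome, R² is computed against (1) the categorical cluster
#' assignment, (2) the first two PC scores, and (3) each accelerometry
#' variable singly. Instrument administration rules are honored through the
#' generator's NA masking (MAL-AoU present only for neurological subjects,
#' DASH only for musculoskeletal ones) via complete-case analysis per cell.
#' The CES-D column is the divergent-validity control. The per-cell
#' significance flag is an uncorrected F test at `alpha`.
#'
#' @param features Feature tibble (subject, self-report columns, the 12
#'   variables).
#' @param pca An `ul_pca` fitted on these subjects.
#' @param assignments Tibble with `subject` and `cluster` (e.g. from
#'   [cluster_assignments()]).
#' @param outcomes Outcome columns (default the eight instruments).
#' @param alpha Significance level for the per-cell F test.
#' @return Object of class `ul_validity`: long tibble with `predictor`,
#'   `outcome`, `r_squared`, `adj_r_squared`, `p_value`, `n`, `significant`.
#' @export
build_validity_table <- function(features, pca, assignments,
                                 outcomes = validity_outcomes(),
                                 alpha = 0.05) {
  outcomes <- intersect(outcomes, names(features))
  if (length(outcomes) == 0) abort("no outcome columns found in `features`.")
  scores <- tibble(subject = rownames(pca$scores),
                   PC1 = pca$scores[, 1],
                   PC2 = if (ncol(pca$scores) >= 2) pca$scores[, 2] else 0)
  d <- features |>
    inner_join(scores, by = "subject") |>
    inner_join(assignments, by = "subject") |>
    mutate(cluster = factor(.data$cluster))
  vars <- intersect(variable_sets()$v12, names(d))
  blocks <- c(list(clusters = "cluster", pcs = c("PC1", "PC2")),
              setNames(as.list(vars), vars))
  rows <- imap(blocks, function(preds, nm) {
    out <- lapply(outcomes, function(oc) {
      bind_cols(tibble(predictor = nm, outcome = oc),
                regress_r2(d, oc, preds))
    })
    list_rbind(out)
  }) |> list_rbind()
  rows$significant <- !is.na(rows$p_value) & rows$p_value < alpha
  class(rows) <- c("ul_validity", class(rows))
  rows
}

#' Reshape a validity table to the wide predictor-by-outcome layout
#'
#' @param validity An `ul_validity` long table.
#' @param value Which cell value to spread (default `r_squared`).
#' @return Wide tibble, one row per predictor block.
#' @export
validity_wide <- function(validity, value = "r_squared") {
  validity |>
    select("predictor", "outcome", all_of(value)) |>
    tidyr::pivot_wider(names_from = "outcome", values_from = all_of(value))
}
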