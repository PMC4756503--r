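#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reclassification result
#'
#' @param x A [reclassification_metrics()] result.
#' @param ... Unused.
#' @return Long tibble with `from`, `to`, `weight` and `prop` per cell of
#'   the 3x3 table.
#' @method tidy reclassification
#' @export
tidy.reclassification <- function(x, ...) {
  tab <- x$table
  tibble::tibble(
    from = factor(rep(rownames(tab), times = 3), levels = rownames(tab),
                  ordered = TRUE),
    to = factor(rep(colnames(tab), each = 3), levels = colnames(tab),
                ordered = TRUE),
    weight = as.numeric(tab),
    prop = as.numeric(tab) / x$total_weight
  )
}

#' @rdname tidy.reclassification
#' @method glance reclassification
#' @export
glance.reclassification <- function(x, ...) {
  tibble::tibble(
    percent_reclassified = x$percent_reclassified,
    collapsed_reclassified = x$collapsed_reclassified,
    downward_from_high = x$downward_from_high,
    total_weight = x$total_weight
  )
}

#' Tidy an exact genetic-value distribution
#'
#' @param x A [exact_distribution()] result.
#' @param ... Unused.
#' @return The `values` tibble (`odds`, `norm_odds`, `control_prob`,
#'   `case_prob`).
#' @method tidy genetic_value_dist
#' @export
tidy.genetic_value_dist <- function(x, ...) x$values

#' @rdname tidy.genetic_value_dist
#' @method glance genetic_value_dist
#' @export
glance.genetic_value_dist <- function(x, ...) {
  tibble::tibble(
    n_snps = x$n_snps,
    n_values = nrow(x$values),
    mean_raw_odds = x$mean_raw_odds,
    mu_case = x$moments$mu_case,
    sd_case = x$moments$sd_case,
    mu_control = x$moments$mu_control,
    sd_control = x$moments$sd_control,
    auc_binormal = analytic_auc(x)$auc
  )
}

#' Tidy a binormal AUC
#'
#' @param x An [analytic_auc()] result.
#' @param ... Unused.
#' @return One-row tibble with `auc`, `a`, `b` and the four moments.
#' @method tidy binormal_auc
#' @export
tidy.binormal_auc <- function(x, ...) {
  tibble::tibble(auc = x$auc, a = x$a, b = x$b,
                 mu_case = x$moments[["mu_case"]],
                 sd_case = x$moments[["sd_case"]],
                 mu_control = x$moments[["mu_control"]],
                 sd_control = x$moments[["sd_control"]])
}

#' Tidy a drift timeline
#'
#' @param x A [drift_timeline()] result.
#' @param ... Unused.
#' @return The per-time-point summary tibble (`by_time`).
#' @method tidy drift_timeline
#' @export
tidy.drift_timeline <- function(x, ...) x$by_time

#' @rdname tidy.drift_timeline
#' @method glance drift_timeline
#' @export
glance.drift_timeline <- function(x, ...) {
  last <- x$between[nrow(x$between), ]
  tibble::tibble(
    n = x$n,
    n_time_points = nrow(x$by_time),
    final_n_snps = x$by_time$n_snps[nrow(x$by_time)],
    final_prop_higher = x$by_time$prop_higher[nrow(x$by_time)],
    final_auc = x$by_time$auc_empirical[nrow(x$by_time)],
    overall_reclassified = last$percent_reclassified,
    overall_nri = last$nri
  )
}
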