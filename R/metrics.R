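#' Reclassification between two risk classifications
#'
#' Cross-tabulates risk tiers at two time points (or under two panels)
#' and summarises movement: the share of (weighted) individuals on the
#' off-diagonal of the 3x3 table, the share reclassified when tiers are
#' collapsed to Higher vs not-Higher, and — among those Higher at the
#' first time point — the share moving down to Average or Lower at the
#' second. The downward share is `NA` when nobody is Higher at the first
#' time point (the comparison is undefined, not zero).
#'
#' @param cat_t1,cat_t2 Equal-length category vectors from
#'   [classify_risk()] (ordered Lower < Average < Higher).
#' @param weights Optional non-negative per-individual weights
#'   (default 1). Probability masses from [enumerate_panel_pair()] give
#'   exact population results.
#' @return A `reclassification` object: `table` (3x3 weighted counts,
#'   rows = first classification), `percent_reclassified`,
#'   `collapsed_reclassified`, `downward_from_high`, `total_weight`.
#' @export
reclassification_metrics <- function(cat_t1, cat_t2, weights = NULL) {
  if (length(cat_t1) != length(cat_t2)) {
    rlang::abort("category vectors must have equal length")
  }
  lev <- c("Lower", "Average", "Higher")
  c1 <- factor(cat_t1, levels = lev, ordered = TRUE)
  c2 <- factor(cat_t2, levels = lev, ordered = TRUE)
  if (is.null(weights)) weights <- rep(1, length(c1))
  if (length(weights) != length(c1) || any(weights < 0)) {
    rlang::abort("weights must be non-negative and match the data length")
  }
  tot <- sum(weights)
  if (tot <= 0) rlang::abort("total weight must be positive")

  tab <- matrix(0, 3, 3, dimnames = list(from = lev, to = lev))
  agg <- stats::aggregate(weights,
                          by = list(from = c1, to = c2), FUN = sum)
  tab[cbind(as.character(agg$from), as.character(agg$to))] <- agg$x

  off <- sum(tab) - sum(diag(tab))
  high1 <- c1 == "Higher"
  w_high <- sum(weights[high1])
  downward <- if (w_high > 0) {
    sum(weights[high1 & c2 != "Higher"]) / w_high
  } else {
    NA_real_
  }
  collapsed <- sum(weights[(c1 == "Higher") != (c2 == "Higher")]) / tot

  structure(
    list(
      table = tab,
      percent_reclassified = off / tot,
      collapsed_reclassified = collapsed,
      downward_from_high = downward,
      total_weight = tot
    ),
    class = "reclassification"
  )
}

#' @export
print.reclassification <- function(x, ...) {
  cat("<reclassification>\n")
  print(round(x$table / x$total_weight, 4))
  cat(sprintf("  reclassified: %.3f (collapsed Higher/not: %.3f)\n",
              x$percent_reclassified, x$collapsed_reclassified))
  if (is.na(x$downward_from_high)) {
    cat("  downward from Higher: undefined (none Higher at t1)\n")
  } else {
    cat(sprintf("  downward from Higher: %.3f\n", x$downward_from_high))
  }
  invisible(x)
}

#' Net reclassification index
#'
#' `NRI = (P_case_up - P_case_down) + (P_ctrl_down - P_ctrl_up)`, where
#' up/down means any move in the ordered tiers Lower < Average < Higher
#' (a two-step move counts once). Cases and controls are the same
#' individuals weighted differently: under the rare-disease cohort path,
#' case weights are proportional to the normalized odds at the earlier
#' panel and control weights are uniform.
#'
#' @inheritParams reclassification_metrics
#' @param case_weights,control_weights Non-negative weight vectors, each
#'   with positive total.
#' @return The NRI (in \[-2, 2\]).
#' @export
nri <- function(cat_t1, cat_t2, case_weights, control_weights) {
  if (length(cat_t1) != length(cat_t2)) {
    rlang::abort("category vectors must have equal length")
  }
  lev <- c("Lower", "Average", "Higher")
  r1 <- as.integer(factor(cat_t1, levels = lev, ordered = TRUE))
  r2 <- as.integer(factor(cat_t2, levels = lev, ordered = TRUE))
  up <- r2 > r1
  down <- r2 < r1
  pr <- function(w, sel) {
    if (any(w < 0) || length(w) != length(r1)) {
      rlang::abort("weights must be non-negative and match the data length")
    }
    tot <- sum(w)
    if (tot <= 0) rlang::abort("weights must have positive total")
    sum(w[sel]) / tot
  }
  (pr(case_weights, up) - pr(case_weights, down)) +
    (pr(control_weights, down) - pr(control_weights, up))
}

#' Summary of absolute changes in adjusted odds
#'
#' Reports the proportion of individuals whose normalized odds changed by
#' at most `thresholds[1]` and by more than `thresholds[2]` between two
#' panels (the two proportions need not sum to 1).
#'
#' @param o_t1,o_t2 Equal-length normalized odds vectors.
#' @param thresholds Small/large change cutoffs, default `c(0.2, 0.5)`.
#' @return One-row tibble with `prop_small_change` and
#'   `prop_large_change`.
#' @export
odds_change_summary <- function(o_t1, o_t2, thresholds = c(0.2, 0.5)) {
  if (length(o_t1) != length(o_t2)) {
    rlang::abort("odds vectors must have equal length")
  }
  d <- abs(o_t2 - o_t1)
  tibble::tibble(
    prop_small_change = mean(d <= thresholds[1]),
    prop_large_change = mean(d > thresholds[2])
  )
}

#' Binormal AUC from log-odds moments
#'
#' Closed-form area under the ROC curve assuming normal log-score
#' distributions in cases and controls:
#' `AUC = Phi(a / sqrt(1 + b^2))` with `a = (mu_D - mu_Dbar) / sigma_D`
#' and `b = sigma_Dbar / sigma_D` (D = cases, Dbar = controls). Exact
#' when both log-score distributions are normal; an approximation
#' otherwise.
#'
#' @param x Either the case mean `mu_case` (with the remaining moments in
#'   the following arguments), or a [exact_distribution()] object whose
#'   stored log-odds moments are used.
#' @param sd_case,mu_control,sd_control Remaining moments (default
#'   method). `sd_case` must be positive unless the two means coincide.
#' @param ... Passed between methods.
#' @return A `binormal_auc` object with fields `auc`, `a`, `b` and the
#'   input moments.
#' @export
analytic_auc <- function(x, ...) UseMethod("analytic_auc")

#' @rdname analytic_auc
#' @export
analytic_auc.genetic_value_dist <- function(x, ...) {
  m <- x$moments
  analytic_auc(m$mu_case, m$sd_case, m$mu_control, m$sd_control)
}

#' @rdname analytic_auc
#' @export
analytic_auc.default <- function(x, sd_case, mu_control, sd_control, ...) {
  mu_case <- x
  if (sd_control < 0) rlang::abort("sd_control must be non-negative")
  if (sd_case <= 0) {
    if (isTRUE(all.equal(mu_case, mu_control)) && sd_control == 0) {
      a <- 0; b <- 0
    } else {
      rlang::abort("degenerate case distribution: sd_case = 0 with distinct means")
    }
  } else {
    a <- (mu_case - mu_control) / sd_case
    b <- sd_control / sd_case
  }
  structure(
    list(
      auc = stats::pnorm(a / sqrt(1 + b^2)),
      a = a, b = b,
      moments = c(mu_case = mu_case, sd_case = sd_case,
                  mu_control = mu_control, sd_control = sd_control)
    ),
    class = "binormal_auc"
  )
}

#' @export
print.binormal_auc <- function(x, ...) {
  cat(sprintf("<binormal_auc> AUC = %.4f (a = %.4f, b = %.4f)\n",
              x$auc, x$a, x$b))
  invisible(x)
}

#' Empirical (weighted Mann-Whitney) AUC
#'
#' Probability that a randomly drawn case outscores a randomly drawn
#' control, with ties counted one half. Cases and controls may be the
#' same individuals carrying different weights (e.g. case weights
#' proportional to normalized odds under the rare-disease
#' approximation), or probability masses from an exact enumeration.
#'
#' @param scores Numeric score vector.
#' @param case_weights,control_weights Non-negative weights with positive
#'   totals.
#' @return The AUC in \[0, 1\].
#' @export
empirical_auc <- function(scores, case_weights, control_weights) {
  n <- length(scores)
  if (length(case_weights) != n || length(control_weights) != n) {
    rlang::abort("weights must match the score length")
  }
  if (any(case_weights < 0) || any(control_weights < 0)) {
    rlang::abort("weights must be non-negative")
  }
  wc <- sum(case_weights); wn <- sum(control_weights)
  if (wc <= 0 || wn <= 0) {
    rlang::abort("both groups need positive total weight")
  }
  ord <- order(scores)
  s <- scores[ord]
  cw <- case_weights[ord]
  nw <- control_weights[ord]
  grp <- cumsum(c(TRUE, s[-1] != s[-n]))
  cw_g <- as.numeric(rowsum(cw, grp))
  nw_g <- as.numeric(rowsum(nw, grp))
  below <- cumsum(nw_g) - nw_g
  sum(cw_g * (below + 0.5 * nw_g)) / (wc * wn)
}
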