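#' Run the full risk-drift timeline on one simulated cohort
#'
#' End-to-end convenience: builds cumulative panels from a catalog at the
#' given time points, simulates genotypes *once* for the union of all
#' panel SNPs (so between-panel reclassification reflects panel change,
#' not genotype resampling), scores every panel on that cohort, and
#' summarises per-panel risk distributions and between-panel
#' reclassification.
#'
#' @param catalog Catalog tibble ([as_catalog()], [simulate_discovery()]).
#' @param time_points Panel dates (strictly increasing).
#' @param n Cohort size, default 100,000.
#' @param seed Genotype simulation seed.
#' @param ld,r2_max,window_bp Passed to [build_panels()].
#' @param hap_models Haplotype models for multi-SNP loci.
#' @inheritParams classify_risk
#' @param comparisons Which panel pairs to compare: `"consecutive"`
#'   (default, plus first-vs-last) or a two-column matrix of time-point
#'   indices.
#' @param nri_weights Which panel's normalized odds define the
#'   rare-disease case weights in the NRI: `"earlier"` (default) or
#'   `"later"`. With earlier-panel weights the NRI measures how the later
#'   model re-ranks the individuals the earlier model called high-risk
#'   (typically negative as provisional high-risk calls are demoted);
#'   later-panel weights treat the better model as the closer proxy for
#'   true case status and typically give the positive
#'   "model improvement" sign.
#' @return A `drift_timeline` list:
#'   * `panels` — the [build_panels()] tibble;
#'   * `by_time` — per time point: `n_snps`, tier proportions,
#'     log-odds moments, empirical and binormal AUC;
#'   * `between` — per compared pair: percent reclassified, collapsed
#'     and downward-from-Higher shares, NRI, odds-change proportions;
#'   * `scores` — matrix of normalized odds (individuals x time points).
#' @export
drift_timeline <- function(catalog, time_points, n = 100000, seed = 1,
                           ld = NULL, r2_max = 0.75, window_bp = 500000,
                           hap_models = NULL, lo = 0.5, hi = 2,
                           comparisons = "consecutive",
                           nri_weights = c("earlier", "later")) {
  nri_weights <- match.arg(nri_weights)
  time_points <- as.Date(time_points)
  panels <- build_panels(catalog, time_points, ld = ld, r2_max = r2_max,
                         window_bp = window_bp)
  # locus labels are per-panel; re-derive them on the union so genotype
  # simulation sees each physical locus once
  union_snps <- panels |>
    dplyr::distinct(.data$rsid, .keep_all = TRUE) |>
    dplyr::select(-dplyr::any_of(c("locus_id", "time_point"))) |>
    assign_loci(window_bp = window_bp)
  if (nrow(union_snps) == 0) {
    rlang::abort("no SNPs in any panel; nothing to simulate")
  }
  geno <- simulate_genotypes(union_snps, n = n, seed = seed,
                             hap_models = hap_models)

  O <- matrix(NA_real_, nrow = n, ncol = length(time_points),
              dimnames = list(NULL, format(time_points, "%Y")))
  by_time <- purrr::imap(time_points, function(m, i) {
    pm <- dplyr::filter(panels, .data$time_point == m)
    o <- if (nrow(pm) == 0) rep(1, n) else normalize_odds(raw_odds(geno, pm))
    O[, i] <<- o
    cat_m <- classify_risk(o, lo, hi)
    logo <- log(o)
    w <- o / sum(o)
    mu_case <- sum(w * logo)
    sd_case <- sqrt(max(sum(w * logo^2) - mu_case^2, 0))
    mu_ctrl <- mean(logo)
    sd_ctrl <- stats::sd(logo)
    auc_emp <- if (sd_ctrl == 0) 0.5 else {
      empirical_auc(o, case_weights = o, control_weights = rep(1, n))
    }
    auc_bin <- if (sd_case == 0 && sd_ctrl == 0) 0.5 else {
      analytic_auc(mu_case, sd_case, mu_ctrl, sd_ctrl)$auc
    }
    tibble::tibble(
      time_point = m, n_snps = nrow(pm),
      prop_lower = mean(cat_m == "Lower"),
      prop_average = mean(cat_m == "Average"),
      prop_higher = mean(cat_m == "Higher"),
      mu_case = mu_case, sd_case = sd_case,
      mu_control = mu_ctrl, sd_control = sd_ctrl,
      auc_empirical = auc_emp, auc_binormal = auc_bin
    )
  }) |> dplyr::bind_rows()

  if (identical(comparisons, "consecutive")) {
    k <- length(time_points)
    pairs <- cbind(seq_len(k - 1), seq_len(k - 1) + 1L)
    if (k > 2) pairs <- rbind(pairs, c(1L, k))
  } else {
    pairs <- comparisons
  }
  between <- apply(pairs, 1, function(ij) {
    i <- ij[1]; j <- ij[2]
    o1 <- O[, i]; o2 <- O[, j]
    c1 <- classify_risk(o1, lo, hi)
    c2 <- classify_risk(o2, lo, hi)
    rec <- reclassification_metrics(c1, c2)
    chg <- odds_change_summary(o1, o2)
    tibble::tibble(
      from = time_points[i], to = time_points[j],
      percent_reclassified = rec$percent_reclassified,
      collapsed_reclassified = rec$collapsed_reclassified,
      downward_from_high = rec$downward_from_high,
      nri = nri(c1, c2,
                case_weights = if (nri_weights == "earlier") o1 else o2,
                control_weights = rep(1, n)),
      prop_small_change = chg$prop_small_change,
      prop_large_change = chg$prop_large_change
    )
  }) |> dplyr::bind_rows()

  structure(
    list(panels = panels, by_time = by_time, between = between,
         scores = O, n = n, seed = seed),
    class = "drift_timeline"
  )
}

#' @export
print.drift_timeline <- function(x, ...) {
  cat("<drift_timeline> cohort n =", x$n, "\n")
  print(dplyr::select(x$by_time, "time_point", "n_snps", "prop_higher",
                      "auc_empirical"))
  print(dplyr::select(x$between, "from", "to", "percent_reclassified", "nri"))
  invisible(x)
}
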