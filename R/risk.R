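#' Multiplicative genetic odds for a cohort
#'
#' Per-individual odds under the multiplicative model
#' `Odds_i = prod_j OR_j ^ g_ij`, accumulated in log space
#' (`exp(sum_j g_ij * log OR_j)`) so that panels with hundreds of SNPs do
#' not overflow.
#'
#' @param genotypes Genotype matrix from [simulate_genotypes()] (columns
#'   named by rsid).
#' @param panel Panel tibble with `rsid` and `or` columns; every panel
#'   SNP must be a genotype column.
#' @return Numeric vector of raw odds, one per individual (all positive;
#'   1 for an all-zero genotype row or an empty panel).
#' @export
raw_odds <- function(genotypes, panel) {
  if (nrow(panel) == 0) return(rep(1, nrow(genotypes)))
  missing_snps <- setdiff(panel$rsid, colnames(genotypes))
  if (length(missing_snps) > 0) {
    rlang::abort(paste0("panel SNP(s) absent from genotype matrix: ",
                        paste(missing_snps, collapse = ", ")))
  }
  lo <- genotypes[, panel$rsid, drop = FALSE] %*% log(panel$or)
  exp(as.numeric(lo))
}

#' Normalize odds by the population mean
#'
#' Divides each individual's odds by the cohort arithmetic mean, so the
#' result is the odds relative to the population average (mean exactly 1).
#'
#' @param odds Positive odds vector.
#' @return Normalized odds with `mean(out) == 1`.
#' @export
normalize_odds <- function(odds) {
  if (length(odds) == 0) rlang::abort("empty odds vector")
  if (any(odds <= 0 | !is.finite(odds))) {
    rlang::abort("odds must be positive and finite")
  }
  odds / mean(odds)
}

#' Three-tier risk classification
#'
#' Classifies normalized odds into ordered tiers: Lower (`O < lo`),
#' Average (`lo <= O <= hi`, boundaries inclusive) and Higher (`O > hi`).
#'
#' @param o Normalized odds vector.
#' @param lo,hi Tier thresholds, `0 < lo < hi`. Defaults 0.5 and 2, a
#'   conventional benchmark for potentially actionable genetic risk.
#' @return Ordered factor with levels Lower < Average < Higher.
#' @export
classify_risk <- function(o, lo = 0.5, hi = 2) {
  if (!(lo > 0 && lo < hi)) rlang::abort("need 0 < lo < hi")
  out <- ifelse(o < lo, "Lower", ifelse(o > hi, "Higher", "Average"))
  factor(out, levels = c("Lower", "Average", "Higher"), ordered = TRUE)
}

#' Score a cohort against a panel
#'
#' Convenience wrapper chaining [raw_odds()], [normalize_odds()] and
#' [classify_risk()] into a tidy per-individual table.
#'
#' @inheritParams raw_odds
#' @inheritParams classify_risk
#' @return A tibble with columns `individual`, `raw_odds`,
#'   `normalized_odds`, `risk_category`.
#' @export
score_cohort <- function(genotypes, panel, lo = 0.5, hi = 2) {
  odds <- raw_odds(genotypes, panel)
  o <- normalize_odds(odds)
  tibble::tibble(
    individual = seq_len(nrow(genotypes)),
    raw_odds = odds,
    normalized_odds = o,
    risk_category = classify_risk(o, lo, hi)
  )
}

# ---- exact enumeration ------------------------------------------------

# Distribution of one locus's contribution(s) to log odds.
# logor: list of named vectors (one per panel), rsid -> log OR (0 if the
# SNP is absent from that panel). Returns tibble(prob, lo1[, lo2, ...]).
locus_logodds_dist <- function(members, raf, logor, hap_model = NULL) {
  k <- length(logor)
  if (length(members) == 1 && is.null(hap_model)) {
    q <- raf[1]
    if (is.na(q) || q <= 0 || q >= 1) {
      rlang::abort(paste0("allele frequency outside (0, 1) for ", members))
    }
    g <- 0:2
    prob <- stats::dbinom(g, 2, q)
    contrib <- vapply(seq_len(k), function(p) {
      g * lookup0(logor[[p]], members[1])
    }, numeric(3))
  } else {
    if (is.null(hap_model)) {
      rlang::abort("multi-SNP locus requires a haplotype model for enumeration")
    }
    H <- hap_model$haplotypes
    ord <- if (!is.null(hap_model$snps)) match(members, hap_model$snps)
           else seq_along(members)
    if (anyNA(ord)) rlang::abort("haplotype model SNPs do not match locus")
    f <- hap_model$frequencies
    nh <- nrow(H)
    i1 <- rep(seq_len(nh), each = nh)
    i2 <- rep(seq_len(nh), times = nh)
    prob <- f[i1] * f[i2]
    Gd <- H[i1, ord, drop = FALSE] + H[i2, ord, drop = FALSE]
    contrib <- vapply(seq_len(k), function(p) {
      as.numeric(Gd %*% lookup0(logor[[p]], members))
    }, numeric(length(prob)))
    contrib <- matrix(contrib, ncol = k)
  }
  out <- tibble::as_tibble(as.data.frame(contrib))
  names(out) <- paste0("lo", seq_len(k))
  out$prob <- prob
  collapse_logodds(out)
}

# aggregate identical log-odds tuples (keyed on rounded values to absorb
# floating noise from different summation orders)
collapse_logodds <- function(d) {
  locols <- grep("^lo", names(d), value = TRUE)
  key <- do.call(paste, c(lapply(d[locols], function(x) sprintf("%.10f", x)),
                          sep = "|"))
  d |>
    dplyr::mutate(.key = key) |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(locols), dplyr::first),
                     prob = sum(.data$prob), .groups = "drop") |>
    dplyr::select(-".key") |>
    dplyr::filter(.data$prob > 0)
}

# convolve independent locus distributions, capping the enumerated space
convolve_loci <- function(dists, cap = 1e6) {
  purrr::reduce(dists, function(acc, nxt) {
    if (nrow(acc) * nrow(nxt) > cap) {
      rlang::abort(paste0(
        "enumerated genotype space exceeds cap (", format(cap, scientific = FALSE),
        "); use the Monte-Carlo cohort path instead"))
    }
    ia <- rep(seq_len(nrow(acc)), times = nrow(nxt))
    ib <- rep(seq_len(nrow(nxt)), each = nrow(acc))
    locols <- grep("^lo", names(acc), value = TRUE)
    out <- acc[ia, locols, drop = FALSE] + nxt[ib, locols, drop = FALSE]
    out$prob <- acc$prob[ia] * nxt$prob[ib]
    collapse_logodds(tibble::as_tibble(out))
  })
}

# shared front-end: enumerate the joint distribution of per-panel log odds
enumerate_panels <- function(panels, hap_models = NULL, cap = 1e6) {
  union_snps <- dplyr::bind_rows(panels) |>
    dplyr::distinct(.data$rsid, .keep_all = TRUE)
  if (!"locus_id" %in% names(union_snps) || anyNA(union_snps$locus_id)) {
    union_snps$locus_id <- union_snps$rsid
  }
  logor <- lapply(panels, function(p) {
    stats::setNames(log(p$or), p$rsid)
  })
  dists <- unique(union_snps$locus_id) |>
    lapply(function(lid) {
      rows <- union_snps[union_snps$locus_id == lid, , drop = FALSE]
      if ("pos" %in% names(rows)) {
        rows <- rows[order(rows$pos, rows$rsid), , drop = FALSE]
      }
      locus_logodds_dist(rows$rsid, rows$raf, logor,
                         hap_model = hap_models[[lid]])
    })
  convolve_loci(dists, cap = cap)
}

#' Exact genetic-value distribution for a panel
#'
#' Enumerates the population distribution of multiplicative genetic odds
#' for a panel without simulation: per-locus genotype distributions
#' (Hardy-Weinberg from the allele frequency, or diplotype probabilities
#' from a haplotype model) are collapsed to their distinct log-odds
#' values and convolved across independent loci. Odds are normalized by
#' the *exact* population mean (so results are seed-free), the control
#' probability mass is the genotype probability, and the case mass is
#' proportional to `O_g * Pr(g)` (rare-disease weighting). Log-odds
#' moments for both populations are retained for the binormal AUC.
#'
#' @param panel Panel tibble (`rsid`, `raf`, `or`, optional `locus_id`,
#'   `pos`).
#' @param hap_models Named list of [haplotype_model()] objects keyed by
#'   `locus_id`, for multi-SNP loci.
#' @param cap Maximum enumerated combinations before erroring with a
#'   pointer to the Monte-Carlo path. Default 1e6.
#' @return A `genetic_value_dist` object: `values` (tibble with
#'   `odds`, `norm_odds`, `control_prob`, `case_prob`), `mean_raw_odds`,
#'   and `moments` (`mu_case`, `sd_case`, `mu_control`, `sd_control`, on
#'   the log normalized-odds scale).
#' @examples
#' p <- tibble::tibble(rsid = "rs1", raf = 0.3, or = 2)
#' d <- exact_distribution(p)
#' d$values
#' @export
exact_distribution <- function(panel, hap_models = NULL, cap = 1e6) {
  if (nrow(panel) == 0) {
    joint <- tibble::tibble(lo1 = 0, prob = 1)
  } else {
    joint <- enumerate_panels(list(panel), hap_models = hap_models, cap = cap)
  }
  odds <- exp(joint$lo1)
  p <- joint$prob
  mean_odds <- sum(p * odds)
  o <- odds / mean_odds
  case_p <- o * p            # sums to 1 by construction
  logo <- log(o)
  mom <- list(
    mu_case = sum(case_p * logo),
    sd_case = sqrt(sum(case_p * logo^2) - sum(case_p * logo)^2),
    mu_control = sum(p * logo),
    sd_control = sqrt(sum(p * logo^2) - sum(p * logo)^2)
  )
  ord <- order(o)
  structure(
    list(
      values = tibble::tibble(
        odds = odds[ord], norm_odds = o[ord],
        control_prob = p[ord], case_prob = case_p[ord]
      ),
      mean_raw_odds = mean_odds,
      moments = mom,
      n_snps = nrow(panel)
    ),
    class = "genetic_value_dist"
  )
}

#' @export
print.genetic_value_dist <- function(x, ...) {
  cat("<genetic_value_dist> ", x$n_snps, " SNP(s), ",
      nrow(x$values), " distinct odds value(s)\n", sep = "")
  cat(sprintf("  log-odds moments: controls N(%.4f, %.4f), cases N(%.4f, %.4f)\n",
              x$moments$mu_control, x$moments$sd_control,
              x$moments$mu_case, x$moments$sd_case))
  invisible(x)
}

#' Joint exact distribution of odds under two panels
#'
#' Enumerates the joint population distribution of normalized odds under
#' two panels over the same genotypes (the union of their SNPs), each
#' panel normalized by its own exact mean. This is the seed-free route to
#' exact reclassification, NRI and AUC between two panels: feed the
#' returned probabilities as weights to [reclassification_metrics()],
#' [nri()] or [empirical_auc()].
#'
#' @param panel_a,panel_b Panel tibbles sharing genotype parameters for
#'   common SNPs (ORs may differ, e.g. after an OR update).
#' @inheritParams exact_distribution
#' @return A tibble with columns `prob` (genotype-class probability),
#'   `odds_a`, `odds_b` (normalized odds under each panel).
#' @export
enumerate_panel_pair <- function(panel_a, panel_b, hap_models = NULL,
                                 cap = 1e6) {
  joint <- enumerate_panels(list(panel_a, panel_b),
                            hap_models = hap_models, cap = cap)
  oa <- exp(joint$lo1); ob <- exp(joint$lo2)
  tibble::tibble(
    prob = joint$prob,
    odds_a = oa / sum(joint$prob * oa),
    odds_b = ob / sum(joint$prob * ob)
  )
}

#' Control distribution at an explicit disease incidence
#'
#' The base enumeration treats the whole population as controls
#' (rare-disease approximation). For a disease of incidence `K`, with
#' `Pr(D | g) = c * O_g` and marginal incidence `K`, the control mass
#' becomes `Pr(g | not D) = (1 - c O_g) Pr(g) / (1 - K)`. Since the
#' normalized odds satisfy `sum O_g Pr(g) = 1`, the scaling constant is
#' `c = K`; feasibility requires `c * max(O_g) <= 1`.
#'
#' @param dist A [exact_distribution()] result.
#' @param incidence Disease incidence `K` in \[0, 0.10\] (guarded range;
#'   `K = 0` returns `dist` unchanged).
#' @return A `genetic_value_dist` with control probabilities and control
#'   moments replaced; the case distribution is unchanged.
#' @export
control_dist_at_incidence <- function(dist, incidence) {
  if (incidence < 0 || incidence > 0.10) {
    rlang::abort("incidence must lie in [0, 0.10]")
  }
  if (incidence == 0) return(dist)
  v <- dist$values
  cc <- incidence  # c = K / sum(O_g Pr(g)) and the denominator is 1
  if (cc * max(v$norm_odds) > 1) {
    rlang::abort(paste0(
      "infeasible incidence: c * max(O_g) = ",
      signif(cc * max(v$norm_odds), 4),
      " exceeds 1; Pr(D|g) = c*O_g cannot be a probability"))
  }
  ctrl <- (1 - cc * v$norm_odds) * v$control_prob
  ctrl <- ctrl / sum(ctrl)
  logo <- log(v$norm_odds)
  out <- dist
  out$values$control_prob <- ctrl
  out$moments$mu_control <- sum(ctrl * logo)
  out$moments$sd_control <- sqrt(sum(ctrl * logo^2) - sum(ctrl * logo)^2)
  out$incidence <- incidence
  out
}

#' Risk-tier proportions of an exact distribution
#'
#' @param dist A [exact_distribution()] result.
#' @param lo,hi Tier thresholds (see [classify_risk()]).
#' @param population `"control"` or `"case"` mass.
#' @return A tibble with `risk_category` and `prop`.
#' @export
risk_category_props <- function(dist, lo = 0.5, hi = 2,
                                population = c("control", "case")) {
  population <- match.arg(population)
  w <- if (population == "control") dist$values$control_prob
       else dist$values$case_prob
  cat <- classify_risk(dist$values$norm_odds, lo, hi)
  tibble::tibble(risk_category = factor(levels(cat), levels = levels(cat),
                                        ordered = TRUE)) |>
    dplyr::left_join(
      tibble::tibble(risk_category = cat, w = w) |>
        dplyr::group_by(.data$risk_category) |>
        dplyr::summarise(prop = sum(.data$w), .groups = "drop"),
      by = "risk_category"
    ) |>
    dplyr::mutate(prop = dplyr::coalesce(.data$prop, 0))
}
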