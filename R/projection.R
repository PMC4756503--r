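#' GWAS study design
#'
#' Bundle of the design quantities entering power calculations: case and
#' control counts, the significance level, and the sample-size multiplier
#' applied when constructing a hypothetical future study.
#'
#' @param n_cases,n_controls Positive integer sample sizes.
#' @param alpha Significance level, default the genome-wide `5e-8`.
#' @param multiplier Future-study sample-size multiplier (>= 1), default 2.
#' @return A `study_design` list.
#' @export
study_design <- function(n_cases, n_controls, alpha = 5e-8, multiplier = 2) {
  if (n_cases < 1 || n_controls < 1) rlang::abort("sample sizes must be positive")
  if (alpha <= 0 || alpha >= 1) rlang::abort("alpha must lie in (0, 1)")
  if (multiplier < 1) rlang::abort("multiplier must be at least 1")
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 alpha = alpha, multiplier = multiplier),
            class = "study_design")
}

#' Park effect size of a SNP
#'
#' `e = beta^2 * 2 q (1 - q)`: the per-SNP contribution to the variance
#' of the log genetic odds, used to group SNPs into effect-size bins.
#' Symmetric in `q` and `1 - q`.
#'
#' @param beta Per-allele log odds ratio.
#' @param q Allele frequency in (0, 1).
#' @return The effect size (>= 0). Vectorised.
#' @export
effect_size <- function(beta, q) {
  if (any(q <= 0 | q >= 1)) rlang::abort("q must lie in (0, 1)")
  beta^2 * 2 * q * (1 - q)
}

#' Power to detect a SNP at genome-wide significance
#'
#' Two-sided power of the per-allele (1-df trend) test under the normal
#' approximation. The standard error of the log OR estimate is
#' `SE = sqrt((1 / (2 q (1 - q))) * (1/n_cases + 1/n_controls))` and
#' `power = Phi(|beta|/SE - z) + Phi(-|beta|/SE - z)` with
#' `z = qnorm(1 - alpha/2)`. Monotone increasing in `|beta|`,
#' `q(1 - q)` and sample size; equals `alpha` at `beta = 0`.
#'
#' @inheritParams effect_size
#' @param design A [study_design()].
#' @return Detection power in (0, 1\]. Vectorised over `beta`, `q`.
#' @export
detection_power <- function(beta, q, design) {
  if (any(q <= 0 | q >= 1)) rlang::abort("q must lie in (0, 1)")
  se <- sqrt((1 / (2 * q * (1 - q))) *
               (1 / design$n_cases + 1 / design$n_controls))
  z <- stats::qnorm(design$alpha / 2, lower.tail = FALSE)
  stats::pnorm(abs(beta) / se - z) + stats::pnorm(-abs(beta) / se - z)
}

#' Estimated total numbers of susceptibility SNPs by effect bin
#'
#' The bin method for the total number of detectable susceptibility
#' SNPs: each observed SNP is inflated by the reciprocal of the power to
#' have detected it under the reference design, `M_T,j = M_j / p_j`, and
#' `M_total = sum_j M_T,j`. By default every observed SNP is its own bin
#' (`M_j = 1`); `breaks` optionally groups SNPs into histogram bins on
#' the effect size `e`, using bin-mean `beta` and `q` for power.
#'
#' @param panel Panel tibble with `rsid`, `or` and `raf` columns.
#' @param design The reference [study_design()] (the largest study at the
#'   panel's time point).
#' @param breaks Optional numeric breaks on `e` for histogram binning.
#' @return An `effect_bins` tibble (one row per bin: `bin`, `beta`, `q`,
#'   `e`, `m_obs`, `power`, `m_total`) with attributes `M_total` and
#'   `design`.
#' @export
bin_totals <- function(panel, design, breaks = NULL) {
  beta <- log(panel$or)
  q <- panel$raf
  e <- effect_size(beta, q)
  if (is.null(breaks)) {
    bins <- tibble::tibble(
      bin = panel$rsid, beta = beta, q = q, e = e, m_obs = 1
    )
  } else {
    grp <- cut(e, breaks = breaks, include.lowest = TRUE)
    bins <- tibble::tibble(beta = beta, q = q, e = e, bin = as.character(grp)) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(beta = mean(.data$beta), q = mean(.data$q),
                       e = mean(.data$e), m_obs = dplyr::n(),
                       .groups = "drop")
  }
  bins$power <- detection_power(bins$beta, bins$q, design)
  if (any(bins$power < 1e-12)) {
    rlang::abort(paste0(
      "detection power numerically zero for bin(s) ",
      paste(bins$bin[bins$power < 1e-12], collapse = ", "),
      ": such SNPs could not have been observed under the stated design"))
  }
  bins$m_total <- bins$m_obs / bins$power
  out <- bins[, c("bin", "beta", "q", "e", "m_obs", "power", "m_total")]
  attr(out, "M_total") <- sum(bins$m_total)
  attr(out, "design") <- design
  class(out) <- c("effect_bins", class(out))
  out
}

#' Number of future SNPs simulated for one effect bin
#'
#' The future panel carries `ceiling(power * m_total)` SNPs for a bin
#' with estimated total `m_total` and future-study detection power
#' `power` (e.g. an estimated 10 SNPs at power 0.8 yields 8; the ceiling
#' rounds a fractional expectation such as 7.2 up to 8). Zero power
#' yields zero SNPs.
#'
#' @param power Future-study detection power in \[0, 1\].
#' @param m_total Estimated total SNPs in the bin.
#' @return Integer count(s).
#' @export
future_snp_count <- function(power, m_total) {
  ifelse(power <= 0, 0L, as.integer(ceiling(power * m_total)))
}

#' Hypothetical panel after a larger future GWAS
#'
#' For each effect bin, recomputes detection power under the design's
#' multiplied sample size and places `ceiling(p'_j * M_T,j)` SNPs of that
#' bin's effect size and allele frequency in the future panel, each in
#' its own locus. In the default `"augment"` mode the originally
#' observed SNP is retained (so current and future panels share its
#' genotypes when both are scored on one cohort) and
#' `ceiling(p'_j * M_T,j) - 1` new SNPs are added; `"all_new"` simulates
#' every future SNP fresh. A bin with zero future power contributes no
#' SNPs.
#'
#' @param panel The current panel tibble.
#' @param bins [bin_totals()] result derived from `panel`.
#' @param design The reference [study_design()]; the future study has
#'   `design$multiplier` times its sample sizes.
#' @param mode `"augment"` (default) or `"all_new"`.
#' @return A panel tibble (`rsid`, `chrom`, `pos`, `raf`, `or`,
#'   `locus_id`); new SNPs carry synthetic identifiers.
#' @export
future_panel <- function(panel, bins, design, mode = c("augment", "all_new")) {
  mode <- match.arg(mode)
  if (design$multiplier < 1) rlang::abort("multiplier must be at least 1")
  future_design <- study_design(design$n_cases * design$multiplier,
                                design$n_controls * design$multiplier,
                                alpha = design$alpha, multiplier = 1)
  p2 <- detection_power(bins$beta, bins$q, future_design)
  counts <- future_snp_count(p2, bins$m_total)
  # power monotone in n, so ceil(p2 * m_obs/p) >= m_obs; guarded regardless
  counts <- pmax(counts, ifelse(p2 > 0, bins$m_obs, 0))

  new_counter <- 0L
  rows <- purrr::pmap(
    list(bins$bin, bins$beta, bins$q, counts),
    function(bin, beta, q, cnt) {
      if (cnt == 0) return(NULL)
      seed_row <- NULL
      n_new <- cnt
      if (mode == "augment") {
        src <- panel[panel$rsid == bin, , drop = FALSE]
        if (nrow(src) == 1) {
          seed_row <- tibble::tibble(
            rsid = src$rsid, chrom = src$chrom, pos = src$pos,
            raf = src$raf, or = src$or,
            locus_id = if ("locus_id" %in% names(src)) src$locus_id
                       else src$rsid
          )
          n_new <- cnt - 1L
        }
      }
      if (n_new > 0) {
        ids <- paste0(bin, ".fut", seq_len(n_new))
        new_counter <<- new_counter + n_new
        new_rows <- tibble::tibble(
          rsid = ids,
          chrom = paste0("sim", new_counter - n_new + seq_len(n_new)),
          pos = 1,
          raf = q, or = exp(beta),
          locus_id = ids
        )
      } else {
        new_rows <- NULL
      }
      dplyr::bind_rows(seed_row, new_rows)
    }
  )
  dplyr::bind_rows(rows)
}

#' Projected reclassification after a hypothetical future GWAS
#'
#' Simulates one cohort over the union of current and future panel SNPs,
#' scores both panels (each normalized by its own cohort mean),
#' and returns the full comparison: 3x3 reclassification, NRI (cases
#' weighted by normalized odds at the *current* panel), odds-change
#' summary, and empirical plus binormal AUC for both panels.
#'
#' @param panel_now Current panel tibble.
#' @param panel_future Future panel from [future_panel()].
#' @param n Cohort size, default 100,000.
#' @param seed Simulation seed.
#' @param hap_models Haplotype models for multi-SNP loci, if any.
#' @param nri_weights `"earlier"` (default) or `"later"`: which panel's
#'   normalized odds define the NRI case weights (see
#'   [drift_timeline()]).
#' @inheritParams classify_risk
#' @return A `risk_projection` list: `reclassification`, `nri`,
#'   `odds_change`, `auc` (tibble with empirical and binormal AUC per
#'   panel), `n`, panel sizes.
#' @export
project_future <- function(panel_now, panel_future, n = 100000, seed = 1,
                           hap_models = NULL, lo = 0.5, hi = 2,
                           nri_weights = c("earlier", "later")) {
  nri_weights <- match.arg(nri_weights)
  union_snps <- dplyr::bind_rows(panel_now, panel_future) |>
    dplyr::distinct(.data$rsid, .keep_all = TRUE)
  if (!"locus_id" %in% names(union_snps)) union_snps$locus_id <- union_snps$rsid
  geno <- simulate_genotypes(union_snps, n = n, seed = seed,
                             hap_models = hap_models)
  o1 <- normalize_odds(raw_odds(geno, panel_now))
  o2 <- normalize_odds(raw_odds(geno, panel_future))
  c1 <- classify_risk(o1, lo, hi)
  c2 <- classify_risk(o2, lo, hi)
  ones <- rep(1, n)
  auc <- purrr::map2(list(o1, o2), c("current", "future"), function(o, tag) {
    logo <- log(o)
    w <- o / sum(o)
    mu_c <- sum(w * logo)
    sd_c <- sqrt(sum(w * logo^2) - mu_c^2)
    tibble::tibble(
      panel = tag,
      n_snps = if (tag == "current") nrow(panel_now) else nrow(panel_future),
      empirical = empirical_auc(o, case_weights = o, control_weights = ones),
      binormal = analytic_auc(mu_c, sd_c, mean(logo), stats::sd(logo))$auc
    )
  }) |> dplyr::bind_rows()

  structure(
    list(
      reclassification = reclassification_metrics(c1, c2),
      nri = nri(c1, c2,
                case_weights = if (nri_weights == "earlier") o1 else o2,
                control_weights = ones),
      odds_change = odds_change_summary(o1, o2),
      auc = auc,
      n = n,
      seed = seed
    ),
    class = "risk_projection"
  )
}

#' @export
print.risk_projection <- function(x, ...) {
  cat("<risk_projection> cohort n =", x$n, "\n")
  print(x$reclassification)
  cat(sprintf("  NRI: %.3f\n", x$nri))
  print(x$auc)
  invisible(x)
}
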