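#' Generate a synthetic universe of causal susceptibility SNPs
#'
#' Draws a polygenic architecture of independent causal SNPs: per-allele
#' log odds ratios `beta = log(or_min) + Exponential(mean = beta_scale)`
#' (so ORs concentrate in roughly 1.05-1.3 by default, with an
#' exponential tail of larger effects) and allele frequencies uniform on
#' `maf_range`. SNPs are placed on 22 chromosome labels with 2 Mb
#' spacing, so every causal SNP is its own locus by default.
#'
#' @param n_causal Number of causal SNPs (>= 0).
#' @param or_min Minimum per-allele OR; default 1.05.
#' @param beta_scale Mean of the exponential excess on the log-OR scale;
#'   default 0.06.
#' @param maf_range Allele-frequency range, default `c(0.05, 0.95)`.
#' @param seed Integer seed.
#' @return A tibble (`rsid`, `chrom`, `pos`, `risk_allele`, `beta`, `q`)
#'   with the generation parameters stored in attribute `"params"`.
#' @export
make_universe <- function(n_causal, or_min = 1.05, beta_scale = 0.06,
                          maf_range = c(0.05, 0.95), seed = 1) {
  if (n_causal < 0) rlang::abort("n_causal must be non-negative")
  if (or_min < 1 || beta_scale <= 0) {
    rlang::abort("need or_min >= 1 and beta_scale > 0")
  }
  if (maf_range[1] <= 0 || maf_range[2] >= 1 || maf_range[1] >= maf_range[2]) {
    rlang::abort("maf_range must be inside (0, 1) and increasing")
  }
  set.seed(seed)
  if (n_causal == 0) {
    out <- tibble::tibble(rsid = character(), chrom = character(),
                          pos = numeric(), risk_allele = character(),
                          beta = numeric(), q = numeric())
  } else {
    i <- seq_len(n_causal)
    out <- tibble::tibble(
      rsid = sprintf("snp%04d", i),
      chrom = paste0("chr", ((i - 1L) %% 22L) + 1L),
      pos = 1e6 + 2e6 * ((i - 1L) %/% 22L),
      risk_allele = "A",
      beta = log(or_min) + stats::rexp(n_causal, rate = 1 / beta_scale),
      q = stats::runif(n_causal, maf_range[1], maf_range[2])
    )
  }
  attr(out, "params") <- list(n_causal = n_causal, or_min = or_min,
                              beta_scale = beta_scale,
                              maf_range = maf_range, seed = seed)
  out
}

#' Discovery schedule for a synthetic GWAS timeline
#'
#' Time points with cumulative study sizes. Defaults mirror a biennial
#' 2007-2013 accumulation with roughly geometrically growing sample
#' sizes, the regime in which each wave of discoveries is large relative
#' to the existing panel.
#'
#' @param dates Date vector of time points (strictly increasing).
#' @param n_cases,n_controls Cumulative sample sizes per time point
#'   (non-decreasing).
#' @param alpha Significance level, default `5e-8`.
#' @return A tibble with one row per time point.
#' @export
discovery_schedule <- function(
    dates = as.Date(c("2007-12-31", "2009-12-31", "2011-12-31", "2013-12-31")),
    n_cases = c(5000, 12000, 25000, 50000),
    n_controls = n_cases,
    alpha = 5e-8) {
  dates <- as.Date(dates)
  if (any(diff(dates) <= 0)) rlang::abort("dates must be strictly increasing")
  if (any(diff(n_cases) < 0) || any(diff(n_controls) < 0)) {
    rlang::abort("sample sizes must be non-decreasing over time")
  }
  tibble::tibble(date = dates, n_cases = n_cases, n_controls = n_controls,
                 alpha = alpha)
}

# draw from N(beta, se^2) conditional on |x| > z*se (the sampling
# distribution of a genome-wide-significant effect estimate)
rtrunc_significant <- function(n, beta, se, z) {
  upper_mass <- stats::pnorm((beta - z * se) / se)
  lower_mass <- stats::pnorm((-z * se - beta) / se)
  tot <- upper_mass + lower_mass
  take_upper <- stats::runif(n) < upper_mass / tot
  u <- stats::runif(n)
  x <- numeric(n)
  p_below_upper <- stats::pnorm((z * se - beta) / se)
  x[take_upper] <- beta + se * stats::qnorm(
    p_below_upper + u[take_upper] * (1 - p_below_upper))
  x[!take_upper] <- beta + se * stats::qnorm(u[!take_upper] * lower_mass)
  x
}

#' Simulate SNP discovery over a GWAS timeline
#'
#' Runs the discovery process over a [discovery_schedule()]: at each time
#' point, each not-yet-discovered causal SNP is reported with probability
#' equal to its [detection_power()] under that time point's cumulative
#' design. A discovered SNP's report carries a p-value derived from an
#' effect estimate drawn from its sampling distribution truncated to
#' significance; the reported OR is the true `exp(beta)` when
#' `winners_curse` is off, or the (upward-biased) `exp(beta_hat)` when
#' on. Every previously discovered SNP is re-reported at each later time
#' point with the larger design, so later, more significant reports
#' exercise the catalog's OR-update rule.
#'
#' @param universe A [make_universe()] tibble.
#' @param schedule A [discovery_schedule()] tibble.
#' @param winners_curse Report the truncated effect estimate instead of
#'   the true OR. Default `FALSE`.
#' @param seed Integer seed.
#' @return A catalog tibble (one row per report) ready for
#'   [as_catalog()] / [build_panels()]; the universe is stored in
#'   attribute `"truth"`.
#' @export
simulate_discovery <- function(universe, schedule, winners_curse = FALSE,
                               seed = 1) {
  set.seed(seed)
  nsnp <- nrow(universe)
  discovered <- rep(FALSE, nsnp)
  out <- vector("list", nrow(schedule))
  for (t in seq_len(nrow(schedule))) {
    des <- study_design(schedule$n_cases[t], schedule$n_controls[t],
                        alpha = schedule$alpha[t], multiplier = 1)
    if (nsnp == 0) break
    pow <- detection_power(universe$beta, universe$q, des)
    new_hit <- !discovered & stats::runif(nsnp) < pow
    idx <- which(new_hit | discovered)
    if (length(idx) == 0) next
    se <- sqrt((1 / (2 * universe$q[idx] * (1 - universe$q[idx]))) *
                 (1 / des$n_cases + 1 / des$n_controls))
    z <- stats::qnorm(1 - des$alpha / 2)
    bhat <- rtrunc_significant(length(idx), universe$beta[idx], se, z)
    out[[t]] <- tibble::tibble(
      rsid = universe$rsid[idx],
      chrom = universe$chrom[idx],
      pos = universe$pos[idx],
      risk_allele = universe$risk_allele[idx],
      raf = universe$q[idx],
      or = if (winners_curse) exp(bhat) else exp(universe$beta[idx]),
      pvalue = 2 * stats::pnorm(-abs(bhat) / se),
      report_date = schedule$date[t],
      source = paste0("gwas_", format(schedule$date[t], "%Y")),
      n_cases = des$n_cases,
      n_controls = des$n_controls
    )
    discovered <- discovered | new_hit
  }
  cat <- dplyr::bind_rows(out)
  attr(cat, "truth") <- universe
  cat
}

#' Construct a haplotype model with a target pairwise r-squared
#'
#' Builds haplotype frequencies for a locus of `n_snps` SNPs whose
#' adjacent-pair squared allelic correlation matches `target_r2`
#' (positive-sign correlation), via a first-order chain: the first SNP
#' has allele frequency `q[1]` and each subsequent allele is drawn
#' conditionally on the previous with covariance
#' `D = r * sqrt(q_a(1-q_a) q_b(1-q_b))`. For two SNPs this reproduces
#' the classic two-locus haplotype table exactly; for longer loci
#' non-adjacent pairs decay geometrically. Infeasible (`r2`, `q`)
#' combinations (negative implied haplotype frequencies) are an error
#' reporting the maximum feasible r-squared.
#'
#' @param target_r2 Desired adjacent-pair r-squared in \[0, 1\].
#' @param q Allele frequencies (recycled to `n_snps`).
#' @param n_snps Number of SNPs at the locus, default `length(q)`
#'   (minimum 2).
#' @param snps Optional SNP names.
#' @return A [haplotype_model()].
#' @export
make_ld_fixture <- function(target_r2, q, n_snps = max(length(q), 2),
                            snps = NULL) {
  if (target_r2 < 0 || target_r2 > 1) rlang::abort("target_r2 must lie in [0, 1]")
  if (n_snps < 2) rlang::abort("an LD fixture needs at least 2 SNPs")
  q <- rep_len(q, n_snps)
  if (any(q <= 0 | q >= 1)) rlang::abort("q must lie in (0, 1)")
  r <- sqrt(target_r2)
  L <- n_snps
  for (t in 2:L) {
    qa <- q[t - 1]; qb <- q[t]
    D <- r * sqrt(qa * (1 - qa) * qb * (1 - qb))
    hap2 <- c(qa * qb + D, qa * (1 - qb) - D, (1 - qa) * qb - D,
              (1 - qa) * (1 - qb) + D)
    if (any(hap2 < -1e-12)) {
      dmax <- min(qa * (1 - qb), (1 - qa) * qb)
      r2max <- dmax^2 / (qa * (1 - qa) * qb * (1 - qb))
      rlang::abort(paste0(
        "target r2 infeasible for q = (", qa, ", ", qb,
        "): maximum feasible r2 is ", signif(r2max, 4)))
    }
  }
  H <- as.matrix(expand.grid(rep(list(0:1), L)))
  storage.mode(H) <- "integer"
  prob <- ifelse(H[, 1] == 1L, q[1], 1 - q[1])
  for (t in 2:L) {
    qa <- q[t - 1]; qb <- q[t]
    D <- r * sqrt(qa * (1 - qa) * qb * (1 - qb))
    p1_given1 <- (qa * qb + D) / qa
    p1_given0 <- ((1 - qa) * qb - D) / (1 - qa)
    pcond <- ifelse(H[, t - 1] == 1L,
                    ifelse(H[, t] == 1L, p1_given1, 1 - p1_given1),
                    ifelse(H[, t] == 1L, p1_given0, 1 - p1_given0))
    prob <- prob * pcond
  }
  keep <- prob > 1e-15
  haplotype_model(H[keep, , drop = FALSE], frequencies = prob[keep],
                  snps = snps)
}
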