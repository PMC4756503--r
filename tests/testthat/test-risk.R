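test_that("raw odds follow the multiplicative model in log space", {
  g <- rbind(c(0, 0), c(1, 2), c(2, 0))
  colnames(g) <- c("rs1", "rs2")
  panel <- tibble::tibble(rsid = c("rs1", "rs2"), or = c(1.5, 1.2))
  odds <- raw_odds(g, panel)
  expect_equal(odds[1], 1)                   # empty product
  expect_equal(odds[2], 1.5 * 1.44)          # 2.16, hand-evaluated
  expect_equal(odds[3], 2.25)

  single <- tibble::tibble(rsid = "rs1", or = 2)
  expect_equal(raw_odds(g, single)[3], 4)    # OR = 2 at g = 2

  expect_error(raw_odds(g, tibble::tibble(rsid = "rs9", or = 2)), "rs9")
  # empty panel scores everyone at odds 1
  expect_equal(raw_odds(g, panel[0, ]), rep(1, 3))
})

test_that("normalization divides by the cohort mean", {
  expect_equal(normalize_odds(c(3, 3, 3)), c(1, 1, 1))
  expect_equal(normalize_odds(c(1, 3)), c(0.5, 1.5))
  set.seed(8)
  x <- exp(rnorm(1000))
  expect_lt(abs(mean(normalize_odds(x)) - 1), 1e-12)
  expect_error(normalize_odds(numeric(0)), "empty")
  expect_error(normalize_odds(c(1, -2)), "positive")
})

test_that("three-tier classification puts boundaries in Average", {
  o <- c(0.4, 0.5, 1.0, 2.0, 2.5)
  expect_equal(as.character(classify_risk(o)),
               c("Lower", "Average", "Average", "Average", "Higher"))
  expect_true(is.ordered(classify_risk(o)))
  expect_error(classify_risk(o, lo = 2, hi = 0.5))
})

test_that("exact enumeration reproduces the single-SNP hand computation", {
  # null SNP: one odds value, identical case/control masses
  d0 <- exact_distribution(tibble::tibble(rsid = "s", raf = 0.5, or = 1))
  expect_equal(nrow(d0$values), 1)
  expect_equal(d0$values$norm_odds, 1)
  expect_equal(d0$moments$mu_case, d0$moments$mu_control)

  # q = 0.3, OR = 2: control (0.49, 0.42, 0.09), mean odds 1.69,
  # case = odds-weighted
  d <- exact_distribution(tibble::tibble(rsid = "s", raf = 0.3, or = 2))
  expect_equal(d$values$control_prob, c(0.49, 0.42, 0.09))
  expect_equal(d$mean_raw_odds, 1.69)
  expect_equal(d$values$case_prob, c(0.49, 0.84, 0.36) / 1.69)
  expect_equal(sum(d$values$control_prob), 1)
  expect_equal(sum(d$values$case_prob), 1)
})

test_that("two independent SNPs convolve to the 9-combination brute force", {
  panel <- tibble::tibble(rsid = c("s1", "s2"), raf = c(0.3, 0.6),
                          or = c(2, 1.5))
  d <- exact_distribution(panel)

  # brute-force oracle: loop over all 9 genotype combinations
  probs <- c(); odds <- c()
  for (g1 in 0:2) for (g2 in 0:2) {
    probs <- c(probs, dbinom(g1, 2, 0.3) * dbinom(g2, 2, 0.6))
    odds <- c(odds, 2^g1 * 1.5^g2)
  }
  mean_odds <- sum(probs * odds)
  expect_equal(d$mean_raw_odds, mean_odds)
  agg <- tapply(probs, round(odds, 9), sum)
  got <- setNames(d$values$control_prob, round(d$values$odds, 9))
  expect_equal(unname(got[names(agg)]), as.numeric(agg), tolerance = 1e-12)
})

test_that("haplotype loci enter enumeration through diplotype probabilities", {
  hm <- make_ld_fixture(0.5, c(0.3, 0.3), snps = c("x", "y"))
  panel <- tibble::tibble(rsid = c("x", "y"), raf = 0.3, or = c(1.5, 1.3),
                          locus_id = "L", pos = 1:2)
  d <- exact_distribution(panel, hap_models = list(L = hm))
  # oracle: enumerate ordered haplotype pairs directly
  H <- hm$haplotypes; f <- hm$frequencies
  o <- c(); p <- c()
  for (i in seq_along(f)) for (j in seq_along(f)) {
    gv <- H[i, ] + H[j, ]
    o <- c(o, 1.5^gv[1] * 1.3^gv[2])
    p <- c(p, f[i] * f[j])
  }
  expect_equal(d$mean_raw_odds, sum(p * o))
  expect_equal(sum(d$values$control_prob), 1)
})

test_that("null SNPs leave odds untouched and informative SNPs widen log odds", {
  base <- tibble::tibble(rsid = "s1", raf = 0.3, or = 1.5)
  plus_null <- dplyr::bind_rows(base,
                                tibble::tibble(rsid = "s2", raf = 0.4, or = 1))
  d1 <- exact_distribution(base)
  d2 <- exact_distribution(plus_null)
  expect_equal(sort(unique(round(d2$values$norm_odds, 9))),
               sort(unique(round(d1$values$norm_odds, 9))))
  expect_equal(d2$moments$sd_control, d1$moments$sd_control)

  plus_real <- dplyr::bind_rows(base,
                                tibble::tibble(rsid = "s3", raf = 0.4, or = 1.2))
  d3 <- exact_distribution(plus_real)
  expect_gt(d3$moments$sd_control, d1$moments$sd_control)
})

test_that("case mass stochastically dominates control mass when some OR > 1", {
  panel <- tibble::tibble(rsid = c("a", "b"), raf = c(0.2, 0.5),
                          or = c(1.6, 1.3))
  d <- exact_distribution(panel)
  cdf_case <- cumsum(d$values$case_prob)
  cdf_ctrl <- cumsum(d$values$control_prob)
  expect_true(all(cdf_case <= cdf_ctrl + 1e-12))
  expect_gt(max(cdf_ctrl - cdf_case), 0)
})

test_that("enumeration cap triggers a Monte-Carlo redirect", {
  big <- tibble::tibble(rsid = paste0("s", 1:14),
                        raf = runif(14, 0.2, 0.8),
                        or = runif(14, 1.05, 1.3))
  expect_error(exact_distribution(big, cap = 100), "Monte-Carlo")
})

test_that("explicit-incidence control distribution solves the scaling constant", {
  d <- exact_distribution(tibble::tibble(rsid = "s", raf = 0.3, or = 2))
  # K = 0 is the identity
  expect_equal(control_dist_at_incidence(d, 0), d)

  # closed-form oracle at K = 0.10: c = K, control ~ (1 - c O) Pr(g)
  K <- 0.10
  adj <- control_dist_at_incidence(d, K)
  O <- d$values$norm_odds
  manual <- (1 - K * O) * d$values$control_prob
  manual <- manual / sum(manual)
  expect_equal(adj$values$control_prob, manual)
  expect_equal(sum((1 - K * O) * d$values$control_prob), 1 - K)
  # case mass is untouched
  expect_equal(adj$values$case_prob, d$values$case_prob)

  # infeasible scaling (c * max odds > 1) is an error
  strong <- exact_distribution(tibble::tibble(rsid = paste0("s", 1:4),
                                              raf = 0.05,
                                              or = c(6, 6, 6, 6)))
  expect_gt(max(strong$values$norm_odds) * 0.10, 1)
  expect_error(control_dist_at_incidence(strong, 0.10), "infeasible")
})

test_that("Monte-Carlo category proportions agree with exact enumeration", {
  panel <- tibble::tibble(rsid = c("a", "b"), raf = c(0.2, 0.4),
                          or = c(1.8, 1.4))
  d <- exact_distribution(panel)
  exact <- risk_category_props(d)$prop
  g <- simulate_genotypes(panel, n = 100000, seed = 12)
  sc <- score_cohort(g, panel)
  mc <- as.numeric(table(sc$risk_category) / nrow(sc))
  expect_true(all(abs(mc - exact) < se_tol(exact, 1e5)))
})
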