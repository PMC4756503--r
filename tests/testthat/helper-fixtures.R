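# Fixture builders shared across test files. Everything is generated in
# code; no binary data.

# minimal well-formed catalog rows
fix_catalog_rows <- function() {
  tibble::tibble(
    rsid = c("rs1", "rs2", "rs3"),
    chrom = c("1", "1", "2"),
    pos = c(1e5, 9e5, 5e4),
    risk_allele = "A",
    raf = c(0.3, 0.2, 0.4),
    or = c(1.3, 1.5, 1.2),
    pvalue = c(1e-10, 1e-12, 4e-8),
    report_date = as.Date(c("2008-05-01", "2009-03-01", "2010-07-01")),
    source = c("s1", "s2", "s3"),
    n_cases = 10000, n_controls = 10000
  )
}

# small panel pair (<= 4 union SNPs) exercising an OR update and growth;
# rs4/rs5 form a haplotype locus with adjacent r2 = 0.5
fix_panel_pair_simple <- function() {
  a <- tibble::tibble(rsid = "rs1", raf = 0.3, or = 1.4)
  b <- tibble::tibble(
    rsid = c("rs1", "rs2", "rs3"),
    raf = c(0.3, 0.2, 0.4),
    or = c(1.35, 1.6, 1.25)
  )
  list(a = a, b = b, hap_models = NULL)
}

fix_panel_pair_hap <- function() {
  hm <- make_ld_fixture(0.5, c(0.3, 0.3), snps = c("rs4", "rs5"))
  a <- tibble::tibble(rsid = c("rs4", "rs5"), raf = 0.3,
                      or = c(1.5, 1.3), locus_id = "L45", pos = c(1, 2))
  b <- dplyr::bind_rows(
    a,
    tibble::tibble(rsid = "rs6", raf = 0.1, or = 2.0,
                   locus_id = "rs6", pos = 1)
  )
  list(a = a, b = b, hap_models = list(L45 = hm))
}

# tolerance: k binomial standard errors around proportion p at size n
se_tol <- function(p, n, k = 3) k * sqrt(pmax(p * (1 - p), 1e-12) / n)
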