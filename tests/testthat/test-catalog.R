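test_that("read_catalog validates, filters to significance, and flips protective ORs", {
  rows <- fix_catalog_rows()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(rows, path)
  cat <- read_catalog(path)
  expect_equal(nrow(cat), 3)
  expect_s3_class(cat$report_date, "Date")

  # a row at p = 1e-7 misses the genome-wide cutoff
  rows2 <- rows
  rows2$pvalue[1] <- 1e-7
  write_catalog(rows2, path)
  expect_equal(nrow(read_catalog(path)), 2)
  # ... but survives a looser alpha
  expect_equal(nrow(read_catalog(path, alpha = 1e-6)), 3)

  # invariant violations are errors naming the row
  rows3 <- rows; rows3$raf[2] <- 1.2
  write_catalog(rows3, path)
  expect_error(read_catalog(path), "raf outside")
  rows4 <- rows; rows4$or[3] <- -0.5
  write_catalog(rows4, path)
  expect_error(read_catalog(path), "not positive")

  # missing required column is a format error
  rows5 <- rows; rows5$raf <- NULL
  readr::write_tsv(rows5, path)
  expect_error(read_catalog(path), class = "riskdrift_format_error")

  # protective OR re-oriented to the risk allele
  rows6 <- rows; rows6$or[1] <- 0.8; rows6$raf[1] <- 0.7
  write_catalog(rows6, path)
  cat6 <- read_catalog(path)
  r1 <- cat6[cat6$rsid == "rs1", ]
  expect_equal(r1$or, 1.25)
  expect_equal(r1$raf, 0.3)
  expect_true(r1$flipped)
})

test_that("assign_loci chains SNPs by adjacent gaps within a chromosome", {
  mk <- function(pos, chrom = "1") {
    tibble::tibble(rsid = paste0("s", seq_along(pos)), chrom = chrom, pos = pos)
  }
  # two SNPs 400 kb apart share a locus
  expect_equal(dplyr::n_distinct(assign_loci(mk(c(0, 4e5) + 1))$locus_id), 1)
  # 0 / 400k / 800k chain into a single locus even though the ends are 800k apart
  expect_equal(dplyr::n_distinct(assign_loci(mk(c(0, 4e5, 8e5) + 1))$locus_id), 1)
  # a 600k gap splits
  expect_equal(dplyr::n_distinct(assign_loci(mk(c(0, 6e5) + 1))$locus_id), 2)
  # same positions on different chromosomes are separate loci
  two <- dplyr::bind_rows(mk(1e5, "1"), mk(1e5, "2"))
  two$rsid <- c("sA", "sB")
  expect_equal(dplyr::n_distinct(assign_loci(two)$locus_id), 2)
  # empty input passes through
  expect_equal(nrow(assign_loci(mk(numeric(0)))), 0)
})

test_that("prune_locus applies stepwise r2 retention with deterministic tie-breaks", {
  locus <- tibble::tibble(
    rsid = c("A", "B"), chrom = "1", pos = c(100, 200),
    pvalue = c(1e-20, 1e-10)
  )
  ld_hi <- tibble::tibble(rsid_a = "A", rsid_b = "B", r2 = 0.9)
  ld_lo <- tibble::tibble(rsid_a = "A", rsid_b = "B", r2 = 0.5)
  expect_equal(prune_locus(locus, ld_hi)$rsid, "A")
  expect_setequal(prune_locus(locus, ld_lo)$rsid, c("A", "B"))
  # sensitivity endpoints: threshold 1 keeps everything, 0 keeps the top SNP
  expect_equal(nrow(prune_locus(locus, ld_hi, r2_max = 1)), 2)
  expect_equal(prune_locus(locus, ld_hi, r2_max = 0)$rsid, "A")
  # an absent r2 pair is an error, not a silent default
  expect_error(prune_locus(locus, tibble::tibble(rsid_a = "A", rsid_b = "C",
                                                 r2 = 0.2)),
               class = "riskdrift_ld_error")
  expect_error(prune_locus(locus, NULL), class = "riskdrift_ld_error")
  # p-value tie broken by smaller position
  tie <- tibble::tibble(rsid = c("B", "A"), chrom = "1", pos = c(200, 100),
                        pvalue = 1e-10)
  expect_equal(prune_locus(tie, ld_hi)$rsid, "A")
})

test_that("pruning is idempotent on randomly generated loci", {
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    locus <- tibble::tibble(
      rsid = paste0("s", 1:k), chrom = "1",
      pos = sort(sample.int(4e5, k)),
      pvalue = 10^(-stats::runif(k, 8, 30))
    )
    pairs <- t(utils::combn(locus$rsid, 2))
    ld <- tibble::tibble(rsid_a = pairs[, 1], rsid_b = pairs[, 2],
                         r2 = stats::runif(nrow(pairs)))
    once <- prune_locus(locus, ld)
    twice <- prune_locus(once, ld)
    expect_equal(twice$rsid, once$rsid)
  }
})

test_that("build_panels accumulates reports and applies the minimum-p OR update", {
  cat <- as_catalog(tibble::tibble(
    rsid = c("rsX", "rsY", "rsY"),
    chrom = c("1", "2", "2"),
    pos = c(1e5, 2e5, 2e5),
    risk_allele = "A",
    raf = c(0.25, 0.3, 0.3),
    or = c(1.2, 1.30, 1.25),
    pvalue = c(1e-9, 1e-9, 1e-15),
    report_date = as.Date(c("2008-06-01", "2009-06-01", "2012-06-01")),
    source = c("s1", "s2", "s3")
  ))
  dates <- as.Date(c("2007-12-31", "2009-12-31", "2011-12-31", "2013-12-31"))
  panels <- build_panels(cat, dates)

  # a SNP first reported 2008 is absent from the 2007 panel, present after
  expect_false("rsX" %in% panels$rsid[panels$time_point == dates[1]])
  for (d in dates[2:4]) {
    expect_true("rsX" %in% panels$rsid[panels$time_point == d])
  }
  # OR update: 2009 carries the 2009 OR, 2013 the more significant 2012 OR
  expect_equal(panels$or[panels$time_point == dates[2] & panels$rsid == "rsY"], 1.30)
  expect_equal(panels$or[panels$time_point == dates[4] & panels$rsid == "rsY"], 1.25)

  # empty catalog gives empty panels for every date
  empty <- build_panels(cat[0, ], dates)
  expect_equal(nrow(empty), 0)

  # duplicate (rsid, report_date, source) is an error
  dup <- dplyr::bind_rows(cat, cat[1, ])
  expect_error(build_panels(dup, dates), "duplicate")
})

test_that("effective OR matches a brute-force scan over random report histories", {
  set.seed(11)
  for (rep in 1:15) {
    n_rep <- sample(1:5, 1)
    hist <- tibble::tibble(
      rsid = "rsZ", chrom = "1", pos = 1e5, risk_allele = "A", raf = 0.3,
      or = round(stats::runif(n_rep, 1.05, 1.6), 3),
      pvalue = 10^(-stats::runif(n_rep, 8, 25)),
      report_date = sort(sample(seq(as.Date("2007-01-01"),
                                    as.Date("2013-12-01"), by = "day"), n_rep)),
      source = paste0("s", 1:n_rep)
    )
    m <- as.Date("2011-12-31")
    panels <- build_panels(as_catalog(hist), m)
    sub <- hist[hist$report_date <= m, ]
    if (nrow(sub) == 0) {
      expect_equal(nrow(panels), 0)
    } else {
      best <- sub[order(sub$pvalue, sub$report_date), ][1, ]
      expect_equal(panels$or, best$or)
    }
  }
})

test_that("panels never contain SNPs reported after their date", {
  set.seed(3)
  uni <- make_universe(40, seed = 3)
  cat <- simulate_discovery(uni, discovery_schedule(), seed = 3)
  dates <- discovery_schedule()$date
  panels <- build_panels(cat, dates)
  first_report <- cat |>
    dplyr::group_by(rsid) |>
    dplyr::summarise(first = min(report_date))
  joined <- dplyr::left_join(panels, first_report, by = "rsid")
  expect_true(all(joined$first <= joined$time_point))
})
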