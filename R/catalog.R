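#' Read a tab-separated SNP catalog
#'
#' Reads a catalog of published risk SNPs (one row per report) in the layout
#' used throughout this package: columns `rsid`, `chrom`, `pos`,
#' `risk_allele`, `raf`, `or`, `pvalue`, `report_date` (YYYY-MM-DD),
#' `source`, and optionally `n_cases` / `n_controls` for the reporting
#' study. Rows are validated and filtered to genome-wide significance; see
#' [as_catalog()] for the rules applied.
#'
#' @param path Path to a tab-separated catalog file with a header row.
#' @param alpha Significance threshold; only reports with
#'   `pvalue < alpha` are retained. Default is the conventional
#'   genome-wide cutoff `5e-8`.
#' @param flip_protective Flip reports with OR below 1 to the other allele
#'   (`or <- 1/or`, `raf <- 1 - raf`) so every stored OR is at least 1 and
#'   genotypes count risk alleles. Default `TRUE`.
#' @return A tibble of validated catalog rows (see [as_catalog()]).
#' @seealso [as_catalog()], [build_panels()], [write_catalog()]
#' @export
read_catalog <- function(path, alpha = 5e-8, flip_protective = TRUE) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      rsid = readr::col_character(),
      chrom = readr::col_character(),
      risk_allele = readr::col_character(),
      source = readr::col_character(),
      report_date = readr::col_date(format = "%Y-%m-%d"),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  as_catalog(raw, alpha = alpha, flip_protective = flip_protective)
}

#' Validate an in-memory SNP catalog
#'
#' Checks a data frame of SNP reports against the catalog contract and
#' returns a significance-filtered tibble. Required columns: `rsid`,
#' `chrom`, `pos`, `risk_allele`, `raf`, `or`, `pvalue`, `report_date`,
#' `source`. Invariants enforced per row: `raf` strictly inside (0, 1),
#' `or > 0`, `pos >= 1`, `pvalue` in (0, 1). Violations are errors naming
#' the offending rows. Reports with OR < 1 are re-oriented to the risk
#' allele when `flip_protective` is `TRUE` (a `flipped` column records
#' which rows were re-oriented).
#'
#' @param x A data frame of catalog rows.
#' @inheritParams read_catalog
#' @return A tibble with the catalog columns plus `flipped`, containing
#'   only reports significant at `alpha`, sorted by chromosome, position,
#'   rsid and report date.
#' @export
as_catalog <- function(x, alpha = 5e-8, flip_protective = TRUE) {
  required <- c("rsid", "chrom", "pos", "risk_allele", "raf", "or",
                "pvalue", "report_date", "source")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("catalog is missing required column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "riskdrift_format_error")
  }
  x <- tibble::as_tibble(x)
  if (!"n_cases" %in% names(x)) x$n_cases <- NA_real_
  if (!"n_controls" %in% names(x)) x$n_controls <- NA_real_
  x$report_date <- as.Date(x$report_date)

  check_rows <- function(bad, what) {
    if (any(bad, na.rm = TRUE) || anyNA(bad)) {
      rows <- which(bad | is.na(bad))
      rlang::abort(
        paste0(what, " in catalog row(s): ",
               paste(utils::head(rows, 10L), collapse = ", ")),
        class = "riskdrift_validation_error"
      )
    }
  }
  check_rows(!(x$raf > 0 & x$raf < 1), "raf outside (0, 1)")
  check_rows(!(x$or > 0), "odds ratio not positive")
  check_rows(!(x$pos >= 1), "position below 1")
  check_rows(!(x$pvalue > 0 & x$pvalue < 1), "p-value outside (0, 1)")
  check_rows(is.na(x$rsid) | is.na(x$chrom) | is.na(x$report_date),
             "missing rsid/chrom/report_date")

  if (flip_protective) {
    flip <- x$or < 1
    x$or[flip] <- 1 / x$or[flip]
    x$raf[flip] <- 1 - x$raf[flip]
    x$flipped <- flip
  } else {
    x$flipped <- FALSE
  }

  x <- dplyr::filter(x, .data$pvalue < alpha)
  dplyr::arrange(x, .data$chrom, .data$pos, .data$rsid, .data$report_date)
}

#' Write a catalog to a tab-separated file
#'
#' @param catalog A catalog tibble (as returned by [as_catalog()] or
#'   [simulate_discovery()]).
#' @param path Output path.
#' @return `catalog`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  out <- catalog
  out$report_date <- format(as.Date(out$report_date), "%Y-%m-%d")
  out$flipped <- NULL
  readr::write_tsv(out, path, progress = FALSE)
  invisible(catalog)
}

#' Group SNPs into loci by physical proximity
#'
#' Partitions SNPs into loci by single-linkage chaining within each
#' chromosome: SNPs are sorted by position and a new locus starts whenever
#' the gap to the previous SNP exceeds `window_bp`. Two SNPs are therefore
#' in the same locus whenever they are connected by a chain of
#' adjacent gaps each at most `window_bp` (pairwise-complete grouping is
#' not well defined for chains, so chaining is the rule used throughout).
#'
#' @param records A data frame with at least `rsid`, `chrom`, `pos`. May
#'   contain repeated reports of the same rsid (positions must agree).
#' @param window_bp Maximum adjacent gap within a locus, in base pairs.
#'   Default 500,000.
#' @return `records` with a `locus_id` column added.
#' @export
assign_loci <- function(records, window_bp = 500000) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    records$locus_id <- character(0)
    return(records)
  }
  snps <- dplyr::distinct(records, .data$rsid, .data$chrom, .data$pos)
  if (anyDuplicated(snps$rsid) > 0) {
    dup <- unique(snps$rsid[duplicated(snps$rsid)])
    rlang::abort(paste0("rsid reported at conflicting positions: ",
                        paste(dup, collapse = ", ")),
                 class = "riskdrift_validation_error")
  }
  snps <- snps |>
    dplyr::arrange(.data$chrom, .data$pos, .data$rsid) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      new_locus = c(TRUE, diff(.data$pos) > window_bp),
      locus_id = paste0(.data$chrom, "_L", cumsum(.data$new_locus))
    ) |>
    dplyr::ungroup() |>
    dplyr::select("rsid", "locus_id")
  dplyr::left_join(records, snps, by = "rsid")
}

#' Read a pairwise LD table
#'
#' Reads a tab-separated table of pairwise squared allelic correlations
#' with columns `rsid_a`, `rsid_b`, `r2`. Values must lie in \[0, 1\];
#' the table is treated as symmetric.
#'
#' @param path Path to the LD TSV.
#' @return A tibble with columns `rsid_a`, `rsid_b`, `r2`.
#' @export
read_ld <- function(path) {
  ld <- readr::read_tsv(
    path,
    col_types = readr::cols(rsid_a = "c", rsid_b = "c", r2 = "d"),
    progress = FALSE
  )
  if (any(ld$r2 < 0 | ld$r2 > 1, na.rm = TRUE) || anyNA(ld$r2)) {
    rlang::abort("r2 values must lie in [0, 1]",
                 class = "riskdrift_validation_error")
  }
  ld
}

# Symmetric r2 lookup; absent pairs are an error, never a silent 0.
ld_r2 <- function(ld, a, b) {
  if (is.null(ld)) {
    rlang::abort("an LD table is required to prune multi-SNP loci",
                 class = "riskdrift_ld_error")
  }
  key <- paste(pmin(ld$rsid_a, ld$rsid_b), pmax(ld$rsid_a, ld$rsid_b))
  lut <- stats::setNames(ld$r2, key)
  want <- paste(pmin(a, b), pmax(a, b))
  out <- lut[want]
  if (anyNA(out)) {
    rlang::abort(paste0("missing r2 for pair(s): ",
                        paste(want[is.na(out)], collapse = "; ")),
                 class = "riskdrift_ld_error")
  }
  unname(out)
}

#' LD-prune the SNPs of one locus
#'
#' Greedy stepwise retention: SNPs are taken in order of ascending p-value
#' (ties broken by smaller position, then lexicographic rsid) and a
#' candidate is kept only if its r-squared with *every* already-kept SNP
#' is strictly below `r2_max`. Two endpoints short-circuit:
#' `r2_max <= 0` keeps only the most significant SNP, and `r2_max >= 1`
#' keeps all SNPs at the locus (no pruning), matching the usual
#' sensitivity-analysis endpoints.
#'
#' @param records Rows for a single locus, one per SNP (columns `rsid`,
#'   `pos`, `pvalue` at minimum).
#' @param ld LD table as from [read_ld()]; required when the locus has
#'   more than one SNP and `0 < r2_max < 1`. A missing pair is an error.
#' @param r2_max Retention threshold on r-squared. Default 0.75.
#' @return The retained rows, sorted by position.
#' @export
prune_locus <- function(records, ld = NULL, r2_max = 0.75) {
  records <- tibble::as_tibble(records)
  if (nrow(records) <= 1 || r2_max >= 1) {
    return(dplyr::arrange(records, .data$pos, .data$rsid))
  }
  ord <- order(records$pvalue, records$pos, records$rsid)
  recs <- records[ord, , drop = FALSE]
  if (r2_max <= 0) {
    return(recs[1, , drop = FALSE])
  }
  kept <- 1L
  for (i in seq_len(nrow(recs))[-1]) {
    r2 <- ld_r2(ld, recs$rsid[i], recs$rsid[kept])
    if (all(r2 < r2_max)) kept <- c(kept, i)
  }
  dplyr::arrange(recs[kept, , drop = FALSE], .data$pos, .data$rsid)
}

#' Build cumulative per-time-point SNP panels
#'
#' For each time point `m`, collects every catalog report dated on or
#' before `m`, reduces each rsid to its *effective* report — the one with
#' the smallest p-value so far (a strictly more significant later report
#' replaces the OR; ties keep the earlier report) — then groups SNPs into
#' loci and LD-prunes each locus. Panels are cumulative in reporting:
#' a panel never contains a SNP first reported after its date, but a SNP
#' present at one time point may be pruned away at a later one if a more
#' significant neighbour appears.
#'
#' @param catalog A catalog tibble ([as_catalog()] / [read_catalog()]).
#'   Duplicate (`rsid`, `report_date`, `source`) rows are an error.
#' @param time_points Strictly increasing `Date` vector of panel dates.
#' @param ld Optional LD table ([read_ld()]); required only for
#'   multi-SNP loci at intermediate thresholds.
#' @inheritParams prune_locus
#' @inheritParams assign_loci
#' @return A tibble of panel members with a leading `time_point` column;
#'   one row per retained SNP per time point, carrying the effective OR.
#' @examples
#' cat <- tibble::tibble(
#'   rsid = c("rs1", "rs1", "rs2"), chrom = "1",
#'   pos = c(100, 100, 2e6), risk_allele = "A",
#'   raf = c(0.3, 0.3, 0.2), or = c(1.30, 1.25, 1.15),
#'   pvalue = c(1e-9, 1e-15, 2e-8),
#'   report_date = as.Date(c("2009-06-01", "2012-06-01", "2012-01-01")),
#'   source = c("gwas09", "gwas12", "gwas12b")
#' )
#' build_panels(as_catalog(cat),
#'              as.Date(c("2009-12-31", "2013-12-31")))
#' @export
build_panels <- function(catalog, time_points, ld = NULL, r2_max = 0.75,
                         window_bp = 500000) {
  time_points <- as.Date(time_points)
  if (length(time_points) == 0 || any(diff(time_points) <= 0)) {
    rlang::abort("time_points must be a non-empty strictly increasing Date vector")
  }
  if (anyDuplicated(catalog[c("rsid", "report_date", "source")]) > 0) {
    rlang::abort("duplicate (rsid, report_date, source) rows in catalog",
                 class = "riskdrift_validation_error")
  }
  empty <- dplyr::mutate(catalog[0, ], locus_id = character(0))

  purrr::map(time_points, function(m) {
    sub <- dplyr::filter(catalog, .data$report_date <= m)
    if (nrow(sub) == 0) {
      return(dplyr::mutate(empty, time_point = as.Date(character(0)),
                           .before = 1))
    }
    eff <- sub |>
      dplyr::group_by(.data$rsid) |>
      dplyr::arrange(.data$pvalue, .data$report_date, .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
    eff <- assign_loci(eff, window_bp = window_bp)
    pruned <- eff |>
      dplyr::group_split(.data$locus_id) |>
      purrr::map(prune_locus, ld = ld, r2_max = r2_max) |>
      dplyr::bind_rows()
    pruned |>
      dplyr::arrange(.data$chrom, .data$pos, .data$rsid) |>
      dplyr::mutate(time_point = m, .before = 1)
  }) |>
    dplyr::bind_rows()
}
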