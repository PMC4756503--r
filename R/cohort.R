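#' Construct a haplotype model for one locus
#'
#' A haplotype model holds the haplotypes of a multi-SNP locus (0/1
#' vectors over the locus SNPs) together with their population
#' frequencies. It drives diplotype simulation under random mating and
#' exact enumeration of the locus genotype distribution. Frequencies may
#' be given directly, or as counts from a phased haplotype pool (which
#' bootstrapping with replacement reduces to sampling with probabilities
#' proportional to the counts).
#'
#' @param haplotypes Character vector of 0/1 strings (e.g. `"010"`), or a
#'   0/1 matrix with one row per haplotype.
#' @param frequencies Haplotype frequencies (non-negative, summing to 1
#'   within 1e-6). Exactly one of `frequencies`/`counts` must be given.
#' @param counts Haplotype counts from a phased pool; converted to
#'   frequencies.
#' @param snps Optional character vector of SNP ids naming the haplotype
#'   positions (in order).
#' @return An object of class `haplotype_model`.
#' @export
haplotype_model <- function(haplotypes, frequencies = NULL, counts = NULL,
                            snps = NULL) {
  if (is.character(haplotypes)) {
    H <- do.call(rbind, lapply(strsplit(haplotypes, ""), as.integer))
  } else {
    H <- as.matrix(haplotypes)
    storage.mode(H) <- "integer"
  }
  if (is.null(frequencies) == is.null(counts)) {
    rlang::abort("give exactly one of `frequencies` or `counts`")
  }
  if (!is.null(counts)) {
    if (any(counts < 0) || sum(counts) <= 0) {
      rlang::abort("counts must be non-negative with positive total")
    }
    frequencies <- counts / sum(counts)
  }
  if (nrow(H) == 0) rlang::abort("empty haplotype model")
  if (length(frequencies) != nrow(H)) {
    rlang::abort("one frequency per haplotype required")
  }
  if (any(frequencies < -1e-12)) rlang::abort("negative haplotype frequency")
  frequencies <- pmax(frequencies, 0)
  if (abs(sum(frequencies) - 1) > 1e-6) {
    rlang::abort("haplotype frequencies must sum to 1")
  }
  frequencies <- frequencies / sum(frequencies)
  if (any(H != 0L & H != 1L)) rlang::abort("haplotypes must be 0/1")
  if (!is.null(snps) && length(snps) != ncol(H)) {
    rlang::abort("`snps` must name every haplotype position")
  }
  structure(
    list(haplotypes = H, frequencies = as.numeric(frequencies), snps = snps),
    class = "haplotype_model"
  )
}

#' @export
print.haplotype_model <- function(x, ...) {
  cat("<haplotype_model> ", ncol(x$haplotypes), " SNP(s), ",
      nrow(x$haplotypes), " haplotype(s)\n", sep = "")
  labs <- apply(x$haplotypes, 1, paste, collapse = "")
  print(tibble::tibble(haplotype = labs, frequency = x$frequencies))
  invisible(x)
}

#' Per-SNP allele frequencies implied by a haplotype model
#'
#' @param model A [haplotype_model()].
#' @return Numeric vector of allele-1 frequencies, one per SNP.
#' @export
implied_freqs <- function(model) {
  as.numeric(crossprod(model$haplotypes, model$frequencies))
}

#' Pairwise r-squared implied by a haplotype model
#'
#' Squared allelic correlation between two SNPs of the locus, computed
#' from the haplotype frequencies (D^2 / (q_i(1-q_i) q_j(1-q_j))).
#'
#' @param model A [haplotype_model()].
#' @param i,j SNP indices within the locus.
#' @return The implied r-squared (NaN if either SNP is monomorphic).
#' @export
implied_r2 <- function(model, i = 1, j = 2) {
  q <- implied_freqs(model)
  p11 <- sum(model$frequencies[model$haplotypes[, i] == 1L &
                                 model$haplotypes[, j] == 1L])
  D <- p11 - q[i] * q[j]
  D^2 / (q[i] * (1 - q[i]) * q[j] * (1 - q[j]))
}

#' Estimate haplotype frequencies from unphased genotypes by EM
#'
#' Maximum-likelihood haplotype frequencies for one locus from unphased
#' risk-allele counts, via the classic expectation-maximisation scheme:
#' the E-step distributes each genotype over its compatible haplotype
#' pairs in proportion to current pair probabilities (Hardy-Weinberg
#' random pairing), and the M-step re-estimates frequencies from the
#' expected haplotype counts. The log-likelihood is non-decreasing across
#' iterations; iteration stops when the largest frequency change drops
#' below `tol` or after `max_iter` iterations (the latter flags the
#' result as unconverged with a warning rather than failing silently).
#'
#' Initialisation is the linkage-equilibrium product of observed allele
#' frequencies, optionally perturbed by a small symmetric jitter to
#' escape symmetric stationary points in degenerate data.
#'
#' @param geno Matrix (individuals x SNPs) of risk-allele counts in
#'   \{0, 1, 2\}; at least one individual.
#' @param tol Convergence tolerance on the frequency update. Default 1e-8.
#' @param max_iter Iteration cap. Default 1000.
#' @param jitter Magnitude of the symmetric initialisation perturbation.
#'   Default 0 (pure linkage-equilibrium start).
#' @return A [haplotype_model()] with attributes `iterations`,
#'   `converged` and `loglik`.
#' @export
em_haplotypes <- function(geno, tol = 1e-8, max_iter = 1000, jitter = 0) {
  geno <- as.matrix(geno)
  if (nrow(geno) < 1) rlang::abort("at least one individual required")
  if (!all(geno %in% c(0, 1, 2))) {
    rlang::abort("genotypes must be risk-allele counts in {0, 1, 2}")
  }
  L <- ncol(geno)
  if (L > 12) rlang::abort("locus too large for exhaustive haplotype EM")
  nh <- 2L^L
  H <- as.matrix(expand.grid(rep(list(0:1), L)))
  colnames(H) <- colnames(geno)
  storage.mode(H) <- "integer"

  # collapse identical genotype rows: EM cost then scales with distinct
  # genotype classes, not cohort size
  key <- apply(geno, 1, paste, collapse = ",")
  tab <- table(key)
  gpat <- do.call(rbind, lapply(strsplit(names(tab), ","), as.integer))
  gcount <- as.numeric(tab)
  n <- nrow(geno)

  # enumerate unordered haplotype pairs and map each to its genotype class
  ph <- which(upper.tri(matrix(0, nh, nh), diag = TRUE), arr.ind = TRUE)
  h1 <- ph[, 1]; h2 <- ph[, 2]
  psum <- H[h1, , drop = FALSE] + H[h2, , drop = FALSE]
  pkey <- apply(psum, 1, paste, collapse = ",")
  pat_of_pair <- match(pkey, names(tab))
  usable <- !is.na(pat_of_pair)
  h1 <- h1[usable]; h2 <- h2[usable]
  pat_of_pair <- pat_of_pair[usable]
  mult <- ifelse(h1 == h2, 1, 2)

  qhat <- pmin(pmax(colMeans(geno) / 2, 1e-6), 1 - 1e-6)
  f <- apply(H, 1, function(h) prod(ifelse(h == 1L, qhat, 1 - qhat)))
  if (jitter > 0) {
    j <- stats::runif(nh, -jitter, jitter)
    f <- pmax(f + j - mean(j), 1e-12)
  }
  f <- f / sum(f)

  loglik <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- mult * f[h1] * f[h2]
    # every observed genotype class has >= 1 compatible pair, so rowsum
    # covers classes 1..npat in order
    tot <- as.numeric(rowsum(w, pat_of_pair))
    loglik <- sum(gcount * log(tot))
    resp <- gcount[pat_of_pair] * w / tot[pat_of_pair]
    cnt <- numeric(nh)
    cnt_h1 <- tapply(resp, h1, sum)
    cnt[as.integer(names(cnt_h1))] <- cnt[as.integer(names(cnt_h1))] + cnt_h1
    cnt_h2 <- tapply(resp, h2, sum)
    cnt[as.integer(names(cnt_h2))] <- cnt[as.integer(names(cnt_h2))] + cnt_h2
    fnew <- cnt / (2 * n)
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    rlang::warn("EM reached max_iter without meeting tol; result flagged unconverged")
  }
  out <- haplotype_model(H, frequencies = f, snps = colnames(geno))
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  attr(out, "loglik") <- loglik
  out
}

#' Simulate cohort genotypes for a set of loci
#'
#' Draws risk-allele counts for `n` individuals at every SNP of `snps`.
#' Single-SNP loci are simulated as Binomial(2, raf) per individual
#' (Hardy-Weinberg equilibrium); multi-SNP loci draw two haplotypes
#' independently (random mating) from the locus [haplotype_model()].
#' Loci are mutually independent; the whole matrix is reproducible from
#' `seed`.
#'
#' @param snps Tibble of SNPs with columns `rsid`, `raf`, and optionally
#'   `locus_id` (absent: every SNP its own locus) and `pos` (orders SNPs
#'   within a locus).
#' @param n Cohort size.
#' @param seed Integer seed recorded on the result.
#' @param hap_models Named list of [haplotype_model()] objects keyed by
#'   `locus_id`; required for every multi-SNP locus. Model SNP names, when
#'   present, must match the locus members.
#' @return Integer matrix `n x k` of risk-allele counts with SNP rsids as
#'   column names and the seed stored in attribute `"seed"`.
#' @export
simulate_genotypes <- function(snps, n, seed = 1, hap_models = NULL) {
  snps <- tibble::as_tibble(snps)
  if (nrow(snps) == 0) rlang::abort("no SNPs to simulate")
  if (anyDuplicated(snps$rsid) > 0) rlang::abort("duplicate rsid in `snps`")
  if (!"locus_id" %in% names(snps)) snps$locus_id <- snps$rsid
  set.seed(seed)

  G <- matrix(0L, nrow = n, ncol = nrow(snps),
              dimnames = list(NULL, snps$rsid))
  for (lid in unique(snps$locus_id)) {
    idx <- which(snps$locus_id == lid)
    if ("pos" %in% names(snps)) idx <- idx[order(snps$pos[idx], snps$rsid[idx])]
    members <- snps$rsid[idx]
    model <- hap_models[[lid]]
    if (length(idx) == 1 && is.null(model)) {
      q <- snps$raf[idx]
      if (is.na(q) || q <= 0 || q >= 1) {
        rlang::abort(paste0("allele frequency outside (0, 1) for ", members))
      }
      G[, members] <- stats::rbinom(n, 2L, q)
    } else {
      if (is.null(model)) {
        rlang::abort(paste0("multi-SNP locus ", lid,
                            " requires a haplotype model"))
      }
      if (!is.null(model$snps)) {
        if (!setequal(model$snps, members)) {
          rlang::abort(paste0("haplotype model SNPs do not match locus ", lid))
        }
        ord <- match(members, model$snps)
      } else {
        if (ncol(model$haplotypes) != length(members)) {
          rlang::abort(paste0("haplotype model width does not match locus ", lid))
        }
        ord <- seq_along(members)
      }
      nh <- nrow(model$haplotypes)
      i1 <- sample.int(nh, n, replace = TRUE, prob = model$frequencies)
      i2 <- sample.int(nh, n, replace = TRUE, prob = model$frequencies)
      G[, members] <- model$haplotypes[i1, ord, drop = FALSE] +
        model$haplotypes[i2, ord, drop = FALSE]
    }
  }
  attr(G, "seed") <- seed
  G
}

#' Read haplotype fixtures for multi-SNP loci
#'
#' Reads a tab-separated file with columns `locus_id`, `haplotype`
#' (0/1 string) and either `frequency` or `count` (a phased pool), and
#' returns one [haplotype_model()] per locus.
#'
#' @param path Path to the fixture TSV.
#' @return Named list of [haplotype_model()] objects.
#' @export
read_haplotypes <- function(path) {
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(locus_id = "c", haplotype = "c",
                            .default = readr::col_double()),
    progress = FALSE
  )
  has_freq <- "frequency" %in% names(x)
  if (!has_freq && !"count" %in% names(x)) {
    rlang::abort("haplotype fixture needs a `frequency` or `count` column",
                 class = "riskdrift_format_error")
  }
  split(x, x$locus_id) |>
    lapply(function(d) {
      if (has_freq) {
        haplotype_model(d$haplotype, frequencies = d$frequency)
      } else {
        haplotype_model(d$haplotype, counts = d$count)
      }
    })
}

#' Write haplotype models to a fixture file
#'
#' @param models Named list of [haplotype_model()] objects.
#' @param path Output path.
#' @return `models`, invisibly.
#' @export
write_haplotypes <- function(models, path) {
  rows <- purrr::imap(models, function(m, id) {
    tibble::tibble(
      locus_id = id,
      haplotype = apply(m$haplotypes, 1, paste, collapse = ""),
      frequency = m$frequencies
    )
  })
  readr::write_tsv(dplyr::bind_rows(rows), path, progress = FALSE)
  invisible(models)
}
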