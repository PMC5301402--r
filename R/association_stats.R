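#' Per-population genotype counts at one SNP
#'
#' @param counts_a,counts_b integer vectors `c(n_AA, n_Aa, n_aa)` of
#'   genotype counts in populations A and B.
#' @return A 2 x 3 integer matrix of class `snp_counts` (rows = populations,
#'   columns = AA/Aa/aa).
#' @export
snp_counts <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == 3, length(counts_b) == 3,
            all(counts_a >= 0), all(counts_b >= 0))
  m <- rbind(A = counts_a, B = counts_b)
  colnames(m) <- c("n_AA", "n_Aa", "n_aa")
  structure(m, class = c("snp_counts", class(m)))
}

# Vectorized Weir-Cockerham (1984) variance components for r = 2
# populations. Inputs are parallel vectors of genotype counts; returns the
# among-population (a), among-individual-within-population (b) and
# within-individual (c) components plus theta = a/(a+b+c).
wc_components <- function(nAA1, nAa1, naa1, nAA2, nAa2, naa2) {
  n1 <- nAA1 + nAa1 + naa1
  n2 <- nAA2 + nAa2 + naa2
  p1 <- (2 * nAA1 + nAa1) / (2 * n1)
  p2 <- (2 * nAA2 + nAa2) / (2 * n2)
  h1 <- nAa1 / n1
  h2 <- nAa2 / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  bad <- n1 < 1 | n2 < 1 | nbar <= 1
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  theta <- ifelse(!bad & denom != 0, a / denom, NA_real_)
  list(a = a, b = b, c = cc, theta = theta,
       defined = !bad & denom != 0)
}

#' Weir-Cockerham Fst estimator for two populations
#'
#' Computes the 1984 analysis-of-variance components at one biallelic SNP:
#' `a` (among populations), `b` (among individuals within populations) and
#' `c` (within individuals), and the fixation-index estimate
#' `theta = a / (a + b + c)`. The estimate is undefined (`defined = FALSE`)
#' when the components sum to zero (monomorphic SNP) or when the mean sample
#' size is at most one individual.
#'
#' @param counts a [snp_counts()] matrix (or any 2 x 3 matrix of genotype
#'   counts, rows = populations, columns = AA/Aa/aa).
#' @return list with `a`, `b`, `c`, `theta`, `defined`.
#' @export
weir_cockerham_fst <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 2, ncol(counts) == 3, all(counts >= 0))
  res <- wc_components(counts[1, 1], counts[1, 2], counts[1, 3],
                       counts[2, 1], counts[2, 2], counts[2, 3])
  lapply(res, unname)
}

# Two-sided Fisher exact p for a 2x2 table [[a, b], [c, d]], PLINK
# convention: sum of hypergeometric probabilities of tables (with the same
# margins) whose probability does not exceed the observed one, with a 1e-7
# relative slack for floating-point ties. Vectorized over tables.
fisher2x2 <- function(a, b, c, d) {
  n <- length(a)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]            # row 1 margin
    m2 <- c[i] + d[i]            # row 2 margin
    k  <- a[i] + c[i]            # column 1 margin
    if (m1 == 0 || m2 == 0 || k == 0 || (b[i] + d[i]) == 0) {
      p[i] <- 1
      next
    }
    lo <- max(0, k - m2)
    hi <- min(k, m1)
    pr <- stats::dhyper(lo:hi, m1, m2, k)
    p_obs <- pr[a[i] - lo + 1]
    p[i] <- min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  }
  p
}

#' Fisher's exact allelic test
#'
#' Builds the 2 x 2 allele-count table (rows = populations, columns =
#' alleles, entries `2 * n_hom + n_het`) and returns the two-sided exact
#' p-value: the sum of hypergeometric probabilities of all tables with the
#' same margins whose probability does not exceed that of the observed table
#' (with a 1e-7 relative slack for ties). A zero margin (an allele absent
#' everywhere) gives p = 1 by convention.
#'
#' @inheritParams weir_cockerham_fst
#' @return two-sided p-value in (0, 1].
#' @export
fisher_allelic_test <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 2, ncol(counts) == 3, all(counts >= 0))
  fisher2x2(2 * counts[1, 1] + counts[1, 2], 2 * counts[1, 3] + counts[1, 2],
            2 * counts[2, 1] + counts[2, 2], 2 * counts[2, 3] + counts[2, 2])
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional on the sample size and the minor-allele count, sums the
#' probabilities of all heterozygote counts whose conditional probability
#' does not exceed that of the observed count (two-sided exact test, the
#' test behind PLINK's `--hwe`). Monomorphic samples give p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("no individuals")
  n_minor <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_minor == 0) return(1)
  # possible heterozygote counts share the parity of the minor-allele count
  het <- seq(n_minor %% 2, n_minor, by = 2)
  hom_min <- (n_minor - het) / 2
  hom_maj <- n - het - hom_min
  logp <- lfactorial(n) - lfactorial(hom_min) - lfactorial(het) -
    lfactorial(hom_maj) + het * log(2) +
    lfactorial(n_minor) + lfactorial(2 * n - n_minor) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, het)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Pearson chi-square test on a contingency table
#'
#' Classic Pearson statistic `sum((O - E)^2 / E)` with
#' `df = (R - 1)(C - 1)` and an upper-tail chi-square p-value. Rows or
#' columns with a zero margin are dropped (with a warning) before the
#' statistic and degrees of freedom are computed.
#'
#' @param table a numeric matrix of non-negative counts.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0))
  rz <- rowSums(table) == 0
  cz <- colSums(table) == 0
  if (any(rz) || any(cz)) {
    warning("dropping ", sum(rz), " zero row(s) and ", sum(cz),
            " zero column(s) before the chi-square test")
    table <- table[!rz, !cz, drop = FALSE]
  }
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("need at least 2 non-zero rows and columns")
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  statistic <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE))
}

#' Genomic inflation factor
#'
#' The median of the observed 1-df chi-square statistics divided by the
#' median of the chi-square(1) distribution (0.4549364...). P-values are
#' converted to chi-square quantiles first. A well-calibrated scan has
#' lambda near 1; confounding inflates it.
#'
#' @param p p-values (converted via the upper-tail chi-square(1) quantile).
#' @param chi2 alternatively, 1-df chi-square statistics.
#' @return lambda, a positive scalar.
#' @export
genomic_inflation <- function(p = NULL, chi2 = NULL) {
  if (is.null(chi2)) {
    if (is.null(p)) stop("supply p-values or chi-square statistics")
    chi2 <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  }
  chi2 <- chi2[is.finite(chi2)]
  if (length(chi2) == 0) stop("no finite values")
  stats::median(chi2) / stats::qchisq(0.5, df = 1)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

# Genotype-class counts per population for every marker.
# Returns a list of 6 integer vectors aligned to the marker map.
pop_genotype_counts <- function(dataset) {
  ia <- dataset$samples$population == "A"
  ga <- dataset$genotypes[ia, , drop = FALSE]
  gb <- dataset$genotypes[!ia, , drop = FALSE]
  list(nAA1 = colSums(ga == 0, na.rm = TRUE),
       nAa1 = colSums(ga == 1, na.rm = TRUE),
       naa1 = colSums(ga == 2, na.rm = TRUE),
       nAA2 = colSums(gb == 0, na.rm = TRUE),
       nAa2 = colSums(gb == 1, na.rm = TRUE),
       naa2 = colSums(gb == 2, na.rm = TRUE))
}

new_assoc_track <- function(dataset, value, statistic) {
  structure(data.frame(marker_id = dataset$markers$id,
                       chrom = dataset$markers$chrom,
                       pos_bp = dataset$markers$pos_bp,
                       value = value, stringsAsFactors = FALSE),
            statistic = statistic, class = c("assoc_track", "data.frame"))
}

#' Per-SNP Weir-Cockerham Fst track
#'
#' Applies [weir_cockerham_fst()] at every marker. Fst is computed for
#' autosomes only; X-chromosome markers get `NA`. Markers with no observed
#' genotypes in one population get `NA` with a warning.
#'
#' @param dataset a QC'd two-population [geno_dataset()].
#' @return a data.frame track (class `assoc_track`) with columns
#'   `marker_id`, `chrom`, `pos_bp`, `value`; attribute `statistic = "fst"`.
#' @export
fst_track <- function(dataset) {
  check_two_pops(dataset)
  ct <- pop_genotype_counts(dataset)
  res <- wc_components(ct$nAA1, ct$nAa1, ct$naa1, ct$nAA2, ct$nAa2, ct$naa2)
  theta <- res$theta
  empty <- (ct$nAA1 + ct$nAa1 + ct$naa1 == 0) |
           (ct$nAA2 + ct$nAa2 + ct$naa2 == 0)
  if (any(empty & is_autosome(dataset$markers$chrom)))
    warning(sum(empty), " marker(s) with all genotypes missing in one ",
            "population: Fst set to NA")
  theta[!is_autosome(dataset$markers$chrom)] <- NA_real_
  new_assoc_track(dataset, theta, "fst")
}

#' Per-SNP Fisher exact allelic test track
#'
#' Applies [fisher_allelic_test()] at every marker (all chromosomes).
#'
#' @inheritParams fst_track
#' @return an `assoc_track` with attribute `statistic = "fisher_p"`.
#' @export
fisher_track <- function(dataset) {
  check_two_pops(dataset)
  ct <- pop_genotype_counts(dataset)
  empty <- (ct$nAA1 + ct$nAa1 + ct$naa1 == 0) |
           (ct$nAA2 + ct$nAa2 + ct$naa2 == 0)
  p <- rep(NA_real_, n_markers(dataset))
  if (any(empty))
    warning(sum(empty), " marker(s) with all genotypes missing in one ",
            "population: Fisher p set to NA")
  ok <- !empty
  p[ok] <- fisher2x2(2 * ct$nAA1[ok] + ct$nAa1[ok],
                     2 * ct$naa1[ok] + ct$nAa1[ok],
                     2 * ct$nAA2[ok] + ct$nAa2[ok],
                     2 * ct$naa2[ok] + ct$nAa2[ok])
  new_assoc_track(dataset, p, "fisher_p")
}

check_two_pops <- function(dataset) {
  tb <- table(dataset$samples$population)
  if (length(tb) < 2 || any(tb == 0))
    stop("both populations must be non-empty")
  invisible(NULL)
}

#' Write an association track as TSV
#'
#' @param track an `assoc_track`.
#' @param path output path.
#' @export
write_track <- function(track, path) {
  out <- as.data.frame(track)
  names(out)[names(out) == "value"] <- attr(track, "statistic")
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(NULL)
}
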