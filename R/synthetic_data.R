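#' Simulation configuration
#'
#' Describes a two-population SNP-array experiment under the
#' Balding-Nichols divergence model: each locus has an ancestral frequency
#' `p0 ~ Uniform(0.05, 0.95)`; each population's frequency is drawn from
#' `Beta(p0 (1 - F) / F, (1 - p0)(1 - F) / F)`, so loci diverge with
#' expected Fst of about `F`. Neutral loci use `f_background`; loci inside
#' a planted region use that region's `f_selected`. Genotypes are binomial
#' (Hardy-Weinberg within population); optional full-sib pairs create
#' within-cohort relatedness; missingness is i.i.d.
#'
#' @param n_pop_a,n_pop_b cohort sizes (defaults 41 and 141, a typical
#'   local-breed versus improved-strain design).
#' @param n_chrom number of chromosomes.
#' @param markers_per_chrom markers per chromosome.
#' @param chrom_length_bp chromosome length (positions are uniform).
#' @param f_background Balding-Nichols F for neutral loci.
#' @param planted_regions data.frame with columns `chrom`, `start_bp`,
#'   `end_bp` and optionally `f_selected` (default 0.5), or NULL.
#' @param missing_rate i.i.d. genotype missingness.
#' @param n_sib_pairs full-sib pairs per population (replacing unrelated
#'   individuals).
#' @param include_x when TRUE the last chromosome is labeled "X".
#' @param seed RNG seed; simulation is deterministic given the config.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_pop_a = 41, n_pop_b = 141, n_chrom = 5,
                       markers_per_chrom = 1000, chrom_length_bp = 100e6,
                       f_background = 0.05, planted_regions = NULL,
                       missing_rate = 0.01, n_sib_pairs = 0,
                       include_x = FALSE, seed = 1) {
  stopifnot(n_pop_a >= 1, n_pop_b >= 1, n_chrom >= 1,
            markers_per_chrom >= 1, chrom_length_bp >= markers_per_chrom,
            f_background >= 0, f_background < 1,
            missing_rate >= 0, missing_rate < 1,
            n_sib_pairs >= 0, 2 * n_sib_pairs <= min(n_pop_a, n_pop_b))
  chroms <- as.character(seq_len(n_chrom))
  if (include_x) chroms[n_chrom] <- "X"
  if (!is.null(planted_regions)) {
    planted_regions <- as.data.frame(planted_regions)
    if (!"f_selected" %in% names(planted_regions))
      planted_regions$f_selected <- 0.5
    planted_regions$chrom <- as.character(planted_regions$chrom)
    stopifnot(all(planted_regions$f_selected >= 0),
              all(planted_regions$f_selected < 1),
              all(planted_regions$chrom %in% chroms),
              all(planted_regions$start_bp >= 1),
              all(planted_regions$end_bp <= chrom_length_bp),
              all(planted_regions$start_bp <= planted_regions$end_bp))
  }
  structure(list(n_pop_a = n_pop_a, n_pop_b = n_pop_b, n_chrom = n_chrom,
                 chroms = chroms, markers_per_chrom = markers_per_chrom,
                 chrom_length_bp = chrom_length_bp,
                 f_background = f_background,
                 planted_regions = planted_regions,
                 missing_rate = missing_rate, n_sib_pairs = n_sib_pairs,
                 include_x = include_x, seed = seed), class = "sim_config")
}

#' Study-scale default simulation
#'
#' A configuration at the scale of a two-breed 50K ovine SNP-array study: cohorts
#' of 41 and 141 diploid individuals, 26 autosomes plus X carrying 1,724
#' markers each (46,548 in total, within 1% of a 46,563-SNP post-QC
#' panel), background divergence F = 0.05, 1% missingness, and ten
#' planted 2-Mb regions at F = 0.5 on autosomes 1-10.
#'
#' @param seed RNG seed.
#' @return a [sim_config()].
#' @export
default_study_config <- function(seed = 1) {
  planted <- data.frame(
    chrom = as.character(1:10),
    start_bp = (seq(15, 60, by = 5)) * 1e6,
    end_bp = (seq(15, 60, by = 5)) * 1e6 + 2e6,
    f_selected = 0.5)
  sim_config(n_pop_a = 41, n_pop_b = 141, n_chrom = 27,
             markers_per_chrom = 1724, chrom_length_bp = 100e6,
             f_background = 0.05, planted_regions = planted,
             missing_rate = 0.01, n_sib_pairs = 0, include_x = TRUE,
             seed = seed)
}

# Drop one diploid offspring from two parent dosage vectors: each parent
# transmits one allele, heterozygotes at random.
gene_drop_child <- function(par1, par2) {
  stats::rbinom(length(par1), 1, par1 / 2) +
    stats::rbinom(length(par2), 1, par2 / 2)
}

# Genotypes for one population: n unrelated individuals, the last
# 2 * n_sib pairs replaced by full sibs gene-dropped from simulated parents.
simulate_pop <- function(n, p, n_sib) {
  m <- length(p)
  g <- matrix(stats::rbinom(n * m, 2, rep(p, each = n)), n, m)
  if (n_sib > 0) {
    for (k in seq_len(n_sib)) {
      par1 <- stats::rbinom(m, 2, p)
      par2 <- stats::rbinom(m, 2, p)
      i <- n - 2 * n_sib + 2 * k - 1
      g[i, ] <- gene_drop_child(par1, par2)
      g[i + 1, ] <- gene_drop_child(par1, par2)
    }
  }
  g
}

#' Simulate a two-population dataset with planted divergent regions
#'
#' Draws marker positions, ancestral and population allele frequencies,
#' genotypes, relatedness and missingness as described in [sim_config()],
#' and returns both the dataset and the ground truth needed for recovery
#' scoring. Dosages count the "B" allele, whose population frequency is the
#' Balding-Nichols draw.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a [geno_dataset()]) and `truth` (class
#'   `sim_truth`: planted `regions` plus per-locus `loci` table with
#'   `marker_id`, `chrom`, `pos_bp`, `F`, `p0`, `p_a`, `p_b`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- config$chroms
  pos <- lapply(chroms, function(ch)
    sort(sample.int(config$chrom_length_bp, config$markers_per_chrom)))
  map <- data.frame(
    chrom = rep(chroms, each = config$markers_per_chrom),
    pos_bp = unlist(pos), stringsAsFactors = FALSE)
  map$id <- paste0("snp_", map$chrom, "_", map$pos_bp)
  m <- nrow(map)

  Fv <- rep(config$f_background, m)
  pr <- config$planted_regions
  if (!is.null(pr) && nrow(pr) > 0) {
    for (i in seq_len(nrow(pr))) {
      inside <- map$chrom == pr$chrom[i] & map$pos_bp >= pr$start_bp[i] &
        map$pos_bp <= pr$end_bp[i]
      if (!any(inside))
        warning("planted region ", i, " (", pr$chrom[i], ":",
                pr$start_bp[i], "-", pr$end_bp[i], ") contains no marker")
      Fv[inside] <- pr$f_selected[i]
    }
  }

  p0 <- stats::runif(m, 0.05, 0.95)
  draw_pop_freq <- function() {
    p <- p0
    div <- Fv > 0
    if (any(div)) {
      shape_scale <- (1 - Fv[div]) / Fv[div]
      p[div] <- stats::rbeta(sum(div), p0[div] * shape_scale,
                             (1 - p0[div]) * shape_scale)
    }
    p
  }
  p_a <- draw_pop_freq()
  p_b <- draw_pop_freq()

  ga <- simulate_pop(config$n_pop_a, p_a, config$n_sib_pairs)
  gb <- simulate_pop(config$n_pop_b, p_b, config$n_sib_pairs)
  g <- rbind(ga, gb)
  if (config$missing_rate > 0)
    g[stats::runif(length(g)) < config$missing_rate] <- NA_integer_

  samples <- data.frame(
    id = c(sprintf("A_%03d", seq_len(config$n_pop_a)),
           sprintf("B_%03d", seq_len(config$n_pop_b))),
    population = rep(c("A", "B"), c(config$n_pop_a, config$n_pop_b)),
    stringsAsFactors = FALSE)
  markers <- data.frame(id = map$id, chrom = map$chrom, pos_bp = map$pos_bp,
                        allele_a = "A", allele_b = "B",
                        stringsAsFactors = FALSE)
  dataset <- geno_dataset(g, markers, samples)

  loci <- data.frame(marker_id = map$id, chrom = map$chrom,
                     pos_bp = map$pos_bp, F = Fv, p0 = p0,
                     p_a = p_a, p_b = p_b, stringsAsFactors = FALSE)
  # geno_dataset sorts markers by (chrom, pos); align the truth table
  loci <- loci[match(dataset$markers$id, loci$marker_id), , drop = FALSE]
  rownames(loci) <- NULL
  regions <- if (is.null(pr)) {
    data.frame(chrom = character(), start_bp = numeric(),
               end_bp = numeric(), f_selected = numeric())
  } else pr
  truth <- structure(list(regions = regions, loci = loci),
                     class = "sim_truth")
  list(dataset = dataset, truth = truth)
}
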