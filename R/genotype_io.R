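#' Construct a genotype dataset
#'
#' The central container of the package: a dosage matrix over two labeled
#' cohorts plus its marker map. Dosages count copies of `allele_b` (the
#' lexicographically larger observed allele when read from PED/MAP), so every
#' non-missing entry is 0, 1 or 2; missing genotypes are `NA`.
#'
#' @param genotypes integer matrix, samples in rows, markers in columns;
#'   values in \{0, 1, 2, NA\}.
#' @param markers data.frame with columns `id`, `chrom`, `pos_bp`,
#'   `allele_a`, `allele_b`; one row per matrix column, sorted by
#'   (chromosome, position).
#' @param samples data.frame with columns `id`, `population` (factor or
#'   character with levels "A"/"B") and optionally `sex`.
#' @return An object of class `geno_dataset`.
#' @export
geno_dataset <- function(genotypes, markers, samples) {
  genotypes <- as.matrix(genotypes)
  stopifnot(is.data.frame(markers), is.data.frame(samples))
  if (ncol(genotypes) != nrow(markers))
    stop("genotype matrix has ", ncol(genotypes), " columns but ",
         nrow(markers), " markers")
  if (nrow(genotypes) != nrow(samples))
    stop("genotype matrix has ", nrow(genotypes), " rows but ",
         nrow(samples), " samples")
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype values must be 0, 1, 2 or NA")
  if (anyDuplicated(markers$id))
    stop("duplicated marker ids: ",
         paste(unique(markers$id[duplicated(markers$id)]), collapse = ", "))
  if (any(markers$pos_bp < 1)) stop("marker positions must be >= 1")
  markers$chrom <- as.character(markers$chrom)
  samples$population <- as.character(samples$population)
  # enforce (chrom, pos) sort order
  o <- order(chrom_rank(markers$chrom), markers$chrom, markers$pos_bp)
  if (!identical(o, seq_len(nrow(markers)))) {
    markers <- markers[o, , drop = FALSE]
    genotypes <- genotypes[, o, drop = FALSE]
  }
  ddup <- duplicated(paste(markers$chrom, markers$pos_bp))
  if (any(ddup))
    stop("duplicate marker position on chromosome ",
         markers$chrom[ddup][1], " at ", markers$pos_bp[ddup][1])
  rownames(markers) <- NULL
  dimnames(genotypes) <- list(samples$id, markers$id)
  structure(list(genotypes = genotypes, markers = markers, samples = samples),
            class = "geno_dataset")
}

#' @export
print.geno_dataset <- function(x, ...) {
  cat("geno_dataset:", nrow(x$samples), "samples x",
      nrow(x$markers), "markers\n")
  tb <- table(x$samples$population)
  cat("  populations:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  cat("  chromosomes:", length(unique(x$markers$chrom)), "\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

n_markers <- function(dataset) nrow(dataset$markers)
n_samples <- function(dataset) nrow(dataset$samples)

# Sort key for chromosome labels: numeric chromosomes in order, then X etc.
chrom_rank <- function(chrom) {
  n <- suppressWarnings(as.numeric(chrom))
  ifelse(is.na(n), Inf, n)
}

# Autosome = chromosome with a purely numeric label.
is_autosome <- function(chrom) is.finite(chrom_rank(chrom))

#' Read PLINK text genotypes (PED/MAP)
#'
#' Parses the whitespace-delimited PLINK text dialect. The MAP file carries
#' four columns (chromosome, marker id, genetic position, bp position); the
#' PED file carries six mandatory columns (family, individual, father,
#' mother, sex, phenotype) followed by two allele columns per marker, with
#' "0" denoting a missing allele. The counted allele (`allele_b`) is the
#' lexicographically larger of the two alleles observed at the marker, a
#' deterministic choice on which the downstream Fst and Fisher statistics do
#' not depend. A genotype with one missing allele is treated as missing.
#' The PED phenotype column assigns populations: 2 maps to "B", anything
#' else to "A".
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return A [geno_dataset()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map) != 4)
    stop("MAP file must have 4 columns, found ", ncol(map))
  markers <- data.frame(id = map[[2]], chrom = map[[1]],
                        pos_bp = as.integer(map[[4]]),
                        allele_a = NA_character_, allele_b = NA_character_,
                        stringsAsFactors = FALSE)
  m <- nrow(markers)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  ns <- length(lines)
  a1 <- matrix("0", ns, m)
  a2 <- matrix("0", ns, m)
  meta <- vector("list", ns)
  for (i in seq_len(ns)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * m)
      stop("malformed PED row at line ", i, ": expected ", 6 + 2 * m,
           " fields (", 2 * m, " alleles), found ", length(tok))
    meta[[i]] <- tok[1:6]
    if (m > 0) {
      al <- tok[-(1:6)]
      a1[i, ] <- al[seq(1, 2 * m, by = 2)]
      a2[i, ] <- al[seq(2, 2 * m, by = 2)]
    }
  }
  meta <- do.call(rbind, meta)
  samples <- data.frame(id = meta[, 2],
                        population = ifelse(meta[, 6] == "2", "B", "A"),
                        sex = meta[, 5], stringsAsFactors = FALSE)

  geno <- matrix(NA_integer_, ns, m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs <- sort(unique(c(x1[!miss], x2[!miss])))
    if (length(obs) > 2)
      stop("more than two alleles at marker ", markers$id[j], ": ",
           paste(obs, collapse = "/"))
    if (length(obs) == 0) {
      markers$allele_a[j] <- "0"; markers$allele_b[j] <- "0"
      next
    }
    if (length(obs) == 1) {
      # monomorphic: the single observed allele is allele_a, dosage 0
      markers$allele_a[j] <- obs; markers$allele_b[j] <- "0"
      geno[!miss, j] <- 0L
      next
    }
    markers$allele_a[j] <- obs[1]; markers$allele_b[j] <- obs[2]
    geno[!miss, j] <- (x1[!miss] == obs[2]) + (x2[!miss] == obs[2])
  }
  geno_dataset(geno, markers, samples)
}

#' Write PLINK text genotypes (PED/MAP)
#'
#' Inverse of [read_ped_map()]: missing genotypes become "0 0", populations
#' are encoded in the PED phenotype column (A = 1, B = 2) and the family id
#' column repeats the population label. Files are re-readable by
#' [read_ped_map()] and by PLINK.
#'
#' @param dataset a [geno_dataset()].
#' @param ped_path,map_path output paths.
#' @export
write_ped_map <- function(dataset, ped_path, map_path) {
  mk <- dataset$markers
  utils::write.table(
    data.frame(mk$chrom, mk$id, rep(0, nrow(mk)), mk$pos_bp),
    map_path, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)

  sm <- dataset$samples
  sex <- if ("sex" %in% names(sm)) as.character(sm$sex) else rep("0", nrow(sm))
  sex[is.na(sex) | sex == ""] <- "0"
  pheno <- ifelse(sm$population == "B", "2", "1")
  g <- dataset$genotypes
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(sm))) {
    fields <- c(sm$population[i], sm$id[i], "0", "0", sex[i], pheno[i])
    if (nrow(mk) > 0) {
      gi <- g[i, ]
      x1 <- ifelse(is.na(gi), "0", ifelse(gi >= 1, mk$allele_b, mk$allele_a))
      x2 <- ifelse(is.na(gi), "0", ifelse(gi == 2, mk$allele_b, mk$allele_a))
      fields <- c(fields, as.vector(rbind(x1, x2)))
    }
    writeLines(paste(fields, collapse = " "), con)
  }
  invisible(NULL)
}

#' Marker quality-control parameters
#'
#' Mirrors the PLINK flags `--geno` (maximum per-marker missing rate),
#' `--maf` (minimum minor allele frequency) and `--hwe` (exact
#' Hardy-Weinberg p-value threshold). `hwe_population` selects the sample
#' set on which the HWE test runs: the pooled cohorts, each cohort
#' separately (a marker fails if either cohort fails), or cohort A alone
#' (PLINK's controls-only behaviour when the phenotype is case/control).
#'
#' @param max_missing_rate maximum fraction of missing genotypes per marker.
#' @param min_maf minimum minor allele frequency (pooled, non-missing).
#' @param hwe_alpha markers with exact HWE p below this are removed.
#' @param hwe_population one of "pooled", "per_population",
#'   "population_A_only".
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(max_missing_rate = 0.1, min_maf = 0.05,
                      hwe_alpha = 0.001,
                      hwe_population = c("pooled", "per_population",
                                         "population_A_only")) {
  hwe_population <- match.arg(hwe_population)
  stopifnot(max_missing_rate >= 0, max_missing_rate <= 1,
            min_maf >= 0, min_maf <= 1, hwe_alpha >= 0, hwe_alpha <= 1)
  structure(list(max_missing_rate = max_missing_rate, min_maf = min_maf,
                 hwe_alpha = hwe_alpha, hwe_population = hwe_population),
            class = "qc_params")
}

#' Apply marker quality control
#'
#' Removes markers sequentially by (1) missing-genotype rate above
#' `max_missing_rate`, (2) pooled minor allele frequency below `min_maf`,
#' (3) exact Hardy-Weinberg p-value below `hwe_alpha`. Samples are never
#' removed and marker order is preserved. Each marker is charged to the
#' first filter it fails, so the per-filter counts sum to
#' `n_input - n_pass`.
#'
#' @param dataset a [geno_dataset()].
#' @param params a [qc_params()] object.
#' @return list with elements `dataset` (filtered) and `report` (class
#'   `qc_report`: `n_input`, `n_pass`, per-filter counts, removed marker
#'   table).
#' @export
apply_qc <- function(dataset, params = qc_params()) {
  g <- dataset$genotypes
  m <- n_markers(dataset)
  keep <- rep(TRUE, m)
  reason <- rep(NA_character_, m)

  miss_rate <- colMeans(is.na(g))
  fail <- keep & miss_rate > params$max_missing_rate
  reason[fail] <- "missingness"; keep[fail] <- FALSE

  dose_sum <- colSums(g, na.rm = TRUE)
  n_obs <- colSums(!is.na(g))
  p_b <- ifelse(n_obs > 0, dose_sum / (2 * n_obs), 0)
  maf <- pmin(p_b, 1 - p_b)
  maf[n_obs == 0] <- 0
  fail <- keep & maf < params$min_maf
  reason[fail] <- "maf"; keep[fail] <- FALSE

  idx <- which(keep)
  if (length(idx) > 0) {
    hwe_sets <- switch(params$hwe_population,
      pooled = list(seq_len(nrow(g))),
      per_population = list(which(dataset$samples$population == "A"),
                            which(dataset$samples$population == "B")),
      population_A_only = list(which(dataset$samples$population == "A")))
    hwe_p <- rep(1, length(idx))
    for (rows in hwe_sets) {
      sub <- g[rows, idx, drop = FALSE]
      nAA <- colSums(sub == 0, na.rm = TRUE)
      nAa <- colSums(sub == 1, na.rm = TRUE)
      naa <- colSums(sub == 2, na.rm = TRUE)
      p_set <- vapply(seq_along(idx), function(k)
        hwe_exact_test(nAA[k], nAa[k], naa[k]), numeric(1))
      hwe_p <- pmin(hwe_p, p_set)
    }
    fail_idx <- idx[hwe_p < params$hwe_alpha]
    reason[fail_idx] <- "hwe"; keep[fail_idx] <- FALSE
  }

  if (!any(keep)) warning("all markers removed by QC")
  removed <- data.frame(marker_id = dataset$markers$id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  report <- structure(list(
    n_input = m, n_pass = sum(keep),
    n_missingness = sum(removed$reason == "missingness"),
    n_maf = sum(removed$reason == "maf"),
    n_hwe = sum(removed$reason == "hwe"),
    removed = removed, params = params), class = "qc_report")
  out <- dataset
  out$genotypes <- dataset$genotypes[, keep, drop = FALSE]
  out$markers <- dataset$markers[keep, , drop = FALSE]
  rownames(out$markers) <- NULL
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Marker QC:", x$n_input, "in,", x$n_pass, "pass\n")
  cat("  removed: missingness", x$n_missingness,
      "| maf", x$n_maf, "| hwe", x$n_hwe, "\n")
  invisible(x)
}
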