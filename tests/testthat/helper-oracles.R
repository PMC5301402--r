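# Independent oracles used across the suite. Each reimplements the checked
# quantity from first principles by a different route than the package code.

# Weir-Cockerham (1984) theta, transcribed directly from the published
# component formulas for r populations (loops, no vectorization; shares no
# code with the package implementation).
wc_fst_oracle <- function(counts) {
  counts <- as.matrix(counts)
  r <- nrow(counts)
  n <- rowSums(counts)
  p <- (2 * counts[, 1] + counts[, 2]) / (2 * n)
  h <- counts[, 2] / n
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
    ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(list(theta = NA_real_, defined = FALSE))
  list(theta = a / (a + b + cc), defined = TRUE, a = a, b = b, c = cc)
}

# Two-sided Fisher exact p for a 2x2 table by exhaustive enumeration over
# all tables with the observed margins; probabilities from log-binomial
# coefficients (not dhyper).
fisher_enum_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, support) + lchoose(m2, k - support) - lchoose(m1 + m2, k)
  pr <- exp(logp)
  p_obs <- pr[match(a, support)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# Exact HWE p by enumeration of every genotype configuration with the
# observed sample size and allele count; probabilities from factorials.
hwe_enum_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  if (nA == 0 || nA == 2 * n) return(1)
  hets <- Filter(function(h) (nA - h) %% 2 == 0 && h <= nA && h <= 2 * n - nA,
                 0:n)
  pr <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) - (lfactorial(2 * n) - lfactorial(nA) -
                          lfactorial(2 * n - nA)))
  }, numeric(1))
  p_obs <- pr[match(nAa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# Literal reapplication of the peak-extension region rule: seeds, window
# neighbors, interval construction, pairwise merge to fixpoint.
call_regions_oracle <- function(track, n_top, secondary_fraction, window_bp,
                                direction = "desc") {
  v <- track$value
  ok <- which(is.finite(v))
  key <- if (direction == "desc") -v else v
  o <- ok[order(key[ok], track$chrom[ok], track$pos_bp[ok])]
  # tie-break by genome position: chrom rank numeric then pos
  cr <- suppressWarnings(as.numeric(track$chrom))
  cr[is.na(cr)] <- Inf
  o <- ok[order(key[ok], cr[ok], track$chrom[ok], track$pos_bp[ok])]
  ranks <- rep(NA_integer_, length(v))
  ranks[o] <- seq_along(o)
  n_ranked <- length(o)
  t1 <- which(!is.na(ranks) & ranks <= min(n_top, n_ranked))
  t2 <- which(!is.na(ranks) & ranks <= ceiling(secondary_fraction * n_ranked))
  regs <- lapply(t1, function(s) {
    nb <- t2[track$chrom[t2] == track$chrom[s] &
               abs(track$pos_bp[t2] - track$pos_bp[s]) <= window_bp]
    mem <- sort(unique(c(s, nb)))
    list(chrom = track$chrom[s], start = min(track$pos_bp[mem]),
         end = max(track$pos_bp[mem]), members = mem)
  })
  # merge any overlapping pair until none remain
  repeat {
    merged <- FALSE
    for (i in seq_along(regs)) {
      for (j in seq_along(regs)) {
        if (i >= j) next
        ri <- regs[[i]]; rj <- regs[[j]]
        if (ri$chrom == rj$chrom && ri$start <= rj$end && rj$start <= ri$end) {
          regs[[i]] <- list(chrom = ri$chrom,
                            start = min(ri$start, rj$start),
                            end = max(ri$end, rj$end),
                            members = sort(unique(c(ri$members, rj$members))))
          regs[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  out <- do.call(rbind, lapply(regs, function(r) {
    peak <- r$members[which.min(ranks[r$members])]
    data.frame(chrom = r$chrom, start_bp = r$start, end_bp = r$end,
               peak_marker_id = track$marker_id[peak],
               stringsAsFactors = FALSE)
  }))
  out[order(cr[match(out$chrom, track$chrom)], out$chrom, out$start_bp), ,
      drop = FALSE]
}

# Small hand-buildable dataset: genotype matrix plus uniform map.
toy_dataset <- function(genotypes, populations,
                        chrom = rep("1", ncol(genotypes)),
                        pos = seq_len(ncol(genotypes)) * 1000L) {
  m <- ncol(genotypes)
  geno_dataset(genotypes,
               markers = data.frame(id = paste0("m", seq_len(m),
                                                recycle0 = TRUE),
                                    chrom = chrom, pos_bp = pos,
                                    allele_a = rep("A", m),
                                    allele_b = rep("G", m),
                                    stringsAsFactors = FALSE),
               samples = data.frame(id = paste0("s", seq_len(nrow(genotypes))),
                                    population = populations,
                                    stringsAsFactors = FALSE))
}

random_snp_counts <- function(max_n = 60) {
  n1 <- sample(2:max_n, 1)
  n2 <- sample(2:max_n, 1)
  p1 <- runif(1, 0.05, 0.95)
  p2 <- runif(1, 0.05, 0.95)
  g1 <- tabulate(rbinom(n1, 2, p1) + 1, 3)
  g2 <- tabulate(rbinom(n2, 2, p2) + 1, 3)
  snp_counts(g1, g2)
}

make_track <- function(value, chrom, pos, statistic = "fst") {
  structure(data.frame(marker_id = paste0("m", seq_along(value)),
                       chrom = as.character(chrom), pos_bp = pos,
                       value = value, stringsAsFactors = FALSE),
            statistic = statistic, class = c("assoc_track", "data.frame"))
}
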