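#' Identity-by-state kinship matrix
#'
#' For every pair of individuals, the mean over markers non-missing in both
#' of `(2 - |g_i - g_j|) / 2`, i.e. the average fraction of alleles shared
#' by state. Computed with cross-products over indicator matrices so it
#' scales to array-sized marker panels. The diagonal is 1 by construction.
#'
#' @param dataset a QC'd [geno_dataset()].
#' @param chromosomes `"autosomes"` (default, the usual kinship convention)
#'   or `"all"`.
#' @return an n x n symmetric matrix with sample ids as dimnames.
#' @export
ibs_kinship <- function(dataset, chromosomes = c("autosomes", "all")) {
  chromosomes <- match.arg(chromosomes)
  g <- dataset$genotypes
  if (chromosomes == "autosomes")
    g <- g[, is_autosome(dataset$markers$chrom), drop = FALSE]
  if (ncol(g) == 0) stop("no markers available for kinship")
  pres <- !is.na(g)
  storage.mode(pres) <- "double"
  n_pair <- tcrossprod(pres)
  if (any(n_pair == 0)) {
    idx <- sort(which(n_pair == 0, arr.ind = TRUE)[1, ])
    stop("samples ", dataset$samples$id[idx[1]], " and ",
         dataset$samples$id[idx[2]], " share no genotyped marker")
  }
  z <- (g == 0) & pres; h <- (g == 1) & pres; t2 <- (g == 2) & pres
  storage.mode(z) <- "double"; storage.mode(h) <- "double"
  storage.mode(t2) <- "double"
  n_equal <- tcrossprod(z) + tcrossprod(h) + tcrossprod(t2)
  n_opp <- tcrossprod(z, t2); n_opp <- n_opp + t(n_opp)
  # |g_i - g_j| summed over shared markers: 1 per unequal pair, +1 more
  # when the pair is opposite homozygotes
  sum_diff <- (n_pair - n_equal) + n_opp
  K <- 1 - sum_diff / (2 * n_pair)
  dimnames(K) <- list(dataset$samples$id, dataset$samples$id)
  K
}

#' REML variance components on the null mixed model (EMMA)
#'
#' Fits `y = X beta + u + e` with `Var(u) = sigma_g2 * K`,
#' `Var(e) = sigma_e2 * I` by restricted maximum likelihood in the single
#' ratio `delta = sigma_e2 / sigma_g2`, using the eigendecomposition of the
#' kinship projected orthogonally to `X`. The restricted log-likelihood is
#' evaluated on a log10(delta) grid over [-10, 10] with 100 intervals; sign
#' changes of its derivative are polished by root finding, the EMMA default
#' strategy. When the likelihood is flat in delta (e.g. `K = I`), the upper
#' grid boundary is returned with `degenerate = TRUE`.
#'
#' @param y numeric phenotype vector.
#' @param X fixed-effect design matrix (default intercept only).
#' @param K kinship matrix, positive semidefinite.
#' @param llim,ulim,ngrid log10(delta) grid bounds and interval count.
#' @return list with `delta`, `sigma_g2`, `sigma_e2`, `reml_loglik`,
#'   `degenerate`.
#' @export
emma_reml <- function(y, X = matrix(1, length(y), 1), K,
                      llim = -10, ulim = 10, ngrid = 100) {
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(n >= 3, nrow(X) == n, nrow(K) == n, ncol(K) == n)
  q <- ncol(X)
  if (qr(X)$rank < q) stop("X is not full column rank")
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  es <- eigen(S %*% K %*% S, symmetric = TRUE)
  xi <- es$values[seq_len(n - q)]
  if (min(es$values) < -1e-8 * max(abs(es$values), 1))
    stop("K is not positive semidefinite")
  xi <- pmax(xi, 0)
  U <- es$vectors[, seq_len(n - q), drop = FALSE]
  eta2 <- as.vector(crossprod(U, y))^2
  nq <- n - q

  ll <- function(logd) {
    d <- 10^logd
    0.5 * (nq * (log(nq / (2 * pi)) - 1 - log(sum(eta2 / (xi + d)))) -
             sum(log(xi + d)))
  }
  dll <- function(logd) {
    d <- 10^logd
    0.5 * (nq * sum(eta2 / (xi + d)^2) / sum(eta2 / (xi + d)) -
             sum(1 / (xi + d)))
  }

  grid <- seq(llim, ulim, length.out = ngrid + 1)
  ll_grid <- vapply(grid, ll, numeric(1))
  if (diff(range(ll_grid)) < 1e-8) {
    # flat restricted likelihood: delta unidentifiable
    delta <- 10^ulim
    return(vc_from_delta(delta, eta2, xi, nq, ll(ulim), degenerate = TRUE))
  }
  cand <- c(llim, ulim)
  d_grid <- vapply(grid, dll, numeric(1))
  sign_change <- which(d_grid[-length(d_grid)] > 0 & d_grid[-1] < 0)
  for (i in sign_change) {
    root <- stats::uniroot(dll, c(grid[i], grid[i + 1]), tol = 1e-10)$root
    cand <- c(cand, root)
  }
  ll_cand <- vapply(cand, ll, numeric(1))
  best <- cand[which.max(ll_cand)]
  vc_from_delta(10^best, eta2, xi, nq, max(ll_cand),
                degenerate = best %in% c(llim, ulim))
}

vc_from_delta <- function(delta, eta2, xi, nq, loglik, degenerate) {
  sigma_g2 <- sum(eta2 / (xi + delta)) / nq
  list(delta = delta, sigma_g2 = sigma_g2, sigma_e2 = delta * sigma_g2,
       reml_loglik = loglik, degenerate = degenerate)
}

#' EMMAX association scan
#'
#' Generalized-least-squares association of every marker with a phenotype,
#' with variance components fixed at their null-model REML estimates: the
#' phenotype, intercept and mean-imputed genotype dosages are whitened by
#' `V^(-1/2)` where `V = sigma_g2 K + sigma_e2 I`, then each marker is
#' tested in a whitened simple regression. The default statistic is the
#' Wald `beta^2 / se^2` against chi-square(1); an F-test with `n - 2`
#' denominator degrees of freedom is available via `test = "f"`. Both
#' autosomes and X are scanned. Markers with zero dosage variance after
#' imputation get `p = NA`.
#'
#' @param dataset a QC'd [geno_dataset()].
#' @param K kinship matrix from [ibs_kinship()].
#' @param vc variance components from [emma_reml()] fitted on the null
#'   (intercept-only) model.
#' @param phenotype numeric vector; default the population indicator
#'   (A = 0, B = 1), the two-cohort GWAS phenotype.
#' @param test `"wald_chisq"` (default) or `"f"`.
#' @return data.frame with columns `marker_id`, `chrom`, `pos_bp`, `beta`,
#'   `se`, `statistic`, `value` (the p-value); attribute
#'   `statistic = "emmax_p"` (class `assoc_track`).
#' @export
emmax_scan <- function(dataset, K, vc, phenotype = NULL,
                       test = c("wald_chisq", "f")) {
  test <- match.arg(test)
  if (is.null(phenotype))
    phenotype <- as.numeric(dataset$samples$population == "B")
  n <- n_samples(dataset)
  stopifnot(length(phenotype) == n, nrow(K) == n)

  V <- vc$sigma_g2 * K + vc$sigma_e2 * diag(n)
  ev <- eigen(V, symmetric = TRUE)
  if (min(ev$values) <= 0) stop("V is not positive definite")
  W <- diag(1 / sqrt(ev$values)) %*% t(ev$vectors)   # V^(-1/2)

  g <- dataset$genotypes
  mu <- colMeans(g, na.rm = TRUE)
  idx <- which(is.na(g))
  if (length(idx) > 0) g[idx] <- mu[(idx - 1) %/% nrow(g) + 1]

  yw <- as.vector(W %*% phenotype)
  ow <- as.vector(W %*% rep(1, n))
  Gw <- W %*% g

  # closed-form GLS for the design [intercept, dosage], vectorized
  a11 <- sum(ow^2)
  a12 <- as.vector(crossprod(Gw, ow))
  a22 <- colSums(Gw^2)
  b1 <- sum(ow * yw)
  b2 <- as.vector(crossprod(Gw, yw))
  yy <- sum(yw^2)
  det <- a11 * a22 - a12^2
  ok <- det > 1e-10 * a11 * pmax(a22, 1e-300)
  beta0 <- (a22 * b1 - a12 * b2) / det
  beta1 <- (a11 * b2 - a12 * b1) / det
  rss <- pmax(yy - beta0 * b1 - beta1 * b2, 0)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 * a11 / det)
  statistic <- (beta1 / se)^2
  p <- if (test == "wald_chisq")
    stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  else
    stats::pf(statistic, 1, n - 2, lower.tail = FALSE)
  p <- pmax(p, 1e-300)   # keep p in (0, 1] under extreme separation
  beta1[!ok] <- NA_real_; se[!ok] <- NA_real_
  statistic[!ok] <- NA_real_; p[!ok] <- NA_real_

  out <- new_assoc_track(dataset, p, "emmax_p")
  out$beta <- beta1
  out$se <- se
  out$statistic <- statistic
  out
}

#' Write a kinship matrix as square TSV with a header row of sample ids
#'
#' @param K kinship matrix.
#' @param path output path.
#' @export
write_kinship <- function(K, path) {
  utils::write.table(K, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE)
  invisible(NULL)
}
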