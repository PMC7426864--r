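# Kinship-corrected mixed-model association of TIPs and SNPs with
# phenotypes. The model is y = X b + u + e with u ~ N(0, sg2 K) and
# e ~ N(0, se2 I); variance components are estimated once on the null
# model by restricted maximum likelihood over the ratio delta = se2/sg2
# (spectral decomposition makes each evaluation closed-form), then every
# marker is tested by generalized least squares under the fitted
# covariance - the classical two-step approximation used by EMMAX-style
# association scans.

#' Filter markers on minor-allele frequency and missingness
#'
#' Retains markers with `MAF >= maf_min` (markers with MAF below the
#' threshold are excluded) and missing fraction `<= miss_max` (markers
#' with more than `miss_max` missing data are excluded).
#'
#' @param x a `tip_matrix`, or a markers-by-accessions 0/1 matrix with NA
#'   for missing.
#' @param maf_min minimum minor-allele frequency (default 1%).
#' @param miss_max maximum missing fraction (default 20%).
#' @return same type as `x`, subset to the retained markers.
#' @export
filter_markers <- function(x, maf_min = 0.01, miss_max = 0.20) {
  if (inherits(x, "tip_matrix")) {
    keep <- !is.na(x$maf) & x$maf >= maf_min & x$missing_frac <= miss_max
    if (!any(keep)) stop("no markers pass filters")
    out <- x
    out$sites <- x$sites[keep, , drop = FALSE]
    out$geno <- x$geno[keep, , drop = FALSE]
    out$support <- if (!is.null(x$support)) x$support[keep, , drop = FALSE]
    out$negcov <- if (!is.null(x$negcov)) x$negcov[keep, , drop = FALSE]
    out$maf <- x$maf[keep]
    out$missing_frac <- x$missing_frac[keep]
    return(out)
  }
  g <- as.matrix(x)
  f <- rowMeans(g == 1L, na.rm = TRUE)
  maf <- pmin(f, 1 - f)
  miss <- rowMeans(is.na(g))
  keep <- !is.na(maf) & maf >= maf_min & miss <= miss_max
  if (!any(keep)) stop("no markers pass filters")
  g[keep, , drop = FALSE]
}

marker_r2 <- function(a, b) {
  suppressWarnings(cor(a, b, use = "pairwise.complete.obs"))^2
}

#' LD pruning with a sliding marker window
#'
#' Re-implements the classical window/step/r2 pruning: a window of
#' `window` markers advances by `step`; within each window, for any pair
#' with r-squared above `r2_max` the later marker (by position order) is
#' removed, repeated until no such pair remains.
#'
#' @param snps markers-by-accessions matrix, rows ordered by genomic
#'   position (rownames = marker ids).
#' @param window window size in markers.
#' @param step step size in markers.
#' @param r2_max maximum pairwise r-squared tolerated.
#' @return the pruned matrix (same orientation).
#' @export
ld_prune <- function(snps, window = 50, step = 5, r2_max = 0.2) {
  g <- as.matrix(snps)
  m <- nrow(g)
  keep <- rep(TRUE, m)
  start <- 1L
  repeat {
    end <- min(start + window - 1L, m)
    idx <- which(keep[start:end]) + start - 1L
    if (length(idx) > 1) {
      repeat {
        cc <- suppressWarnings(
          cor(t(g[idx, , drop = FALSE]), use = "pairwise.complete.obs"))^2
        cc[lower.tri(cc, diag = TRUE)] <- NA
        bad <- which(cc > r2_max, arr.ind = TRUE)
        if (nrow(bad) == 0) break
        drop_i <- idx[max(bad[, "col"])]  # remove the later marker
        keep[drop_i] <- FALSE
        idx <- setdiff(idx, drop_i)
        if (length(idx) < 2) break
      }
    }
    if (end == m) break
    start <- start + step
  }
  g[keep, , drop = FALSE]
}

#' Identity-by-state kinship matrix
#'
#' `K[i, j]` is the fraction of pairwise-complete markers at which
#' accessions i and j carry identical genotypes (simple matching on 0/1
#' inbred coding). Symmetric with unit diagonal.
#'
#' @param snps markers-by-accessions 0/1 matrix, NA for missing.
#' @return accessions-by-accessions kinship matrix.
#' @export
kinship <- function(snps) {
  g <- as.matrix(snps)
  if (ncol(g) < 2) stop("need >=2 accessions")
  ones <- (!is.na(g) & g == 1L) + 0
  zeros <- (!is.na(g) & g == 0L) + 0
  obs <- (!is.na(g)) + 0
  matches <- crossprod(ones) + crossprod(zeros)
  denom <- crossprod(obs)
  if (any(denom == 0)) stop("accession pair with zero complete markers")
  K <- matches / denom
  dimnames(K) <- list(colnames(g), colnames(g))
  K
}

# restricted log-likelihood profile over delta given the spectral pieces
# lambda (eigenvalues of S K S restricted to the non-null space) and
# eta = U' y
reml_ll <- function(delta, lambda, eta2) {
  nq <- length(lambda)
  denom <- lambda + delta
  0.5 * (nq * log(nq / (2 * pi)) - nq - nq * log(sum(eta2 / denom)) -
           sum(log(denom)))
}

#' Fit the null mixed model by REML
#'
#' Maximises the restricted likelihood of y = X b + u + e, u ~ N(0, sg2 K),
#' e ~ N(0, se2 I) over delta = se2/sg2 on a log10 grid in [-5, 5] refined
#' by [stats::optimize] (golden section) around the grid optimum. The
#' spectral decomposition of the projected kinship makes each likelihood
#' evaluation closed-form.
#'
#' @param y numeric phenotype (complete cases; aligned with K rows).
#' @param K kinship matrix (positive semi-definite).
#' @param X covariate matrix; an intercept column is always included.
#' @param grid_points points on the log10-delta grid.
#' @param tol eigenvalue tolerance below which K is declared non-PSD.
#' @return list of class `lmm_null`: `sigma_g2`, `sigma_e2`, `delta`,
#'   `logREML`, `h2`, plus cached pieces used by [marker_scan()].
#' @export
fit_null <- function(y, K, X = NULL, grid_points = 100, tol = 1e-8) {
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  X <- cbind(`(Intercept)` = rep(1, n), X)
  q <- ncol(X)
  eK <- eigen(K, symmetric = TRUE)
  if (min(eK$values) < -1e-6 * max(abs(eK$values))) {
    stop("K is not positive semi-definite; consider regularizing (K + 1e-6 I)")
  }
  # projection orthogonal to X, then spectral decomposition of S K S
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  eS <- eigen(S %*% K %*% S, symmetric = TRUE)
  keep <- seq_len(n - q)
  lambda <- pmax(eS$values[keep], 0)
  U <- eS$vectors[, keep, drop = FALSE]
  eta2 <- as.vector(crossprod(U, y))^2

  lg <- seq(-5, 5, length.out = grid_points)
  ll <- vapply(10^lg, reml_ll, numeric(1), lambda = lambda, eta2 = eta2)
  i <- which.max(ll)
  lo <- lg[max(1, i - 1)]; hi <- lg[min(grid_points, i + 1)]
  opt <- optimize(function(l) reml_ll(10^l, lambda, eta2),
                  interval = c(lo, hi), maximum = TRUE)
  delta <- 10^opt$maximum
  if (opt$objective < ll[i]) delta <- 10^lg[i]
  sigma_g2 <- sum(eta2 / (lambda + delta)) / (n - q)
  sigma_e2 <- delta * sigma_g2
  structure(list(
    sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, delta = delta,
    logREML = max(opt$objective, ll[i]),
    h2 = sigma_g2 / (sigma_g2 + sigma_e2),
    n = n, q = q, y = y, X = X,
    K_eigen = eK
  ), class = "lmm_null")
}

#' @export
print.lmm_null <- function(x, ...) {
  cat(sprintf(
    "lmm_null: sigma_g2 = %.4g, sigma_e2 = %.4g (delta = %.3g, h2 = %.3f)\n",
    x$sigma_g2, x$sigma_e2, x$delta, x$h2))
  invisible(x)
}

# whitening transform W such that W V W' = I for V = sg2 (K + delta I)
null_whitener <- function(null) {
  d <- pmax(null$K_eigen$values, 0)
  w <- 1 / sqrt(null$sigma_g2 * (d + null$delta))
  t(null$K_eigen$vectors) * w  # rows scaled
}

gls_one <- function(yt, Xt, gt) {
  Xg <- cbind(Xt, gt)
  XtX <- crossprod(Xg)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  XtXinv <- chol2inv(R)
  coefs <- XtXinv %*% crossprod(Xg, yt)
  resid <- yt - Xg %*% coefs
  rdf <- length(yt) - ncol(Xg)
  if (rdf <= 0) return(NULL)
  rss <- sum(resid^2)
  k <- ncol(Xg)
  beta <- coefs[k, 1]
  se <- sqrt(rss / rdf * XtXinv[k, k])
  tstat <- beta / se
  list(beta = beta, se = se, statistic = tstat,
       p_value = 2 * pt(-abs(tstat), rdf))
}

#' Mixed-model marker scan (GLS under the null covariance)
#'
#' Tests every marker by generalized least squares with the covariance
#' sg2 K + se2 I fixed from the null fit. Missing genotypes are handled
#' per marker by complete-case analysis (or optional mean imputation);
#' markers monomorphic after complete-case reduction are skipped.
#'
#' @param markers markers-by-accessions matrix (0/1 or dosage; NA
#'   missing), columns aligned with the null fit's phenotype.
#' @param null an `lmm_null` from [fit_null()].
#' @param impute_missing replace missing genotypes by the marker mean
#'   instead of complete-case testing.
#' @return data.frame of class `association_result`: `marker_id`, `beta`,
#'   `se`, `statistic`, `p_value`, `maf`, `n_used`; skipped markers are
#'   counted in `attr(, "n_skipped")`.
#' @export
marker_scan <- function(markers, null, impute_missing = FALSE) {
  stopifnot(inherits(null, "lmm_null"))
  g <- as.matrix(markers)
  n <- null$n
  stopifnot(ncol(g) == n)
  W <- null_whitener(null)
  yt <- as.vector(W %*% null$y)
  Xt <- W %*% null$X
  ids <- rownames(g) %||% paste0("m", seq_len(nrow(g)))
  res <- vector("list", nrow(g))
  n_skipped <- 0L
  # per-marker covariance subset for complete-case rows
  V <- null$sigma_g2 *
    (null$K_eigen$vectors %*% (t(null$K_eigen$vectors) *
                                 pmax(null$K_eigen$values, 0)) +
       null$delta * diag(n))
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    if (impute_missing && anyNA(gi)) gi[is.na(gi)] <- mean(gi, na.rm = TRUE)
    miss <- is.na(gi)
    if (!any(miss)) {
      if (var(gi) == 0) { n_skipped <- n_skipped + 1L; next }
      fit <- gls_one(yt, Xt, as.vector(W %*% gi))
    } else {
      idx <- which(!miss)
      if (length(idx) <= null$q + 1 || var(gi[idx]) == 0) {
        n_skipped <- n_skipped + 1L; next
      }
      R <- chol(V[idx, idx])
      Wi <- backsolve(R, diag(length(idx)), transpose = TRUE)
      fit <- gls_one(as.vector(Wi %*% null$y[idx]),
                     Wi %*% null$X[idx, , drop = FALSE],
                     as.vector(Wi %*% gi[idx]))
    }
    if (is.null(fit)) { n_skipped <- n_skipped + 1L; next }
    f <- mean(gi, na.rm = TRUE)
    res[[i]] <- data.frame(
      marker_id = ids[i], beta = fit$beta, se = fit$se,
      statistic = fit$statistic, p_value = fit$p_value,
      maf = min(f, 1 - f), n_used = sum(!is.na(gi)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(marker_id = character(0), beta = numeric(0),
                      se = numeric(0), statistic = numeric(0),
                      p_value = numeric(0), maf = numeric(0),
                      n_used = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("association_result", class(out))
  out
}

#' Carrier-label permutation test for one marker
#'
#' Permutes the carrier/noncarrier labels of a binary marker `n_perm`
#' times, re-runs the association test under the same null covariance,
#' and reports the empirical family-wise p-value
#' `(1 + #{permuted p <= observed p}) / (n_perm + 1)`.
#'
#' @param marker binary 0/1 vector (NA allowed).
#' @param null an `lmm_null`.
#' @param n_perm number of permutations.
#' @param seed RNG seed (bit-for-bit reproducible).
#' @return list: `observed_p`, `empirical_p`, `n_perm`.
#' @export
permutation_test <- function(marker, null, n_perm = 1000, seed = 1) {
  stopifnot(inherits(null, "lmm_null"))
  g <- as.numeric(marker)
  obs <- marker_scan(matrix(g, 1, dimnames = list("obs", NULL)), null)
  if (nrow(obs) == 0) stop("marker untestable (monomorphic?)")
  set.seed(seed)
  perm_p <- vapply(seq_len(n_perm), function(b) {
    gp <- sample(g)
    r <- marker_scan(matrix(gp, 1, dimnames = list("p", NULL)), null)
    if (nrow(r) == 0) 1 else r$p_value
  }, numeric(1))
  list(observed_p = obs$p_value,
       empirical_p = (1 + sum(perm_p <= obs$p_value)) / (n_perm + 1),
       n_perm = n_perm)
}

#' Run a TIP (or SNP) GWAS end to end
#'
#' Applies the marker filters, fits the null model with the supplied
#' kinship, scans all markers and reports the Bonferroni threshold.
#'
#' @param pheno named numeric phenotype vector (names = accessions;
#'   booleans coded 0/1).
#' @param markers markers-by-accessions matrix.
#' @param K kinship matrix over the same accessions.
#' @param maf_min,miss_max marker filters.
#' @return list: `scan` (association results ordered by p),
#'   `null` (the variance-component fit), `bonferroni` (0.05 / markers
#'   tested).
#' @export
run_gwas <- function(pheno, markers, K, maf_min = 0.01, miss_max = 0.20) {
  accs <- names(pheno)
  stopifnot(!is.null(accs), all(accs %in% colnames(markers)),
            all(accs %in% rownames(K)))
  g <- filter_markers(markers[, accs, drop = FALSE],
                      maf_min = maf_min, miss_max = miss_max)
  null <- fit_null(unname(pheno), K[accs, accs])
  scan <- marker_scan(g, null)
  scan <- scan[order(scan$p_value), ]
  rownames(scan) <- NULL
  list(scan = scan, null = null,
       bonferroni = 0.05 / max(nrow(scan), 1))
}
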