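test_that("marker filters apply the MAF and missingness boundaries", {
  n <- 1000
  mk_marker <- function(n_carrier, n_missing = 0) {
    v <- c(rep(1L, n_carrier), rep(0L, n - n_carrier))
    if (n_missing > 0) v[sample(n, n_missing)] <- NA
    v
  }
  set.seed(1)
  g <- rbind(
    maf009 = mk_marker(9),            # MAF 0.009 -> excluded
    maf011 = mk_marker(11),           # MAF 0.011 -> retained
    maf010 = mk_marker(10),           # MAF exactly 1% -> retained
    miss21 = mk_marker(400, 210),     # 21% missing -> excluded
    miss20 = mk_marker(400, 200),     # exactly 20% -> retained
    common = mk_marker(500)
  )
  colnames(g) <- paste0("a", 1:n)
  kept <- filter_markers(g)
  expect_setequal(rownames(kept), c("maf011", "maf010", "miss20", "common"))
  # hand enumeration on a constructed 10-marker table
  set.seed(2)
  g10 <- matrix(rbinom(10 * 200, 1, runif(10, 0, 0.08)), 10, 200,
                byrow = FALSE)
  g10[1, sample(200, 60)] <- NA
  rownames(g10) <- paste0("m", 1:10)
  colnames(g10) <- paste0("a", 1:200)
  want <- rownames(g10)[sapply(seq_len(10), function(i) {
    v <- g10[i, ]; f <- mean(v, na.rm = TRUE)
    min(f, 1 - f) >= 0.01 && mean(is.na(v)) <= 0.2
  })]
  expect_setequal(rownames(filter_markers(g10)), want)
  expect_error(filter_markers(rbind(mono = rep(0L, 50))), "no markers")
})

test_that("LD pruning removes duplicates and leaves independent sets alone", {
  set.seed(3)
  v <- rbinom(100, 1, 0.5)
  g <- rbind(s1 = v, s2 = v, s3 = rbinom(100, 1, 0.5))
  colnames(g) <- paste0("a", 1:100)
  pruned <- ld_prune(g)
  expect_equal(nrow(pruned), 2L)
  expect_true("s1" %in% rownames(pruned))  # the later duplicate is removed
  expect_false("s2" %in% rownames(pruned))

  set.seed(4)
  ind <- matrix(rbinom(500 * 150, 1, 0.5), 500, 150,
                dimnames = list(paste0("s", 1:500), paste0("a", 1:150)))
  pr <- ld_prune(ind, window = 50, step = 5, r2_max = 0.2)
  expect_gt(nrow(pr), 450)

  # post-check: no surviving within-window pair above the threshold
  set.seed(5)
  block <- matrix(rbinom(40 * 120, 1, 0.5), 40, 120)
  block[2, ] <- block[1, ]; block[10, ] <- abs(block[9, ] - 0L)
  block[20, ] <- ifelse(runif(120) < 0.95, block[19, ], 1 - block[19, ])
  rownames(block) <- paste0("s", 1:40)
  colnames(block) <- paste0("a", 1:120)
  pb <- ld_prune(block, window = 10, step = 2, r2_max = 0.2)
  idx <- match(rownames(pb), rownames(block))
  for (w_start in seq(1, 40 - 9, by = 2)) {
    inw <- which(idx >= w_start & idx <= w_start + 9)
    if (length(inw) < 2) next
    cc <- suppressWarnings(cor(t(pb[inw, , drop = FALSE])))^2
    cc[lower.tri(cc, diag = TRUE)] <- NA
    expect_true(all(cc[!is.na(cc)] <= 0.2))
  }
})

test_that("kinship is IBS simple matching with the right extremes", {
  g <- rbind(c(1, 1, 0), c(0, 0, 1), c(1, 1, 0), c(0, 0, 1))
  colnames(g) <- c("a", "b", "c")
  K <- kinship(g)
  expect_equal(unname(diag(K)), rep(1, 3))
  expect_equal(K["a", "b"], 1)  # identical accessions
  expect_equal(K["a", "c"], 0)  # complementary accessions
  expect_identical(K, t(K))

  set.seed(6)
  m <- 1000
  g2 <- matrix(rbinom(2 * m, 1, 0.5), m, 2,
               dimnames = list(NULL, c("x", "y")))
  K2 <- kinship(g2)
  expect_lt(abs(K2["x", "y"] - 0.5), 4 * sqrt(0.25 / m))

  g3 <- rbind(c(NA, 1), c(NA, 0))
  colnames(g3) <- c("u", "v")
  expect_error(kinship(g3), "zero complete markers")
})

test_that("the null REML fit degenerates to OLS for pure noise", {
  set.seed(7)
  n <- 120
  K <- kinship(matrix(rbinom(300 * n, 1, 0.5), 300, n,
                      dimnames = list(NULL, paste0("a", 1:n))))
  y <- rnorm(n)
  fit <- fit_null(y, K)
  expect_lt(fit$h2, 0.25)
  # total variance close to the sample variance, and the marker test in
  # this regime matches OLS
  expect_lt(abs((fit$sigma_g2 + fit$sigma_e2) - var(y)) / var(y), 0.3)
  set.seed(71)
  marker <- rbinom(n, 1, 0.5)
  scan <- marker_scan(rbind(m1 = marker), fit)
  ols <- summary(lm(y ~ marker))$coefficients
  expect_equal(scan$p_value, ols[2, 4], tolerance = 0.05)
})

test_that("heritability is recovered from simulated genetic signals", {
  set.seed(8)
  n <- 200
  errs <- vapply(1:5, function(s) {
    set.seed(100 + s)
    A <- matrix(rnorm(n * n), n)
    K <- tcrossprod(A) / n
    d <- diag(K); K <- K / mean(d)
    L <- t(chol(K + 1e-8 * diag(n)))
    u <- as.vector(L %*% rnorm(n))          # sg2 = 1
    y <- u + rnorm(n, sd = 0.5)             # se2 = 0.25 -> h2 = 0.8
    fit <- fit_null(y, K)
    fit$h2 - 0.8
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.1)
})

test_that("with K = I the scan reproduces OLS exactly", {
  set.seed(9)
  n <- 80
  y <- rnorm(n)
  g <- matrix(rbinom(30 * n, 1, 0.4), 30, n,
              dimnames = list(paste0("m", 1:30), paste0("a", 1:n)))
  null <- fit_null(y, diag(n))
  scan <- marker_scan(g, null)
  for (i in seq_len(nrow(scan))) {
    mid <- scan$marker_id[i]
    ols <- summary(lm(y ~ g[mid, ]))$coefficients
    expect_equal(scan$beta[i], ols[2, 1], tolerance = 1e-8)
    expect_equal(scan$se[i], ols[2, 2], tolerance = 1e-8)
    expect_equal(scan$p_value[i], ols[2, 4], tolerance = 1e-8)
  }
})

test_that("complete-case handling and monomorphic skipping work", {
  set.seed(10)
  n <- 60
  y <- rnorm(n)
  g <- matrix(rbinom(3 * n, 1, 0.5), 3, n,
              dimnames = list(c("ok", "namiss", "mono"), paste0("a", 1:n)))
  g["namiss", 1:10] <- NA
  g["mono", ] <- 1L
  null <- fit_null(y, diag(n))
  scan <- marker_scan(g, null)
  expect_setequal(scan$marker_id, c("ok", "namiss"))
  expect_equal(scan$n_used[scan$marker_id == "namiss"], n - 10L)
  expect_equal(attr(scan, "n_skipped"), 1L)
  # complete-case equals OLS on the subset when K = I
  keep <- !is.na(g["namiss", ])
  ols <- summary(lm(y[keep] ~ g["namiss", keep]))$coefficients
  expect_equal(scan$p_value[scan$marker_id == "namiss"], ols[2, 4],
               tolerance = 1e-8)
})

test_that("a planted strong marker is found with kinship correction", {
  set.seed(11)
  n <- 150
  pop <- rep(0:1, each = n / 2)
  snps <- t(vapply(1:300, function(i) {
    p <- runif(1, 0.1, 0.9)
    probs <- ifelse(pop == 1, pmin(p + 0.2, 0.95), p)
    rbinom(n, 1, probs)
  }, integer(n)))
  colnames(snps) <- paste0("a", 1:n)
  K <- kinship(snps)
  causal <- rbinom(n, 1, 0.5)
  y <- causal * 1.5 + rnorm(n) + 0.5 * pop
  g <- rbind(snps[1:50, ], causal = causal)
  null <- fit_null(y, K)
  scan <- marker_scan(g, null)
  expect_equal(scan$marker_id[which.min(scan$p_value)], "causal")
})

test_that("the carrier permutation test hits its floor and is reproducible", {
  set.seed(12)
  n <- 80
  marker <- rep(c(0L, 1L), each = n / 2)
  y <- marker + rnorm(n, sd = 0.01)
  null <- fit_null(y, diag(n))
  pt1 <- permutation_test(marker, null, n_perm = 200, seed = 5)
  expect_equal(pt1$empirical_p, 1 / 201)
  pt2 <- permutation_test(marker, null, n_perm = 200, seed = 5)
  expect_identical(pt1, pt2)
})

test_that("run_gwas wires filters, kinship and the scan together", {
  set.seed(13)
  n <- 100
  snps <- matrix(rbinom(200 * n, 1, 0.5), 200, n,
                 dimnames = list(paste0("s", 1:200), paste0("a", 1:n)))
  K <- kinship(snps)
  causal <- snps["s7", ]
  pheno <- setNames(causal * 2 + rnorm(n), colnames(snps))
  res <- run_gwas(pheno, snps, K)
  expect_equal(res$scan$marker_id[1], "s7")
  expect_lt(res$scan$p_value[1], res$bonferroni)
  expect_true(all(res$scan$p_value > 0 & res$scan$p_value <= 1))
})
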