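# build a tip_matrix directly from a genotype matrix
mk_tm <- function(geno, families = NULL, chrom = "chr1",
                  positions = NULL) {
  ns <- nrow(geno)
  sdf <- data.frame(
    site_id = sprintf("S%03d", seq_len(ns)), chrom = chrom,
    position = positions %||% (seq_len(ns) * 1000L),
    ci_lo = 0L, ci_hi = 0L,
    te_family = families %||% rep("FAM01", ns),
    stringsAsFactors = FALSE)
  rownames(geno) <- sdf$site_id
  mobilomekit:::new_tip_matrix(sdf, colnames(geno), geno)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("PCA separates groups with disjoint private TIP sets", {
  set.seed(2)
  gA <- matrix(0L, 20, 12)
  gA[1:10, 1:6] <- rbinom(60, 1, 0.7)
  gA[11:20, 7:12] <- rbinom(60, 1, 0.7)
  colnames(gA) <- sprintf("acc%02d", 1:12)
  tm <- mk_tm(gA)
  pc <- tip_pca(tm, 2)
  grp <- rep(c("A", "B"), each = 6)
  a_range <- range(pc$scores[grp == "A", 1])
  b_range <- range(pc$scores[grp == "B", 1])
  expect_true(a_range[2] < b_range[1] || b_range[2] < a_range[1])
  expect_true(all(pc$explained_variance >= 0))
  expect_lte(sum(pc$explained_variance), 1 + 1e-12)
})

test_that("duplicated accessions get duplicated PCA coordinates", {
  set.seed(3)
  g <- matrix(rbinom(80, 1, 0.4), 10, 8)
  colnames(g) <- sprintf("a%d", 1:8)
  g[, 8] <- g[, 1]
  pc <- tip_pca(mk_tm(g), 2)
  expect_equal(unname(pc$scores[8, ]), unname(pc$scores[1, ]))
})

test_that("PCA coordinates are sign-invariant under site reordering", {
  set.seed(4)
  g <- matrix(rbinom(120, 1, 0.4), 15, 8)
  colnames(g) <- sprintf("a%d", 1:8)
  pc1 <- tip_pca(mk_tm(g), 2)
  perm <- sample(nrow(g))
  pc2 <- tip_pca(mk_tm(g[perm, , drop = FALSE]), 2)
  expect_equal(abs(unname(pc1$scores)), abs(unname(pc2$scores)),
               tolerance = 1e-8)
})

test_that("constant matrices are rejected", {
  g <- matrix(1L, 5, 4, dimnames = list(NULL, paste0("a", 1:4)))
  expect_error(tip_pca(mk_tm(g)), "no variance")
})

test_that("accumulation curves are monotone with the right endpoint", {
  tm <- small_tip_matrix()
  ac <- family_accumulation(tm, n_boot = 100, seed = 1)
  expect_true(all(diff(ac$mean_families) >= -1e-12))
  n_fam <- length(unique(tm$sites$te_family))
  expect_equal(ac$mean_families[nrow(ac)], n_fam)
  expect_true(all(ac$ci_lo <= ac$mean_families + 1e-12 &
                    ac$mean_families <= ac$ci_hi + 1e-12))
})

test_that("accumulation at k = 1 matches exhaustive per-accession richness", {
  set.seed(5)
  g <- matrix(rbinom(60, 1, 0.3), 12, 5,
              dimnames = list(NULL, paste0("a", 1:5)))
  fam <- rep(c("F1", "F2", "F3"), each = 4)
  tm <- mk_tm(g, families = fam)
  ac <- family_accumulation(tm, n_boot = 400, seed = 9)
  # oracle: direct enumeration of per-accession family richness
  rich <- vapply(colnames(g), function(a) {
    length(unique(fam[g[, a] == 1]))
  }, numeric(1))
  expect_lt(abs(ac$mean_families[1] - mean(rich)),
            3 * sd(rich) / sqrt(400) + 1e-9)
})

test_that("group richness flags enriched groups and calibrates on nulls", {
  set.seed(6)
  # group B carries 10 extra families absent from A
  nA <- 6; nB <- 6
  base <- matrix(rbinom(8 * (nA + nB), 1, 0.6), 8, nA + nB)
  extra <- matrix(0L, 10, nA + nB)
  extra[, (nA + 1):(nA + nB)] <- rbinom(10 * nB, 1, 0.7)
  g <- rbind(base, extra)
  colnames(g) <- sprintf("x%02d", seq_len(nA + nB))
  fam <- sprintf("F%02d", seq_len(18))
  tm <- mk_tm(g, families = fam)
  groups <- setNames(rep(c("A", "B"), c(nA, nB)), colnames(g))
  gr <- group_richness(tm, groups, n_boot = 100, n_perm = 500, seed = 3)
  rA <- gr$richness[gr$richness$group == "A", ]
  rB <- gr$richness[gr$richness$group == "B", ]
  expect_gt(rB$mean_richness, rA$mean_richness)
  expect_lt(gr$pairwise$p_value, 0.05)

  # identical groups: difference near zero, permutation p not extreme
  g2 <- base
  colnames(g2) <- colnames(g)
  tm2 <- mk_tm(g2, families = sprintf("F%02d", 1:8))
  gr2 <- group_richness(tm2, groups, n_boot = 50, n_perm = 300, seed = 4)
  expect_gt(gr2$pairwise$p_value, 0.01)

  expect_error(group_richness(tm, setNames(rep("A", nA + nB), colnames(g))),
               ">=2 groups")
})

test_that("r2 equals the haplotype-table formula on all pairs (n <= 20)", {
  set.seed(8)
  n_acc <- 20
  g <- matrix(rbinom(10 * n_acc, 1, 0.4), 10, n_acc,
              dimnames = list(NULL, paste0("a", 1:n_acc)))
  g[sample(length(g), 15)] <- NA
  snps <- matrix(rbinom(12 * n_acc, 1, 0.5), 12, n_acc,
                 dimnames = list(paste0("s", 1:12), paste0("a", 1:n_acc)))
  snp_pos <- data.frame(snp_id = rownames(snps), chrom = "chr1",
                        pos = seq(100, 1200, by = 100))
  tm <- mk_tm(g, positions = seq(150L, 9150L, by = 1000L))
  lp <- ld_profile(tm, snps, snp_pos, n_flank = 6)
  for (r in seq_len(nrow(lp$tip_snp))) {
    si <- match(lp$tip_snp$site_id[r], tm$sites$site_id)
    want <- oracle_r2(g[si, ], snps[lp$tip_snp$snp_id[r], ])
    if (is.na(want)) {
      expect_true(is.na(lp$tip_snp$r2[r]))
    } else {
      expect_equal(lp$tip_snp$r2[r], want, tolerance = 1e-12)
    }
  }
  expect_true(all(lp$snp_snp_r2 >= 0 & lp$snp_snp_r2 <= 1 + 1e-12))
})

test_that("identical marker vectors give r2 = 1", {
  n_acc <- 12
  v <- rep(c(0L, 1L, 1L, 0L), 3)
  g <- rbind(v)
  colnames(g) <- paste0("a", 1:n_acc)
  snps <- rbind(s1 = v)
  colnames(snps) <- colnames(g)
  tm <- mk_tm(matrix(as.integer(v), 1, n_acc,
                     dimnames = list(NULL, colnames(g))))
  lp <- ld_profile(tm, snps, data.frame(snp_id = "s1", chrom = "chr1",
                                        pos = 500), n_flank = 1)
  expect_equal(lp$tip_snp$r2, 1)
})

test_that("independent markers have E[r2] near 1/n", {
  set.seed(10)
  n <- 200; reps <- 1000
  r2 <- vapply(seq_len(reps), function(i) {
    a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
    oracle_r2(a, b)
  }, numeric(1))
  r2 <- r2[!is.na(r2)]
  expect_lt(abs(mean(r2) - 1 / n), 3 * sd(r2) / sqrt(length(r2)) + 5e-4)
})

test_that("planted low-LD TIPs reproduce the TIP-SNP vs SNP-SNP contrast", {
  set.seed(12)
  n_acc <- 60
  # structured SNP haplotypes: two subpopulations -> high SNP-SNP LD
  pop <- rep(0:1, each = n_acc / 2)
  snps <- t(vapply(1:20, function(i) {
    base <- pop
    flip <- rbinom(n_acc, 1, 0.1)
    as.integer(xor(base, flip))
  }, integer(n_acc)))
  rownames(snps) <- paste0("s", 1:20)
  colnames(snps) <- paste0("a", 1:n_acc)
  # TIP carrier sets drawn independently of the haplotype structure
  g <- matrix(rbinom(5 * n_acc, 1, 0.15), 5, n_acc,
              dimnames = list(NULL, colnames(snps)))
  tm <- mk_tm(g, positions = seq(500L, 4500L, by = 1000L))
  snp_pos <- data.frame(snp_id = rownames(snps), chrom = "chr1",
                        pos = seq(100, 2000, by = 100))
  lp <- ld_profile(tm, snps, snp_pos, n_flank = 10)
  prop <- lp$proportions[lp$proportions$threshold == 0.4, ]
  expect_lt(prop$tip_snp, prop$snp_snp)
})

test_that("density tracks conserve totals", {
  sim <- small_sim()
  sites <- small_sites()$sites
  sites$superfamily <- family_superfamily(sim$lib)[sites$te_family]
  tr <- density_tracks(sites, sim$genome$genes, sim$genome$te_annotation,
                       reference_lengths(sim), window = 5e4)
  expect_equal(sum(tr$n_tips), nrow(sites))
  expect_equal(sum(tr$n_tes), length(sim$genome$te_annotation))
  sf_cols <- grep("^tips_", names(tr), value = TRUE)
  expect_equal(sum(unlist(tr[sf_cols])), nrow(sites))

  ten <- sites[rep(1, 10), ]
  ten$position <- seq(1000L, 10000L, by = 1000L)
  tr10 <- density_tracks(ten, NULL, NULL,
                         c(chr1 = 100000L, chr2 = 100000L), window = 5e4)
  expect_equal(tr10$n_tips, c(10L, 0L, 0L, 0L))
})

test_that("mappability is ~1 on random sequence and ~0 on duplications", {
  set.seed(14)
  rand <- paste(sample(c("A", "C", "G", "T"), 60000, replace = TRUE),
                collapse = "")
  ref <- Biostrings::DNAStringSet(c(chr1 = rand))
  mt <- mappability_track(ref, read_len = 100, step = 20, window = 1e4)
  expect_true(all(mt$fraction >= 0 & mt$fraction <= 1))
  expect_true(all(mt$fraction > 0.99))

  dup <- Biostrings::DNAStringSet(c(chr1 = paste0(rand, rand)))
  md <- mappability_track(dup, read_len = 100, step = 20, window = 1e4)
  # interior windows are fully duplicated; only the window containing the
  # junction holds a handful of unique junction-spanning pseudo-reads
  expect_true(all(md$fraction < 0.05))
  expect_lte(sum(md$fraction > 0.01), 1L)

  expect_error(mappability_track(ref, read_len = 100, window = 50),
               "window smaller")
})

test_that("bootstrap CI width shrinks with more replicates", {
  tm <- small_tip_matrix()
  a100 <- family_accumulation(tm, n_boot = 100, seed = 2)
  a1000 <- family_accumulation(tm, n_boot = 1000, seed = 2)
  mid <- ceiling(nrow(a100) / 2)
  w100 <- a100$ci_hi[mid] - a100$ci_lo[mid]
  w1000 <- a1000$ci_hi[mid] - a1000$ci_lo[mid]
  expect_lte(w1000, w100 + 1)
})
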