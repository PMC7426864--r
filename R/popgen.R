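# Population statistics over the TIP presence/absence matrix: PCA, family
# accumulation and richness, TIP-SNP linkage disequilibrium, and genomic
# tracks (density, mappability).

geno_from <- function(x) {
  if (inherits(x, "tip_matrix")) x$geno else as.matrix(x)
}

#' PCA of accessions on the TIP presence/absence matrix
#'
#' Carriers are coded 1, noncarriers 0; missing calls are imputed to the
#' site mean. Sites are centred and the decomposition uses [stats::prcomp]
#' (singular value decomposition).
#'
#' @param tm a `tip_matrix` or a sites-by-accessions 0/1 matrix.
#' @param n_components number of components to return.
#' @return list: `scores` (accessions x components), `explained_variance`
#'   (fractions, sum <= 1), `sdev`.
#' @export
tip_pca <- function(tm, n_components = 2) {
  g <- geno_from(tm)
  if (nrow(g) < 2 || ncol(g) < 2) stop("need >=2 accessions and >=2 sites")
  X <- t(g)  # accessions x sites
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx) > 0) X[idx] <- mu[idx[, 2]]
  keep <- apply(X, 2, function(v) var(v) > 0)
  if (!any(keep)) stop("no variance")
  X <- X[, keep, drop = FALSE]
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained_variance = ev[seq_len(k)],
       sdev = pc$sdev)
}

# accessions x families incidence: does accession carry >=1 site of family?
family_incidence <- function(tm, family_map = NULL) {
  g <- geno_from(tm)
  fam <- family_map %||% tm$sites$te_family
  if (is.null(fam) || length(fam) != nrow(g)) {
    stop("every site must be mapped to a family")
  }
  fams <- sort(unique(fam))
  inc <- sapply(fams, function(f) {
    rows <- which(fam == f)
    as.integer(colSums(g[rows, , drop = FALSE] == 1L, na.rm = TRUE) > 0)
  })
  if (is.null(dim(inc))) inc <- matrix(inc, nrow = ncol(g))
  dimnames(inc) <- list(colnames(g), fams)
  inc
}

#' Family accumulation curve with bootstrap confidence intervals
#'
#' Counts mobile families detected (>= 1 carrier site) in growing
#' accession subsets. Subsets are nested within each bootstrap replicate
#' (a random accession ordering is accumulated), which makes every
#' replicate curve - and hence the mean curve - non-decreasing; the
#' machinery is [vegan::specaccum] with `method = "random"`.
#'
#' @param tm a `tip_matrix`.
#' @param family_map optional site-to-family map (defaults to the sites
#'   table's `te_family`).
#' @param n_boot number of bootstrap orderings.
#' @param seed RNG seed.
#' @param conf confidence level for the percentile interval.
#' @return data.frame: `k`, `mean_families`, `ci_lo`, `ci_hi`.
#' @export
family_accumulation <- function(tm, family_map = NULL, n_boot = 100,
                                seed = 1, conf = 0.95) {
  inc <- family_incidence(tm, family_map)
  set.seed(seed)
  sac <- vegan::specaccum(inc, method = "random", permutations = n_boot)
  a <- (1 - conf) / 2
  ci <- apply(sac$perm, 1, quantile, probs = c(a, 1 - a))
  data.frame(k = sac$sites, mean_families = sac$richness,
             ci_lo = ci[1, ], ci_hi = ci[2, ], row.names = NULL)
}

# exact expected family richness of a random subset of size m (incidence
# rarefaction): E[S_m] = sum_f (1 - choose(n - n_f, m)/choose(n, m))
rarefied_richness <- function(inc, m) {
  n <- nrow(inc)
  nf <- colSums(inc > 0)
  sum(1 - exp(lchoose(n - nf, m) - lchoose(n, m)))
}

#' Per-group family richness with bootstrap CI and randomization test
#'
#' Richness is compared at a common subsample size (the smallest group)
#' via bootstrap subsampling; pairwise significance comes from a
#' randomization test permuting group labels and comparing the exact
#' rarefied-richness difference to its permutation null.
#'
#' @param tm a `tip_matrix`.
#' @param groups named character vector accession -> group.
#' @param family_map optional site-to-family map.
#' @param n_boot bootstrap subsamples per group.
#' @param n_perm label permutations for the pairwise test.
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return list: `richness` (data.frame `group`, `n_accessions`,
#'   `mean_richness`, `ci_lo`, `ci_hi`, `rarefied_richness`), `pairwise`
#'   (data.frame `group1`, `group2`, `observed_diff`, `p_value`),
#'   `subsample_size`.
#' @export
group_richness <- function(tm, groups, family_map = NULL, n_boot = 100,
                           n_perm = 1000, seed = 1, conf = 0.95) {
  inc <- family_incidence(tm, family_map)
  groups <- groups[rownames(inc)]
  if (any(is.na(groups))) stop("every accession needs a group")
  gl <- split(rownames(inc), groups)
  if (length(gl) < 2) stop("need >=2 groups")
  if (any(lengths(gl) == 0)) stop("empty group")
  m <- min(lengths(gl))
  set.seed(seed)
  a <- (1 - conf) / 2
  rich <- do.call(rbind, lapply(names(gl), function(gn) {
    accs <- gl[[gn]]
    boots <- vapply(seq_len(n_boot), function(b) {
      sub <- sample(accs, m)
      sum(colSums(inc[sub, , drop = FALSE]) > 0)
    }, numeric(1))
    data.frame(group = gn, n_accessions = length(accs),
               mean_richness = mean(boots),
               ci_lo = quantile(boots, a), ci_hi = quantile(boots, 1 - a),
               rarefied_richness = rarefied_richness(
                 inc[accs, , drop = FALSE], m),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(names(gl), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(pi) {
    g1 <- pairs[1, pi]; g2 <- pairs[2, pi]
    accs <- c(gl[[g1]], gl[[g2]])
    n1 <- length(gl[[g1]])
    obs <- rarefied_richness(inc[gl[[g1]], , drop = FALSE], m) -
      rarefied_richness(inc[gl[[g2]], , drop = FALSE], m)
    perm <- vapply(seq_len(n_perm), function(b) {
      sh <- sample(accs)
      rarefied_richness(inc[sh[seq_len(n1)], , drop = FALSE], m) -
        rarefied_richness(inc[sh[-seq_len(n1)], , drop = FALSE], m)
    }, numeric(1))
    data.frame(group1 = g1, group2 = g2, observed_diff = obs,
               p_value = (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1),
               stringsAsFactors = FALSE)
  }))
  list(richness = rich, pairwise = pw, subsample_size = m)
}

#' TIP-SNP linkage-disequilibrium profile
#'
#' For each TIP, r-squared (squared Pearson correlation over accessions
#' complete in both markers, equivalent to D^2/(p1 q1 p2 q2) for inbred
#' 0/1 coding) against the `n_flank` nearest SNPs on each side, plus the
#' background r-squared among all pairs of those same flanking SNPs.
#' Pairs monomorphic in their complete-case subset are skipped and
#' counted.
#'
#' @param tm a `tip_matrix` (or sites-by-accessions 0/1 matrix with a
#'   `sites` data.frame passed via `tip_sites_df`).
#' @param snps SNP genotype matrix (SNPs x accessions, 0/1, NA allowed);
#'   rownames are SNP ids. Accession columns must cover the TIP matrix
#'   accessions.
#' @param snp_pos data.frame `snp_id`, `chrom`, `pos`.
#' @param n_flank SNPs taken on each side of the TIP.
#' @param thresholds r-squared thresholds for the high-LD proportions.
#' @param tip_sites_df site table when `tm` is a bare matrix.
#' @return list of class `ld_profile`: `tip_snp` (data.frame `site_id`,
#'   `snp_id`, `r2`), `snp_snp_r2` (numeric), `proportions` (data.frame
#'   `threshold`, `tip_snp`, `snp_snp`), `n_monomorphic_skipped`.
#' @export
ld_profile <- function(tm, snps, snp_pos, n_flank = 300,
                       thresholds = c(0.4, 0.2), tip_sites_df = NULL) {
  g <- geno_from(tm)
  sdf <- tip_sites_df %||% tm$sites
  accs <- colnames(g) %||% tm$accessions
  snps <- snps[, accs, drop = FALSE]
  stopifnot(all(snp_pos$snp_id %in% rownames(snps)))
  tip_rows <- list(); bg <- list(); n_mono <- 0L
  for (i in seq_len(nrow(sdf))) {
    ps <- snp_pos[snp_pos$chrom == sdf$chrom[i], ]
    if (nrow(ps) == 0) next
    d <- ps$pos - sdf$position[i]
    up <- ps$snp_id[d < 0][order(-d[d < 0])]
    dn <- ps$snp_id[d >= 0][order(d[d >= 0])]
    sel <- c(rev(head(up, n_flank)), head(dn, n_flank))
    if (length(sel) == 0) next
    block <- t(rbind(tip = g[i, ], snps[sel, , drop = FALSE]))
    cc <- suppressWarnings(cor(block, use = "pairwise.complete.obs"))
    r2 <- cc^2
    tip_r2 <- r2[1, -1]
    n_mono <- n_mono + sum(is.na(tip_r2))
    tip_rows[[length(tip_rows) + 1]] <- data.frame(
      site_id = sdf$site_id[i] %||% rownames(g)[i], snp_id = sel,
      r2 = unname(tip_r2), stringsAsFactors = FALSE
    )
    ss <- r2[-1, -1, drop = FALSE]
    v <- ss[upper.tri(ss)]
    n_mono <- n_mono + sum(is.na(v))
    bg[[length(bg) + 1]] <- v[!is.na(v)]
  }
  tip_snp <- do.call(rbind, tip_rows) %||%
    data.frame(site_id = character(0), snp_id = character(0), r2 = numeric(0))
  snp_snp <- unlist(bg) %||% numeric(0)
  ts <- tip_snp$r2[!is.na(tip_snp$r2)]
  props <- data.frame(
    threshold = thresholds,
    tip_snp = vapply(thresholds, function(t) mean(ts > t), numeric(1)),
    snp_snp = vapply(thresholds, function(t) mean(snp_snp > t), numeric(1))
  )
  structure(list(tip_snp = tip_snp, snp_snp_r2 = snp_snp,
                 proportions = props, n_monomorphic_skipped = n_mono),
            class = "ld_profile")
}

#' Windowed density tracks of TIPs, genes and annotated TEs
#'
#' @param sites a sites data.frame (needs `chrom`, `position`, optionally
#'   `superfamily`).
#' @param genes gene models GRanges (rows with `type == "gene"` counted),
#'   or NULL.
#' @param te_annotation TE annotation GRanges, or NULL.
#' @param ref_lengths named contig lengths.
#' @param window window size in bases (default 500 kb).
#' @return data.frame: `chrom`, `start`, `end`, `n_tips`, per-superfamily
#'   TIP counts (`tips_<superfamily>`), `n_genes`, `n_tes`.
#' @export
density_tracks <- function(sites, genes = NULL, te_annotation = NULL,
                           ref_lengths, window = 5e5) {
  tiles <- unlist(GenomicRanges::tileGenome(ref_lengths, tilewidth = window))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(tiles)),
    start = GenomicRanges::start(tiles),
    end = GenomicRanges::end(tiles)
  )
  count_in <- function(gr) GenomicRanges::countOverlaps(tiles, gr)
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$position, sites$position))
  out$n_tips <- count_in(site_gr)
  sfam <- sites$superfamily %||% rep("other", nrow(sites))
  for (sf in sort(unique(sfam))) {
    out[[paste0("tips_", sf)]] <- count_in(site_gr[sfam == sf])
  }
  if (!is.null(genes)) {
    gg <- if (!is.null(genes$type)) genes[genes$type == "gene"] else genes
    out$n_genes <- count_in(gg)
  }
  if (!is.null(te_annotation)) out$n_tes <- count_in(te_annotation)
  out
}

#' Mappability track from exact pseudo-read uniqueness
#'
#' Tiles pseudo-reads of `read_len` every `step` bases across the
#' reference; a pseudo-read is unique when its sequence occurs exactly
#' once in the genome over both strands (a deterministic, aligner-free
#' proxy for "uniquely mapped, MAPQ >= 10"). Reports the unique fraction
#' per `window`.
#'
#' @param reference a [Biostrings::DNAStringSet] or FASTA path.
#' @param read_len pseudo-read length.
#' @param step tiling step.
#' @param window reporting window (must be >= `read_len`).
#' @return data.frame: `chrom`, `start`, `end`, `fraction`.
#' @export
mappability_track <- function(reference, read_len = 100, step = 10,
                              window = 1e4) {
  ref <- load_reference(reference)
  if (window < read_len) stop("window smaller than read_len")
  reads <- list(); meta <- list()
  for (chrom in names(ref)) {
    L <- Biostrings::width(ref[chrom])
    if (L < read_len) next
    st <- seq(1L, L - read_len + 1L, by = step)
    v <- Biostrings::Views(ref[[chrom]], start = st, width = read_len)
    reads[[chrom]] <- Biostrings::DNAStringSet(v)
    meta[[chrom]] <- data.frame(chrom = chrom, start = st)
  }
  pr <- do.call(c, unname(reads))
  md <- do.call(rbind, meta)
  pd <- Biostrings::PDict(pr)
  counts <- integer(length(pr))
  for (chrom in names(ref)) {
    counts <- counts + Biostrings::countPDict(pd, ref[[chrom]])
    counts <- counts +
      Biostrings::countPDict(pd, Biostrings::reverseComplement(ref[[chrom]]))
  }
  unique_read <- counts == 1L
  out <- list()
  for (chrom in names(ref)) {
    L <- Biostrings::width(ref[chrom])
    ws <- seq(1L, L, by = window)
    sel <- md$chrom == chrom
    bin <- findInterval(md$start[sel], ws)
    frac <- tapply(unique_read[sel], factor(bin, levels = seq_along(ws)),
                   mean)
    out[[chrom]] <- data.frame(
      chrom = chrom, start = ws, end = pmin(ws + window - 1L, L),
      fraction = as.numeric(frac)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a windowed track as bedGraph
#'
#' @param track a data.frame with `chrom`, `start`, `end` and the value
#'   column (1-based closed intervals; converted to BED half-open).
#' @param path output path.
#' @param value_col name of the value column.
#' @return invisibly, `path`.
#' @export
write_bedgraph <- function(track, path, value_col = "fraction") {
  lines <- sprintf("%s\t%d\t%d\t%g", track$chrom, track$start - 1L,
                   track$end, track[[value_col]])
  writeLines(lines, path)
  invisible(path)
}
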