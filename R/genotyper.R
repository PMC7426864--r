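# Presence/absence genotyping of TIP sites by supporting evidence and
# negative coverage: the minimum read depth over the two boundaries of a
# putative insertion site in an accession lacking supporting reads
# distinguishes confident absence (noncarrier) from missing data.

#' Count evidence reads supporting each site per accession
#'
#' An evidence read supports a site when its breakpoint proxy (anchor end
#' for upstream-type evidence, anchor start for downstream-type) falls
#' within `window` bases of the site's confidence interval.
#'
#' @param evidence an evidence frame (possibly several accessions bound
#'   together).
#' @param sites a `tip_sites` object or its `sites` data.frame.
#' @param window support window in bases; should cover the insert-size
#'   reach of discordant mate anchors.
#' @return data.frame `site_id`, `accession`, `n_up`, `n_down`.
#' @export
count_site_support <- function(evidence, sites, window = 600) {
  sdf <- if (inherits(sites, "tip_sites")) sites$sites else sites
  out <- list()
  if (nrow(evidence) > 0 && nrow(sdf) > 0) {
    up <- is_upstream_kind(evidence$evidence_kind)
    proxy <- ifelse(up, evidence$aend, evidence$astart)
    for (i in seq_len(nrow(sdf))) {
      sel <- evidence$chrom == sdf$chrom[i] &
        proxy >= sdf$ci_lo[i] - window & proxy <= sdf$ci_hi[i] + window
      if (!any(sel)) next
      sub <- evidence[sel, , drop = FALSE]
      per <- split(up[sel], sub$accession)
      out[[length(out) + 1]] <- data.frame(
        site_id = sdf$site_id[i],
        accession = names(per),
        n_up = vapply(per, sum, integer(1)),
        n_down = vapply(per, function(u) sum(!u), integer(1)),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_support()
  rownames(res) <- NULL
  res
}

#' Negative coverage at site boundaries
#'
#' Computes, for each site, the minimum over the two insertion boundaries
#' of the number of reads (mapping quality at least `mapq_floor`) whose
#' aligned span covers the boundary with at least one base on each side.
#' When a boundary lies within `flank` of a contig edge only the interior
#' boundary is used (logged).
#'
#' @param aln an alignment frame for one accession.
#' @param sites a `tip_sites` object or its `sites` data.frame.
#' @param flank fetch/edge window in bases.
#' @param mapq_floor minimum mapping quality.
#' @param ref_lengths optional named contig lengths for edge handling.
#' @return integer vector of negative coverage per site (in `sites` order).
#' @export
negative_coverage <- function(aln, sites, flank = 50, mapq_floor = 10,
                              ref_lengths = NULL) {
  sdf <- if (inherits(sites, "tip_sites")) sites$sites else sites
  validate_aln(aln)
  mapped <- !flag_has(aln$flag, FLAG_UNMAPPED) & !is.na(aln$pos) &
    !is.na(aln$mapq) & aln$mapq >= mapq_floor
  sub <- aln[mapped, , drop = FALSE]
  ends <- aln_end(sub)
  out <- integer(nrow(sdf))
  for (chrom in unique(sdf$chrom)) {
    ci <- which(sdf$chrom == chrom)
    ri <- which(sub$rname == chrom)
    st <- sub$pos[ri]; en <- ends[ri]
    for (i in ci) {
      b_lo <- sdf$ci_lo[i]; b_hi <- sdf$ci_hi[i]
      span <- function(b) sum(st <= b - 1L & en >= b + 1L)
      lo_ok <- b_lo > flank
      hi_ok <- is.null(ref_lengths) ||
        b_hi < (ref_lengths[[chrom]] %||% Inf) - flank
      d_lo <- if (lo_ok) span(b_lo) else NA_integer_
      d_hi <- if (hi_ok) span(b_hi) else NA_integer_
      if (is.na(d_lo) && is.na(d_hi)) {
        out[i] <- 0L
      } else {
        if (is.na(d_lo) || is.na(d_hi)) {
          mk_log("site ", sdf$site_id[i], " near contig edge; one boundary used")
        }
        out[i] <- min(d_lo, d_hi, na.rm = TRUE)
      }
    }
  }
  out
}

#' Trichotomous genotype call
#'
#' An accession with at least one supporting read is a carrier. Without
#' support, negative coverage above `negcov_threshold` makes it a
#' noncarrier; at or below the threshold the call is missing (`NA`) -
#' exactly `negcov_threshold` is treated conservatively as missing.
#'
#' @param support_reads supporting read count(s).
#' @param negcov negative coverage value(s).
#' @param negcov_threshold threshold (default 5).
#' @return character vector: `"carrier"`, `"noncarrier"` or `"missing"`.
#' @export
genotype_call <- function(support_reads, negcov, negcov_threshold = 5) {
  stopifnot(all(support_reads >= 0), all(negcov >= 0))
  ifelse(support_reads >= 1, "carrier",
         ifelse(negcov > negcov_threshold, "noncarrier", "missing"))
}

#' Assemble the accessions-by-sites TIP genotype matrix
#'
#' @param sites a `tip_sites` object or its `sites` data.frame.
#' @param support a support data.frame (`site_id`, `accession`, `n_up`,
#'   `n_down`) covering the accessions to genotype.
#' @param negcov a sites-by-accessions matrix of negative coverage
#'   (rownames = site ids, colnames = accession ids).
#' @param accessions accession order; defaults to `colnames(negcov)`.
#' @param negcov_threshold see [genotype_call()].
#' @param drop_empty drop sites with zero carriers after genotyping.
#' @return an object of class `tip_matrix`: list with `sites`,
#'   `accessions`, `geno` (sites x accessions; 1 carrier / 0 noncarrier /
#'   NA missing), `support`, `negcov`, `maf`, `missing_frac`.
#' @export
build_tip_matrix <- function(sites, support, negcov,
                             accessions = colnames(negcov),
                             negcov_threshold = 5, drop_empty = TRUE) {
  sdf <- if (inherits(sites, "tip_sites")) sites$sites else sites
  if (anyDuplicated(accessions)) stop("duplicate accession ids")
  ns <- nrow(sdf); na <- length(accessions)
  sup <- matrix(0L, ns, na, dimnames = list(sdf$site_id, accessions))
  if (nrow(support) > 0) {
    ii <- cbind(match(support$site_id, sdf$site_id),
                match(support$accession, accessions))
    ok <- !is.na(ii[, 1]) & !is.na(ii[, 2])
    sup[ii[ok, , drop = FALSE]] <- support$n_up[ok] + support$n_down[ok]
  }
  if (is.null(dim(negcov))) negcov <- matrix(negcov, ns, na,
                                             dimnames = list(sdf$site_id, accessions))
  calls <- genotype_call(as.vector(sup), as.vector(negcov), negcov_threshold)
  geno <- matrix(ifelse(calls == "carrier", 1L,
                        ifelse(calls == "noncarrier", 0L, NA_integer_)),
                 ns, na, dimnames = list(sdf$site_id, accessions))
  if (drop_empty && ns > 0) {
    n_car <- rowSums(geno == 1L, na.rm = TRUE)
    if (any(n_car == 0)) {
      mk_log(sum(n_car == 0), " site(s) without carriers dropped")
    }
    keep <- n_car > 0
    sdf <- sdf[keep, , drop = FALSE]
    geno <- geno[keep, , drop = FALSE]
    sup <- sup[keep, , drop = FALSE]
    negcov <- negcov[keep, , drop = FALSE]
  }
  new_tip_matrix(sdf, accessions, geno, sup, negcov)
}

new_tip_matrix <- function(sdf, accessions, geno, support = NULL,
                           negcov = NULL) {
  f <- rowMeans(geno == 1L, na.rm = TRUE)
  f[is.nan(f)] <- NA_real_
  structure(list(
    sites = sdf, accessions = accessions, geno = geno,
    support = support, negcov = negcov,
    maf = pmin(f, 1 - f),
    missing_frac = rowMeans(is.na(geno))
  ), class = "tip_matrix")
}

#' @export
print.tip_matrix <- function(x, ...) {
  cat("tip_matrix:", nrow(x$geno), "sites x", length(x$accessions),
      "accessions; median MAF", signif(median(x$maf, na.rm = TRUE), 3),
      "\n")
  invisible(x)
}

#' Genotype all accessions at all sites
#'
#' @param sites a `tip_sites` object.
#' @param evidence_by_acc named list of evidence frames per accession.
#' @param aln_by_acc named list of alignment frames, or a function
#'   `function(accession)` returning one (so large alignments need not be
#'   held simultaneously).
#' @param negcov_threshold,flank,mapq_floor,support_window see
#'   [genotype_call()], [negative_coverage()], [count_site_support()].
#' @param ref_lengths optional named contig lengths.
#' @return a `tip_matrix`.
#' @export
genotype_accessions <- function(sites, evidence_by_acc, aln_by_acc,
                                negcov_threshold = 5, flank = 50,
                                mapq_floor = 10, support_window = 600,
                                ref_lengths = NULL) {
  accs <- names(evidence_by_acc)
  if (anyDuplicated(accs)) stop("duplicate accession ids")
  ev <- do.call(rbind, evidence_by_acc)
  support <- count_site_support(ev, sites, window = support_window)
  sdf <- sites$sites
  negcov <- matrix(0L, nrow(sdf), length(accs),
                   dimnames = list(sdf$site_id, accs))
  for (a in accs) {
    aln <- if (is.function(aln_by_acc)) aln_by_acc(a) else aln_by_acc[[a]]
    negcov[, a] <- negative_coverage(aln, sites, flank = flank,
                                     mapq_floor = mapq_floor,
                                     ref_lengths = ref_lengths)
  }
  build_tip_matrix(sites, support, negcov, accessions = accs,
                   negcov_threshold = negcov_threshold)
}

#' Carrier-count spectrum of a TIP matrix
#'
#' @param tm a `tip_matrix`.
#' @return data.frame `carrier_count`, `n_sites`; the counts sum to the
#'   number of sites.
#' @export
allele_counts <- function(tm) {
  stopifnot(inherits(tm, "tip_matrix"))
  cc <- rowSums(tm$geno == 1L, na.rm = TRUE)
  tab <- table(factor(cc, levels = 0:length(tm$accessions)))
  data.frame(carrier_count = as.integer(names(tab)),
             n_sites = as.integer(tab))
}
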