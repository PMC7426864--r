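# Transcriptional impact of TIPs: genic position classes, carrier vs
# noncarrier expression fold changes, and the downstream/upstream
# elongation-ratio statistic that flags transcript truncation.

POSITION_CLASSES <- c("utr5", "utr3", "exon", "intron",
                      "upstream_1kb", "downstream_1kb")
ELONGATION_BINS <- c("<=0.5", "(0.5-1.5]", "(1.5-2.5]", "(2.5-3.5]",
                     "(3.5-4.5]", ">4.5")

#' Classify TIP positions relative to gene models
#'
#' Assigns each site to the nearest gene within `flank` bases and a
#' position class. Inside a gene the class follows the precedence
#' UTR > exon > intron; outside, `upstream_1kb` / `downstream_1kb` are
#' strand-aware ("within 1 kb" is inclusive at exactly `flank` bases).
#' Sites equidistant from two genes are assigned to both and flagged.
#'
#' @param sites sites data.frame (`site_id`, `chrom`, `position`).
#' @param gene_models GRanges with columns `type` (gene / exon /
#'   five_prime_UTR / three_prime_UTR), `gene_id` and strand.
#' @param flank flank distance in bases (default 1 kb).
#' @return data.frame: `site_id`, `gene_id`, `position_class`,
#'   `distance`, `equidistant`.
#' @export
classify_position <- function(sites, gene_models, flank = 1000) {
  gm <- gene_models
  genes <- gm[gm$type == "gene"]
  out <- list()
  for (i in seq_len(nrow(sites))) {
    p <- sites$position[i]
    on_chr <- as.character(GenomicRanges::seqnames(genes)) == sites$chrom[i]
    if (!any(on_chr)) next
    gs <- GenomicRanges::start(genes)[on_chr]
    ge <- GenomicRanges::end(genes)[on_chr]
    # gap to the gene body; 0 when inside
    d <- ifelse(p < gs, gs - p, ifelse(p > ge, p - ge, 0L))
    within <- which(d <= flank)
    if (length(within) == 0) next
    dmin <- min(d[within])
    nearest <- within[d[within] == dmin]
    equid <- length(nearest) > 1 && dmin > 0
    for (j in nearest) {
      g <- genes[on_chr][j]
      gid <- g$gene_id
      strand <- as.character(GenomicRanges::strand(g))
      if (d[j] == 0) {
        feats <- gm[gm$gene_id == gid & gm$type != "gene"]
        hit <- p >= GenomicRanges::start(feats) & p <= GenomicRanges::end(feats)
        types <- feats$type[hit]
        cls <- if ("five_prime_UTR" %in% types) "utr5"
          else if ("three_prime_UTR" %in% types) "utr3"
          else if ("exon" %in% types) "exon"
          else "intron"
      } else {
        before <- p < GenomicRanges::start(g)
        upstream <- (before && strand != "-") || (!before && strand == "-")
        cls <- if (upstream) "upstream_1kb" else "downstream_1kb"
      }
      out[[length(out) + 1]] <- data.frame(
        site_id = sites$site_id[i], gene_id = gid, position_class = cls,
        distance = d[j], equidistant = equid, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(site_id = character(0), gene_id = character(0),
                      position_class = character(0), distance = integer(0),
                      equidistant = logical(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Carrier vs noncarrier expression effect of a TIP on a gene
#'
#' Restricted to genes expressed above zero in at least `min_expressed`
#' samples. The effect is `log2((mean carriers + eps) / (mean
#' noncarriers + eps))` with a pseudo-count of one normalized unit, and
#' the two-fold classes are `up>=2x` (`log2fc >= 1`), `down>=2x`
#' (`log2fc <= -1`) and `<2x` otherwise.
#'
#' @param expr genes-by-accessions matrix of normalized expression.
#' @param tm a `tip_matrix`.
#' @param gene_id,site_id the gene/site pair to test.
#' @param min_expressed minimum samples with expression > 0.
#' @param min_group minimum carriers and noncarriers with expression data.
#' @param eps pseudo-count (normalized units).
#' @return data.frame row: `site_id`, `gene_id`, `n_carriers`,
#'   `n_noncarriers`, `log2fc_expression`, `expression_class`; or `NULL`
#'   with a message when filtered/skipped.
#' @export
expression_effect <- function(expr, tm, gene_id, site_id,
                              min_expressed = 1, min_group = 2, eps = 1) {
  if (!gene_id %in% rownames(expr)) stop("unknown gene: ", gene_id)
  e <- expr[gene_id, ]
  if (sum(e > 0, na.rm = TRUE) < min_expressed) {
    mk_log(gene_id, " filtered: not expressed in enough samples")
    return(NULL)
  }
  si <- match(site_id, tm$sites$site_id)
  if (is.na(si)) stop("unknown site: ", site_id)
  gt <- tm$geno[si, ]
  accs <- intersect(names(e)[!is.na(e)], tm$accessions[!is.na(gt)])
  car <- accs[gt[accs] == 1L]
  non <- accs[gt[accs] == 0L]
  if (length(car) < min_group || length(non) < min_group) {
    mk_log(site_id, "/", gene_id, " skipped: insufficient group sizes")
    return(NULL)
  }
  l2 <- log2((mean(e[car]) + eps) / (mean(e[non]) + eps))
  data.frame(
    site_id = site_id, gene_id = gene_id,
    n_carriers = length(car), n_noncarriers = length(non),
    log2fc_expression = l2,
    expression_class = if (l2 >= 1) "up>=2x" else if (l2 <= -1) "down>=2x"
      else "<2x",
    stringsAsFactors = FALSE
  )
}

#' Bin an elongation effect magnitude
#'
#' The bins partition the half-line: `<=0.5`, `(0.5-1.5]`, `(1.5-2.5]`,
#' `(2.5-3.5]`, `(3.5-4.5]`, `>4.5` (right-closed edges). The third bin
#' is included to keep the partition contiguous.
#'
#' @param effect non-negative effect magnitude(s).
#' @return character vector of bin labels.
#' @export
elongation_bin <- function(effect) {
  cut(effect, breaks = c(-Inf, 0.5, 1.5, 2.5, 3.5, 4.5, Inf),
      labels = ELONGATION_BINS, right = TRUE) |> as.character()
}

#' Elongation (transcript truncation) effect of a TIP
#'
#' Each accession's elongation ratio is `(downstream reads + eps) /
#' (upstream reads + eps)` over windows flanking the insertion point; the
#' effect is the absolute log2 ratio of the carrier-group median to the
#' noncarrier-group median, binned with [elongation_bin()].
#'
#' @param flank_counts data.frame `accession`, `up_count`, `down_count`
#'   (normalized read counts in the upstream/downstream windows).
#' @param tm a `tip_matrix`.
#' @param site_id the site to test.
#' @param min_group minimum carriers and noncarriers with counts.
#' @param eps pseudo-count.
#' @return data.frame row: `site_id`, `n_carriers`, `n_noncarriers`,
#'   `elongation_log2fc` (signed), `effect` (absolute),
#'   `elongation_bin`; or `NULL` when skipped.
#' @export
elongation_effect <- function(flank_counts, tm, site_id, min_group = 2,
                              eps = 1) {
  si <- match(site_id, tm$sites$site_id)
  if (is.na(si)) stop("unknown site: ", site_id)
  fc <- flank_counts
  if (all(fc$up_count == 0 & fc$down_count == 0)) {
    mk_log(site_id, " skipped: zero counts in all accessions")
    return(NULL)
  }
  gt <- tm$geno[si, ]
  fc <- fc[fc$accession %in% tm$accessions[!is.na(gt)], , drop = FALSE]
  ratio <- (fc$down_count + eps) / (fc$up_count + eps)
  is_car <- gt[fc$accession] == 1L
  if (sum(is_car) < min_group || sum(!is_car) < min_group) {
    mk_log(site_id, " skipped: insufficient group sizes")
    return(NULL)
  }
  l2 <- log2(median(ratio[is_car]) / median(ratio[!is_car]))
  data.frame(
    site_id = site_id, n_carriers = sum(is_car),
    n_noncarriers = sum(!is_car), elongation_log2fc = l2,
    effect = abs(l2), elongation_bin = elongation_bin(abs(l2)),
    stringsAsFactors = FALSE
  )
}

#' Impact table for many site/gene pairs
#'
#' Convenience wrapper combining [classify_position()],
#' [expression_effect()] and (when flank counts are given)
#' [elongation_effect()].
#'
#' @param tm a `tip_matrix`.
#' @param gene_models gene model GRanges.
#' @param expr genes-by-accessions normalized expression matrix.
#' @param flank_counts optional named list per site of flank-count
#'   data.frames.
#' @param flank classification flank (bases).
#' @return data.frame of impact records.
#' @export
impact_table <- function(tm, gene_models, expr, flank_counts = NULL,
                         flank = 1000) {
  cls <- classify_position(tm$sites, gene_models, flank = flank)
  rows <- list()
  for (i in seq_len(nrow(cls))) {
    if (!cls$gene_id[i] %in% rownames(expr)) next
    ee <- expression_effect(expr, tm, cls$gene_id[i], cls$site_id[i])
    if (is.null(ee)) next
    rec <- cbind(cls[i, c("gene_id", "position_class", "distance")],
                 ee[, setdiff(names(ee), "gene_id")])
    rec$site_id <- cls$site_id[i]
    if (!is.null(flank_counts) && cls$site_id[i] %in% names(flank_counts)) {
      el <- elongation_effect(flank_counts[[cls$site_id[i]]], tm,
                              cls$site_id[i])
      if (!is.null(el)) {
        rec$elongation_log2fc <- el$elongation_log2fc
        rec$elongation_bin <- el$elongation_bin
      }
    }
    rows[[length(rows) + 1]] <- rec
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) rownames(out) <- NULL
  out
}
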