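# VCF 4.2 serialisation of TIP sites and genotypes using symbolic
# mobile-element insertion alleles: ALT = <INS:ME:FAMILY>, INFO key MEINFO
# (family, ci_lo, ci_hi, superfamily), FORMAT GT (1 carrier / 0 noncarrier
# / . missing), DP (negative coverage), SR (supporting reads).

#' Write a TIP matrix to VCF
#'
#' @param tm a `tip_matrix`.
#' @param path output `.vcf` path.
#' @param ref_lengths optional named contig lengths for `##contig` lines.
#' @param superfamilies optional named character vector mapping family to
#'   superfamily (e.g. from [family_superfamily()]).
#' @return invisibly, `path`.
#' @export
write_tips_vcf <- function(tm, path, ref_lengths = NULL,
                           superfamilies = NULL) {
  stopifnot(inherits(tm, "tip_matrix"))
  sdf <- tm$sites
  sfam <- sdf$superfamily %||% unname(superfamilies[sdf$te_family]) %||%
    rep(NA_character_, nrow(sdf))
  sfam[is.na(sfam)] <- "other"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mobilomekit",
    if (!is.null(ref_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(ref_lengths),
              as.integer(ref_lengths))
    },
    "##ALT=<ID=INS:ME,Description=\"Mobile element insertion\">",
    paste0("##INFO=<ID=MEINFO,Number=4,Type=String,Description=",
           "\"Mobile element info: family,ci_lo,ci_hi,superfamily\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype (1 carrier, 0 noncarrier)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Negative coverage\">",
    "##FORMAT=<ID=SR,Number=1,Type=Integer,Description=\"Supporting reads\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", tm$accessions), collapse = "\t")
  )
  n <- nrow(sdf)
  body <- character(n)
  for (i in seq_len(n)) {
    gt <- tm$geno[i, ]
    dp <- if (!is.null(tm$negcov)) tm$negcov[i, ] else rep(0L, length(gt))
    sr <- if (!is.null(tm$support)) tm$support[i, ] else rep(0L, length(gt))
    samp <- sprintf("%s:%d:%d",
                    ifelse(is.na(gt), ".", as.character(gt)),
                    as.integer(dp), as.integer(sr))
    info <- sprintf("MEINFO=%s,%d,%d,%s", sdf$te_family[i],
                    sdf$ci_lo[i], sdf$ci_hi[i], sfam[i])
    body[i] <- paste(c(sdf$chrom[i], sdf$position[i], sdf$site_id[i], "N",
                       sprintf("<INS:ME:%s>", sdf$te_family[i]), ".",
                       "PASS", info, "GT:DP:SR", samp), collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a TIP VCF back into a `tip_matrix`
#'
#' Understands the profile written by [write_tips_vcf()].
#' @param path a `.vcf` path.
#' @return a `tip_matrix`.
#' @export
read_tips_vcf <- function(path) {
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM", lines)
  if (length(hdr_i) != 1) stop("not a VCF: missing #CHROM header")
  cols <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  accessions <- cols[-(1:9)]
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body)]
  n <- length(body)
  parts <- strsplit(body, "\t", fixed = TRUE)
  sdf <- data.frame(
    site_id = vapply(parts, `[[`, character(1), 3),
    chrom = vapply(parts, `[[`, character(1), 1),
    position = as.integer(vapply(parts, `[[`, character(1), 2)),
    stringsAsFactors = FALSE
  )
  info <- vapply(parts, `[[`, character(1), 8)
  me <- strsplit(sub(".*MEINFO=([^;]*).*", "\\1", info), ",", fixed = TRUE)
  sdf$ci_lo <- as.integer(vapply(me, `[[`, character(1), 2))
  sdf$ci_hi <- as.integer(vapply(me, `[[`, character(1), 3))
  sdf$te_family <- vapply(me, `[[`, character(1), 1)
  sdf$superfamily <- vapply(me, `[[`, character(1), 4)
  na <- length(accessions)
  geno <- matrix(NA_integer_, n, na, dimnames = list(sdf$site_id, accessions))
  dp <- matrix(0L, n, na, dimnames = dimnames(geno))
  sr <- matrix(0L, n, na, dimnames = dimnames(geno))
  for (i in seq_len(n)) {
    fields <- strsplit(parts[[i]][-(1:9)], ":", fixed = TRUE)
    g <- vapply(fields, `[[`, character(1), 1)
    geno[i, ] <- ifelse(g == ".", NA_integer_, as.integer(g))
    dp[i, ] <- as.integer(vapply(fields, `[[`, character(1), 2))
    sr[i, ] <- as.integer(vapply(fields, `[[`, character(1), 3))
  }
  sdf$n_accessions <- rowSums(sr > 0)
  new_tip_matrix(sdf, accessions, geno, sr, dp)
}

#' Write / read a TIP matrix as TSV (sites x accessions)
#'
#' Genotypes are 1 (carrier), 0 (noncarrier) or NA (missing); site
#' metadata occupy the leading columns.
#' @param tm a `tip_matrix`.
#' @param path output path.
#' @return invisibly `path` (writer); a `tip_matrix` (reader).
#' @export
write_matrix_tsv <- function(tm, path) {
  stopifnot(inherits(tm, "tip_matrix"))
  meta_cols <- intersect(c("site_id", "chrom", "position", "ci_lo", "ci_hi",
                           "te_family", "superfamily"), names(tm$sites))
  out <- cbind(tm$sites[, meta_cols, drop = FALSE], as.data.frame(tm$geno))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(c("site_id", "chrom", "position", "ci_lo", "ci_hi",
                           "te_family", "superfamily"), names(df))
  sdf <- df[, meta_cols, drop = FALSE]
  geno <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  mode(geno) <- "integer"
  rownames(geno) <- sdf$site_id
  new_tip_matrix(sdf, colnames(geno), geno)
}
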