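# Split-read / discordant-pair detection of non-reference TE insertions.
# The four classical steps: (i) extract reads that are unmapped or
# discordant, (ii) align them locally to the TE library and keep partial
# (>=20 nt) hits or full hits whose mate is not TE-derived, (iii) remap the
# non-TE portion (or use the mate) as an oriented reference anchor, and
# (iv) cluster oriented evidence into candidate insertion loci, intersected
# across accessions into TIP sites.

#' Estimate insert-size metrics from proper pairs
#'
#' @param aln an alignment frame (see [read_alignments()]).
#' @param sample_size use at most this many proper pairs.
#' @return a list of class `insert_metrics`: `mean_insert`, `sd_insert`,
#'   `read_len`, and `discordance_distance` (ten times the mean library
#'   size; pairs mapping further apart are treated as discordant).
#' @export
estimate_insert_metrics <- function(aln, sample_size = 10000) {
  validate_aln(aln)
  if (any(!flag_has(aln$flag, FLAG_PAIRED))) stop("unpaired reads in input")
  sel <- flag_has(aln$flag, FLAG_PROPER) & flag_has(aln$flag, FLAG_FIRST) &
    !flag_has(aln$flag, FLAG_UNMAPPED) & !is.na(aln$isize) & aln$isize > 0
  tl <- head(aln$isize[sel], sample_size)
  if (length(tl) < 100) stop("cannot estimate insert size")
  m <- mean(tl)
  structure(list(
    mean_insert = m,
    sd_insert = sd(tl),
    read_len = round(median(nchar(aln$seq), na.rm = TRUE)),
    discordance_distance = 10 * m
  ), class = "insert_metrics")
}

#' Extract candidate evidence reads
#'
#' Keeps exactly the reads that are (a) unmapped (SAM flag 4), (b) in a
#' pair whose mates map to different contigs, or (c) in a same-contig pair
#' whose mapped positions are separated by more than the discordance
#' distance. Each retained read carries its mate's anchor coordinates and
#' mapping quality when the mate is mapped.
#'
#' @param aln a coordinate-sorted, paired alignment frame.
#' @param metrics an [estimate_insert_metrics()] result.
#' @return subset of `aln` with extra columns `mate_mapped`, `mate_rname`,
#'   `mate_pos`, `mate_reverse`, `mate_mapq`, `mate_len`.
#' @export
extract_candidate_reads <- function(aln, metrics) {
  validate_aln(aln)
  stopifnot(inherits(metrics, "insert_metrics"))
  if (any(!flag_has(aln$flag, FLAG_PAIRED))) stop("unpaired reads in input")
  mapped <- !flag_has(aln$flag, FLAG_UNMAPPED)
  pos_by_chr <- split(aln$pos[mapped], aln$rname[mapped])
  if (any(vapply(pos_by_chr, is.unsorted, logical(1), na.rm = TRUE))) {
    stop("input is not coordinate-sorted")
  }
  mate_mapped <- !flag_has(aln$flag, FLAG_MATE_UNMAPPED)
  dd <- metrics$discordance_distance
  cand <- !mapped |
    (mapped & mate_mapped & !is.na(aln$mrnm) & aln$mrnm != aln$rname) |
    (mapped & mate_mapped & !is.na(aln$mrnm) & aln$mrnm == aln$rname &
       abs(aln$pos - aln$mpos) > dd)
  out <- aln[cand, , drop = FALSE]

  # pull the mate's own record for mapq / length
  mate_bit <- ifelse(flag_has(aln$flag, FLAG_FIRST), 2L, 1L)
  key <- paste(aln$qname, ifelse(flag_has(aln$flag, FLAG_FIRST), 1L, 2L))
  mate_key <- paste(out$qname, mate_bit[cand])
  mi <- match(mate_key, key)
  out$mate_mapped <- mate_mapped[cand]
  out$mate_rname <- out$mrnm
  out$mate_pos <- out$mpos
  out$mate_reverse <- flag_has(out$flag, FLAG_MATE_REVERSE)
  out$mate_mapq <- ifelse(is.na(mi), NA_integer_, aln$mapq[mi])
  out$mate_seq <- ifelse(is.na(mi), NA_character_, aln$seq[mi])
  out$mate_len <- nchar(out$mate_seq)
  rownames(out) <- NULL
  out
}

# ---- local alignment of candidates to the TE library ------------------------

# Seeded, ungapped-first local alignment of reads against library copies.
# 20-mers sampled every 10 bases seed (read, copy, strand) pairs; on the
# modal diagonal the maximal-scoring segment under match +2 / mismatch -3
# is found exactly (Kadane); when seeds disagree on the diagonal (indel
# signal) the pair is refined with an exact Smith-Waterman
# (Biostrings::pairwiseAlignment, gap open -5, gap extend -2).
te_seed_hits <- function(reads, subjects, k = 20L, stride = 10L) {
  w <- nchar(reads)
  offs <- lapply(w, function(wi) {
    if (wi < k) return(integer(0))
    unique(c(seq(1L, wi - k + 1L, by = stride), wi - k + 1L))
  })
  n_per <- lengths(offs)
  read_idx <- rep(seq_along(reads), n_per)
  off_vec <- unlist(offs)
  if (length(off_vec) == 0) return(NULL)
  kmers <- substring(reads[read_idx], off_vec, off_vec + k - 1L)
  ok <- !grepl("[^ACGT]", kmers)
  read_idx <- read_idx[ok]; off_vec <- off_vec[ok]; kmers <- kmers[ok]
  if (length(kmers) == 0) return(NULL)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  hits <- list()
  for (si in seq_along(subjects)) {
    m <- Biostrings::matchPDict(pd, subjects[[si]])
    st <- Biostrings::startIndex(m)  # plain list: cheap to manipulate
    cnt <- lengths(st)
    hit <- which(cnt > 0)
    if (length(hit) == 0) next
    hits[[length(hits) + 1]] <- data.frame(
      read = rep(read_idx[hit], cnt[hit]),
      off = rep(off_vec[hit], cnt[hit]),
      subject = si,
      te_pos = unlist(st[hit], use.names = FALSE)
    )
  }
  if (length(hits) == 0) return(NULL)
  do.call(rbind, hits)
}

# best-scoring ungapped segment of read vs subject along diagonal d
# (te_pos = d + read_pos); returns read_start/read_end/score
kadane_diag <- function(read, subject_chars, d, match = 2, mismatch = -3) {
  w <- nchar(read)
  S <- length(subject_chars)
  i_lo <- max(1L, 1L - d)
  i_hi <- min(w, S - d)
  if (i_hi < i_lo) return(NULL)
  rch <- charToRaw(substr(read, i_lo, i_hi))
  sch <- subject_chars[(d + i_lo):(d + i_hi)]
  sc <- ifelse(rch == sch, match, mismatch)
  best <- 0; best_s <- 0L; best_e <- -1L
  cur <- 0; cur_s <- 1L
  for (i in seq_along(sc)) {
    cur <- cur + sc[i]
    if (cur <= 0) { cur <- 0; cur_s <- i + 1L } else if (cur > best) {
      best <- cur; best_s <- cur_s; best_e <- i
    }
  }
  if (best_e < best_s) return(NULL)
  list(read_start = i_lo + best_s - 1L, read_end = i_lo + best_e - 1L,
       score = best)
}

#' Align candidate reads to the TE library
#'
#' `builtin_local` mode uses a seeded local aligner (exact 20-mer seeds,
#' ungapped extension under match +2 / mismatch -3, Smith-Waterman
#' refinement with gap open -5 / gap extend -2 when seeds disagree on the
#' diagonal) and reports the best-scoring family per read, on either
#' strand. `external_adapter` mode parses a SAM file produced by any local
#' aligner run against the library FASTA written by [write_library()].
#'
#' @param candidates output of [extract_candidate_reads()].
#' @param lib a `te_library`.
#' @param mode `"builtin_local"` or `"external_adapter"`.
#' @param min_partial minimum partial alignment length (used to derive the
#'   default score threshold `2 * min_partial`, which a perfect
#'   `min_partial`-mer meets exactly).
#' @param min_score score threshold for reporting a hit.
#' @param external_sam path to the SAM file for `external_adapter` mode.
#' @return data.frame with one row per read with a hit: `idx` (row in
#'   `candidates`), `qname`, `te_family`, `te_copy`, `te_strand`, `score`,
#'   `read_start`, `read_end`, `te_aligned_len`, `clip5`, `clip3`.
#' @export
align_to_te <- function(candidates, lib,
                        mode = c("builtin_local", "external_adapter"),
                        min_partial = 20, min_score = 2 * min_partial,
                        external_sam = NULL) {
  mode <- match.arg(mode)
  if (length(lib$families) == 0) stop("empty TE library")
  if (mode == "external_adapter") {
    return(te_hits_from_sam(candidates, external_sam, min_score))
  }
  reads <- candidates$seq
  w <- nchar(reads)
  copies <- library_sequences(lib)
  n_cop <- length(copies)
  subjects <- c(as.list(copies), as.list(Biostrings::reverseComplement(copies)))
  subj_chars <- lapply(subjects, function(s) charToRaw(as.character(s)))
  seed <- te_seed_hits(reads, subjects)
  if (is.null(seed)) return(empty_te_hits())

  seed$diag <- seed$te_pos - seed$off
  # per (read, subject): number of distinct seeded offsets and modal diagonal
  grp <- paste(seed$read, seed$subject)
  agg <- lapply(split(seq_len(nrow(seed)), grp), function(ii) {
    dg <- seed$diag[ii]
    tab <- sort(table(dg), decreasing = TRUE)
    list(read = seed$read[ii[1]], subject = seed$subject[ii[1]],
         n_off = length(unique(seed$off[ii])),
         diag = as.integer(names(tab)[1]),
         n_diag = length(tab))
  })
  per_read <- split(agg, vapply(agg, `[[`, numeric(1), "read"))

  res <- vector("list", length(per_read))
  nm <- names(copies)
  for (pi in seq_along(per_read)) {
    entries <- per_read[[pi]]
    # evaluate the best-seeded subjects (cap at 4) and keep the top score
    n_off <- vapply(entries, `[[`, numeric(1), "n_off")
    entries <- entries[order(-n_off)][seq_len(min(4L, length(entries)))]
    best <- NULL
    for (en in entries) {
      ri <- en$read; si <- en$subject
      seg <- kadane_diag(reads[ri], subj_chars[[si]], en$diag)
      if (en$n_diag > 1) {
        # possible indel: exact SW refinement
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::DNAStringSet(reads[ri]), subjects[[si]],
          type = "local",
          substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = 2, mismatch = -3, baseOnly = FALSE),
          gapOpening = 5, gapExtension = 2
        )
        sw <- list(
          read_start = Biostrings::start(Biostrings::pattern(pa)),
          read_end = Biostrings::end(Biostrings::pattern(pa)),
          score = Biostrings::score(pa)
        )
        if (is.null(seg) || sw$score > seg$score) seg <- sw
      }
      if (is.null(seg)) next
      cand_nm <- nm[(si - 1L) %% n_cop + 1L]
      if (is.null(best) || seg$score > best$score ||
          (seg$score == best$score && cand_nm < best$copy_name)) {
        best <- seg
        best$subject <- si
        best$copy_name <- cand_nm
        best$read <- ri
      }
    }
    if (is.null(best) || best$score < min_score) next
    parts <- strsplit(best$copy_name, "|", fixed = TRUE)[[1]]
    res[[pi]] <- data.frame(
      idx = best$read, qname = candidates$qname[best$read],
      te_family = parts[1], te_copy = parts[2],
      te_strand = if (best$subject <= n_cop) "+" else "-",
      score = best$score,
      read_start = best$read_start, read_end = best$read_end,
      te_aligned_len = best$read_end - best$read_start + 1L,
      clip5 = best$read_start - 1L,
      clip3 = w[best$read] - best$read_end,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(empty_te_hits())
  rownames(out) <- NULL
  out
}

empty_te_hits <- function() {
  data.frame(idx = integer(0), qname = character(0),
             te_family = character(0), te_copy = character(0),
             te_strand = character(0), score = numeric(0),
             read_start = integer(0), read_end = integer(0),
             te_aligned_len = integer(0), clip5 = integer(0),
             clip3 = integer(0), stringsAsFactors = FALSE)
}

te_hits_from_sam <- function(candidates, external_sam, min_score) {
  if (is.null(external_sam)) stop("external_adapter mode needs external_sam")
  sam <- read_alignments(external_sam)
  sam <- sam[!flag_has(sam$flag, FLAG_UNMAPPED), , drop = FALSE]
  idx <- match(sam$qname, candidates$qname)
  keep <- !is.na(idx)
  sam <- sam[keep, , drop = FALSE]; idx <- idx[keep]
  clip5 <- as.integer(sub("^([0-9]+)S.*", "\\1",
                          ifelse(grepl("^[0-9]+S", sam$cigar), sam$cigar, "0S")))
  clip3 <- as.integer(sub(".*?([0-9]+)S$", "\\1",
                          ifelse(grepl("[0-9]+S$", sam$cigar), sam$cigar, "0S")))
  w <- nchar(candidates$seq[idx])
  parts <- strsplit(sam$rname, "|", fixed = TRUE)
  rev <- flag_has(sam$flag, FLAG_REVERSE)
  # CIGAR clips are in reference orientation; flip back to read coords
  c5 <- ifelse(rev, clip3, clip5)
  c3 <- ifelse(rev, clip5, clip3)
  aligned <- w - c5 - c3
  data.frame(
    idx = idx, qname = sam$qname,
    te_family = vapply(parts, `[[`, character(1), 1),
    te_copy = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                     character(1)),
    te_strand = ifelse(rev, "-", "+"),
    score = 2 * aligned,
    read_start = c5 + 1L, read_end = w - c3,
    te_aligned_len = aligned, clip5 = c5, clip3 = c3,
    stringsAsFactors = FALSE
  )
}

#' Select TE-supported evidence reads
#'
#' Keeps reads with a partial TE alignment of at least `min_partial` nt
#' and a non-TE remainder of at least `min_partial` nt (split evidence),
#' or a full TE alignment whose mate has no TE hit and can serve as the
#' reference anchor (discordant evidence). Everything else is dropped.
#'
#' @param hits output of [align_to_te()].
#' @param candidates the candidate frame the hits refer to.
#' @param min_partial minimum partial alignment / remainder length (nt).
#' @return data.frame of evidence precursors with columns `idx`, `qname`,
#'   `kind_pre` (`"split"`/`"full"`), TE hit columns, `anchor_seq` and
#'   `te_side` (split), mate anchor columns (full).
#' @export
select_evidence <- function(hits, candidates, min_partial = 20) {
  if (nrow(hits) == 0) return(hits[0, , drop = FALSE])
  w <- nchar(candidates$seq[hits$idx])
  big_clip <- pmax(hits$clip5, hits$clip3)
  is_split <- hits$te_aligned_len >= min_partial & big_clip >= min_partial
  is_full <- !is_split & hits$clip5 < min_partial & hits$clip3 < min_partial

  # key of the mate among TE hits: a full-TE read is evidence only if its
  # mate is NOT itself TE-derived
  mate_of <- function(df) {
    first <- flag_has(df$flag, FLAG_FIRST)
    paste(df$qname, ifelse(first, 2L, 1L))
  }
  hit_keys <- paste(candidates$qname[hits$idx],
                    ifelse(flag_has(candidates$flag[hits$idx], FLAG_FIRST),
                           1L, 2L))
  cand_sub <- candidates[hits$idx, , drop = FALSE]
  mate_has_te <- mate_of(cand_sub) %in% hit_keys
  mate_anchorable <- cand_sub$mate_mapped |
    (!is.na(cand_sub$mate_seq) & !mate_has_te)
  is_full <- is_full & !mate_has_te & mate_anchorable

  out <- cbind(hits, cand_sub[, c("flag", "seq", "mate_mapped", "mate_rname",
                                  "mate_pos", "mate_reverse", "mate_mapq",
                                  "mate_seq", "mate_len")])
  out$kind_pre <- ifelse(is_split, "split", ifelse(is_full, "full", "drop"))
  out <- out[out$kind_pre != "drop", , drop = FALSE]
  if (nrow(out) == 0) return(out)
  # anchor = the larger non-TE remainder
  te_side <- ifelse(out$clip5 >= out$clip3, "5p_anchor", "3p_anchor")
  out$anchor_seq <- ifelse(
    out$kind_pre == "split",
    ifelse(out$clip5 >= out$clip3,
           substr(out$seq, 1L, out$read_start - 1L),
           substring(out$seq, out$read_end + 1L)),
    NA_character_
  )
  # side of the read occupied by TE sequence, in read coordinates: when the
  # larger (anchoring) remainder is the 5' prefix, the TE occupies the 3' end
  out$te_side <- ifelse(out$clip5 >= out$clip3, "3p", "5p")
  rownames(out) <- NULL
  out
}

# occurrence counting of an anchor in the reference (both strands), at the
# smallest mismatch level 0..max_mm with any hit
anchor_place <- function(anchor, ref_chars, max_mm = 2) {
  pat <- Biostrings::DNAString(anchor)
  rc <- Biostrings::reverseComplement(pat)
  for (m in 0:max_mm) {
    found <- NULL
    n_hits <- 0L
    for (chrom in names(ref_chars)) {
      for (strand in c("+", "-")) {
        p <- if (strand == "+") pat else rc
        mt <- Biostrings::matchPattern(p, ref_chars[[chrom]], max.mismatch = m)
        if (length(mt) > 0) {
          n_hits <- n_hits + length(mt)
          if (is.null(found)) {
            found <- list(chrom = chrom, start = BiocGenerics::start(mt)[1],
                          end = BiocGenerics::end(mt)[1], strand = strand,
                          mismatches = m)
          }
        }
        if (n_hits > 1) return(list(n = n_hits))
      }
    }
    if (n_hits == 1) return(c(list(n = 1L), found))
    if (n_hits > 1) return(list(n = n_hits))
  }
  list(n = 0L)
}

#' Remap evidence anchors to the reference and orient the evidence
#'
#' The non-TE remainder of split reads is located in the reference by
#' exact search, escalating the allowed mismatch count up to `max_mm`
#' until a hit is found; anchors hitting more than one locus at their best
#' level are dropped as multimapped (tallied). Full-TE reads use their
#' mapped mate as the anchor (mapping quality at least `mapq_floor`), or
#' their mate's sequence remapped the same way when the mate was unmapped.
#'
#' Evidence kinds: a split read whose TE portion sits at the genomic 3'
#' side of the anchor is `softclip_3p` (upstream evidence; the anchor's
#' end estimates the breakpoint); at the 5' side, `softclip_5p`. A
#' plus-strand mate anchor is `discordant_plus` (TE expected to its
#' right); minus-strand, `discordant_minus`.
#'
#' @param selected output of [select_evidence()].
#' @param reference a [Biostrings::DNAStringSet] or FASTA path.
#' @param accession accession id stored on the evidence.
#' @param max_mm maximum mismatches allowed when placing anchors.
#' @param mapq_floor minimum mate mapping quality for mate anchors.
#' @return data.frame of class columns: `accession`, `read_id`,
#'   `evidence_kind`, `chrom`, `astart`, `aend`, `te_family`,
#'   `te_aligned_len`, `clip_len`. The number of anchors dropped as
#'   multimapped is available as `attr(, "n_multimapped")`.
#' @export
remap_anchors <- function(selected, reference, accession = "sample",
                          max_mm = 2, mapq_floor = 10) {
  ref <- load_reference(reference)
  ref_chars <- as.list(ref)
  n_multi <- 0L
  rows <- vector("list", nrow(selected))
  if (nrow(selected) > 0) for (i in seq_len(nrow(selected))) {
    e <- selected[i, ]
    if (e$kind_pre == "split") {
      pl <- anchor_place(e$anchor_seq, ref_chars, max_mm)
      if (pl$n != 1L) { n_multi <- n_multi + (pl$n > 1L); next }
      te_side_genomic <- if (pl$strand == "+") e$te_side else
        c(`5p` = "3p", `3p` = "5p")[[e$te_side]]
      kind <- if (te_side_genomic == "3p") "softclip_3p" else "softclip_5p"
      rows[[i]] <- data.frame(
        accession = accession, read_id = e$qname, evidence_kind = kind,
        chrom = pl$chrom, astart = pl$start, aend = pl$end,
        te_family = e$te_family, te_aligned_len = e$te_aligned_len,
        clip_len = e$te_aligned_len, stringsAsFactors = FALSE
      )
    } else {
      if (isTRUE(e$mate_mapped)) {
        if (!is.na(e$mate_mapq) && e$mate_mapq < mapq_floor) next
        chrom <- e$mate_rname; st <- e$mate_pos
        en <- st + (e$mate_len %||% nchar(e$seq)) - 1L
        rev <- isTRUE(e$mate_reverse)
      } else {
        pl <- anchor_place(e$mate_seq, ref_chars, max_mm)
        if (pl$n != 1L) { n_multi <- n_multi + (pl$n > 1L); next }
        chrom <- pl$chrom; st <- pl$start; en <- pl$end
        rev <- pl$strand == "-"
      }
      kind <- if (!rev) "discordant_plus" else "discordant_minus"
      rows[[i]] <- data.frame(
        accession = accession, read_id = e$qname, evidence_kind = kind,
        chrom = chrom, astart = st, aend = en,
        te_family = e$te_family, te_aligned_len = e$te_aligned_len,
        clip_len = NA_integer_, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_evidence()
  rownames(out) <- NULL
  attr(out, "n_multimapped") <- n_multi
  out
}

empty_evidence <- function() {
  data.frame(accession = character(0), read_id = character(0),
             evidence_kind = character(0), chrom = character(0),
             astart = integer(0), aend = integer(0),
             te_family = character(0), te_aligned_len = integer(0),
             clip_len = integer(0), stringsAsFactors = FALSE)
}

is_upstream_kind <- function(kind) kind %in% c("softclip_3p", "discordant_plus")

#' Cluster oriented evidence into candidate insertion loci
#'
#' Evidence on one contig is grouped by a greedy scan: a locus collects
#' all evidence whose anchor start lies within `max_span` of the locus
#' seed. A locus becomes a cluster when it holds at least two reads in
#' valid orientation order: no downstream-type element
#' (`softclip_5p`/`discordant_minus`) may lie strictly left of an
#' upstream-type element (`softclip_3p`/`discordant_plus`), comparing
#' anchor starts. Breakpoints: `breakpoint_lo` is the maximal end of
#' 3'-soft-clip anchors (else of plus-discordant anchors);
#' `breakpoint_hi` the minimal start of 5'-soft-clip anchors (else of
#' minus-discordant anchors). Target-site duplications make
#' `breakpoint_hi < breakpoint_lo`; an overlap beyond `tsd_tol` rejects
#' the cluster as incoherent.
#'
#' @param evidence an evidence frame from [remap_anchors()].
#' @param max_span locus span in bases (typically
#'   `mean_insert + 3 * sd_insert`).
#' @param tsd_tol maximal allowed breakpoint overlap (bases).
#' @return data.frame of clusters: `accession`, `chrom`, `breakpoint_lo`,
#'   `breakpoint_hi`, `position`, `te_family`, `n_up`, `n_down`,
#'   `n_total`, `precise`.
#' @export
call_clusters <- function(evidence, max_span, tsd_tol = 25) {
  if (nrow(evidence) == 0) return(empty_clusters())
  ev <- evidence[order(evidence$chrom, evidence$astart), ]
  rows <- list()
  for (chrom in unique(ev$chrom)) {
    sub <- ev[ev$chrom == chrom, ]
    i <- 1L
    while (i <= nrow(sub)) {
      seed <- sub$astart[i]
      in_locus <- which(sub$astart >= seed & sub$astart <= seed + max_span)
      loc <- sub[in_locus, ]
      cl <- summarise_cluster(loc, tsd_tol)
      if (!is.null(cl)) rows[[length(rows) + 1]] <- cl
      i <- max(in_locus) + 1L
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_clusters())
  rownames(out) <- NULL
  out
}

summarise_cluster <- function(loc, tsd_tol) {
  if (nrow(loc) < 2) return(NULL)
  up <- is_upstream_kind(loc$evidence_kind)
  # valid ordering: no downstream element strictly left of an upstream one
  if (any(up) && any(!up) &&
      max(loc$astart[up]) > min(loc$astart[!up])) {
    # tolerate pairs caused by the anchor layout only when every up/down
    # pair is still orderable: strict violation -> no cluster
    if (!all(outer(loc$astart[up], loc$astart[!up], `<=`))) {
      # some pair violates; the rule requires all pairs ordered
      return(NULL)
    }
  }
  sc3 <- loc$evidence_kind == "softclip_3p"
  sc5 <- loc$evidence_kind == "softclip_5p"
  dp <- loc$evidence_kind == "discordant_plus"
  dm <- loc$evidence_kind == "discordant_minus"
  lo <- if (any(sc3)) max(loc$aend[sc3]) else if (any(dp)) max(loc$aend[dp]) else NA
  hi <- if (any(sc5)) min(loc$astart[sc5]) else if (any(dm)) min(loc$astart[dm]) else NA
  if (!is.na(lo) && !is.na(hi) && hi < lo - tsd_tol) return(NULL)
  fam_tab <- sort(table(loc$te_family), decreasing = TRUE)
  if (length(fam_tab) > 1 && fam_tab[1] == fam_tab[2]) {
    tied <- names(fam_tab)[fam_tab == fam_tab[1]]
    fam <- sort(tied)[1]
    mk_log("family tie at ", loc$chrom[1], ":", loc$astart[1],
           " resolved to ", fam)
  } else {
    fam <- names(fam_tab)[1]
  }
  blo <- if (is.na(lo)) min(loc$astart) else lo
  bhi <- if (is.na(hi)) max(loc$aend) else hi
  data.frame(
    accession = loc$accession[1], chrom = loc$chrom[1],
    breakpoint_lo = blo, breakpoint_hi = bhi,
    position = floor((blo + bhi) / 2),
    te_family = fam,
    n_up = sum(up), n_down = sum(!up), n_total = nrow(loc),
    precise = any(sc3) && any(sc5),
    stringsAsFactors = FALSE
  )
}

empty_clusters <- function() {
  data.frame(accession = character(0), chrom = character(0),
             breakpoint_lo = integer(0), breakpoint_hi = integer(0),
             position = integer(0), te_family = character(0),
             n_up = integer(0), n_down = integer(0), n_total = integer(0),
             precise = logical(0), stringsAsFactors = FALSE)
}

#' Intersect per-accession clusters into TIP sites
#'
#' Clusters from all accessions whose positions lie within `merge_window`
#' (single linkage on cluster positions) are merged into one candidate
#' site. A site is emitted when at least one accession's merged support
#' satisfies `n_up >= 1`, `n_down >= 1` and `n_total >= min_reads`.
#'
#' @param clusters a data.frame of clusters (rows from [call_clusters()],
#'   possibly many accessions), or a list of such frames.
#' @param merge_window merge distance in bases.
#' @param min_reads minimum total evidence reads in the best accession.
#' @return a list of class `tip_sites`: `sites` (data.frame `site_id`,
#'   `chrom`, `position`, `ci_lo`, `ci_hi`, `te_family`, `n_accessions`)
#'   and `support` (data.frame `site_id`, `accession`, `n_up`, `n_down`).
#' @export
intersect_sites <- function(clusters, merge_window = 100, min_reads = 3) {
  if (is.list(clusters) && !is.data.frame(clusters)) {
    clusters <- do.call(rbind, clusters)
  }
  if (is.null(clusters) || nrow(clusters) == 0) {
    return(structure(list(sites = empty_sites(),
                          support = empty_support()), class = "tip_sites"))
  }
  cl <- clusters[order(clusters$chrom, clusters$position), ]
  grp_id <- integer(nrow(cl))
  gid <- 0L
  for (chrom in unique(cl$chrom)) {
    idx <- which(cl$chrom == chrom)
    pos <- cl$position[idx]
    newgrp <- c(TRUE, diff(pos) > merge_window)
    gid_local <- cumsum(newgrp) + gid
    grp_id[idx] <- gid_local
    gid <- max(gid_local)
  }
  sites <- list(); support <- list()
  sid <- 0L
  for (g in unique(grp_id)) {
    sub <- cl[grp_id == g, , drop = FALSE]
    sup <- do.call(rbind, lapply(split(sub, sub$accession), function(s) {
      data.frame(accession = s$accession[1],
                 n_up = sum(s$n_up), n_down = sum(s$n_down),
                 stringsAsFactors = FALSE)
    }))
    ok <- any(sup$n_up >= 1 & sup$n_down >= 1 &
                (sup$n_up + sup$n_down) >= min_reads)
    if (!ok) next
    sid <- sid + 1L
    fam_tab <- sort(tapply(sub$n_total, sub$te_family, sum), decreasing = TRUE)
    tied <- names(fam_tab)[fam_tab == fam_tab[1]]
    fam <- sort(tied)[1]
    prec <- sub$precise
    pos <- if (any(prec)) round(median(sub$position[prec])) else
      round(median(sub$position))
    site_id <- sprintf("TIP%05d", sid)
    sites[[sid]] <- data.frame(
      site_id = site_id, chrom = sub$chrom[1], position = pos,
      ci_lo = min(sub$breakpoint_lo, sub$breakpoint_hi),
      ci_hi = max(sub$breakpoint_lo, sub$breakpoint_hi),
      te_family = fam, n_accessions = nrow(sup),
      stringsAsFactors = FALSE
    )
    sup$site_id <- site_id
    support[[sid]] <- sup[, c("site_id", "accession", "n_up", "n_down")]
  }
  structure(list(
    sites = if (length(sites)) do.call(rbind, sites) else empty_sites(),
    support = if (length(support)) do.call(rbind, support) else empty_support()
  ), class = "tip_sites")
}

empty_sites <- function() {
  data.frame(site_id = character(0), chrom = character(0),
             position = integer(0), ci_lo = integer(0), ci_hi = integer(0),
             te_family = character(0), n_accessions = integer(0),
             stringsAsFactors = FALSE)
}

empty_support <- function() {
  data.frame(site_id = character(0), accession = character(0),
             n_up = integer(0), n_down = integer(0),
             stringsAsFactors = FALSE)
}

#' @export
print.tip_sites <- function(x, ...) {
  cat("tip_sites:", nrow(x$sites), "sites across",
      length(unique(x$support$accession)), "accessions\n")
  invisible(x)
}

#' Run the full per-accession detection
#'
#' Convenience wrapper running insert-size estimation, candidate
#' extraction, TE-library alignment, evidence selection, anchor remapping
#' and clustering for one accession.
#'
#' @param aln an alignment frame.
#' @param lib a `te_library`.
#' @param reference reference genome ([Biostrings::DNAStringSet] or path).
#' @param accession accession id.
#' @param min_partial,max_mm,mapq_floor,tsd_tol see the stage functions.
#' @param max_span cluster span; default `mean_insert + 3 * sd_insert`.
#' @return a list: `metrics`, `evidence`, `clusters`, `n_multimapped`.
#' @export
detect_insertions <- function(aln, lib, reference,
                              accession = attr(aln, "accession") %||% "sample",
                              min_partial = 20, max_mm = 2, mapq_floor = 10,
                              max_span = NULL, tsd_tol = 25) {
  metrics <- estimate_insert_metrics(aln)
  max_span <- max_span %||% (metrics$mean_insert + 3 * metrics$sd_insert)
  cand <- extract_candidate_reads(aln, metrics)
  hits <- align_to_te(cand, lib, min_partial = min_partial)
  sel <- select_evidence(hits, cand, min_partial = min_partial)
  ev <- remap_anchors(sel, reference, accession = accession,
                      max_mm = max_mm, mapq_floor = mapq_floor)
  cls <- call_clusters(ev, max_span = max_span, tsd_tol = tsd_tol)
  list(metrics = metrics, evidence = ev, clusters = cls,
       n_multimapped = attr(ev, "n_multimapped"))
}
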