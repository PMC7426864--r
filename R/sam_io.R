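# Alignment records are carried through the pipeline as a plain data.frame
# ("aln frame") with the canonical SAM columns:
#   qname, flag, rname, pos, mapq, cigar, mrnm, mpos, isize, seq
# Unmapped reads keep their sequence and, when placed, the mate's
# rname/pos (standard SAM placement convention). Coordinates are 1-based.

ALN_COLS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
              "mrnm", "mpos", "isize", "seq")

validate_aln <- function(aln) {
  if (!is.data.frame(aln) || !all(ALN_COLS %in% names(aln))) {
    stop("alignment frame must contain columns: ", paste(ALN_COLS, collapse = ", "))
  }
  invisible(aln)
}

#' Read paired-end alignments into an alignment frame
#'
#' Accepts a coordinate-sorted BAM file, or a plain-text SAM file which is
#' converted on the fly with [Rsamtools::asBam()].
#'
#' @param path path to a `.bam` or `.sam` file.
#' @return a data.frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `mrnm`, `mpos`, `isize`, `seq`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
            "mrnm", "mpos", "isize", "seq")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
  data.frame(
    qname = res$qname,
    flag = as.integer(res$flag),
    rname = as.character(res$rname),
    pos = as.integer(res$pos),
    mapq = as.integer(res$mapq),
    cigar = as.character(res$cigar),
    mrnm = as.character(res$mrnm),
    mpos = as.integer(res$mpos),
    isize = as.integer(res$isize),
    seq = as.character(res$seq),
    stringsAsFactors = FALSE
  )
}

#' Write an alignment frame to a SAM file
#'
#' @param aln an alignment frame (see [read_alignments()]).
#' @param path output `.sam` path.
#' @param ref_lengths named integer vector of contig lengths for the `@SQ`
#'   header lines.
#' @return invisibly, `path`.
#' @export
write_sam <- function(aln, path, ref_lengths) {
  validate_aln(aln)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  rname <- ifelse(is.na(aln$rname), "*", aln$rname)
  mrnm <- ifelse(is.na(aln$mrnm), "*",
                 ifelse(!is.na(aln$rname) & aln$mrnm == aln$rname, "=", aln$mrnm))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
                  aln$qname, aln$flag, rname,
                  ifelse(is.na(aln$pos), 0L, aln$pos),
                  ifelse(is.na(aln$mapq), 0L, aln$mapq),
                  ifelse(is.na(aln$cigar), "*", aln$cigar),
                  mrnm,
                  ifelse(is.na(aln$mpos), 0L, aln$mpos),
                  ifelse(is.na(aln$isize), 0L, aln$isize),
                  ifelse(is.na(aln$seq), "*", aln$seq))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Reference end (inclusive) of each mapped record; NA for unmapped.
aln_end <- function(aln) {
  end <- rep(NA_integer_, nrow(aln))
  mapped <- !flag_has(aln$flag, FLAG_UNMAPPED) & !is.na(aln$pos)
  end[mapped] <- aln$pos[mapped] + cigar_ref_width(aln$cigar[mapped]) - 1L
  end
}

#' Write paired reads to a pair of FASTQ files
#'
#' @param aln an alignment frame holding both mates of each pair.
#' @param prefix output prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written with `/1` `/2` read-name suffixes.
#' @return invisibly, the two paths.
#' @export
write_fastq_pairs <- function(aln, prefix) {
  validate_aln(aln)
  out <- character(2)
  for (mate in 1:2) {
    bit <- if (mate == 1) FLAG_FIRST else FLAG_SECOND
    sub <- aln[flag_has(aln$flag, bit), ]
    sub <- sub[order(sub$qname), ]
    # reads are stored in reference orientation; FASTQ wants as-sequenced
    seqs <- ifelse(flag_has(sub$flag, FLAG_REVERSE) &
                     !flag_has(sub$flag, FLAG_UNMAPPED),
                   revcomp_chr(sub$seq), sub$seq)
    qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
    lines <- as.vector(rbind(paste0("@", sub$qname, "/", mate),
                             seqs, "+", qual))
    out[mate] <- paste0(prefix, "_", mate, ".fastq")
    writeLines(lines, out[mate])
  }
  invisible(out)
}
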