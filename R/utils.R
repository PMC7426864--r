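# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# SAM flag bits
FLAG_PAIRED <- 0x1L
FLAG_PROPER <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_MATE_REVERSE <- 0x20L
FLAG_FIRST <- 0x40L
FLAG_SECOND <- 0x80L

flag_has <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

#' @noRd
mk_log <- function(..., verbose = getOption("mobilomekit.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[mobilomekit] ", ...)
  invisible(NULL)
}

# Reference-consumed width of a CIGAR string (M/D/N/=/X).
cigar_ref_width <- function(cigar) {
  w <- integer(length(cigar))
  ok <- !is.na(cigar) & cigar != "*"
  if (any(ok)) {
    w[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[ok])
  }
  w
}

# Fast vectorised reverse complement on plain character vectors.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

stop_mk <- function(msg, class) {
  stop(structure(
    class = c(class, "mobilomekit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
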