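# TE family library: extraction of annotated TE copies from a reference
# genome, organised per family with superfamily metadata. The library is the
# alignment target for candidate evidence reads.

SUPERFAMILIES <- c("GYPSY", "COPIA", "LINE", "MuDR", "hAT", "CACTA", "other")
SUPERFAMILY_CLASS <- c(
  GYPSY = "I", COPIA = "I", LINE = "I",
  MuDR = "II", hAT = "II", CACTA = "II", other = NA_character_
)

normalize_superfamily <- function(x) {
  x <- as.character(x)
  key <- toupper(x)
  map <- c(
    GYPSY = "GYPSY", COPIA = "COPIA", LINE = "LINE",
    MUDR = "MuDR", HAT = "hAT", CACTA = "CACTA"
  )
  out <- unname(map[key])
  out[is.na(out)] <- "other"
  out
}

#' Build a TE family library from a reference genome and TE annotation
#'
#' Extracts the sequence of every annotated TE copy from the reference
#' (reverse-complementing minus-strand copies) and groups copies by family.
#' A family is retained when at least one of its annotated copies reaches
#' `min_copy_len`; within retained families, copies shorter than
#' `copy_floor` are excluded from the alignment target as they add noise
#' without contributing anchoring power.
#'
#' @param reference a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param te_annotation a [GenomicRanges::GRanges] with metadata columns
#'   `family` (or `Family`) and optionally `superfamily`/`Superfamily`, or a
#'   path to a GFF3 (`Family=`/`Superfamily=` attributes, fallback: `ID`
#'   prefix before the first dot) or 6-column BED file whose name field is
#'   `family#superfamily`.
#' @param min_copy_len minimum length (bases) of the longest copy for a
#'   family to be retained. Default 1000.
#' @param copy_floor minimum copy length kept inside retained families.
#' @param max_n_frac copies with a higher fraction of N bases are dropped
#'   with a warning.
#'
#' @return an object of class `te_library`: a list with elements
#'   `families` (named list; each family has `name`, `superfamily`, `class`,
#'   `sequences` (a named [Biostrings::DNAStringSet]) and
#'   `longest_copy_len`) and `min_copy_len`.
#'
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 600), collapse = "")))
#' ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1200),
#'   strand = "+", family = "F1", superfamily = "COPIA")
#' lib <- build_te_library(ref, ann)
#' library_summary(lib)
#' @export
build_te_library <- function(reference, te_annotation, min_copy_len = 1000,
                             copy_floor = 200, max_n_frac = 0.10) {
  ref <- load_reference(reference)
  ann <- load_te_annotation(te_annotation)

  fam <- as.character(ann$family)
  bad <- is.na(fam) | fam == ""
  if (any(bad)) {
    warning(sum(bad), " annotation record(s) missing a family attribute; dropped")
    ann <- ann[!bad]
    fam <- fam[!bad]
  }
  if (length(ann) == 0L) stop("empty TE library")

  sf <- normalize_superfamily(ann$superfamily %||% rep("other", length(ann)))
  chrom <- as.character(GenomicRanges::seqnames(ann))
  if (!all(chrom %in% names(ref))) {
    stop("annotation references sequences absent from the reference: ",
         paste(unique(setdiff(chrom, names(ref))), collapse = ", "))
  }
  st <- GenomicRanges::start(ann)
  en <- GenomicRanges::end(ann)
  too_far <- en > Biostrings::width(ref)[match(chrom, names(ref))] | st < 1L
  if (any(too_far)) stop("annotation interval(s) outside reference bounds")

  widths <- en - st + 1L
  # family retained iff its longest annotated copy reaches min_copy_len
  fam_max <- tapply(widths, fam, max)
  keep_fams <- names(fam_max)[fam_max >= min_copy_len]
  if (length(keep_fams) == 0L) stop("empty TE library")

  keep <- fam %in% keep_fams & widths >= copy_floor
  ann <- ann[keep]; fam <- fam[keep]; sf <- sf[keep]
  chrom <- chrom[keep]; st <- st[keep]; en <- en[keep]

  seqs <- Biostrings::DNAStringSet(lapply(seq_along(ann), function(i) {
    s <- Biostrings::subseq(ref[[chrom[i]]], st[i], en[i])
    if (as.character(GenomicRanges::strand(ann)[i]) == "-") {
      s <- Biostrings::reverseComplement(s)
    }
    s
  }))
  copy_id <- ann$copy_id %||% NULL
  if (is.null(copy_id)) {
    copy_id <- paste0(fam, ".", stats::ave(seq_along(fam), fam, FUN = seq_along))
  }
  names(seqs) <- copy_id

  n_frac <- Biostrings::letterFrequency(seqs, "N", as.prob = TRUE)[, 1]
  if (any(n_frac > max_n_frac)) {
    warning(sum(n_frac > max_n_frac), " copies with >", 100 * max_n_frac,
            "% N dropped")
    ok <- n_frac <= max_n_frac
    seqs <- seqs[ok]; fam <- fam[ok]; sf <- sf[ok]
  }
  if (length(seqs) == 0L) stop("empty TE library")

  fams <- lapply(sort(unique(fam)), function(f) {
    idx <- which(fam == f)
    sfam <- names(sort(table(sf[idx]), decreasing = TRUE))[1]
    structure(list(
      name = f,
      superfamily = sfam,
      class = unname(SUPERFAMILY_CLASS[sfam]),
      sequences = seqs[idx],
      longest_copy_len = max(Biostrings::width(seqs[idx]))
    ), class = "te_family")
  })
  names(fams) <- vapply(fams, `[[`, character(1), "name")
  structure(list(families = fams, min_copy_len = min_copy_len),
            class = "te_library")
}

load_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) return(reference)
  if (is.character(reference) && length(reference) == 1L) {
    return(Biostrings::readDNAStringSet(reference))
  }
  stop("reference must be a DNAStringSet or FASTA path")
}

# Accepts GRanges, GFF3 or BED. Returns GRanges with mcols family,
# superfamily, copy_id.
load_te_annotation <- function(te_annotation) {
  if (is.character(te_annotation) && length(te_annotation) == 1L) {
    if (grepl("\\.bed$", te_annotation, ignore.case = TRUE)) {
      gr <- rtracklayer::import(te_annotation, format = "BED")
      nm <- gr$name %||% rep(NA_character_, length(gr))
      parts <- strsplit(nm, "#", fixed = TRUE)
      gr$family <- vapply(parts, function(p) p[1] %||% NA_character_, character(1))
      gr$superfamily <- vapply(parts, function(p) {
        if (length(p) >= 2) p[2] else "other"
      }, character(1))
      return(gr)
    }
    gr <- rtracklayer::import(te_annotation)
  } else if (inherits(te_annotation, "GRanges")) {
    gr <- te_annotation
  } else {
    stop("te_annotation must be a GRanges or GFF3/BED path")
  }
  mc <- S4Vectors::mcols(gr)
  fam <- mc$family %||% mc$Family
  if (is.null(fam)) {
    id <- mc$ID
    fam <- if (is.null(id)) rep(NA_character_, length(gr)) else sub("\\..*$", "", id)
  }
  gr$family <- as.character(fam)
  sfc <- mc$superfamily %||% mc$Superfamily %||% rep("other", length(gr))
  gr$superfamily <- as.character(sfc)
  if (!is.null(mc$ID) && is.null(mc$copy_id)) gr$copy_id <- as.character(mc$ID)
  gr
}

#' Summarise a TE library
#'
#' @param lib a `te_library` from [build_te_library()].
#' @return a data.frame with one row per family: `family`, `superfamily`,
#'   `class`, `n_copies`, `longest_copy_len`.
#' @export
library_summary <- function(lib) {
  stopifnot(inherits(lib, "te_library"))
  do.call(rbind, lapply(lib$families, function(f) {
    data.frame(family = f$name, superfamily = f$superfamily, class = f$class,
               n_copies = length(f$sequences),
               longest_copy_len = f$longest_copy_len,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' All copy sequences of a library as one set
#'
#' Names follow `family|copy_id|superfamily`, the header convention of the
#' exported library FASTA.
#' @param lib a `te_library`.
#' @return a named [Biostrings::DNAStringSet].
#' @export
library_sequences <- function(lib) {
  stopifnot(inherits(lib, "te_library"))
  out <- Biostrings::DNAStringSet()
  for (f in lib$families) {
    s <- f$sequences
    names(s) <- paste(f$name, names(s), f$superfamily, sep = "|")
    out <- c(out, s)
  }
  out
}

#' @export
print.te_library <- function(x, ...) {
  n_cop <- sum(vapply(x$families, function(f) length(f$sequences), integer(1)))
  cat("te_library:", length(x$families), "families,", n_cop,
      "copies (min family copy length", x$min_copy_len, "bp)\n")
  invisible(x)
}

#' Write a TE library to FASTA plus a TSV summary
#'
#' @param lib a `te_library`.
#' @param fasta,summary_tsv output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_library <- function(lib, fasta = NULL, summary_tsv = NULL) {
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(library_sequences(lib), fasta)
  }
  if (!is.null(summary_tsv)) {
    write.table(library_summary(lib), summary_tsv, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(c(fasta, summary_tsv))
}

#' Family to superfamily lookup for a library
#' @param lib a `te_library`.
#' @return named character vector family -> superfamily.
#' @export
family_superfamily <- function(lib) {
  vapply(lib$families, `[[`, character(1), "superfamily")
}
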