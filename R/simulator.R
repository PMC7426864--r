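# Deterministic mobilome simulator. Produces a random reference genome with
# planted, slightly degenerate "ancestral" TE copies (the source of the TE
# library) and toy gene models; spikes full-length TE insertions (with a
# 0-6 bp target-site duplication) into per-accession genomes under a
# rare-allele-skewed sharing model and superfamily placement biases; and
# simulates paired-end reads. In perfect-alignment mode each read's true
# origin is lifted back to reference coordinates, emulating an end-to-end
# aligner: reads fully contained in reference-derived segments are emitted
# as mapped records, while reads overlapping inserted TE sequence are
# emitted as unmapped records (SAM flag 4) with their sequence and, when
# available, their mate's anchor - the hermetic input to the detection
# pipeline.

DEFAULT_SIM_SUPERFAMILIES <- c("COPIA", "GYPSY", "MuDR", "hAT", "LINE", "CACTA")

#' Simulation configuration
#'
#' Defaults describe the hermetic benchmark condition used throughout the
#' package tests: a 1 Mb genome in two contigs, five TE families, ten
#' accessions, fifty insertion events with a rare-skewed sharing spectrum
#' (P(k carriers) proportional to k^-2), 20x depth, 100 bp error-free
#' paired reads with a 400 +/- 40 bp insert.
#'
#' @param genome_len total genome length in bases.
#' @param n_chroms number of equal-length contigs.
#' @param n_families number of TE families.
#' @param copy_len_range range (bases) of family consensus lengths.
#' @param n_ancestral planted degenerate copies per family (library source).
#' @param n_accessions number of inbred accessions.
#' @param n_events number of distinct insertion events.
#' @param sharing `"powerlaw"` (P(k) ~ k^-2, truncated at `n_accessions`)
#'   or `"private"` (every event has exactly one carrier).
#' @param placement_bias named list per superfamily with probabilities
#'   `genic`, `pericentromeric`, `uniform` (must sum to 1). Defaults bias
#'   COPIA and the Class II superfamilies towards genes and GYPSY/LINE
#'   towards the pericentromere.
#' @param depth mean per-accession sequencing depth.
#' @param read_len read length in bases.
#' @param insert_mean,insert_sd fragment-size distribution (Normal,
#'   truncated at `2 * read_len`).
#' @param error_rate per-base substitution error rate.
#' @param tsd_range target-site duplication lengths, sampled uniformly.
#' @param min_event_spacing minimum distance between events on a contig;
#'   colliding draws are resampled. Kept above the evidence-cluster span so
#'   events yield separable clusters.
#' @param edge_margin minimum distance of events from contig ends.
#' @param seed integer seed fixing all randomness downstream.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(genome_len = 1e6, n_chroms = 2, n_families = 5,
                       copy_len_range = c(1000, 3000), n_ancestral = 2,
                       n_accessions = 10, n_events = 50,
                       sharing = c("powerlaw", "private"),
                       placement_bias = NULL,
                       depth = 20, read_len = 100,
                       insert_mean = 400, insert_sd = 40,
                       error_rate = 0, tsd_range = c(0, 6),
                       min_event_spacing = 2500, edge_margin = 1500,
                       seed = 1) {
  sharing <- match.arg(sharing)
  if (is.null(placement_bias)) {
    genic <- c(genic = 0.7, pericentromeric = 0.1, uniform = 0.2)
    peri <- c(genic = 0.1, pericentromeric = 0.7, uniform = 0.2)
    placement_bias <- list(COPIA = genic, MuDR = genic, hAT = genic,
                           CACTA = genic, GYPSY = peri, LINE = peri,
                           other = c(genic = 1 / 3, pericentromeric = 1 / 3,
                                     uniform = 1 / 3))
  }
  stopifnot(genome_len > 0, n_chroms >= 1, n_families >= 1,
            n_accessions >= 1, n_events >= 1, depth > 0, read_len > 0,
            insert_mean > 0, insert_sd >= 0, error_rate >= 0,
            all(abs(vapply(placement_bias, sum, numeric(1)) - 1) < 1e-8))
  structure(list(
    genome_len = genome_len, n_chroms = n_chroms, n_families = n_families,
    copy_len_range = copy_len_range, n_ancestral = n_ancestral,
    n_accessions = n_accessions, n_events = n_events, sharing = sharing,
    placement_bias = placement_bias, depth = depth, read_len = read_len,
    insert_mean = insert_mean, insert_sd = insert_sd,
    error_rate = error_rate, tsd_range = tsd_range,
    min_event_spacing = min_event_spacing, edge_margin = edge_margin,
    seed = as.integer(seed)
  ), class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, rate) {
  n <- nchar(s)
  k <- rbinom(1, n, rate)
  if (k == 0) return(s)
  pos <- sample.int(n, k)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ch[pos] <- vapply(ch[pos], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  paste(ch, collapse = "")
}

#' Simulate a reference genome with planted TE copies and gene models
#'
#' @param cfg a [sim_config()].
#' @return a list of class `sim_genome`: `reference`
#'   ([Biostrings::DNAStringSet]), `te_annotation` (GRanges with `family`,
#'   `superfamily`, `copy_id`), `genes` (GRanges with `type` in
#'   gene/exon/five_prime_UTR/three_prime_UTR and `gene_id`),
#'   `pericentromere` (GRanges), and `cfg`.
#' @export
sim_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  clen <- rep(floor(cfg$genome_len / cfg$n_chroms), cfg$n_chroms)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  seqs <- vapply(clen, random_dna, character(1))
  names(seqs) <- chroms

  sfams <- rep_len(DEFAULT_SIM_SUPERFAMILIES, cfg$n_families)
  fam_names <- sprintf("FAM%02d", seq_len(cfg$n_families))
  cons_len <- sample(seq(cfg$copy_len_range[1], cfg$copy_len_range[2]),
                     cfg$n_families, replace = TRUE)
  consensus <- vapply(cons_len, random_dna, character(1))

  # plant degenerate ancestral copies, non-overlapping, away from the edges
  occupied <- lapply(chroms, function(x) cbind(numeric(0), numeric(0)))
  names(occupied) <- chroms
  ann <- list()
  for (i in seq_len(cfg$n_families)) {
    for (j in seq_len(cfg$n_ancestral)) {
      len <- cons_len[i]
      for (try in 1:200) {
        chr <- sample(chroms, 1)
        if (clen[match(chr, chroms)] < len + 2 * cfg$edge_margin) next
        st <- sample(seq(cfg$edge_margin,
                         clen[match(chr, chroms)] - len - cfg$edge_margin), 1)
        occ <- occupied[[chr]]
        if (nrow(occ) == 0 ||
            all(st + len - 1 < occ[, 1] - 200 | st > occ[, 2] + 200)) {
          occupied[[chr]] <- rbind(occ, c(st, st + len - 1))
          strand <- sample(c("+", "-"), 1)
          degen <- mutate_seq(consensus[i], 0.02)
          planted <- if (strand == "-") revcomp_chr(degen) else degen
          substr(seqs[chr], st, st + len - 1) <- planted
          ann[[length(ann) + 1]] <- data.frame(
            chrom = chr, start = st, end = st + len - 1, strand = strand,
            family = fam_names[i], superfamily = sfams[i],
            copy_id = sprintf("%s.%d", fam_names[i], j),
            stringsAsFactors = FALSE
          )
          break
        }
      }
    }
  }
  ann <- do.call(rbind, ann)
  te_gr <- GenomicRanges::GRanges(ann$chrom,
                                  IRanges::IRanges(ann$start, ann$end),
                                  strand = ann$strand)
  te_gr$family <- ann$family
  te_gr$superfamily <- ann$superfamily
  te_gr$copy_id <- ann$copy_id

  # toy gene models: one ~2 kb gene every ~8 kb, two exons separated by a
  # 400 bp intron, 100 bp UTRs
  genes <- list()
  gid <- 0L
  for (ci in seq_along(chroms)) {
    starts <- seq(3000, clen[ci] - 5000, by = 8000)
    for (st in starts) {
      occ <- occupied[[chroms[ci]]]
      if (nrow(occ) > 0 && any(st <= occ[, 2] & st + 1999 >= occ[, 1])) next
      gid <- gid + 1L
      gene_id <- sprintf("GENE%04d", gid)
      strand <- if (gid %% 2 == 0) "-" else "+"
      rows <- data.frame(
        chrom = chroms[ci],
        start = c(st, st, st + 1200, st, st + 1900),
        end = c(st + 1999, st + 799, st + 1999, st + 99, st + 1999),
        type = c("gene", "exon", "exon", "five_prime_UTR", "three_prime_UTR"),
        stringsAsFactors = FALSE
      )
      if (strand == "-") {
        rows$type[rows$type == "five_prime_UTR"] <- "tmp"
        rows$type[rows$type == "three_prime_UTR"] <- "five_prime_UTR"
        rows$type[rows$type == "tmp"] <- "three_prime_UTR"
      }
      rows$strand <- strand
      rows$gene_id <- gene_id
      genes[[length(genes) + 1]] <- rows
    }
  }
  genes <- do.call(rbind, genes)
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end),
                                    strand = genes$strand)
  gene_gr$type <- genes$type
  gene_gr$gene_id <- genes$gene_id

  peri <- GenomicRanges::GRanges(
    chroms, IRanges::IRanges(floor(clen / 3), floor(2 * clen / 3))
  )
  structure(list(
    reference = Biostrings::DNAStringSet(seqs),
    te_annotation = te_gr,
    genes = gene_gr,
    pericentromere = peri,
    cfg = cfg
  ), class = "sim_genome")
}

draw_carrier_count <- function(n, n_acc, sharing) {
  if (sharing == "private") return(rep(1L, n))
  k <- seq_len(n_acc)
  p <- k^-2 / sum(k^-2)
  sample(k, n, replace = TRUE, prob = p)
}

#' Spike TE insertions into per-accession genomes
#'
#' Each event inserts a full-length copy of a library family (its longest
#' copy) plus a target-site duplication at a position drawn by the
#' superfamily placement bias; carrier sets are drawn from the sharing
#' model. Per-accession genomes and segment maps (the liftover between
#' accession and reference coordinates) are recorded.
#'
#' Truth `position` is the 1-based coordinate of the last reference base
#' before the duplicated target site: the accession haplotype is
#' `ref[1..position+tsd] + TE + ref[position+1..]`.
#'
#' @param genome a [sim_genome()].
#' @param lib a `te_library` (typically built from the simulated genome's
#'   own annotation with [build_te_library()]).
#' @param cfg optional [sim_config()]; defaults to `genome$cfg`.
#' @return a list of class `sim_mobilome` with `truth` (data.frame:
#'   `event_id`, `chrom`, `position`, `tsd`, `te_family`, `superfamily`,
#'   `carriers` list-column), `accessions`, `segments` (per-accession
#'   liftover tables), `genomes` (per-accession named character vectors of
#'   contig sequences), plus the inputs.
#' @export
spike_insertions <- function(genome, lib, cfg = NULL) {
  stopifnot(inherits(genome, "sim_genome"), inherits(lib, "te_library"))
  cfg <- cfg %||% genome$cfg
  set.seed(cfg$seed + 1017L)
  ref <- as.character(genome$reference)
  clen <- nchar(ref)
  chroms <- names(ref)
  fams <- names(lib$families)
  sfam <- family_superfamily(lib)

  gene_tbl <- genome$genes[genome$genes$type == "gene"]
  peri <- genome$pericentromere

  placed <- data.frame(chrom = character(0), pos = integer(0))
  events <- list()
  n_collisions <- 0L
  for (i in seq_len(cfg$n_events)) {
    fam <- sample(fams, 1)
    sf <- sfam[[fam]]
    bias <- cfg$placement_bias[[sf]] %||% cfg$placement_bias[["other"]]
    ok <- FALSE
    for (try in 1:1000) {
      mode <- sample(names(bias), 1, prob = bias)
      if (mode == "genic" && length(gene_tbl) > 0) {
        g <- gene_tbl[sample(length(gene_tbl), 1)]
        chr <- as.character(GenomicRanges::seqnames(g))
        lo <- max(GenomicRanges::start(g) - 500, cfg$edge_margin)
        hi <- min(GenomicRanges::end(g) + 500,
                  clen[chr] - cfg$edge_margin)
      } else if (mode == "pericentromeric") {
        idx <- sample(length(peri), 1)
        chr <- as.character(GenomicRanges::seqnames(peri))[idx]
        lo <- max(GenomicRanges::start(peri)[idx], cfg$edge_margin)
        hi <- min(GenomicRanges::end(peri)[idx], clen[chr] - cfg$edge_margin)
      } else {
        chr <- sample(chroms, 1, prob = clen)
        lo <- cfg$edge_margin
        hi <- clen[chr] - cfg$edge_margin
      }
      if (hi <= lo) next
      p <- sample(seq(lo, hi), 1)
      near <- placed$chrom == chr & abs(placed$pos - p) < cfg$min_event_spacing
      if (any(near)) { n_collisions <- n_collisions + 1L; next }
      placed <- rbind(placed, data.frame(chrom = chr, pos = p))
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place event ", i, "; genome too crowded")
    tsd <- sample(seq(cfg$tsd_range[1], cfg$tsd_range[2]), 1)
    events[[i]] <- data.frame(
      event_id = sprintf("EV%03d", i), chrom = chr, position = p,
      tsd = tsd, te_family = fam, superfamily = sf,
      stringsAsFactors = FALSE
    )
  }
  if (n_collisions > 0) {
    mk_log(n_collisions, " placement collisions resampled")
  }
  truth <- do.call(rbind, events)
  accs <- sprintf("acc%02d", seq_len(cfg$n_accessions))
  k <- draw_carrier_count(nrow(truth), cfg$n_accessions, cfg$sharing)
  truth$carriers <- lapply(k, function(ki) sort(sample(accs, ki)))

  # insertion sequences: longest copy per family
  ins_seq <- vapply(fams, function(f) {
    s <- lib$families[[f]]$sequences
    as.character(s[[which.max(Biostrings::width(s))]])
  }, character(1))

  genomes <- list()
  segments <- list()
  for (a in accs) {
    segs <- list()
    acc_seq <- character(length(chroms))
    names(acc_seq) <- chroms
    for (chr in chroms) {
      ev <- truth[truth$chrom == chr &
                    vapply(truth$carriers, function(cs) a %in% cs, logical(1)), ]
      ev <- ev[order(ev$position), ]
      pieces <- character(0)
      seg_rows <- list()
      prev <- 0L
      acc_off <- 0L
      if (nrow(ev) > 0) {
        for (j in seq_len(nrow(ev))) {
          p <- ev$position[j]; t <- ev$tsd[j]
          rs <- prev + 1L; re <- p + t
          piece <- substr(ref[chr], rs, re)
          pieces <- c(pieces, piece)
          seg_rows[[length(seg_rows) + 1]] <- data.frame(
            chrom = chr, a_start = acc_off + 1L,
            a_end = acc_off + nchar(piece), kind = "ref",
            ref_start = rs, ref_end = re, event_id = NA_character_,
            stringsAsFactors = FALSE
          )
          acc_off <- acc_off + nchar(piece)
          te <- ins_seq[[ev$te_family[j]]]
          pieces <- c(pieces, te)
          seg_rows[[length(seg_rows) + 1]] <- data.frame(
            chrom = chr, a_start = acc_off + 1L,
            a_end = acc_off + nchar(te), kind = "te",
            ref_start = NA_integer_, ref_end = NA_integer_,
            event_id = ev$event_id[j], stringsAsFactors = FALSE
          )
          acc_off <- acc_off + nchar(te)
          prev <- p
        }
      }
      piece <- substr(ref[chr], prev + 1L, clen[chr])
      pieces <- c(pieces, piece)
      seg_rows[[length(seg_rows) + 1]] <- data.frame(
        chrom = chr, a_start = acc_off + 1L, a_end = acc_off + nchar(piece),
        kind = "ref", ref_start = prev + 1L, ref_end = clen[[chr]],
        event_id = NA_character_, stringsAsFactors = FALSE
      )
      acc_seq[chr] <- paste(pieces, collapse = "")
      segs[[chr]] <- do.call(rbind, seg_rows)
    }
    genomes[[a]] <- acc_seq
    segments[[a]] <- do.call(rbind, segs)
  }
  structure(list(
    genome = genome, lib = lib, cfg = cfg, truth = truth,
    accessions = accs, segments = segments, genomes = genomes
  ), class = "sim_mobilome")
}

#' Simulate paired-end reads for one accession
#'
#' Fragment positions are uniform over the accession genome with
#' Normal(insert_mean, insert_sd) fragment sizes truncated at
#' `2 * read_len`; substitution errors are applied at `error_rate`. In
#' perfect mode each read is lifted to reference coordinates through the
#' accession's segment map: reads fully inside reference-derived segments
#' become mapped records; reads overlapping inserted TE sequence become
#' unmapped records (flag 4) carrying their sequence, placed at the mate's
#' position when the mate maps. Sequences are stored in accession-forward
#' orientation.
#'
#' @param sim a `sim_mobilome` from [spike_insertions()].
#' @param accession accession id.
#' @param perfect emit lifted alignment records (default) or unaligned
#'   records only.
#' @return an alignment frame (see [read_alignments()]), coordinate-sorted.
#' @export
simulate_reads <- function(sim, accession, perfect = TRUE) {
  stopifnot(inherits(sim, "sim_mobilome"))
  cfg <- sim$cfg
  ai <- match(accession, sim$accessions)
  if (is.na(ai)) stop("unknown accession: ", accession)
  set.seed(cfg$seed + 9001L + 131L * ai)
  rl <- cfg$read_len
  acc <- sim$genomes[[accession]]
  alen <- nchar(acc)
  total <- sum(alen)
  n_pairs <- round(cfg$depth * total / (2 * rl))
  if (n_pairs < 1) stop("depth implies < 1 read")

  chr_of <- sample(names(acc), n_pairs, replace = TRUE, prob = alen)
  frag <- pmax(2L * rl, round(rnorm(n_pairs, cfg$insert_mean, cfg$insert_sd)))
  frag <- pmin(frag, alen[chr_of])
  start <- floor(runif(n_pairs) * (alen[chr_of] - frag + 1)) + 1L

  s1 <- start; e1 <- start + rl - 1L
  s2 <- start + frag - rl; e2 <- start + frag - 1L
  seq1 <- substring(acc[chr_of], s1, e1)
  seq2 <- substring(acc[chr_of], s2, e2)
  if (cfg$error_rate > 0) {
    seq1 <- apply_read_errors(seq1, cfg$error_rate)
    seq2 <- apply_read_errors(seq2, cfg$error_rate)
  }

  segs <- sim$segments[[accession]]
  lift <- function(chr, s, e) {
    # returns ref pos (NA when the read is not fully in one ref segment)
    out <- rep(NA_integer_, length(s))
    for (cc in unique(chr)) {
      idx <- which(chr == cc)
      sg <- segs[segs$chrom == cc, ]
      k <- findInterval(s[idx], sg$a_start)
      within <- k >= 1 & e[idx] <= sg$a_end[k] & sg$kind[k] == "ref"
      out[idx[within]] <- sg$ref_start[k[within]] +
        (s[idx[within]] - sg$a_start[k[within]])
    }
    out
  }
  p1 <- lift(chr_of, s1, e1)
  p2 <- lift(chr_of, s2, e2)

  m1 <- !is.na(p1); m2 <- !is.na(p2)
  tlen <- ifelse(m1 & m2, (p2 + rl - 1L) - p1 + 1L, NA_integer_)
  proper <- m1 & m2 & !is.na(tlen) &
    tlen >= rl & tlen <= cfg$insert_mean + 5 * max(cfg$insert_sd, 1)

  qname <- sprintf("%s_p%07d", accession, seq_len(n_pairs))
  mk_flags <- function(first, mapped, mate_mapped, reverse, mate_reverse,
                       proper) {
    f <- rep(FLAG_PAIRED, length(mapped))
    f <- f + ifelse(first, FLAG_FIRST, FLAG_SECOND)
    f <- f + ifelse(mapped, 0L, FLAG_UNMAPPED)
    f <- f + ifelse(mate_mapped, 0L, FLAG_MATE_UNMAPPED)
    f <- f + ifelse(mapped & reverse, FLAG_REVERSE, 0L)
    f <- f + ifelse(mate_mapped & mate_reverse, FLAG_MATE_REVERSE, 0L)
    f + ifelse(proper, FLAG_PROPER, 0L)
  }
  if (!perfect) {
    m1[] <- FALSE; m2[] <- FALSE; p1[] <- NA_integer_; p2[] <- NA_integer_
    proper[] <- FALSE; tlen[] <- NA_integer_
  }
  # placed-unmapped convention: unmapped reads take the mate's coordinates
  pos1 <- ifelse(m1, p1, ifelse(m2, p2, NA_integer_))
  pos2 <- ifelse(m2, p2, ifelse(m1, p1, NA_integer_))
  rn1 <- ifelse(m1 | m2, chr_of, NA_character_)
  r1 <- data.frame(
    qname = qname,
    flag = mk_flags(TRUE, m1, m2, rep(FALSE, n_pairs), rep(TRUE, n_pairs),
                    proper),
    rname = rn1, pos = pos1,
    mapq = ifelse(m1, 60L, 0L),
    cigar = ifelse(m1, paste0(rl, "M"), NA_character_),
    mrnm = ifelse(m2 | m1, chr_of, NA_character_),
    mpos = ifelse(m2, p2, ifelse(m1, p1, NA_integer_)),
    isize = ifelse(m1 & m2, tlen, 0L),
    seq = seq1, stringsAsFactors = FALSE
  )
  r2 <- data.frame(
    qname = qname,
    flag = mk_flags(FALSE, m2, m1, rep(TRUE, n_pairs), rep(FALSE, n_pairs),
                    proper),
    rname = rn1, pos = pos2,
    mapq = ifelse(m2, 60L, 0L),
    cigar = ifelse(m2, paste0(rl, "M"), NA_character_),
    mrnm = ifelse(m1 | m2, chr_of, NA_character_),
    mpos = ifelse(m1, p1, ifelse(m2, p2, NA_integer_)),
    isize = ifelse(m1 & m2, -tlen, 0L),
    seq = seq2, stringsAsFactors = FALSE
  )
  aln <- rbind(r1, r2)
  aln <- aln[order(is.na(aln$rname), aln$rname, aln$pos, aln$qname,
                   method = "radix"), ]
  rownames(aln) <- NULL
  attr(aln, "accession") <- accession
  aln
}

apply_read_errors <- function(seqs, rate) {
  rl <- nchar(seqs)
  total <- sum(rl)
  k <- rbinom(1, total, rate)
  if (k == 0) return(seqs)
  idx <- sort(sample.int(total, k))
  bounds <- cumsum(rl)
  read <- findInterval(idx - 1L, c(0L, bounds), rightmost.closed = FALSE)
  off <- idx - c(0L, bounds)[read]
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(idx)) {
    old <- substr(seqs[read[i]], off[i], off[i])
    substr(seqs[read[i]], off[i], off[i]) <-
      sample(setdiff(bases, old), 1)
  }
  seqs
}

#' Reference lengths of a simulated genome
#' @param sim a `sim_genome` or `sim_mobilome`.
#' @return named integer vector of contig lengths.
#' @export
reference_lengths <- function(sim) {
  g <- if (inherits(sim, "sim_mobilome")) sim$genome else sim
  stats::setNames(Biostrings::width(g$reference), names(g$reference))
}

#' Write simulation truth to TSV
#'
#' Carrier sets are serialised as comma-joined accession ids.
#' @param truth the `truth` data.frame of a `sim_mobilome`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_truth_tsv <- function(truth, path) {
  out <- truth
  out$carriers <- vapply(truth$carriers, paste, character(1), collapse = ",")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  tr <- read.delim(path, stringsAsFactors = FALSE)
  tr$carriers <- strsplit(tr$carriers, ",", fixed = TRUE)
  tr
}

#' Score insertion calls against simulation truth
#'
#' A called site matches a truth event when it lies on the same contig,
#' carries the same family, and is within `tol` bases; matching is greedy
#' one-to-one by distance. Genotype accuracy compares, over all
#' (accession, matched site) cells, the trichotomous call against the true
#' carrier status; `missing` calls count as incorrect and are also
#' reported separately.
#'
#' @param sites a TIP site table (from [intersect_sites()]).
#' @param truth a truth data.frame (from [spike_insertions()]).
#' @param matrix optionally, a `tip_matrix` for genotype accuracy.
#' @param tol matching tolerance in bases.
#' @return a list: `recall`, `precision`, `n_matched`, `n_calls`,
#'   `n_truth`, `genotype_accuracy`, `missing_fraction`,
#'   `per_superfamily` (data.frame).
#' @export
score_calls <- function(sites, truth, matrix = NULL, tol = 100) {
  n_calls <- nrow(sites)
  n_truth <- nrow(truth)
  pairs <- NULL
  if (n_calls > 0 && n_truth > 0) {
    cand <- do.call(rbind, lapply(seq_len(n_calls), function(i) {
      j <- which(truth$chrom == sites$chrom[i] &
                   truth$te_family == sites$te_family[i] &
                   abs(truth$position - sites$position[i]) <= tol)
      if (length(j) == 0) return(NULL)
      data.frame(call = i, event = j,
                 dist = abs(truth$position[j] - sites$position[i]))
    }))
    if (!is.null(cand) && nrow(cand) > 0) {
      cand <- cand[order(cand$dist), ]
      used_c <- logical(n_calls); used_e <- logical(n_truth)
      keep <- logical(nrow(cand))
      for (r in seq_len(nrow(cand))) {
        if (!used_c[cand$call[r]] && !used_e[cand$event[r]]) {
          keep[r] <- TRUE
          used_c[cand$call[r]] <- TRUE
          used_e[cand$event[r]] <- TRUE
        }
      }
      pairs <- cand[keep, ]
    }
  }
  n_matched <- if (is.null(pairs)) 0L else nrow(pairs)
  per_sf <- do.call(rbind, lapply(split(seq_len(n_truth), truth$superfamily),
    function(idx) {
      data.frame(
        superfamily = truth$superfamily[idx[1]],
        n_truth = length(idx),
        n_recovered = if (is.null(pairs)) 0L else sum(pairs$event %in% idx),
        stringsAsFactors = FALSE
      )
    }))
  if (!is.null(per_sf)) {
    per_sf$recall <- per_sf$n_recovered / per_sf$n_truth
    rownames(per_sf) <- NULL
  }
  geno_acc <- NA_real_
  miss_frac <- NA_real_
  if (!is.null(matrix) && n_matched > 0) {
    stopifnot(inherits(matrix, "tip_matrix"))
    correct <- 0L; ncell <- 0L; nmiss <- 0L
    for (r in seq_len(n_matched)) {
      sid <- sites$site_id[pairs$call[r]]
      si <- match(sid, matrix$sites$site_id)
      if (is.na(si)) next
      truth_carrier <- matrix$accessions %in% truth$carriers[[pairs$event[r]]]
      call <- matrix$geno[si, ]
      ncell <- ncell + length(call)
      nmiss <- nmiss + sum(is.na(call))
      correct <- correct + sum(!is.na(call) & call == as.integer(truth_carrier))
    }
    geno_acc <- correct / ncell
    miss_frac <- nmiss / ncell
  }
  list(
    recall = if (n_truth > 0) n_matched / n_truth else NA_real_,
    precision = if (n_calls > 0) n_matched / n_calls else NA_real_,
    n_matched = n_matched, n_calls = n_calls, n_truth = n_truth,
    genotype_accuracy = geno_acc, missing_fraction = miss_frac,
    per_superfamily = per_sf
  )
}
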