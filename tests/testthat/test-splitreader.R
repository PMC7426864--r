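# helpers to construct tiny alignment frames
mk_pair <- function(qname, rname1, pos1, rname2, pos2, rl = 100,
                    mapped1 = TRUE, mapped2 = TRUE, proper = FALSE,
                    seq1 = strrep("A", rl), seq2 = strrep("A", rl)) {
  f1 <- 0x1 + 0x40 + (if (!mapped1) 0x4 else 0) + (if (!mapped2) 0x8 else 0) +
    (if (proper) 0x2 else 0) + (if (mapped2) 0x20 else 0)
  f2 <- 0x1 + 0x80 + (if (!mapped2) 0x4 else 0) + (if (!mapped1) 0x8 else 0) +
    (if (proper) 0x2 else 0) + (if (mapped2) 0x10 else 0)
  isz <- if (mapped1 && mapped2 && identical(rname1, rname2)) {
    pos2 + rl - pos1
  } else 0L
  data.frame(
    qname = qname, flag = c(f1, f2),
    rname = c(if (mapped1) rname1 else if (mapped2) rname2 else NA,
              if (mapped2) rname2 else if (mapped1) rname1 else NA),
    pos = c(if (mapped1) pos1 else if (mapped2) pos2 else NA,
            if (mapped2) pos2 else if (mapped1) pos1 else NA),
    mapq = c(if (mapped1) 60L else 0L, if (mapped2) 60L else 0L),
    cigar = c(if (mapped1) paste0(rl, "M") else NA,
              if (mapped2) paste0(rl, "M") else NA),
    mrnm = c(if (mapped2) rname2 else if (mapped1) rname1 else NA,
             if (mapped1) rname1 else if (mapped2) rname2 else NA),
    mpos = c(if (mapped2) pos2 else if (mapped1) pos1 else NA,
             if (mapped1) pos1 else if (mapped2) pos2 else NA),
    isize = c(isz, -isz),
    seq = c(seq1, seq2), stringsAsFactors = FALSE
  )
}

test_that("insert metrics come from proper pairs and set the discordance rule", {
  pairs <- do.call(rbind, lapply(1:150, function(i) {
    mk_pair(paste0("q", i), "chr1", 1000L + 10L * i, "chr1",
            1000L + 10L * i + 200L, proper = TRUE)
  }))
  pairs <- pairs[order(pairs$pos), ]
  m <- estimate_insert_metrics(pairs)
  expect_equal(m$mean_insert, 300)
  expect_equal(m$sd_insert, 0)
  expect_equal(m$discordance_distance, 3000)

  few <- pairs[1:100, ]  # 50 pairs only
  expect_error(estimate_insert_metrics(few), "cannot estimate insert size")
})

test_that("insert metrics recover a simulated Normal insert distribution", {
  sim <- small_sim()
  aln <- simulate_reads(sim, "acc01")
  m <- estimate_insert_metrics(aln)
  sel <- bitwAnd(aln$flag, 0x2) > 0 & bitwAnd(aln$flag, 0x40) > 0 &
    !is.na(aln$isize) & aln$isize > 0
  expect_equal(m$mean_insert, mean(head(aln$isize[sel], 10000)))
  expect_lt(abs(m$mean_insert - 400), 10)
})

test_that("candidate extraction equals the flag-based oracle", {
  toy <- rbind(
    mk_pair("proper", "chr1", 100L, "chr1", 300L, proper = TRUE),
    mk_pair("unmapped_mate", "chr1", 500L, "chr1", 500L, mapped2 = FALSE),
    mk_pair("cross_chrom", "chr1", 900L, "chr2", 400L),
    mk_pair("far_cis", "chr1", 1000L, "chr1", 900000L),
    mk_pair("near_cis", "chr1", 2000L, "chr1", 2350L, proper = TRUE),
    mk_pair("both_unmapped", "chr1", NA, "chr1", NA,
            mapped1 = FALSE, mapped2 = FALSE),
    mk_pair("proper2", "chr2", 100L, "chr2", 280L, proper = TRUE),
    mk_pair("far_cis2", "chr2", 200L, "chr2", 100000L)
  )
  toy <- toy[order(is.na(toy$rname), toy$rname, toy$pos), ]
  metrics <- structure(list(mean_insert = 300, sd_insert = 30,
                            read_len = 100, discordance_distance = 3000),
                       class = "insert_metrics")
  cand <- extract_candidate_reads(toy, metrics)
  # oracle: enumerate each record's retention from raw flags/positions
  oracle <- vapply(seq_len(nrow(toy)), function(i) {
    r <- toy[i, ]
    if (bitwAnd(r$flag, 4L) > 0) return(TRUE)
    if (bitwAnd(r$flag, 8L) > 0) return(FALSE)
    if (!is.na(r$mrnm) && r$mrnm != r$rname) return(TRUE)
    !is.na(r$mpos) && abs(r$pos - r$mpos) > 3000
  }, logical(1))
  expect_setequal(
    paste(cand$qname, bitwAnd(cand$flag, 0x40) > 0),
    paste(toy$qname, bitwAnd(toy$flag, 0x40) > 0)[oracle])
  # both mates of a cross-chromosome pair retained
  expect_equal(sum(cand$qname == "cross_chrom"), 2L)
  # a proper near pair is not retained
  expect_false(any(cand$qname %in% c("proper", "near_cis", "proper2")))
})

test_that("unsorted input is rejected", {
  toy <- rbind(
    mk_pair("a", "chr1", 500L, "chr1", 700L, proper = TRUE),
    mk_pair("b", "chr1", 100L, "chr1", 300L, proper = TRUE)
  )
  metrics <- structure(list(mean_insert = 300, sd_insert = 0,
                            read_len = 100, discordance_distance = 3000),
                       class = "insert_metrics")
  expect_error(extract_candidate_reads(toy, metrics), "not.*sorted")
})

test_that("builtin TE alignment resolves clip structure and rejects noise", {
  lib <- small_sim()$lib
  te <- as.character(library_sequences(lib)[[1]])
  fam <- strsplit(names(library_sequences(lib))[1], "|", fixed = TRUE)[[1]][1]
  set.seed(21)
  genomic <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                   collapse = "")
  # 100-nt read whose last 40 nt equal the TE prefix
  read_split <- paste0(genomic, substr(te, 1, 40))
  read_full <- substr(te, 501, 600)
  read_random <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                       collapse = "")
  cand <- data.frame(qname = c("split", "full", "random"),
                     flag = c(65L, 65L, 65L), rname = NA, pos = NA,
                     mapq = 0L, cigar = NA, mrnm = NA, mpos = NA,
                     isize = 0L,
                     seq = c(read_split, read_full, read_random),
                     stringsAsFactors = FALSE)
  hits <- align_to_te(cand, lib)
  split_hit <- hits[hits$qname == "split", ]
  expect_equal(nrow(split_hit), 1L)
  expect_equal(split_hit$te_family, fam)
  expect_equal(split_hit$te_aligned_len, 40L)
  expect_equal(split_hit$clip5, 60L)
  expect_equal(split_hit$clip3, 0L)
  full_hit <- hits[hits$qname == "full", ]
  expect_equal(full_hit$te_aligned_len, 100L)
  expect_equal(full_hit$clip5 + full_hit$clip3, 0L)
  expect_false("random" %in% hits$qname)
})

test_that("random reads almost never hit the library (score threshold)", {
  lib <- small_sim()$lib
  set.seed(77)
  rnd <- vapply(1:300, function(i) {
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  }, character(1))
  cand <- data.frame(qname = paste0("r", 1:300), flag = 65L, rname = NA,
                     pos = NA, mapq = 0L, cigar = NA, mrnm = NA, mpos = NA,
                     isize = 0L, seq = rnd, stringsAsFactors = FALSE)
  hits <- align_to_te(cand, lib)
  expect_lt(nrow(hits) / 300, 0.01)
})

test_that("evidence selection enforces the 20-nt partial threshold", {
  lib <- small_sim()$lib
  te <- as.character(library_sequences(lib)[[1]])
  set.seed(8)
  anchor <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                  collapse = "")
  mk_cand <- function(qname, seq, mate_mapped = TRUE) {
    data.frame(qname = qname, flag = 69L, rname = NA, pos = NA, mapq = 0L,
               cigar = NA, mrnm = "chr1", mpos = 500L, isize = 0L,
               seq = seq, mate_mapped = mate_mapped, mate_rname = "chr1",
               mate_pos = 500L, mate_reverse = FALSE, mate_mapq = 60L,
               mate_seq = anchor, mate_len = 80L, stringsAsFactors = FALSE)
  }
  cand <- rbind(mk_cand("keep20", paste0(anchor, substr(te, 1, 20))),
                mk_cand("drop19", paste0(anchor, substr(te, 1, 19))))
  hits <- align_to_te(cand, lib, min_score = 30)
  sel <- select_evidence(hits, cand, min_partial = 20)
  expect_true("keep20" %in% sel$qname[sel$kind_pre == "split"])
  expect_false("drop19" %in% sel$qname[sel$kind_pre == "split"])
})

test_that("a fully TE-mapped read whose mate also hits the TE is dropped", {
  lib <- small_sim()$lib
  te <- as.character(library_sequences(lib)[[1]])
  cand <- data.frame(
    qname = c("pair1", "pair1"), flag = c(69L, 133L), rname = NA, pos = NA,
    mapq = 0L, cigar = NA, mrnm = NA, mpos = NA, isize = 0L,
    seq = c(substr(te, 101, 200), substr(te, 401, 500)),
    mate_mapped = FALSE, mate_rname = NA, mate_pos = NA,
    mate_reverse = FALSE, mate_mapq = NA,
    mate_seq = c(substr(te, 401, 500), substr(te, 101, 200)),
    mate_len = 100L, stringsAsFactors = FALSE)
  hits <- align_to_te(cand, lib)
  expect_equal(nrow(hits), 2L)
  sel <- select_evidence(hits, cand)
  expect_equal(nrow(sel), 0L)
})

test_that("anchors remap to truth breakpoints; ambiguous anchors drop", {
  sim <- small_sim()
  dets <- small_detections()
  truth <- sim$truth
  # every softclip_3p anchor ends at the left breakpoint (position + TSD)
  # and every softclip_5p anchor starts at the right breakpoint
  # (position + 1), up to the few bases by which a maximal local alignment
  # can chance-extend across the junction
  jitter <- 8
  for (a in sim$accessions) {
    ev <- dets[[a]]$evidence
    sc3 <- ev[ev$evidence_kind == "softclip_3p", ]
    for (i in seq_len(nrow(sc3))) {
      d <- abs(truth$position + truth$tsd - sc3$aend[i])
      expect_lte(min(d[truth$chrom == sc3$chrom[i]]), jitter)
    }
    sc5 <- ev[ev$evidence_kind == "softclip_5p", ]
    for (i in seq_len(nrow(sc5))) {
      d <- abs(truth$position + 1L - sc5$astart[i])
      expect_lte(min(d[truth$chrom == sc5$chrom[i]]), jitter)
    }
  }

  # an anchor present twice in the reference is dropped as multimapped
  dup_block <- strrep("ACGT", 30)
  set.seed(31)
  filler <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                  collapse = "")
  ref <- Biostrings::DNAStringSet(c(
    chr1 = paste0(dup_block, filler, dup_block)))
  lib <- small_sim()$lib
  te <- as.character(library_sequences(lib)[[1]])
  sel <- data.frame(
    qname = "amb", kind_pre = "split", te_family = "FAM01",
    te_aligned_len = 40L, clip5 = 120L, clip3 = 0L,
    read_start = 121L, read_end = 160L,
    seq = paste0(dup_block, substr(te, 1, 40)),
    anchor_seq = dup_block, te_side = "3p",
    mate_mapped = FALSE, mate_rname = NA, mate_pos = NA,
    mate_reverse = FALSE, mate_mapq = NA, mate_seq = NA, mate_len = NA,
    stringsAsFactors = FALSE)
  out <- remap_anchors(sel, ref, accession = "x")
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_multimapped"), 1L)
})

test_that("cluster calling follows the orientation rule on examples", {
  # one 3' soft-clip upstream of a 5' soft-clip: a precise cluster with
  # breakpoints (1000, 1008)
  ev <- make_evidence(c("softclip_3p", "softclip_5p"),
                      astart = c(921, 1008), aend = c(1000, 1087))
  cl <- call_clusters(ev, max_span = 500)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$breakpoint_lo, 1000)
  expect_equal(cl$breakpoint_hi, 1008)
  expect_true(cl$precise)
  expect_equal(cl$n_up, 1L)
  expect_equal(cl$n_down, 1L)

  # minus-discordant left of plus-discordant: wrong order, no cluster
  ev2 <- make_evidence(c("discordant_minus", "discordant_plus"),
                       astart = c(900, 1100), aend = c(999, 1199))
  expect_equal(nrow(call_clusters(ev2, max_span = 500)), 0L)
})

test_that("cluster decisions equal the brute-force oracle on all subsets", {
  base <- make_evidence(
    c("softclip_3p", "discordant_plus", "softclip_5p", "discordant_minus",
      "discordant_minus", "softclip_3p"),
    astart = c(921, 860, 1008, 1100, 900, 950),
    aend = c(1000, 949, 1087, 1199, 999, 1040))
  n <- nrow(base)
  for (mask in 1:(2^n - 1)) {
    sel <- base[which(bitwAnd(mask, 2^(0:(n - 1))) > 0), , drop = FALSE]
    got <- call_clusters(sel, max_span = 500)
    want <- oracle_cluster(sel)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L, info = paste("mask", mask))
    } else {
      expect_equal(nrow(got), 1L, info = paste("mask", mask))
      expect_equal(got$breakpoint_lo, want$lo, info = paste("mask", mask))
      expect_equal(got$breakpoint_hi, want$hi, info = paste("mask", mask))
      expect_equal(got$n_up, want$n_up, info = paste("mask", mask))
      expect_equal(got$n_down, want$n_down, info = paste("mask", mask))
    }
  }
})

test_that("site intersection applies the 3-read up+down filter and window", {
  mk_cluster <- function(accession, pos, n_up, n_down) {
    data.frame(accession = accession, chrom = "chr1",
               breakpoint_lo = pos, breakpoint_hi = pos + 4L,
               position = pos + 2L, te_family = "FAM01",
               n_up = n_up, n_down = n_down, n_total = n_up + n_down,
               precise = TRUE, stringsAsFactors = FALSE)
  }
  # accession A satisfies (2 up, 1 down); B's one-sided support is recorded
  cl <- rbind(mk_cluster("A", 1000L, 2L, 1L), mk_cluster("B", 1002L, 1L, 0L))
  ts <- intersect_sites(cl)
  expect_equal(nrow(ts$sites), 1L)
  expect_setequal(ts$support$accession, c("A", "B"))

  # 2-up/0-down alone never seeds a site
  expect_equal(nrow(intersect_sites(mk_cluster("A", 1000L, 2L, 0L))$sites),
               0L)
  # 2-up/1-down accepted
  expect_equal(nrow(intersect_sites(mk_cluster("A", 1000L, 2L, 1L))$sites),
               1L)

  # window semantics: clusters 150 bp apart
  cl2 <- rbind(mk_cluster("A", 1000L, 2L, 1L), mk_cluster("B", 1150L, 2L, 1L))
  expect_equal(nrow(intersect_sites(cl2, merge_window = 100)$sites), 2L)
  expect_equal(nrow(intersect_sites(cl2, merge_window = 200)$sites), 1L)
})

test_that("every emitted site satisfies its support invariant", {
  sites <- small_sites()
  best <- tapply(seq_len(nrow(sites$support)), sites$support$site_id,
                 function(ii) {
    s <- sites$support[ii, ]
    any(s$n_up >= 1 & s$n_down >= 1 & s$n_up + s$n_down >= 3)
  })
  expect_true(all(best))
})

test_that("detection is deterministic for fixed inputs", {
  sim <- small_sim()
  aln <- simulate_reads(sim, "acc01")
  d1 <- detect_insertions(aln, sim$lib, sim$genome$reference,
                          accession = "acc01")
  d2 <- detect_insertions(aln, sim$lib, sim$genome$reference,
                          accession = "acc01")
  expect_identical(d1$clusters, d2$clusters)
  expect_identical(d1$evidence, d2$evidence)
})
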