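# Shared fixtures, built once per test run. The small simulated mobilome
# (200 kb, 4 accessions, 8 events, error-free, 20x) exercises the whole
# detection path at desk scale.

.fixture_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    cfg <- sim_config(genome_len = 2e5, n_chroms = 2, n_families = 3,
                      n_accessions = 4, n_events = 8, depth = 20, seed = 7)
    g <- sim_genome(cfg)
    lib <- build_te_library(g$reference, g$te_annotation)
    .fixture_cache$sim <- spike_insertions(g, lib)
  }
  .fixture_cache$sim
}

small_detections <- function() {
  if (is.null(.fixture_cache$dets)) {
    sim <- small_sim()
    alns <- lapply(sim$accessions, function(a) simulate_reads(sim, a))
    names(alns) <- sim$accessions
    dets <- lapply(sim$accessions, function(a) {
      detect_insertions(alns[[a]], sim$lib, sim$genome$reference,
                        accession = a)
    })
    names(dets) <- sim$accessions
    .fixture_cache$alns <- alns
    .fixture_cache$dets <- dets
  }
  .fixture_cache$dets
}

small_alignments <- function() {
  small_detections()
  .fixture_cache$alns
}

small_tip_matrix <- function() {
  if (is.null(.fixture_cache$tm)) {
    sim <- small_sim()
    dets <- small_detections()
    sites <- intersect_sites(lapply(dets, `[[`, "clusters"))
    .fixture_cache$sites <- sites
    .fixture_cache$tm <- genotype_accessions(
      sites, lapply(dets, `[[`, "evidence"), small_alignments(),
      ref_lengths = reference_lengths(sim))
  }
  .fixture_cache$tm
}

small_sites <- function() {
  small_tip_matrix()
  .fixture_cache$sites
}

# deterministic toy evidence frame builder
make_evidence <- function(kind, astart, aend, family = "FAM01",
                          accession = "accA") {
  data.frame(accession = accession,
             read_id = sprintf("r%02d", seq_along(kind)),
             evidence_kind = kind, chrom = "chr1",
             astart = as.integer(astart), aend = as.integer(aend),
             te_family = family, te_aligned_len = 30L, clip_len = 30L,
             stringsAsFactors = FALSE)
}

# brute-force evaluation of the cluster orientation rule: at least two
# reads, no downstream-type element left of any upstream-type element
# (anchor starts), breakpoints per definition, coherence within tsd_tol
oracle_cluster <- function(ev, tsd_tol = 25) {
  if (nrow(ev) < 2) return(NULL)
  up_kinds <- c("softclip_3p", "discordant_plus")
  for (i in seq_len(nrow(ev))) {
    for (j in seq_len(nrow(ev))) {
      if (ev$evidence_kind[i] %in% up_kinds &&
          !(ev$evidence_kind[j] %in% up_kinds) &&
          ev$astart[j] < ev$astart[i]) {
        return(NULL)  # a downstream element left of an upstream one
      }
    }
  }
  sc3 <- ev$evidence_kind == "softclip_3p"
  sc5 <- ev$evidence_kind == "softclip_5p"
  dp <- ev$evidence_kind == "discordant_plus"
  dm <- ev$evidence_kind == "discordant_minus"
  lo <- if (any(sc3)) max(ev$aend[sc3]) else if (any(dp)) max(ev$aend[dp]) else NA
  hi <- if (any(sc5)) min(ev$astart[sc5]) else if (any(dm)) min(ev$astart[dm]) else NA
  if (!is.na(lo) && !is.na(hi) && hi < lo - tsd_tol) return(NULL)
  list(lo = if (is.na(lo)) min(ev$astart) else lo,
       hi = if (is.na(hi)) max(ev$aend) else hi,
       n_up = sum(sc3 | dp), n_down = sum(sc5 | dm))
}

# independent reverse complement (no Biostrings)
rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# brute-force r2 from the 2x2 haplotype table: D^2 / (p1 q1 p2 q2)
oracle_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  p1 <- mean(a); p2 <- mean(b)
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) return(NA_real_)
  D <- mean(a * b) - p1 * p2
  D^2 / (p1 * (1 - p1) * p2 * (1 - p2))
}
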