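# End-to-end orchestration: a single structured configuration drives the
# stages library -> detect -> intersect -> genotype, with uniform outputs
# and a provenance manifest (versions, parameters, input checksums).

#' Default pipeline configuration
#'
#' @return nested list with every stage parameter at its documented
#'   default. `paths$alignments` is a named list accession -> SAM/BAM.
#' @export
default_run_config <- function() {
  list(
    outdir = "mobilome_out",
    seed = 1L,
    paths = list(reference = NULL, te_annotation = NULL, alignments = NULL),
    library = list(min_copy_len = 1000, copy_floor = 200),
    detect = list(min_partial = 20, max_mm = 2, mapq_floor = 10,
                  tsd_tol = 25),
    intersect = list(merge_window = 100, min_reads = 3),
    genotype = list(negcov_threshold = 5, flank = 50, mapq_floor = 10,
                    support_window = 600)
  )
}

merge_config <- function(user, defaults, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop_mk(paste0("unknown configuration key(s): ",
                   paste0(path, unknown, collapse = ", ")),
            "mobilomekit_validation_error")
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      merge_config(user[[k]], defaults[[k]], paste0(path, k, "$"))
    } else {
      user[[k]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' @param config a YAML file path or a nested list; unknown keys are
#'   rejected.
#' @return the validated configuration merged over the defaults.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  merge_config(config, default_run_config())
}

pipeline_dep_error <- function(what, stage) {
  stop_mk(paste0("missing dependency: ", what,
                 "; run stage '", stage, "' first"),
          "mobilomekit_dependency_error")
}

#' Run the detection/genotyping pipeline
#'
#' Stages run in dependency order (`library`, `detect`, `intersect`,
#' `genotype`); a stage not requested must already have its outputs in
#' `outdir` if a later stage needs them, otherwise an error of class
#' `mobilomekit_dependency_error` names the stage to run first. A
#' manifest (JSON) records the package version, parameters, and md5
#' checksums of inputs and outputs; reruns with the same configuration
#' are idempotent.
#'
#' @param config a configuration ([load_run_config()]) or YAML path.
#' @param stages subset of stages to run.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config,
                         stages = c("library", "detect", "intersect",
                                    "genotype")) {
  cfg <- load_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(cfg$outdir, ...)
  manifest <- list(
    tool = "mobilomekit",
    version = as.character(utils::packageVersion("mobilomekit")),
    seed = cfg$seed,
    stages = stages,
    parameters = cfg[c("library", "detect", "intersect", "genotype")],
    inputs = list(), outputs = list()
  )
  add_md5 <- function(slot, files) {
    files <- files[file.exists(files)]
    manifest[[slot]] <<- c(manifest[[slot]],
                           as.list(tools::md5sum(files)))
  }

  ref_path <- cfg$paths$reference
  lib <- NULL

  if ("library" %in% stages) {
    if (is.null(ref_path) || is.null(cfg$paths$te_annotation)) {
      stop_mk("library stage needs paths$reference and paths$te_annotation",
              "mobilomekit_validation_error")
    }
    lib <- build_te_library(ref_path, cfg$paths$te_annotation,
                            min_copy_len = cfg$library$min_copy_len,
                            copy_floor = cfg$library$copy_floor)
    write_library(lib, fasta = p("library.fasta"),
                  summary_tsv = p("library_summary.tsv"))
    add_md5("inputs", c(ref_path, cfg$paths$te_annotation))
    add_md5("outputs", c(p("library.fasta"), p("library_summary.tsv")))
  }

  accs <- names(cfg$paths$alignments)
  evidence_files <- function() p(paste0(accs, ".evidence.tsv"))
  cluster_files <- function() p(paste0(accs, ".clusters.tsv"))

  if ("detect" %in% stages) {
    if (is.null(lib)) {
      if (!file.exists(p("library.fasta"))) {
        pipeline_dep_error("TE library", "library")
      }
      lib <- library_from_fasta(p("library.fasta"))
    }
    if (is.null(accs)) {
      stop_mk("detect stage needs paths$alignments",
              "mobilomekit_validation_error")
    }
    ref <- load_reference(ref_path)
    for (a in accs) {
      aln <- read_alignments(cfg$paths$alignments[[a]])
      det <- detect_insertions(
        aln, lib, ref, accession = a,
        min_partial = cfg$detect$min_partial, max_mm = cfg$detect$max_mm,
        mapq_floor = cfg$detect$mapq_floor, tsd_tol = cfg$detect$tsd_tol)
      write.table(det$evidence, p(paste0(a, ".evidence.tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(det$clusters, p(paste0(a, ".clusters.tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    add_md5("inputs", unlist(cfg$paths$alignments))
    add_md5("outputs", c(evidence_files(), cluster_files()))
  }

  if ("intersect" %in% stages) {
    cf <- cluster_files()
    if (is.null(accs) || !all(file.exists(cf))) {
      pipeline_dep_error("per-accession clusters", "detect")
    }
    clusters <- do.call(rbind, lapply(cf, read.delim,
                                      stringsAsFactors = FALSE))
    sites <- intersect_sites(clusters,
                             merge_window = cfg$intersect$merge_window,
                             min_reads = cfg$intersect$min_reads)
    write.table(sites$sites, p("sites.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(sites$support, p("sites_support.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    add_md5("outputs", c(p("sites.tsv"), p("sites_support.tsv")))
  }

  if ("genotype" %in% stages) {
    if (!file.exists(p("sites.tsv"))) {
      pipeline_dep_error("TIP sites", "intersect")
    }
    ef <- evidence_files()
    if (is.null(accs) || !all(file.exists(ef))) {
      pipeline_dep_error("per-accession evidence", "detect")
    }
    sites_df <- read.delim(p("sites.tsv"), stringsAsFactors = FALSE)
    sites <- structure(list(sites = sites_df, support = empty_support()),
                       class = "tip_sites")
    ev <- lapply(ef, function(f) read.delim(f, stringsAsFactors = FALSE))
    names(ev) <- accs
    ref_lengths <- NULL
    if (!is.null(ref_path)) {
      ref <- load_reference(ref_path)
      ref_lengths <- setNames(Biostrings::width(ref), names(ref))
    }
    tm <- genotype_accessions(
      sites, ev,
      aln_by_acc = function(a) read_alignments(cfg$paths$alignments[[a]]),
      negcov_threshold = cfg$genotype$negcov_threshold,
      flank = cfg$genotype$flank, mapq_floor = cfg$genotype$mapq_floor,
      support_window = cfg$genotype$support_window,
      ref_lengths = ref_lengths)
    sfam <- NULL
    if (file.exists(p("library_summary.tsv"))) {
      ls <- read.delim(p("library_summary.tsv"), stringsAsFactors = FALSE)
      sfam <- setNames(ls$superfamily, ls$family)
    }
    write_tips_vcf(tm, p("tips.vcf"), ref_lengths = ref_lengths,
                   superfamilies = sfam)
    write_matrix_tsv(tm, p("matrix.tsv"))
    add_md5("outputs", c(p("tips.vcf"), p("matrix.tsv")))
  }

  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Rebuild a `te_library` from a library FASTA written by [write_library()]
#'
#' @param path library FASTA with `family|copy_id|superfamily` headers.
#' @return a `te_library`.
#' @export
library_from_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  fam <- vapply(parts, `[[`, character(1), 1)
  cid <- vapply(parts, `[[`, character(1), 2)
  sf <- vapply(parts, `[[`, character(1), 3)
  fams <- lapply(sort(unique(fam)), function(f) {
    idx <- which(fam == f)
    s <- seqs[idx]
    names(s) <- cid[idx]
    structure(list(
      name = f, superfamily = sf[idx[1]],
      class = unname(SUPERFAMILY_CLASS[sf[idx[1]]]),
      sequences = s,
      longest_copy_len = max(Biostrings::width(s))
    ), class = "te_family")
  })
  names(fams) <- vapply(fams, `[[`, character(1), "name")
  structure(list(families = fams, min_copy_len = NA_integer_),
            class = "te_library")
}
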