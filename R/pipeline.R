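# Stage orchestration: a run directory with a fixed layout, one manifest
# per stage, and deterministic re-runs.

PIPELINE_STAGES <- c("simulate", "qc", "consensus", "windows", "codon",
                     "splice", "ssr", "enrich", "report")

#' Pipeline configuration
#'
#' Bundles the per-module configurations and a run directory. Any element
#' can be overridden by name.
#'
#' @param out_dir Run directory (created if missing).
#' @param seed Integer seed forwarded to the simulation stage.
#' @param ... Overrides: `sim`, `qc`, `consensus`, `windows`, `filter`,
#'   `mng`, `ssr` configuration objects.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("oryzaevol_run_"),
                            seed = 1L, ...) {
  cfg <- list(out_dir = out_dir, seed = seed,
              sim = sim_config(seed = seed), qc = qc_config(),
              consensus = consensus_config(), windows = window_config(),
              filter = alignment_filter(), mng = mng_params(),
              ssr = ssr_config())
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

manifest_path <- function(cfg, stage) {
  file.path(cfg$out_dir, paste0(stage, ".manifest.json"))
}

write_manifest <- function(cfg, stage, inputs, outputs, params = list()) {
  checksums <- vapply(outputs[file.exists(outputs)],
                      function(f) unname(tools::md5sum(f)), character(1))
  jsonlite::write_json(
    list(stage = stage, inputs = inputs, outputs = as.list(outputs),
         checksums = as.list(checksums), params = params,
         package_version = as.character(utils::packageVersion("oryzaevol"))),
    manifest_path(cfg, stage), auto_unbox = TRUE, digits = NA)
}

stage_file <- function(cfg, name) file.path(cfg$out_dir, name)

require_input <- function(cfg, name, producer) {
  f <- stage_file(cfg, name)
  if (!file.exists(f)) {
    stop("missing input '", name, "': run stage '", producer, "' first")
  }
  f
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic genomes, reads, truth), `qc` (trim +
#' filter reads), `consensus` (map reads, build consensus and supported
#' sites), `windows` (substitution profile and ts/tv), `codon` (per-lineage
#' dN/dS and amino-acid branch lengths), `splice` (splice-site records and
#' lineage summary), `ssr` (detection, clustering, classification, tests),
#' `enrich` (G-tests over a user-provided TSV of 2x2 tables, if present),
#' `report` (aggregate JSON). Each stage writes its outputs plus a
#' manifest with checksums under the run directory; deterministic stages
#' re-run to identical checksums.
#'
#' @param name Stage name.
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the list of output files written.
#' @export
run_stage <- function(name, cfg = pipeline_config()) {
  if (!name %in% PIPELINE_STAGES) {
    stop("unknown stage '", name, "'; stages: ",
         paste(PIPELINE_STAGES, collapse = ", "))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- switch(
    name,
    simulate = {
      sim <- simulate_genomes(cfg$sim)
      rds_free_save(sim, stage_file(cfg, "sim"))
      reads <- simulate_reads(sim$genomes$og, cfg$sim)
      rds_free_save(reads, stage_file(cfg, "reads"))
      write_fastq(reads$reads, stage_file(cfg, "og_reads.fastq"))
      write_fasta(unlist(sim$genomes), stage_file(cfg, "genomes.fasta"))
      c(stage_file(cfg, "og_reads.fastq"), stage_file(cfg, "genomes.fasta"))
    },
    qc = {
      require_input(cfg, "reads.json", "simulate")
      reads <- rds_free_load(stage_file(cfg, "reads"))
      trimmed <- trim_3prime(reads$reads, cfg$qc)
      scr <- organelle_screen(reads$organelle)
      flt <- filter_reads(trimmed, cfg$qc, scr)
      rds_free_save(flt, stage_file(cfg, "qc"))
      write_fastq(flt$kept, stage_file(cfg, "kept_reads.fastq"))
      stage_file(cfg, "kept_reads.fastq")
    },
    consensus = {
      require_input(cfg, "qc.json", "qc")
      sim <- rds_free_load(stage_file(cfg, "sim"))
      flt <- rds_free_load(stage_file(cfg, "qc"))
      hits <- kmer_align(flt$kept, c(chr1 = sim$genomes$osj))
      best <- do.call(rbind, lapply(split(hits, hits$read_id),
                                    select_best_hit, cfg = cfg$qc))
      mapped <- merge(flt$kept, best[, c("read_id", "chrom", "start",
                                         "strand")],
                      by.x = "id", by.y = "read_id")
      mapped$read_id <- mapped$id
      cons <- build_consensus(mapped, cfg$consensus)
      supp <- supported_sites(cons, cfg$consensus)
      rds_free_save(list(sites = cons$sites, contigs = cons$contigs,
                         supported = supp),
                    stage_file(cfg, "consensus"))
      utils::write.table(cons$contigs, stage_file(cfg, "contigs.bed"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      stage_file(cfg, "contigs.bed")
    },
    windows = {
      sim <- rds_free_load(require_sim(cfg))
      cols <- alignment_columns(sim$alignment, sim$annotation$classes)
      win <- window_counts(cols, cfg$windows)
      write_window_tsv(win, stage_file(cfg, "windows.tsv"))
      ratio <- tstv_ratio(cols)
      jsonlite::write_json(list(tstv = ratio), stage_file(cfg,
                                                          "tstv.json"),
                           auto_unbox = TRUE, digits = NA)
      c(stage_file(cfg, "windows.tsv"), stage_file(cfg, "tstv.json"))
    },
    codon = {
      sim <- rds_free_load(require_sim(cfg))
      alns <- sim_codon_alignments(sim, cfg$filter)
      res <- lineage_dnds(alns, cfg$mng, n_replicates = 200L,
                          seed = cfg$seed)
      aa <- aa_branch_lengths(alns)
      jsonlite::write_json(
        list(omega = as.list(res$omega), omega_sd = as.list(res$omega_sd),
             bS = as.list(res$bS), bN = as.list(res$bN),
             counts = as.list(res$counts),
             gtest_p = if (!is.null(res$gtest)) res$gtest$p_value else NA,
             aa_branches = as.list(aa$b),
             tajima_p = if (!is.null(aa$tajima)) aa$tajima$p_value else NA),
        stage_file(cfg, "codon.json"), auto_unbox = TRUE, digits = NA)
      stage_file(cfg, "codon.json")
    },
    splice = {
      sim <- rds_free_load(require_sim(cfg))
      rec <- extract_splice_contexts(sim$genes, sim$alignment)
      rec <- assign_splice_lineage(rec)
      utils::write.table(rec[, setdiff(names(rec), "intron_seq")],
                         stage_file(cfg, "splice_records.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      splice_tab <- summarize_splice_lineages(rec)
      utils::write.table(splice_tab, stage_file(cfg, "splice_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      c(stage_file(cfg, "splice_records.tsv"),
        stage_file(cfg, "splice_summary.tsv"))
    },
    ssr = {
      sim <- rds_free_load(require_sim(cfg))
      loci <- lapply(sim$genomes[c("osj", "og", "osi")], detect_ssrs,
                     cfg = cfg$ssr, chrom = "chr1")
      cl <- cluster_across_genomes(loci, sim$alignment, cfg$ssr)
      if (!is.null(cl)) {
        cl <- classify_cluster(cl)
        cl <- assign_region(cl, sim$annotation$cds,
                            sim$annotation$transcripts)
        utils::write.table(cl, stage_file(cfg, "ssr_clusters.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      write_ssr_bed(loci$osj, stage_file(cfg, "ssr_osj.bed"))
      c(stage_file(cfg, "ssr_clusters.tsv"), stage_file(cfg, "ssr_osj.bed"))
    },
    enrich = {
      f <- stage_file(cfg, "enrichment_tables.tsv")
      if (!file.exists(f)) {
        character(0)
      } else {
        tab <- utils::read.delim(f)
        res <- enrichment_gtests(tab)
        utils::write.table(res, stage_file(cfg, "enrichment_results.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        stage_file(cfg, "enrichment_results.tsv")
      }
    },
    report = {
      manifests <- list.files(cfg$out_dir, "\\.manifest\\.json$",
                              full.names = TRUE)
      rep <- lapply(manifests, jsonlite::read_json)
      jsonlite::write_json(rep, stage_file(cfg, "report.json"),
                           auto_unbox = TRUE, digits = NA)
      stage_file(cfg, "report.json")
    })
  write_manifest(cfg, name,
                 inputs = list(seed = cfg$seed), outputs = outputs)
  invisible(outputs)
}

require_sim <- function(cfg) {
  f <- stage_file(cfg, "sim")
  if (!file.exists(paste0(f, ".json"))) {
    stop("missing input 'sim': run stage 'simulate' first")
  }
  f
}

# Text-only persistence of intermediate R objects between stages
# (serialized as JSON so the run directory stays plain text).
rds_free_save <- function(obj, path_stem) {
  saveRDS_json(obj, paste0(path_stem, ".json"))
}

rds_free_load <- function(path_stem) {
  readRDS_json(paste0(path_stem, ".json"))
}

saveRDS_json <- function(obj, path) {
  writeLines(jsonlite::serializeJSON(obj, digits = NA), path)
}

readRDS_json <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}

#' Run a sequence of pipeline stages
#'
#' @param cfg A [pipeline_config()].
#' @param stages Stages to run, in order.
#' @return Invisibly, the run directory.
#' @export
run_pipeline <- function(cfg = pipeline_config(),
                         stages = c("simulate", "windows", "codon",
                                    "splice", "ssr", "report")) {
  for (s in stages) run_stage(s, cfg)
  invisible(cfg$out_dir)
}

#' Extract three-taxon codon alignments from a simulation
#'
#' Pulls the CDS columns of each gene model from the simulated alignment
#' (japonica frame), pairs them with the outgroup row, and applies
#' [build_codon_alignment()]; genes whose CDS columns contain alignment
#' gaps in any taxon are rejected by the filter.
#'
#' @param sim Output of [simulate_genomes()].
#' @param filter An [alignment_filter()].
#' @return List of `codon_alignment` objects.
#' @export
sim_codon_alignments <- function(sim, filter = alignment_filter(
                                   min_aa = 30L, min_coverage = 0.7,
                                   trim_termini_aa = 10L)) {
  alns <- list()
  for (g in sim$genes) {
    m <- aln_matrix(sim$alignment, g$chrom)
    ex <- g$exons[order(g$exons[, 1]), , drop = FALSE]
    cols <- unlist(lapply(seq_len(nrow(ex)), function(e)
      aln_cols_for_ref(sim$alignment, g$chrom, ex[e, 1], ex[e, 2])))
    seq_of <- function(tx) {
      s <- paste(m[tx, cols], collapse = "")
      if (g$strand == "-") revcomp(s) else s
    }
    a <- tryCatch(
      build_codon_alignment(g$gene_id, seq_of("osj"), seq_of("og"),
                            seq_of("outgroup"), coverage = 1,
                            filter = filter),
      error = function(e) NULL)
    if (!is.null(a)) alns[[length(alns) + 1L]] <- a
  }
  alns
}
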