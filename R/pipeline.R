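# End-to-end orchestration: simulate -> merge -> assemble -> quantify ->
# proteome -> selection, with a single config, per-stage logging, output
# checksums and table generation.

#' Build a pipeline configuration
#'
#' @param outdir Output directory for all stage files.
#' @param seed Global seed propagated to every stochastic step.
#' @param sim A [simulation_config()] (its seed is overridden by `seed`).
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "merge", "assemble", "quantify", "proteome",
#'   "selection")`.
#' @param species_labels Names for the two simulated species.
#' @param min_overlap,max_mismatch_fraction Merge parameters.
#' @param min_identity_assembly,min_coverage Assembly consensus parameters.
#' @param min_identity_quant Quantification mapping identity.
#' @param detectability Proteome simulation detectability.
#' @param rate_method Pairwise rate estimator for the selection stage.
#' @param max_selection_pairs Cap on ortholog pairs analyzed in the
#'   selection stage (keeps desk-scale runs fast).
#' @return A `vf_pipeline_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("venomforge_run_"),
                            seed = 1L,
                            sim = simulation_config(seed = seed),
                            stages = c("simulate", "merge", "assemble",
                                       "quantify", "proteome", "selection"),
                            species_labels = c(A = "species_A", B = "species_B"),
                            min_overlap = 25L, max_mismatch_fraction = 0.05,
                            min_identity_assembly = 0.85, min_coverage = 5L,
                            min_identity_quant = 0.95,
                            detectability = 0.8,
                            rate_method = "counting",
                            max_selection_pairs = 60L) {
  sim$seed <- as.integer(seed)
  cfg <- list(outdir = outdir, seed = as.integer(seed), sim = sim,
              stages = stages, species_labels = species_labels,
              min_overlap = min_overlap,
              max_mismatch_fraction = max_mismatch_fraction,
              min_identity_assembly = min_identity_assembly,
              min_coverage = min_coverage,
              min_identity_quant = min_identity_quant,
              detectability = detectability,
              rate_method = rate_method,
              max_selection_pairs = max_selection_pairs)
  class(cfg) <- "vf_pipeline_config"
  cfg
}

vf_log <- function(run_log, stage, msg, ...) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(msg, ...))
  message(line)
  if (!is.null(run_log)) cat(line, "\n", file = run_log, append = TRUE)
  invisible(NULL)
}

checksum_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  md5 <- tools::md5sum(paths)
  tibble::tibble(file = basename(names(md5)), md5 = unname(md5))
}

#' Run the full pipeline
#'
#' Stages execute in dependency order; each stage's written outputs are
#' checksummed into the manifest, so reruns with the same configuration
#' reproduce identical checksums.  A failing stage halts the run with the
#' stage named; earlier outputs are retained.
#'
#' @param config A [pipeline_config()].
#' @return A `vf_manifest` list: per-stage blocks with parameters, outputs
#'   and checksums, plus `config` and package version.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "vf_pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  run_log <- file.path(config$outdir, "run.log")
  cat("", file = run_log)
  manifest <- list(config = config,
                   version = as.character(utils::packageVersion("venomforge")),
                   stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(stage, fn) {
    if (!(stage %in% config$stages)) return(invisible(NULL))
    vf_log(run_log, stage, "starting")
    res <- tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[stage]] <<- res
    vf_log(run_log, stage, "done (%d output file(s))",
           nrow(res$checksums %||% tibble::tibble()))
    invisible(NULL)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  run_stage("simulate", function() {
    truth <- simulate_transcriptomes(config$sim)
    state$truth <- truth
    tdir <- file.path(config$outdir, "truth")
    write_truth(truth, tdir)
    reads <- simulate_reads(truth, config$sim, species = "A")
    state$reads <- reads
    r1 <- file.path(config$outdir, "reads_R1.fastq")
    r2 <- file.path(config$outdir, "reads_R2.fastq")
    write_fastq(reads$id, reads$read1, reads$qual1, r1)
    write_fastq(reads$id, reads$read2, reads$qual2, r2)
    files <- c(list.files(tdir, full.names = TRUE), r1, r2)
    list(parameters = list(seed = config$seed,
                           n_read_pairs = config$sim$n_read_pairs),
         n_transcripts = nrow(truth$transcripts),
         checksums = checksum_files(files))
  })

  run_stage("merge", function() {
    res <- merge_set(state$reads, min_overlap = config$min_overlap,
                     max_mismatch_fraction = config$max_mismatch_fraction)
    state$merged <- res$merged
    prefix <- file.path(config$outdir, "merge")
    write_merge_result(res, prefix)
    list(parameters = list(min_overlap = config$min_overlap,
                           max_mismatch_fraction = config$max_mismatch_fraction),
         stats = res$stats,
         checksums = checksum_files(paste0(prefix,
           c("_merged.fastq", "_unmerged_R1.fastq", "_unmerged_R2.fastq",
             "_merge_stats.json"))))
  })

  run_stage("assemble", function() {
    tx <- state$truth$transcripts
    txA <- tx[tx$species == "A", ]
    refs <- tibble::tibble(
      id = txA$id, sequence = txA$sequence,
      cds_start = nchar(txA$utr5) + 1L,
      cds_end = nchar(txA$utr5) + nchar(txA$cds)
    )
    cons <- reference_consensus(state$merged, refs,
                                min_identity = config$min_identity_assembly,
                                min_coverage = config$min_coverage)
    cons$cds <- substr(cons$sequence, cons$cds_start, cons$cds_end)
    cons <- deduplicate(cons)
    ann <- annotate_and_name(cons)
    state$assembly <- ann
    path <- file.path(config$outdir, "assembly.fasta")
    hdr <- sprintf("%s|cluster=%s|class=%s|member=%s", ann$id,
                   ifelse(is.na(ann$cluster_name), ann$id, ann$cluster_name),
                   ann$class_label,
                   ifelse(is.na(ann$member), "a", ann$member))
    write_fasta(setNames(ann$cds, hdr), path)
    list(parameters = list(min_identity = config$min_identity_assembly,
                           min_coverage = config$min_coverage),
         n_transcripts = nrow(ann),
         n_toxins = sum(ann$class_label != "nontoxin"),
         checksums = checksum_files(path))
  })

  run_stage("quantify", function() {
    ann <- state$assembly
    db <- tibble::tibble(
      name = ann$id,
      cluster = ifelse(is.na(ann$cluster_name), ann$id, ann$cluster_name),
      sequence = ann$cds,
      is_toxin = ann$class_label != "nontoxin"
    )
    mp <- map_reads_to_cds(state$merged, db,
                           min_identity = config$min_identity_quant,
                           seed = config$seed)
    tab <- abundance_table(mp, db)
    state$abundance <- tab
    path <- file.path(config$outdir, "abundance.tsv")
    readr::write_tsv(tab, path)
    list(parameters = list(min_identity = config$min_identity_quant),
         n_mapped = mp$n_mapped,
         toxin_pct_total = class_summary(tab)$toxin_pct_total,
         checksums = checksum_files(path))
  })

  run_stage("proteome", function() {
    tx <- state$truth$transcripts
    txA <- tx[tx$species == "A", ]
    report <- simulate_id_report(state$truth, species = "A",
                                 detectability = config$detectability,
                                 seed = config$seed + 202L)
    db <- build_search_db(txA)
    mp <- map_peptides(report, db)
    acc <- accept_identifications(mp$identifications)
    acc <- group_identifications(acc)
    state$proteome <- acc
    clusters <- unique(txA$cluster_name[txA$class != "nontoxin"])
    xr <- cross_reference(dplyr::rename(acc, transcript_name = "protein_id"),
                          sub("[a-z]$", "", clusters))
    path <- file.path(config$outdir, "identifications.tsv")
    readr::write_tsv(acc[, c("protein_id", "score", "peptide_matches",
                             "pct_coverage", "group")], path)
    list(parameters = list(detectability = config$detectability),
         n_accepted = nrow(acc),
         n_confirmed_clusters = xr$n_confirmed,
         checksums = checksum_files(path))
  })

  run_stage("selection", function() {
    tx <- state$truth$transcripts
    om <- state$truth$ortholog_map
    if (nrow(om) > config$max_selection_pairs) {
      tox <- om[om$is_toxin, ]
      nt <- om[!om$is_toxin, ]
      keep_nt <- min(nrow(nt), config$max_selection_pairs - nrow(tox))
      om <- dplyr::bind_rows(tox, nt[seq_len(keep_nt), ])
    }
    pairs <- tibble::tibble(
      id_a = om$id_a, id_b = om$id_b,
      cds_a = tx$cds[match(om$id_a, tx$id)],
      cds_b = tx$cds[match(om$id_b, tx$id)],
      is_toxin = om$is_toxin
    )
    rates <- rate_table(pairs, method = config$rate_method)
    rates_ok <- rates[!rates$excluded, ]
    null <- rate_outlier_analysis(rates_ok[rates_ok$is_toxin, ],
                                  rates_ok[!rates_ok$is_toxin, ])
    state$selection <- null
    path <- file.path(config$outdir, "rates.tsv")
    out <- rates_ok |>
      dplyr::mutate(exceeds_dN = .data$dN > null$thresholds["dN"],
                    exceeds_dS = .data$dS > null$thresholds["dS"],
                    exceeds_omega = .data$omega > null$thresholds["omega"])
    readr::write_tsv(out, path)
    list(parameters = list(method = config$rate_method),
         thresholds = as.list(null$thresholds),
         wilcoxon_p = as.list(null$wilcoxon_p),
         toxin_exceed = as.list(null$toxin_exceed_counts),
         checksums = checksum_files(path))
  })

  class(manifest) <- "vf_manifest"
  manifest
}

#' @export
print.vf_manifest <- function(x, ...) {
  cat("venomforge pipeline manifest (version", x$version, ")\n")
  for (s in names(x$stages)) {
    cat("  stage", s, "-", nrow(x$stages[[s]]$checksums), "output file(s)\n")
  }
  invisible(x)
}

round_df <- function(df, digits_map) {
  for (col in names(digits_map)) {
    if (col %in% names(df)) df[[col]] <- round(df[[col]], digits_map[[col]])
  }
  df
}

#' Generate report tables from a pipeline manifest
#'
#' Writes the abundance, identification and selection tables with the
#' documented column layouts (percentages to 3 decimals, coverage to 2
#' decimals); stages missing from the manifest are skipped with a notice.
#'
#' @param manifest A `vf_manifest` from [run_pipeline()].
#' @param dir Output directory (defaults to `<outdir>/report`).
#' @return Named character vector of written files, invisibly.
#' @export
make_tables <- function(manifest, dir = file.path(manifest$config$outdir,
                                                  "report")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  outdir <- manifest$config$outdir
  if ("quantify" %in% names(manifest$stages)) {
    tab <- readr::read_tsv(file.path(outdir, "abundance.tsv"),
                           show_col_types = FALSE)
    tab <- round_df(tab, list(median_coverage = 0, pct_toxin_reads = 3,
                              pct_total_reads = 3))
    names(tab) <- c("Rank", "Cluster name", "Cluster size", "CDS length",
                    "Median coverage", "% Toxin reads", "% Total reads")
    p <- file.path(dir, "abundance_report.tsv")
    readr::write_tsv(tab, p)
    written["abundance"] <- p
  } else message("stage 'quantify' missing; abundance report skipped")
  if ("proteome" %in% names(manifest$stages)) {
    tab <- readr::read_tsv(file.path(outdir, "identifications.tsv"),
                           show_col_types = FALSE)
    tab <- round_df(tab, list(score = 2, pct_coverage = 2))
    names(tab) <- c("Transcript name", "Protein score", "Peptide matches",
                    "% Seq. coverage", "Group")
    p <- file.path(dir, "identification_report.tsv")
    readr::write_tsv(tab, p)
    written["identifications"] <- p
  } else message("stage 'proteome' missing; identification report skipped")
  if ("selection" %in% names(manifest$stages)) {
    tab <- readr::read_tsv(file.path(outdir, "rates.tsv"),
                           show_col_types = FALSE)
    tab <- round_df(tab, list(dN = 4, dS = 4, omega = 4))
    p <- file.path(dir, "selection_report.tsv")
    readr::write_tsv(tab, p)
    written["selection"] <- p
  } else message("stage 'selection' missing; selection report skipped")
  invisible(written)
}
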