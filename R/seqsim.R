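# Synthetic two-species venom-gland data with known ground truth: toxin gene
# families (clusters of near-identical paralogs/alleles), nontoxins, strongly
# toxin-biased expression, 151-nt paired reads with 3'-overlapping inserts
# and adapter read-through, and peptide-identification reports with decoys.

# reserved separator carrying truth provenance inside read names
VF_READ_SEP <- " vf:"

#' Default toxin family structure
#'
#' Mirrors the class composition of a strongly three-finger-toxin biased
#' rear-fanged snake venom gland: 46 clusters across 15 toxin classes, with
#' the large 3FTx families carrying most of the multi-member clusters.
#' @return Tibble with columns `class`, `n_clusters`, `cluster_size`, `omega`.
#' @export
default_toxin_families <- function() {
  tibble::tribble(
    ~class,     ~n_clusters, ~cluster_size, ~omega,
    "3FTx",      10L,         6L,            1.8,
    "SVMPIII",    4L,         2L,            1.2,
    "CRISP",      1L,         4L,            1.0,
    "CTL",        9L,         1L,            0.6,
    "Ficolin",    5L,         1L,            0.4,
    "AChE",       3L,         1L,            0.3,
    "NP",         1L,         2L,            0.5,
    "KUN",        2L,         1L,            0.6,
    "VEGF",       3L,         1L,            0.3,
    "Waprin",     2L,         1L,            0.6,
    "PLA2",       1L,         2L,            0.8,
    "CF",         2L,         1L,            0.2,
    "VF",         1L,         1L,            0.2,
    "HYAL",       1L,         1L,            0.2,
    "PDE",        1L,         1L,            0.2
  )
}

#' Build a simulation configuration
#'
#' All downstream stages are exercised against data drawn from this
#' configuration.  Defaults emulate the venom-gland study conditions at desk
#' scale: 151-nt paired reads with mostly full-length 3' overlap (mean insert
#' 142 nt), a toxin fraction of 36.2% of transcription, and toxin families
#' whose members differ by <1% in their coding sequences.
#'
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#' @param n_nontoxins Number of nontoxin transcripts per species.
#' @param toxin_family_spec Tibble with columns `class`, `n_clusters`,
#'   `cluster_size`, `omega` (dN/dS used when diverging the two species).
#' @param expression_model List with `nontoxin` and `toxin` log-normal
#'   parameters (`meanlog`, `sdlog`) and `toxin_fraction`, the target share
#'   of transcription from toxin coding sequences.
#' @param read_length Read length in nucleotides.
#' @param insert_mean,insert_sd Insert-length distribution (normal, truncated
#'   at 30 nt).
#' @param error_rate Per-base substitution error probability.
#' @param quality_mean,quality_sd Phred quality model by cycle (raw scores
#'   capped at 41).
#' @param adapter Adapter sequence appended on fragment read-through.
#' @param chimera_rate Fraction of inserts that are single-breakpoint fusions
#'   of two transcripts.
#' @param unspliced_rate Fraction of inserts drawn from an intron-bearing
#'   (unspliced) copy of the transcript.
#' @param n_read_pairs Number of read pairs to simulate.
#' @param divergence_time Expected substitutions per codon site separating
#'   the two species.
#' @param kappa Transition/transversion rate ratio used in codon evolution.
#' @return A `vf_sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_nontoxins = 300L,
                              toxin_family_spec = default_toxin_families(),
                              expression_model = list(
                                nontoxin = c(meanlog = 0, sdlog = 1),
                                toxin = c(meanlog = 0, sdlog = 1.5),
                                toxin_fraction = 0.362
                              ),
                              read_length = 151L,
                              insert_mean = 142,
                              insert_sd = 20,
                              error_rate = 0.001,
                              quality_mean = 35,
                              quality_sd = 3,
                              adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                              chimera_rate = 0.002,
                              unspliced_rate = 0.002,
                              n_read_pairs = 50000L,
                              divergence_time = 0.3,
                              kappa = 2) {
  cfg <- list(seed = as.integer(seed), n_nontoxins = as.integer(n_nontoxins),
              toxin_family_spec = toxin_family_spec,
              expression_model = expression_model,
              read_length = as.integer(read_length),
              insert_mean = insert_mean, insert_sd = insert_sd,
              error_rate = error_rate, quality_mean = quality_mean,
              quality_sd = quality_sd, adapter = adapter,
              chimera_rate = chimera_rate, unspliced_rate = unspliced_rate,
              n_read_pairs = as.integer(n_read_pairs),
              divergence_time = divergence_time, kappa = kappa)
  class(cfg) <- "vf_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fs <- cfg$toxin_family_spec
  stopifnot(is.data.frame(fs),
            all(c("class", "n_clusters", "cluster_size", "omega") %in% names(fs)))
  rates <- c(cfg$error_rate, cfg$chimera_rate, cfg$unspliced_rate,
             cfg$expression_model$toxin_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (any(fs$omega <= 0)) stop("omega must be > 0", call. = FALSE)
  if (any(fs$n_clusters < 1L)) stop("n_clusters must be >= 1", call. = FALSE)
  if (any(fs$cluster_size < 1L))
    stop("impossible family spec: cluster_size must be >= 1", call. = FALSE)
  if (cfg$read_length < 1L) stop("read_length must be >= 1", call. = FALSE)
  if (cfg$n_read_pairs < 0L) stop("n_read_pairs must be >= 0", call. = FALSE)
  if (cfg$divergence_time < 0) stop("divergence_time must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Packaged synthetic toxin reference proteins
#'
#' A small, fully synthetic set of class-labeled reference proteins (one per
#' toxin class) used both to seed the simulated toxin families and as the
#' alignment reference for keyword-based toxin annotation.  Each description
#' carries the class keyword; the first 20 residues of each entry act as the
#' signal peptide.
#'
#' @return Tibble with columns `class`, `protein`, `description`.
#' @export
toxin_reference <- function() {
  path <- system.file("extdata", "toxin_reference_synthetic.fasta",
                      package = "venomforge")
  seqs <- read_fasta(path, type = "protein")
  hdr <- names(seqs)
  tibble::tibble(
    class = sub("_ref.*$", "", hdr),
    protein = unname(seqs),
    description = sub("^\\S+\\s*", "", hdr)
  )
}

# -- sequence construction helpers ------------------------------------------

random_sense_codons <- function(n) {
  sc <- sense_codons()
  sample(sc, n, replace = TRUE)
}

random_cds <- function(n_codons_core) {
  stops <- stop_codons()
  paste0("ATG", paste(random_sense_codons(n_codons_core), collapse = ""),
         sample(stops, 1L))
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(NUC, n, replace = TRUE), collapse = "")
}

#' Reverse-translate a protein using uniform synonymous codon choice
#' @noRd
reverse_translate <- function(protein) {
  sc <- sense_codons()
  by_aa <- split(sc, codon_aa(sc))
  aas <- strsplit(protein, "")[[1]]
  cods <- vapply(aas, function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste0(paste(cods, collapse = ""), sample(stop_codons(), 1L))
}

#' Sprinkle sense-preserving-ish random substitutions on a CDS
#'
#' Substitutions avoid the start codon and the stop codon and are rejected
#' when they would introduce an internal stop, so the result is always a
#' valid CDS.
#' @noRd
sprinkle_substitutions <- function(cds, n_sub) {
  if (n_sub <= 0L) return(cds)
  bases <- strsplit(cds, "")[[1]]
  L <- length(bases)
  eligible <- 4:(L - 3L)
  placed <- 0L
  guard <- 0L
  while (placed < n_sub && guard < 50L * n_sub) {
    guard <- guard + 1L
    p <- sample(eligible, 1L)
    old <- bases[p]
    new <- sample(setdiff(NUC, old), 1L)
    cod_i <- (p - 1L) %/% 3L + 1L
    cod <- bases[(3L * cod_i - 2L):(3L * cod_i)]
    cod[(p - 1L) %% 3L + 1L] <- new
    if (codon_aa(paste(cod, collapse = "")) == "*") next
    bases[p] <- new
    placed <- placed + 1L
  }
  paste(bases, collapse = "")
}

#' Evolve an ancestral CDS into two descendant CDSs
#'
#' Continuous-time GY94 codon simulation with exponential waiting times along
#' two independent branches of length `t/2`.  The start codon and the stop
#' codon are held fixed; internal codons never pass through a stop state
#' (the chain lives on the 61 sense codons).
#'
#' @param ancestor A valid CDS (ATG ... stop).
#' @param omega dN/dS ratio (scalar or per-internal-codon vector).
#' @param kappa Transition/transversion rate ratio.
#' @param t Total divergence in expected substitutions per codon site under
#'   neutrality (omega = 1).  All genes share this mutational clock, so
#'   synonymous divergence is omega-independent while nonsynonymous
#'   divergence scales with omega, as in real coding sequences.
#' @param freqs Codon frequencies of the process (default uniform).
#' @return List with `cds1`, `cds2`, and realized event counts
#'   `n_syn`, `n_nonsyn` (summed over both branches).
#' @export
evolve_codon_sequences <- function(ancestor, omega, kappa = 2, t = 0.3,
                                   freqs = codon_freqs_uniform()) {
  validate_cds(ancestor)
  cods <- split_codons(ancestor)
  n <- length(cods)
  core <- cods[2:(n - 1L)]
  if (t == 0) {
    return(list(cds1 = ancestor, cds2 = ancestor, n_syn = 0L, n_nonsyn = 0L))
  }
  neutral_rate <- -sum(freqs * diag(gy94_rate_matrix(kappa, 1, freqs,
                                                     scale = FALSE)))
  b1 <- sim_codon_branch(core, t / 2, kappa, omega, freqs,
                         scale_rate = neutral_rate)
  b2 <- sim_codon_branch(core, t / 2, kappa, omega, freqs,
                         scale_rate = neutral_rate)
  mk <- function(b) paste0(cods[1L], paste(b$codons, collapse = ""), cods[n])
  list(cds1 = mk(b1), cds2 = mk(b2),
       n_syn = b1$n_syn + b2$n_syn,
       n_nonsyn = b1$n_nonsyn + b2$n_nonsyn)
}

# -- transcriptome simulation ------------------------------------------------

#' Simulate two diverged venom-gland transcriptomes with known truth
#'
#' Builds an ancestral transcriptome (toxin families seeded from the
#' packaged class references, nontoxins as random coding sequences), splits
#' it into two species by GY94 codon evolution at the configured divergence,
#' generates within-cluster variants by sprinkling <1% substitutions on the
#' cluster ancestor, and draws expression weights rescaled so the toxin
#' share of transcription equals the configured target.
#'
#' @param config A [simulation_config()].
#' @return A `vf_truth` list with elements `transcripts` (tibble: `species`,
#'   `id`, `class`, `cluster_name`, `member`, `cds`, `utr5`, `utr3`,
#'   `sequence`, `expression_weight`, `signal_start`, `signal_end`,
#'   `ancestor`), `ortholog_map` (tibble `id_a`, `id_b`), `site_omega_map`
#'   (named list of per-codon omega vectors per ancestor), and `config`.
#' @export
simulate_transcriptomes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  fs <- config$toxin_family_spec
  refs <- toxin_reference()

  anc <- list()   # one row per ancestral locus
  # toxin families: per class, clusters diverge from the class ancestor
  for (r in seq_len(nrow(fs))) {
    cls <- fs$class[r]
    ref_prot <- refs$protein[match(cls, refs$class)]
    if (is.na(ref_prot)) stop("no packaged reference for class ", cls, call. = FALSE)
    class_anc <- reverse_translate(ref_prot)
    for (cl in seq_len(fs$n_clusters[r])) {
      ccods <- split_codons(class_anc)
      core <- sim_codon_branch(ccods[2:(length(ccods) - 1L)], t = 0.3,
                               kappa = config$kappa, omega = fs$omega[r])
      cl_anc <- paste0(ccods[1L], paste(core$codons, collapse = ""),
                       ccods[length(ccods)])
      anc[[length(anc) + 1L]] <- list(
        locus = sprintf("%s-%d", cls, cl), class = cls,
        cluster_name = sprintf("%s-%d", cls, cl),
        cds = cl_anc, omega = fs$omega[r],
        n_members = fs$cluster_size[r],
        signal_start = 1L, signal_end = 20L
      )
    }
  }
  # nontoxins: random CDS, lengths log-normal around ~1.4 kb
  for (i in seq_len(config$n_nontoxins)) {
    ncod <- max(60L, round(rlnorm(1, meanlog = log(450), sdlog = 0.45)))
    anc[[length(anc) + 1L]] <- list(
      locus = sprintf("NTX-%d", i), class = "nontoxin",
      cluster_name = sprintf("NTX-%d", i),
      cds = random_cds(ncod), omega = 0.12, n_members = 1L,
      signal_start = NA_integer_, signal_end = NA_integer_
    )
  }

  site_omega_map <- list()
  rows <- list()
  ortho <- list()
  for (a in anc) {
    n_core <- nchar(a$cds) / 3 - 2L
    site_omega_map[[a$locus]] <- rep(a$omega, n_core)
    ev <- evolve_codon_sequences(a$cds, omega = a$omega, kappa = config$kappa,
                                 t = config$divergence_time)
    for (sp_i in 1:2) {
      sp <- c("A", "B")[sp_i]
      sp_cds <- if (sp_i == 1L) ev$cds1 else ev$cds2
      utr5 <- random_dna(sample(30:150, 1L))
      utr3 <- random_dna(sample(30:200, 1L))
      for (m in seq_len(a$n_members)) {
        member <- letters[m]
        var_cds <- if (m == 1L) sp_cds else
          sprinkle_substitutions(sp_cds, max(1L, round(0.003 * nchar(sp_cds))))
        id <- if (a$n_members > 1L) paste0(sp, "_", a$locus, member) else
          paste0(sp, "_", a$locus)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          species = sp, id = id, class = a$class,
          cluster_name = a$cluster_name, member = member,
          cds = var_cds, utr5 = utr5, utr3 = utr3,
          sequence = paste0(utr5, var_cds, utr3),
          signal_start = a$signal_start, signal_end = a$signal_end,
          ancestor = a$locus
        )
      }
    }
    idA <- if (a$n_members > 1L) paste0("A_", a$locus, "a") else paste0("A_", a$locus)
    idB <- if (a$n_members > 1L) paste0("B_", a$locus, "a") else paste0("B_", a$locus)
    ortho[[length(ortho) + 1L]] <- tibble::tibble(
      id_a = idA, id_b = idB, ancestor = a$locus,
      is_toxin = a$class != "nontoxin"
    )
  }
  tx <- dplyr::bind_rows(rows)

  # expression weights: log-normal per transcript, rescaled per species so
  # the toxin fraction of transcription hits the configured target
  em <- config$expression_model
  tx$expression_weight <- NA_real_
  for (sp in c("A", "B")) {
    sel <- tx$species == sp
    is_tox <- tx$class[sel] != "nontoxin"
    w <- numeric(sum(sel))
    w[is_tox] <- rlnorm(sum(is_tox), em$toxin["meanlog"], em$toxin["sdlog"])
    w[!is_tox] <- rlnorm(sum(!is_tox), em$nontoxin["meanlog"], em$nontoxin["sdlog"])
    tf <- em$toxin_fraction
    if (any(is_tox)) w[is_tox] <- w[is_tox] / sum(w[is_tox]) * tf else tf <- 0
    if (any(!is_tox)) w[!is_tox] <- w[!is_tox] / sum(w[!is_tox]) * (1 - tf)
    tx$expression_weight[sel] <- w
  }

  out <- list(transcripts = tx,
              ortholog_map = dplyr::bind_rows(ortho),
              site_omega_map = site_omega_map,
              config = config)
  class(out) <- "vf_truth"
  out
}

#' @export
print.vf_truth <- function(x, ...) {
  tx <- x$transcripts
  cat("Synthetic two-species venom-gland truth\n")
  for (sp in unique(tx$species)) {
    sel <- tx$species == sp
    cat(sprintf("  species %s: %d transcripts (%d toxin, %d nontoxin), toxin fraction %.3f\n",
                sp, sum(sel), sum(sel & tx$class != "nontoxin"),
                sum(sel & tx$class == "nontoxin"),
                sum(tx$expression_weight[sel & tx$class != "nontoxin"])))
  }
  invisible(x)
}

# -- read simulation ---------------------------------------------------------

apply_sequencing_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), error_rate)
  todo <- which(n_err > 0L)
  for (i in todo) {
    b <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(b), n_err[i])
    b[pos] <- vapply(b[pos], function(x) sample(setdiff(NUC, x), 1L), character(1))
    seqs[i] <- paste(b, collapse = "")
  }
  seqs
}

draw_qualities <- function(n_reads, read_length, qmean, qsd) {
  q <- matrix(round(rnorm(n_reads * read_length, qmean, qsd)),
              nrow = read_length)
  q[q < 2L] <- 2L
  q[q > 41L] <- 41L
  q
}

#' Simulate paired-end reads from a synthetic transcriptome
#'
#' Inserts are drawn per transcript proportionally to expression weight;
#' short inserts produce adapter read-through; a configured fraction of
#' inserts are single-breakpoint two-parent fusions (chimeras) or carry a
#' random intron (unspliced).  Read ids carry truth provenance after the
#' reserved separator `" vf:"`.
#'
#' @param truth A `vf_truth` object.
#' @param config The [simulation_config()] (defaults to the truth's own).
#' @param species Which species to draw reads from (`"A"` or `"B"`).
#' @param blind Strip truth provenance from read names.
#' @return Tibble with `id`, `read1`, `read2` and list-columns `qual1`,
#'   `qual2`; attribute `provenance` maps reads to source transcripts.
#' @export
simulate_reads <- function(truth, config = truth$config, species = "A",
                           blind = FALSE) {
  stopifnot(inherits(truth, "vf_truth"))
  set.seed(config$seed + 101L)
  tx <- truth$transcripts[truth$transcripts$species == species, ]
  n <- config$n_read_pairs
  rl <- config$read_length
  if (n == 0L) {
    out <- tibble::tibble(id = character(), read1 = character(),
                          read2 = character(), qual1 = list(), qual2 = list())
    attr(out, "provenance") <- tibble::tibble(id = character(),
                                              origin = character(),
                                              kind = character())
    return(out)
  }
  src <- sample.int(nrow(tx), n, replace = TRUE, prob = tx$expression_weight)
  kind <- sample(c("normal", "chimera", "unspliced"), n, replace = TRUE,
                 prob = c(1 - config$chimera_rate - config$unspliced_rate,
                          config$chimera_rate, config$unspliced_rate))
  ins_len <- pmax(30L, round(rnorm(n, config$insert_mean, config$insert_sd)))

  templates <- tx$sequence[src]
  origin <- tx$id[src]
  chim <- which(kind == "chimera")
  if (length(chim) > 0L) {
    partner <- sample.int(nrow(tx), length(chim), replace = TRUE,
                          prob = tx$expression_weight)
    for (j in seq_along(chim)) {
      i <- chim[j]
      s1 <- templates[i]; s2 <- tx$sequence[partner[j]]
      bp1 <- sample.int(nchar(s1), 1L)
      bp2 <- sample.int(nchar(s2), 1L)
      templates[i] <- paste0(substr(s1, 1L, bp1), substr(s2, bp2, nchar(s2)))
      origin[i] <- paste0(origin[i], "+", tx$id[partner[j]])
    }
  }
  unspl <- which(kind == "unspliced")
  if (length(unspl) > 0L) {
    for (i in unspl) {
      s <- templates[i]
      at <- sample.int(nchar(s), 1L)
      intron <- random_dna(sample(80:200, 1L))
      templates[i] <- paste0(substr(s, 1L, at), intron,
                             substr(s, at + 1L, nchar(s)))
    }
  }

  tlen <- nchar(templates)
  ins_len <- pmin(ins_len, tlen)
  start <- floor(runif(n) * (tlen - ins_len + 1L)) + 1L
  insert <- substr(templates, start, start + ins_len - 1L)

  read_from <- function(frag) {
    # read of length rl from the 5' end of frag, adapter-padded on read-through
    short <- nchar(frag) < rl
    if (any(short)) {
      pad <- paste0(config$adapter,
                    strrep("A", max(0, rl - nchar(config$adapter))))
      frag[short] <- paste0(frag[short],
                            substring(pad, 1L, rl - nchar(frag[short])))
    }
    substr(frag, 1L, rl)
  }
  r1 <- read_from(insert)
  r2 <- read_from(unname(reverse_complement(insert)))
  r1 <- apply_sequencing_errors(r1, config$error_rate)
  r2 <- apply_sequencing_errors(r2, config$error_rate)
  q1 <- draw_qualities(n, rl, config$quality_mean, config$quality_sd)
  q2 <- draw_qualities(n, rl, config$quality_mean, config$quality_sd)

  ids <- sprintf("rp%06d", seq_len(n))
  prov <- tibble::tibble(id = ids, origin = origin, kind = kind,
                         insert_start = start, insert_length = ins_len)
  if (!blind) {
    ids <- sprintf("%s%svtx=%s;kind=%s;pos=%d;len=%d", ids, VF_READ_SEP,
                   origin, kind, start, ins_len)
  }
  out <- tibble::tibble(
    id = ids, read1 = r1, read2 = r2,
    qual1 = lapply(seq_len(n), function(i) q1[, i]),
    qual2 = lapply(seq_len(n), function(i) q2[, i])
  )
  attr(out, "provenance") <- prov
  out
}

#' Strip truth provenance from read ids
#' @param ids Character vector of read ids.
#' @return Ids truncated at the reserved separator.
#' @export
strip_provenance <- function(ids) sub(paste0(VF_READ_SEP, ".*$"), "", ids)

#' Parse truth provenance back out of read ids
#' @param ids Read ids produced by [simulate_reads()] with `blind = FALSE`.
#' @return Tibble with `id`, `origin`, `kind`, `insert_start`, `insert_length`.
#' @export
read_provenance <- function(ids) {
  tag <- sub(paste0("^.*", VF_READ_SEP), "", ids)
  tibble::tibble(
    id = strip_provenance(ids),
    origin = stringr::str_match(tag, "vtx=([^;]+)")[, 2],
    kind = stringr::str_match(tag, "kind=([^;]+)")[, 2],
    insert_start = as.integer(stringr::str_match(tag, "pos=([0-9]+)")[, 2]),
    insert_length = as.integer(stringr::str_match(tag, "len=([0-9]+)")[, 2])
  )
}

# -- identification-report simulation ---------------------------------------

#' Simulate a peptide-identification report with decoys
#'
#' Emulates the tabular output of a protein-identification search engine:
#' for each mature protein present in the (simulated) venom, a protein score
#' and a set of matched tryptic peptides with per-peptide scores; decoy rows
#' drawn from reversed sequences with the decoy score distribution.
#'
#' @param truth A `vf_truth` object.
#' @param species Species to report on.
#' @param detectability Probability that a given toxin protein is present in
#'   the venom sample and detected.
#' @param score_model List with `target` and `decoy` location/scale pairs
#'   for the protein score distributions.
#' @param peptide_detect_prob Per-peptide detection probability for present
#'   proteins.
#' @param n_decoy_rows Number of decoy identifications reported.
#' @param seed Integer seed.
#' @return Tibble with `protein_id`, `protein_score`, `peptide`,
#'   `peptide_score`, `is_decoy`; attribute `present` lists the transcript
#'   ids genuinely present.
#' @export
simulate_id_report <- function(truth, species = "A", detectability = 0.8,
                               score_model = list(
                                 target = c(location = 1000, scale = 200),
                                 decoy = c(location = 50, scale = 15)
                               ),
                               peptide_detect_prob = 0.7,
                               n_decoy_rows = 5L,
                               seed = truth$config$seed + 202L) {
  stopifnot(inherits(truth, "vf_truth"))
  stopifnot(detectability >= 0, detectability <= 1)
  set.seed(seed)
  tx <- truth$transcripts[truth$transcripts$species == species &
                            truth$transcripts$class != "nontoxin", ]
  mature <- vapply(seq_len(nrow(tx)), function(i) {
    p <- translate_cds(tx$cds[i])
    if (!is.na(tx$signal_end[i])) substr(p, tx$signal_end[i] + 1L, nchar(p)) else p
  }, character(1))
  present <- tx$id[runif(nrow(tx)) < detectability]
  rows <- list()
  for (i in seq_len(nrow(tx))) {
    if (!(tx$id[i] %in% present)) next
    peps <- tryptic_digest(mature[i])
    if (nrow(peps) == 0L) next
    det <- peps$peptide[runif(nrow(peps)) < peptide_detect_prob]
    det <- unique(det)
    if (length(det) == 0L) next
    score <- max(1, rnorm(1, score_model$target["location"],
                          score_model$target["scale"]))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      protein_id = tx$id[i], protein_score = score, peptide = det,
      peptide_score = pmax(1, rnorm(length(det), score / 10, score / 50)),
      is_decoy = FALSE
    )
  }
  # decoy identifications from reversed mature sequences
  if (n_decoy_rows > 0L && nrow(tx) > 0L) {
    pick <- sample.int(nrow(tx), min(n_decoy_rows, nrow(tx)))
    for (i in pick) {
      revseq <- paste(rev(strsplit(mature[i], "")[[1]]), collapse = "")
      peps <- tryptic_digest(revseq)
      if (nrow(peps) == 0L) next
      det <- unique(peps$peptide[sample.int(nrow(peps),
                                            min(2L, nrow(peps)))])
      score <- max(0.1, rnorm(1, score_model$decoy["location"],
                              score_model$decoy["scale"]))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        protein_id = paste0(tx$id[i], "|decoy"), protein_score = score,
        peptide = det,
        peptide_score = pmax(0.1, rnorm(length(det), score / 10, score / 50)),
        is_decoy = TRUE
      )
    }
  }
  out <- if (length(rows) > 0L) dplyr::bind_rows(rows) else
    tibble::tibble(protein_id = character(), protein_score = numeric(),
                   peptide = character(), peptide_score = numeric(),
                   is_decoy = logical())
  attr(out, "present") <- present
  out
}

#' Write a truth object to disk (FASTA + JSON)
#'
#' @param truth A `vf_truth` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx <- truth$transcripts
  for (sp in unique(tx$species)) {
    sel <- tx[tx$species == sp, ]
    hdr <- sprintf("%s|cluster=%s|class=%s|member=%s", sel$id,
                   sel$cluster_name, sel$class, sel$member)
    write_fasta(setNames(sel$sequence, hdr),
                file.path(dir, sprintf("transcripts_%s.fasta", sp)))
    write_fasta(setNames(sel$cds, hdr),
                file.path(dir, sprintf("cds_%s.fasta", sp)))
    prot <- vapply(sel$cds, translate_cds, character(1), USE.NAMES = FALSE)
    write_fasta(setNames(prot, hdr),
                file.path(dir, sprintf("proteins_%s.fasta", sp)),
                type = "protein")
  }
  truth_json <- list(
    transcripts = tx[, setdiff(names(tx), c("sequence"))],
    ortholog_map = truth$ortholog_map
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
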