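# Synthetic-data generator: configuration validation, ground-truth
# invariants, codon evolution, read simulation and identification reports.

test_that("configuration validation rejects impossible specs", {
  expect_error(simulation_config(error_rate = 1.5), "rates")
  fam <- default_toxin_families()
  fam$cluster_size[1] <- 0L
  expect_error(simulation_config(toxin_family_spec = fam), "cluster_size")
  fam2 <- default_toxin_families()
  fam2$omega[2] <- -1
  expect_error(simulation_config(toxin_family_spec = fam2), "omega")
})

test_that("simulated truth satisfies its structural invariants", {
  cfg <- simulation_config(seed = 21, n_nontoxins = 10, n_read_pairs = 0,
                           toxin_family_spec = tiny_families())
  truth <- simulate_transcriptomes(cfg)
  tx <- truth$transcripts
  for (sp in c("A", "B")) {
    sel <- tx[tx$species == sp, ]
    expect_equal(sum(sel$expression_weight), 1, tolerance = 1e-9)
    # every CDS is valid (ATG...stop, no internal stop)
    for (cds in sel$cds) expect_true(validate_cds(cds))
    # toxin fraction equals the configured target
    expect_equal(sum(sel$expression_weight[sel$class != "nontoxin"]),
                 cfg$expression_model$toxin_fraction, tolerance = 1e-9)
  }
  # members of one cluster have pairwise divergence < 0.01
  tox <- tx[tx$class != "nontoxin" & tx$species == "A", ]
  for (cl in unique(tox$cluster_name)) {
    members <- tox$cds[tox$cluster_name == cl]
    if (length(members) < 2) next
    for (i in seq_len(length(members) - 1)) {
      a <- utf8ToInt(members[i]); b <- utf8ToInt(members[i + 1])
      expect_lt(sum(a != b) / length(a), 0.01)
    }
  }
  # ortholog map points at real transcripts in both species
  expect_true(all(truth$ortholog_map$id_a %in% tx$id[tx$species == "A"]))
  expect_true(all(truth$ortholog_map$id_b %in% tx$id[tx$species == "B"]))
})

test_that("identical seeds give identical truth and reads", {
  cfg <- simulation_config(seed = 33, n_nontoxins = 5, n_read_pairs = 200,
                           toxin_family_spec = tiny_families("CRISP"))
  t1 <- simulate_transcriptomes(cfg)
  t2 <- simulate_transcriptomes(cfg)
  expect_identical(t1$transcripts, t2$transcripts)
  r1 <- simulate_reads(t1, cfg)
  r2 <- simulate_reads(t2, cfg)
  expect_identical(r1$read1, r2$read1)
  expect_identical(r1$qual2, r2$qual2)
})

test_that("codon evolution respects the zero-divergence and omega=0 limits", {
  anc <- random_cds_fixture(100, seed = 2)
  e0 <- evolve_codon_sequences(anc, omega = 0.5, t = 0)
  expect_identical(e0$cds1, anc)
  expect_identical(e0$cds2, anc)
  set.seed(9)
  ez <- evolve_codon_sequences(random_cds_fixture(800, seed = 3),
                               omega = 0, t = 0.3)
  expect_identical(ez$n_nonsyn, 0L)
  expect_gt(ez$n_syn, 0L)
  expect_true(validate_cds(ez$cds1))
  expect_error(evolve_codon_sequences("ATGTAAAAATAA", omega = 1),
               "internal stop")
})

test_that("NG86 on simulated descendants is consistent with realized events", {
  anc <- random_cds_fixture(10000, seed = 4)
  set.seed(5)
  ev <- evolve_codon_sequences(anc, omega = 0.5, kappa = 2, t = 0.2)
  al <- codon_align(ev$cds1, ev$cds2)
  r <- ng86_rates(al$aln1, al$aln2)
  # omega recovered within +/- 0.1
  expect_lt(abs(r$omega - 0.5), 0.1)
  # dN consistent with the per-event record within 10%
  # (events double-count back substitutions only negligibly at t = 0.2)
  dn_events <- ev$n_nonsyn / r$N
  expect_lt(abs(r$dN - dn_events) / dn_events, 0.1)
})

test_that("read simulation honors provenance, adapters and expression", {
  cfg <- simulation_config(seed = 41, n_nontoxins = 4, n_read_pairs = 4000,
                           error_rate = 0, chimera_rate = 0,
                           unspliced_rate = 0,
                           toxin_family_spec = tiny_families("CRISP"))
  truth <- simulate_transcriptomes(cfg)
  reads <- simulate_reads(truth, cfg)
  prov <- attr(reads, "provenance")
  expect_equal(nrow(reads), cfg$n_read_pairs)
  expect_identical(read_provenance(reads$id)$origin, prov$origin)
  tx <- truth$transcripts[truth$transcripts$species == "A", ]
  # error-free reads are substrings of their template (or its rc), with
  # adapter read-through for short inserts
  idx <- sample.int(nrow(reads), 200)
  for (i in idx) {
    tmpl <- tx$sequence[match(prov$origin[i], tx$id)]
    ins <- substr(tmpl, prov$insert_start[i],
                  prov$insert_start[i] + prov$insert_length[i] - 1)
    if (prov$insert_length[i] >= cfg$read_length) {
      expect_identical(reads$read1[i], substr(ins, 1, cfg$read_length))
    } else {
      expect_identical(substr(reads$read1[i], 1, prov$insert_length[i]), ins)
      overhang <- cfg$read_length - prov$insert_length[i]
      pad <- paste0(cfg$adapter,
                    strrep("A", max(0, cfg$read_length - nchar(cfg$adapter))))
      expect_identical(
        substr(reads$read1[i], prov$insert_length[i] + 1, cfg$read_length),
        substr(pad, 1, overhang))
    }
  }
  # read counts per transcript follow expression weights (binomial, 3 SD)
  top <- tx$id[which.max(tx$expression_weight)]
  w <- tx$expression_weight[match(top, tx$id)]
  frac <- mean(prov$origin == top)
  expect_lt(abs(frac - w), 3 * sqrt(w * (1 - w) / nrow(reads)))
  # n_read_pairs = 0 is a valid empty read set
  cfg0 <- simulation_config(seed = 41, n_nontoxins = 4, n_read_pairs = 0,
                            toxin_family_spec = tiny_families("CRISP"))
  expect_equal(nrow(simulate_reads(truth, cfg0)), 0)
})

test_that("identification reports respect detectability and decoy structure", {
  cfg <- simulation_config(seed = 55, n_nontoxins = 3, n_read_pairs = 0,
                           toxin_family_spec = tiny_families())
  truth <- simulate_transcriptomes(cfg)
  none <- simulate_id_report(truth, detectability = 0)
  expect_true(all(none$is_decoy))
  expect_length(attr(none, "present"), 0)
  rep <- simulate_id_report(truth, detectability = 1)
  tox_ids <- truth$transcripts$id[truth$transcripts$species == "A" &
                                    truth$transcripts$class != "nontoxin"]
  expect_setequal(attr(rep, "present"), tox_ids)
  expect_true(any(rep$is_decoy))
  expect_true(all(grepl("\\|decoy$", rep$protein_id[rep$is_decoy])))
})

test_that("truth files are written in standard formats", {
  cfg <- simulation_config(seed = 60, n_nontoxins = 3, n_read_pairs = 0,
                           toxin_family_spec = tiny_families("CRISP"))
  truth <- simulate_transcriptomes(cfg)
  dir <- tempfile("truthdir")
  write_truth(truth, dir)
  fa <- read_fasta(file.path(dir, "cds_A.fasta"))
  tx <- truth$transcripts[truth$transcripts$species == "A", ]
  expect_equal(length(fa), nrow(tx))
  expect_identical(unname(fa), tx$cds)
  hdr <- parse_cds_header <- names(fa)
  expect_true(all(grepl("\\|cluster=.*\\|class=.*\\|member=", hdr)))
  expect_true(file.exists(file.path(dir, "truth.json")))
})
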