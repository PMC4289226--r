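# Assembly: seed extension, reference consensus, deduplication, clustering,
# chimera screening, annotation and naming.

make_tiling <- function(tx, starts, read_len = 151, phred = 35L) {
  tibble::tibble(
    sequence = substring(tx, starts, pmin(starts + read_len - 1, nchar(tx))),
    quality = lapply(starts, function(s)
      rep(phred, min(read_len, nchar(tx) - s + 1)))
  )
}

test_that("seed extension recovers a planted transcript from tiled reads", {
  set.seed(10)
  tx <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  reads <- make_tiling(tx, c(seq(1, 441, by = 10), 450))
  contig <- extend_seed(reads$sequence[23], reads)
  expect_identical(contig, tx)
  # output always contains the seed
  expect_true(grepl(reads$sequence[23], contig, fixed = TRUE))
})

test_that("extension respects the 100-nt overlap and phred-30 rules", {
  set.seed(11)
  tx <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  seed <- substr(tx, 100, 250)
  # read overlapping by exactly 99 nt is not used
  r99 <- tibble::tibble(sequence = substr(tx, 152, 300),
                        quality = list(rep(35L, 149)))
  expect_identical(extend_seed(seed, r99), seed)
  # 100 nt exact overlap extends
  r100 <- tibble::tibble(sequence = substr(tx, 151, 300),
                         quality = list(rep(35L, 150)))
  expect_identical(extend_seed(seed, r100), substr(tx, 100, 300))
  # same read with one phred-29 base is ineligible
  r_lowq <- r100
  q <- rep(35L, 150); q[75] <- 29L
  r_lowq$quality <- list(q)
  expect_identical(extend_seed(seed, r_lowq), seed)
  # a read with one mismatch in the overlap is ineligible (exact match rule)
  r_mm <- r100
  s <- r_mm$sequence
  substr(s, 50, 50) <- setdiff(c("A", "C", "G", "T"), substr(s, 50, 50))[1]
  r_mm$sequence <- s
  expect_identical(extend_seed(seed, r_mm), seed)
  expect_error(extend_seed(substr(tx, 1, 50), r100), "min_overlap")
})

test_that("reference consensus enforces coverage rules and majority vote", {
  set.seed(12)
  utr5 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  cds <- random_cds_fixture(150, seed = 13)
  utr3 <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  ref_seq <- paste0(utr5, cds, utr3)
  refs <- tibble::tibble(id = "ref1", sequence = ref_seq,
                         cds_start = 61L, cds_end = 60L + nchar(cds))
  reads <- make_tiling(ref_seq, seq(1, nchar(ref_seq) - 150, by = 15))
  cons <- reference_consensus(reads, refs, min_coverage = 5L)
  expect_equal(nrow(cons), 1)
  expect_identical(substr(cons$sequence, cons$cds_start, cons$cds_end), cds)
  # a homozygous substitution in the reads wins the majority vote
  mut_seq <- ref_seq
  substr(mut_seq, 200, 200) <- setdiff(c("A", "C", "G", "T"),
                                       substr(ref_seq, 200, 200))[1]
  reads_mut <- make_tiling(mut_seq, seq(1, nchar(mut_seq) - 150, by = 8))
  cons_mut <- reference_consensus(reads_mut, refs, min_coverage = 5L)
  off <- 200 - (61 - cons_mut$cds_start[1])  # position in trimmed output
  expect_identical(substr(cons_mut$sequence, off, off), substr(mut_seq, 200, 200))
  # sparse tiling drops below 5x inside the CDS: reference dropped
  sparse <- make_tiling(ref_seq, seq(1, nchar(ref_seq) - 150, by = 60))
  expect_equal(nrow(reference_consensus(sparse, refs, min_coverage = 5L)), 0)
  expect_error(reference_consensus(reads, refs[, c("id", "sequence")]),
               "cds_start")
})

test_that("deduplication collapses identical and contained CDSs", {
  tx <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    cds = c("ATGAAACCCGGGTAA", "ATGAAACCCGGGTAA",   # identical pair
            "AAACCCGGG",                             # substring of a
            "ATGTTTCCCAAATAG")                       # unrelated
  )
  out <- deduplicate(tx)
  expect_setequal(out$id, c("a", "d"))
  expect_identical(out$id, sort(out$id))
})

test_that("single-linkage clustering at <1% divergence partitions correctly", {
  set.seed(14)
  base <- random_cds_fixture(99, seed = 15)   # 300 nt
  mutate_at <- function(s, pos) {
    for (p in pos) {
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
    }
    s
  }
  A <- base
  B <- mutate_at(base, c(8, 11))        # A-B: 2/300 = 0.67%
  C <- mutate_at(base, c(8, 11, 14, 17))  # B-C: 2, A-C: 4 (1.3%)
  far <- mutate_at(base, seq(5, 250, by = 12))
  cl <- cluster_toxins(tibble::tibble(id = c("A", "B", "C", "far"),
                                      cds = c(A, B, C, far)))
  expect_equal(length(unique(cl$cluster_id[cl$id %in% c("A", "B", "C")])), 1)
  expect_false(cl$cluster_id[cl$id == "far"] %in%
                 cl$cluster_id[cl$id %in% c("A", "B", "C")])
  # every CDS in exactly one cluster
  expect_identical(sort(cl$id), sort(c("A", "B", "C", "far")))
  # all identical sequences give one cluster; empty input gives none
  same <- cluster_toxins(tibble::tibble(id = c("x", "y"), cds = c(A, A)))
  expect_equal(unique(same$cluster_id), 1L)
  expect_equal(nrow(cluster_toxins(tibble::tibble(id = character(),
                                                  cds = character()))), 0)
})

test_that("clusters are numbered by abundance and members lettered", {
  set.seed(16)
  base1 <- random_cds_fixture(80, seed = 17)
  base2 <- random_cds_fixture(80, seed = 18)
  v <- function(s, p) { substr(s, p, p) <- "A"; s }
  cds_set <- tibble::tibble(
    id = c("m1", "m2", "n1"),
    cds = c(base1, v(base1, 11), base2),
    abundance = c(5, 20, 100)
  )
  cl <- cluster_toxins(cds_set)
  # cluster with n1 (abundance 100) is numbered 1
  expect_equal(cl$cluster_id[cl$id == "n1"], 1L)
  # within cluster 2, m2 (20) is member a and the representative
  expect_equal(cl$member[cl$id == "m2"], "a")
  expect_true(cl$representative[cl$id == "m2"])
  expect_equal(cl$member[cl$id == "m1"], "b")
})

test_that("chimera screening flags fusions and spares genuine transcripts", {
  cfg <- simulation_config(seed = 91, n_nontoxins = 2, n_read_pairs = 0,
                           toxin_family_spec = tiny_families("CRISP"))
  truth <- simulate_transcriptomes(cfg)
  tx <- truth$transcripts[truth$transcripts$species == "A", ]
  X <- tx$sequence[1]; Y <- tx$sequence[nrow(tx)]
  bp <- floor(nchar(X) / 2)
  bp2 <- floor(nchar(Y) / 2)
  fusion <- paste0(substr(X, 1, bp), substr(Y, bp2 + 1, nchar(Y)))
  db <- tibble::tibble(id = tx$id, sequence = tx$sequence)
  reads <- dplyr::bind_rows(
    make_tiling(X, seq(1, nchar(X) - 150, by = 12)),
    make_tiling(Y, seq(1, nchar(Y) - 150, by = 12))
  )
  cand <- tibble::tibble(id = c("fusion", tx$id[1]),
                         sequence = c(fusion, X))
  verdict <- detect_chimeras(cand, reads, db)
  expect_true(verdict$is_chimera[verdict$id == "fusion"])
  expect_setequal(verdict$parents[[which(verdict$id == "fusion")]],
                  c(tx$id[1], tx$id[nrow(tx)]))
  expect_lt(abs(verdict$breakpoint[verdict$id == "fusion"] - bp), 61)
  # the genuine transcript with uniform coverage is spared
  expect_false(verdict$is_chimera[verdict$id == tx$id[1]])
  # uniformly low depth does not trigger the evenness test
  lowdepth <- make_tiling(X, seq(1, nchar(X) - 150, by = 70))
  v2 <- detect_chimeras(tibble::tibble(id = tx$id[1], sequence = X),
                        lowdepth, db)
  expect_false(v2$is_chimera[1])
})

test_that("annotation assigns classes via the packaged reference and names", {
  cfg <- simulation_config(seed = 95, n_nontoxins = 5, n_read_pairs = 0,
                           toxin_family_spec = tiny_families(c("3FTx", "SVMPIII")))
  truth <- simulate_transcriptomes(cfg)
  tx <- truth$transcripts[truth$transcripts$species == "A", ]
  ann <- annotate_and_name(tibble::tibble(id = tx$id, cds = tx$cds,
                                          abundance = tx$expression_weight))
  got <- ann$class_label
  want <- ifelse(tx$class == "nontoxin", "nontoxin", tx$class)
  expect_identical(got, want)
  # naming: multi-member clusters get letters, singletons do not
  named <- ann[ann$class_label != "nontoxin", ]
  multi <- named$cluster_name[duplicated(named$cluster_name)][1]
  members <- named$toxin_name[named$cluster_name == multi]
  expect_true(all(grepl("^[A-Za-z0-9]+-[0-9]+[a-z]$", members)))
  expect_true(any(grepl("a$", members)))
})
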