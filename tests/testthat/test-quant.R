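# Read mapping against CDS databases and expression tables.

test_that("mapping honors the identity threshold and assigns best hits", {
  cds1 <- random_cds_fixture(120, seed = 20)   # 366 nt
  cds2 <- random_cds_fixture(120, seed = 21)
  db <- tibble::tibble(name = c("c1", "c2"), cluster = c("c1", "c2"),
                       sequence = c(cds1, cds2))
  read_exact <- substr(cds1, 50, 200)          # 151 nt, exact
  # 151-nt read with 10 mismatches: identity 141/151 = 93.4% < 95%
  read_bad <- read_exact
  set.seed(22)
  for (p in sample(20:140, 10)) {
    substr(read_bad, p, p) <- setdiff(c("A", "C", "G", "T"),
                                      substr(read_bad, p, p))[1]
  }
  reads <- tibble::tibble(sequence = c(read_exact, read_bad))
  mp <- map_reads_to_cds(reads, db, min_identity = 0.95, seed = 1)
  expect_equal(mp$n_mapped, 1L)
  expect_equal(mp$counts$cluster, "c1")
  # reverse-complement reads map too
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read_exact)))
  mp2 <- map_reads_to_cds(tibble::tibble(sequence = rc), db, seed = 1)
  expect_equal(mp2$counts$cluster, "c1")
  expect_error(map_reads_to_cds(reads, db[0, ], seed = 1), "empty")
})

test_that("mapped fractions track configured expression weights", {
  cfg <- simulation_config(seed = 101, n_nontoxins = 0, n_read_pairs = 6000,
                           error_rate = 0, chimera_rate = 0, unspliced_rate = 0,
                           toxin_family_spec = tibble::tibble(
                             class = c("CRISP", "CTL", "KUN"),
                             n_clusters = 1L, cluster_size = 1L, omega = 0.5))
  truth <- simulate_transcriptomes(cfg)
  # rescale weights to 0.5 / 0.3 / 0.2 per species
  tx <- truth$transcripts
  for (sp in c("A", "B")) {
    sel <- which(tx$species == sp)
    tx$expression_weight[sel] <- c(0.5, 0.3, 0.2)
  }
  truth$transcripts <- tx
  reads <- simulate_reads(truth, cfg)
  m <- merge_set(reads)
  txA <- tx[tx$species == "A", ]
  db <- tibble::tibble(name = txA$id, cluster = txA$cluster_name,
                       sequence = txA$cds,
                       is_toxin = TRUE)
  mp <- map_reads_to_cds(m$merged, db, seed = 5)
  fr <- mp$counts$reads / mp$n_mapped
  names(fr) <- mp$counts$cluster
  w <- setNames(txA$expression_weight, txA$cluster_name)
  for (cl in names(w)) {
    expect_lt(abs(fr[[cl]] - w[[cl]]), 3 * sqrt(w[[cl]] * (1 - w[[cl]]) / mp$n_mapped) + 0.02)
  }
})

test_that("abundance tables satisfy the percentage identities", {
  cfg <- simulation_config(seed = 105, n_nontoxins = 6, n_read_pairs = 5000,
                           error_rate = 0,
                           toxin_family_spec = tiny_families(c("3FTx", "CRISP")))
  truth <- simulate_transcriptomes(cfg)
  reads <- simulate_reads(truth, cfg)
  m <- merge_set(reads)
  txA <- truth$transcripts[truth$transcripts$species == "A", ]
  db <- tibble::tibble(name = txA$id, cluster = txA$cluster_name,
                       sequence = txA$cds, is_toxin = txA$class != "nontoxin",
                       member = txA$member)
  mp <- map_reads_to_cds(m$merged, db, seed = 2)
  tab <- abundance_table(mp, db)
  # toxin percentages sum to 100
  expect_equal(sum(tab$pct_toxin_reads), 100, tolerance = 0.05)
  # ranks ordered by pct_toxin_reads
  expect_identical(tab$rank, seq_len(nrow(tab)))
  expect_false(is.unsorted(rev(tab$pct_toxin_reads)))
  # pct_total / pct_toxin constant across rows (the toxin share)
  ratio <- tab$pct_total_reads / tab$pct_toxin_reads
  expect_lt(max(ratio) - min(ratio), 1e-9)
  # pct_toxin >= pct_total row-wise
  expect_true(all(tab$pct_toxin_reads >= tab$pct_total_reads))
  # median coverage on a constructed depth vector
  mp_small <- list(counts = tibble::tibble(cluster = "x", reads = 5L,
                                           scaled_reads = 5),
                   depth = list(x1 = c(1, 2, 3, 4, 100)), n_mapped = 5L)
  db_small <- tibble::tibble(name = "x1", cluster = "x", sequence = "AAAAA",
                             is_toxin = TRUE)
  tab_small <- abundance_table(mp_small, db_small)
  expect_equal(tab_small$median_coverage, 3)
  expect_equal(tab_small$pct_toxin_reads, 100)
  expect_equal(tab_small$pct_total_reads, 100)
})

test_that("class summaries aggregate published tables to the printed totals", {
  b <- published_expression("boiga")
  cs <- class_summary(b)
  by <- cs$by_class
  expect_equal(by$pct_toxin_reads[by$class == "3FTx"], 67.5, tolerance = 0.05)
  expect_equal(cs$toxin_pct_total, 36.2, tolerance = 0.05)
  h <- published_expression("hypsiglena")
  csh <- class_summary(h)
  expect_equal(csh$by_class$pct_toxin_reads[csh$by_class$class == "SVMPIII"],
               68.7, tolerance = 0.05)
  # one class only -> 100% of the class share
  one <- b[class_of_cluster(b$cluster_name) == "CRISP", ]
  expect_equal(sum(class_summary(one)$by_class$pct_toxin_reads),
               sum(one$pct_toxin_reads))
  # unknown labels fall into "other" with a warning
  expect_warning(class_summary(b, classes = c(`SVMPIII-2a` = "SVMPIII")),
                 "other")
})
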