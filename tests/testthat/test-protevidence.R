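# Search databases, tryptic digestion, peptide mapping, acceptance filters,
# grouping and cluster cross-referencing.

test_that("search databases pair every target with its reversed decoy", {
  tx <- tibble::tibble(
    id = c("t1", "t2"),
    cds = c(random_cds_fixture(60, seed = 30), random_cds_fixture(80, seed = 31)),
    signal_start = c(1L, NA), signal_end = c(10L, NA)
  )
  db <- build_search_db(tx)
  expect_equal(nrow(db), 4)
  expect_equal(sum(db$is_decoy), 2)
  p1 <- translate_cds(tx$cds[1])
  expect_identical(db$sequence[db$protein_id == "t1"],
                   substr(p1, 11, nchar(p1)))
  fwd <- db$sequence[db$protein_id == "t2"]
  rev_ <- db$sequence[db$protein_id == "t2|decoy"]
  expect_identical(rev_, paste(rev(strsplit(fwd, "")[[1]]), collapse = ""))
  # decoy of ACDEF is FEDCA
  db2 <- build_search_db(tibble::tibble(id = "x", cds = "ATGGCCTGTGACGAATTTTAA"))
  expect_identical(db2$sequence[db2$protein_id == "x|decoy"],
                   paste(rev(strsplit(db2$sequence[1], "")[[1]]), collapse = ""))
  # span outside the CDS is rejected
  bad <- tx; bad$signal_end[1] <- 1000L
  expect_error(build_search_db(bad), "signal")
})

test_that("tryptic digestion follows the K/R-not-before-P rule", {
  d <- tryptic_digest("AAAKBBBRCCC", max_missed_cleavages = 1, min_length = 1)
  expect_setequal(d$peptide[d$missed == 0], c("AAAK", "BBBR", "CCC"))
  expect_setequal(d$peptide[d$missed == 1], c("AAAKBBBR", "BBBRCCC"))
  # no cleavage before proline
  d2 <- tryptic_digest("AAAKPBBB", min_length = 1)
  expect_identical(d2$peptide, "AAAKPBBB")
  # no K/R at all: one peptide equal to the protein
  d3 <- tryptic_digest("AAACCCDDD", min_length = 1)
  expect_identical(d3$peptide, "AAACCCDDD")
  # length filter applies after enumeration
  d4 <- tryptic_digest("AAAKBBBRCCC", min_length = 6)
  expect_true(all(nchar(d4$peptide) >= 6))
  expect_true("AAAKBBBR" %in% d4$peptide)
})

test_that("peptide mapping computes coverage and I/L equivalence", {
  set.seed(33)
  p1_seq <- paste(sample(strsplit("ACDEFGHMNQSTVWY", "")[[1]], 100, TRUE),
                  collapse = "")
  db <- tibble::tibble(
    protein_id = c("p1", "p2"),
    sequence = c(p1_seq, "MKTILERAAAAKRLLLL"),
    is_decoy = FALSE
  )
  report <- tibble::tibble(
    protein_id = c("p1", "p2"),
    protein_score = c(100, 200),
    peptide = c(substr(p1_seq, 1, 50), "MKTLLER")
  )
  mp <- map_peptides(report, db)
  i1 <- mp$identifications[mp$identifications$protein_id == "p1", ]
  expect_equal(i1$pct_coverage, 50)
  # I/L equivalence: MKTLLER matches MKTILER
  i2 <- mp$identifications[mp$identifications$protein_id == "p2", ]
  expect_equal(i2$peptide_matches, 1)
  mp_strict <- map_peptides(report, db, leucine_isoleucine_equivalent = FALSE)
  i2s <- mp_strict$identifications[mp_strict$identifications$protein_id == "p2", ]
  expect_equal(i2s$peptide_matches, 0)
  # unmappable peptides are recorded as orphans, not errors
  rep_orphan <- tibble::tibble(protein_id = "p1", protein_score = 5,
                               peptide = "WWWWWWW")
  expect_identical(map_peptides(rep_orphan, db)$orphans, "WWWWWWW")
})

test_that("acceptance applies all three filters and is monotone", {
  idents <- tibble::tibble(
    protein_id = c("a", "b", "c", "d"),
    score = c(500, 500, 500, 90),
    peptide_matches = c(2L, 5L, 5L, 5L),
    pct_coverage = c(90, 19.9, 45, 45),
    is_decoy = FALSE,
    peptides = list("x", "x", "x", "x")
  )
  acc <- accept_identifications(idents, decoy_scores = c(10, 100))
  expect_identical(acc$protein_id, "c")   # a: <3 peptides; b: <20%; d: <= decoy
  # raising any threshold never adds an identification
  for (mp_ in c(3L, 5L)) for (mc in c(20, 30)) {
    sub <- accept_identifications(idents, decoy_scores = c(10, 100),
                                  min_peptides = mp_, min_coverage = mc)
    expect_true(all(sub$protein_id %in% acc$protein_id))
  }
  # empty decoy set: only the count/coverage rules apply
  acc2 <- accept_identifications(idents, decoy_scores = numeric(0))
  expect_setequal(acc2$protein_id, c("c", "d"))
})

test_that("decoy guarantee holds on simulated reports across seeds", {
  cfg <- simulation_config(seed = 120, n_nontoxins = 3, n_read_pairs = 0,
                           toxin_family_spec = tiny_families())
  truth <- simulate_transcriptomes(cfg)
  txA <- truth$transcripts[truth$transcripts$species == "A", ]
  db <- build_search_db(txA)
  for (seed in c(1, 2, 3, 4, 5)) {
    rep_ <- simulate_id_report(truth, detectability = 0.6, seed = seed)
    mp <- map_peptides(rep_, db)
    acc <- accept_identifications(mp$identifications)
    expect_equal(sum(acc$is_decoy), 0)
    expect_true(all(acc$protein_id %in% attr(rep_, "present")))
  }
})

test_that("grouping follows the shared-unique-peptide reconstruction", {
  mk <- function(id, peps) tibble::tibble(
    protein_id = id, score = 100, peptide_matches = length(peps),
    pct_coverage = 50, is_decoy = FALSE, peptides = list(peps))
  # A and B share a unique peptide; C is disjoint
  acc <- dplyr::bind_rows(mk("A", c("pp1", "shared")),
                          mk("B", c("pp1", "shared")),
                          mk("C", "pp2"))
  g <- group_identifications(acc)
  expect_equal(g$group[g$protein_id == "A"], g$group[g$protein_id == "B"])
  expect_false(g$group[g$protein_id == "C"] == g$group[g$protein_id == "A"])
  # two entries sharing all peptides and nothing else form one group
  g2 <- group_identifications(dplyr::bind_rows(mk("X", "q"), mk("Y", "q")))
  expect_equal(g2$group, c(1L, 1L))
  # entries whose every peptide also maps into an already-grouped set get NA
  acc3 <- dplyr::bind_rows(
    mk("E", c("u1", "s")), mk("F", c("u1", "s")),   # u1 unique to E,F
    mk("G", "s"))                                    # only the broad peptide
  g3 <- group_identifications(acc3)
  expect_equal(g3$group[g3$protein_id == "E"], g3$group[g3$protein_id == "F"])
  expect_true(is.na(g3$group[g3$protein_id == "G"]))
})

test_that("cross-referencing published identifications counts clusters", {
  b_ids <- published_identifications("boiga")
  b_clusters <- unique(sub("(?<=[0-9])[a-z]$", "",
                           published_expression("boiga")$cluster_name,
                           perl = TRUE))
  xr <- cross_reference(b_ids, b_clusters)
  expect_equal(xr$n_confirmed, 14)
  h_ids <- published_identifications("hypsiglena")
  h_clusters <- unique(sub("(?<=[0-9])[a-z]$", "",
                           published_expression("hypsiglena")$cluster_name,
                           perl = TRUE))
  expect_equal(cross_reference(h_ids, h_clusters)$n_confirmed, 18)
  # no accepted identifications -> nothing confirmed
  empty <- cross_reference(tibble::tibble(protein_id = character()),
                           b_clusters)
  expect_equal(empty$n_confirmed, 0)
})
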