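# Ortholog detection, codon alignment, pairwise rates, outlier analysis,
# trees, and the likelihood-ratio arithmetic.

test_that("reciprocal best hits recover identical and simulated orthologs", {
  prot <- tibble::tibble(
    id = c("x", "y"),
    protein = c(paste(rep("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", 3), collapse = ""),
                paste(rep("MNSLDWFFQKAAERERTGGHHPLNMDLLAQWST", 3), collapse = "")))
  self <- rbh_orthologs(prot, prot)
  expect_equal(nrow(self), 2)
  expect_identical(self$id_a, self$id_b)
  empty <- rbh_orthologs(prot[0, ], prot)
  expect_equal(nrow(empty), 0)
  # simulated two-species truth: all pairs recovered, no false pairs
  cfg <- simulation_config(seed = 130, n_nontoxins = 8, n_read_pairs = 0,
                           toxin_family_spec = tiny_families("CRISP"))
  truth <- simulate_transcriptomes(cfg)
  tx <- truth$transcripts[!duplicated(paste(truth$transcripts$species,
                                            truth$transcripts$ancestor)), ]
  mk <- function(sp) {
    s <- tx[tx$species == sp, ]
    tibble::tibble(id = s$id, protein = vapply(s$cds, translate_cds, "",
                                               USE.NAMES = FALSE))
  }
  orth <- rbh_orthologs(mk("A"), mk("B"))
  truth_pairs <- paste(truth$ortholog_map$id_a, truth$ortholog_map$id_b)
  got <- paste(orth$id_a, orth$id_b)
  expect_gte(mean(truth_pairs %in% got), 0.95)
  expect_true(all(got %in% truth_pairs))
})

test_that("codon alignment applies the 24-gapped-position filter", {
  cds <- random_cds_fixture(60, seed = 40)
  al0 <- codon_align(cds, cds)
  expect_false(al0$excluded)
  expect_equal(al0$gapped_positions, 0L)
  expect_identical(al0$aln1, al0$aln2)
  drop_codons <- function(cds, k) {
    cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    n <- length(cods)
    paste(cods[-(seq_len(k) + 10)], collapse = "")
  }
  # 8-codon (24-nt) deletion is retained, 9-codon (27-nt) excluded
  al24 <- codon_align(cds, drop_codons(cds, 8))
  expect_false(al24$excluded)
  expect_equal(al24$gapped_positions, 24L)
  al27 <- codon_align(cds, drop_codons(cds, 9))
  expect_true(al27$excluded)
  expect_equal(al27$gapped_positions, 27L)
  expect_error(codon_align("ATGAA", cds), "divisible")
})

test_that("NG86 handles degenerate and hand-checked cases", {
  r0 <- pairwise_rates("ATGAAA", "ATGAAA")
  expect_equal(r0$dN, 0)
  expect_equal(r0$dS, 0)
  expect_true(is.na(r0$omega))
  # TTT|TTA vs TTT|TTG: third-position Leu change is synonymous both ways
  r <- ng86_rates("TTTTTA", "TTTTTG")
  o <- oracle_ng86("TTTTTA", "TTTTTG")
  expect_equal(r$dN, 0)
  expect_equal(r$S, o$S)
  expect_equal(r$Sd, o$Sd)
  expect_identical(is.na(r$dS), is.na(o$dS))
})

test_that("NG86 matches the brute-force pathway oracle on random pairs", {
  set.seed(41)
  sense <- oracle_sense()
  for (rep_ in 1:40) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    imp <- venomforge:::ng86_path_counts(c1, c2)
    orc <- oracle_path_counts(c1, c2)
    expect_equal(unname(imp), unname(orc), tolerance = 1e-12,
                 label = paste(c1, c2))
  }
  # and on a short random alignment end-to-end
  s1 <- paste(sample(sense, 30, TRUE), collapse = "")
  s2 <- paste(sample(sense, 30, TRUE), collapse = "")
  a <- ng86_rates(s1, s2); b <- oracle_ng86(s1, s2)
  expect_equal(a$S, b$S); expect_equal(a$Sd, b$Sd); expect_equal(a$Nd, b$Nd)
})

test_that("ML pairwise rates recover the generating omega", {
  set.seed(43)
  errs <- vapply(1:3, function(i) {
    anc <- random_cds_fixture(5000, seed = 42 + i)
    ev <- evolve_codon_sequences(anc, omega = 0.25, kappa = 2, t = 0.2)
    al <- codon_align(ev$cds1, ev$cds2)
    r <- pairwise_rates(al$aln1, al$aln2, method = "ML")
    abs(r$omega - 0.25)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("outlier analysis: thresholds, exceed counts and Wilcoxon tests", {
  # toxins drawn from the nontoxin distribution exceed ~5% of the time
  set.seed(44)
  null_draws <- tibble::tibble(dN = rlnorm(1000, -2, 0.5),
                               dS = rlnorm(1000, -1.5, 0.4))
  null_draws$omega <- null_draws$dN / null_draws$dS
  tox <- tibble::tibble(dN = rlnorm(1000, -2, 0.5),
                        dS = rlnorm(1000, -1.5, 0.4))
  tox$omega <- tox$dN / tox$dS
  res <- rate_outlier_analysis(tox, null_draws)
  for (s in c("dN", "dS", "omega")) {
    expect_lt(abs(res$toxin_exceed_counts[[s]] / 1000 - 0.05),
              3 * sqrt(0.05 * 0.95 / 1000))
  }
  # exact Wilcoxon on a hand-enumerable case
  x <- tibble::tibble(dN = c(1, 2, 3), dS = c(1, 2, 3), omega = c(1, 2, 3))
  y <- tibble::tibble(dN = c(4, 5, 6), dS = c(4, 5, 6), omega = c(4, 5, 6))
  res2 <- rate_outlier_analysis(x, y)
  expect_equal(unname(res2$wilcoxon_p["dN"]), 0.1)
  # identical samples give p = 1
  res3 <- rate_outlier_analysis(x, x)
  expect_equal(unname(res3$wilcoxon_p["dN"]), 1)
  expect_error(rate_outlier_analysis(x, x[0, ]), "empty")
})

test_that("exact Wilcoxon matches full enumeration for small samples", {
  set.seed(45)
  for (rep_ in 1:10) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    x <- round(rnorm(n), 3); y <- round(rnorm(m) + 0.5, 3)
    if (anyDuplicated(c(x, y))) next
    p_pkg <- suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value)
    expect_equal(p_pkg, oracle_wilcoxon_p(x, y), tolerance = 1e-10)
  }
})

test_that("neighbor-joining trees behave on degenerate and simulated input", {
  set.seed(46)
  seqs <- setNames(replicate(3, paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                                      collapse = "")), c("a", "b", "c"))
  tr <- nj_tree(seqs)
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 3)
  expect_error(nj_tree(seqs[1:2]), "at least 3")
  # identical sequences: star tree with zero branch lengths
  same <- setNames(rep(seqs[1], 4), c("a", "b", "c", "d"))
  tr0 <- nj_tree(same)
  expect_true(all(tr0$edge.length < 1e-8))
  # four simulated taxa: generating topology recovered
  anc <- random_cds_fixture(400, seed = 47)
  e1 <- evolve_codon_sequences(anc, omega = 0.5, t = 0.4)
  e11 <- evolve_codon_sequences(e1$cds1, omega = 0.5, t = 0.1)
  e12 <- evolve_codon_sequences(e1$cds2, omega = 0.5, t = 0.1)
  tips <- c(A = e11$cds1, B = e11$cds2, C = e12$cds1, D = e12$cds2)
  tr4 <- nj_tree(tips)
  # A,B form a cherry (as do C,D) in the unrooted quartet
  ab_parent <- tr4$edge[match(match(c("A", "B"), tr4$tip.label),
                              tr4$edge[, 2]), 1]
  expect_equal(ab_parent[1], ab_parent[2])
})

test_that("LRT arithmetic reproduces chi-square tail probabilities", {
  expect_equal(lrt_pvalue(100, 100)$p, 1)
  expect_warning(res <- lrt_pvalue(99, 100), "clamped")
  expect_equal(res$p, 1)
  r <- lrt_pvalue(4092.28, 4035.46)
  expect_equal(signif(r$p, 2), 2.1e-25)
  r2 <- lrt_pvalue(1300.92, 1269.86)
  expect_equal(signif(r2$p, 2), 3.2e-14)
  # df = 2 upper tail is exactly exp(-stat/2)
  expect_equal(lrt_pvalue(10, 5)$p, exp(-5))
})
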