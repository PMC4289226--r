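# Ortholog detection, codon-aware alignment, pairwise substitution rates
# (counting and maximum likelihood), null-distribution outlier analysis,
# and neighbor-joining trees.

#' Karlin-Altschul E-value for a local protein alignment score
#'
#' Classical extreme-value formula with precomputed constants for the
#' standard BLOSUM62 gapped scoring scheme.
#' @noRd
ka_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  K * m * n * exp(-lambda * score)
}

#' Reciprocal-best-hit orthologs between two proteomes
#'
#' All-vs-all local protein alignment (BLOSUM62); pairs are kept iff the two
#' sequences are each other's best match and the match's E-value is below
#' `evalue_cutoff`.
#'
#' @param proteins_a,proteins_b Tibbles with `id`, `protein`; rows with
#'   `mitochondrial = TRUE` are excluded when that column is present.
#' @param evalue_cutoff Maximum E-value.
#' @return Tibble with `id_a`, `id_b`, `score`, `evalue`.
#' @export
rbh_orthologs <- function(proteins_a, proteins_b, evalue_cutoff = 1e-4) {
  drop_mt <- function(x) {
    if ("mitochondrial" %in% names(x)) x[!x$mitochondrial, , drop = FALSE] else x
  }
  pa <- drop_mt(proteins_a); pb <- drop_mt(proteins_b)
  if (nrow(pa) == 0L || nrow(pb) == 0L) {
    return(tibble::tibble(id_a = character(), id_b = character(),
                          score = numeric(), evalue = numeric()))
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  sa <- Biostrings::AAStringSet(setNames(pa$protein, pa$id))
  sb <- Biostrings::AAStringSet(setNames(pb$protein, pb$id))
  S <- matrix(0, nrow(pa), nrow(pb))
  for (i in seq_len(nrow(pa))) {
    S[i, ] <- Biostrings::pairwiseAlignment(
      sb, sa[[i]], type = "local", substitutionMatrix = B62,
      gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE)
  }
  dbn_a <- sum(nchar(pa$protein)); dbn_b <- sum(nchar(pb$protein))
  rows <- list()
  best_ab <- apply(S, 1L, which.max)
  best_ba <- apply(S, 2L, which.max)
  for (i in seq_len(nrow(pa))) {
    j <- best_ab[i]
    if (best_ba[j] != i) next
    ev <- ka_evalue(S[i, j], nchar(pa$protein[i]), dbn_b)
    if (ev >= evalue_cutoff) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id_a = pa$id[i], id_b = pb$id[j], score = S[i, j], evalue = ev)
  }
  dplyr::bind_rows(rows)
}

#' Codon-aware pairwise alignment with a gap filter
#'
#' Globally aligns the two translated proteins (BLOSUM62), back-threads the
#' alignment onto codons, counts gapped nucleotide positions, and excludes
#' the pair when the count exceeds `max_gapped_positions`.  Gapped codon
#' columns are removed before any rate estimation.
#'
#' @param cds1,cds2 Valid coding sequences (terminal stop tolerated).
#' @param max_gapped_positions Maximum gapped nucleotide positions.
#' @return List with `excluded` (logical), `gapped_positions`, and (when
#'   retained) `aln1`, `aln2`: gap-free aligned CDS cores of equal length.
#' @export
codon_align <- function(cds1, cds2, max_gapped_positions = 24L) {
  strip_stop <- function(cds) {
    cods <- split_codons(cds)
    if (codon_aa(cods[length(cods)]) == "*") cods <- cods[-length(cods)]
    cods
  }
  co1 <- strip_stop(cds1); co2 <- strip_stop(cds2)
  p1 <- paste(codon_aa(co1), collapse = "")
  p2 <- paste(codon_aa(co2), collapse = "")
  if (grepl("\\*", p1) || grepl("\\*", p2)) {
    stop("internal stop codon in coding sequence", call. = FALSE)
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  al <- Biostrings::pairwiseAlignment(p1, p2, type = "global",
                                      substitutionMatrix = B62,
                                      gapOpening = 10, gapExtension = 0.5)
  a1 <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
  a2 <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
  gap1 <- a1 == "-"; gap2 <- a2 == "-"
  gapped_nt <- 3L * sum(gap1 | gap2)
  if (gapped_nt > max_gapped_positions) {
    return(list(excluded = TRUE, gapped_positions = gapped_nt))
  }
  i1 <- cumsum(!gap1); i2 <- cumsum(!gap2)
  keep <- !gap1 & !gap2
  list(excluded = FALSE, gapped_positions = gapped_nt,
       aln1 = paste(co1[i1[keep]], collapse = ""),
       aln2 = paste(co2[i2[keep]], collapse = ""))
}

#' Two-sequence GY94 maximum-likelihood rates
#' @noRd
pairwise_ml_rates <- function(aln1, aln2) {
  co1 <- split_codons(aln1); co2 <- split_codons(aln2)
  sc <- sense_codons()
  freqs <- codon_freqs_f3x4(c(aln1, aln2))
  freqs <- pmax(freqs, 1e-8); freqs <- freqs / sum(freqs)
  tipA <- match(co1, sc) - 1L
  tipB <- match(co2, sc) - 1L
  pat <- paste(tipA, tipB)
  upat <- !duplicated(pat)
  w <- as.numeric(table(factor(pat, levels = pat[upat])))
  tips <- rbind(tipA[upat], tipB[upat])
  edge <- matrix(c(3L, 1L, 3L, 2L), nrow = 2, byrow = TRUE)
  type <- codon_type_matrix()
  nll <- function(par) {
    t <- exp(par[1]); kappa <- exp(par[2]); omega <- exp(par[3])
    -cpp_codon_mixture_loglik(edge, 2L, c(t / 2, t / 2), tips, w, freqs,
                              type, kappa, omega, 1, 1)
  }
  fit <- optim(log(c(0.3, 2, 0.5)), nll, method = "L-BFGS-B",
               lower = log(c(1e-5, 0.05, 1e-4)), upper = log(c(30, 50, 50)))
  t_hat <- exp(fit$par[1]); kappa_hat <- exp(fit$par[2]); omega_hat <- exp(fit$par[3])
  fl <- gy94_flux(kappa_hat, omega_hat, freqs)
  fl1 <- gy94_flux(kappa_hat, 1, freqs)
  dS <- t_hat * fl$syn / (3 * fl1$syn)
  dN <- t_hat * fl$nonsyn / (3 * fl1$nonsyn)
  list(dN = dN, dS = dS,
       omega = if (dS > 0) dN / dS else NA_real_,
       t = t_hat, kappa = kappa_hat, lnL = -fit$value)
}

#' Proportion of synonymous vs nonsynonymous flux of a GY94 process
#' @noRd
gy94_flux <- function(kappa, omega, freqs) {
  chg <- codon_change_structure()
  Q <- gy94_rate_matrix(kappa, omega, freqs, scale = TRUE)
  syn_flux <- sum(freqs * rowSums(Q * (chg$single & chg$synonymous)))
  nonsyn_flux <- sum(freqs * rowSums(Q * (chg$single & !chg$synonymous)))
  tot <- syn_flux + nonsyn_flux
  list(syn = syn_flux / tot, nonsyn = nonsyn_flux / tot)
}

#' Single-step type matrix for the C++ likelihood
#' @noRd
codon_type_matrix <- function() {
  if (is.null(.vf_cache$typemat)) {
    chg <- codon_change_structure()
    tm <- matrix(0L, 61L, 61L)
    tm[chg$single & chg$synonymous & !chg$transition] <- 1L
    tm[chg$single & chg$synonymous & chg$transition] <- 2L
    tm[chg$single & !chg$synonymous & !chg$transition] <- 3L
    tm[chg$single & !chg$synonymous & chg$transition] <- 4L
    .vf_cache$typemat <- tm
  }
  .vf_cache$typemat
}

#' Pairwise dN/dS for an aligned codon pair
#'
#' `method = "counting"` uses the Nei-Gojobori pathway estimator with
#' Jukes-Cantor correction; `method = "ML"` maximizes the two-sequence GY94
#' likelihood (F3x4 frequencies) over divergence, kappa and omega.
#'
#' @param aln1,aln2 Gap-free aligned coding sequences (no stop codons).
#' @param method `"counting"` or `"ML"`.
#' @return Tibble row: `dN`, `dS`, `omega` (NA when `dS` is 0 or a rate is
#'   undefined), `method`, `note`.
#' @export
pairwise_rates <- function(aln1, aln2, method = c("counting", "ML")) {
  method <- match.arg(method)
  stopifnot(nchar(aln1) == nchar(aln2))
  if (method == "counting") {
    r <- ng86_rates(aln1, aln2)
    note <- if (is.na(r$dS) && !is.na(r$pS) && r$pS >= 0.75)
      "dS undefined (corrected proportion >= 0.75)" else NA_character_
    if (is.na(r$dN) && !is.na(r$pN) && r$pN >= 0.75)
      note <- "dN undefined (corrected proportion >= 0.75)"
    return(tibble::tibble(dN = r$dN, dS = r$dS, omega = r$omega,
                          method = "counting", note = note))
  }
  r <- pairwise_ml_rates(aln1, aln2)
  tibble::tibble(dN = r$dN, dS = r$dS, omega = r$omega, method = "ML",
                 note = NA_character_)
}

#' Rate table for a set of ortholog pairs
#'
#' Convenience wrapper: codon-aligns each CDS pair, applies the gap filter,
#' and estimates pairwise rates.
#'
#' @param pairs Tibble with `id_a`, `id_b`, `cds_a`, `cds_b`, optional
#'   `is_toxin`.
#' @param method Passed to [pairwise_rates()].
#' @param max_gapped_positions Passed to [codon_align()].
#' @return Tibble with one row per retained pair: ids, `dN`, `dS`, `omega`,
#'   `is_toxin`, `excluded`.
#' @export
rate_table <- function(pairs, method = "counting", max_gapped_positions = 24L) {
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    al <- codon_align(pairs$cds_a[i], pairs$cds_b[i], max_gapped_positions)
    if (al$excluded) {
      rows[[i]] <- tibble::tibble(
        id_a = pairs$id_a[i], id_b = pairs$id_b[i], dN = NA_real_,
        dS = NA_real_, omega = NA_real_,
        is_toxin = if ("is_toxin" %in% names(pairs)) pairs$is_toxin[i] else NA,
        excluded = TRUE)
      next
    }
    r <- pairwise_rates(al$aln1, al$aln2, method = method)
    rows[[i]] <- tibble::tibble(
      id_a = pairs$id_a[i], id_b = pairs$id_b[i], dN = r$dN, dS = r$dS,
      omega = r$omega,
      is_toxin = if ("is_toxin" %in% names(pairs)) pairs$is_toxin[i] else NA,
      excluded = FALSE)
  }
  dplyr::bind_rows(rows)
}

#' Nontoxin null-distribution outlier analysis
#'
#' Computes the empirical `q`-quantile (linear interpolation) of the
#' nontoxin dN, dS and dN/dS distributions, counts the toxin pairs
#' exceeding each threshold, and compares the distributions with two-sided
#' Wilcoxon rank-sum tests (exact when both samples are small and tie-free).
#'
#' @param toxin_rates,nontoxin_rates Tibbles with `dN`, `dS`, `omega`.
#' @param q Quantile defining the thresholds.
#' @return A `vf_rate_null` list: `thresholds`, `toxin_exceed_counts`,
#'   `n_toxin`, `wilcoxon_p`, `n_dropped_omega` and the input samples.
#' @export
rate_outlier_analysis <- function(toxin_rates, nontoxin_rates, q = 0.95) {
  if (nrow(nontoxin_rates) == 0L) stop("empty nontoxin set", call. = FALSE)
  stats <- c("dN", "dS", "omega")
  thresholds <- setNames(numeric(3), stats)
  exceed <- setNames(integer(3), stats)
  pvals <- setNames(rep(NA_real_, 3), stats)
  dropped <- sum(is.na(toxin_rates$omega)) + sum(is.na(nontoxin_rates$omega))
  for (s in stats) {
    x <- toxin_rates[[s]]; x <- x[!is.na(x)]
    y <- nontoxin_rates[[s]]; y <- y[!is.na(y)]
    thresholds[s] <- quantile(y, q, type = 7, names = FALSE)
    exceed[s] <- sum(x > thresholds[s])
    if (length(x) >= 2L && length(y) >= 2L) {
      exact <- min(length(x), length(y)) <= 20L &&
        !anyDuplicated(c(x, y))
      pvals[s] <- suppressWarnings(
        wilcox.test(x, y, alternative = "two.sided", exact = exact,
                    correct = TRUE)$p.value)
    }
  }
  out <- list(thresholds = thresholds, toxin_exceed_counts = exceed,
              n_toxin = sum(!is.na(toxin_rates$dN)),
              wilcoxon_p = pvals, n_dropped_omega = dropped,
              toxin_rates = toxin_rates, nontoxin_rates = nontoxin_rates,
              q = q)
  class(out) <- "vf_rate_null"
  out
}

#' @export
print.vf_rate_null <- function(x, ...) {
  cat(sprintf("Nontoxin null-distribution analysis (q = %.2f)\n", x$q))
  for (s in names(x$thresholds)) {
    cat(sprintf("  %-5s threshold %.4f; %d/%d toxin pairs exceed; Wilcoxon p = %.3g\n",
                s, x$thresholds[s], x$toxin_exceed_counts[s], x$n_toxin,
                x$wilcoxon_p[s]))
  }
  invisible(x)
}

#' Pairwise HKY maximum-likelihood distance
#' @noRd
hky_distance <- function(s1, s2) {
  b1 <- strsplit(s1, "")[[1]]; b2 <- strsplit(s2, "")[[1]]
  keep <- b1 %in% NUC & b2 %in% NUC
  b1 <- b1[keep]; b2 <- b2[keep]
  n <- length(b1)
  if (n == 0L) return(0)
  if (all(b1 == b2)) return(0)
  freqs <- table(factor(c(b1, b2), levels = NUC)) / (2 * n)
  pi_ <- pmax(as.numeric(freqs), 1e-6); pi_ <- pi_ / sum(pi_)
  # counts of site patterns
  tab <- table(factor(b1, levels = NUC), factor(b2, levels = NUC))
  nllk <- function(par) {
    t <- exp(par[1]); kappa <- exp(par[2])
    Q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
    for (i in 1:4) for (j in 1:4) {
      if (i == j) next
      Q[i, j] <- pi_[j] * if (is_transition(NUC[i], NUC[j])) kappa else 1
    }
    diag(Q) <- -rowSums(Q)
    Q <- Q / (-sum(pi_ * diag(Q)))
    P <- as.matrix(Matrix::expm(Q * t))
    P[P < 1e-12] <- 1e-12
    -sum(tab * log(pi_ * P))
  }
  fit <- optim(log(c(0.1, 2)), nllk, method = "L-BFGS-B",
               lower = log(c(1e-6, 0.05)), upper = log(c(20, 50)))
  exp(fit$par[1])
}

#' Neighbor-joining tree from coding sequences
#'
#' Pairwise maximum-likelihood HKY distances followed by neighbor joining;
#' negative branch lengths are clamped to zero.  The tree is unrooted.
#'
#' @param seqs Named character vector of (aligned, equal-length) sequences.
#' @return An `ape` `phylo` object.
#' @export
nj_tree <- function(seqs) {
  if (length(seqs) < 3L) stop("need at least 3 sequences", call. = FALSE)
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- hky_distance(seqs[[i]], seqs[[j]])
    }
  }
  tr <- ape::nj(as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Likelihood-ratio test p-value against chi-square
#'
#' Inputs follow the reporting convention of codon-model tables: the
#' magnitudes of the negative log-likelihoods.  The statistic is
#' `2 * (lnL_null - lnL_alt)` on that convention; for `df = 2` the upper
#' tail is exactly `exp(-statistic / 2)`.
#'
#' @param lnL_null,lnL_alt Negative log-likelihood magnitudes of the nested
#'   null and alternative fits.
#' @param df Degrees of freedom.
#' @return Tibble row: `statistic`, `df`, `p`.
#' @export
lrt_pvalue <- function(lnL_null, lnL_alt, df = 2L) {
  statistic <- 2 * (lnL_null - lnL_alt)
  if (any(statistic < 0)) {
    warning("negative LRT statistic clamped to 0")
    statistic <- pmax(statistic, 0)
  }
  tibble::tibble(statistic = statistic, df = df,
                 p = pchisq(statistic, df = df, lower.tail = FALSE))
}
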