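# Genetic-code tables and codon-level utilities shared by the simulator and
# the molecular-evolution routines.  Standard nuclear code throughout; the 61
# sense codons are the state space for all codon models.

NUC <- c("A", "C", "G", "T")

#' All 64 codons in lexicographic order
#' @noRd
all_codons <- function() {
  if (is.null(.vf_cache$codons64)) {
    .vf_cache$codons64 <- as.vector(outer(
      outer(NUC, NUC, paste0), NUC, paste0
    ))
    .vf_cache$codons64 <- sort(.vf_cache$codons64)
  }
  .vf_cache$codons64
}

#' Translate one codon under the standard code ("*" for stop)
#' @noRd
codon_aa <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

#' The 61 sense codons (stops removed), fixed order
#' @noRd
sense_codons <- function() {
  if (is.null(.vf_cache$sense)) {
    cods <- all_codons()
    .vf_cache$sense <- cods[codon_aa(cods) != "*"]
  }
  .vf_cache$sense
}

stop_codons <- function() setdiff(all_codons(), sense_codons())

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Split a CDS string into codon triplets
#' @noRd
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length must be divisible by 3", call. = FALSE)
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Validate a coding sequence
#'
#' A valid CDS is built from A/C/G/T, has length divisible by three, starts
#' with ATG, ends with a stop codon, and contains no internal stop.
#'
#' @param cds Character scalar, nucleotide coding sequence.
#' @param require_atg,require_stop Relax the terminal checks (internal
#'   codon-model routines work on stop-free cores that need not begin ATG).
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_cds <- function(cds, require_atg = TRUE, require_stop = TRUE) {
  stopifnot(is.character(cds), length(cds) == 1L)
  if (grepl("[^ACGT]", cds)) stop("CDS contains non-ACGT characters", call. = FALSE)
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3", call. = FALSE)
  cods <- split_codons(cds)
  aas <- codon_aa(cods)
  n <- length(aas)
  if (require_atg && cods[1L] != "ATG") stop("CDS does not start with ATG", call. = FALSE)
  if (require_stop) {
    if (aas[n] != "*") stop("CDS does not end with a stop codon", call. = FALSE)
    if (any(aas[-n] == "*")) stop("CDS has an internal stop codon", call. = FALSE)
  } else if (any(aas == "*")) {
    stop("CDS has an internal stop codon", call. = FALSE)
  }
  invisible(TRUE)
}

#' Translate a CDS to protein, dropping the terminal stop if present
#' @param cds Character scalar coding sequence.
#' @return Character scalar amino-acid sequence.
#' @export
translate_cds <- function(cds) {
  aa <- paste(codon_aa(split_codons(cds)), collapse = "")
  sub("\\*$", "", aa)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# ---------------------------------------------------------------------------
# Nei-Gojobori (1986) counting machinery.
#
# Site counts: at each codon position the three single-nucleotide changes are
# classified as synonymous or nonsynonymous; changes creating a stop codon
# are excluded from the denominator (MEGA convention).  Pathway counts
# between two codons average synonymous/nonsynonymous differences over all
# orderings of the differing positions, skipping orderings that pass through
# a stop codon.

#' Synonymous site count of one codon (0..3)
#' @noRd
ng86_syn_sites_codon <- function(codon) {
  bases <- strsplit(codon, "")[[1]]
  aa0 <- codon_aa(codon)
  s <- 0
  for (pos in 1:3) {
    alts <- setdiff(NUC, bases[pos])
    n_valid <- 0L
    n_syn <- 0L
    for (b in alts) {
      mut <- bases
      mut[pos] <- b
      mutc <- paste(mut, collapse = "")
      aa1 <- codon_aa(mutc)
      if (aa1 == "*") next
      n_valid <- n_valid + 1L
      if (aa1 == aa0) n_syn <- n_syn + 1L
    }
    if (n_valid > 0L) s <- s + n_syn / n_valid
  }
  s
}

#' Pathway-averaged (syn, nonsyn) difference counts between two codons
#' @noRd
ng86_path_counts <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  diffpos <- which(b1 != b2)
  perms <- switch(as.character(length(diffpos)),
    "1" = list(diffpos),
    "2" = list(diffpos, rev(diffpos)),
    "3" = {
      p <- diffpos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    }
  )
  walk <- function(skip_stops) {
    tally <- matrix(NA_real_, nrow = length(perms), ncol = 2)
    for (i in seq_along(perms)) {
      cur <- b1
      sd <- 0; nd <- 0; ok <- TRUE
      for (pos in perms[[i]]) {
        nxt <- cur
        nxt[pos] <- b2[pos]
        aa_cur <- codon_aa(paste(cur, collapse = ""))
        aa_nxt <- codon_aa(paste(nxt, collapse = ""))
        if (skip_stops && aa_nxt == "*") { ok <- FALSE; break }
        if (aa_nxt == aa_cur) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) tally[i, ] <- c(sd, nd)
    }
    tally[!is.na(tally[, 1]), , drop = FALSE]
  }
  tally <- walk(skip_stops = TRUE)
  # all orderings pass through a stop: count over every ordering instead
  if (nrow(tally) == 0L) tally <- walk(skip_stops = FALSE)
  c(sd = mean(tally[, 1]), nd = mean(tally[, 2]))
}

#' Lazily built NG86 lookup tables over the 61 sense codons
#' @noRd
ng86_tables <- function() {
  if (is.null(.vf_cache$ng86)) {
    sc <- sense_codons()
    n <- length(sc)
    ssites <- vapply(sc, ng86_syn_sites_codon, numeric(1))
    sd <- matrix(0, n, n, dimnames = list(sc, sc))
    nd <- matrix(0, n, n, dimnames = list(sc, sc))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        pc <- ng86_path_counts(sc[i], sc[j])
        sd[i, j] <- pc[["sd"]]
        nd[i, j] <- pc[["nd"]]
      }
    }
    .vf_cache$ng86 <- list(ssites = ssites, sd = sd, nd = nd)
  }
  .vf_cache$ng86
}

jukes_cantor <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori pairwise dN/dS
#'
#' Counting estimator of synonymous and nonsynonymous substitution rates for
#' a gap-free pair of aligned coding sequences: average synonymous and
#' nonsynonymous site counts over the two sequences, pathway-averaged
#' difference counts, and a Jukes-Cantor multiple-hit correction.
#'
#' @param cds1,cds2 Aligned coding sequences of equal length (no gaps, no
#'   stop codons; strip terminal stops first).
#' @return A list with `dN`, `dS`, `omega` (NA when `dS` is 0 or a rate is
#'   undefined), raw proportions `pN`, `pS`, and site/difference counts
#'   `N`, `S`, `Nd`, `Sd`.
#' @export
ng86_rates <- function(cds1, cds2) {
  stopifnot(nchar(cds1) == nchar(cds2))
  tab <- ng86_tables()
  co1 <- split_codons(cds1)
  co2 <- split_codons(cds2)
  if (!all(co1 %in% sense_codons()) || !all(co2 %in% sense_codons())) {
    stop("sequences must contain sense codons only", call. = FALSE)
  }
  S <- (sum(tab$ssites[co1]) + sum(tab$ssites[co2])) / 2
  N <- 3 * length(co1) - S
  idx <- cbind(match(co1, sense_codons()), match(co2, sense_codons()))
  Sd <- sum(tab$sd[idx])
  Nd <- sum(tab$nd[idx])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jukes_cantor(pS)
  dN <- jukes_cantor(pN)
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  list(dN = dN, dS = dS, omega = omega, pN = pN, pS = pS,
       N = N, S = S, Nd = Nd, Sd = Sd)
}
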