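# Independent oracles, written before the implementations they check and
# kept deliberately naive.

# All 64 codons and their translation, built from scratch (not via the
# package's own tables).
oracle_codons <- function() {
  nuc <- c("A", "C", "G", "T")
  cods <- apply(expand.grid(nuc, nuc, nuc, stringsAsFactors = FALSE)[, 3:1],
                1, paste, collapse = "")
  sort(cods)
}

oracle_translate <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

oracle_sense <- function() {
  cods <- oracle_codons()
  cods[oracle_translate(cods) != "*"]
}

# Naive NG86: per-codon synonymous site fractions (stop neighbors excluded
# from the denominator) and pathway enumeration via recursion.
oracle_syn_sites <- function(codon) {
  nuc <- c("A", "C", "G", "T")
  b <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    nsyn <- 0; nval <- 0
    for (alt in setdiff(nuc, b[pos])) {
      m <- b; m[pos] <- alt
      aa <- oracle_translate(paste(m, collapse = ""))
      if (aa == "*") next
      nval <- nval + 1
      if (aa == oracle_translate(codon)) nsyn <- nsyn + 1
    }
    if (nval > 0) total <- total + nsyn / nval
  }
  total
}

# recursively enumerate all orderings of the differing positions
oracle_paths <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  dif <- which(b1 != b2)
  if (length(dif) == 0) return(list())
  recurse <- function(cur, remaining, sd, nd) {
    if (length(remaining) == 0) return(list(c(sd = sd, nd = nd, stopped = 0)))
    out <- list()
    for (pos in remaining) {
      nxt <- cur; nxt[pos] <- b2[pos]
      aa_cur <- oracle_translate(paste(cur, collapse = ""))
      aa_nxt <- oracle_translate(paste(nxt, collapse = ""))
      hit_stop <- aa_nxt == "*"
      step <- recurse(nxt, setdiff(remaining, pos),
                      sd + (aa_nxt == aa_cur),
                      nd + (aa_nxt != aa_cur))
      for (s in step) {
        s["stopped"] <- max(s["stopped"], as.numeric(hit_stop))
        out[[length(out) + 1]] <- s
      }
    }
    out
  }
  recurse(b1, dif, 0, 0)
}

# pathway-averaged difference counts, skipping stop-crossing orderings
# (falling back to all orderings when every path crosses a stop)
oracle_path_counts <- function(c1, c2) {
  paths <- oracle_paths(c1, c2)
  if (length(paths) == 0) return(c(sd = 0, nd = 0))
  m <- do.call(rbind, paths)
  ok <- m[, "stopped"] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(sd = mean(m[ok, "sd"]), nd = mean(m[ok, "nd"]))
}

oracle_ng86 <- function(s1, s2) {
  co1 <- substring(s1, seq(1, nchar(s1), 3), seq(3, nchar(s1), 3))
  co2 <- substring(s2, seq(1, nchar(s2), 3), seq(3, nchar(s2), 3))
  S <- (sum(vapply(co1, oracle_syn_sites, 0)) +
          sum(vapply(co2, oracle_syn_sites, 0))) / 2
  N <- 3 * length(co1) - S
  cnt <- rowSums(vapply(seq_along(co1), function(i)
    oracle_path_counts(co1[i], co2[i]), c(sd = 0, nd = 0)))
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  pS <- if (S > 0) cnt[["sd"]] / S else NA_real_
  pN <- if (N > 0) cnt[["nd"]] / N else NA_real_
  list(S = S, N = N, Sd = cnt[["sd"]], Nd = cnt[["nd"]],
       dS = jc(pS), dN = jc(pN))
}

# full enumeration of the Wilcoxon rank-sum null for small samples
oracle_wilcoxon_p <- function(x, y) {
  n <- length(x); m <- length(y)
  obs <- sum(rank(c(x, y))[seq_len(n)])
  combos <- utils::combn(n + m, n)
  ranks <- rank(c(x, y))
  stats <- apply(combos, 2, function(ix) sum(ranks[ix]))
  mu <- n * (n + m + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# shared tiny fixtures ------------------------------------------------------

tiny_families <- function(classes = c("3FTx", "CRISP")) {
  fam <- default_toxin_families()
  fam[fam$class %in% classes, , drop = FALSE]
}

random_cds_fixture <- function(n_codons, seed = 1) {
  set.seed(seed)
  sense <- setdiff(oracle_sense(), "ATG")
  paste0("ATG", paste(sample(sense, n_codons, TRUE), collapse = ""), "TAA")
}
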