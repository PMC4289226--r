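# Goldman-Yang style codon substitution model: 61 sense codons, a
# transition/transversion ratio kappa, nonsynonymous rate multiplier omega,
# equilibrium codon frequencies (uniform or F3x4).  Used both to simulate
# divergence and, via eigendecomposition, for likelihood computation.

#' Structural description of single-step codon changes
#'
#' Precomputes, for every ordered pair of sense codons differing at exactly
#' one position, whether the change is a transition and whether it is
#' synonymous.  Cached per session.
#' @noRd
codon_change_structure <- function() {
  if (!is.null(.vf_cache$chg)) return(.vf_cache$chg)
  sc <- sense_codons()
  n <- length(sc)
  aa <- codon_aa(sc)
  m1 <- matrix(substr(sc, 1, 1), n, n)
  m2 <- matrix(substr(sc, 2, 2), n, n)
  m3 <- matrix(substr(sc, 3, 3), n, n)
  d1 <- m1 != t(m1); d2 <- m2 != t(m2); d3 <- m3 != t(m3)
  ndiff <- d1 + d2 + d3
  single <- ndiff == 1L
  ts <- matrix(FALSE, n, n)
  ts[d1] <- is_transition(t(m1)[d1], m1[d1])
  ts2 <- is_transition(t(m2)[d2], m2[d2]); ts[d2] <- ts[d2] | ts2
  ts3 <- is_transition(t(m3)[d3], m3[d3]); ts[d3] <- ts[d3] | ts3
  # ts only meaningful where single step
  syn <- outer(aa, aa, "==")
  .vf_cache$chg <- list(single = single, transition = ts & single,
                        synonymous = syn, codons = sc)
  .vf_cache$chg
}

#' F3x4 codon frequencies from observed sequences
#'
#' Position-specific nucleotide frequencies across codon positions, with
#' stop-codon mass redistributed over the sense codons.
#'
#' @param cds_set Character vector of coding sequences (terminal stops are
#'   tolerated and ignored in the model's state space).
#' @return Named numeric vector over the 61 sense codons, summing to 1.
#' @export
codon_freqs_f3x4 <- function(cds_set) {
  sc <- sense_codons()
  pos_counts <- matrix(0, nrow = 3, ncol = 4, dimnames = list(NULL, NUC))
  for (cds in cds_set) {
    cods <- split_codons(cds)
    for (p in 1:3) {
      b <- substr(cods, p, p)
      tb <- table(factor(b, levels = NUC))
      pos_counts[p, ] <- pos_counts[p, ] + as.numeric(tb)
    }
  }
  pos_freq <- pos_counts / rowSums(pos_counts)
  f <- pos_freq[1, substr(sc, 1, 1)] *
    pos_freq[2, substr(sc, 2, 2)] *
    pos_freq[3, substr(sc, 3, 3)]
  f <- f / sum(f)
  names(f) <- sc
  f
}

#' Uniform sense-codon frequencies
#' @export
codon_freqs_uniform <- function() {
  sc <- sense_codons()
  setNames(rep(1 / length(sc), length(sc)), sc)
}

#' GY94 instantaneous rate matrix
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param freqs Equilibrium codon frequencies over the 61 sense codons.
#' @param scale If `TRUE` (default) the matrix is scaled so the expected
#'   number of substitutions per codon per unit time is 1.
#' @return 61 x 61 rate matrix with rows summing to zero.
#' @export
gy94_rate_matrix <- function(kappa, omega, freqs = codon_freqs_uniform(),
                             scale = TRUE) {
  stopifnot(kappa > 0, omega >= 0, length(freqs) == 61L)
  chg <- codon_change_structure()
  n <- 61L
  Q <- matrix(0, n, n, dimnames = list(chg$codons, chg$codons))
  Q[chg$single] <- rep(freqs, each = n)[chg$single]
  Q[chg$transition] <- Q[chg$transition] * kappa
  nonsyn <- chg$single & !chg$synonymous
  Q[nonsyn] <- Q[nonsyn] * omega
  diag(Q) <- -rowSums(Q)
  if (scale) {
    rate <- -sum(freqs * diag(Q))
    if (rate > 0) Q <- Q / rate
  }
  Q
}

#' Eigendecomposition of a reversible rate matrix for fast P(t)
#' @noRd
gy94_eigen <- function(Q, freqs) {
  sq <- sqrt(freqs)
  B <- (sq %o% (1 / sq)) * Q      # symmetric similarity transform
  B <- (B + t(B)) / 2             # symmetrize against rounding
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       right = (1 / sq) * e$vectors,      # D^{-1/2} U
       left = t(e$vectors * sq))          # U^T D^{1/2}
}

#' Transition probability matrix P(t) from a cached eigendecomposition
#' @noRd
gy94_pmat <- function(eig, t) {
  P <- eig$right %*% (exp(eig$values * t) * eig$left)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate codon substitution along one branch
#'
#' Exact stochastic simulation (exponential waiting times) of the GY94
#' process for each codon site independently, with a per-site omega.
#' Realized synonymous and nonsynonymous event counts are recorded so that
#' estimators can be checked against the generating process.
#'
#' @param codons Character vector of sense codons (the starting state).
#' @param t Branch length in expected substitutions per codon site.  With
#'   the default `scale_rate = NULL` each site's rate matrix is normalized
#'   under its own omega (natural for a single-omega sequence); for
#'   site-class mixtures pass a common `scale_rate` so that higher-omega
#'   sites evolve proportionally faster, matching the mixture-model
#'   convention.
#' @param kappa Transition/transversion rate ratio.
#' @param omega Scalar or per-site vector of dN/dS values.
#' @param freqs Equilibrium codon frequencies.
#' @param scale_rate Optional common rate divisor for the unscaled rate
#'   matrices (e.g. the mixture-averaged rate).
#' @return List with `codons` (end state), `n_syn`, `n_nonsyn` (realized
#'   event totals).
#' @export
sim_codon_branch <- function(codons, t, kappa, omega,
                             freqs = codon_freqs_uniform(),
                             scale_rate = NULL) {
  stopifnot(all(codons %in% sense_codons()), t >= 0)
  omega <- rep_len(omega, length(codons))
  if (t == 0) return(list(codons = codons, n_syn = 0L, n_nonsyn = 0L))
  chg <- codon_change_structure()
  sc <- chg$codons
  n_syn <- 0L; n_nonsyn <- 0L
  # per-omega cache of rate rows (total exit rate + jump distribution)
  rate_cache <- new.env(parent = emptyenv())
  row_for <- function(w) {
    key <- format(w, digits = 12)
    got <- rate_cache[[key]]
    if (is.null(got)) {
      if (is.null(scale_rate)) {
        Q <- gy94_rate_matrix(kappa, w, freqs, scale = TRUE)
      } else {
        Q <- gy94_rate_matrix(kappa, w, freqs, scale = FALSE) / scale_rate
      }
      got <- list(Q = Q, exit = -diag(Q))
      rate_cache[[key]] <- got
    }
    got
  }
  out <- codons
  for (i in seq_along(out)) {
    r <- row_for(omega[i])
    state <- match(out[i], sc)
    remaining <- t
    repeat {
      rate <- r$exit[state]
      if (rate <= 0) break
      wait <- rexp(1L, rate)
      if (wait > remaining) break
      remaining <- remaining - wait
      jump_p <- r$Q[state, ]
      jump_p[state] <- 0
      nxt <- sample.int(61L, 1L, prob = jump_p)
      if (chg$synonymous[state, nxt]) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
      state <- nxt
    }
    out[i] <- sc[state]
  }
  list(codons = out, n_syn = n_syn, n_nonsyn = n_nonsyn)
}
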