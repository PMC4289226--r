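# Codon site-model fitting (M0, M1a, M2a, M7, M8) by pruning over the
# 61-sense-codon state space with GY94 rates and F3x4 frequencies, and
# simulation of codon alignments along a tree for power/recovery checks.

#' Discretized beta distribution (equal-probability categories, category means)
#' @noRd
beta_categories <- function(p, q, K = 10L) {
  bounds <- seq(0, 1, length.out = K + 1L)
  # extreme shape parameters explored by the optimizer trip qbeta's
  # accuracy warning; the category means only need the bin boundaries
  qs <- suppressWarnings(qbeta(bounds, p, q))
  mean_total <- p / (p + q)
  means <- numeric(K)
  for (k in seq_len(K)) {
    mass <- pbeta(qs[k + 1L], p + 1, q) - pbeta(qs[k], p + 1, q)
    means[k] <- mean_total * mass * K
  }
  means[means < 1e-8] <- 1e-8
  means
}

#' Pattern-compress a codon alignment
#' @noRd
codon_patterns <- function(seqs) {
  sc <- sense_codons()
  mats <- lapply(seqs, function(s) match(split_codons(s), sc) - 1L)
  if (any(vapply(mats, anyNA, logical(1)))) {
    stop("alignment contains stop or ambiguous codons", call. = FALSE)
  }
  M <- do.call(rbind, mats)   # ntaxa x nsites
  key <- apply(M, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[u])))
  list(tips = M[, u, drop = FALSE], weights = w, n_sites = ncol(M))
}

site_model_pars <- function(model, start_omega) {
  # returns list(par0, lower, upper, unpack(par) -> list(omegas, props,
  # extra params), names)
  switch(model,
    M0 = list(
      par0 = c(log(start_omega), log(2), log(1)),
      lower = c(log(1e-4), log(0.1), log(1e-3)),
      upper = c(log(40), log(40), log(50)),
      unpack = function(par) list(omegas = exp(par[1]), props = 1,
                                  kappa = exp(par[2]), scale = exp(par[3]))
    ),
    M1a = list(
      par0 = c(qlogis(0.7), qlogis(min(start_omega, 0.9)), log(2), log(1)),
      lower = c(-8, -8, log(0.1), log(1e-3)),
      upper = c(8, 8, log(40), log(50)),
      unpack = function(par) {
        p0 <- plogis(par[1]); w0 <- plogis(par[2])
        list(omegas = c(w0, 1), props = c(p0, 1 - p0),
             kappa = exp(par[3]), scale = exp(par[4]))
      }
    ),
    M2a = list(
      par0 = c(qlogis(0.6), qlogis(0.5), qlogis(0.5),
               log(1 + 2 * start_omega - 1), log(2), log(1)),
      lower = c(-8, -8, -8, log(1e-3), log(0.1), log(1e-3)),
      upper = c(8, 8, 8, log(40), log(40), log(50)),
      unpack = function(par) {
        p0 <- plogis(par[1]); p1 <- (1 - p0) * plogis(par[2])
        p2 <- 1 - p0 - p1
        w0 <- plogis(par[3]); w2 <- 1 + exp(par[4])
        list(omegas = c(w0, 1, w2), props = c(p0, p1, p2),
             kappa = exp(par[5]), scale = exp(par[6]))
      }
    ),
    M7 = list(
      par0 = c(log(0.5), log(1), log(2), log(1)),
      lower = c(log(0.005), log(0.005), log(0.1), log(1e-3)),
      upper = c(log(99), log(99), log(40), log(50)),
      unpack = function(par) {
        w <- beta_categories(exp(par[1]), exp(par[2]), 10L)
        list(omegas = w, props = rep(1 / 10, 10),
             kappa = exp(par[3]), scale = exp(par[4]),
             beta_p = exp(par[1]), beta_q = exp(par[2]))
      }
    ),
    M8 = list(
      par0 = c(qlogis(0.85), log(0.5), log(1),
               log(1 + 2 * start_omega - 1), log(2), log(1)),
      lower = c(-8, log(0.005), log(0.005), log(1e-3), log(0.1), log(1e-3)),
      upper = c(8, log(99), log(99), log(40), log(40), log(50)),
      unpack = function(par) {
        p0 <- plogis(par[1])
        w <- beta_categories(exp(par[2]), exp(par[3]), 10L)
        ws <- 1 + exp(par[4])
        list(omegas = c(w, ws), props = c(rep(p0 / 10, 10), 1 - p0),
             kappa = exp(par[5]), scale = exp(par[6]),
             beta_p = exp(par[2]), beta_q = exp(par[3]))
      }
    ),
    stop("unknown model: ", model, call. = FALSE)
  )
}

#' Fit a codon site model
#'
#' Likelihood by pruning over the 61 sense codons with a GY94 rate matrix
#' and F3x4 codon frequencies estimated from the data; site-class mixtures
#' integrated per site; the beta distribution of M7/M8 discretized into
#' `K = 10` equal-probability categories at category means.  Parameters
#' (site-class mixture, kappa, and a global branch-length scale) are
#' optimized by bounded quasi-Newton from three deterministic omega starts
#' (0.1, 0.5, 2.0): the starts are screened by likelihood and the best is
#' optimized to convergence.
#'
#' @param seqs Named character vector of equal-length, gap-free, stop-free
#'   aligned coding sequences (use [codon_align()] output cores).
#' @param tree `ape` `phylo` with the alignment's taxa; defaults to the
#'   neighbor-joining tree.  Branch lengths are rescaled by an optimized
#'   factor.
#' @param model One of `"M0"`, `"M1a"`, `"M2a"`, `"M7"`, `"M8"`.
#' @param maxit Optimizer iteration cap per start.
#' @return A `vf_site_fit` list: `model`, `lnL`, `p` (class proportions),
#'   `w` (class omegas), `kappa`, `scale`, `tree`, `codon_freqs`,
#'   `convergence`, `n_sites`, `n_taxa`.
#' @export
fit_site_model <- function(seqs, tree = NULL, model = c("M0", "M1a", "M2a",
                                                        "M7", "M8"),
                           maxit = 200L) {
  model <- match.arg(model)
  stopifnot(length(unique(nchar(seqs))) == 1L)
  if (is.null(names(seqs)) && length(seqs) > 0L)
    names(seqs) <- paste0("t", seq_along(seqs))
  if (is.null(tree)) tree <- nj_tree(seqs)
  if (length(tree$tip.label) > 2L) tree <- ape::unroot(tree)
  tree <- stats::reorder(tree, "postorder")
  if (!setequal(tree$tip.label, names(seqs))) {
    stop("tree taxa do not match alignment names", call. = FALSE)
  }
  pat <- codon_patterns(seqs[tree$tip.label])
  freqs <- codon_freqs_f3x4(unname(seqs))
  freqs <- pmax(freqs, 1e-8); freqs <- freqs / sum(freqs)
  el <- tree$edge.length
  if (is.null(el)) el <- rep(0.1, nrow(tree$edge))
  el <- pmax(el, 1e-8)
  type <- codon_type_matrix()
  edge <- tree$edge
  storage.mode(edge) <- "integer"
  ntip <- length(tree$tip.label)

  objective <- function(spec) {
    function(par) {
      u <- spec$unpack(par)
      -cpp_codon_mixture_loglik(edge, ntip, el, pat$tips, pat$weights,
                                freqs, type, u$kappa, u$omegas, u$props,
                                u$scale)
    }
  }
  starts <- c(0.1, 0.5, 2.0)
  specs <- lapply(starts, function(s) site_model_pars(model, s))
  # short pilot optimization from every start, full run from the best
  pilots <- lapply(specs, function(spec)
    optim(spec$par0, objective(spec), method = "L-BFGS-B",
          lower = spec$lower, upper = spec$upper,
          control = list(maxit = 15L, factr = 1e12)))
  best_i <- which.min(vapply(pilots, `[[`, numeric(1), "value"))
  spec <- specs[[best_i]]
  fit <- optim(pilots[[best_i]]$par, objective(spec), method = "L-BFGS-B",
               lower = spec$lower, upper = spec$upper,
               control = list(maxit = maxit, factr = 1e9))
  u <- spec$unpack(fit$par)
  out <- list(model = model, lnL = -fit$value, p = u$props, w = u$omegas,
              kappa = u$kappa, scale = u$scale,
              beta_p = u$beta_p, beta_q = u$beta_q,
              tree = tree, branch_lengths = el * u$scale,
              codon_freqs = freqs,
              convergence = fit$convergence, n_sites = pat$n_sites,
              n_taxa = ntip)
  class(out) <- "vf_site_fit"
  out
}

#' @export
print.vf_site_fit <- function(x, ...) {
  cat(sprintf("Codon site model %s: lnL = %.4f (%d taxa, %d codon sites)\n",
              x$model, x$lnL, x$n_taxa, x$n_sites))
  cat("  p:", paste(sprintf("%.3f", x$p), collapse = " "), "\n")
  cat("  w:", paste(sprintf("%.3f", x$w), collapse = " "), "\n")
  cat(sprintf("  kappa = %.3f, branch scale = %.3f\n", x$kappa, x$scale))
  invisible(x)
}

#' Broom-style tidier for site-model fits
#'
#' @param x A `vf_site_fit`.
#' @param ... Unused.
#' @return Tibble with one row per site class: `class`, `proportion`,
#'   `omega`.
#' @export
tidy.vf_site_fit <- function(x, ...) {
  tibble::tibble(class = seq_along(x$p), proportion = x$p, omega = x$w)
}

#' One-row model summary for site-model fits
#'
#' @param x A `vf_site_fit`.
#' @param ... Unused.
#' @return Tibble with `model`, `lnL`, `kappa`, `n_taxa`, `n_sites`,
#'   `convergence`.
#' @export
glance.vf_site_fit <- function(x, ...) {
  tibble::tibble(model = x$model, lnL = x$lnL, kappa = x$kappa,
                 n_taxa = x$n_taxa, n_sites = x$n_sites,
                 convergence = x$convergence)
}

#' Compare two nested site-model fits
#'
#' @param null_fit,alt_fit `vf_site_fit` objects (e.g. M1a and M2a).
#' @param df Degrees of freedom of the comparison.
#' @return [lrt_pvalue()] tibble row.
#' @export
compare_site_models <- function(null_fit, alt_fit, df = 2L) {
  lrt_pvalue(-null_fit$lnL, -alt_fit$lnL, df = df)
}

#' Simulate a codon alignment along a tree
#'
#' Draws the root sequence from the codon frequencies and evolves it along
#' each branch under GY94 with a per-site omega, using exact exponential
#' waiting times.
#'
#' @param tree `ape` `phylo` with branch lengths in expected substitutions
#'   per codon site.
#' @param n_codons Number of codon sites.
#' @param omega Scalar or per-site vector of dN/dS values.
#' @param kappa Transition/transversion ratio.
#' @param freqs Codon frequencies.
#' @return Named character vector of tip coding sequences (no start/stop
#'   handling: these are alignment cores).
#' @export
simulate_codon_alignment <- function(tree, n_codons, omega, kappa = 2,
                                     freqs = codon_freqs_uniform()) {
  tree <- stats::reorder(tree, "cladewise")
  omega <- rep_len(omega, n_codons)
  sc <- sense_codons()
  # common scaling: branch lengths are expected substitutions per codon
  # averaged over sites, so higher-omega sites evolve proportionally faster
  uo <- unique(omega)
  rates <- vapply(uo, function(w)
    -sum(freqs * diag(gy94_rate_matrix(kappa, w, freqs, scale = FALSE))),
    numeric(1))
  rbar <- mean(rates[match(omega, uo)])
  nnode <- max(tree$edge)
  seqs <- vector("list", nnode)
  root <- length(tree$tip.label) + 1L
  seqs[[root]] <- sample(sc, n_codons, replace = TRUE, prob = freqs)
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    b <- sim_codon_branch(seqs[[parent]], tree$edge.length[e], kappa,
                          omega, freqs, scale_rate = rbar)
    seqs[[child]] <- b$codons
  }
  tips <- vapply(seq_along(tree$tip.label),
                 function(i) paste(seqs[[i]], collapse = ""), character(1))
  setNames(tips, tree$tip.label)
}
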