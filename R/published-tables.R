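# Accessors for the published venom-gland characterization tables of the two
# study species (Brown Treesnake, Boiga irregularis, and the Desert Night
# Snake, Hypsiglena sp.), shipped as plain TSV.  These printed tables act as
# inputs for consistency checks: toxin-class transcription totals,
# proteomic cross-reference counts, and likelihood-ratio-test arithmetic.

vf_extdata <- function(file) {
  path <- system.file("extdata", file, package = "venomforge")
  if (path == "") stop("missing packaged table: ", file, call. = FALSE)
  path
}

#' Published toxin-cluster expression table for one study species
#'
#' Columns mirror the study's expression report: rank, cluster name, cluster
#' size, CDS length, median coverage at the 10-million-mapped-read scale,
#' percent of toxin reads, percent of total reads.
#'
#' @param species `"boiga"` (Brown Treesnake) or `"hypsiglena"` (Desert
#'   Night Snake).
#' @return Tibble with one row per toxin cluster.
#' @export
published_expression <- function(species = c("boiga", "hypsiglena")) {
  species <- match.arg(species)
  readr::read_tsv(vf_extdata(paste0(species, "_toxin_expression.tsv")),
                  show_col_types = FALSE)
}

#' Published venom protein identifications for one study species
#'
#' One row per identified transcript: PLGS-style protein score, number of
#' matched peptides, percent sequence coverage, and the shared-unique-peptide
#' group (NA for identifications without a group designation).
#'
#' @inheritParams published_expression
#' @return Tibble with one row per identification.
#' @export
published_identifications <- function(species = c("boiga", "hypsiglena")) {
  species <- match.arg(species)
  readr::read_tsv(vf_extdata(paste0(species, "_protein_ids.tsv")),
                  show_col_types = FALSE, na = "NA")
}

#' Published codon site-model fits (negative log-likelihood pairs)
#'
#' Per toxin alignment: the M0 omega, the null and alternative model
#' negative log-likelihoods, and the printed p-value of the likelihood-ratio
#' test (df = 2).
#'
#' @param comparison `"m1m2"` (nearly-neutral vs positive selection) or
#'   `"m7m8"` (beta vs beta plus selection).
#' @return Tibble with one row per toxin alignment.
#' @export
published_site_model_fits <- function(comparison = c("m1m2", "m7m8")) {
  comparison <- match.arg(comparison)
  readr::read_tsv(vf_extdata(paste0("site_model_fits_", comparison, ".tsv")),
                  show_col_types = FALSE)
}
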