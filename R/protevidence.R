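# Proteomic cross-validation: mature-protein + reversed-decoy search
# databases, in-silico tryptic digestion, peptide-to-protein mapping with
# coverage, the three acceptance filters (>= 3 matched peptides, >= 20%
# coverage, score above the best decoy), shared-unique-peptide grouping,
# and cluster-level cross-referencing.

#' Build a target+decoy protein search database
#'
#' Transcripts are translated, the annotated signal peptide is removed, and
#' one reversed-sequence decoy is appended per target (id suffixed
#' `"|decoy"`).
#'
#' @param transcripts Tibble with `id`, `cds`, and optional `signal_start`,
#'   `signal_end` (1-based inclusive codon span of the signal peptide).
#' @param internal_standard Optional named character scalar added as an
#'   extra (undecoyed) entry.
#' @return Tibble with `protein_id`, `sequence`, `is_decoy`.
#' @export
build_search_db <- function(transcripts, internal_standard = NULL) {
  prots <- character(nrow(transcripts))
  has_sig <- all(c("signal_start", "signal_end") %in% names(transcripts))
  for (i in seq_len(nrow(transcripts))) {
    p <- translate_cds(transcripts$cds[i])
    if (has_sig && !is.na(transcripts$signal_end[i])) {
      se <- transcripts$signal_end[i]
      if (is.na(transcripts$signal_start[i]) || transcripts$signal_start[i] < 1L ||
          se >= nchar(p)) {
        stop("signal-peptide span outside the CDS for ", transcripts$id[i],
             call. = FALSE)
      }
      p <- substr(p, se + 1L, nchar(p))
    }
    prots[i] <- p
  }
  targets <- tibble::tibble(protein_id = transcripts$id, sequence = prots,
                            is_decoy = FALSE)
  decoys <- tibble::tibble(
    protein_id = paste0(transcripts$id, "|decoy"),
    sequence = vapply(prots, function(s)
      paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1),
      USE.NAMES = FALSE),
    is_decoy = TRUE
  )
  out <- dplyr::bind_rows(targets, decoys)
  if (!is.null(internal_standard)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      protein_id = names(internal_standard), sequence = unname(internal_standard),
      is_decoy = FALSE))
  }
  out
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P; emits all
#' fragments with at most `max_missed_cleavages` internal sites and length
#' at least `min_length`.
#'
#' @param protein Amino-acid sequence.
#' @param max_missed_cleavages Maximum internal missed cleavage sites.
#' @param min_length Minimum peptide length (applied after enumeration).
#' @return Tibble with `peptide`, `start`, `end` (1-based residue spans),
#'   `missed`.
#' @export
tryptic_digest <- function(protein, max_missed_cleavages = 1L,
                           min_length = 6L) {
  stopifnot(nchar(protein) > 0L)
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n)
  starts <- head(bounds, -1L) + 1L
  ends <- bounds[-1L]
  rows <- list()
  nfrag <- length(starts)
  for (i in seq_len(nfrag)) {
    for (m in 0:max_missed_cleavages) {
      j <- i + m
      if (j > nfrag) break
      s <- starts[i]; e <- ends[j]
      if (e - s + 1L < min_length) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        peptide = substr(protein, s, e), start = s, end = e, missed = m)
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(peptide = character(), start = integer(),
                          end = integer(), missed = integer()))
  }
  dplyr::bind_rows(rows)
}

collapse_il <- function(x) chartr("I", "L", x)

strip_modifications <- function(x) gsub("\\[[^]]*\\]|\\([^)]*\\)", "", x)

#' Map report peptides onto a search database
#'
#' Each report peptide is mapped to every database entry containing it
#' (isoleucine/leucine collapsed when `leucine_isoleucine_equivalent`);
#' coverage is the union of mapped spans over the protein length.  A
#' peptide is distinguishing when the set of entries it maps to is a proper
#' subset of the entries its protein shares peptides with (or a singleton).
#'
#' @param report Tibble with `protein_id`, `protein_score`, `peptide` (one
#'   row per protein-peptide), optional `peptide_score`.
#' @param db Search database from [build_search_db()].
#' @param leucine_isoleucine_equivalent Collapse I and L before lookup.
#' @return List with `identifications` (tibble: `protein_id`, `score`,
#'   `peptide_matches`, `pct_coverage`, `is_decoy`, list-column `peptides`),
#'   `peptide_map` (tibble: `peptide`, list-column `mapped_ids`), and
#'   `orphans` (report peptides mapping to nothing).
#' @export
map_peptides <- function(report, db, leucine_isoleucine_equivalent = TRUE) {
  il <- function(x) if (leucine_isoleucine_equivalent) collapse_il(x) else x
  db_seq <- il(db$sequence)
  peps <- unique(strip_modifications(report$peptide))
  mapped <- lapply(peps, function(p) {
    hit <- which(stringr::str_detect(db_seq, stringr::fixed(il(p))))
    db$protein_id[hit]
  })
  names(mapped) <- peps
  orphans <- peps[lengths(mapped) == 0L]

  ids <- unique(report$protein_id)
  rows <- vector("list", length(ids))
  for (u in seq_along(ids)) {
    pid <- ids[u]
    sub <- report[report$protein_id == pid, ]
    d <- match(pid, db$protein_id)
    if (is.na(d)) next
    prot <- il(db$sequence[d])
    own <- unique(strip_modifications(sub$peptide))
    own <- own[vapply(own, function(p)
      stringr::str_detect(prot, stringr::fixed(il(p))), logical(1))]
    # coverage from the union of all mapped spans
    covered <- logical(nchar(prot))
    for (p in own) {
      loc <- stringr::str_locate_all(prot, stringr::fixed(il(p)))[[1]]
      for (r in seq_len(nrow(loc))) covered[loc[r, 1]:loc[r, 2]] <- TRUE
    }
    rows[[u]] <- tibble::tibble(
      protein_id = pid,
      score = max(sub$protein_score),
      peptide_matches = length(own),
      pct_coverage = mean(covered) * 100,
      is_decoy = db$is_decoy[d],
      peptides = list(own)
    )
  }
  idents <- dplyr::bind_rows(rows)
  list(identifications = idents,
       peptide_map = tibble::tibble(peptide = peps, mapped_ids = mapped),
       orphans = orphans)
}

#' Apply the three acceptance filters
#'
#' Keeps identifications with at least 3 matched peptides, at least 20%
#' sequence coverage, and a protein score strictly above the highest-scoring
#' decoy (the maximum over an empty decoy set is -Inf, so with no decoys
#' only the first two filters apply).
#'
#' @param idents Identification tibble from [map_peptides()].
#' @param decoy_scores Numeric vector of decoy identification scores; by
#'   default taken from the decoy rows of `idents`.
#' @param min_peptides,min_coverage Acceptance thresholds.
#' @return The accepted subset (decoy rows are never accepted).
#' @export
accept_identifications <- function(idents,
                                   decoy_scores = idents$score[idents$is_decoy],
                                   min_peptides = 3L, min_coverage = 20) {
  best_decoy <- if (length(decoy_scores) == 0L) -Inf else max(decoy_scores)
  idents[!idents$is_decoy &
           idents$peptide_matches >= min_peptides &
           idents$pct_coverage >= min_coverage &
           idents$score > best_decoy, , drop = FALSE]
}

#' Group accepted identifications by shared unique peptides
#'
#' Candidate groups are the distinct sets of accepted entries sharing a
#' peptide; groups are assigned greedily from the most specific set upward,
#' and an entry whose every peptide also maps to already-grouped entries
#' outside its own candidate set ends up without a group (reported as NA),
#' mirroring identifications that lack a distinguishing peptide.
#'
#' @param accepted Accepted identification tibble (with `peptides`
#'   list-column).
#' @return The input with an integer `group` column (NA = no group),
#'   numbered consecutively from 1 in input order of first members.
#' @export
group_identifications <- function(accepted) {
  n <- nrow(accepted)
  accepted$group <- rep(NA_integer_, n)
  if (n == 0L) return(accepted)
  # peptide -> set of accepted entries containing it
  pep_sets <- list()
  for (i in seq_len(n)) {
    for (p in accepted$peptides[[i]]) {
      pep_sets[[p]] <- c(pep_sets[[p]], i)
    }
  }
  if (length(pep_sets) == 0L) return(accepted)
  sets <- unique(lapply(pep_sets, sort))
  ord <- order(vapply(sets, length, integer(1)),
               vapply(sets, min, integer(1)))
  grouped <- logical(n)
  groups <- list()
  for (s in sets[ord]) {
    if (any(grouped[s])) next
    groups[[length(groups) + 1L]] <- s
    grouped[s] <- TRUE
  }
  # number groups consecutively by first member's table position
  first <- vapply(groups, min, integer(1))
  for (k in seq_along(groups)) {
    g <- groups[[order(first)[k]]]
    accepted$group[g] <- k
  }
  accepted
}

#' Cross-reference accepted identifications with toxin clusters
#'
#' A cluster is proteomically confirmed when at least one accepted
#' identification belongs to it (member letters stripped).  Identifications
#' whose names do not follow the class-number-letter grammar are excluded
#' with a warning; names absent from `toxin_clusters` (e.g. nontoxins) are
#' ignored.
#'
#' @param accepted Accepted identification tibble (`protein_id` column, or
#'   a `transcript_name` column for published tables).
#' @param toxin_clusters Character vector of toxin cluster names.
#' @return List with `confirmed` (character vector), `n_confirmed`,
#'   `n_total`, `fraction`.
#' @export
cross_reference <- function(accepted, toxin_clusters) {
  nm <- if ("protein_id" %in% names(accepted)) accepted$protein_id else
    accepted$transcript_name
  ok <- grepl("^[A-Za-z0-9]+([-_][A-Za-z0-9]+)*[a-z]?$", nm)
  if (any(!ok)) {
    warning("excluding ", sum(!ok), " identification(s) not matching the ",
            "naming grammar")
    nm <- nm[ok]
  }
  clusters <- sub("(?<=[0-9])[a-z]$", "", nm, perl = TRUE)
  confirmed <- intersect(toxin_clusters, clusters)
  list(confirmed = confirmed,
       n_confirmed = length(confirmed),
       n_total = length(toxin_clusters),
       fraction = if (length(toxin_clusters) > 0L)
         length(confirmed) / length(toxin_clusters) else NA_real_)
}
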