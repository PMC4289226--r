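# Transcript construction from merged reads: greedy exact-overlap seed
# extension, reference-guided majority-vote consensus with coverage rules,
# duplicate elimination, <1% divergence clustering of toxin coding
# sequences, chimera screening, and keyword toxin annotation with the
# class-number-letter naming scheme.

#' Greedy seed extension from merged reads
#'
#' Iteratively extends both ends of a seed sequence.  A read is eligible to
#' extend iff its overlap with the contig end is at least `min_overlap`
#' nucleotides, exactly matching, and every base of the read has phred
#' at least `min_phred`; at each step the eligible read contributing the
#' most new bases is appended.
#'
#' @param seed Seed sequence (length >= `min_overlap`).
#' @param reads Tibble of merged reads with `sequence` and list-column
#'   `quality` (integer phred), as from [merge_set()].
#' @param min_overlap Minimum exact overlap (default 100 nt).
#' @param min_phred Minimum phred at every base of an extending read.
#' @param max_length Safety cap on contig length.
#' @return The extended contig (character scalar); always contains the seed.
#' @export
extend_seed <- function(seed, reads, min_overlap = 100L, min_phred = 30L,
                        max_length = 30000L) {
  if (nchar(seed) < min_overlap) {
    stop("seed shorter than min_overlap (", min_overlap, ")", call. = FALSE)
  }
  ok <- vapply(reads$quality, function(q) all(q >= min_phred), logical(1))
  pool <- reads$sequence[ok]
  pool <- pool[!grepl("[^ACGT]", pool)]
  if (length(pool) == 0L) return(seed)
  res <- cpp_extend_seed(seed, pool, as.integer(min_overlap),
                         as.integer(max_length))
  res$contig
}

#' Reference-guided consensus assembly
#'
#' Reads are placed on the references by k-mer-seeded ungapped alignment and
#' assigned wherever identity is at least `min_identity`; a per-reference
#' majority-vote consensus is called.  A consensus is kept only when depth
#' is at least `min_coverage` at every CDS position; flanking (UTR) regions
#' with depth below `min_coverage` are trimmed.
#'
#' @param reads Tibble of merged reads (`sequence` column).
#' @param references Tibble with `id`, `sequence`, `cds_start`, `cds_end`
#'   (1-based inclusive CDS coordinates within `sequence`).
#' @param min_identity Minimum alignment identity for read assignment.
#' @param min_coverage Minimum depth over the CDS (and for retaining UTR).
#' @return Tibble of retained consensus transcripts: `id`, `sequence`,
#'   `cds_start`, `cds_end` (coordinates within the trimmed consensus),
#'   `n_reads`, `min_cds_depth`.
#' @export
reference_consensus <- function(reads, references, min_identity = 0.85,
                                min_coverage = 5L) {
  if (!all(c("cds_start", "cds_end") %in% names(references))) {
    stop("references must carry cds_start/cds_end", call. = FALSE)
  }
  if (nrow(references) == 0L) return(tibble::tibble(
    id = character(), sequence = character(), cds_start = integer(),
    cds_end = integer(), n_reads = integer(), min_cds_depth = numeric()))
  mp <- cpp_map_reads(reads$sequence, references$sequence, 15L,
                      min_identity, 30L)
  out <- vector("list", nrow(references))
  # per reference: base counts A/C/G/T x positions
  counts <- lapply(nchar(references$sequence),
                   function(L) matrix(0L, nrow = 4L, ncol = L))
  nreads <- integer(nrow(references))
  for (i in seq_along(mp$hits)) {
    h <- mp$hits[[i]]
    if (is.null(h)) next
    seqs <- reads$sequence[i]
    if (mp$strand[i] == -1L) seqs <- unname(reverse_complement(seqs))
    b <- utf8ToInt(seqs)
    bidx <- integer(length(b))
    bidx[b == utf8ToInt("A")] <- 1L; bidx[b == utf8ToInt("C")] <- 2L
    bidx[b == utf8ToInt("G")] <- 3L; bidx[b == utf8ToInt("T")] <- 4L
    for (r in seq_len(nrow(h))) {
      ref <- h[r, 1L]; off <- h[r, 2L]
      L <- ncol(counts[[ref]])
      rpos <- seq_along(bidx) + off          # 1-based ref positions
      keep <- rpos >= 1L & rpos <= L & bidx > 0L
      idx <- cbind(bidx[keep], rpos[keep])
      counts[[ref]][idx] <- counts[[ref]][idx] + 1L
      nreads[ref] <- nreads[ref] + 1L
    }
  }
  for (j in seq_len(nrow(references))) {
    cm <- counts[[j]]
    depth <- colSums(cm)
    cs <- references$cds_start[j]; ce <- references$cds_end[j]
    if (any(depth[cs:ce] < min_coverage)) next
    cons <- NUC[max.col(t(cm), ties.method = "first")]
    # trim UTR flanks below min_coverage (keep contiguous covered flank)
    left <- cs
    while (left > 1L && depth[left - 1L] >= min_coverage) left <- left - 1L
    right <- ce
    while (right < length(depth) && depth[right + 1L] >= min_coverage) right <- right + 1L
    out[[j]] <- tibble::tibble(
      id = references$id[j],
      sequence = paste(cons[left:right], collapse = ""),
      cds_start = cs - left + 1L,
      cds_end = ce - left + 1L,
      n_reads = nreads[j],
      min_cds_depth = min(depth[cs:ce])
    )
  }
  dplyr::bind_rows(out)
}

#' Collapse duplicate and contained coding sequences
#'
#' Exact-duplicate CDSs and CDSs wholly contained in a longer sequence's
#' identical region are collapsed, keeping the longest sequence.  Output
#' order is stable by id.
#'
#' @param transcripts Tibble with `id` and `cds` columns.
#' @return The surviving subset, ordered by `id`.
#' @export
deduplicate <- function(transcripts) {
  if (nrow(transcripts) == 0L) return(transcripts)
  tx <- transcripts[order(-nchar(transcripts$cds), transcripts$id), ]
  keep <- logical(nrow(tx))
  kept_seqs <- character(0)
  for (i in seq_len(nrow(tx))) {
    contained <- any(vapply(kept_seqs, function(s)
      grepl(tx$cds[i], s, fixed = TRUE), logical(1)))
    if (!contained) {
      keep[i] <- TRUE
      kept_seqs <- c(kept_seqs, tx$cds[i])
    }
  }
  out <- tx[keep, , drop = FALSE]
  out[order(out$id), , drop = FALSE]
}

#' Pairwise CDS divergence (mismatches over aligned non-gap columns)
#' @noRd
pairwise_divergence <- function(s1, s2) {
  if (s1 == s2) return(0)
  if (nchar(s1) == nchar(s2)) {
    a <- utf8ToInt(s1); b <- utf8ToInt(s2)
    return(sum(a != b) / length(a))
  }
  al <- Biostrings::pairwiseAlignment(s1, s2, type = "global",
                                      gapOpening = 10, gapExtension = 0.5)
  p1 <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
  p2 <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
  nongap <- p1 != "-" & p2 != "-"
  sum(p1[nongap] != p2[nongap]) / sum(nongap)
}

#' Cluster toxin coding sequences at <1% nucleotide divergence
#'
#' Single-linkage clustering: two CDSs link when their pairwise divergence
#' (mismatches over aligned non-gap columns of a global alignment) is
#' strictly below `threshold`.  Clusters are numbered by descending total
#' abundance (input order when abundance is absent) and members lettered
#' a, b, c, ... by descending abundance.
#'
#' @param cds_set Tibble with `id` and `cds`; optional `abundance` column.
#' @param threshold Divergence threshold (strict `<`).
#' @return Tibble with `id`, `cluster_id` (integer), `member` (letter),
#'   `representative` (logical; the most abundant member).
#' @export
cluster_toxins <- function(cds_set, threshold = 0.01) {
  n <- nrow(cds_set)
  if (n == 0L) {
    return(tibble::tibble(id = character(), cluster_id = integer(),
                          member = character(), representative = logical()))
  }
  abund <- if ("abundance" %in% names(cds_set)) cds_set$abundance else
    rev(seq_len(n))   # input order stands in for abundance
  parent <- seq_len(n)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ri <- findp(i); rj <- findp(j)
        if (ri == rj) next
        if (pairwise_divergence(cds_set$cds[i], cds_set$cds[j]) < threshold) {
          parent[rj] <- ri
        }
      }
    }
  }
  root <- vapply(seq_len(n), findp, integer(1))
  groups <- split(seq_len(n), root)
  tot <- vapply(groups, function(ix) sum(abund[ix]), numeric(1))
  ord <- order(-tot)
  rows <- list()
  for (k in seq_along(ord)) {
    ix <- groups[[ord[k]]]
    mord <- ix[order(-abund[ix])]
    rows[[k]] <- tibble::tibble(
      id = cds_set$id[mord], cluster_id = k,
      member = letters[seq_along(mord)],
      representative = seq_along(mord) == 1L
    )
  }
  dplyr::bind_rows(rows)
}

#' Screen candidate transcripts for chimeric origin
#'
#' Two tests, flagging when either fires and a parent partition exists:
#' a coverage-evenness test (reads remapped at high identity; the statistic
#' `U` is the minimum sliding-window mean depth over the window length
#' divided by the median depth, flagged when `U < 0.1`) and a mosaic test
#' (a single breakpoint splitting the candidate into two segments that each
#' match distinct database parents at >= 95% identity).
#'
#' @param candidates Tibble with `id`, `sequence`.
#' @param reads Tibble of merged reads (`sequence`).
#' @param toxin_db Tibble with `id`, `sequence`: the database searched for
#'   parents (the candidate itself is excluded automatically).
#' @param remap_identity Identity for the coverage remapping.
#' @param window Sliding window (nt) for the evenness statistic.
#' @param u_cutoff Evenness threshold.
#' @return Tibble with `id`, `is_chimera`, `u_stat`, `breakpoint`,
#'   list-column `parents`.
#' @export
detect_chimeras <- function(candidates, reads, toxin_db,
                            remap_identity = 0.98, window = 100L,
                            u_cutoff = 0.1) {
  out <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates$sequence[i]
    cid <- candidates$id[i]
    L <- nchar(cand)
    win <- if (L < window) max(10L, floor(L / 2)) else window
    # (a) coverage evenness
    u_stat <- NA_real_
    cov_flag <- FALSE
    if (L >= window && nrow(reads) > 0L) {
      mp <- cpp_map_reads(reads$sequence, cand, 15L, remap_identity, 30L)
      hit <- which(!vapply(mp$hits, is.null, logical(1)))
      if (length(hit) > 0L) {
        starts <- vapply(hit, function(r) mp$hits[[r]][1L, 2L] + 1L, numeric(1))
        ends <- starts + nchar(reads$sequence[hit]) - 1L
        depth <- cpp_accumulate_depth(L, as.integer(starts), as.integer(ends))
        cmean <- (cumsum(c(0, depth))[(win + 1L):(L + 1L)] -
                    cumsum(c(0, depth))[1L:(L - win + 1L)]) / win
        md <- median(depth)
        u_stat <- if (md > 0) min(cmean) / md else NA_real_
        cov_flag <- !is.na(u_stat) && u_stat < u_cutoff
      }
    }
    # (b) mosaic test against database parents (candidate excluded)
    db <- toxin_db[toxin_db$id != cid & toxin_db$sequence != cand, ]
    mosaic <- find_mosaic_parents(cand, db, seg_identity = 0.95)
    # a parent partition must exist (near-identical cluster siblings are
    # screened out inside the mosaic search by the whole-length-relative
    # guard); the evenness statistic is reported as supporting evidence
    flagged <- mosaic$found || (cov_flag && mosaic$found)
    out[[i]] <- tibble::tibble(
      id = cid, is_chimera = flagged, u_stat = u_stat,
      breakpoint = if (mosaic$found) mosaic$breakpoint else NA_integer_,
      parents = list(if (mosaic$found) mosaic$parents else character(0))
    )
  }
  dplyr::bind_rows(out)
}

#' Single-breakpoint mosaic search
#' @noRd
find_mosaic_parents <- function(cand, db, seg_identity = 0.95,
                                step = 60L) {
  L <- nchar(cand)
  if (nrow(db) == 0L || L < 2L * step) {
    return(list(found = FALSE))
  }
  seg_id <- function(seg, min_span_frac = 0.9) {
    # identity of seg against every db entry (ungapped, best placement)
    ids <- rep(-1, nrow(db))
    if (nchar(seg) < 20L) return(ids)
    span <- max(20L, floor(min_span_frac * nchar(seg)))
    for (d in seq_len(nrow(db))) {
      m <- cpp_map_reads(seg, db$sequence[d], 15L, 0, span)
      if (!is.null(m$hits[[1L]])) ids[d] <- m$identity[1L]
    }
    ids
  }
  # whole-length relatives (e.g. cluster siblings) rule out a chimera call
  whole <- seg_id(cand, min_span_frac = 0.95)
  if (any(whole >= seg_identity)) return(list(found = FALSE))
  bps <- seq(step, L - step, by = step)
  best <- list(found = FALSE, score = -Inf)
  for (bp in bps) {
    idL <- seg_id(substr(cand, 1L, bp))
    idR <- seg_id(substr(cand, bp + 1L, L))
    okL <- which(idL >= seg_identity)
    okR <- which(idR >= seg_identity)
    for (a in okL) {
      for (b in okR) {
        if (db$id[a] == db$id[b]) next
        sc <- idL[a] + idR[b]
        if (sc > best$score) {
          best <- list(found = TRUE, score = sc, breakpoint = bp,
                       parents = c(db$id[a], db$id[b]))
        }
      }
    }
  }
  best
}

default_toxin_keywords <- function() {
  c("toxin", "metalloproteinase", "three-finger", "lectin", "secretory",
    "natriuretic", "ficolin", "acetylcholinesterase", "protease inhibitor",
    "growth factor", "waprin", "phospholipase", "coagulation",
    "venom factor", "hyaluronidase", "phosphodiesterase")
}

#' Annotate transcripts as toxins and assign cluster-aware names
#'
#' Each translated CDS is aligned locally (BLOSUM62) against the reference
#' toxin proteins; the best hit assigns the class when its score reaches
#' `score_threshold` and its description matches a toxin keyword; other
#' transcripts are labeled `"nontoxin"`.  When clustering information is
#' supplied, toxins are named `CLASS-number` with a lower-case member letter
#' for clusters of size > 1 (e.g. `3FTx-9a`).
#'
#' @param transcripts Tibble with `id` and `cds`; optional `abundance`.
#' @param reference Tibble of reference proteins (`class`, `protein`,
#'   `description`), default the packaged synthetic reference.
#' @param keywords Character vector of toxin keywords.
#' @param score_threshold Minimum local alignment score.
#' @param cluster Logical: cluster toxins and emit names.
#' @param threshold Clustering divergence threshold.
#' @return The input tibble with added `class_label`, and (when `cluster`)
#'   `cluster_id`, `cluster_name`, `member`, `toxin_name`.
#' @export
annotate_and_name <- function(transcripts, reference = toxin_reference(),
                              keywords = default_toxin_keywords(),
                              score_threshold = 100, cluster = TRUE,
                              threshold = 0.01) {
  tx <- transcripts
  prots <- vapply(tx$cds, translate_cds, character(1), USE.NAMES = FALSE)
  refset <- Biostrings::AAStringSet(reference$protein)
  kw_ok <- vapply(reference$description, function(d)
    any(stringr::str_detect(tolower(d), stringr::fixed(tolower(keywords)))),
    logical(1))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  cls <- character(nrow(tx))
  for (i in seq_len(nrow(tx))) {
    sc <- Biostrings::pairwiseAlignment(
      refset, Biostrings::AAString(prots[i]), type = "local",
      substitutionMatrix = B62, gapOpening = 10, gapExtension = 0.5,
      scoreOnly = TRUE)
    best <- which.max(sc)
    cls[i] <- if (sc[best] >= score_threshold && kw_ok[best])
      reference$class[best] else "nontoxin"
  }
  tx$class_label <- cls
  if (!cluster) return(tx)

  tx$cluster_id <- NA_integer_
  tx$cluster_name <- NA_character_
  tx$member <- NA_character_
  tx$toxin_name <- NA_character_
  is_tox <- tx$class_label != "nontoxin"
  for (cl in unique(tx$class_label[is_tox])) {
    sel <- which(tx$class_label == cl)
    sub <- tx[sel, c("id", "cds")]
    if ("abundance" %in% names(tx)) sub$abundance <- tx$abundance[sel]
    cl_tab <- cluster_toxins(sub, threshold = threshold)
    m <- match(tx$id[sel], cl_tab$id)
    tx$cluster_id[sel] <- cl_tab$cluster_id[m]
    tx$member[sel] <- cl_tab$member[m]
    tx$cluster_name[sel] <- sprintf("%s-%d", cl, cl_tab$cluster_id[m])
    sizes <- table(cl_tab$cluster_id)
    single <- sizes[as.character(cl_tab$cluster_id[m])] == 1L
    tx$toxin_name[sel] <- ifelse(
      single, tx$cluster_name[sel],
      paste0(tx$cluster_name[sel], tx$member[sel]))
  }
  tx
}
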