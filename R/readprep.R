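# Merging of 3'-overlapping read pairs into high-quality consensus
# fragments.  The overlap maximizing matches-minus-mismatches is chosen;
# agreement sums the two phred scores (capped at 93), disagreement keeps the
# higher-quality base with quality |q1 - q2|; adapter read-through beyond the
# insert end is discarded.

#' Merge one read pair on its 3' overlap
#'
#' @param read1,read2 Read sequences (A/C/G/T/N); `read2` is
#'   reverse-complemented internally before overlap scanning.
#' @param qual1,qual2 Integer phred vectors matching the reads.
#' @param min_overlap Minimum acceptable overlap in nucleotides.
#' @param max_mismatch_fraction Maximum fraction of mismatching columns in
#'   the chosen overlap.
#' @param id Identifier carried through to the result.
#' @return A list with `merged` (logical); when merged also `sequence`,
#'   `quality`, `overlap_length`, `insert_length`, `mismatches`, `id`.
#' @export
merge_read_pair <- function(read1, read2, qual1, qual2,
                            min_overlap = 25L, max_mismatch_fraction = 0.05,
                            id = NA_character_) {
  if (nchar(read1) == 0L || nchar(read2) == 0L) return(list(merged = FALSE, id = id))
  stopifnot(nchar(read1) == length(qual1), nchar(read2) == length(qual2))
  r2rc <- unname(reverse_complement(read2))
  res <- cpp_merge_pair(read1, r2rc, as.integer(qual1), rev(as.integer(qual2)),
                        as.integer(min_overlap), max_mismatch_fraction)
  if (!isTRUE(res$merged)) return(list(merged = FALSE, id = id))
  list(merged = TRUE, id = id, sequence = res$sequence,
       quality = as.integer(res$quality), overlap_length = res$overlap,
       insert_length = res$insert_length, mismatches = res$mismatches)
}

#' Merge a set of read pairs and compute merge statistics
#'
#' @param pairs Tibble with columns `id`, `read1`, `read2` and list-columns
#'   `qual1`, `qual2` (as produced by [simulate_reads()] or
#'   [read_fastq_pairs()]).
#' @param min_overlap,max_mismatch_fraction Merge thresholds; see
#'   [merge_read_pair()].
#' @return List with `merged` (tibble: `id`, `sequence`, `quality`,
#'   `overlap_length`), `unmerged` (the untouched input rows), and `stats`
#'   (tibble: `n_pairs`, `n_merged`, `fraction_merged`, `mean_length`,
#'   `mean_phred_merged`, `mean_phred_unmerged`).
#' @export
merge_set <- function(pairs, min_overlap = 25L, max_mismatch_fraction = 0.05) {
  n <- nrow(pairs)
  if (n == 0L) {
    return(list(
      merged = tibble::tibble(id = character(), sequence = character(),
                              quality = list(), overlap_length = integer()),
      unmerged = pairs,
      stats = tibble::tibble(n_pairs = 0L, n_merged = 0L, fraction_merged = 0,
                             mean_length = 0, mean_phred_merged = 0,
                             mean_phred_unmerged = 0)
    ))
  }
  # vectorized reverse complement once, then the C++ overlap scan per pair
  r2rc_all <- unname(reverse_complement(pairs$read2))
  res <- vector("list", n)
  for (i in seq_len(n)) {
    if (nchar(pairs$read1[i]) == 0L || nchar(pairs$read2[i]) == 0L) {
      res[[i]] <- list(merged = FALSE, id = pairs$id[i])
      next
    }
    r <- cpp_merge_pair(pairs$read1[i], r2rc_all[i],
                        as.integer(pairs$qual1[[i]]),
                        rev(as.integer(pairs$qual2[[i]])),
                        as.integer(min_overlap), max_mismatch_fraction)
    res[[i]] <- if (isTRUE(r$merged)) {
      list(merged = TRUE, id = pairs$id[i], sequence = r$sequence,
           quality = as.integer(r$quality),
           overlap_length = as.integer(r$overlap),
           insert_length = r$insert_length, mismatches = r$mismatches)
    } else list(merged = FALSE, id = pairs$id[i])
  }
  ok <- vapply(res, function(x) isTRUE(x$merged), logical(1))
  merged <- tibble::tibble(
    id = vapply(res[ok], `[[`, character(1), "id"),
    sequence = vapply(res[ok], `[[`, character(1), "sequence"),
    quality = lapply(res[ok], `[[`, "quality"),
    overlap_length = vapply(res[ok], `[[`, integer(1), "overlap_length")
  )
  unmerged <- pairs[!ok, , drop = FALSE]
  mean_or0 <- function(x) if (length(x) == 0L) 0 else mean(x)
  stats <- tibble::tibble(
    n_pairs = n, n_merged = sum(ok),
    fraction_merged = sum(ok) / n,
    mean_length = mean_or0(nchar(merged$sequence)),
    mean_phred_merged = mean_or0(unlist(merged$quality)),
    mean_phred_unmerged = mean_or0(unlist(c(unmerged$qual1, unmerged$qual2)))
  )
  list(merged = merged, unmerged = unmerged, stats = stats)
}

#' Read paired FASTQ files into the pair tibble layout
#' @param r1_path,r2_path FASTQ files for mate 1 and mate 2.
#' @return Tibble with `id`, `read1`, `read2`, `qual1`, `qual2`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  a <- read_fastq(r1_path)
  b <- read_fastq(r2_path)
  if (nrow(a) != nrow(b)) stop("mate files differ in read count", call. = FALSE)
  tibble::tibble(id = sub("/[12]$", "", a$id), read1 = a$sequence,
                 read2 = b$sequence, qual1 = a$quality, qual2 = b$quality)
}

#' Write merged and unmerged outputs plus JSON stats
#' @param result Output of [merge_set()].
#' @param out_prefix Path prefix for `*_merged.fastq`, `*_unmerged_R1.fastq`,
#'   `*_unmerged_R2.fastq`, `*_merge_stats.json`.
#' @export
write_merge_result <- function(result, out_prefix) {
  m <- result$merged
  write_fastq(m$id, m$sequence, m$quality, paste0(out_prefix, "_merged.fastq"))
  u <- result$unmerged
  write_fastq(u$id, u$read1, u$qual1, paste0(out_prefix, "_unmerged_R1.fastq"))
  write_fastq(u$id, u$read2, u$qual2, paste0(out_prefix, "_unmerged_R2.fastq"))
  jsonlite::write_json(as.list(result$stats),
                       paste0(out_prefix, "_merge_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_prefix)
}
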