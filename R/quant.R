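# Abundance estimation: merged reads mapped against a CDS-only database,
# per-cluster read counts and per-base depth scaled to 10 million mapped
# reads, expression tables, and per-class summaries.

#' Map merged reads to a CDS-only database
#'
#' Each read is assigned to its best-identity CDS with identity at least
#' `min_identity`; reads tying across clusters are assigned uniformly at
#' random (seeded); ties within one cluster count once for the cluster.
#'
#' @param merged_reads Tibble with `sequence` (and optionally `id`).
#' @param cds_db Tibble with `name`, `cluster`, `sequence` (pure CDS);
#'   optionally `class`.
#' @param min_identity Minimum alignment identity.
#' @param seed Seed for the uniform tie-break.
#' @param scale_to Total mapped reads the counts/depths are scaled to.
#' @return List with `counts` (tibble: `cluster`, `reads`, `scaled_reads`),
#'   `depth` (named list of per-CDS scaled depth vectors for each `name`),
#'   `n_mapped`, `n_reads`.
#' @export
map_reads_to_cds <- function(merged_reads, cds_db, min_identity = 0.95,
                             seed = 1L, scale_to = 1e7) {
  if (nrow(cds_db) == 0L) stop("empty CDS database", call. = FALSE)
  stopifnot(all(c("name", "cluster", "sequence") %in% names(cds_db)))
  set.seed(seed)
  mp <- cpp_map_reads(merged_reads$sequence, cds_db$sequence, 15L,
                      min_identity, 30L)
  n <- nrow(merged_reads)
  assigned_ref <- integer(n)   # 0 = unmapped
  for (i in seq_len(n)) {
    h <- mp$hits[[i]]
    if (is.null(h)) next
    refs <- h[, 1L]
    clusters <- unique(cds_db$cluster[refs])
    if (length(clusters) > 1L) {
      # tie across clusters: choose one cluster uniformly at random
      cl <- clusters[sample.int(length(clusters), 1L)]
      refs <- refs[cds_db$cluster[refs] == cl]
    }
    assigned_ref[i] <- refs[1L]
  }
  mapped <- assigned_ref > 0L
  n_mapped <- sum(mapped)
  scale <- if (n_mapped > 0L) scale_to / n_mapped else 0
  counts <- tibble::tibble(cluster = cds_db$cluster[assigned_ref[mapped]]) |>
    dplyr::count(.data$cluster, name = "reads") |>
    dplyr::mutate(scaled_reads = .data$reads * scale)
  depth <- setNames(vector("list", nrow(cds_db)), cds_db$name)
  for (j in seq_len(nrow(cds_db))) depth[[j]] <- numeric(nchar(cds_db$sequence[j]))
  for (i in which(mapped)) {
    h <- mp$hits[[i]]
    ref <- assigned_ref[i]
    off <- h[match(ref, h[, 1L]), 2L]
    L <- nchar(cds_db$sequence[ref])
    a <- max(1L, off + 1L)
    b <- min(L, off + nchar(merged_reads$sequence[i]))
    if (b >= a) depth[[ref]][a:b] <- depth[[ref]][a:b] + 1
  }
  depth <- lapply(depth, function(d) d * scale)
  list(counts = counts, depth = depth, n_mapped = n_mapped, n_reads = n)
}

#' Build an expression table (one row per toxin cluster)
#'
#' Percentages follow the read-count convention: `pct_total_reads` is
#' cluster reads over all mapped reads, `pct_toxin_reads` is cluster reads
#' over toxin-mapped reads; `median_coverage` is the median per-position
#' scaled depth over the representative CDS.  Rows are sorted by
#' `pct_toxin_reads` descending and ranked 1..N.
#'
#' @param mapping Result of [map_reads_to_cds()].
#' @param cds_db The database tibble passed to [map_reads_to_cds()], with a
#'   logical `is_toxin` column and optionally `member` (representative =
#'   member "a" or the first entry per cluster).
#' @return Tibble of expression records: `rank`, `cluster_name`,
#'   `cluster_size`, `cds_length`, `median_coverage`, `pct_toxin_reads`,
#'   `pct_total_reads`.
#' @export
abundance_table <- function(mapping, cds_db) {
  stopifnot("is_toxin" %in% names(cds_db))
  counts <- mapping$counts
  if (nrow(counts) == 0L || mapping$n_mapped == 0L) {
    warning("zero mapped reads; empty abundance table")
    return(tibble::tibble(rank = integer(), cluster_name = character(),
                          cluster_size = integer(), cds_length = integer(),
                          median_coverage = numeric(),
                          pct_toxin_reads = numeric(),
                          pct_total_reads = numeric()))
  }
  cl_info <- cds_db |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      cluster_size = dplyr::n(),
      is_toxin = .data$is_toxin[1L],
      rep_name = .data$name[1L],
      cds_length = nchar(.data$sequence[1L]),
      .groups = "drop"
    )
  tot_reads <- sum(counts$reads)
  tox_clusters <- cl_info$cluster[cl_info$is_toxin]
  tox_reads <- sum(counts$reads[counts$cluster %in% tox_clusters])
  tab <- counts |>
    dplyr::inner_join(cl_info, by = "cluster") |>
    dplyr::filter(.data$is_toxin) |>
    dplyr::mutate(
      pct_total_reads = .data$reads / tot_reads * 100,
      pct_toxin_reads = .data$reads / tox_reads * 100,
      median_coverage = vapply(.data$rep_name, function(nm)
        median(mapping$depth[[nm]]), numeric(1), USE.NAMES = FALSE)
    ) |>
    dplyr::arrange(dplyr::desc(.data$pct_toxin_reads)) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", cluster_name = "cluster", "cluster_size",
                  "cds_length", "median_coverage", "pct_toxin_reads",
                  "pct_total_reads")
  tab
}

#' Toxin class from a cluster name
#'
#' Strips the cluster number and member letter from names like `3FTx-9a`,
#' `SVMPIII-2`, `CFVII`, `Fused`.
#' @param cluster_name Character vector.
#' @return Character vector of class labels.
#' @export
class_of_cluster <- function(cluster_name) {
  sub("-[0-9]+[a-z]?$", "", cluster_name)
}

#' Per-class expression summary
#'
#' Sums the percentage columns per toxin class and reports the grand toxin
#' share of total transcription.
#'
#' @param table An expression table ([abundance_table()] or a published
#'   table with the same columns).
#' @param classes Optional named vector mapping cluster name to class;
#'   defaults to [class_of_cluster()] on the cluster names.
#' @return List with `by_class` (tibble: `class`, `n_clusters`,
#'   `pct_toxin_reads`, `pct_total_reads`) and `toxin_pct_total` (sum of
#'   `pct_total_reads` over all toxin rows).
#' @export
class_summary <- function(table, classes = NULL) {
  cls <- if (is.null(classes)) class_of_cluster(table$cluster_name) else {
    out <- unname(classes[table$cluster_name])
    if (anyNA(out)) {
      warning("unknown class label for some clusters; grouped as 'other'")
      out[is.na(out)] <- "other"
    }
    out
  }
  by_class <- table |>
    dplyr::mutate(class = cls) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n_clusters = dplyr::n(),
      pct_toxin_reads = sum(.data$pct_toxin_reads),
      pct_total_reads = sum(.data$pct_total_reads),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$pct_toxin_reads))
  list(by_class = by_class,
       toxin_pct_total = sum(table$pct_total_reads))
}
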