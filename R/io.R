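# File-format helpers: FASTA/FASTQ through Biostrings, TSV through readr.

#' Write named sequences to FASTA
#' @param seqs Named character vector (DNA or protein).
#' @param path Output file.
#' @param type `"dna"` or `"protein"`.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::DNAStringSet(seqs) else
    Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA file.
#' @param type `"dna"` or `"protein"`.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::readDNAStringSet(path) else
    Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

phred_to_char <- function(q) {
  vapply(q, function(v) intToUtf8(pmin(v, 93L) + 33L), character(1))
}

char_to_phred <- function(s) {
  lapply(s, function(x) utf8ToInt(x) - 33L)
}

#' Write reads to a 4-line FASTQ file (phred+33)
#'
#' @param ids,sequences Character vectors.
#' @param qualities List of integer phred vectors (one per read).
#' @param path Output file.
#' @export
write_fastq <- function(ids, sequences, qualities, path) {
  stopifnot(length(ids) == length(sequences),
            length(sequences) == length(qualities))
  qc <- phred_to_char(qualities)
  lines <- character(4L * length(ids))
  idx <- seq_along(ids)
  lines[4L * idx - 3L] <- paste0("@", ids)
  lines[4L * idx - 2L] <- sequences
  lines[4L * idx - 1L] <- "+"
  lines[4L * idx] <- qc
  writeLines(lines, path)
  invisible(path)
}

#' Read a 4-line FASTQ file into a tibble
#'
#' @param path FASTQ file.
#' @return Tibble with columns `id`, `sequence`, and list-column `quality`
#'   (integer phred scores).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(tibble::tibble(id = character(), sequence = character(),
                          quality = list()))
  }
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ: ", path, call. = FALSE)
  idx <- seq_len(length(lines) / 4L)
  tibble::tibble(
    id = sub("^@", "", lines[4L * idx - 3L]),
    sequence = lines[4L * idx - 2L],
    quality = char_to_phred(lines[4L * idx])
  )
}

#' Documented CDS FASTA header grammar: name|cluster=...|class=...|member=...
#' @noRd
parse_cds_header <- function(headers) {
  name <- sub("\\|.*$", "", headers)
  grab <- function(key) {
    m <- stringr::str_match(headers, paste0("\\|", key, "=([^|]+)"))[, 2]
    m
  }
  tibble::tibble(name = name, cluster = grab("cluster"),
                 class = grab("class"), member = grab("member"))
}
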