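#' Read 5'UTR sequences from a FASTA file
#'
#' Parses a FASTA file of 5'UTR sequences into a tibble of UTR records.
#' The first whitespace-delimited token of each header is taken as the
#' RefSeq id; an optional `gene=` tag supplies the gene symbol (falling
#' back to the RefSeq id). Sequences are upper-cased and `U` is mapped to
#' `T`, so both DNA and RNA spellings are accepted; any other letter is a
#' format error.
#'
#' Position 1 of each sequence is the 5' terminus, the anchor position of
#' the TOP-motif scan ([scan_top()]).
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `gene_id`, `refseq_id`, `sequence`, `length`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">NM_025587 gene=Rps21", "ctcctgaaa"), fa)
#' read_utr_fasta(fa)
#' @export
read_utr_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) {
    return(tibble(
      gene_id = character(), refseq_id = character(),
      sequence = character(), length = integer()
    ))
  }
  headers <- names(seqs)
  refseq_id <- stringr::str_split_i(headers, "\\s+", 1)
  gene_id <- stringr::str_match(headers, "gene=(\\S+)")[, 2]
  gene_id <- ifelse(is.na(gene_id), refseq_id, gene_id)
  sequence <- toupper(as.character(seqs))
  empty <- which(nchar(sequence) == 0)
  if (length(empty)) {
    abort(paste0("Empty sequence under header '", headers[empty[1]], "'."))
  }
  bad <- which(stringr::str_detect(sequence, "[^ACGTU]"))
  if (length(bad)) {
    ch <- stringr::str_extract(sequence[bad[1]], "[^ACGTU]")
    abort(paste0(
      "Sequence '", refseq_id[bad[1]], "' contains character '", ch,
      "' outside the A/C/G/T/U alphabet."
    ))
  }
  sequence <- stringr::str_replace_all(sequence, "U", "T")
  tibble(
    gene_id = gene_id, refseq_id = refseq_id,
    sequence = sequence, length = nchar(sequence)
  )
}

#' Write UTR records to a FASTA file
#'
#' @param utrs Tibble with columns `gene_id`, `refseq_id`, `sequence`, as
#'   returned by [read_utr_fasta()] or [simulate_utrs()].
#' @param path Output path.
#' @return `utrs`, invisibly.
#' @export
write_utr_fasta <- function(utrs, path) {
  lines <- character(2L * nrow(utrs))
  lines[c(TRUE, FALSE)] <- paste0(">", utrs$refseq_id, " gene=", utrs$gene_id)
  lines[c(FALSE, TRUE)] <- utrs$sequence
  writeLines(lines, path)
  invisible(utrs)
}
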