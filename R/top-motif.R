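#' Scan a 5'UTR for 5'-terminal oligopyrimidine (TOP) motifs
#'
#' A TOP motif here is a cap-adjacent `C` followed by an uninterrupted run
#' of at least `min_pyrimidines` pyrimidines (`C`/`T`) and closed by a `G`.
#' The scan is anchored at position 1: the first motif must start at the 5'
#' terminus, and after each motif the scan restarts immediately after its
#' closing `G`, so consecutive motifs chain without gaps. The scan stops at
#' the first position that does not open a motif. Internal (non-anchored)
#' motifs can be requested with `anchored = FALSE`, which reports every
#' non-overlapping motif from left to right.
#'
#' The pyrimidine run is maximal; no backtracking is needed because a `G`
#' terminates any pyrimidine run, making the greedy scan equivalent to the
#' regular expression `C[CT]{min,}G` applied iteratively.
#'
#' @param sequence Character vector of DNA sequences over `A`/`C`/`G`/`T`
#'   (position 1 = 5' terminus), or a tibble of UTR records with columns
#'   `gene_id`, `refseq_id`, `sequence` as from [read_utr_fasta()].
#' @param min_pyrimidines Minimum interior pyrimidine run length
#'   (default 3).
#' @param anchored Restrict to position-1-anchored motif chains
#'   (default `TRUE`).
#' @return Tibble with one row per motif hit: `refseq_id`, `gene_id`
#'   (where the input carries them), `start` and `end` (1-based,
#'   inclusive), `matched` (the motif subsequence, starting with `C` and
#'   ending with `G`).
#' @examples
#' scan_top("CTCCTG")
#' scan_top("CTTCCTTTCTCGCTCCCCG") # two consecutive motifs
#' @export
scan_top <- function(sequence, min_pyrimidines = 3, anchored = TRUE) {
  stopifnot(min_pyrimidines >= 1)
  if (is.data.frame(sequence)) {
    utrs <- sequence
    stopifnot(all(c("refseq_id", "sequence") %in% names(utrs)))
    hits <- purrr::map(seq_len(nrow(utrs)), function(i) {
      h <- scan_top_chain(utrs$sequence[i], min_pyrimidines, anchored)
      if (nrow(h) == 0) {
        return(NULL)
      }
      bind_cols(
        tibble(
          refseq_id = utrs$refseq_id[i],
          gene_id = if ("gene_id" %in% names(utrs)) utrs$gene_id[i] else utrs$refseq_id[i]
        ),
        h
      )
    })
    res <- bind_rows(hits)
    return(if (nrow(res) == 0) empty_hits() else res)
  }
  bind_rows(lapply(sequence, scan_top_chain,
    min_pyrimidines = min_pyrimidines, anchored = anchored
  ))
}

empty_hits <- function() {
  tibble(
    refseq_id = character(), gene_id = character(),
    start = integer(), end = integer(), matched = character()
  )
}

# one sequence -> tibble(start, end, matched)
scan_top_chain <- function(seq, min_pyrimidines, anchored) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_pyr <- chars == "C" | chars == "T"
  starts <- integer()
  ends <- integer()
  q <- 1L
  while (q <= n) {
    hit_end <- match_top_at(chars, is_pyr, q, n, min_pyrimidines)
    if (is.na(hit_end)) {
      if (anchored) break
      q <- q + 1L
      next
    }
    starts <- c(starts, q)
    ends <- c(ends, hit_end)
    q <- hit_end + 1L
  }
  if (!length(starts)) {
    return(tibble(start = integer(), end = integer(), matched = character()))
  }
  tibble(
    start = starts, end = ends,
    matched = substring(seq, starts, ends)
  )
}

# end position of a TOP motif opening at q, or NA
match_top_at <- function(chars, is_pyr, q, n, min_pyrimidines) {
  if (chars[q] != "C") {
    return(NA_integer_)
  }
  run_end <- q
  while (run_end + 1L <= n && is_pyr[run_end + 1L]) run_end <- run_end + 1L
  run_len <- run_end - q
  if (run_len < min_pyrimidines) {
    return(NA_integer_)
  }
  if (run_end + 1L > n || chars[run_end + 1L] != "G") {
    return(NA_integer_)
  }
  run_end + 1L
}

#' Per-gene TOP motif summary
#'
#' Aggregates motif hits per gene: a gene is TOP-bearing iff at least one
#' of its transcripts carries an anchored motif, and genes with two or more
#' consecutive motifs on one transcript are flagged separately.
#'
#' @param utrs Tibble of UTR records (`gene_id`, `refseq_id`, `sequence`).
#' @param min_pyrimidines Passed to [scan_top()].
#' @return Tibble with one row per gene: `gene_id`, `n_motifs` (total
#'   anchored hits over its transcripts), `top_bearing` (logical),
#'   `consecutive` (logical, >= 2 chained motifs on one transcript).
#' @export
summarize_top <- function(utrs, min_pyrimidines = 3) {
  hits <- scan_top(utrs, min_pyrimidines = min_pyrimidines)
  per_seq <- count(hits, .data$gene_id, .data$refseq_id, name = "n_hits")
  per_gene <- summarise(group_by(per_seq, .data$gene_id),
    n_motifs = sum(.data$n_hits),
    consecutive = any(.data$n_hits >= 2L),
    .groups = "drop"
  )
  out <- left_join(distinct(utrs, .data$gene_id), per_gene, by = "gene_id")
  mutate(out,
    n_motifs = tidyr::replace_na(.data$n_motifs, 0L),
    top_bearing = .data$n_motifs > 0L,
    consecutive = tidyr::replace_na(.data$consecutive, FALSE)
  ) |>
    select("gene_id", "n_motifs", "top_bearing", "consecutive")
}
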