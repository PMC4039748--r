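# Published nine-group sizes of the adipogenesis time course, in group order
# 1..9 (TC:up/TL:up ... TC:unchanged/TL:unchanged).
table1_sizes <- c(813, 754, 25, 660, 10, 87, 358, 37, 2536)

# Published TOP-motif hits of the TC:up/TL:up group: RefSeq, gene symbol,
# 5'UTR length, 1-based motif coordinates and matched subsequence.
table2_motifs <- tibble::tribble(
  ~refseq_id, ~gene_id, ~seq_length, ~start, ~end, ~matched,
  "NM_001042672", "Prei4", 205, 1, 6, "CCTTCG",
  "NM_010072", "Dpm1", 26, 1, 6, "CTTCCG",
  "NM_025587", "Rps21", 82, 1, 6, "CTCCTG",
  "NM_025592", "Rpl35", 45, 1, 12, "CTCTTTCTCTCG",
  "NM_027015", "Rps27", 33, 1, 8, "CCTTTCCG",
  "NM_027193", "Dph5", 118, 1, 5, "CTCTG",
  "NM_009096", "Rps6", 41, 1, 10, "CTCTTTTTCG",
  "NM_026147", "Rps20", 114, 1, 8, "CCTTTCTG",
  "NM_009419", "Tpst2", 168, 1, 5, "CCTCG",
  "NM_172086", "Rpl32", 51, 1, 11, "CTTCTTCCTCG",
  "NM_009081", "Rpl28", 42, 1, 9, "CTCTTTCCG",
  "NM_026020", "Rplp2", 59, 1, 7, "CCTTTCG",
  "NM_170669", "Rps15a", 17, 1, 9, "CTTCCCTCG",
  "NM_145596", "Gatad2a", 540, 1, 6, "CCCTCG",
  "NM_025974", "Rpl14", 22, 1, 7, "CTTCTCG",
  "NM_207625", "Acsl4", 460, 1, 8, "CTTTTCCG",
  "NM_025313", "Atp5d", 151, 1, 6, "CCTTCG",
  "NM_153529", "Nrn1", 164, 1, 8, "CTTCCTCG",
  "NM_178668", "E430028B21Rik", 294, 1, 6, "CCCTCG",
  "NM_009083", "Rpl30", 180, 1, 12, "CTTCCTTTCTCG",
  "NM_009083", "Rpl30", 180, 13, 19, "CTCCCCG",
  "NM_013481", "Bop1", 48, 1, 6, "CTCCCG",
  "NM_145632", "Polr2h", 96, 1, 5, "CTCTG",
  "NM_145632", "Polr2h", 96, 6, 10, "CCCTG",
  "NM_016844", "Rps28", 26, 1, 10, "CTCCTCTCCG"
)

# reassemble the full scanned prefix of each transcript from its motif rows
table2_utrs <- function() {
  dplyr::summarise(
    dplyr::group_by(table2_motifs, refseq_id, gene_id),
    sequence = paste(matched[order(start)], collapse = ""),
    .groups = "drop"
  )
}

# classified tibble with prescribed group sizes (statuses from group ids)
classification_with_sizes <- function(sizes) {
  groups <- dplyr::bind_rows(lapply(1:9, function(g) {
    if (sizes[g] == 0) {
      return(NULL)
    }
    tibble::tibble(group_id = rep(g, sizes[g]))
  }))
  defs <- polyeff:::regulation_groups()
  dplyr::mutate(
    dplyr::left_join(groups, defs, by = "group_id"),
    gene_id = sprintf("g%05d", dplyr::row_number())
  )
}

# small balanced dataset from explicit per-cell replicate values:
# `cells` is a list(p0 =, p6 =, np0 =, np6 =) of genes x r matrices
expr_set_from_cells <- function(cells, spikein = NULL) {
  r <- ncol(cells$p0)
  n <- nrow(cells$p0)
  samples <- tibble::tibble(
    sample_id = c(
      paste0("p0_", 1:r), paste0("p6_", 1:r),
      paste0("np0_", 1:r), paste0("np6_", 1:r)
    ),
    fraction = rep(c("polysomal", "nonpolysomal"), each = 2 * r),
    time_h = rep(c(0, 6, 0, 6), each = r),
    replicate = rep(1:r, 4)
  )
  values <- cbind(cells$p0, cells$p6, cells$np0, cells$np6)
  colnames(values) <- samples$sample_id
  expr_set(
    dplyr::bind_cols(
      tibble::tibble(
        gene_id = sprintf("g%03d", 1:n),
        spikein = spikein %||% rep(FALSE, n)
      ),
      tibble::as_tibble(values)
    ),
    samples
  )
}

`%||%` <- rlang::`%||%`
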