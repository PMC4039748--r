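#' Assemble an expression dataset
#'
#' Bundles a wide expression table (one row per gene, one numeric column per
#' sample, all values log2 intensities) with its sample metadata into a
#' validated `expr_set` object, the raw input of the pipeline.
#'
#' @param expression Tibble with a `gene_id` character column, an optional
#'   logical `spikein` column (defaults to all `FALSE`), and one numeric
#'   column per sample named by `sample_id`.
#' @param samples Tibble with columns `sample_id`, `fraction`
#'   (`"polysomal"` or `"nonpolysomal"`), `time_h` (0 or 6) and `replicate`
#'   (positive integer). Every sample column of `expression` must appear
#'   here exactly once.
#'
#' @details Validation enforces the design contract: unique gene and sample
#'   ids, finite values, and at least two replicates in every
#'   fraction-by-time cell that is present (otherwise no within-cell
#'   variance is estimable).
#'
#' @return An object of class `expr_set`: a list with elements `expression`
#'   and `samples` (both tibbles).
#' @examples
#' es <- expr_set(
#'   tibble::tibble(
#'     gene_id = c("g1", "g2"), spikein = c(FALSE, TRUE),
#'     s1 = c(1, 2), s2 = c(1.5, 2), s3 = c(3, 2), s4 = c(2.5, 2)
#'   ),
#'   tibble::tibble(
#'     sample_id = c("s1", "s2", "s3", "s4"),
#'     fraction = rep("polysomal", 4),
#'     time_h = c(0, 0, 6, 6), replicate = c(1, 2, 1, 2)
#'   )
#' )
#' es
#' @export
expr_set <- function(expression, samples) {
  expression <- as_tibble(expression)
  samples <- as_tibble(samples)
  if (!"gene_id" %in% names(expression)) {
    abort("`expression` must have a `gene_id` column.")
  }
  if (!"spikein" %in% names(expression)) {
    expression$spikein <- FALSE
  }
  expression <- select(expression, "gene_id", "spikein", dplyr::everything())
  if (anyDuplicated(expression$gene_id)) {
    dup <- unique(expression$gene_id[duplicated(expression$gene_id)])
    abort(paste0("Duplicate gene ids: ", paste(head(dup, 5), collapse = ", ")))
  }
  need <- c("sample_id", "fraction", "time_h", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    abort(paste0("Sample metadata lacks column(s): ", paste(miss, collapse = ", ")))
  }
  samples <- mutate(samples,
    sample_id = as.character(.data$sample_id),
    fraction = as.character(.data$fraction),
    time_h = as.numeric(.data$time_h),
    replicate = as.integer(.data$replicate)
  )
  if (anyDuplicated(samples$sample_id)) {
    abort("Sample ids must be unique.")
  }
  if (!all(samples$fraction %in% c("polysomal", "nonpolysomal"))) {
    abort("`fraction` must be 'polysomal' or 'nonpolysomal'.")
  }
  if (!all(samples$time_h %in% c(0, 6))) {
    abort("`time_h` must be 0 or 6.")
  }
  if (any(samples$replicate < 1L)) {
    abort("`replicate` must be a positive integer.")
  }
  value_cols <- setdiff(names(expression), c("gene_id", "spikein"))
  missing_meta <- setdiff(value_cols, samples$sample_id)
  if (length(missing_meta)) {
    abort(paste0(
      "Sample(s) present in the expression table but absent from the metadata: ",
      paste(missing_meta, collapse = ", ")
    ))
  }
  missing_col <- setdiff(samples$sample_id, value_cols)
  if (length(missing_col)) {
    abort(paste0(
      "Sample(s) declared in the metadata but missing from the expression table: ",
      paste(missing_col, collapse = ", ")
    ))
  }
  # column order follows the metadata order
  expression <- select(expression, "gene_id", "spikein", dplyr::all_of(samples$sample_id))
  for (cn in samples$sample_id) {
    col <- expression[[cn]]
    if (!is.numeric(col)) {
      abort(paste0("Expression column '", cn, "' is not numeric."))
    }
    if (any(!is.finite(col))) {
      abort(paste0(
        "Non-finite expression value for gene '",
        expression$gene_id[which(!is.finite(col))[1]], "' in sample '", cn, "'."
      ))
    }
  }
  cells <- count(samples, .data$fraction, .data$time_h)
  if (any(cells$n < 2L)) {
    bad <- cells[cells$n < 2L, ]
    abort(paste0(
      "Design cell ", bad$fraction[1], "/", bad$time_h[1],
      " h has fewer than 2 replicates; variance is not estimable."
    ))
  }
  structure(list(expression = expression, samples = samples), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(
    "<expr_set> ", nrow(x$expression), " genes x ", nrow(x$samples), " samples (",
    sum(x$expression$spikein), " spike-ins)\n",
    sep = ""
  )
  cells <- count(x$samples, .data$fraction, .data$time_h)
  for (i in seq_len(nrow(cells))) {
    cat("  ", cells$fraction[i], " ", cells$time_h[i], " h: ", cells$n[i],
      " replicate(s)\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @method as_tibble expr_set
#' @export
as_tibble.expr_set <- function(x, ...) {
  tidyr::pivot_longer(x$expression,
    cols = -c("gene_id", "spikein"),
    names_to = "sample_id", values_to = "log2_intensity"
  ) |>
    left_join(x$samples, by = "sample_id")
}

# genes x samples numeric matrix view
expr_matrix <- function(es) {
  m <- as.matrix(es$expression[, es$samples$sample_id, drop = FALSE])
  rownames(m) <- es$expression$gene_id
  m
}

#' Read an expression dataset from TSV files
#'
#' Reads a tab-delimited expression table (first column `gene_id`, one column
#' per sample, optional logical `spikein` column) together with its sample
#' metadata and returns a validated [expr_set].
#'
#' @param path Path to the expression TSV.
#' @param metadata_path Path to the metadata TSV with columns `sample_id`,
#'   `fraction`, `time_h`, `replicate`.
#' @param spikein_path Optional path to a two-column TSV (`gene_id`,
#'   `spikein`) carrying the spike-in flags when they are not a column of the
#'   expression table.
#' @return An [expr_set].
#' @seealso [write_expression_table()]
#' @export
read_expression_table <- function(path, metadata_path, spikein_path = NULL) {
  raw <- readr::read_tsv(path, comment = "#",
    col_types = readr::cols(.default = readr::col_character())
  )
  if (!"gene_id" %in% names(raw)) {
    abort(paste0("'", path, "': first column must be named 'gene_id'."))
  }
  value_cols <- setdiff(names(raw), c("gene_id", "spikein"))
  for (cn in value_cols) {
    parsed <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(parsed) & !is.na(raw[[cn]]))
    if (length(bad)) {
      abort(paste0(
        "'", path, "': non-numeric value '", raw[[cn]][bad[1]],
        "' at row ", bad[1], ", column '", cn, "'."
      ))
    }
    raw[[cn]] <- parsed
  }
  if ("spikein" %in% names(raw)) {
    raw$spikein <- parse_flag(raw$spikein, "spikein")
  }
  if (!is.null(spikein_path)) {
    flags <- readr::read_tsv(spikein_path, comment = "#", col_types = readr::cols(
      gene_id = readr::col_character(), .default = readr::col_character()
    ))
    if (!all(c("gene_id", "spikein") %in% names(flags))) {
      abort(paste0("'", spikein_path, "': expected columns gene_id, spikein."))
    }
    raw$spikein <- NULL
    raw <- left_join(raw,
      mutate(flags, spikein = parse_flag(.data$spikein, "spikein")),
      by = "gene_id"
    )
    raw$spikein[is.na(raw$spikein)] <- FALSE
  }
  samples <- readr::read_tsv(metadata_path, comment = "#", col_types = readr::cols(
    sample_id = readr::col_character(),
    fraction = readr::col_character(),
    time_h = readr::col_double(),
    replicate = readr::col_integer()
  ))
  expr_set(raw, samples)
}

parse_flag <- function(x, what) {
  if (is.logical(x)) {
    return(x)
  }
  out <- toupper(trimws(as.character(x)))
  ok <- out %in% c("TRUE", "FALSE", "1", "0")
  if (!all(ok)) {
    abort(paste0("Column '", what, "': value '", x[which(!ok)[1]], "' is not a flag."))
  }
  out %in% c("TRUE", "1")
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [read_expression_table()]: the written files re-read to an
#' identical dataset.
#'
#' @param es An [expr_set].
#' @param path Output path for the expression TSV (includes the `spikein`
#'   column).
#' @param metadata_path Output path for the sample metadata TSV.
#' @param header Optional character vector of `#`-prefixed comment lines
#'   written above both tables (skipped on reading).
#' @return `es`, invisibly.
#' @export
write_expression_table <- function(es, path, metadata_path, header = NULL) {
  stopifnot(inherits(es, "expr_set"))
  for (p in c(path, metadata_path)) {
    if (!is.null(header)) writeLines(header, p)
  }
  readr::write_tsv(es$expression, path,
    append = !is.null(header), col_names = TRUE
  )
  readr::write_tsv(es$samples, metadata_path,
    append = !is.null(header), col_names = TRUE
  )
  invisible(es)
}
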