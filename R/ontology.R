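#' Build a gene ontology object
#'
#' Combines a term table (with `is_a` parent links) and a direct gene
#' annotation table into a validated `gene_ontology` object. The is_a graph
#' must be acyclic and every parent id must resolve. Direct annotations are
#' propagated up the DAG under the true-path rule: a gene annotated to a
#' term is implicitly annotated to all of that term's ancestors, so each
#' term's propagated gene set is the union of its own direct genes and those
#' of all its descendants.
#'
#' @param terms Tibble with columns `term_id`, `name`, `namespace`
#'   (`"BP"`, `"MF"`, ...) and a list-column `parents` of character vectors
#'   of parent term ids (is_a only).
#' @param annotations Tibble with columns `gene_id`, `term_id` (direct
#'   annotations). Annotations to unknown terms are dropped with a message
#'   reporting how many.
#' @return An object of class `gene_ontology`: list with `terms`,
#'   `annotations` (the retained direct annotations), `propagated` (named
#'   list mapping term id to the sorted character vector of annotated genes
#'   after true-path propagation) and `n_dropped_annotations`.
#' @seealso [read_ontology()] for the OBO/TSV reader,
#'   [propagate_annotations()] to recompute the propagated map.
#' @export
gene_ontology <- function(terms, annotations) {
  terms <- as_tibble(terms)
  annotations <- as_tibble(annotations)
  stopifnot(
    all(c("term_id", "name", "namespace", "parents") %in% names(terms)),
    all(c("gene_id", "term_id") %in% names(annotations))
  )
  if (anyDuplicated(terms$term_id)) {
    abort("Duplicate term ids in the ontology.")
  }
  unknown_parent <- setdiff(unlist(terms$parents), terms$term_id)
  if (length(unknown_parent)) {
    abort(paste0("Unresolved parent term id(s): ", paste(head(unknown_parent, 5), collapse = ", ")))
  }
  check_acyclic(terms)
  known <- annotations$term_id %in% terms$term_id
  n_dropped <- sum(!known)
  if (n_dropped > 0) {
    inform(paste0("Dropped ", n_dropped, " annotation(s) to unknown terms."))
    annotations <- annotations[known, , drop = FALSE]
  }
  annotations <- distinct(annotations, .data$gene_id, .data$term_id)
  onto <- structure(
    list(
      terms = terms, annotations = annotations,
      propagated = NULL, n_dropped_annotations = n_dropped
    ),
    class = "gene_ontology"
  )
  onto$propagated <- propagate_annotations(onto)
  onto
}

#' @export
print.gene_ontology <- function(x, ...) {
  cat("<gene_ontology> ", nrow(x$terms), " terms (",
    paste(names(table(x$terms$namespace)), table(x$terms$namespace),
      sep = ": ", collapse = ", "
    ),
    "), ", nrow(x$annotations), " direct annotations of ",
    dplyr::n_distinct(x$annotations$gene_id), " genes\n",
    sep = ""
  )
  invisible(x)
}

# Kahn's algorithm on the is_a DAG; on failure, report one concrete cycle.
check_acyclic <- function(terms) {
  parents <- setNames(terms$parents, terms$term_id)
  n_children <- setNames(integer(nrow(terms)), terms$term_id)
  for (ps in parents) {
    for (p in ps) n_children[[p]] <- n_children[[p]] + 1L
  }
  queue <- names(n_children)[n_children == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (p in parents[[t]]) {
      n_children[[p]] <- n_children[[p]] - 1L
      if (n_children[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen < nrow(terms)) {
    remaining <- names(n_children)[n_children > 0L]
    cycle <- find_cycle(parents, remaining[1])
    abort(paste0("Cycle in is_a graph: ", paste(cycle, collapse = " -> ")))
  }
  invisible(TRUE)
}

# Walk parent links from `start` until a node repeats.
find_cycle <- function(parents, start) {
  path <- character()
  node <- start
  repeat {
    if (node %in% path) {
      return(c(path[which(path == node):length(path)], node))
    }
    path <- c(path, node)
    nxt <- intersect(parents[[node]], names(parents))
    node <- nxt[1]
  }
}

#' Propagate direct annotations under the true-path rule
#'
#' Recomputes, from the direct annotations only, the mapping term id ->
#' gene set where each term collects its own genes plus those of all
#' descendants. Idempotent by construction: the result depends only on the
#' direct annotations and the DAG.
#'
#' @param ontology A [gene_ontology].
#' @return Named list of sorted character vectors, one per term.
#' @export
propagate_annotations <- function(ontology) {
  terms <- ontology$terms
  parents <- setNames(terms$parents, terms$term_id)
  direct <- split(ontology$annotations$gene_id, ontology$annotations$term_id)
  prop <- setNames(vector("list", nrow(terms)), terms$term_id)
  for (id in terms$term_id) prop[[id]] <- direct[[id]] %||% character()
  # children before parents: Kahn order starting from leaf terms
  n_children <- setNames(integer(nrow(terms)), terms$term_id)
  for (ps in parents) {
    for (p in ps) n_children[[p]] <- n_children[[p]] + 1L
  }
  queue <- names(n_children)[n_children == 0L]
  while (length(queue)) {
    t <- queue[[1]]
    queue <- queue[-1]
    for (p in parents[[t]]) {
      prop[[p]] <- union(prop[[p]], prop[[t]])
      n_children[[p]] <- n_children[[p]] - 1L
      if (n_children[[p]] == 0L) queue <- c(queue, p)
    }
  }
  lapply(prop, function(g) sort(unique(g)))
}

#' Read a gene ontology from OBO and annotation files
#'
#' Parses an OBO 1.2 subset (`[Term]` stanzas with `id`, `name`,
#' `namespace`, `is_a`; obsolete terms are dropped) and a two-column TSV of
#' direct gene annotations (`gene_id`, `term_id`), then builds a
#' [gene_ontology] with true-path propagation. Namespaces
#' `biological_process`, `molecular_function` and `cellular_component` are
#' abbreviated to `BP`, `MF`, `CC`.
#'
#' @param obo_path Path to the OBO file.
#' @param annotation_path Path to the annotation TSV (header `gene_id`,
#'   `term_id`).
#' @return A [gene_ontology].
#' @export
read_ontology <- function(obo_path, annotation_path) {
  lines <- readLines(obo_path, warn = FALSE)
  lines <- trimws(lines)
  stanza_starts <- which(lines == "[Term]")
  if (!length(stanza_starts)) {
    abort(paste0("'", obo_path, "': no [Term] stanzas found."))
  }
  boundaries <- c(stanza_starts, length(lines) + 1L)
  ns_map <- c(
    biological_process = "BP", molecular_function = "MF",
    cellular_component = "CC"
  )
  recs <- purrr::map(seq_along(stanza_starts), function(i) {
    block <- lines[(boundaries[i] + 1L):(boundaries[i + 1L] - 1L)]
    other <- which(startsWith(block, "["))  # stop at a following non-Term stanza
    if (length(other)) block <- block[seq_len(other[1] - 1L)]
    grab <- function(key) {
      hit <- block[startsWith(block, paste0(key, ":"))]
      trimws(sub(paste0("^", key, ":"), "", hit))
    }
    if (any(grab("is_obsolete") == "true")) {
      return(NULL)
    }
    id <- grab("id")
    if (!length(id)) {
      return(NULL)
    }
    ns <- grab("namespace")
    ns <- if (length(ns) && ns[1] %in% names(ns_map)) ns_map[[ns[1]]] else ns[1]
    name <- grab("name")
    is_a <- trimws(stringr::str_split_i(grab("is_a"), "\\s*!", 1))
    tibble(
      term_id = id[1],
      name = if (length(name)) name[1] else id[1],
      namespace = if (length(ns)) ns else NA_character_,
      parents = list(is_a)
    )
  })
  terms <- bind_rows(recs)
  # is_a links to dropped (obsolete) terms are pruned
  terms$parents <- lapply(terms$parents, intersect, terms$term_id)
  annotations <- readr::read_tsv(annotation_path, comment = "#", col_types = readr::cols(
    gene_id = readr::col_character(), term_id = readr::col_character()
  ))
  gene_ontology(terms, annotations)
}

#' Write a gene ontology to OBO and annotation files
#'
#' @param ontology A [gene_ontology].
#' @param obo_path Output OBO path.
#' @param annotation_path Output annotation TSV path.
#' @param header Optional `#`-prefixed comment lines written above the
#'   annotation table.
#' @return `ontology`, invisibly.
#' @export
write_ontology <- function(ontology, obo_path, annotation_path, header = NULL) {
  ns_map <- c(BP = "biological_process", MF = "molecular_function", CC = "cellular_component")
  blocks <- purrr::pmap_chr(
    ontology$terms,
    function(term_id, name, namespace, parents) {
      paste(c(
        "[Term]",
        paste0("id: ", term_id),
        paste0("name: ", name),
        paste0("namespace: ", unname(ns_map[namespace] %||% namespace)),
        if (length(parents)) paste0("is_a: ", parents),
        ""
      ), collapse = "\n")
    }
  )
  writeLines(c("format-version: 1.2", "", blocks), obo_path)
  if (!is.null(header)) writeLines(header, annotation_path)
  readr::write_tsv(ontology$annotations, annotation_path,
    append = !is.null(header), col_names = TRUE
  )
  invisible(ontology)
}
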