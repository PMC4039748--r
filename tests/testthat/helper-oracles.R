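# Independent oracles used to validate the package's statistics. They apply
# textbook definitions directly and share no code with the implementation.

# Benjamini-Hochberg by the step-up definition on sorted p-values
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  fdr_sorted <- vapply(
    seq_len(n),
    function(i) min(1, min(ps[i:n] * n / (i:n))),
    numeric(1)
  )
  out <- numeric(n)
  out[ord] <- fdr_sorted
  out
}

# Exact table probability from binomial coefficients (no dhyper)
table_prob <- function(a, b, c, d) {
  choose(a + b, a) * choose(c + d, c) / choose(a + b + c + d, a + c)
}

# Fisher's exact test by full enumeration of all tables with the margins
fisher_oracle <- function(a, b, c, d, alternative = "two.sided") {
  m <- a + c
  k <- a + b
  n2 <- b + d
  support <- max(0, k - n2):min(k, m)
  probs <- vapply(
    support,
    function(x) table_prob(x, k - x, m - x, n2 - (k - x)),
    numeric(1)
  )
  obs <- probs[support == a]
  if (alternative == "greater") {
    sum(probs[support >= a])
  } else {
    min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  }
}

# Iterated anchored regular expression: motifs are ^C[CT]{min,}G chains
regex_top_oracle <- function(seq, min_pyrimidines = 3) {
  re <- paste0("^C[CT]{", min_pyrimidines, ",}G")
  hits <- character()
  pos <- 1L
  repeat {
    m <- regmatches(seq, regexpr(re, seq, perl = TRUE))
    if (!length(m)) break
    hits <- c(hits, m)
    pos <- pos + nchar(m)
    seq <- substring(seq, nchar(m) + 1L)
  }
  hits
}

# True-path propagation by brute-force ancestor closure: a term's gene set
# is every gene directly annotated to any term that can reach it via is_a.
propagation_oracle <- function(ontology) {
  terms <- ontology$terms
  ids <- terms$term_id
  parents <- stats::setNames(terms$parents, ids)
  ancestors_of <- function(t) {
    seen <- character()
    frontier <- t
    while (length(frontier)) {
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(parents[frontier])), seen)
    }
    seen
  }
  anc <- lapply(ids, ancestors_of) # term -> itself + all ancestors
  names(anc) <- ids
  prop <- stats::setNames(replicate(length(ids), character()), ids)
  ann <- ontology$annotations
  for (i in seq_len(nrow(ann))) {
    for (t in anc[[ann$term_id[i]]]) {
      prop[[t]] <- union(prop[[t]], ann$gene_id[i])
    }
  }
  lapply(prop, function(g) sort(unique(g)))
}
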