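# Shared fixtures and tiny independent oracles used across test files.

# A 64-codon code over two labels: Lys on AAA/AAG, Ala elsewhere.
two_label_code <- function() {
  m <- stats::setNames(rep("A", 64), codon_order())
  m[c("AAA", "AAG")] <- "K"
  genetic_code(m, source = "toy")
}

# A code with every codon encoding the same amino acid (no stop).
constant_code <- function(label = "G") {
  genetic_code(stats::setNames(rep(label, 64), codon_order()), source = "toy")
}

# Plain-R weighted pair mean over neighbor_pairs(), independent of
# mutational_error()'s internals.
naive_pair_delta <- function(code, table, index, w) {
  np <- neighbor_pairs(code)
  v <- stats::setNames(table[[paste0(index, "_norm")]], table$code1)
  e <- abs(v[np$aa1] - v[np$aa2])
  wt <- ifelse(np$kind == "transition", w, 1)
  sum(wt * e) / sum(wt)
}

block_size_multiset <- function(code) {
  sort(unname(lengths(synonymous_blocks(code))))
}

# Codon->label map with class/attribute stripped, for identity comparisons.
code_map <- function(code) {
  v <- unclass(code)
  attributes(v) <- list(names = names(v))
  v
}

census <- function(x, levels) as.vector(table(factor(x, levels = levels)))
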