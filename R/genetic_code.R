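#' All 64 codons in translation-table order
#'
#' DNA codons ordered as in NCBI translation tables: third position cycling
#' fastest through T, C, A, G, then second, then first. This is the fixed
#' order used by 64-character translation strings.
#'
#' @return Character vector of length 64 (`"TTT"`, `"TTC"`, ..., `"GGG"`).
#' @export
codon_order <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(vapply(b, function(b1)
    vapply(b, function(b2) paste0(b1, b2, b), character(4)),
    character(16)))
}

# standard genetic code as a translation string in codon_order()
.SGC_STRING <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

.normalize_codons <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

#' Construct a genetic code
#'
#' A genetic code is a total map from the 64 codons to the 21 labels (20
#' amino acids plus `"X"` for stop). RNA codons (with U) are accepted and
#' converted to DNA.
#'
#' @param mapping Named character vector of length 64: names are codons,
#'   values are single-letter labels (`"*"` is accepted for stop).
#' @param source Provenance tag, e.g. `"sgc"`, `"permuted"`, `"hopfield"`.
#' @return Named character vector of class `genetic_code`, ordered by
#'   [codon_order()], with attribute `source`.
#' @export
genetic_code <- function(mapping, source = "custom") {
  names(mapping) <- .normalize_codons(names(mapping))
  mapping[mapping == "*"] <- "X"
  ord <- codon_order()
  if (!setequal(names(mapping), ord) || length(mapping) != 64) {
    stop("a genetic code must map exactly the 64 codons")
  }
  mapping <- mapping[ord]
  bad <- setdiff(unique(mapping), amino_acid_labels())
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  structure(mapping, class = "genetic_code", source = source)
}

#' The standard genetic code (SGC)
#'
#' @return A [genetic_code()] encoding the standard table (e.g. `AAA -> K`,
#'   `ATG -> M`, `TAA`/`TAG`/`TGA` -> `X`).
#' @export
sgc <- function() {
  if (is.null(.hopcode_env$sgc)) {
    .hopcode_env$sgc <- code_from_string(.SGC_STRING, source = "sgc")
  }
  .hopcode_env$sgc
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> source:", attr(x, "source"),
      "| labels:", length(unique(x)), "\n")
  m <- matrix(paste0(names(x), ":", unname(x)), nrow = 16)
  print(m, quote = FALSE)
  invisible(x)
}

#' Convert a genetic code to a 64-character translation string
#'
#' @param code A `genetic_code`.
#' @return Single string over [codon_order()], with `"*"` for stop.
#' @export
code_to_string <- function(code) {
  x <- unname(unclass(code)[codon_order()])
  x[x == "X"] <- "*"
  paste(x, collapse = "")
}

#' Build a genetic code from a 64-character translation string
#'
#' @param s String of 64 single-letter labels in [codon_order()]; `"*"`
#'   denotes stop.
#' @param source Provenance tag.
#' @return A `genetic_code`.
#' @export
code_from_string <- function(s, source = "custom") {
  if (nchar(s) != 64) stop("translation string must have 64 characters")
  genetic_code(stats::setNames(strsplit(s, "")[[1]], codon_order()),
               source = source)
}

#' Read / write genetic codes as CSV
#'
#' The CSV format has columns `codon` and `label` (one row per codon; `"*"`
#' accepted for stop on input).
#'
#' @param file Path.
#' @param code A `genetic_code` (for writing).
#' @param source Provenance tag attached on reading.
#' @return `read_genetic_code()` returns a `genetic_code`;
#'   `write_genetic_code()` returns `file` invisibly.
#' @export
read_genetic_code <- function(file, source = "custom") {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("codon", "label") %in% names(d))) {
    stop("code CSV needs columns 'codon' and 'label'")
  }
  genetic_code(stats::setNames(d$label, d$codon), source = source)
}

#' @rdname read_genetic_code
#' @export
write_genetic_code <- function(code, file) {
  utils::write.csv(data.frame(codon = names(code), label = unname(unclass(code))),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Classify a single-nucleotide difference between two codons
#'
#' If the two codons differ at exactly one position, returns that position
#' and whether the substitution is a transition (A<->G or C<->T) or a
#' transversion. Identical codons and codons differing at two or more
#' positions are not single-mutation neighbours and yield the `NA` sentinel
#' rather than an error.
#'
#' @param c1,c2 Codon strings (vectorized; recycled to a common length).
#' @return Data frame with columns `position` (1-3 or `NA`) and `kind`
#'   (`"transition"`, `"transversion"`, or `NA`).
#' @examples
#' mutation_class("AAA", "AAG")  # position 3, transition
#' mutation_class("AAA", "AGG")  # not a neighbour -> NA sentinel
#' @export
mutation_class <- function(c1, c2) {
  c1 <- .normalize_codons(c1); c2 <- .normalize_codons(c2)
  n <- max(length(c1), length(c2))
  c1 <- rep_len(c1, n); c2 <- rep_len(c2, n)
  pos <- rep(NA_integer_, n)
  kind <- rep(NA_character_, n)
  a <- matrix(unlist(strsplit(c1, "")), nrow = 3)
  b <- matrix(unlist(strsplit(c2, "")), nrow = 3)
  ndiff <- colSums(a != b)
  one <- which(ndiff == 1)
  for (k in one) {
    p <- which(a[, k] != b[, k])
    pos[k] <- p
    pair <- paste(sort(c(a[p, k], b[p, k])), collapse = "")
    kind[k] <- if (pair %in% c("AG", "CT")) "transition" else "transversion"
  }
  data.frame(position = pos, kind = kind, stringsAsFactors = FALSE)
}

# All 288 unordered single-base codon pairs with position/kind annotation
# and integer indices into codon_order(); cached.
.single_base_pairs <- function() {
  if (!is.null(.hopcode_env$pairs)) return(.hopcode_env$pairs)
  ord <- codon_order()
  idx <- utils::combn(64, 2)
  cls <- mutation_class(ord[idx[1, ]], ord[idx[2, ]])
  keep <- !is.na(cls$position)
  pairs <- data.frame(i1 = idx[1, keep], i2 = idx[2, keep],
                      codon1 = ord[idx[1, keep]], codon2 = ord[idx[2, keep]],
                      position = cls$position[keep], kind = cls$kind[keep],
                      stringsAsFactors = FALSE)
  .hopcode_env$pairs <- pairs
  pairs
}

#' Single-base codon pairs of a genetic code, stop pairs excluded
#'
#' Enumerates all unordered codon pairs that differ at exactly one position
#' and encode amino acids on both sides under `code` (pairs involving a stop
#' codon are excluded). For the standard code this census is 263 pairs; the
#' count varies with where a code places its stop block.
#'
#' @param code A `genetic_code`.
#' @return Data frame with columns `codon1`, `codon2`, `position`, `kind`,
#'   `aa1`, `aa2`.
#' @examples
#' nrow(neighbor_pairs(sgc()))  # 263
#' @export
neighbor_pairs <- function(code) {
  p <- .single_base_pairs()
  v <- unclass(code)
  keep <- v[p$i1] != "X" & v[p$i2] != "X"
  out <- p[keep, c("codon1", "codon2", "position", "kind")]
  out$aa1 <- unname(v[p$i1[keep]])
  out$aa2 <- unname(v[p$i2[keep]])
  rownames(out) <- NULL
  out
}

#' Synonymous codon blocks of a genetic code
#'
#' @param code A `genetic_code`.
#' @return Named list mapping each label to its codons (the synonymous
#'   block); 21 blocks for SGC-structured codes.
#' @export
synonymous_blocks <- function(code) {
  split(names(code), unclass(code))
}
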