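#' The four transversion-minimizing base cyclings
#'
#' Each variant id lists the forward base cycle (first four letters) followed
#' by its reverse; cycling bases in this order alternates transitions (A<->G,
#' C<->T) with transversions and is the minimal-transversion way to visit all
#' four bases cyclically.
#'
#' @return Character vector of the four variant ids.
#' @export
wheel_variants <- function() {
  c("AGCTTCGA", "AGTCCTGA", "GACTTCAG", "GATCCTAG")
}

#' Build a codon wheel
#'
#' Constructs the cyclic ordering of all 64 codons in which consecutive
#' codons (including the wrap-around) differ at exactly one position. The
#' third codon position cycles fastest, then the first, then the second --
#' mirroring the decreasing mutational cost of substitutions at positions 3,
#' 1, 2 -- and each position traverses its four bases boustrophedon
#' (direction-reversing), i.e. the wheel is a reflected base-4 Gray code.
#' The step census over the 64 cyclic steps is always 48 third-position, 12
#' first-position and 4 second-position changes.
#'
#' @param variant One of [wheel_variants()]; its first four letters give the
#'   base cycling order.
#' @param start Codon placed at rank 1 (the wheel is rotated to it).
#' @return Object of class `codon_wheel`: a data frame with columns `rank`,
#'   `codon`, `step_position`, `step_kind` (the step from each codon to the
#'   next, wrapping at rank 64), with attributes `variant` and `start`.
#' @examples
#' w <- build_wheel()
#' head(w$codon, 8)  # AAA AAG AAC AAT GAT GAC GAG GAA
#' @export
build_wheel <- function(variant = "AGCTTCGA", start = "AAA") {
  if (!variant %in% wheel_variants()) {
    stop("unknown wheel variant: ", variant,
         " (expected one of ", paste(wheel_variants(), collapse = ", "), ")")
  }
  start <- .normalize_codons(start)
  bases <- strsplit(substr(variant, 1, 4), "")[[1]]
  codons <- character(64)
  for (k in 0:63) {
    d2 <- k %/% 16          # 2nd position, slowest
    r <- k %% 16
    d1 <- r %/% 4           # 1st position
    d0 <- r %% 4            # 3rd position, fastest
    i1 <- if (d2 %% 2 == 0) d1 else 3 - d1
    i0 <- if ((d2 + i1) %% 2 == 0) d0 else 3 - d0
    codons[k + 1] <- paste0(bases[i1 + 1], bases[d2 + 1], bases[i0 + 1])
  }
  s <- match(start, codons)
  if (is.na(s)) stop("invalid start codon: ", start)
  codons <- codons[((seq_len(64) - 1 + s - 1) %% 64) + 1]
  nxt <- c(codons[-1], codons[1])
  cls <- mutation_class(codons, nxt)
  stopifnot(!anyNA(cls$position))  # construction invariant
  structure(
    data.frame(rank = seq_len(64), codon = codons,
               step_position = cls$position, step_kind = cls$kind,
               stringsAsFactors = FALSE),
    variant = variant, start = start,
    class = c("codon_wheel", "data.frame"))
}

#' Assign wheel addresses to codons
#'
#' Walks the wheel clockwise from its start codon and ranks the reference
#' code's labels by first encounter; every codon inherits the rank of its
#' label. With the standard code as reference this yields 21 addresses, one
#' per synonymous block (e.g. starting at AAA: `AAA`/`AAG` -> 1 (Lys),
#' `AAC`/`AAT` -> 2 (Asn), `GAT`/`GAC` -> 3 (Asp), `GAG`/`GAA` -> 4 (Glu)).
#'
#' @param wheel A [build_wheel()] result.
#' @param reference A `genetic_code` with exactly 21 labels (default SGC).
#' @return Object of class `address_map`: data frame with columns `codon`,
#'   `address`, `label`, plus attribute `labels` (the address -> label
#'   vector in rank order).
#' @export
assign_addresses <- function(wheel, reference = sgc()) {
  v <- unclass(reference)
  labs <- unique(unname(v[wheel$codon]))  # first-encounter order
  if (length(labs) != 21) {
    stop("reference code must use exactly 21 labels, got ", length(labs))
  }
  addr <- match(unname(v[wheel$codon]), labs)
  out <- data.frame(codon = wheel$codon, address = addr,
                    label = unname(v[wheel$codon]),
                    stringsAsFactors = FALSE)
  structure(out, labels = labs, class = c("address_map", "data.frame"))
}

.check_tour <- function(path, labels) {
  if (!setequal(path, labels) || length(path) != length(labels) ||
      anyDuplicated(path)) {
    stop("invalid tour path: must visit each of the ",
         length(labels), " labels exactly once")
  }
  invisible(TRUE)
}

#' Map an amino-acid tour onto a genetic code
#'
#' The label at tour position `k` is assigned to every codon whose wheel
#' address is `k`. The resulting code is total over the 64 codons and
#' preserves the reference code's synonymous-block size distribution; the
#' identity tour (labels in address order) reproduces the reference code
#' exactly, and a uniformly random tour is equivalent to a random permutation
#' of labels among synonymous blocks.
#'
#' @param path Character vector of the 21 labels, each exactly once, in tour
#'   order.
#' @param addresses An [assign_addresses()] result.
#' @param source Provenance tag for the new code.
#' @return A `genetic_code`.
#' @export
code_from_path <- function(path, addresses, source = "hopfield") {
  labs <- attr(addresses, "labels")
  .check_tour(path, labs)
  mapping <- stats::setNames(path[addresses$address], addresses$codon)
  genetic_code(mapping, source = source)
}

#' Length of an amino-acid tour in index space
#'
#' Sum of Euclidean amino-acid distances along consecutive tour labels,
#' optionally closing the cycle (the wheel is a circle, so cyclic closure is
#' the default). Reversing a path leaves the cyclic length unchanged.
#'
#' @param path Character vector of the 21 labels (each once).
#' @param table An `aa_index_table`.
#' @param indices Nonempty subset of [index_names()].
#' @param cyclic Include the closing edge?
#' @return Nonnegative number.
#' @export
tour_length <- function(path, table = aa_index_table(),
                        indices = "polarity", cyclic = TRUE) {
  m <- index_matrix(table, indices)
  if (!all(path %in% rownames(m))) stop("invalid tour path: unknown labels")
  if (anyDuplicated(path)) stop("invalid tour path: repeated label")
  x <- m[path, , drop = FALSE]
  steps <- sqrt(rowSums((x[-1, , drop = FALSE] -
                           x[-nrow(x), , drop = FALSE])^2))
  tot <- sum(steps)
  if (cyclic) tot <- tot + sqrt(sum((x[nrow(x), ] - x[1, ])^2))
  tot
}

#' Export a wheel (with addresses) as a plain data frame
#'
#' @param wheel A `codon_wheel`.
#' @param addresses Optional [assign_addresses()] result to merge in.
#' @return Data frame with columns `rank`, `codon`, `step_position`,
#'   `step_kind`, and (if addresses given) `address`, `label`; suitable for
#'   `write.csv()` and for re-drawing wheel figures.
#' @export
wheel_table <- function(wheel, addresses = NULL) {
  out <- as.data.frame(wheel)
  if (!is.null(addresses)) {
    out$address <- addresses$address[match(out$codon, addresses$codon)]
    out$label <- addresses$label[match(out$codon, addresses$codon)]
  }
  out
}
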