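#' @keywords internal
.hopcode_env <- new.env(parent = emptyenv())

#' Names of the four amino-acid physio-chemical indices
#'
#' @return Character vector: `"polarity"`, `"hydrophobicity"`, `"volume"`,
#'   `"isoelectric"`.
#' @export
index_names <- function() {
  c("polarity", "hydrophobicity", "volume", "isoelectric")
}

#' The 21 amino-acid labels (20 canonical amino acids plus stop)
#'
#' One-letter codes for the 20 canonical amino acids plus `"X"` for the
#' translational stop signal.
#'
#' @return Character vector of length 21, alphabetical with `"X"` between
#'   `"W"` and `"Y"`.
#' @export
amino_acid_labels <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
    "N", "P", "Q", "R", "S", "T", "V", "W", "X", "Y")
}

#' Raw amino-acid index values shipped with the package
#'
#' Reads the bundled CSV of raw index values (Grantham polarity,
#' Kyte-Doolittle hydrophobicity, residue volume, isoelectric point) for the
#' 20 canonical amino acids, together with the published normalized values
#' and the fixed stop pseudo-values.
#'
#' @return A data frame with one row per label (20 amino acids + stop) and
#'   columns `code1`, `code3`, then `<index>_raw` and `<index>_printed` for
#'   each of the four indices. The stop row has `NA` raw values; its
#'   `_printed` entries are the fixed pseudo-constants.
#' @export
raw_index_values <- function() {
  path <- system.file("extdata", "amino_acid_indices.csv", package = "hopcode")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Build the normalized amino-acid index table
#'
#' Normalizes each physio-chemical index to a z-score across the 20 canonical
#' amino acids: `(raw - mean)/sd`, with the sample standard deviation
#' (denominator n-1; the convention pinned by exact agreement with the
#' published normalized values). The stop signal does not take part in the
#' normalization; its coordinates are fixed pseudo-values chosen as outliers
#' so that stop-to-amino-acid distances exceed any amino-acid pair distance.
#'
#' @param raw Data frame of raw values with columns `code1`, `code3` and one
#'   column per index named after [index_names()] (or `<index>_raw`). Must
#'   contain all 20 amino acids.
#' @param stop_values Named numeric vector of length 4 giving the stop
#'   pseudo-coordinates on the normalized scale, named after [index_names()].
#' @return An object of class `aa_index_table`: a data frame with columns
#'   `code1`, `code3`, `<index>_raw` and `<index>_norm`, 21 rows.
#' @examples
#' tab <- aa_index_table()
#' subset(tab, code1 == "A")$polarity_norm  # -0.1672
#' @export
build_index_table <- function(raw, stop_values = stop_pseudo_values()) {
  idx <- index_names()
  raw_cols <- ifelse(paste0(idx, "_raw") %in% names(raw),
                     paste0(idx, "_raw"), idx)
  missing_idx <- idx[!(raw_cols %in% names(raw))]
  if (length(missing_idx)) {
    stop("raw index values missing for: ", paste(missing_idx, collapse = ", "))
  }
  if (!all(idx %in% names(stop_values))) {
    stop("stop pseudo-values must be named after index_names()")
  }
  aa <- raw[raw$code1 != "X", , drop = FALSE]
  need <- setdiff(amino_acid_labels(), "X")
  if (!setequal(aa$code1, need)) {
    stop("raw table must contain exactly the 20 canonical amino acids; missing: ",
         paste(setdiff(need, aa$code1), collapse = ", "))
  }
  aa <- aa[order(aa$code1), , drop = FALSE]
  out <- data.frame(code1 = c(aa$code1, "X"),
                    code3 = c(aa$code3, "Stop"),
                    stringsAsFactors = FALSE)
  for (k in seq_along(idx)) {
    x <- aa[[raw_cols[k]]]
    if (anyNA(x)) stop("raw ", idx[k], " values contain NA")
    z <- (x - mean(x)) / stats::sd(x)
    out[[paste0(idx[k], "_raw")]] <- c(x, NA_real_)
    out[[paste0(idx[k], "_norm")]] <- c(z, unname(stop_values[idx[k]]))
  }
  rownames(out) <- out$code1
  out <- out[amino_acid_labels(), , drop = FALSE]
  class(out) <- c("aa_index_table", "data.frame")
  out
}

#' Stop-signal pseudo-coordinates
#'
#' The fixed normalized-scale coordinates assigned to the translational stop
#' signal. They are constants, not outputs of the normalization, placed
#' outside the amino-acid cloud so the stop behaves as an outlier "city" in
#' tours and distances.
#'
#' @return Named numeric vector over [index_names()].
#' @export
stop_pseudo_values <- function() {
  c(polarity = -1.5993, hydrophobicity = 1.672,
    volume = -1.5833, isoelectric = -2.6562)
}

#' The normalized amino-acid index table
#'
#' Returns the package's operative index table: raw values from
#' [raw_index_values()] z-scored by [build_index_table()], with the stop
#' pseudo-values appended. With `normalized = "printed"` the published
#' normalized values are substituted verbatim instead of being recomputed;
#' the two versions differ only in the three cells flagged by
#' [index_table_discrepancies()].
#'
#' @param normalized `"computed"` (default) to z-score the raw values, or
#'   `"printed"` to use the published normalized values as-is.
#' @return An `aa_index_table` data frame (see [build_index_table()]).
#' @export
aa_index_table <- function(normalized = c("computed", "printed")) {
  normalized <- match.arg(normalized)
  key <- paste0("index_table_", normalized)
  if (!is.null(.hopcode_env[[key]])) return(.hopcode_env[[key]])
  raw <- raw_index_values()
  tab <- build_index_table(raw)
  if (normalized == "printed") {
    raw <- raw[match(tab$code1, raw$code1), , drop = FALSE]
    for (ix in index_names()) {
      tab[[paste0(ix, "_norm")]] <- raw[[paste0(ix, "_printed")]]
    }
  }
  .hopcode_env[[key]] <- tab
  tab
}

#' Cells where recomputed z-scores disagree with the published table
#'
#' Compares the computed z-scores against the published normalized values at
#' 4 significant figures and reports the disagreeing cells. Three cells of
#' the published table are internally inconsistent with its own raw values
#' (Leu polarity, and sign flips for Trp and Tyr hydrophobicity); this
#' function flags them rather than silently preferring either value.
#'
#' @param tol Relative tolerance for agreement after rounding to 4
#'   significant figures.
#' @return Data frame with columns `code1`, `index`, `computed`, `printed`.
#' @export
index_table_discrepancies <- function(tol = 2e-3) {
  comp <- aa_index_table("computed")
  prnt <- aa_index_table("printed")
  out <- list()
  for (ix in index_names()) {
    z <- signif(comp[[paste0(ix, "_norm")]], 4)
    p <- prnt[[paste0(ix, "_norm")]]
    bad <- abs(z - p) > tol * pmax(abs(p), 1e-6)
    bad[comp$code1 == "X"] <- FALSE  # pseudo-values pass through
    if (any(bad)) {
      out[[ix]] <- data.frame(code1 = comp$code1[bad], index = ix,
                              computed = z[bad], printed = p[bad],
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(code1 = character(), index = character(),
                      computed = numeric(), printed = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalized index coordinates as a matrix
#'
#' @param table An `aa_index_table`.
#' @param indices Subset of [index_names()].
#' @param include_stop Keep the stop row?
#' @return Numeric matrix, rows labelled by `code1`, one column per index.
#' @export
index_matrix <- function(table = aa_index_table(), indices = index_names(),
                         include_stop = TRUE) {
  if (!length(indices)) stop("'indices' must name at least one index")
  bad <- setdiff(indices, index_names())
  if (length(bad)) stop("unknown index: ", paste(bad, collapse = ", "))
  m <- as.matrix(table[, paste0(indices, "_norm"), drop = FALSE])
  dimnames(m) <- list(table$code1, indices)
  if (!include_stop) m <- m[rownames(m) != "X", , drop = FALSE]
  m
}

#' Euclidean distance between two amino acids in index space
#'
#' Distance between two labels over the selected normalized indices:
#' `sqrt(sum_i (X_i - Y_i)^2)`.
#'
#' @param x,y Single-letter labels (among [amino_acid_labels()]).
#' @param table An `aa_index_table`.
#' @param indices Nonempty subset of [index_names()].
#' @return Nonnegative number.
#' @examples
#' amino_acid_distance("A", "C", indices = "polarity")  # 0.8758 on printed values
#' @export
amino_acid_distance <- function(x, y, table = aa_index_table(),
                                indices = index_names()) {
  m <- index_matrix(table, indices)
  if (!all(c(x, y) %in% rownames(m))) {
    stop("unknown amino-acid label: ",
         paste(setdiff(c(x, y), rownames(m)), collapse = ", "))
  }
  sqrt(sum((m[x, ] - m[y, ])^2))
}

#' Pairwise amino-acid distance matrix
#'
#' The symmetric 21 x 21 (or 20 x 20) Euclidean distance matrix over the
#' selected normalized indices; the "city" distances of the amino-acid
#' traveling salesman problem.
#'
#' @inheritParams amino_acid_distance
#' @param include_stop Include the stop pseudo-city?
#' @return Symmetric nonnegative matrix with zero diagonal, labelled by
#'   amino-acid code.
#' @export
aa_distance_matrix <- function(table = aa_index_table(),
                               indices = index_names(),
                               include_stop = TRUE) {
  m <- index_matrix(table, indices, include_stop = include_stop)
  as.matrix(stats::dist(m))
}
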