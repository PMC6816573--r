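#' Principal component analysis of the amino-acid index space
#'
#' PCA of the normalized index table (correlation-matrix PCA by default,
#' i.e. columns re-scaled to unit variance). The stop pseudo-entry is
#' included by default: with it the polarity-hydrophobicity correlation
#' matches the published value (see [index_correlation()]); the 20-point
#' variant is available via `include_stop = FALSE`.
#'
#' @param table An `aa_index_table`.
#' @param include_stop Include the stop pseudo-entry (default `TRUE`)?
#' @param scale. Scale columns to unit variance (default `TRUE`).
#' @return List with `variance_pct` (percent variance per component,
#'   summing to 100), `rotation` (loadings), `scores`, `sdev`.
#' @export
index_pca <- function(table = aa_index_table(), include_stop = TRUE,
                      scale. = TRUE) {
  m <- index_matrix(table, include_stop = include_stop)
  p <- stats::prcomp(m, center = TRUE, scale. = scale.)
  list(variance_pct = 100 * p$sdev^2 / sum(p$sdev^2),
       rotation = p$rotation, scores = p$x, sdev = p$sdev)
}

#' Pearson correlation between two indices
#'
#' @param table An `aa_index_table`.
#' @param a,b Index names.
#' @param include_stop Include the stop pseudo-entry (default `TRUE`)?
#' @return Correlation in `[-1, 1]`.
#' @examples
#' round(index_correlation(a = "polarity", b = "hydrophobicity"), 2)  # -0.81
#' @export
index_correlation <- function(table = aa_index_table(), a = "polarity",
                              b = "hydrophobicity", include_stop = TRUE) {
  m <- index_matrix(table, indices = unique(c(a, b)),
                    include_stop = include_stop)
  stats::cor(m[, a], m[, b])
}

#' Run a Hopfield optimization ensemble
#'
#' Repeatedly solves the 21-city amino-acid traveling salesman problem on
#' distances built from the selected index subset, maps each valid tour to a
#' genetic code through the codon wheel, and scores every code on all four
#' indices. Errors are normalized (z-scores) against a single
#' block-permutation null per index, shared by the whole ensemble. The
#' fraction of codes beating the standard code on the first selected index
#' is computed per batch of restarts and averaged.
#'
#' @param indices Nonempty subset of [index_names()] defining the distance
#'   function (first element is the "optimized" index used for the
#'   beats-SGC fraction).
#' @param restarts Number of solver restarts.
#' @param table An `aa_index_table`.
#' @param wheel_variant,start_codon Codon wheel configuration.
#' @param n_perm Size of the permutation null per index.
#' @param w Transition/transversion weight for the error statistic.
#' @param collapse Aggregation level passed to [mutational_error()].
#' @param solver Named list of arguments forwarded to [solve_tsp()]
#'   (defaults: `d_p = 0.7`, `temp = 0.1`, annealed from 0.5).
#' @param batch_size Restart batch size for the averaged fraction.
#' @param seed Optional integer seed set once at entry (makes the whole
#'   ensemble, including the null, reproducible).
#' @return Object of class `code_ensemble`: list with
#'   \describe{
#'     \item{codes}{data frame, one row per valid code: `restart`, the four
#'       `delta_*` errors, the four `z_*` normalized errors, and `code`
#'       (64-character translation string).}
#'     \item{delta_sgc, z_sgc}{standard-code errors on the same scales.}
#'     \item{null_mean, null_sd}{per-index null summaries.}
#'     \item{frac_beats_sgc}{batch-averaged fraction beating SGC on the
#'       optimized index.}
#'     \item{n_valid, restarts, indices, params}{bookkeeping.}
#'   }
#' @export
run_ensemble <- function(indices = "polarity", restarts = 100,
                         table = aa_index_table(),
                         wheel_variant = "AGCTTCGA", start_codon = "AAA",
                         n_perm = 1000, w = 5,
                         collapse = c("type", "codon"),
                         solver = list(), batch_size = 100, seed = NULL) {
  collapse <- match.arg(collapse)
  if (!length(indices)) stop("'indices' must name at least one index")
  if (!is.null(seed)) set.seed(seed)
  d <- aa_distance_matrix(table, indices)
  wheel <- build_wheel(wheel_variant, start_codon)
  addr <- assign_addresses(wheel, sgc())
  solver_args <- utils::modifyList(list(anneal_from = 0.5), solver)
  all_idx <- index_names()

  nulls <- lapply(all_idx, function(ix)
    null_distribution(table, ix, w, n_perm, collapse)$deltas)
  names(nulls) <- all_idx
  null_mean <- vapply(nulls, mean, numeric(1))
  null_sd <- vapply(nulls, stats::sd, numeric(1))
  delta_sgc <- vapply(all_idx, function(ix)
    mutational_error(sgc(), table, ix, w, collapse)$delta, numeric(1))

  rows <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    sol <- do.call(solve_tsp, c(list(d = d), solver_args))
    if (!sol$valid) next
    code <- code_from_path(sol$labels, addr)
    deltas <- vapply(all_idx, function(ix)
      mutational_error(code, table, ix, w, collapse)$delta, numeric(1))
    rows[[r]] <- c(restart = r, deltas, code = code_to_string(code))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    warning("no valid tours produced; empty ensemble")
    codes <- data.frame(restart = integer())
    frac <- NA_real_
  } else {
    codes <- data.frame(
      restart = as.integer(vapply(rows, `[`, character(1), "restart")),
      stringsAsFactors = FALSE)
    for (ix in all_idx) {
      codes[[paste0("delta_", ix)]] <-
        as.numeric(vapply(rows, `[`, character(1), ix))
      codes[[paste0("z_", ix)]] <-
        (codes[[paste0("delta_", ix)]] - null_mean[ix]) / null_sd[ix]
    }
    codes$code <- vapply(rows, `[`, character(1), "code")
    opt <- indices[1]
    beats <- codes[[paste0("delta_", opt)]] < delta_sgc[opt]
    batch <- ceiling(codes$restart / batch_size)
    frac <- mean(tapply(beats, batch, mean))
  }
  structure(list(codes = codes,
                 delta_sgc = delta_sgc,
                 z_sgc = (delta_sgc - null_mean) / null_sd,
                 null_mean = null_mean, null_sd = null_sd,
                 frac_beats_sgc = frac,
                 n_valid = nrow(codes), restarts = restarts,
                 indices = indices, w = w, collapse = collapse,
                 params = solver_args),
            class = "code_ensemble")
}

#' @export
print.code_ensemble <- function(x, ...) {
  cat(sprintf("<code_ensemble> %d valid / %d restarts (indices: %s)\n",
              x$n_valid, x$restarts, paste(x$indices, collapse = "+")))
  if (x$n_valid) {
    cat(sprintf("  beats SGC on %s: %.1f%%\n", x$indices[1],
                100 * x$frac_beats_sgc))
    zc <- x$codes[[paste0("z_", x$indices[1])]]
    cat(sprintf("  z(%s): SGC %.2f | ensemble mean %.2f, best %.2f\n",
                x$indices[1], x$z_sgc[x$indices[1]], mean(zc), min(zc)))
  }
  invisible(x)
}

#' Codes whose normalized errors are below a threshold on every index
#'
#' @param ensemble A [run_ensemble()] result.
#' @param threshold_z Z-score threshold (e.g. `-2`).
#' @return The subset of `ensemble$codes` whose four `z_*` values are all
#'   strictly below `threshold_z`.
#' @export
find_super_optimal <- function(ensemble, threshold_z = -2) {
  codes <- ensemble$codes
  if (!nrow(codes)) return(codes)
  zc <- as.matrix(codes[, paste0("z_", index_names())])
  codes[apply(zc < threshold_z, 1, all), , drop = FALSE]
}

#' Deterministic synthetic fixtures for testing
#'
#' @param kind `"random-distances"` (symmetric matrix with zero diagonal),
#'   `"random-code"` (block-permuted genetic code), or `"toy-index-table"`
#'   (small index table with known correlation structure).
#' @param size Number of cities / rows (ignored for `"random-code"`).
#' @param seed Integer seed (required; same seed, same fixture).
#' @return The fixture object.
#' @export
generate_fixture <- function(kind = c("random-distances", "random-code",
                                      "toy-index-table"),
                             size = 5, seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  switch(kind,
    "random-distances" = {
      m <- matrix(stats::runif(size^2), size, size)
      d <- (m + t(m)) / 2
      diag(d) <- 0
      d
    },
    "random-code" = permute_code(),
    "toy-index-table" = {
      x <- stats::rnorm(size)
      data.frame(label = paste0("aa", seq_len(size)),
                 a = x, b = x, c = stats::rnorm(size))
    })
}

#' Read an experiment configuration from YAML or JSON
#'
#' Flat key-value configuration mirroring the arguments of
#' [run_ensemble()]; unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list suitable for `do.call(run_ensemble, cfg)`.
#' @export
read_experiment_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is needed to read YAML configs")
    }
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("the 'jsonlite' package is needed to read JSON configs")
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json")
  }
  allowed <- c("indices", "restarts", "wheel_variant", "start_codon",
               "n_perm", "w", "collapse", "solver", "batch_size", "seed")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg
}
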