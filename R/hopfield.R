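#' Mean field of the traveling-salesman Hopfield network
#'
#' For activities `v[X, i]` (probability of city `X` at tour position `i`)
#' and symmetric distances `d`, the field on neuron (X, i) is
#' `E[X, i] = d_p * sum_{Y != X} v[Y, i] +
#'            sum_{Y != X} d[X, Y] * (v[Y, i+1] + v[Y, i-1])`,
#' with tour positions wrapping cyclically. The first term penalizes two
#' cities occupying one position; the second couples each city to its
#' would-be tour neighbours in proportion to distance.
#'
#' @param v Activity matrix (cities x positions), entries in `[0, 1]`.
#' @param d Symmetric nonnegative distance matrix with zero diagonal.
#' @param d_p Positive occupancy penalty.
#' @return Field matrix of the same shape as `v`.
#' @export
mean_field <- function(v, d, d_p = 0.7) {
  if (!is.matrix(v) || !is.matrix(d) || nrow(v) != nrow(d) ||
      nrow(d) != ncol(d)) {
    stop("shape mismatch: 'v' must be n x m and 'd' n x n")
  }
  n <- ncol(v)
  ip <- c(2:n, 1)[seq_len(n)]
  im <- c(n, seq_len(n - 1))[seq_len(n)]
  occupancy <- matrix(colSums(v), nrow(v), n, byrow = TRUE) - v
  d_p * occupancy + d %*% (v[, ip, drop = FALSE] + v[, im, drop = FALSE])
}

#' Boltzmann (softmax) normalization of neuron fields
#'
#' Row-wise softmax of `-E / temp`: each city's activities over tour
#' positions become a probability vector (`v[X, i] = exp(-E[X, i]/T) /
#' sum_j exp(-E[X, j]/T)`). As `temp` grows the rows tend to the uniform
#' `1/n`; as it shrinks the mass concentrates on the lowest-field position.
#'
#' @param E Field matrix.
#' @param temp Positive temperature.
#' @return Row-stochastic activity matrix.
#' @export
boltzmann_update <- function(E, temp) {
  if (!is.numeric(temp) || length(temp) != 1 || temp <= 0) {
    stop("'temp' must be a positive number")
  }
  z <- -E / temp
  z <- z - apply(z, 1, max)       # log-sum-exp guard
  v <- exp(z)
  v / rowSums(v)
}

#' Validate a decoded tour
#'
#' @param path Integer vector of city indices in tour-position order.
#' @param n_cities Number of cities.
#' @return `TRUE`, or `FALSE` with attribute `reason`.
#' @export
validate_path <- function(path, n_cities) {
  if (length(path) != n_cities) {
    return(structure(FALSE, reason = "wrong length"))
  }
  if (anyDuplicated(path) || !setequal(path, seq_len(n_cities))) {
    return(structure(FALSE, reason = "cities repeated or missing"))
  }
  TRUE
}

#' Solve a traveling salesman instance with a mean-field Hopfield network
#'
#' Relaxes an `n x n` grid of neuron activities (city x tour position) by
#' iterating [mean_field()] and [boltzmann_update()] until the largest
#' activity change in a sweep falls below `tol` or `max_sweeps` is reached.
#' Updates are asynchronous: one city row is recomputed at a time, in random
#' order within each sweep (synchronous full-matrix updates oscillate at
#' working temperatures and are available via `update = "sync"` for study).
#' Activities start at `0.5` plus uniform noise in `[-init_spread,
#' +init_spread]`. Optionally the temperature is annealed geometrically
#' from `anneal_from` down to `temp` (factor `cool` per sweep); otherwise
#' the network relaxes at fixed `temp`.
#'
#' The tour is decoded by the per-position argmax over cities (ties broken
#' by lowest city index). Decodings that do not visit every city exactly
#' once are reported as invalid rather than repaired.
#'
#' @param d Symmetric nonnegative distance matrix (optionally with
#'   rownames naming the cities).
#' @param d_p Occupancy penalty (default 0.7).
#' @param temp Working temperature (default 0.1).
#' @param anneal_from If non-`NULL`, starting temperature of a geometric
#'   cooling schedule ending at `temp`.
#' @param cool Cooling factor per sweep (used with `anneal_from`).
#' @param init_spread Half-width of the uniform initialization band around
#'   0.5 (default 0.1).
#' @param tol Convergence tolerance on the max activity change per sweep.
#' @param max_sweeps Sweep cap.
#' @param update `"async"` (default) or `"sync"`.
#' @param normalize_distances Divide `d` by its maximum so the default
#'   `d_p`/`temp` operate on a common scale regardless of index units
#'   (default `TRUE`).
#' @return Object of class `tsp_solution`: list with `valid`, `path`
#'   (integer positions -> city indices; `NULL` if invalid), `labels`
#'   (city names along the tour, if `d` has rownames), `sweeps`,
#'   `converged`, `activities`, and the parameters used.
#' @examples
#' set.seed(1)
#' d <- as.matrix(dist(runif(6)))
#' solve_tsp(d, anneal_from = 0.5)$valid
#' @export
solve_tsp <- function(d, d_p = 0.7, temp = 0.1, anneal_from = NULL,
                      cool = 0.98, init_spread = 0.1, tol = 1e-6,
                      max_sweeps = 10000, update = c("async", "sync"),
                      normalize_distances = TRUE) {
  update <- match.arg(update)
  if (d_p <= 0 || temp <= 0) stop("'d_p' and 'temp' must be positive")
  if (!isSymmetric(unname(d)) || any(d < 0)) {
    stop("'d' must be a symmetric nonnegative matrix")
  }
  n <- nrow(d)
  if (normalize_distances && max(d) > 0) d <- d / max(d)
  v <- matrix(0.5 + stats::runif(n * n, -init_spread, init_spread), n, n)
  ip <- c(2:n, 1)
  im <- c(n, 1:(n - 1))
  tc <- if (is.null(anneal_from)) temp else anneal_from
  converged <- FALSE
  sweeps <- 0L
  for (s in seq_len(max_sweeps)) {
    sweeps <- s
    v_old <- v
    if (update == "async") {
      for (X in sample.int(n)) {
        ex <- d_p * (colSums(v) - v[X, ]) +
          as.vector(d[X, ] %*% (v[, ip, drop = FALSE] +
                                  v[, im, drop = FALSE]))
        z <- -ex / tc
        z <- z - max(z)
        e <- exp(z)
        v[X, ] <- e / sum(e)
      }
    } else {
      v <- boltzmann_update(mean_field(v, d, d_p), tc)
    }
    at_floor <- tc <= temp + 1e-12
    tc <- max(temp, tc * cool)
    if (max(abs(v - v_old)) < tol && at_floor) {
      converged <- TRUE
      break
    }
  }
  dec <- apply(v, 2, which.max)
  valid <- isTRUE(validate_path(dec, n))
  structure(list(
    valid = valid,
    path = if (valid) dec else NULL,
    labels = if (valid && !is.null(rownames(d))) rownames(d)[dec] else NULL,
    decoded = dec, sweeps = sweeps, converged = converged,
    activities = v,
    params = list(d_p = d_p, temp = temp, anneal_from = anneal_from,
                  cool = cool, init_spread = init_spread, tol = tol,
                  max_sweeps = max_sweeps, update = update)),
    class = "tsp_solution")
}

#' @export
print.tsp_solution <- function(x, ...) {
  cat(sprintf("<tsp_solution> valid=%s converged=%s sweeps=%d\n",
              x$valid, x$converged, x$sweeps))
  if (x$valid) cat("tour:", paste(if (!is.null(x$labels)) x$labels else x$path,
                                  collapse = " "), "\n")
  invisible(x)
}

#' Cyclic tour length from a distance matrix
#'
#' @param d Distance matrix.
#' @param path Integer city indices in tour order.
#' @param cyclic Include the closing edge?
#' @return Tour length.
#' @export
path_length <- function(d, path, cyclic = TRUE) {
  idx <- if (cyclic) cbind(path, c(path[-1], path[1]))
         else cbind(path[-length(path)], path[-1])
  sum(d[idx])
}

#' Exact traveling salesman optimum by exhaustive search
#'
#' Enumerates all `(n-1)!/2` distinct cyclic tours (first city fixed,
#' reflections identified); practical for `n <= 9`. Serves as an
#' independent optimum for assessing the heuristic solver on small
#' instances.
#'
#' @param d Symmetric distance matrix, `n <= 9`.
#' @return List with `path` (integer tour starting at city 1) and `length`.
#' @export
tsp_brute_force <- function(d) {
  n <- nrow(d)
  if (n > 9) stop("exhaustive search limited to n <= 9")
  if (n <= 2) return(list(path = seq_len(n), length = path_length(d, seq_len(n))))
  perms <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x)) {
      for (p in perms(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
    }
    out
  }
  best <- NULL; best_len <- Inf
  for (p in perms(2:n)) {
    if (p[1] > p[length(p)]) next  # identify reflections
    tour <- c(1L, p)
    len <- path_length(d, tour)
    if (len < best_len) { best_len <- len; best <- tour }
  }
  list(path = best, length = best_len)
}
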