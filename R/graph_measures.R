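#' Centrality vector
#'
#' Per-region centrality values tagged with the measure and the space
#' they live in (raw or standardized), plus the standardization constants
#' needed to invert back to raw space.
#'
#' @param values Named (or unnamed) numeric vector, one value per region.
#' @param measure `"degree"`, `"eigenvector"` or `"pagerank"`.
#' @param space `"raw"` or `"standardized"`.
#' @param standardization Optional list with fields `mean`, `sd`,
#'   `post_z_min`, `post_z_max` (see [standardize_rescale()]).
#' @return An object of class `centrality_vector`.
#' @export
centrality_vector <- function(values,
                              measure = c("degree", "eigenvector", "pagerank"),
                              space = c("raw", "standardized"),
                              standardization = NULL) {
  measure <- match.arg(measure)
  space <- match.arg(space)
  values <- unlist(values)
  if (space == "standardized") {
    if (any(values < -1 - 1e-9) || any(values > 1 + 1e-9)) {
      stop("standardized centrality values must lie in [-1, 1]")
    }
    if (is.null(standardization)) {
      stop("standardized centrality requires standardization constants")
    }
  }
  if (!is.null(standardization)) {
    stopifnot(standardization$sd > 0,
              standardization$post_z_max > standardization$post_z_min)
  }
  structure(list(values = values, measure = measure, space = space,
                 standardization = standardization),
            class = "centrality_vector")
}

#' @export
print.centrality_vector <- function(x, ...) {
  cat("<centrality_vector> ", x$measure, " (", x$space, "), ",
      length(x$values), " regions\n", sep = "")
  invisible(x)
}

#' Critical correlation coefficient for a two-tailed Pearson test
#'
#' The smallest `|r|` reaching significance at `p_two_tailed` for a sample
#' of `n_samples` observations: with `df = n_samples - 2` and `t*` the
#' two-tailed Student-t critical value, `r* = t* / sqrt(df + t*^2)`.
#' With p = 1e-4 and the 4800 timepoints of four concatenated 1200-point
#' sessions this is about 0.056, the lower threshold applied to
#' functional connectivity before graph construction.
#'
#' @param p_two_tailed Two-tailed significance level in (0, 1).
#' @param n_samples Number of paired observations (>= 4).
#' @return The critical correlation, a number in (0, 1).
#' @export
critical_r <- function(p_two_tailed = 1e-4, n_samples) {
  if (!(p_two_tailed > 0 && p_two_tailed < 1)) stop("p must be in (0, 1)")
  if (n_samples < 4) stop("n_samples must be >= 4 (need df >= 2)")
  df <- n_samples - 2
  tcrit <- stats::qt(p_two_tailed / 2, df = df, lower.tail = FALSE)
  tcrit / sqrt(df + tcrit^2)
}

#' Threshold a functional connectivity matrix
#'
#' Zeroes every entry below `r_crit`, keeping only positive
#' supra-threshold correlations at their original weights ("lower
#' threshold" semantics: negative correlations are dropped).  Set
#' `absolute = TRUE` to threshold on `|r|` instead, retaining strong
#' negative correlations.
#'
#' @param fc A functional `connectivity_matrix`.
#' @param r_crit Threshold in (0, 1), typically from [critical_r()].
#' @param absolute Threshold on magnitude instead of signed value.
#' @return The thresholded functional `connectivity_matrix`.
#' @export
threshold_fc <- function(fc, r_crit, absolute = FALSE) {
  stopifnot(inherits(fc, "connectivity_matrix"))
  if (fc$kind != "functional") stop("threshold_fc expects a functional matrix")
  if (!(r_crit > 0 && r_crit < 1)) stop("r_crit must be in (0, 1)")
  v <- fc$values
  keep <- if (absolute) abs(v) >= r_crit else v >= r_crit
  v[!keep] <- 0
  diag(v) <- 0
  connectivity_matrix(v, "functional", fc$atlas)
}

#' Degree centrality
#'
#' Number of nonzero off-diagonal entries per row (binary degree), or the
#' row sum of weights when `weighted = TRUE`.
#'
#' @param m A `connectivity_matrix`.
#' @param weighted Use strength (sum of weights) instead of edge count.
#' @return A raw-space `centrality_vector` with measure `"degree"`.
#' @export
degree_centrality <- function(m, weighted = FALSE) {
  stopifnot(inherits(m, "connectivity_matrix"))
  a <- m$values
  diag(a) <- 0
  vals <- if (weighted) rowSums(a) else rowSums(a != 0)
  centrality_vector(stats::setNames(as.numeric(vals), m$atlas$names),
                    "degree", "raw")
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the (binary by default) adjacency matrix,
#' non-negative with unit Euclidean norm, obtained by power iteration.
#'
#' @param m A `connectivity_matrix` (non-negative weights).
#' @param weighted Use edge weights; default binary, matching the common
#'   graph-library default.
#' @param tol Convergence tolerance on the iterate change.
#' @param max_iter Iteration cap.
#' @return A raw-space `centrality_vector` with measure `"eigenvector"`.
#' @export
eigenvector_centrality <- function(m, weighted = FALSE, tol = 1e-10,
                                   max_iter = 1000L) {
  stopifnot(inherits(m, "connectivity_matrix"))
  a <- m$values
  diag(a) <- 0
  if (any(a < 0)) stop("eigenvector centrality requires non-negative weights")
  if (!weighted) a <- (a != 0) * 1
  if (all(a == 0)) stop("graph has no edges; eigenvector centrality undefined")
  n <- nrow(a)
  x <- rep(1 / sqrt(n), n)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    # iterate on A + I: same principal eigenvector, but strictly dominant
    # eigenvalue even on bipartite graphs (where A alone oscillates)
    y <- as.numeric(a %*% x) + x
    ny <- sqrt(sum(y^2))
    if (ny == 0) stop("graph has no edges; eigenvector centrality undefined")
    y <- y / ny
    if (max(abs(y - x)) < tol) {
      x <- y
      converged <- TRUE
      break
    }
    x <- y
  }
  if (!converged) {
    stop("power iteration did not converge in ", max_iter,
         " iterations; check that all connected nodes form one component")
  }
  centrality_vector(stats::setNames(abs(x), m$atlas$names),
                    "eigenvector", "raw")
}

#' PageRank centrality
#'
#' Damped random-walk stationary distribution with uniform teleport:
#' `x = d * P' x + (1 - d) / n`, with weight-proportional transitions and
#' dangling nodes (zero out-strength) redistributed uniformly.  Values
#' sum to one.
#'
#' @param m A `connectivity_matrix`.
#' @param damping Damping factor in (0, 1); default 0.85.
#' @param weighted Weight-proportional transitions (default, the common
#'   graph-library behaviour for weighted graphs).
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap.
#' @return A raw-space `centrality_vector` with measure `"pagerank"`.
#' @export
pagerank_centrality <- function(m, damping = 0.85, weighted = TRUE,
                                tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(m, "connectivity_matrix"))
  if (!(damping > 0 && damping < 1)) stop("damping must be in (0, 1)")
  a <- m$values
  diag(a) <- 0
  if (!weighted) a <- (a != 0) * 1
  n <- nrow(a)
  out_strength <- rowSums(a)
  dangling <- out_strength == 0
  p <- a / ifelse(out_strength == 0, 1, out_strength)  # row-stochastic
  x <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    dang_mass <- sum(x[dangling])
    y <- damping * (as.numeric(crossprod(p, x)) + dang_mass / n) +
      (1 - damping) / n
    if (sum(abs(y - x)) < tol) {
      x <- y
      break
    }
    x <- y
  }
  centrality_vector(stats::setNames(x / sum(x), m$atlas$names),
                    "pagerank", "raw")
}

#' Z-score then rescale to [-1, 1]
#'
#' Standardizes the values across regions (z-score, sample SD) and then
#' affinely maps the post-z minimum to -1 and maximum to +1.  The four
#' constants (mean, sd, post-z min and max) are stored on the result so
#' the map can be inverted exactly by [unstandardize()].
#'
#' @param v A raw-space `centrality_vector` (or plain numeric vector)
#'   with at least 2 distinct values.
#' @return A standardized `centrality_vector` (or, for plain numeric
#'   input, a list with `values` and `standardization`).
#' @export
standardize_rescale <- function(v) {
  is_cv <- inherits(v, "centrality_vector")
  vals <- if (is_cv) v$values else v
  if (length(unique(vals)) < 2) {
    stop("cannot standardize a constant vector")
  }
  mu <- mean(vals)
  sd <- stats::sd(vals)
  z <- (vals - mu) / sd
  zmin <- min(z)
  zmax <- max(z)
  out <- 2 * (z - zmin) / (zmax - zmin) - 1
  params <- list(mean = mu, sd = sd, post_z_min = zmin, post_z_max = zmax)
  if (is_cv) {
    centrality_vector(out, v$measure, "standardized", standardization = params)
  } else {
    list(values = out, standardization = params)
  }
}

#' Invert the z-score + rescale map
#'
#' Exact inverse of [standardize_rescale()]: maps standardized values in
#' `[-1, 1]` back to raw space using the stored constants.  Used to
#' unstandardize model outputs before thresholding and centrality
#' computation.
#'
#' @param v A standardized `centrality_vector`, or a plain numeric vector
#'   of standardized values.
#' @param params Standardization constants; taken from `v` when absent.
#' @return A raw-space `centrality_vector`, or a plain numeric vector.
#' @export
unstandardize <- function(v, params = NULL) {
  is_cv <- inherits(v, "centrality_vector")
  vals <- if (is_cv) v$values else v
  if (is.null(params)) {
    if (!is_cv || is.null(v$standardization)) {
      stop("no standardization constants available")
    }
    params <- v$standardization
  }
  z <- (vals + 1) / 2 * (params$post_z_max - params$post_z_min) +
    params$post_z_min
  raw <- z * params$sd + params$mean
  if (is_cv) centrality_vector(raw, v$measure, "raw") else raw
}

#' All three centralities of a matrix, raw and standardized
#'
#' Convenience wrapper: computes degree, eigenvector and PageRank
#' centrality and their standardized versions.  Functional matrices are
#' expected to be thresholded first; structural matrices are used as-is.
#'
#' @param m A `connectivity_matrix`.
#' @return Named list of standardized `centrality_vector`s (each carrying
#'   its standardization constants) keyed by measure.
#' @export
all_centralities <- function(m) {
  list(degree = standardize_rescale(degree_centrality(m)),
       eigenvector = standardize_rescale(eigenvector_centrality(m)),
       pagerank = standardize_rescale(pagerank_centrality(m)))
}
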