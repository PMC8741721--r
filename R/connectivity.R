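#' Region atlas
#'
#' A minimal parcellation descriptor: an ordered vector of unique region
#' labels.  All connectivity matrices and centrality vectors in a cohort are
#' indexed against one atlas.
#'
#' @param names Character vector of unique region labels (length >= 2).
#' @return An object of class `region_atlas` with fields `names` and
#'   `n_regions`.
#' @examples
#' atlas <- region_atlas(c("L_frontal", "R_frontal", "L_parietal"))
#' atlas$n_regions
#' @export
region_atlas <- function(names) {
  names <- as.character(names)
  if (length(names) < 2) {
    stop("an atlas needs at least 2 regions, got ", length(names))
  }
  if (anyDuplicated(names)) {
    stop("atlas region names must be unique; duplicated: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  structure(list(names = names, n_regions = length(names)),
            class = "region_atlas")
}

#' Construct a default atlas of numbered regions
#'
#' @param n Number of regions.
#' @param prefix Label prefix.
#' @return A `region_atlas`.
#' @export
default_atlas <- function(n, prefix = "region") {
  region_atlas(sprintf("%s%03d", prefix, seq_len(n)))
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("<region_atlas> ", x$n_regions, " regions: ",
      paste(utils::head(x$names, 4), collapse = ", "),
      if (x$n_regions > 4) ", ..." else "", "\n", sep = "")
  invisible(x)
}

SYMMETRY_TOL <- 1e-8

#' Connectivity matrix
#'
#' A validated square region-by-region matrix.  Structural matrices hold
#' non-negative streamline counts; functional matrices hold Pearson
#' correlations in `[-1, 1]`.  The diagonal is always exactly zero and the
#' matrix must be symmetric; asymmetry at or below `1e-8` (e.g. from text
#' round-trips) is repaired by averaging, anything larger is an error.
#'
#' @param values Square numeric matrix.
#' @param kind `"structural"` or `"functional"`.
#' @param atlas A `region_atlas`; defaults to numbered regions.
#' @return An object of class `connectivity_matrix` with fields `values`,
#'   `kind`, `atlas`.
#' @examples
#' m <- matrix(c(0, 2, 2, 0), 2, 2)
#' connectivity_matrix(m, "structural")
#' @export
connectivity_matrix <- function(values, kind = c("structural", "functional"),
                                atlas = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("connectivity matrix must be square, got ",
         nrow(values), "x", ncol(values))
  }
  if (any(!is.finite(values))) stop("connectivity matrix has non-finite values")
  asym <- abs(values - t(values))
  worst <- max(asym)
  if (worst > SYMMETRY_TOL) {
    idx <- which(asym == worst, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "matrix asymmetric beyond tolerance: |[%d,%d] - [%d,%d]| = %g > %g",
      idx[1], idx[2], idx[2], idx[1], worst, SYMMETRY_TOL))
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (kind == "structural" && any(values < 0)) {
    stop("structural connectivity entries must be non-negative; min = ",
         min(values))
  }
  if (kind == "functional" && (any(values < -1) || any(values > 1))) {
    stop("functional connectivity entries must lie in [-1, 1]")
  }
  if (is.null(atlas)) {
    atlas <- if (!is.null(rownames(values))) {
      region_atlas(rownames(values))
    } else {
      default_atlas(nrow(values))
    }
  }
  if (atlas$n_regions != nrow(values)) {
    stop("atlas has ", atlas$n_regions, " regions but matrix is ",
         nrow(values), "x", ncol(values))
  }
  dimnames(values) <- list(atlas$names, atlas$names)
  structure(list(values = values, kind = kind, atlas = atlas),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  nz <- sum(x$values[upper.tri(x$values)] != 0)
  cat("<connectivity_matrix> ", x$kind, ", ", x$atlas$n_regions, " regions, ",
      nz, " nonzero edges\n", sep = "")
  invisible(x)
}

#' Subject record
#'
#' Bundles one subject's structural matrix, functional matrix (possibly
#' absent until computed) and named centrality vectors, all on one atlas.
#'
#' @param subject_id Character id.
#' @param sc Structural `connectivity_matrix`.
#' @param fc Functional `connectivity_matrix` or `NULL`.
#' @param struct_centrality,func_centrality Named lists of
#'   `centrality_vector` objects keyed by measure.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, sc, fc = NULL,
                           struct_centrality = list(),
                           func_centrality = list()) {
  stopifnot(inherits(sc, "connectivity_matrix"), sc$kind == "structural")
  if (!is.null(fc)) {
    stopifnot(inherits(fc, "connectivity_matrix"), fc$kind == "functional")
    if (!identical(fc$atlas$names, sc$atlas$names)) {
      stop("subject ", subject_id, ": sc and fc atlases differ")
    }
  }
  structure(list(subject_id = as.character(subject_id), sc = sc, fc = fc,
                 struct_centrality = struct_centrality,
                 func_centrality = func_centrality),
            class = "subject_record")
}

#' Cohort of subjects with a train/validation/test partition
#'
#' @param subjects List of `subject_record`s.
#' @param partition Named character vector mapping subject id to one of
#'   `"train"`, `"val"`, `"test"`; must cover exactly the subject ids.
#' @return An object of class `cohort`.
#' @export
cohort <- function(subjects, partition) {
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject ids in cohort")
  if (!setequal(names(partition), ids) ||
      length(partition) != length(ids)) {
    stop("partition must cover exactly the subject ids")
  }
  if (!all(partition %in% c("train", "val", "test"))) {
    stop("partition values must be train/val/test")
  }
  names(subjects) <- ids
  structure(list(subjects = subjects, partition = partition[ids]),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(factor(x$partition, levels = c("train", "val", "test")))
  cat("<cohort> ", length(x$subjects), " subjects (train ", tab[["train"]],
      " / val ", tab[["val"]], " / test ", tab[["test"]], ")\n", sep = "")
  invisible(x)
}

#' Subject ids belonging to one split
#'
#' @param ch A `cohort`.
#' @param split `"train"`, `"val"` or `"test"`.
#' @return Character vector of ids.
#' @export
cohort_split_ids <- function(ch, split = c("train", "val", "test")) {
  split <- match.arg(split)
  names(ch$partition)[ch$partition == split]
}
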