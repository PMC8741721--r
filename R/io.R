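#' Read a connectivity matrix from delimited text
#'
#' Accepts comma- or tab-delimited square numeric matrices with one header
#' row of region names (a headerless file of plain numbers is also
#' accepted, in which case numbered region labels are generated).
#' Asymmetry at or below `1e-8` is repaired by averaging; anything larger
#' fails validation naming the worst cell.
#'
#' @param path File path.
#' @param kind `"structural"` or `"functional"`.
#' @return A `connectivity_matrix`.
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, kind = c("structural", "functional")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- {
    cells <- strsplit(first, sep, fixed = TRUE)[[1]]
    suppressWarnings(any(is.na(as.numeric(cells))))
  }
  df <- utils::read.table(path, header = has_header, sep = sep,
                          check.names = FALSE, quote = "\"",
                          comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in matrix file: ", path)
  if (nrow(m) != ncol(m)) {
    stop("matrix file is not square (", nrow(m), " rows x ", ncol(m),
         " columns): ", path)
  }
  atlas <- if (has_header) region_atlas(colnames(df)) else NULL
  rownames(m) <- NULL
  connectivity_matrix(m, kind, atlas)
}

#' Write a connectivity matrix as comma-delimited text
#'
#' One header row of region names followed by the full-precision (17
#' significant digits) matrix rows, so that write-then-read is the
#' identity to machine precision.  Region names containing the delimiter
#' or a quote character are rejected rather than silently mangled.
#'
#' @param m A `connectivity_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "connectivity_matrix"))
  nm <- m$atlas$names
  if (any(grepl('[,\t"\n]', nm))) {
    stop("region names may not contain the delimiter, quotes or newlines")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nm, collapse = ","), con)
  body <- apply(m$values, 1L, function(row) {
    paste(format(row, digits = 17, trim = TRUE), collapse = ",")
  })
  writeLines(body, con)
  invisible(path)
}

#' Read a centrality vector (CSV + optional JSON sidecar)
#'
#' @param path Two-column CSV `region,value`.  If `<path>.json` exists it
#'   is read as the standardization sidecar.
#' @param measure Measure tag (`"degree"`, `"eigenvector"`, `"pagerank"`).
#' @param space `"raw"` or `"standardized"`.
#' @return A `centrality_vector`.
#' @export
read_centrality <- function(path, measure, space = c("raw", "standardized")) {
  space <- match.arg(space)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("region", "value") %in% names(df))) {
    stop("centrality file needs columns region,value: ", path)
  }
  std <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    std <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  centrality_vector(stats::setNames(df$value, df$region), measure, space,
                    standardization = std)
}

#' Write a centrality vector (CSV + JSON sidecar of standardization)
#'
#' @param v A `centrality_vector`.
#' @param path Output CSV path; standardization constants, when present,
#'   go to `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_centrality <- function(v, path) {
  stopifnot(inherits(v, "centrality_vector"))
  df <- data.frame(region = names(v$values), value = unname(v$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(v$standardization)) {
    jsonlite::write_json(v$standardization, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a cohort directory
#'
#' Expects the layout `dir/partition.csv` (columns `subject_id,split`) and
#' one subdirectory per subject holding `sc.csv` and optionally `fc.csv`
#' and `ts_session<k>.csv`.  A missing `fc.csv` is tolerated (functional
#' connectivity may be computed later from the timeseries).
#'
#' @param dir Cohort directory.
#' @return A `cohort`.  Each subject gains a `ts_paths` field listing any
#'   session timeseries files found, in session order.
#' @export
read_cohort <- function(dir) {
  pfile <- file.path(dir, "partition.csv")
  if (!file.exists(pfile)) stop("no partition.csv in ", dir)
  pdf <- utils::read.csv(pfile, colClasses = "character")
  if (nrow(pdf) == 0) stop("no subjects found in ", dir)
  missing <- pdf$subject_id[!dir.exists(file.path(dir, pdf$subject_id))]
  if (length(missing)) {
    stop("subjects in partition.csv without a directory: ",
         paste(missing, collapse = ", "))
  }
  subjects <- lapply(pdf$subject_id, function(id) {
    sdir <- file.path(dir, id)
    sc <- read_matrix(file.path(sdir, "sc.csv"), "structural")
    fcp <- file.path(sdir, "fc.csv")
    fc <- if (file.exists(fcp)) read_matrix(fcp, "functional") else NULL
    rec <- subject_record(id, sc, fc)
    ts <- list.files(sdir, pattern = "^ts_session[0-9]+\\.csv$",
                     full.names = TRUE)
    if (length(ts)) {
      k <- as.integer(sub("^ts_session([0-9]+)\\.csv$", "\\1", basename(ts)))
      rec$ts_paths <- ts[order(k)]
    }
    rec
  })
  cohort(subjects, stats::setNames(pdf$split, pdf$subject_id))
}

#' Write a cohort directory
#'
#' Inverse of [read_cohort()]: writes `partition.csv` plus per-subject
#' `sc.csv` and (when present) `fc.csv`.
#'
#' @param ch A `cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(ch, dir) {
  stopifnot(inherits(ch, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pdf <- data.frame(subject_id = names(ch$partition),
                    split = unname(ch$partition))
  utils::write.csv(pdf, file.path(dir, "partition.csv"),
                   row.names = FALSE, quote = FALSE)
  for (s in ch$subjects) {
    sdir <- file.path(dir, s$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    write_matrix(s$sc, file.path(sdir, "sc.csv"))
    if (!is.null(s$fc)) write_matrix(s$fc, file.path(sdir, "fc.csv"))
  }
  invisible(dir)
}

#' Read a multi-session timeseries file
#'
#' Regions x timepoints delimited text, one file per session, with an
#' optional header row of region names.
#'
#' @param path File path.
#' @param tr_seconds Sampling interval in seconds.
#' @return A `timeseries_session`.
#' @export
read_timeseries <- function(path, tr_seconds) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  cells <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(cells))))
  m <- as.matrix(utils::read.table(path, header = has_header, sep = sep,
                                   check.names = FALSE))
  rownames(m) <- NULL
  timeseries_session(m, tr_seconds)
}

#' Save trained model parameters
#'
#' Writes a directory of named flat CSV arrays (one file per weight or
#' bias tensor, with a shape header line) plus a `hyperparams.json`
#' sidecar, so the archive is language-portable and diff-able.
#'
#' @param params A `model_params` object (see [init_model_params()]).
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_model_params <- function(params, dir) {
  stopifnot(inherits(params, "model_params"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- flatten_params(params)
  for (nm in names(flat)) {
    a <- flat[[nm]]
    d <- if (is.matrix(a)) dim(a) else c(length(a), 1L)
    con <- file(file.path(dir, paste0(nm, ".csv")), "w")
    writeLines(paste0("# shape ", d[1], " ", d[2]), con)
    writeLines(paste(format(as.numeric(a), digits = 17, trim = TRUE),
                     collapse = ","), con)
    close(con)
  }
  hp <- params$hyper
  jsonlite::write_json(c(hp, list(array_names = names(flat))),
                       file.path(dir, "hyperparams.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load model parameters written by [write_model_params()]
#'
#' @param dir Archive directory.
#' @return A `model_params` object.
#' @export
read_model_params <- function(dir) {
  hp <- jsonlite::read_json(file.path(dir, "hyperparams.json"),
                            simplifyVector = TRUE)
  flat <- list()
  for (nm in hp$array_names) {
    lines <- readLines(file.path(dir, paste0(nm, ".csv")))
    d <- as.integer(strsplit(sub("^# shape ", "", lines[1]), " ")[[1]])
    vals <- as.numeric(strsplit(lines[2], ",", fixed = TRUE)[[1]])
    flat[[nm]] <- if (d[2] == 1L && !grepl("\\.W[0-9]$", nm)) {
      vals
    } else {
      matrix(vals, d[1], d[2])
    }
  }
  hp$array_names <- NULL
  unflatten_params(flat, hp)
}
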