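#' Read a cohort of subject input files
#'
#' Reads every regular file in `inputDir` (lexicographic filename
#' order; the filename stem becomes the subject identifier) and parses
#' it according to `inputKind`:
#' \describe{
#'   \item{timeseries}{delimited text, time points in rows and regions
#'     in columns (set `transpose = TRUE` for the opposite layout);
#'     optional header row of region names.}
#'   \item{matrix}{delimited n x n symmetric connectivity matrix,
#'     optional header row of region names.}
#'   \item{edgelist}{three delimited columns node_a, node_b, weight;
#'     the node set is the union of labels, ordered alphabetically.}
#' }
#' The field delimiter (comma or tab/whitespace) is auto-detected per
#' file. Region counts (and names, when present) must agree across
#' subjects; files with no header get generated names `R001..` with a
#' warning when other files do carry headers.
#'
#' @param inputDir directory containing one file per subject.
#' @param inputKind one of `"timeseries"`, `"matrix"`, `"edgelist"`.
#' @param transpose timeseries only: input is regions x time points.
#' @return Named list of [TimeSeriesMatrix-class] or
#'   [WeightedNetwork-class] objects (names are subject ids).
#' @export
readSubjectInputs <- function(inputDir,
                              inputKind = c("timeseries", "matrix", "edgelist"),
                              transpose = FALSE) {
  inputKind <- match.arg(inputKind)
  if (!dir.exists(inputDir)) stop("input directory not found: ", inputDir)
  files <- sort(list.files(inputDir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("input directory is empty: ", inputDir)
  objs <- lapply(files, function(f) {
    tryCatch(
      switch(inputKind,
             timeseries = .readTimeSeriesFile(f, transpose),
             matrix     = .readMatrixFile(f),
             edgelist   = .readEdgeListFile(f)),
      error = function(e) stop("while reading ", basename(f), ": ",
                               conditionMessage(e), call. = FALSE))
  })
  ids <- sub("\\.[^.]*$", "", basename(files))
  names(objs) <- ids
  dims <- vapply(objs, nNodes, integer(1))
  if (length(unique(dims)) > 1L) {
    ref <- as.integer(names(sort(table(dims), decreasing = TRUE))[1L])
    bad <- ids[dims != ref]
    stop("inconsistent region counts across subjects (expected ", ref,
         "): ", paste(bad, collapse = ", "))
  }
  nameSets <- lapply(objs, function(o)
    if (is(o, "TimeSeriesMatrix")) o@regionNames else o@regionNames)
  hasHeader <- !vapply(nameSets, function(nm)
    identical(nm, defaultRegionNames(length(nm))), logical(1))
  if (any(hasHeader) && !all(hasHeader))
    warning("some files lack a region header; generated names were used for: ",
            paste(ids[!hasHeader], collapse = ", "))
  if (sum(hasHeader) > 1L) {
    ref <- nameSets[[which(hasHeader)[1L]]]
    bad <- ids[hasHeader][!vapply(nameSets[hasHeader], identical, logical(1), ref)]
    if (length(bad))
      stop("region names differ across subjects: ", paste(bad, collapse = ", "))
  }
  objs
}

.sniffSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first, fixed = TRUE)) "," else ""
}

.hasHeaderRow <- function(path, sep) {
  first <- readLines(path, n = 1L)
  toks <- if (sep == ",") strsplit(first, ",")[[1]] else strsplit(trimws(first), "[ \t]+")[[1]]
  suppressWarnings(any(is.na(as.numeric(toks))))
}

.readDelim <- function(path) {
  sep <- .sniffSep(path)
  header <- .hasHeaderRow(path, sep)
  df <- read.table(path, header = header, sep = sep, strip.white = TRUE,
                   check.names = FALSE, comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric field in table body")
  list(values = unname(m),
       names = if (header) colnames(df) else NULL)
}

.readTimeSeriesFile <- function(path, transpose = FALSE) {
  p <- .readDelim(path)
  v <- p$values
  nm <- p$names
  if (transpose) v <- t(v)
  TimeSeriesMatrix(v, if (!transpose) nm else NULL)
}

.readMatrixFile <- function(path) {
  p <- .readDelim(path)
  v <- p$values
  if (nrow(v) != ncol(v)) stop("matrix is not square (", nrow(v), " x ", ncol(v), ")")
  WeightedNetwork(v, p$names)
}

.readEdgeListFile <- function(path) {
  sep <- .sniffSep(path)
  df <- read.table(path, header = .hasHeaderRow2(path, sep), sep = sep,
                   strip.white = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) != 3L) stop("edge list must have 3 columns (node_a, node_b, weight)")
  nodes <- sort(unique(c(as.character(df[[1]]), as.character(df[[2]]))))
  n <- length(nodes)
  w <- matrix(0, n, n)
  ia <- match(as.character(df[[1]]), nodes)
  ib <- match(as.character(df[[2]]), nodes)
  wt <- as.numeric(df[[3]])
  if (anyNA(wt)) stop("non-numeric weight in edge list")
  w[cbind(ia, ib)] <- wt
  w[cbind(ib, ia)] <- wt
  WeightedNetwork(w, nodes)
}

# edge lists have string node columns, so numeric-token sniffing on the
# whole line misfires; test only the third column token
.hasHeaderRow2 <- function(path, sep) {
  first <- readLines(path, n = 1L)
  toks <- if (sep == ",") strsplit(first, ",")[[1]] else strsplit(trimws(first), "[ \t]+")[[1]]
  length(toks) == 3L && suppressWarnings(is.na(as.numeric(toks[3L])))
}

#' Read a subject class-label file
#'
#' Two delimited columns (subject_id, class) or a single class column in
#' subject order. Classes are re-coded to 0-based integers in order of
#' first appearance.
#'
#' @param path label file.
#' @param subjectIds subject order to match against (required for the
#'   two-column form).
#' @return Integer vector of 0-based classes, parallel to `subjectIds`.
#' @export
readClassLabels <- function(path, subjectIds = NULL) {
  sep <- .sniffSep(path)
  df <- read.table(path, header = FALSE, sep = sep, strip.white = TRUE,
                   stringsAsFactors = FALSE)
  if (ncol(df) >= 2L) {
    if (is.null(subjectIds)) stop("subjectIds required for (id, class) label files")
    idx <- match(subjectIds, as.character(df[[1]]))
    if (anyNA(idx))
      stop("no class label for subject(s): ",
           paste(subjectIds[is.na(idx)], collapse = ", "))
    cl <- df[[2]][idx]
  } else {
    cl <- df[[1]]
    if (!is.null(subjectIds) && length(cl) != length(subjectIds))
      stop("label count (", length(cl), ") does not match subject count (",
           length(subjectIds), ")")
  }
  as.integer(factor(cl, levels = unique(cl))) - 1L
}

#' Write a numeric matrix as delimited text
#'
#' Tab-delimited, 12 significant digits, optional header row/column of
#' labels; the format [readSubjectInputs()] and [readMatrixText()] read
#' back losslessly at that precision.
#'
#' @param m numeric matrix.
#' @param path output file.
#' @param labels optional row/column labels (header written when given).
#' @export
writeMatrixText <- function(m, path, labels = NULL) {
  m <- as.matrix(m)
  fm <- matrix(formatC(m, format = "g", digits = 12), nrow(m), ncol(m))
  lines <- apply(fm, 1L, paste, collapse = "\t")
  if (!is.null(labels)) lines <- c(paste(labels, collapse = "\t"), lines)
  writeLines(lines, path)
}

#' Read a delimited numeric matrix written by [writeMatrixText()]
#' @param path input file.
#' @return Numeric matrix (labels, when present, as dimnames).
#' @export
readMatrixText <- function(path) {
  p <- .readDelim(path)
  v <- p$values
  if (!is.null(p$names)) dimnames(v) <- list(p$names, p$names)
  v
}

#' Write clustering results, similarity matrices and a run manifest
#'
#' Writes into `outputDir`: `labels.tsv` (subject_id, cluster),
#' `similarity_fused.tsv` / `similarity_attribute.tsv` /
#' `similarity_structure.tsv` for whichever matrices are supplied, and
#' `manifest.txt`, a flat key-value record of all parameters, the seed
#' and the package version — enough to re-run identically.
#'
#' @param result a [ClusteringResult-class].
#' @param matrices named list of [SimilarityMatrix-class] objects
#'   (names among `fused`, `attribute`, `structure`), may be empty.
#' @param config named list of run parameters recorded in the manifest.
#' @param outputDir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeResults <- function(result, matrices = list(), config = list(), outputDir) {
  stopifnot(is(result, "ClusteringResult"))
  if (!length(result@labels)) stop("empty cohort: nothing to write")
  if (!dir.exists(outputDir)) {
    ok <- dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outputDir)) stop("cannot create output directory: ", outputDir)
  }
  paths <- character(0)
  labPath <- file.path(outputDir, "labels.tsv")
  writeLines(paste(result@subjectIds, result@labels, sep = "\t"), labPath)
  paths <- c(paths, labPath)
  for (nm in names(matrices)) {
    sm <- matrices[[nm]]
    stopifnot(is(sm, "SimilarityMatrix"))
    p <- file.path(outputDir, sprintf("similarity_%s.tsv", nm))
    writeMatrixText(sm@values, p, labels = sm@subjectIds)
    paths <- c(paths, p)
  }
  manifest <- c(list(package = "mstClust",
                     version = as.character(utils::packageVersion("mstClust")),
                     clusters = result@m,
                     delta = result@delta, h = result@h, d = result@d,
                     consistency = result@consistency),
                config)
  manPath <- file.path(outputDir, "manifest.txt")
  writeLines(paste(names(manifest),
                   vapply(manifest, function(x) paste(format(x), collapse = ","),
                          character(1)),
                   sep = "\t"), manPath)
  paths <- c(paths, manPath)
  invisible(paths)
}

#' Write a synthetic cohort to disk in the cluster-ready layout
#'
#' One file per subject (connectivity matrix for tree mode, time series
#' for timeseries mode) plus `labels.tsv`, in exactly the formats
#' [readSubjectInputs()] and [readClassLabels()] read.
#'
#' @param cohort result of [plantedTreeCohort()] or
#'   [plantedTimeseriesCohort()].
#' @param outputDir output directory (created if missing).
#' @return Invisibly, the subject directory path.
#' @export
writeCohort <- function(cohort, outputDir) {
  subjDir <- file.path(outputDir, "subjects")
  dir.create(subjDir, recursive = TRUE, showWarnings = FALSE)
  objs <- if (!is.null(cohort$trees)) cohort$trees else cohort$series
  for (i in seq_along(objs)) {
    o <- objs[[i]]
    f <- file.path(subjDir, paste0(cohort$subjectIds[i], ".tsv"))
    if (is(o, "TreeNetwork")) {
      writeMatrixText(o@adjacency, f, labels = o@nodes)
    } else {
      writeMatrixText(o@values, f, labels = o@regionNames)
    }
  }
  writeLines(paste(cohort$subjectIds, cohort$classes, sep = "\t"),
             file.path(outputDir, "labels.tsv"))
  invisible(subjDir)
}
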