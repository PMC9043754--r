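#' Read and write cohorts
#'
#' Subject time series are TSV files, T rows x N numeric columns, with an
#' optional single header row. The manifest is a CSV with header
#' \code{subject_id,path,group}; relative paths are resolved against the
#' manifest's directory. All subjects must parse to the same N.
#'
#' @param manifestPath path to the manifest CSV.
#' @return list of \linkS4class{SubjectTimeSeries} in manifest order.
#' @export
readCohort <- function(manifestPath) {
  man <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "group")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(man$subject_id))
    stop("duplicate subject ids in manifest")
  base <- dirname(normalizePath(manifestPath))
  subjects <- vector("list", nrow(man))
  ncols <- integer(nrow(man))
  for (r in seq_len(nrow(man))) {
    p <- man$path[r]
    if (!file.exists(p)) p <- file.path(base, man$path[r])
    if (!file.exists(p))
      stop("subject ", man$subject_id[r], ": file not found: ", man$path[r])
    X <- readSubjectTSV(p, man$subject_id[r])
    ncols[r] <- ncol(X)
    if (r > 1L && ncols[r] != ncols[1L])
      stop(sprintf("component count mismatch: subject %s has %d, subject %s has %d",
                   man$subject_id[1L], ncols[1L], man$subject_id[r], ncols[r]))
    subjects[[r]] <- SubjectTimeSeries(man$subject_id[r], man$group[r], X)
  }
  subjects
}

readSubjectTSV <- function(path, id) {
  first <- utils::read.delim(path, header = FALSE, nrows = 1L,
                             colClasses = "character")
  hasHeader <- anyNA(suppressWarnings(as.numeric(unlist(first))))
  X <- utils::read.delim(path, header = hasHeader)
  for (j in seq_len(ncol(X))) {
    v <- suppressWarnings(as.numeric(X[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L] + hasHeader
      stop(sprintf("subject %s: non-numeric value at row %d, column %d of %s",
                   id, bad, j, path))
    }
    X[[j]] <- v
  }
  as.matrix(X)
}

#' @rdname readCohort
#' @param subjects list of \linkS4class{SubjectTimeSeries}.
#' @param dir output directory (created if absent).
#' @return \code{writeCohort} returns the manifest path invisibly.
#' @export
writeCohort <- function(subjects, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(subjects, function(s) {
    f <- paste0(s@subjectId, ".tsv")
    utils::write.table(s@data, file.path(dir, f), sep = "\t",
                       row.names = FALSE,
                       col.names = paste0("IC", seq_len(ncol(s@data))))
    data.frame(subject_id = s@subjectId, path = f, group = s@group)
  })
  man <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE)
  invisible(mp)
}

#' Read and write hyperedge lists
#'
#' Plain-text format: a header line \code{#nodes=<M>} (node ids are
#' 1-based), then one line per hyperedge:
#' \code{<seed>\\t<lambda1>\\t<comma-separated node ids>}.
#'
#' @param H a \linkS4class{Hypernetwork}.
#' @param path output file.
#' @export
writeHyperedgeList <- function(H, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#nodes=%d", H@nNodes), con)
  for (e in H@hyperedges) {
    writeLines(sprintf("%d\t%g\t%s", e$seed, e$lambda1,
                       paste(e$nodes, collapse = ",")), con)
  }
  invisible(path)
}

#' @rdname writeHyperedgeList
#' @param subjectId id to store on the read object.
#' @export
readHyperedgeList <- function(path, subjectId = "subject") {
  lines <- readLines(path)
  if (!grepl("^#nodes=\\d+$", lines[1L]))
    stop("missing #nodes= header in ", path)
  M <- as.integer(sub("^#nodes=", "", lines[1L]))
  body <- lines[-1L]
  body <- body[nzchar(body)]
  edges <- lapply(body, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 3L) stop("malformed hyperedge line: ", ln)
    list(nodes = sort(as.integer(strsplit(parts[3L], ",")[[1L]])),
         seed = as.integer(parts[1L]), lambda1 = as.numeric(parts[2L]))
  })
  new("Hypernetwork", nNodes = M, nodeLabels = as.character(seq_len(M)),
      hyperedges = edges, subjectId = subjectId)
}

#' Write a node metric table as TSV
#'
#' @param tb a \code{\link{metricTable}} result.
#' @param path output file.
#' @export
writeMetricTable <- function(tb, path) {
  df <- data.frame(node = rownames(tb$values), tb$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a classification report as JSON
#'
#' The report embeds the configuration echo and the seeds used, so any two
#' artifacts of one run can be cross-checked.
#'
#' @param report result of \code{\link{runPipeline}}.
#' @param path output file.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
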