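# Reading and writing: time-series tables, run manifests, lobe maps,
# tabular result reports. Tables are delimiter-sniffed (comma or tab) and a
# header row is mandatory.

sniffSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("schema error: empty file: ", path)
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_com <- lengths(regmatches(first, gregexpr(",", first)))
  if (n_tab > n_com) "\t" else ","
}

#' Load a parcellated ROI time-series table
#'
#' Reads a delimited text table (comma or tab, sniffed from the header row)
#' whose header holds ROI names and whose rows are time points. Any missing
#' or non-numeric cell is a load error naming the offending row and column.
#'
#' @param path path to the table.
#' @param trSeconds repetition time in seconds (required; never inferred).
#' @param participantId,session,runId run identity recorded on the result.
#' @param manifestEntry optionally, a one-row data.frame with columns
#'   \code{participant_id}, \code{session}, \code{run_id}, \code{tr_seconds}
#'   (and \code{path}, ignored here) supplying all metadata at once.
#' @return A \linkS4class{RoiTimeSeries}.
#' @export
loadTimeSeries <- function(path, trSeconds = NULL, participantId = "p01",
                           session = "pre_op", runId = "r01",
                           manifestEntry = NULL) {
  if (!is.null(manifestEntry)) {
    stopifnot(nrow(manifestEntry) == 1L)
    participantId <- manifestEntry$participant_id
    session <- manifestEntry$session
    runId <- manifestEntry$run_id
    trSeconds <- manifestEntry$tr_seconds
  }
  if (is.null(trSeconds))
    stop("trSeconds is required; the repetition time is never inferred")
  sep <- sniffSep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  if (anyDuplicated(names(tab)))
    stop("schema error: duplicate ROI names in header of ", path)
  if (nrow(tab) < 2L)
    stop("schema error: need at least 2 time points, found ", nrow(tab),
         " in ", path)
  m <- matrix(NA_real_, nrow(tab), ncol(tab),
              dimnames = list(NULL, names(tab)))
  for (j in seq_along(tab)) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("load error: missing or non-numeric value at row %d, column '%s' of %s",
                   bad[1], names(tab)[j], path))
    m[, j] <- v
  }
  RoiTimeSeries(m, trSeconds = trSeconds, participantId = participantId,
                session = session, runId = runId)
}

#' Write a time-series matrix as a CSV table
#'
#' @param run a \linkS4class{RoiTimeSeries}.
#' @param path output path.
#' @export
writeTimeSeries <- function(run, path) {
  df <- as.data.frame(roiData(run), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Validate a run manifest table
#'
#' @param manifest data.frame with columns \code{participant_id},
#'   \code{session}, \code{run_id}, \code{tr_seconds}, \code{path}.
#' @param checkPaths if TRUE, every path must exist.
#' @return the manifest, invisibly, after validation.
#' @export
validateManifest <- function(manifest, checkPaths = FALSE) {
  need <- c("participant_id", "session", "run_id", "tr_seconds", "path")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop("schema error: manifest is missing columns: ",
         paste(miss, collapse = ", "))
  bad <- !manifest$session %in% VALID_SESSIONS
  if (any(bad))
    stop("schema error: invalid session label(s): ",
         paste(unique(manifest$session[bad]), collapse = ", "),
         " (must be pre_op/post_op)")
  key <- manifest[c("participant_id", "session", "run_id")]
  if (anyDuplicated(key))
    stop("schema error: duplicate (participant_id, session, run_id) triples")
  if (any(!is.finite(manifest$tr_seconds)) || any(manifest$tr_seconds <= 0))
    stop("schema error: tr_seconds must be positive")
  if (checkPaths) {
    absent <- !file.exists(manifest$path)
    if (any(absent))
      stop("load error: manifest path(s) not found: ",
           paste(manifest$path[absent], collapse = ", "))
  }
  invisible(manifest)
}

#' Read a run manifest CSV
#'
#' @param path manifest CSV with columns \code{participant_id},
#'   \code{session}, \code{run_id}, \code{tr_seconds}, \code{path}. Relative
#'   time-series paths are resolved against the manifest's directory.
#' @param checkPaths if TRUE (default), every listed path must exist.
#' @return validated manifest data.frame.
#' @export
readManifest <- function(path, checkPaths = TRUE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  validateManifest(m, checkPaths = checkPaths)
  m
}

#' Load every run listed in a manifest
#'
#' @param manifest validated manifest data.frame (see
#'   \code{\link{readManifest}}).
#' @return list of \linkS4class{RoiTimeSeries}, one per manifest row.
#' @export
loadRuns <- function(manifest) {
  validateManifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i)
    loadTimeSeries(manifest$path[i], manifestEntry = manifest[i, ]))
}

#' Load an ROI-to-lobe mapping table
#'
#' Two-column (roi, lobe) delimited table. Lobes are kept in first-appearance
#' order. The package ships a 116-ROI AAL atlas to six-lobe mapping as
#' \code{defaultLobeMap()}.
#'
#' @param path path to the mapping table.
#' @return list with elements \code{roi_to_lobe} (named character vector)
#'   and \code{lobes} (lobe labels in first-appearance order).
#' @export
loadLobeMap <- function(path) {
  sep <- sniffSep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE)
  if (ncol(tab) < 2L || nrow(tab) == 0L)
    stop("schema error: lobe map must be a nonempty two-column (roi, lobe) table")
  roi <- tab[[1]]; lobe <- tab[[2]]
  dup <- duplicated(roi)
  if (any(dup)) {
    conflict <- tapply(lobe, roi, function(x) length(unique(x)) > 1L)
    if (any(conflict))
      stop("schema error: ROI(s) mapped to more than one lobe: ",
           paste(names(conflict)[conflict], collapse = ", "))
    roi <- roi[!dup]; lobe <- lobe[!dup]
  }
  list(roi_to_lobe = setNames(lobe, roi), lobes = unique(lobe))
}

#' Shipped AAL-116 six-lobe mapping
#'
#' The 116 AAL atlas regions grouped into the frontal, occipital, parietal,
#' subcortical, temporal and cerebellum lobes. The grouping follows common
#' anatomical practice (insula, cingulate and basal ganglia/thalamus counted
#' as subcortical; hippocampus, parahippocampus, amygdala and fusiform as
#' temporal); it is shipped as an editable data file, not code.
#'
#' @return a lobe map list as from \code{\link{loadLobeMap}}.
#' @export
defaultLobeMap <- function() {
  loadLobeMap(system.file("extdata", "aal116_lobes.csv",
                          package = "dfcstates", mustWork = TRUE))
}

#' Write a tabular pipeline result
#'
#' Writes a data.frame (or matrix) result as CSV with full double precision,
#' so that \code{readReport(writeReport(x))} round-trips values to at least
#' 12 significant digits.
#'
#' @param results data.frame or matrix.
#' @param path output path.
#' @export
writeReport <- function(results, path) {
  if (is.matrix(results))
    results <- as.data.frame(results, check.names = FALSE)
  if (!is.data.frame(results))
    stop("writeReport handles tabular results (data.frame or matrix)")
  out <- results
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.15g", out[[j]])
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e)
    stop("I/O error: cannot write ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a report written by \code{writeReport}
#'
#' @param path CSV path.
#' @return data.frame with numeric columns restored.
#' @export
readReport <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
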