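## Edge-list I/O: delimited two-column tables, CSV or TSV, UTF-8,
## optional single header row, "#"-prefixed comment lines ignored.

.detectDelimiter <- function(line) if (grepl("\t", line, fixed = TRUE)) "\t" else ","

#' Read a bipartite edge list
#'
#' Reads a delimited two-column edge table (column 1 = part-A identifier,
#' column 2 = part-B identifier) into a \linkS4class{BipartiteNetwork}.
#' The delimiter is auto-detected (tab vs comma) from the first data line
#' unless given.  Lines starting with \code{#} are treated as comments.
#' Duplicate rows are collapsed with a message; a row with a field count other
#' than two is a parse error naming the offending line; an identifier found in
#' both columns is a part-conflict error.  Row order never affects the result.
#'
#' @param source a file path or connection.
#' @param delimiter \code{","}, \code{"\t"}, or \code{NULL} to auto-detect.
#' @param header logical: skip one header row?
#' @return a \code{BipartiteNetwork}.
#' @seealso [writeEdgeTable()]
#' @export
readEdgeTable <- function(source, delimiter = NULL, header = FALSE) {
  lines <- readLines(source, encoding = "UTF-8", warn = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  idx <- which(keep)
  if (header && length(idx)) idx <- idx[-1L]
  if (!length(idx)) stop("no data rows in edge list")
  if (is.null(delimiter)) delimiter <- .detectDelimiter(lines[idx[1L]])
  fields <- strsplit(lines[idx], delimiter, fixed = TRUE)
  nf <- lengths(fields)
  bad <- nf != 2L
  if (!any(bad)) {
    a <- vapply(fields, `[[`, "", 1L)
    b <- vapply(fields, `[[`, "", 2L)
    empty <- !nzchar(trimws(a)) | !nzchar(trimws(b))
    if (any(empty)) bad <- empty
  }
  if (any(bad))
    stop("malformed edge row at line ", idx[which(bad)[1L]],
         ": expected exactly 2 non-empty fields")
  BipartiteNetwork(data.frame(a = a, b = b, stringsAsFactors = FALSE))
}

#' Write a bipartite edge list
#'
#' Writes the network's edges as a delimited two-column table in canonical
#' (sorted) order, the same dialect [readEdgeTable()] reads; round-trip safe.
#'
#' @param x a \code{BipartiteNetwork}.
#' @param path output file path.
#' @param delimiter field separator (default comma).
#' @return \code{path}, invisibly.
#' @export
writeEdgeTable <- function(x, path, delimiter = ",") {
  e <- edgeTable(x)
  writeLines(paste(e$a, e$b, sep = delimiter), con = path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a generator configuration
#'
#' A plain-text \code{key = value} serialization of the synthetic-generator
#' parameters, used as the sidecar provenance file of [cmdSimulate()]; a
#' sidecar re-run reproduces the generated edge list byte-for-byte.
#'
#' @param config a named list of scalar parameters.
#' @param path file path.
#' @return \code{readGeneratorConfig} returns a named list with numeric
#'   values coerced back to numeric.
#' @export
writeGeneratorConfig <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  vals <- vapply(config, function(v)
    format(v, digits = 17, scientific = FALSE, trim = TRUE), "")
  writeLines(paste(names(config), "=", vals), con = path, useBytes = TRUE)
  invisible(path)
}

#' @rdname writeGeneratorConfig
#' @export
readGeneratorConfig <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  pos <- regexpr("=", lines, fixed = TRUE)
  if (any(pos < 0L)) stop("malformed config line in ", path)
  keys <- trimws(substr(lines, 1L, pos - 1L))
  vals <- trimws(substring(lines, pos + 1L))
  if (any(!nzchar(keys))) stop("malformed config line in ", path)
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  names(out) <- keys
  out
}
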