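## Family-by-species profile matrices (binary presence or integer copy
## number), stored as plain integer matrices with a "mode" attribute and
## lexicographically ordered dimnames so that file output is deterministic.

#' Construct a profile matrix
#'
#' @param values numeric matrix, rownames = family ids, colnames = species.
#' @param mode `"presence"` (values 0/1) or `"count"` (non-negative integers).
#' @return an integer matrix of class `profile_matrix` with rows and columns
#'   sorted lexicographically.
#' @export
profile_matrix <- function(values, mode = c("presence", "count")) {
  mode <- match.arg(mode)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("profile matrix needs family rownames and species colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate family id")
  if (anyDuplicated(colnames(values))) stop("duplicate species id")
  if (any(values < 0) || any(values != round(values))) {
    stop("profile values must be non-negative integers")
  }
  if (mode == "presence" && any(values > 1)) stop("presence values must be 0/1")
  m <- values[order(rownames(values)), order(colnames(values)), drop = FALSE]
  storage.mode(m) <- "integer"
  structure(m, mode_flag = mode, class = c("profile_matrix", "matrix", "array"))
}

#' Mode of a profile matrix ("presence" or "count")
#' @param x a profile matrix
#' @export
profile_mode <- function(x) attr(x, "mode_flag")

#' Collapse a count matrix to presence/absence
#' @param x a profile matrix
#' @return a presence-mode profile matrix (count > 0)
#' @export
as_presence <- function(x) {
  m <- unclass(x) > 0
  storage.mode(m) <- "integer"
  profile_matrix(m, "presence")
}

#' Write a profile matrix to TSV
#'
#' First line is a `# mode=` comment, then a header row of species; row and
#' column order is lexicographic, so the file is a canonical form.
#'
#' @param x a profile matrix
#' @param file output path
#' @export
write_profile_matrix <- function(x, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# mode=%s", profile_mode(x)), con)
  writeLines(paste(c("family_id", colnames(x)), collapse = "\t"), con)
  for (i in seq_len(nrow(x))) {
    writeLines(paste(c(rownames(x)[i], unclass(x)[i, ]), collapse = "\t"), con)
  }
  invisible(file)
}

#' Read a profile matrix written by [write_profile_matrix()]
#' @param file TSV path (plain or gzip)
#' @return a profile matrix
#' @export
read_profile_matrix <- function(file) {
  lines <- readLines(gzfile(file))
  mode <- sub("^# mode=", "", lines[1])
  if (!mode %in% c("presence", "count")) stop("missing '# mode=' header")
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  header <- fields[[1]]
  rows <- fields[-1]
  if (anyDuplicated(vapply(rows, `[`, "", 1))) stop("duplicate family id")
  m <- matrix(
    as.integer(unlist(lapply(rows, `[`, -1))),
    nrow = length(rows), byrow = TRUE,
    dimnames = list(vapply(rows, `[`, "", 1), header[-1])
  )
  profile_matrix(m, mode)
}
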