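# Plain-text interchange formats: participants.csv uses the short trait
# codes N,E,O,A,C; in-memory tables use the full factor names. Time series
# are time-major TSVs with a node-label header; connectivity matrices are
# labelled square TSVs. All numeric I/O is locale-independent ('.' decimal,
# full precision repr round-trip).

trait_csv_codes <- function() {
  c(neuroticism = "N", extraversion = "E", openness = "O",
    agreeableness = "A", conscientiousness = "C")
}

participants_csv_header <- function() {
  c("participant_id", "age", "sex", unname(trait_csv_codes()), facet_names())
}

#' Write a participants table
#'
#' @param participants Data frame in the [generate_participants()] layout.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_participants <- function(participants, path) {
  need <- c("participant_id", "age", "sex", trait_names(), facet_names())
  missing <- setdiff(need, names(participants))
  if (length(missing))
    stop_data("participants table lacks columns: ",
              paste(missing, collapse = ", "))
  out <- participants[need]
  names(out) <- participants_csv_header()
  write.table(format(out, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a participants table
#'
#' Parses the `participants.csv` interchange format (short trait codes in
#' the header) back into the in-memory layout with full factor names.
#'
#' @param path CSV path.
#' @return Data frame with `participant_id`, `age`, `sex`, five trait and
#'   four facet columns.
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  missing <- setdiff(participants_csv_header(), names(df))
  if (length(missing))
    stop_data(path, ": missing columns: ", paste(missing, collapse = ", "))
  codes <- trait_csv_codes()
  names(df)[match(unname(codes), names(df))] <- names(codes)
  if (anyDuplicated(df$participant_id))
    stop_data(path, ": duplicate participant_id")
  df
}

#' Write one participant's node time series
#'
#' Tab-separated, time-major: first row the node labels, each further row
#' one timepoint.
#'
#' @param values Node x time numeric matrix with node labels as row names.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_time_series <- function(values, path) {
  if (is.null(rownames(values))) stop_data("time series lacks node labels")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rownames(values), collapse = "\t"), con)
  write.table(format(t(values), digits = 17, trim = TRUE,
                     scientific = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read one participant's node time series
#'
#' @param path TSV path in the [write_time_series()] layout.
#' @return Node x time numeric matrix with node labels as row names.
#' @export
read_time_series <- function(path) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  header <- readLines(path, n = 1L)
  labels <- strsplit(header, "\t", fixed = TRUE)[[1]]
  if (length(labels) < 2 || any(labels == "") ||
      !anyNA(suppressWarnings(as.numeric(labels))))
    stop_data(path, ": line 1: expected a node-label header row")
  body <- tryCatch(
    utils::read.table(path, sep = "\t", skip = 1L, colClasses = "numeric",
                      col.names = labels, check.names = FALSE),
    error = function(e) stop_data(path, ": parse error after header: ",
                                  conditionMessage(e)))
  if (ncol(body) != length(labels))
    stop_data(path, ": row length does not match ", length(labels),
              " node labels")
  if (anyNA(body)) {
    bad <- which(apply(body, 1L, anyNA))[1]
    stop_data(path, ": line ", bad + 1L, ": non-numeric or missing value")
  }
  m <- t(as.matrix(body))
  rownames(m) <- labels
  m
}

#' Write a connectivity matrix
#'
#' Square tab-separated matrix with node labels on both axes, full
#' precision.
#'
#' @param m Symmetric numeric matrix with dimnames.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_connectivity <- function(m, path) {
  if (is.null(rownames(m))) stop_data("connectivity matrix lacks labels")
  df <- data.frame(node = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a connectivity matrix
#'
#' @param path TSV path in the [write_connectivity()] layout.
#' @return Symmetric numeric matrix with node labels as dimnames.
#' @export
read_connectivity <- function(path) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE,
                          colClasses = c(node = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$node
  if (!identical(rownames(m), colnames(m)))
    stop_data(path, ": row and column labels disagree")
  m
}
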