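#' Read a numeric data matrix from CSV/TSV
#'
#' The first row carries column names; a leading column of non-numeric
#' content is auto-detected as row identifiers. The tokens `""`, `"NA"`
#' and `"NaN"` (case-insensitive) mark missing cells. The delimiter is
#' taken from the file extension (`.tsv` / `.txt` = tab) or sniffed from
#' the header line. Parsing is locale-independent (dot decimal separator).
#'
#' @param path Path to a delimited text file.
#' @param delimiter Optional explicit delimiter overriding autodetection.
#' @param missing_tokens Strings treated as missing (case-insensitive).
#' @return A numeric matrix with row and column names; missing cells are
#'   `NA`.
#' @export
read_matrix <- function(path, delimiter = NULL,
                        missing_tokens = c("", "NA", "NaN")) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- readLines(path, n = 1L)
  delimiter <- delimiter %||%
    if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE) ||
        (grepl("\t", header) && !grepl(",", header))) "\t" else ","
  raw <- read.delim(path, sep = delimiter, header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    strip.white = TRUE, na.strings = character())
  if (ncol(raw) < 1L || nrow(raw) < 1L) abort("empty table")
  if (anyDuplicated(names(raw))) {
    abort(paste0("duplicated column name(s): ",
                 toString(unique(names(raw)[duplicated(names(raw))]))))
  }
  tokens <- tolower(missing_tokens)
  parse_col <- function(v) {
    v <- trimws(v)
    out <- rep(NA_real_, length(v))
    keep <- !is.na(v) & !(tolower(v) %in% tokens)
    suppressWarnings(out[keep] <- as.numeric(v[keep]))
    list(values = out, bad = keep & is.na(out))
  }
  first <- parse_col(raw[[1L]])
  rn <- NULL
  # a leading column of non-numeric content -- or carrying the conventional
  # header written by write_matrix() -- holds the row identifiers
  if (ncol(raw) >= 2L &&
      (any(first$bad) || tolower(names(raw)[1L]) == "row")) {
    rn <- trimws(raw[[1L]])
    raw <- raw[, -1L, drop = FALSE]
  }
  cols <- lapply(raw, parse_col)
  for (j in seq_along(cols)) {
    if (any(cols[[j]]$bad)) {
      abort(sprintf("non-numeric cell(s) in column '%s' (row %s)",
                    names(raw)[j], toString(which(cols[[j]]$bad))))
    }
  }
  m <- do.call(cbind, lapply(cols, `[[`, "values"))
  colnames(m) <- names(raw)
  rownames(m) <- rn %||% as.character(seq_len(nrow(m)))
  if (anyDuplicated(rownames(m))) abort("duplicated row identifiers")
  m
}

# full-precision numeric formatting that survives a read round-trip
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a numeric data matrix to CSV/TSV
#'
#' Values are written at full precision (17 significant digits) so a
#' write/read round-trip is bit-exact; missing cells are written as `NA`.
#' The delimiter follows the file extension (`.tsv` / `.txt` = tab).
#'
#' @param x Numeric matrix or data frame.
#' @param path Output path.
#' @param delimiter Optional explicit delimiter.
#' @param row_ids Write the row identifiers as a leading `row` column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, delimiter = NULL, row_ids = TRUE) {
  m <- as_curation_matrix(x)
  delimiter <- delimiter %||%
    if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  body <- apply(m, 1L, function(r) paste(.fmt_num(r), collapse = delimiter))
  hdr <- paste(colnames(m), collapse = delimiter)
  if (row_ids) {
    hdr <- paste("row", hdr, sep = delimiter)
    body <- paste(rownames(m), body, sep = delimiter)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Write a network edge list
#'
#' Writes edges sorted by (source, target) either as a TSV with columns
#' `source`, `target`, `strength`, `direction`, `lag`, or in the SIF
#' format (`source mi target`, one line per edge). An empty network yields
#' a header-only TSV (or an empty SIF file).
#'
#' @param network An `inferred_network` (or edge data frame).
#' @param path Output path.
#' @param format `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(network, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  e <- if (inherits(network, "inferred_network")) network$edges else
    as_network(network)$edges
  e <- e[order(e$source, e$target), , drop = FALSE]
  if (format == "sif") {
    writeLines(if (nrow(e)) paste(e$source, "mi", e$target) else character(),
               path)
    return(invisible(path))
  }
  hdr <- "source\ttarget\tstrength\tdirection\tlag"
  body <- if (nrow(e)) {
    paste(e$source, e$target, .fmt_num(e$strength), e$direction,
          ifelse(is.na(e$lag), "NA", e$lag), sep = "\t")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a network edge list written by [write_edgelist()]
#'
#' @param path Path to a TSV edge list.
#' @return An `inferred_network`.
#' @export
read_edgelist <- function(path) {
  raw <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) {
    return(new_inferred_network(empty_edges(), character()))
  }
  as_network(tibble(
    source = raw$source,
    target = raw$target,
    strength = as.numeric(raw$strength),
    direction = raw$direction,
    lag = suppressWarnings(as.integer(raw$lag))
  ))
}
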