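#' Read a FASTA genome into a named sequence vector
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file and returns the
#' contigs as a named character vector of uppercase DNA strings. Soft-masked
#' (lowercase) bases are folded to uppercase; IUPAC ambiguity codes other than
#' A/C/G/T are collapsed to `N` so that downstream motif counting sees the
#' five-letter alphabet `{A,C,G,T,N}`.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase DNA string per contig, in
#'   file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgtACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  # Biostrings downgrades unknown letters to a warning and drops them;
  # here an illegal character is a hard format error with a line number
  set <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path, format = "fasta"),
      error = function(e) fasta_format_error(path, conditionMessage(e))
    ),
    warning = function(w) {
      if (grepl("invalid one-letter sequence", conditionMessage(w))) {
        fasta_format_error(path, conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    }
  )
  ids <- names(set)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("FASTA format error in '", path, "': empty record header", call. = FALSE)
  }
  # keep only the first whitespace-delimited token of each header
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) {
    stop("FASTA format error in '", path, "': duplicate contig id '",
         ids[duplicated(ids)][1], "'", call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTMRWSYKVHDBN.-]", seqs)
  if (any(bad)) fasta_format_error(path, "illegal character")
  # collapse IUPAC ambiguity codes to N; {A,C,G,T,N} is the working alphabet
  seqs <- gsub("[^ACGT]", "N", seqs)
  names(seqs) <- ids
  seqs
}

# locate the first offending line so format errors are actionable
fasta_format_error <- function(path, parent_msg) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, ">")) next
    bad <- grepl("[^ACGTMRWSYKVHDBNacgtmrwsykvhdbn.-]", ln)
    if (bad) {
      stop("FASTA format error in '", path, "' at line ", i,
           ": illegal character outside the IUPAC alphabet", call. = FALSE)
    }
  }
  if (length(lines) && !startsWith(trimws(lines[1]), ">")) {
    stop("FASTA format error in '", path, "' at line 1: malformed header",
         call. = FALSE)
  }
  stop("FASTA format error in '", path, "': ", parent_msg, call. = FALSE)
}

#' Read a per-CG percent-methylation track
#'
#' Parses a tab-separated methylation track into a tibble of per-site calls.
#' Two dialects are supported:
#' \describe{
#'   \item{`simple5`}{five columns: contig, 0-based position of the C,
#'     strand, percent methylation, read coverage.}
#'   \item{`encode_rrbs`}{BED9+2 as distributed for HAIB RRBS tracks: the
#'     interval start (column 2, already 0-based) is taken as the C position,
#'     strand is column 6, and by default the 11th field carries percent
#'     methylation and the 10th the read count. Both indices are
#'     configurable because the dialect's column semantics vary between
#'     releases.}
#' }
#' Positions are 0-based in both dialects. Rows with coverage 0 are retained;
#' filtering is the curation stage's job.
#'
#' @param path Path to the tab-separated track.
#' @param dialect `"simple5"` or `"encode_rrbs"`.
#' @param percent_col,coverage_col 1-based column indices of the percent
#'   methylation and read-count fields for the `encode_rrbs` dialect.
#' @return A tibble with columns `contig`, `position` (0-based integer),
#'   `strand`, `percent_meth`, `coverage`.
#' @export
read_methylation_track <- function(path,
                                   dialect = c("simple5", "encode_rrbs"),
                                   percent_col = 11L,
                                   coverage_col = 10L) {
  dialect <- tryCatch(match.arg(dialect), error = function(e) {
    stop("unknown methylation-track dialect: ",
         paste(dialect, collapse = "/"), call. = FALSE)
  })
  if (!file.exists(path)) {
    stop("methylation track not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(tibble::tibble(contig = character(), position = integer(),
                          strand = character(), percent_meth = double(),
                          coverage = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_min <- if (dialect == "simple5") 5L else max(6L, percent_col, coverage_col)
  short <- lengths(fields) < n_min
  if (any(short)) {
    stop("track format error in '", path, "' at line ", line_no[short][1],
         ": expected at least ", n_min, " tab-separated fields", call. = FALSE)
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  if (dialect == "simple5") {
    out <- tibble::tibble(
      contig       = col(1),
      position     = parse_int(col(2), path, line_no, "position"),
      strand       = col(3),
      percent_meth = parse_num(col(4), path, line_no, "percent methylation"),
      coverage     = parse_int(col(5), path, line_no, "coverage")
    )
  } else {
    out <- tibble::tibble(
      contig       = col(1),
      position     = parse_int(col(2), path, line_no, "start"),
      strand       = col(6),
      percent_meth = parse_num(col(percent_col), path, line_no,
                               "percent methylation"),
      coverage     = parse_int(col(coverage_col), path, line_no, "read count")
    )
  }
  bad_pct <- out$percent_meth < 0 | out$percent_meth > 100
  if (any(bad_pct)) {
    stop("track value error in '", path, "' at line ", line_no[bad_pct][1],
         ": percent methylation outside [0, 100]", call. = FALSE)
  }
  bad_strand <- !out$strand %in% c("+", "-")
  if (any(bad_strand)) {
    stop("track value error in '", path, "' at line ", line_no[bad_strand][1],
         ": strand must be '+' or '-'", call. = FALSE)
  }
  bad_pos <- out$position < 0
  if (any(bad_pos)) {
    stop("track value error in '", path, "' at line ", line_no[bad_pos][1],
         ": negative position", call. = FALSE)
  }
  out
}

parse_num <- function(x, path, line_no, what) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    stop("track value error in '", path, "' at line ", line_no[is.na(v)][1],
         ": non-numeric ", what, " field", call. = FALSE)
  }
  v
}

parse_int <- function(x, path, line_no, what) {
  v <- parse_num(x, path, line_no, what)
  as.integer(round(v))
}

#' Write / read a labeled feature table
#'
#' Feature tables serialize as plain CSV with a header row: first column
#' `site_id` (`contig:position:strand`), then one column per motif, and an
#' optional trailing integer `label` column (0 = unmethylated,
#' 1 = methylated). The round trip `read_feature_table(write_feature_table(x))`
#' reproduces the table exactly, including row order, column order and
#' integer types.
#'
#' @param features A tibble as produced by [build_dataset()].
#' @param path Output (or input) CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the tibble.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(is.data.frame(features))
  if (anyDuplicated(names(features))) {
    stop("feature table has duplicate column names", call. = FALSE)
  }
  if (names(features)[1] != "site_id") {
    stop("feature table must have 'site_id' as its first column", call. = FALSE)
  }
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    stop("feature table not found: ", path, call. = FALSE)
  }
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", header)
  if (anyDuplicated(header)) {
    stop("feature table format error in '", path,
         "': duplicate column names", call. = FALSE)
  }
  spec <- lapply(header, function(nm) {
    if (nm == "site_id") readr::col_character() else readr::col_guess()
  })
  names(spec) <- header
  out <- readr::read_csv(path, col_types = do.call(readr::cols, spec),
                         progress = FALSE)
  # counts and labels are integers; transformed features may be doubles
  for (nm in setdiff(names(out), "site_id")) {
    v <- out[[nm]]
    if (is.numeric(v) && !is.integer(v) && all(is.finite(v) & v == round(v))) {
      out[[nm]] <- as.integer(v)
    }
  }
  out
}

#' Names of the motif (feature) columns of a feature table
#'
#' @param features A feature tibble.
#' @return Character vector of feature column names (everything except
#'   `site_id` and `label`).
#' @export
feature_columns <- function(features) {
  setdiff(names(features), c("site_id", "label"))
}

# matrix view of the feature columns
feature_matrix <- function(features) {
  cols <- feature_columns(features)
  m <- as.matrix(features[cols])
  storage.mode(m) <- "double"
  rownames(m) <- features$site_id
  m
}
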