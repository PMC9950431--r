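#' @useDynLib knotminer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cophenetic cor dist hclust optimize prcomp qgamma quantile
#'   rbinom runif sd setNames
#' @importFrom utils head read.csv write.csv modifyList
"_PACKAGE"

AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
NUC_ALPHABET <- c("A", "C", "G", "T", "N")

#' Create an amino-acid sequence record
#'
#' A `seq_record` is the unit of data flowing through the pipeline: a peptide
#' (or, via [nuc_record()], nucleotide) sequence with an identifier, free-text
#' description and a provenance tag.
#'
#' @param id Unique identifier (non-empty string).
#' @param residues Uppercase amino-acid string over the 20 standard letters
#'   plus `X` (unknown). No gaps or whitespace.
#' @param description Free-text description.
#' @param source Provenance tag, e.g. `"synthetic"`, `"fixture"`, `"user"`.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, residues, description = "", source = "user") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) {
    stop("seq_record '", id, "': residues must be non-empty")
  }
  bad <- setdiff(strsplit(residues, "")[[1]], c(AA_ALPHABET20, "X"))
  if (length(bad) > 0) {
    stop("seq_record '", id, "': illegal residue character(s): ",
         paste(unique(bad), collapse = ", "))
  }
  structure(
    list(id = id, description = description, residues = residues,
         source = source),
    class = "seq_record"
  )
}

#' Create a nucleotide sequence record
#'
#' @param id Unique identifier.
#' @param residues Uppercase string over A, C, G, T, N.
#' @param description Free-text description.
#' @param source Provenance tag.
#' @return An object of class `nuc_record`.
#' @export
nuc_record <- function(id, residues, description = "", source = "user") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) {
    stop("nuc_record '", id, "': residues must be non-empty")
  }
  bad <- setdiff(strsplit(residues, "")[[1]], NUC_ALPHABET)
  if (length(bad) > 0) {
    stop("nuc_record '", id, "': illegal nucleotide character(s): ",
         paste(unique(bad), collapse = ", "))
  }
  structure(
    list(id = id, description = description, residues = residues,
         source = source),
    class = "nuc_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s> %d aa [%s]%s\n", x$id, nchar(x$residues),
              x$source,
              if (nzchar(x$description)) paste0(" ", x$description) else ""))
  invisible(x)
}

#' @export
print.nuc_record <- function(x, ...) {
  cat(sprintf("<nuc_record %s> %d nt [%s]\n", x$id, nchar(x$residues),
              x$source))
  invisible(x)
}

record_ids <- function(records) vapply(records, function(r) r$id, character(1))

record_lengths <- function(records) {
  vapply(records, function(r) nchar(r$residues), integer(1))
}

check_unique_ids <- function(records) {
  ids <- record_ids(records)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate record id(s): ", paste(dup, collapse = ", "))
  }
  invisible(ids)
}

#' Convert records to a Biostrings AAStringSet
#'
#' @param records List of [seq_record()] objects.
#' @return An [Biostrings::AAStringSet] named by record id.
#' @export
as_aastringset <- function(records) {
  seqs <- vapply(records, function(r) r$residues, character(1))
  Biostrings::AAStringSet(setNames(seqs, record_ids(records)))
}

#' Read a FASTA file into sequence records
#'
#' Parses plain (uncompressed) FASTA. Multi-line sequence bodies are
#' concatenated and record order is preserved. Residues are validated
#' against the amino-acid (or nucleotide) alphabet; an illegal character is
#' reported with the line it occurs on.
#'
#' @param path Path to a FASTA file.
#' @param type `"AA"` (default) for peptide records, `"DNA"` for nucleotide.
#' @param source Provenance tag attached to every record.
#' @return List of [seq_record()] (or [nuc_record()]) objects; empty list for
#'   an empty file.
#' @export
read_fasta <- function(path, type = c("AA", "DNA"), source = "user") {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  # locate headers ourselves so parse errors can name a line number; the
  # heavy lifting of validation stays in seq_record()/nuc_record()
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) return(list())
  is_header <- startsWith(trimws(lines), ">")
  if (!is_header[nonblank[1]]) {
    stop("FASTA parse error at line ", nonblank[1],
         ": expected '>' header before sequence data")
  }
  headers <- which(is_header)
  records <- vector("list", length(headers))
  bounds <- c(headers, length(lines) + 1L)
  ctor <- if (type == "AA") seq_record else nuc_record
  for (k in seq_along(headers)) {
    h <- trimws(sub("^>", "", trimws(lines[headers[k]])))
    id <- sub("\\s.*$", "", h)
    desc <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
    body_lines <- lines[seq.int(bounds[k] + 1L, bounds[k + 1L] - 1L,
                                length.out = max(0L, bounds[k + 1L] - bounds[k] - 1L))]
    body <- gsub("\\s", "", paste(body_lines, collapse = ""))
    if (!nzchar(id)) {
      stop("FASTA parse error at line ", headers[k], ": empty header")
    }
    rec <- tryCatch(ctor(id, body, description = desc, source = source),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      stop("FASTA parse error in record starting at line ", headers[k],
           ": ", conditionMessage(rec))
    }
    records[[k]] <- rec
  }
  check_unique_ids(records)
  records
}

#' Write sequence records to FASTA
#'
#' Deterministic byte output for a fixed input: headers are
#' `>id description` (description omitted when empty) and sequence lines are
#' wrapped at `wrap_width`.
#'
#' @param records List of [seq_record()] / [nuc_record()] objects.
#' @param path Output path.
#' @param wrap_width Positive integer line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap_width = 60L) {
  stopifnot(wrap_width >= 1)
  check_unique_ids(records)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$description)) {
      paste0(">", r$id, " ", r$description)
    } else {
      paste0(">", r$id)
    }
    writeLines(header, con, sep = "\n")
    n <- nchar(r$residues)
    starts <- seq.int(1L, n, by = wrap_width)
    writeLines(substring(r$residues, starts,
                         pmin(starts + wrap_width - 1L, n)), con, sep = "\n")
  }
  invisible(path)
}
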