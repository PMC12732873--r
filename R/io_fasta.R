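#' Read labeled promoter sequences from FASTA
#'
#' Reads a plain FASTA file (single-line or wrapped sequences) and assembles a
#' [promoter_dataset()]. Labels are taken either from the header dialect
#' `>id|stage1|stage2` (missing labels written as `.`) or from a separate
#' tab-separated table with columns `id`, `stage1`, `stage2`.
#'
#' Sequences are uppercased, then validated: every record must be exactly
#' `seq_length` nucleotides of A/C/G/T. Ambiguity codes such as `N` are
#' rejected with the record id and offending position, not imputed, because
#' the downstream encodings are defined only for the four bases.
#'
#' @param path path to a FASTA file.
#' @param label_source `"header"` to parse `id|stage1|stage2` headers,
#'   `"table"` to join labels from `label_table`, `"none"` to leave labels
#'   unset.
#' @param label_table path to a TSV with header row `id<TAB>stage1<TAB>stage2`
#'   (required when `label_source = "table"`).
#' @param seq_length expected sequence length (default 81); `NULL` accepts
#'   the length of the first record as the common length.
#' @return a [promoter_dataset()] preserving the input record order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, label_source = c("header", "table", "none"),
                       label_table = NULL, seq_length = 81L) {
  label_source <- match.arg(label_source)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(trimws(first), ">")) {
    stop("malformed FASTA '", path, "': first line is not a '>' header")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  headers <- names(set)
  seqs <- toupper(as.character(set))
  if (length(seqs) == 0L) stop("FASTA '", path, "' contains no records")
  if (is.null(seq_length)) seq_length <- nchar(seqs[1])

  if (label_source == "header") {
    parts <- strsplit(headers, "|", fixed = TRUE)
    id <- vapply(parts, `[`, "", 1L)
    s1 <- vapply(parts, function(p) if (length(p) >= 2) p[2] else ".", "")
    s2 <- vapply(parts, function(p) if (length(p) >= 3) p[3] else ".", "")
    s1[s1 %in% c(".", "", "unknown", "NA")] <- NA
    s2[s2 %in% c(".", "", "unknown", "NA")] <- NA
  } else {
    id <- vapply(strsplit(headers, "[| \t]"), `[`, "", 1L)
    s1 <- s2 <- rep(NA_character_, length(id))
    if (label_source == "table") {
      if (is.null(label_table)) stop("label_source = 'table' requires 'label_table'")
      tab <- utils::read.delim(label_table, stringsAsFactors = FALSE)
      need <- c("id", "stage1", "stage2")
      if (!all(need %in% names(tab))) {
        stop("label table must have columns id, stage1, stage2")
      }
      m <- match(id, tab$id)
      if (anyNA(m)) {
        stop("no label-table entry for record '", id[which(is.na(m))[1]], "'")
      }
      s1 <- as.character(tab$stage1[m]); s1[s1 %in% c(".", "")] <- NA
      s2 <- as.character(tab$stage2[m]); s2[s2 %in% c(".", "")] <- NA
    }
  }
  promoter_dataset(id, seqs, s1, s2, seq_length = seq_length)
}

#' Write a promoter dataset to FASTA
#'
#' Writes single-line FASTA with the label dialect `>id|stage1|stage2`,
#' unknown labels serialized as `.`, so that `read_fasta()` round-trips ids,
#' sequences and both label stages exactly.
#'
#' @param ds a non-empty [promoter_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ds, path) {
  validate_dataset(ds)
  if (nrow(ds) == 0L) stop("refusing to write an empty dataset")
  dot <- function(x) ifelse(is.na(x), ".", x)
  lines <- as.vector(rbind(
    sprintf(">%s|%s|%s", ds$id, dot(ds$stage1), dot(ds$stage2)),
    ds$seq
  ))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing", call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a stage-label table
#'
#' Companion TSV (`id`, `stage1`, `stage2`) for the `label_source = "table"`
#' input path of [read_fasta()].
#'
#' @param ds a [promoter_dataset()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(ds, path) {
  validate_dataset(ds)
  tab <- data.frame(id = ds$id,
                    stage1 = ifelse(is.na(ds$stage1), ".", ds$stage1),
                    stage2 = ifelse(is.na(ds$stage2), ".", ds$stage2))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
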