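#' Labeled promoter sequence dataset
#'
#' A `promoter_dataset` is a data frame with one row per sequence and columns
#' `id`, `seq`, `stage1` and `stage2`. `stage1` holds the promoter /
#' non-promoter call (`"promoter"`, `"non_promoter"` or `NA` when unknown);
#' `stage2` holds the strength call (`"strong"`, `"weak"` or `NA`) and may be
#' set only for records whose `stage1` is `"promoter"`. All sequences are
#' uppercase ACGT strings of a common fixed length (81 nt by default, the
#' window length used for bacterial promoter benchmarks).
#'
#' @param id character vector of record identifiers.
#' @param seq character vector of DNA sequences (A/C/G/T, case-insensitive).
#' @param stage1 promoter / non-promoter labels, or `NA`.
#' @param stage2 strong / weak labels for promoters, or `NA`.
#' @param seq_length expected common sequence length; every record is
#'   validated against it.
#' @return an object of class `promoter_dataset` (a data frame).
#' @examples
#' ds <- promoter_dataset(c("s1", "s2"),
#'                        c(strrep("ACGT", 5), strrep("TTAA", 5)),
#'                        c("promoter", "non_promoter"),
#'                        c("strong", NA), seq_length = 20)
#' nrow(ds)
#' @export
promoter_dataset <- function(id, seq, stage1 = NA, stage2 = NA,
                             seq_length = 81L) {
  n <- length(seq)
  ds <- data.frame(
    id = as.character(id),
    seq = toupper(as.character(seq)),
    stage1 = rep_len(as.character(stage1), n),
    stage2 = rep_len(as.character(stage2), n),
    stringsAsFactors = FALSE
  )
  class(ds) <- c("promoter_dataset", "data.frame")
  attr(ds, "seq_length") <- as.integer(seq_length)
  validate_dataset(ds)
  ds
}

#' Validate a promoter dataset
#'
#' Checks the container invariants: sequences contain only A/C/G/T, share the
#' expected length, labels come from the allowed vocabularies, and strength
#' labels are present only on promoter records. Called by every constructor
#' and reader; exported so user-assembled data frames can be checked too.
#'
#' @param ds a `promoter_dataset`.
#' @return `ds`, invisibly, if valid; otherwise an error describing the first
#'   offending record (id and position for alphabet violations).
#' @export
validate_dataset <- function(ds) {
  stopifnot(is.data.frame(ds))
  expected <- attr(ds, "seq_length")
  if (is.null(expected)) expected <- nchar(ds$seq[1])
  if (anyDuplicated(ds$id)) {
    stop("duplicate record ids: ", ds$id[anyDuplicated(ds$id)])
  }
  bad_len <- which(nchar(ds$seq) != expected)
  if (length(bad_len)) {
    stop(sprintf("record '%s' has length %d, expected %d",
                 ds$id[bad_len[1]], nchar(ds$seq[bad_len[1]]), expected))
  }
  for (i in seq_len(nrow(ds))) {
    pos <- regexpr("[^ACGT]", ds$seq[i])
    if (pos > 0) {
      stop(sprintf(
        "record '%s' contains invalid symbol '%s' at position %d (only A/C/G/T allowed)",
        ds$id[i], substr(ds$seq[i], pos, pos), pos))
    }
  }
  ok1 <- is.na(ds$stage1) | ds$stage1 %in% c("promoter", "non_promoter")
  if (!all(ok1)) {
    stop("invalid stage-1 label '", ds$stage1[which(!ok1)[1]],
         "' for record '", ds$id[which(!ok1)[1]], "'")
  }
  ok2 <- is.na(ds$stage2) | ds$stage2 %in% c("strong", "weak")
  if (!all(ok2)) {
    stop("invalid stage-2 label '", ds$stage2[which(!ok2)[1]],
         "' for record '", ds$id[which(!ok2)[1]], "'")
  }
  misplaced <- !is.na(ds$stage2) & (is.na(ds$stage1) | ds$stage1 != "promoter")
  if (any(misplaced)) {
    stop("record '", ds$id[which(misplaced)[1]],
         "' has a strength label but is not labeled as a promoter")
  }
  invisible(ds)
}

#' @export
print.promoter_dataset <- function(x, ...) {
  cat(sprintf("promoter_dataset: %d sequences of length %d nt\n",
              nrow(x), attr(x, "seq_length")))
  t1 <- table(factor(x$stage1, c("promoter", "non_promoter")), useNA = "ifany")
  cat("  stage 1:", paste(names(t1), t1, sep = "=", collapse = ", "), "\n")
  if (any(!is.na(x$stage2))) {
    t2 <- table(factor(x$stage2, c("strong", "weak")))
    cat("  stage 2:", paste(names(t2), t2, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# subsetting keeps the class and the expected-length attribute
#' @export
`[.promoter_dataset` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    class(out) <- c("promoter_dataset", "data.frame")
    attr(out, "seq_length") <- attr(x, "seq_length")
  }
  out
}
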