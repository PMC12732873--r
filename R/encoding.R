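#' Sequence encodings: one-hot, NCP and their hybrid
#'
#' Three per-position numeric representations of an ACGT string:
#'
#' * one-hot — each base as a 4-dimensional standard basis vector, columns
#'   ordered A, T, C, G: A=(1,0,0,0), T=(0,1,0,0), C=(0,0,1,0), G=(0,0,0,1).
#' * NCP (nucleotide chemical property) — three indicators per base: ring
#'   structure (purine A/G = 1), functional group (amino A/C = 1) and
#'   hydrogen-bond strength (two bonds A/T = 1), so A=(1,1,1), C=(0,1,0),
#'   G=(1,0,0), T=(0,0,1).
#' * hybrid — the column-wise concatenation `[one-hot | NCP]`, n rows by 7
#'   columns, carrying both positional identity and chemistry per base.
#'
#' @param seq a non-empty ACGT string (case-insensitive).
#' @return a numeric matrix with one row per position, of class
#'   `encoded_matrix` with attribute `scheme`.
#' @examples
#' encode_one_hot("ATCG")
#' encode_hybrid("A")        # (1,0,0,0, 1,1,1)
#' @export
encode_one_hot <- function(seq) {
  idx <- seq_to_index(seq)
  map <- matrix(c(1, 0, 0, 0,
                  0, 0, 1, 0,   # C
                  0, 0, 0, 1,   # G
                  0, 1, 0, 0),  # T
                nrow = 4, byrow = TRUE,
                dimnames = list(c("A", "C", "G", "T"), c("A", "T", "C", "G")))
  out <- map[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, scheme = "one_hot", class = c("encoded_matrix", "matrix", "array"))
}

#' @rdname encode_one_hot
#' @export
encode_ncp <- function(seq) {
  idx <- seq_to_index(seq)
  map <- matrix(c(1, 1, 1,   # A: purine, amino, 2 H-bonds
                  0, 1, 0,   # C
                  1, 0, 0,   # G
                  0, 0, 1),  # T
                nrow = 4, byrow = TRUE,
                dimnames = list(c("A", "C", "G", "T"), c("ring", "func", "hbond")))
  out <- map[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, scheme = "ncp", class = c("encoded_matrix", "matrix", "array"))
}

#' @rdname encode_one_hot
#' @export
encode_hybrid <- function(seq) {
  out <- cbind(unclass(encode_one_hot(seq)), unclass(encode_ncp(seq)))
  structure(out, scheme = "hybrid", class = c("encoded_matrix", "matrix", "array"))
}

#' Recover the sequence from a hybrid or one-hot encoding
#'
#' Inverts the one-hot block by arg-max, the exact inverse of
#' [encode_one_hot()] / [encode_hybrid()].
#'
#' @param mat an `encoded_matrix` (scheme `one_hot` or `hybrid`).
#' @return the ACGT string.
#' @export
decode_sequence <- function(mat) {
  scheme <- attr(mat, "scheme")
  if (is.null(scheme) || !scheme %in% c("one_hot", "hybrid")) {
    stop("decoding requires a one_hot or hybrid encoded matrix")
  }
  oh <- unclass(mat)[, 1:4, drop = FALSE]
  bases <- c("A", "T", "C", "G")[max.col(oh, ties.method = "first")]
  paste(bases, collapse = "")
}

#' Encode every sequence of a dataset
#'
#' Stacks per-sequence hybrid encodings into a 3-dimensional array
#' (records x positions x 7 channels), the input tensor of the model.
#'
#' @param ds a [promoter_dataset()] (or character vector of equal-length
#'   sequences).
#' @return numeric array `c(n_records, seq_length, 7)`.
#' @export
encode_dataset <- function(ds) {
  seqs <- if (is.data.frame(ds)) ds$seq else as.character(ds)
  n <- length(seqs)
  L <- nchar(seqs[1])
  out <- array(0, c(n, L, 7L))
  for (i in seq_len(n)) out[i, , ] <- encode_hybrid(seqs[i])
  out
}

# map an ACGT string to integer codes 1..4 (A,C,G,T), validating the alphabet
seq_to_index <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("cannot encode an empty sequence")
  chars <- strsplit(toupper(seq), "")[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1]
    stop(sprintf("invalid symbol '%s' at position %d (only A/C/G/T supported)",
                 chars[p], p))
  }
  idx
}
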