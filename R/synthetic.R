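#' Simulate promoter-like labeled sequences
#'
#' Seeded generator of fixed-length ACGT datasets with planted motifs, used
#' to exercise every stage of the pipeline without external data. Positives
#' ("promoters") carry the consensus motif (default `TATAAT`, the sigma-70
#' -10 box) at a fixed window position, with independent per-base mutation
#' noise at rate `mutation_rate`. Negatives are pure i.i.d. background.
#' Within the positives, strong promoters additionally receive
#' `strength_dose` copies of the strength motif (default `TTGACA`, the -35
#' box consensus) planted at random non-overlapping positions, while weak
#' promoters receive none, so promoter strength is dosage-controlled.
#'
#' Defaults mirror an 81-nt window centred on a bacterial transcription
#' start site: with the TSS at position 61 the -10 element occupies
#' positions 51-56, which is the default `motif_position`.
#'
#' @param n_per_class sequences per stage-1 class (positives are split
#'   half strong, half weak).
#' @param seq_length sequence length in nt (default 81).
#' @param motif consensus motif planted in every positive.
#' @param motif_position 1-based start of the planted motif, or `"random"`
#'   for a uniform random window per sequence.
#' @param mutation_rate per-base probability that a planted motif base is
#'   replaced by a different random base, in `[0, 1]`.
#' @param strength_motif motif whose dosage separates strong from weak.
#' @param strength_dose number of extra strength-motif copies planted in
#'   strong positives (weak positives receive none).
#' @param background per-base probabilities for A, C, G, T (default
#'   uniform).
#' @param seed RNG seed; identical seeds give byte-identical datasets.
#' @return a fully labeled [promoter_dataset()] with `2 * n_per_class`
#'   records.
#' @examples
#' ds <- simulate_promoters(10, mutation_rate = 0, seed = 1)
#' table(ds$stage1)
#' @export
simulate_promoters <- function(n_per_class, seq_length = 81L,
                               motif = "TATAAT", motif_position = 51L,
                               mutation_rate = 0.1,
                               strength_motif = "TTGACA",
                               strength_dose = 2L,
                               background = c(0.25, 0.25, 0.25, 0.25),
                               seed = 1L) {
  bases <- c("A", "C", "G", "T")
  motif <- toupper(motif); strength_motif <- toupper(strength_motif)
  if (nchar(motif) > seq_length || nchar(strength_motif) > seq_length) {
    stop("motif longer than the sequence")
  }
  if (!grepl("^[ACGT]+$", motif) || !grepl("^[ACGT]+$", strength_motif)) {
    stop("motifs must be ACGT strings")
  }
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must be in [0, 1]")
  }
  random_pos <- identical(motif_position, "random")
  if (!random_pos) {
    motif_position <- as.integer(motif_position)
    if (motif_position < 1L || motif_position + nchar(motif) - 1L > seq_length) {
      stop("motif does not fit at position ", motif_position)
    }
  }
  set.seed(seed)
  background <- background / sum(background)
  rand_seq <- function() sample(bases, seq_length, TRUE, prob = background)

  mutate <- function(chars) {
    hit <- stats::runif(length(chars)) < mutation_rate
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit],
                           function(b) sample(setdiff(bases, b), 1L), "")
    }
    chars
  }

  mlen <- nchar(motif); slen <- nchar(strength_motif)
  mchars <- strsplit(motif, "")[[1]]
  schars <- strsplit(strength_motif, "")[[1]]

  make_positive <- function(strong) {
    s <- rand_seq()
    pos <- if (random_pos) sample.int(seq_length - mlen + 1L, 1L) else motif_position
    s[pos:(pos + mlen - 1L)] <- mutate(mchars)
    occupied <- pos:(pos + mlen - 1L)
    if (strong && strength_dose > 0L) {
      placed <- 0L
      tries <- 0L
      while (placed < strength_dose && tries < 200L) {
        tries <- tries + 1L
        sp <- sample.int(seq_length - slen + 1L, 1L)
        span <- sp:(sp + slen - 1L)
        if (!any(span %in% occupied)) {
          s[span] <- mutate(schars)
          occupied <- c(occupied, span)
          placed <- placed + 1L
        }
      }
      if (placed < strength_dose) {
        stop("could not place ", strength_dose,
             " non-overlapping strength motifs in ", seq_length, " nt")
      }
    }
    paste(s, collapse = "")
  }

  n_strong <- ceiling(n_per_class / 2)
  n_weak <- n_per_class - n_strong
  pos_seqs <- c(vapply(seq_len(n_strong), function(i) make_positive(TRUE), ""),
                vapply(seq_len(n_weak), function(i) make_positive(FALSE), ""))
  neg_seqs <- vapply(seq_len(n_per_class),
                     function(i) paste(rand_seq(), collapse = ""), "")

  promoter_dataset(
    id = c(sprintf("pos_%04d", seq_len(n_per_class)),
           sprintf("neg_%04d", seq_len(n_per_class))),
    seq = c(pos_seqs, neg_seqs),
    stage1 = rep(c("promoter", "non_promoter"), each = n_per_class),
    stage2 = c(rep("strong", n_strong), rep("weak", n_weak),
               rep(NA_character_, n_per_class)),
    seq_length = seq_length
  )
}
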