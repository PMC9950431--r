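#' Translate a transcript to candidate open reading frames
#'
#' Scans all six reading frames and emits every maximal stop-free stretch of
#' codons (stop-to-stop; no initiator methionine is required and sequence
#' ends count as open boundaries) of at least `min_len` amino acids. Codons
#' containing `N` translate to `X`. Frames are named `+1,+2,+3` on the given
#' strand and `-1,-2,-3` on the reverse complement; ORF ids encode the parent
#' id, frame, and 1-based inclusive coordinates on the forward strand of the
#' parent.
#'
#' @param nuc A [nuc_record()].
#' @param min_len Minimum ORF length in amino acids (default 40, the usual
#'   cutoff for candidate venom-peptide ORFs).
#' @return List of [seq_record()] objects; empty when the record is shorter
#'   than one codon or no ORF reaches `min_len`.
#' @export
translate_orfs <- function(nuc, min_len = 40L) {
  stopifnot(inherits(nuc, "nuc_record"), min_len >= 1)
  n <- nchar(nuc$residues)
  if (n < 3L) return(list())
  fwd <- Biostrings::DNAString(nuc$residues)
  rev <- Biostrings::reverseComplement(fwd)
  out <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) fwd else rev
    for (off in 0:2) {
      frame <- strand * (off + 1L)
      len <- length(s) - off
      n_codon <- len %/% 3L
      if (n_codon < 1L) next
      aa <- as.character(Biostrings::translate(
        Biostrings::subseq(s, start = off + 1L, width = n_codon * 3L),
        if.fuzzy.codon = "X", no.init.codon = TRUE))
      aa <- chartr("*", "#", aa) # '#' as a split-safe stop marker
      pieces <- strsplit(aa, "#", fixed = TRUE)[[1]]
      pos <- 1L # codon index within frame (1-based)
      for (p in pieces) {
        w <- nchar(p)
        if (w >= min_len) {
          # codon positions pos..pos+w-1 within this frame
          nt_start <- off + (pos - 1L) * 3L + 1L
          nt_end <- off + (pos + w - 1L) * 3L
          if (strand == 1L) {
            fwd_start <- nt_start
            fwd_end <- nt_end
          } else {
            fwd_start <- n - nt_end + 1L
            fwd_end <- n - nt_start + 1L
          }
          id <- sprintf("%s|f%+d|%d-%d", nuc$id, frame, fwd_start, fwd_end)
          out[[length(out) + 1L]] <- seq_record(
            id, p,
            description = sprintf("ORF frame %+d of %s", frame, nuc$id),
            source = nuc$source)
        }
        pos <- pos + w + 1L
      }
    }
  }
  out
}
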