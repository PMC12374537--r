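#' Glocal pairwise alignment of two nucleotide sequences
#'
#' Global alignment with free (and unreported) terminal gaps, the behaviour of
#' BLAST-like tools on mostly-collinear genes. Scoring is match +1, mismatch
#' -1, gap -2 (linear). Identity counts internal gap columns as mismatches and
#' excludes terminal gaps from the alignment length; columns involving a
#' non-ACGT character (e.g. N) count as mismatches. The result is symmetric in
#' its arguments.
#'
#' @param seq_a,seq_b Non-empty nucleotide strings.
#' @param band Optional half-width of the alignment band beyond the diagonal
#'   offset implied by the length difference. `NULL` (default) computes the
#'   full dynamic-programming matrix.
#' @return A one-row tibble with `identity` (percent), `aln_len`,
#'   `mismatches` and `score`.
#' @examples
#' align_pair("ATGAAACCC", "ATGAAACCG")  # 8/9 identity
#' align_pair("ATGAAA", "ATGAAATTT")     # 100% over 6 aligned columns
#' @export
align_pair <- function(seq_a, seq_b, band = NULL) {
  if (!is.character(seq_a) || !is.character(seq_b) ||
      length(seq_a) != 1L || length(seq_b) != 1L) {
    rb_abort("align_pair expects two single sequences")
  }
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) rb_abort("empty sequence")
  if (is.null(band)) band <- max(nchar(seq_a), nchar(seq_b))
  res <- align_pair_cpp(seq_a, seq_b, as.integer(band))
  tibble::tibble(identity = res$identity, aln_len = res$aln_len,
                 mismatches = res$mismatches, score = res$score)
}
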