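#' Reciprocal best matches between two genomes
#'
#' Aligns genes of genome `a` against genes of genome `b` and reports every
#' reciprocal best match (RBM): a gene pair in which each member is the
#' other's highest-identity hit at or above an identity floor, covering at
#' least `min_cov` of the shorter gene. Best-hit ties are broken by longer
#' alignment, then lexicographic gene id, so the result is deterministic.
#'
#' Candidate hits are found with a shared k-mer prefilter and then aligned
#' with the banded glocal aligner; queries that share no k-mer with the other
#' gene set (or are shorter than `3 * k`) fall back to all-vs-all alignment,
#' so the output equals the brute-force all-vs-all argmax for any realistic
#' input (asserted against a brute-force oracle in the package tests).
#'
#' @param genes Gene tibble (see [read_gene_fasta()]) holding both genomes,
#'   or a `genome_set`.
#' @param genome_a,genome_b Genome ids to compare.
#' @param id_floor Minimum percent identity for a hit (default 70).
#' @param min_cov Minimum alignment coverage of the shorter gene (default 0.5).
#' @param k Prefilter k-mer size.
#' @param band_extra,band_frac Banding of the bulk aligner: the band half-width
#'   is `band_extra + band_frac * max(length)` beyond the length difference.
#' @param prefilter Set to `FALSE` to force all-vs-all alignment.
#' @param min_kmer_hits Minimum shared k-mer count for a candidate; a
#'   homolog at the identity floor shares far more (about 17 at 70%
#'   identity for a 900-bp gene), so this only discards sub-floor noise.
#' @param gapless_tau Equal-length pairs whose ungapped identity is at least
#'   this percent are reported without gap search (indel-bearing pairs fall
#'   far below it and take the full dynamic programme); set above 100 to
#'   disable.
#' @return A tibble with one row per RBM: `genome_a`, `genome_b`, `gene_a`,
#'   `gene_b`, `identity`, `aln_len`, `mismatches`.
#' @export
rbm_pair <- function(genes, genome_a, genome_b,
                     id_floor = 70, min_cov = 0.5, k = 11,
                     band_extra = 50, band_frac = 0.02,
                     prefilter = TRUE, min_kmer_hits = 8, gapless_tau = 97) {
  if (inherits(genes, "genome_set")) genes <- genes$genes
  assert_cols(genes, c("gene_id", "genome_id", "seq"), "genes")
  ga <- dplyr::filter(genes, .data$genome_id == genome_a)
  gb <- dplyr::filter(genes, .data$genome_id == genome_b)
  if (nrow(ga) == 0 || nrow(gb) == 0) {
    rb_abort(paste0("no genes for genome ", if (nrow(ga) == 0) genome_a else genome_b))
  }
  hits <- rbm_engine_cpp(ga$seq, gb$seq, ga$gene_id, gb$gene_id,
                         as.integer(k), id_floor, min_cov,
                         as.integer(band_extra), band_frac,
                         prefilter, 0.2, as.integer(min_kmer_hits), gapless_tau)
  tibble::tibble(
    genome_a = genome_a, genome_b = genome_b,
    gene_a = ga$gene_id[hits$idx_a], gene_b = gb$gene_id[hits$idx_b],
    identity = hits$identity, aln_len = hits$aln_len, mismatches = hits$mismatches
  )
}

#' All-vs-all reciprocal best matches
#'
#' Runs [rbm_pair()] for every unordered genome pair in the gene table.
#'
#' @inheritParams rbm_pair
#' @param verbose Print one line per genome pair.
#' @return A tibble of RBM rows for all genome pairs, with `genome_a` <
#'   `genome_b` lexicographically.
#' @export
rbm_all_pairs <- function(genes, id_floor = 70, min_cov = 0.5, k = 11,
                          band_extra = 50, band_frac = 0.02,
                          prefilter = TRUE, min_kmer_hits = 8, gapless_tau = 97,
                          verbose = FALSE) {
  if (inherits(genes, "genome_set")) genes <- genes$genes
  ids <- sort(unique(genes$genome_id))
  if (length(ids) < 2) rb_abort("need at least two genomes")
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  purrr::map(pairs, function(p) {
    if (verbose) message("RBM ", p[1], " vs ", p[2])
    rbm_pair(genes, p[1], p[2], id_floor = id_floor, min_cov = min_cov, k = k,
             band_extra = band_extra, band_frac = band_frac, prefilter = prefilter,
             min_kmer_hits = min_kmer_hits, gapless_tau = gapless_tau)
  }) |>
    dplyr::bind_rows()
}

#' Gene-based average nucleotide identity from RBM identities
#'
#' ANI is the arithmetic mean RBM identity after dropping RBMs below the
#' reporting floor (low-identity hits are unreliable). Fewer than `min_rbm`
#' qualifying RBMs yields `NA` (undefined ANI), the behaviour needed for
#' incomplete, SAG-like genomes.
#'
#' @param identities Numeric vector of RBM percent identities for one genome
#'   pair.
#' @param floor Reporting floor in percent identity (default 75).
#' @param min_rbm Minimum number of qualifying RBMs (default 50).
#' @return Scalar percent ANI, or `NA_real_` when undefined.
#' @examples
#' compute_ani(c(96, 94), min_rbm = 1)  # 95
#' compute_ani(c(95, 95, 60), min_rbm = 1)  # 95, the 60 is below the floor
#' @export
compute_ani <- function(identities, floor = 75, min_rbm = 50) {
  keep <- identities[!is.na(identities) & identities >= floor]
  if (length(keep) < min_rbm) return(NA_real_)
  mean(keep)
}

#' Per-pair summary: ANI, F100 and the recombination excess test
#'
#' Collapses an RBM table into one row per genome pair with gene-based ANI,
#' RBM count, observed F100, its no-recombination null expectation at the
#' pair's ANI, and a one-sided exact binomial p-value for excess identical
#' genes.
#'
#' @param rbms RBM tibble from [rbm_all_pairs()].
#' @param params Null-model parameters from [null_model_params()].
#' @param ani_floor,min_rbm Passed to [compute_ani()].
#' @param f100_tau Identity threshold (percent) for the F100 numerator.
#' @return Tibble with columns `genome_a`, `genome_b`, `ani`, `n_rbm`,
#'   `f100_observed`, `f100_expected`, `p_excess`.
#' @export
pairwise_summary <- function(rbms, params = null_model_params(),
                             ani_floor = 75, min_rbm = 50, f100_tau = 100) {
  assert_cols(rbms, c("genome_a", "genome_b", "identity"), "rbms")
  rbms |>
    dplyr::group_by(.data$genome_a, .data$genome_b) |>
    dplyr::summarise(
      ani = compute_ani(.data$identity, floor = ani_floor, min_rbm = min_rbm),
      n_rbm = dplyr::n(),
      k_identical = sum(.data$identity >= f100_tau),
      f100_observed = k_identical / n_rbm,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      f100_expected = ifelse(is.na(.data$ani), NA_real_,
                             expected_f100(.data$ani, params, tau = f100_tau)),
      p_excess = purrr::pmap_dbl(
        list(.data$k_identical, .data$n_rbm, .data$f100_expected),
        function(k, n, e) if (is.na(e)) NA_real_ else f100_excess_test(k, n, e))
    ) |>
    dplyr::select(-"k_identical")
}
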