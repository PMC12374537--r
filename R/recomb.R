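#' Flag constraint-conserved gene families
#'
#' Genes under strong functional constraint (rRNA-like) stay near-identical
#' even between species and must not be mistaken for recent exchange. A
#' family is flagged when its RBM identity is at least `ident_tau` in at
#' least `min_frac` of the genome pairs below the species ANI floor. When the
#' collection contains no inter-species pair the filter is inactive: an empty
#' set is returned with a warning.
#'
#' @param families Family membership tibble from [build_gene_families()].
#' @param rbms RBM table over all pairs.
#' @param pairwise Per-pair summary with ANI.
#' @param species_floor Percent ANI below which a pair counts as
#'   inter-species (default 91).
#' @param ident_tau Near-identity threshold in percent (default 99.8).
#' @param min_frac Minimum fraction of inter-species pairs at near-identity.
#' @return Character vector of flagged `family_id`s.
#' @export
flag_constraint_conserved <- function(families, rbms, pairwise,
                                      species_floor = 91, ident_tau = 99.8,
                                      min_frac = 0.5) {
  fam_map <- setNames(families$family_id, paste(families$genome_id, families$gene_id))
  ani_map <- setNames(pairwise$ani, pair_key(pairwise$genome_a, pairwise$genome_b))
  rows <- rbms |>
    dplyr::mutate(family_id = fam_map[paste(.data$genome_a, .data$gene_a)],
                  pair_ani = ani_map[pair_key(.data$genome_a, .data$genome_b)]) |>
    dplyr::filter(!is.na(.data$family_id), !is.na(.data$pair_ani),
                  .data$pair_ani < species_floor)
  if (nrow(rows) == 0) {
    rlang::warn("no inter-species genome pairs: constraint-conserved filter inactive")
    return(character(0))
  }
  flagged <- rows |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(frac = mean(.data$identity >= ident_tau), .groups = "drop") |>
    dplyr::filter(.data$frac >= min_frac)
  unname(flagged$family_id)
}

#' Call recently recombined genes between genome pairs
#'
#' A gene is called recently exchanged between two genomes when its RBM
#' identity is at least `call_tau` (the 99.8-100% near-identity band) while
#' the genomes belong to different genomovars (pair ANI below
#' `genomovar_threshold`), and its family is not constraint-conserved. Same-
#' genomovar pairs yield no calls by definition: at >98.5% ANI identical
#' genes are expected from vertical descent alone.
#'
#' @param rbms RBM table over all pairs.
#' @param pairwise Per-pair summary with ANI.
#' @param constraint Character vector of constraint-conserved family ids
#'   (from [flag_constraint_conserved()]).
#' @param families Optional classified family table ([classify_families()]);
#'   when supplied a `class` column is added so core-only filters can be
#'   reproduced downstream.
#' @param call_tau Near-identity call threshold in percent (default 99.8).
#' @param genomovar_threshold Percent ANI above which a pair belongs to the
#'   same genomovar (default 98.5).
#' @param on_undefined What to do with pairs whose ANI is undefined:
#'   `"error"` (default) or `"drop"`.
#' @return Tibble of calls: `genome_a`, `genome_b`, `gene_a`, `gene_b`,
#'   `identity`, `pair_ani`, `class` (if families given).
#' @export
call_recombinant_genes <- function(rbms, pairwise, constraint = character(0),
                                   families = NULL, call_tau = 99.8,
                                   genomovar_threshold = 98.5,
                                   on_undefined = c("error", "drop")) {
  on_undefined <- match.arg(on_undefined)
  ani_map <- setNames(pairwise$ani, pair_key(pairwise$genome_a, pairwise$genome_b))
  out <- rbms |>
    dplyr::mutate(pair_ani = ani_map[pair_key(.data$genome_a, .data$genome_b)])
  if (anyNA(out$pair_ani)) {
    if (on_undefined == "error") rb_abort("undefined ANI for a genome pair present in the RBM table")
    out <- dplyr::filter(out, !is.na(.data$pair_ani))
  }
  out <- dplyr::filter(out, .data$identity >= call_tau,
                       .data$pair_ani < genomovar_threshold)
  if (!is.null(families)) {
    fam_map <- setNames(families$family_id, paste(families$genome_id, families$gene_id))
    out$family_id <- fam_map[paste(out$genome_a, out$gene_a)]
    if ("class" %in% names(families)) {
      class_map <- families |>
        dplyr::distinct(.data$family_id, .data$class)
      out$class <- class_map$class[match(out$family_id, class_map$family_id)]
    }
    out <- dplyr::filter(out, is.na(.data$family_id) | !(.data$family_id %in% constraint))
  } else if (length(constraint) > 0) {
    rb_abort("constraint families supplied without a family table")
  }
  out
}

#' Candidate donor genomes for called genes
#'
#' For each call, lists the genomes of a different genomovar than the focal
#' (gene_a side) genome whose family homolog is at least `call_tau` identical
#' to the called gene — the sampled candidates for the donor of the exchange
#' (an empty list means the donor lineage was not sampled).
#'
#' @param calls Call table from [call_recombinant_genes()].
#' @param rbms RBM table over all pairs.
#' @param families Family membership tibble.
#' @param tiers Tier assignment ([assign_tiers()]).
#' @param call_tau Near-identity threshold in percent.
#' @return `calls` with a list-column `donor_candidates`.
#' @export
find_donors <- function(calls, rbms, families, tiers, call_tau = 99.8) {
  fam_map <- setNames(families$family_id, paste(families$genome_id, families$gene_id))
  gv <- setNames(tiers$genomovar, tiers$genome_id)
  # near-identical family partners of every (genome, family)
  edges <- rbms |>
    dplyr::filter(.data$identity >= call_tau) |>
    dplyr::mutate(family_id = fam_map[paste(.data$genome_a, .data$gene_a)]) |>
    dplyr::filter(!is.na(.data$family_id))
  both <- dplyr::bind_rows(
    dplyr::transmute(edges, focal = .data$genome_a, other = .data$genome_b,
                     family_id = .data$family_id),
    dplyr::transmute(edges, focal = .data$genome_b, other = .data$genome_a,
                     family_id = .data$family_id)
  ) |>
    dplyr::filter(gv[.data$focal] != gv[.data$other])
  lookup <- split(both$other, paste(both$focal, both$family_id))
  calls$donor_candidates <- purrr::map2(
    calls$genome_a, fam_map[paste(calls$genome_a, calls$gene_a)],
    function(g, f) {
      if (is.na(f)) return(character(0))
      v <- lookup[[paste(g, f)]]
      if (is.null(v)) character(0) else sort(unique(v))
    })
  calls
}

#' Cumulative fraction of reference genes present in a record set
#'
#' The union-counting engine of the divergence-group analysis: the fraction
#' of the reference genome's genes that appear (on the reference side) in at
#' least one record against any of the given partners. Each gene counts once
#' however many partners share it, so recombination is not overestimated.
#'
#' @param records Gene-level pair records (calls or near-identity records)
#'   with `genome_a`, `genome_b`, `gene_a`, `gene_b`.
#' @param genes Gene tibble or `genome_set`.
#' @param reference Reference genome id.
#' @param partners Partner genome ids (default: all partners present).
#' @return Fraction in `[0, 1]`.
#' @export
cumulative_recombined_fraction <- function(records, genes, reference, partners = NULL) {
  if (inherits(genes, "genome_set")) genes <- genes$genes
  n_ref <- sum(genes$genome_id == reference)
  if (n_ref == 0) rb_abort(paste0("reference genome absent: ", reference))
  rec <- records |>
    dplyr::filter(.data$genome_a == reference | .data$genome_b == reference) |>
    dplyr::mutate(partner = ifelse(.data$genome_a == reference, .data$genome_b, .data$genome_a),
                  ref_gene = ifelse(.data$genome_a == reference, .data$gene_a, .data$gene_b))
  if (!is.null(partners)) rec <- dplyr::filter(rec, .data$partner %in% partners)
  length(unique(rec$ref_gene)) / n_ref
}

#' Recombinant tracts: runs of consecutive called genes
#'
#' Groups the genes called between a reference and one partner into maximal
#' runs of positionally consecutive genes on each reference contig — the
#' proxy for the length distribution of recombined fragments. By default any
#' intervening uncalled gene breaks a run; with `bridge_missing = TRUE` genes
#' lacking an RBM against the partner (accessory genes) are skipped over
#' instead.
#'
#' @param calls Call table.
#' @param genes Gene tibble or `genome_set`.
#' @param reference,partner Genome ids.
#' @param bridge_missing Bridge genes with no RBM against the partner.
#' @param rbms RBM table; required when `bridge_missing = TRUE`.
#' @return Tibble of tracts: `genome_id`, `contig_id`, `first_gene_index`,
#'   `last_gene_index`, `n_genes`, `span_bp`, `first_gene_id`, `last_gene_id`.
#' @export
recombinant_tracts <- function(calls, genes, reference, partner,
                               bridge_missing = FALSE, rbms = NULL) {
  if (inherits(genes, "genome_set")) genes <- genes$genes
  ref <- genes |>
    dplyr::filter(.data$genome_id == reference) |>
    dplyr::arrange(.data$contig_id, .data$start)
  if (nrow(ref) == 0) rb_abort(paste0("reference genome absent: ", reference))
  pc <- calls |>
    dplyr::filter((.data$genome_a == reference & .data$genome_b == partner) |
                    (.data$genome_b == reference & .data$genome_a == partner)) |>
    dplyr::mutate(ref_gene = ifelse(.data$genome_a == reference, .data$gene_a, .data$gene_b))
  called <- unique(pc$ref_gene)
  if (length(called) == 0) {
    return(tibble::tibble(genome_id = character(), contig_id = character(),
                          first_gene_index = integer(), last_gene_index = integer(),
                          n_genes = integer(), span_bp = integer(),
                          first_gene_id = character(), last_gene_id = character()))
  }
  keep <- rep(TRUE, nrow(ref))
  if (bridge_missing) {
    if (is.null(rbms)) rb_abort("bridge_missing = TRUE requires the RBM table")
    pr <- rbms |>
      dplyr::filter((.data$genome_a == reference & .data$genome_b == partner) |
                      (.data$genome_b == reference & .data$genome_a == partner)) |>
      dplyr::mutate(ref_gene = ifelse(.data$genome_a == reference, .data$gene_a, .data$gene_b))
    keep <- ref$gene_id %in% pr$ref_gene
  }
  ref2 <- ref[keep, , drop = FALSE]
  ref2$pos <- seq_len(nrow(ref2))
  ref2$called <- ref2$gene_id %in% called
  runs <- ref2 |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::mutate(run = cumsum(!.data$called | dplyr::lag(!.data$called, default = TRUE))) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$called)
  # positional index within the full (unfiltered) reference gene order
  full_index <- setNames(seq_len(nrow(ref)), ref$gene_id)
  runs |>
    dplyr::group_by(.data$contig_id, .data$run) |>
    dplyr::summarise(
      first_gene_index = unname(full_index[.data$gene_id[1]]),
      last_gene_index = unname(full_index[.data$gene_id[dplyr::n()]]),
      n_genes = dplyr::n(),
      span_bp = max(.data$end) - min(.data$start),
      first_gene_id = .data$gene_id[1],
      last_gene_id = .data$gene_id[dplyr::n()],
      .groups = "drop"
    ) |>
    dplyr::mutate(genome_id = reference, .before = 1) |>
    dplyr::select(-"run")
}

max_gap_from_midpoints <- function(mids_by_contig, contig_lengths) {
  gaps <- purrr::imap_dbl(contig_lengths, function(len, cid) {
    m <- sort(mids_by_contig[[cid]])
    if (length(m) == 0) return(len)
    max(diff(c(0, m, len)))
  })
  max(gaps)
}

#' Longest recombination-free interval on the reference genome
#'
#' Pools the calls of a reference genome over all partners and returns the
#' longest interval (bp, per contig, linear coordinates) containing no called
#' gene midpoint. Contig ends bound the intervals; with zero calls the gap is
#' the longest contig.
#'
#' @param calls Call table (all partners).
#' @param gs `genome_set` (contig lengths are required).
#' @param reference Reference genome id.
#' @return Longest gap in bp.
#' @export
max_recombination_free_gap <- function(calls, gs, reference) {
  stopifnot(inherits(gs, "genome_set"))
  ref <- dplyr::filter(gs$genes, .data$genome_id == reference)
  if (nrow(ref) == 0) rb_abort(paste0("reference genome absent: ", reference))
  contig_lengths <- gs$contigs |>
    dplyr::filter(.data$genome_id == reference)
  contig_lengths <- setNames(contig_lengths$length, contig_lengths$contig_id)
  pc <- calls |>
    dplyr::filter(.data$genome_a == reference | .data$genome_b == reference) |>
    dplyr::mutate(ref_gene = ifelse(.data$genome_a == reference, .data$gene_a, .data$gene_b))
  called <- ref |>
    dplyr::filter(.data$gene_id %in% unique(pc$ref_gene)) |>
    dplyr::mutate(mid = (.data$start + .data$end) / 2)
  mids <- split(called$mid, factor(called$contig_id, levels = names(contig_lengths)))
  max_gap_from_midpoints(mids, contig_lengths)
}

#' Permutation test for spatial randomness of recombination
#'
#' Tests whether called genes are spread across the genome as expected under
#' random placement. The statistic is the longest recombination-free gap
#' ([max_recombination_free_gap()]); the null places the same number of calls
#' uniformly (without replacement) on the midpoints of the reference's
#' RBM-bearing genes. A small p-value means the calls are more clustered
#' (leaving a longer free gap) than uniform placement explains.
#'
#' @param calls Call table pooled over partners.
#' @param gs `genome_set`.
#' @param reference Reference genome id.
#' @param rbms RBM table (defines the RBM-bearing candidate genes); `NULL`
#'   uses all reference genes.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return p-value `(1 + #\{perm >= obs\}) / (n_perm + 1)`; `NA` with a
#'   warning when fewer than 2 calls.
#' @export
spatial_uniformity_test <- function(calls, gs, reference, rbms = NULL,
                                    n_perm = 999, seed = 1) {
  if (n_perm < 1) rb_abort("n_perm must be at least 1")
  stopifnot(inherits(gs, "genome_set"))
  ref <- gs$genes |>
    dplyr::filter(.data$genome_id == reference) |>
    dplyr::mutate(mid = (.data$start + .data$end) / 2)
  pc <- calls |>
    dplyr::filter(.data$genome_a == reference | .data$genome_b == reference) |>
    dplyr::mutate(ref_gene = ifelse(.data$genome_a == reference, .data$gene_a, .data$gene_b))
  n_called <- length(unique(pc$ref_gene))
  if (n_called < 2) {
    rlang::warn("fewer than 2 calls: spatial test undefined")
    return(NA_real_)
  }
  candidates <- ref
  if (!is.null(rbms)) {
    pr <- rbms |>
      dplyr::filter(.data$genome_a == reference | .data$genome_b == reference) |>
      dplyr::mutate(ref_gene = ifelse(.data$genome_a == reference, .data$gene_a, .data$gene_b))
    candidates <- dplyr::filter(ref, .data$gene_id %in% unique(pr$ref_gene))
  }
  contig_lengths <- gs$contigs |> dplyr::filter(.data$genome_id == reference)
  contig_lengths <- setNames(contig_lengths$length, contig_lengths$contig_id)
  observed <- max_recombination_free_gap(calls, gs, reference)
  set.seed(seed)
  contig_f <- factor(candidates$contig_id, levels = names(contig_lengths))
  perm_stats <- vapply(seq_len(n_perm), function(i) {
    pick <- sample.int(nrow(candidates), n_called)
    mids <- split(candidates$mid[pick], contig_f[pick])
    max_gap_from_midpoints(mids, contig_lengths)
  }, numeric(1))
  (1 + sum(perm_stats >= observed)) / (n_perm + 1)
}

#' Empirical r/m: substitutions purged by recombination vs created by mutation
#'
#' For each genome pair, the background divergence `d_bg` is estimated from
#' the non-recombinant RBMs (1 - mean identity / 100). Every called gene of
#' length L carrying `mm` mismatches would have carried about `d_bg * L`
#' substitutions had it not been recently replaced, so recombination purged
#' `max(0, d_bg * L - mm)` substitutions; summing over called genes gives
#' `r`. `m` is the total mismatch count over non-recombinant RBMs. The ratio
#' is reported as `rm_purged` — a purged-substitution estimator, not a
#' coalescent-model r/m, and not comparable in magnitude to ClonalFrameML.
#'
#' @param rbms RBM table over all pairs.
#' @param calls Call table.
#' @param genes Gene tibble or `genome_set` (for called gene lengths).
#' @param min_background Minimum number of non-recombinant RBMs per pair.
#' @return Tibble: `genome_a`, `genome_b`, `d_bg`, `r`, `m`, `rm_purged`
#'   (`NA` when `m` is 0 or the background is too small).
#' @export
estimate_rm <- function(rbms, calls, genes, min_background = 50) {
  if (inherits(genes, "genome_set")) genes <- genes$genes
  len_map <- setNames(genes$end - genes$start, paste(genes$genome_id, genes$gene_id))
  call_key <- paste(calls$genome_a, calls$gene_a, calls$genome_b, calls$gene_b)
  rbms |>
    dplyr::mutate(called = paste(.data$genome_a, .data$gene_a,
                                 .data$genome_b, .data$gene_b) %in% call_key,
                  gene_len = len_map[paste(.data$genome_a, .data$gene_a)]) |>
    dplyr::group_by(.data$genome_a, .data$genome_b) |>
    dplyr::summarise(
      n_background = sum(!.data$called),
      d_bg = 1 - mean(.data$identity[!.data$called]) / 100,
      r = sum(pmax(0, d_bg * .data$gene_len[.data$called] -
                     .data$mismatches[.data$called])),
      m = sum(.data$mismatches[!.data$called]),
      .groups = "drop"
    ) |>
    dplyr::mutate(rm_purged = dplyr::if_else(
      .data$m > 0 & .data$n_background >= min_background, .data$r / .data$m, NA_real_)) |>
    dplyr::select(-"n_background")
}

#' Per-gene identity profile of one genome pair
#'
#' The data behind a pair-profile plot: every gene of the reference in
#' positional order with its RBM identity against the partner, its family
#' class, and whether it was called recently exchanged.
#'
#' @param rbms RBM table.
#' @param calls Call table.
#' @param genes Gene tibble or `genome_set`.
#' @param families Classified family table, or `NULL`.
#' @param reference,partner Genome ids.
#' @return Tibble: `gene_id`, `contig_id`, `start`, `mid`, `identity`,
#'   `class`, `called`.
#' @export
pair_profile <- function(rbms, calls, genes, families = NULL, reference, partner) {
  if (inherits(genes, "genome_set")) genes <- genes$genes
  ref <- genes |>
    dplyr::filter(.data$genome_id == reference) |>
    dplyr::arrange(.data$contig_id, .data$start)
  take_side <- function(df) {
    df |>
      dplyr::filter((.data$genome_a == reference & .data$genome_b == partner) |
                      (.data$genome_b == reference & .data$genome_a == partner)) |>
      dplyr::mutate(ref_gene = ifelse(.data$genome_a == reference, .data$gene_a, .data$gene_b))
  }
  pr <- take_side(rbms)
  pc <- take_side(calls)
  out <- ref |>
    dplyr::transmute(.data$gene_id, .data$contig_id, .data$start,
                     mid = (.data$start + .data$end) / 2,
                     identity = pr$identity[match(.data$gene_id, pr$ref_gene)],
                     called = .data$gene_id %in% pc$ref_gene)
  if (!is.null(families)) {
    fam <- families |> dplyr::filter(.data$genome_id == reference)
    out$class <- fam$class[match(out$gene_id, fam$gene_id)]
    out$class[is.na(out$class)] <- "accessory"
  } else {
    out$class <- ifelse(is.na(out$identity), "accessory", "core")
  }
  out
}
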