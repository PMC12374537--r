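#' Symmetric ANI matrix from a per-pair summary
#'
#' @param pairwise Per-pair tibble from [pairwise_summary()] (needs
#'   `genome_a`, `genome_b`, `ani`).
#' @param genome_ids Optional full genome id set (to include genomes with no
#'   defined pair).
#' @return A symmetric numeric matrix in percent with 100 on the diagonal and
#'   `NA` where ANI is undefined.
#' @export
ani_matrix <- function(pairwise, genome_ids = NULL) {
  assert_cols(pairwise, c("genome_a", "genome_b", "ani"), "pairwise")
  ids <- genome_ids %||% sort(unique(c(pairwise$genome_a, pairwise$genome_b)))
  if (length(ids) < 2) rb_abort("need at least two genomes")
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 100
  ia <- match(pairwise$genome_a, ids)
  ib <- match(pairwise$genome_b, ids)
  m[cbind(ia, ib)] <- pairwise$ani
  m[cbind(ib, ia)] <- pairwise$ani
  m
}

#' Single-linkage clustering at an ANI threshold
#'
#' Clusters are the connected components of the graph whose edges join genome
#' pairs with ANI strictly above `threshold` — the operational reading of
#' "genomes sharing >X% ANI". Undefined (NA) cells contribute no edge.
#' Cluster labels are deterministic: each cluster is named after its
#' lexicographically smallest member.
#'
#' @param m Symmetric ANI matrix from [ani_matrix()].
#' @param threshold Percent ANI threshold.
#' @return Named character vector: genome id -> cluster label.
#' @export
cluster_at_threshold <- function(m, threshold) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  adj <- !is.na(m) & m > threshold
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  ids <- rownames(m)
  labels <- vapply(split(ids, comp), function(members) min(members), character(1))
  setNames(labels[as.character(comp)], ids)
}

#' Nested genomovar / phylogroup / species assignment
#'
#' Single-linkage clusters at the three ANI thresholds. Because the
#' thresholds are ordered and the linkage is single, the clusters nest:
#' same genomovar implies same phylogroup implies same species.
#'
#' @param pairwise Per-pair summary, or an ANI matrix.
#' @param genomovar,phylogroup,species Percent ANI thresholds (defaults
#'   98.5 / 96.5 / 91).
#' @return Tibble with `genome_id`, `genomovar`, `phylogroup`, `species`,
#'   carrying the thresholds as an attribute.
#' @export
assign_tiers <- function(pairwise, genomovar = 98.5, phylogroup = 96.5, species = 91) {
  if (!(genomovar > phylogroup && phylogroup > species)) {
    rb_abort("tier thresholds must satisfy genomovar > phylogroup > species")
  }
  m <- if (is.matrix(pairwise)) pairwise else ani_matrix(pairwise)
  out <- tibble::tibble(
    genome_id = rownames(m),
    genomovar = unname(cluster_at_threshold(m, genomovar)),
    phylogroup = unname(cluster_at_threshold(m, phylogroup)),
    species = unname(cluster_at_threshold(m, species))
  )
  attr(out, "thresholds") <- c(genomovar = genomovar, phylogroup = phylogroup,
                               species = species)
  out
}

#' ANI band label (A-D) for a genome pair
#'
#' The divergence bands of the cumulative identical-gene analysis:
#' A = same genomovar (ANI > 98.5), B = (96.5, 98.5], C = (93.5, 96.5],
#' D = \[91, 93.5\]. Boundary values are assigned downward (an exact 96.5
#' falls in C); pairs below the species floor get `NA` (inter-species).
#'
#' @param ani Percent ANI, vectorised.
#' @param genomovar,phylogroup,lower_c,species Band boundaries.
#' @return Character vector of labels `"A"`, `"B"`, `"C"`, `"D"` or `NA`.
#' @export
assign_pair_group <- function(ani, genomovar = 98.5, phylogroup = 96.5,
                              lower_c = 93.5, species = 91) {
  if (any(is.na(ani))) rb_abort("undefined ANI has no band")
  dplyr::case_when(
    ani > genomovar ~ "A",
    ani > phylogroup ~ "B",
    ani > lower_c ~ "C",
    ani >= species ~ "D",
    TRUE ~ NA_character_
  )
}

#' Cumulative identical-gene profiles by divergence group (A-F)
#'
#' For one reference genome, reports the cumulative fraction of its genes
#' that are near-identical (RBM identity >= `tau`) to at least one genome of
#' each comparison set, counting every reference gene at most once per set.
#' Groups A-D are computed per comparison genomovar (one row per genomovar in
#' the band, the band being determined by the mean ANI of the reference
#' against the genomovar's members); E and F are the unions across all
#' genomovars of the B and D bands respectively.
#'
#' @param rbms RBM table over all pairs ([rbm_all_pairs()]).
#' @param pairwise Per-pair summary with ANI.
#' @param tiers Tier assignment from [assign_tiers()].
#' @param reference Reference genome id.
#' @param genes Gene tibble (for the reference gene count), or `genome_set`.
#' @param tau Near-identity threshold in percent (default 99.8).
#' @return Tibble with `reference`, `group`, `genomovar` (`NA` for E/F),
#'   `n_partners` and `fraction`.
#' @export
group_profiles <- function(rbms, pairwise, tiers, reference, genes, tau = 99.8) {
  if (inherits(genes, "genome_set")) genes <- genes$genes
  ref_genes <- dplyr::filter(genes, .data$genome_id == reference)
  if (nrow(ref_genes) == 0) rb_abort(paste0("reference genome absent: ", reference))
  gv <- setNames(tiers$genomovar, tiers$genome_id)
  if (!reference %in% names(gv)) rb_abort("reference not in tier assignment")

  # mean ANI of the reference against each other genomovar
  pw <- pairwise |>
    dplyr::filter(.data$genome_a == reference | .data$genome_b == reference) |>
    dplyr::mutate(partner = ifelse(.data$genome_a == reference, .data$genome_b, .data$genome_a),
                  partner_gv = gv[.data$partner]) |>
    dplyr::filter(!is.na(.data$ani))

  # near-identical reference genes per partner genome
  ident <- rbms |>
    dplyr::filter(.data$genome_a == reference | .data$genome_b == reference,
                  .data$identity >= tau) |>
    dplyr::mutate(partner = ifelse(.data$genome_a == reference, .data$genome_b, .data$genome_a),
                  ref_gene = ifelse(.data$genome_a == reference, .data$gene_a, .data$gene_b))

  frac_for <- function(partners) {
    genes_hit <- unique(ident$ref_gene[ident$partner %in% partners])
    length(genes_hit) / nrow(ref_genes)
  }

  own_gv <- gv[reference]
  rows <- list()
  # group A: the reference's own genomovar
  own_members <- setdiff(names(gv)[gv == own_gv], reference)
  if (length(own_members) > 0) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      group = "A", genomovar = unname(own_gv), n_partners = length(own_members),
      fraction = frac_for(own_members))
  }
  # groups B-D: per comparison genomovar, band from mean reference-vs-genomovar ANI
  gv_ani <- pw |>
    dplyr::filter(.data$partner_gv != own_gv) |>
    dplyr::group_by(.data$partner_gv) |>
    dplyr::summarise(ani = mean(.data$ani), n_partners = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(band = assign_pair_group(.data$ani))
  for (b in c("B", "C", "D")) {
    sel <- dplyr::filter(gv_ani, !is.na(.data$band), .data$band == b)
    for (i in seq_len(nrow(sel))) {
      members <- names(gv)[gv == sel$partner_gv[i]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = b, genomovar = unname(sel$partner_gv[i]), n_partners = length(members),
        fraction = frac_for(members))
    }
  }
  # E/F: unions across all genomovars of the B and D bands
  for (u in c(E = "B", F = "D")) {
    sel <- dplyr::filter(gv_ani, !is.na(.data$band), .data$band == u)
    if (nrow(sel) > 0) {
      members <- names(gv)[gv %in% sel$partner_gv]
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = names(which(c(E = "B", F = "D") == u)), genomovar = NA_character_,
        n_partners = length(members), fraction = frac_for(members))
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(reference = reference, .before = 1)
}

#' Detect an ANI gap (species valley) in a set of pairwise ANI values
#'
#' Estimates a gaussian-kernel density of the ANI values above `lo_bound`
#' and searches for a valley between two modes whose minimum density falls
#' below `depth_ratio` of the smaller flanking peak. The reported gap is the
#' widest sub-threshold interval between two qualifying modes; `NULL` is
#' returned for a unimodal distribution.
#'
#' @param values Pairwise percent ANI values (>= 30 above `lo_bound`).
#' @param bandwidth Kernel bandwidth in ANI percentage points.
#' @param lo_bound Reliability floor; values below are discarded.
#' @param depth_ratio Valley depth criterion relative to the smaller flanking
#'   peak.
#' @param min_peak_frac Peaks smaller than this fraction of the global
#'   maximum are ignored as noise.
#' @return A list of class `ani_gap` with `lo`, `hi` and `depth`
#'   (valley density / smaller flanking peak density), or `NULL`.
#' @export
detect_ani_gap <- function(values, bandwidth = 0.5, lo_bound = 75,
                           depth_ratio = 0.25, min_peak_frac = 0.05) {
  values <- values[!is.na(values) & values >= lo_bound]
  if (length(values) < 30) rb_abort("need at least 30 ANI values above the floor")
  den <- density(values, bw = bandwidth, from = lo_bound, to = 100, n = 1024)
  y <- den$y; x <- den$x
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  peaks <- which(is_peak & y >= min_peak_frac * max(y))
  if (length(peaks) < 2) return(NULL)

  best <- NULL
  for (i in seq_len(length(peaks) - 1)) {
    p1 <- peaks[i]; p2 <- peaks[i + 1]
    seg <- p1:p2
    v <- seg[which.min(y[seg])]
    small_peak <- min(y[p1], y[p2])
    if (y[v] >= depth_ratio * small_peak) next
    thr <- depth_ratio * small_peak
    lo_idx <- max(seg[seg <= v & y[seg] >= thr])
    hi_idx <- min(seg[seg >= v & y[seg] >= thr])
    gap <- list(lo = x[lo_idx], hi = x[hi_idx], depth = y[v] / small_peak)
    if (is.null(best) || (gap$hi - gap$lo) > (best$hi - best$lo)) best <- gap
  }
  if (is.null(best)) return(NULL)
  structure(best, class = "ani_gap")
}

#' @export
print.ani_gap <- function(x, ...) {
  cat(sprintf("<ani_gap> %.2f%% - %.2f%% (valley depth %.3f of flanking peak)\n",
              x$lo, x$hi, x$depth))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ani_gap <- function(x, ...) {
  tibble::tibble(lo = x$lo, hi = x$hi, depth = x$depth)
}
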