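#' Gene families from the RBM graph
#'
#' Families are the connected components of the graph whose vertices are
#' genes and whose edges are RBMs. A component containing two genes of the
#' same genome is a conflict (spurious transitive linking); conflicts are
#' resolved by iteratively dropping the lowest-identity edge of the affected
#' component until every family has at most one member per genome.
#'
#' @param rbms RBM table over all pairs.
#' @return Tibble with `family_id`, `genome_id`, `gene_id`; family ids are
#'   `fam_<n>` numbered by the lexicographically smallest member gene.
#' @export
build_gene_families <- function(rbms) {
  assert_cols(rbms, c("genome_a", "genome_b", "gene_a", "gene_b", "identity"), "rbms")
  va <- paste(rbms$genome_a, rbms$gene_a, sep = "\r")
  vb <- paste(rbms$genome_b, rbms$gene_b, sep = "\r")
  keep <- rep(TRUE, nrow(rbms))
  repeat {
    g <- igraph::graph_from_data_frame(
      data.frame(from = va[keep], to = vb[keep], weight = rbms$identity[keep]),
      directed = FALSE)
    memb <- igraph::components(g)$membership
    genome_of <- sub("\r.*$", "", names(memb))
    conflict <- tapply(genome_of, memb, anyDuplicated)
    bad <- names(conflict)[conflict > 0]
    if (length(bad) == 0) break
    # drop the weakest edge within each conflicted component
    comp_a <- memb[va]
    for (b in bad) {
      in_comp <- which(keep & !is.na(comp_a) & comp_a == as.integer(b))
      drop <- in_comp[which.min(rbms$identity[in_comp])]
      keep[drop] <- FALSE
    }
  }
  members <- split(names(memb), memb)
  singles <- setdiff(unique(c(va, vb)), names(memb)) # genes isolated by dropped edges
  members <- c(members, as.list(singles))
  first <- vapply(members, min, character(1))
  ord <- order(first)
  purrr::imap(members[ord], function(m, i) {
    parts <- stringr::str_split_fixed(m, "\r", 2)
    tibble::tibble(family_id = sprintf("fam_%05d", as.integer(i)),
                   genome_id = parts[, 1], gene_id = parts[, 2])
  }) |>
    dplyr::bind_rows()
}

#' Classify gene families as constraint-conserved, core or accessory
#'
#' A family is `constraint_conserved` when flagged by
#' [flag_constraint_conserved()]; otherwise `core` when present in at least
#' `core_frac` of the genomes of some species, else `accessory`.
#'
#' @param families Family membership tibble.
#' @param tiers Tier assignment with a `species` column.
#' @param constraint Flagged family ids.
#' @param core_frac Core presence threshold (default 0.8).
#' @return `families` with a `class` column.
#' @export
classify_families <- function(families, tiers, constraint = character(0),
                              core_frac = 0.8) {
  sp <- setNames(tiers$species, tiers$genome_id)
  sp_size <- table(tiers$species)
  cls <- families |>
    dplyr::mutate(species = sp[.data$genome_id]) |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(max_cov = {
      tab <- table(.data$species)
      max(as.numeric(tab) / as.numeric(sp_size[names(tab)]))
    }, .groups = "drop") |>
    dplyr::mutate(class = dplyr::if_else(.data$max_cov >= core_frac, "core", "accessory"))
  families$class <- cls$class[match(families$family_id, cls$family_id)]
  families$class[families$family_id %in% constraint] <- "constraint_conserved"
  families
}

#' Partition a gene family into alleles
#'
#' An allele is a single-linkage cluster of family members at pairwise
#' identity strictly above `threshold` (default 98.5%). Member pairs with no
#' RBM identity available are treated as below threshold.
#'
#' @param members Tibble with `genome_id`, `gene_id` for one family.
#' @param identities Pairwise identity table for the family's members:
#'   columns `genome_a`, `gene_a`, `genome_b`, `gene_b`, `identity` (an RBM
#'   table restricted to the family works).
#' @param threshold Percent identity threshold.
#' @return `members` with an `allele_id` column (`allele_<n>`, numbered by
#'   smallest member).
#' @export
allele_partition <- function(members, identities, threshold = 98.5) {
  key <- paste(members$genome_id, members$gene_id, sep = "\r")
  ka <- paste(identities$genome_a, identities$gene_a, sep = "\r")
  kb <- paste(identities$genome_b, identities$gene_b, sep = "\r")
  sel <- ka %in% key & kb %in% key & identities$identity > threshold
  g <- igraph::graph_from_data_frame(
    data.frame(from = ka[sel], to = kb[sel]), directed = FALSE,
    vertices = data.frame(name = key))
  memb <- igraph::components(g)$membership
  first <- vapply(split(names(memb), memb), min, character(1))
  rank <- match(first, sort(first))
  allele_of <- sprintf("allele_%03d", rank[memb[key]])
  members$allele_id <- allele_of
  members
}

#' Scan gene families for gene sweeps
#'
#' A gene sweep is one allele of a family spreading through a species by
#' recombination while the rest of the genome stays diverse. Per species
#' (skipped with a warning below `min_genomes` members), every non-constraint
#' family is partitioned into alleles; the dominant allele is the one carried
#' by most genomes. The family is flagged `swept` when that allele covers at
#' least `min_coverage` of the species' genomes while the genomes carrying it
#' span pairs at no more than `max_allele_ani` percent ANI — near-identity of
#' the gene against a diverse genomic background.
#'
#' @param families Classified family tibble ([classify_families()]).
#' @param rbms RBM table over all pairs.
#' @param pairwise Per-pair summary with ANI.
#' @param tiers Tier assignment.
#' @param allele_threshold Allele identity threshold in percent.
#' @param min_coverage Dominant-allele coverage required for a sweep.
#' @param max_allele_ani Maximum `min_pair_ani` (percent) for a sweep.
#' @param min_genomes Minimum genomes per species to scan.
#' @return Tibble sorted by coverage then identity-vs-ANI discrepancy:
#'   `species`, `family_id`, `dominant_allele`, `coverage`, `min_pair_ani`,
#'   `mean_allele_identity`, `discrepancy`, `swept`.
#' @export
sweep_scan <- function(families, rbms, pairwise, tiers,
                       allele_threshold = 98.5, min_coverage = 0.9,
                       max_allele_ani = 95, min_genomes = 4) {
  if (!"class" %in% names(families)) rb_abort("families must carry a class column")
  fam_map <- setNames(families$family_id, paste(families$genome_id, families$gene_id))
  ani_map <- setNames(pairwise$ani, pair_key(pairwise$genome_a, pairwise$genome_b))
  rbm_fam <- rbms |>
    dplyr::mutate(family_id = fam_map[paste(.data$genome_a, .data$gene_a)])
  sp <- setNames(tiers$species, tiers$genome_id)

  out <- list()
  for (s in sort(unique(tiers$species))) {
    genomes_s <- tiers$genome_id[tiers$species == s]
    if (length(genomes_s) < min_genomes) {
      rlang::warn(paste0("species ", s, " has fewer than ", min_genomes,
                         " genomes: sweep scan skipped"))
      next
    }
    fams_s <- families |>
      dplyr::filter(.data$genome_id %in% genomes_s, .data$class != "constraint_conserved")
    idents_s <- rbm_fam |>
      dplyr::filter(!is.na(.data$family_id),
                    .data$genome_a %in% genomes_s, .data$genome_b %in% genomes_s)
    members_by_fam <- split(fams_s, fams_s$family_id)
    idents_by_fam <- split(idents_s, idents_s$family_id)
    for (f in names(members_by_fam)) {
      members <- members_by_fam[[f]]
      if (nrow(members) < 2) next
      idents <- idents_by_fam[[f]]
      if (is.null(idents)) idents <- idents_s[0, , drop = FALSE]
      part <- allele_partition(members, idents, threshold = allele_threshold)
      sizes <- sort(table(part$allele_id), decreasing = TRUE)
      dom <- names(sizes)[1]
      carriers <- part$genome_id[part$allele_id == dom]
      coverage <- length(unique(carriers)) / length(genomes_s)
      pairs_c <- if (length(carriers) >= 2) utils::combn(sort(unique(carriers)), 2) else NULL
      min_ani <- if (is.null(pairs_c)) NA_real_ else
        suppressWarnings(min(ani_map[pair_key(pairs_c[1, ], pairs_c[2, ])], na.rm = TRUE))
      allele_ident <- idents |>
        dplyr::filter(.data$genome_a %in% carriers, .data$genome_b %in% carriers,
                      .data$identity > allele_threshold)
      mean_id <- if (nrow(allele_ident) > 0) mean(allele_ident$identity) else NA_real_
      swept <- !is.na(min_ani) && coverage >= min_coverage && min_ani <= max_allele_ani
      out[[length(out) + 1]] <- tibble::tibble(
        species = s, family_id = f, dominant_allele = dom,
        coverage = coverage, min_pair_ani = min_ani,
        mean_allele_identity = mean_id,
        discrepancy = mean_id - min_ani, swept = swept)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(species = character(), family_id = character(),
                          dominant_allele = character(), coverage = numeric(),
                          min_pair_ani = numeric(), mean_allele_identity = numeric(),
                          discrepancy = numeric(), swept = logical()))
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(dplyr::desc(.data$coverage), dplyr::desc(.data$discrepancy))
}
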