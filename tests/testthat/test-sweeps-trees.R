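test_that("gene families are RBM components with per-genome uniqueness", {
  rbms <- tibble::tibble(
    genome_a = c("x", "x", "y"), genome_b = c("y", "z", "z"),
    gene_a = c("x1", "x1", "y1"), gene_b = c("y1", "z1", "z1"),
    identity = c(99, 98, 99), aln_len = 900L, mismatches = 9L)
  fam <- build_gene_families(rbms)
  expect_equal(dplyr::n_distinct(fam$family_id), 1)
  expect_equal(nrow(fam), 3)
  # a conflicting second x-gene joined by a weak edge is split off
  rbms2 <- dplyr::bind_rows(rbms, tibble::tibble(
    genome_a = "x", genome_b = "y", gene_a = "x2", gene_b = "y1",
    identity = 80, aln_len = 900L, mismatches = 180L))
  fam2 <- build_gene_families(rbms2)
  members <- fam2 |>
    dplyr::count(family_id, genome_id) |>
    dplyr::filter(n > 1)
  expect_equal(nrow(members), 0)
})

test_that("family classes follow the core-presence rule and constraint flags", {
  fam <- tibble::tibble(family_id = c("f1", "f1", "f1", "f2", "f2"),
                        genome_id = c("x", "y", "z", "x", "y"),
                        gene_id = c("x1", "y1", "z1", "x2", "y2"))
  tiers <- tibble::tibble(genome_id = c("x", "y", "z"), genomovar = c("x", "y", "z"),
                          phylogroup = "p", species = "s")
  cls <- classify_families(fam, tiers)
  expect_equal(unique(cls$class[cls$family_id == "f1"]), "core")     # 3/3
  expect_equal(unique(cls$class[cls$family_id == "f2"]), "accessory") # 2/3 < 0.8
  cls2 <- classify_families(fam, tiers, constraint = "f1")
  expect_equal(unique(cls2$class[cls2$family_id == "f1"]), "constraint_conserved")
})

test_that("allele partitions are single-linkage clusters with monotone refinement", {
  members <- tibble::tibble(genome_id = c("w", "x", "y", "z"),
                            gene_id = c("w1", "x1", "y1", "z1"))
  idents <- tibble::tibble(
    genome_a = c("w", "w", "w", "x", "x", "y"),
    genome_b = c("x", "y", "z", "y", "z", "z"),
    gene_a = c("w1", "w1", "w1", "x1", "x1", "y1"),
    gene_b = c("x1", "y1", "z1", "y1", "z1", "z1"),
    identity = c(99.9, 94, 94, 94, 94, 99.9))
  part <- allele_partition(members, idents)
  expect_equal(dplyr::n_distinct(part$allele_id), 2)
  expect_equal(part$allele_id[part$genome_id == "w"],
               part$allele_id[part$genome_id == "x"])
  expect_equal(part$allele_id[part$genome_id == "y"],
               part$allele_id[part$genome_id == "z"])
  # threshold 0: one allele; threshold 100: all singletons
  expect_equal(dplyr::n_distinct(allele_partition(members, idents, 0)$allele_id), 1)
  expect_equal(dplyr::n_distinct(allele_partition(members, idents, 100)$allele_id), 4)
})

test_that("neighbour joining recovers additive topologies exactly", {
  # 4 taxa, additive distances from the tree ((A,B),(C,D))
  d <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  alt <- ape::read.tree(text = "((A,C),(B,D));")
  ref <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(compare_trees(tr, ref)$rf_distance, 0)
  expect_equal(compare_trees(tr, alt)$rf_distance, 2)
  # ultrametric 3-taxon: the closest pair are sisters (midpoint root)
  d3 <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  expect_true(ape::is.monophyletic(t3, c("A", "B")))
  expect_error(nj_tree(d3[1:2, 1:2]), "3 taxa")
})

test_that("NJ matches the least-squares brute-force topology and distances on random additive trees", {
  set.seed(77)
  for (n in c(4, 5, 6)) {
    ra <- random_additive_tree(n)
    got <- nj_tree(ra$d)
    # oracle: exhaustive topology search by OLS residual
    best <- oracle_best_topology(ra$d)
    expect_lt(best$rss, 1e-16)
    oracle_tree <- topology_to_phylo(best$tr, rownames(ra$d))
    expect_equal(compare_trees(got, oracle_tree)$rf_distance, 0)
    # branch lengths: the cophenetic matrix of the NJ tree equals the input
    expect_equal(ape::cophenetic.phylo(got)[rownames(ra$d), colnames(ra$d)],
                 ra$d, tolerance = 1e-8)
  }
})

test_that("NJ topology is invariant to taxon order", {
  set.seed(78)
  ra <- random_additive_tree(6)
  t1 <- nj_tree(ra$d)
  perm <- sample(6)
  t2 <- nj_tree(ra$d[perm, perm])
  expect_equal(compare_trees(t1, t2)$rf_distance, 0)
})

test_that("Robinson-Foulds distance and discordant splits match phangorn", {
  set.seed(79)
  t1 <- nj_tree(random_additive_tree(7)$d)
  for (rep in 1:5) {
    t2 <- nj_tree(random_additive_tree(7)$d)
    got <- compare_trees(t1, t2)
    expect_equal(got$rf_distance,
                 as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))))
    expect_equal(length(got$discordant_splits), got$rf_distance)
  }
  expect_equal(compare_trees(t1, t1)$rf_distance, 0)
  t3 <- nj_tree(random_additive_tree(6, labels = paste0("x", 1:6))$d)
  expect_error(compare_trees(t1, t3), "leaf set")
})

test_that("the sweep scan flags a planted operon sweep and respects its guards", {
  set.seed(80)
  cfg <- sim_config(n_species = 1, genomes_per_species = 6,
                    phylogroups = list(2, 2, 1, 1),
                    phylogroup_half_divergence = c(0.027, 0.029, 0.0335, 0.0455),
                    n_genes = 80, recomb_rate = 0, n_constraint_genes = 0,
                    sweep_ops = list(c(30, 3)), seed = 80)
  pop <- generate_population(cfg)
  gs <- as_genome_set(pop)
  rbms <- rbm_all_pairs(gs)
  pw <- pairwise_summary(rbms, min_rbm = 20)
  tiers <- assign_tiers(pw)
  fams <- classify_families(build_gene_families(rbms), tiers)
  scan <- sweep_scan(fams, rbms, pw, tiers)
  # families of the swept genes (indices 30-32) are flagged
  swept_gene_ids <- pop$genes$gene_id[pop$genes$gene_index %in% 30:32 &
                                        pop$genes$genome_id == "s1_g01"]
  swept_fams <- fams$family_id[fams$gene_id %in% swept_gene_ids]
  hit <- scan[scan$family_id %in% swept_fams, ]
  expect_true(all(hit$swept))
  expect_true(all(hit$coverage >= 0.9))
  expect_true(all(hit$min_pair_ani <= 95))
  # a species with too few genomes is skipped with a warning
  tiers_small <- dplyr::mutate(tiers, species = genome_id)
  expect_warning(out <- sweep_scan(fams, rbms, pw, tiers_small), "fewer than")
  expect_equal(nrow(out), 0)
})
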