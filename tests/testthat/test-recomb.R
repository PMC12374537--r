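# shared toy fixture: three genomes, simple families
toy_recomb_fixture <- function() {
  genes <- dplyr::bind_rows(
    toy_genes("ga", replicate(6, random_seq(900))),
    toy_genes("gb", replicate(6, random_seq(900))),
    toy_genes("gc", replicate(6, random_seq(900))))
  mk <- function(a, b, idents) {
    ga <- genes$gene_id[genes$genome_id == a]
    gb <- genes$gene_id[genes$genome_id == b]
    tibble::tibble(genome_a = a, genome_b = b, gene_a = ga, gene_b = gb,
                   identity = idents, aln_len = 900L,
                   mismatches = as.integer(round(900 * (1 - idents / 100))))
  }
  rbms <- dplyr::bind_rows(
    mk("ga", "gb", c(99.9, 94, 94, 94, 100, 94)),
    mk("ga", "gc", c(100, 88, 88, 88, 88, 88)),
    mk("gb", "gc", c(100, 88, 88, 88, 88, 88)))
  pairwise <- tibble::tibble(genome_a = c("ga", "ga", "gb"),
                             genome_b = c("gb", "gc", "gc"),
                             ani = c(94.0, 88.0, 88.0))
  families <- build_gene_families(rbms)
  list(genes = genes, rbms = rbms, pairwise = pairwise, families = families)
}

test_that("constraint-conserved families are flagged from inter-species near-identity", {
  set.seed(31)
  fx <- toy_recomb_fixture()
  flagged <- flag_constraint_conserved(fx$families, fx$rbms, fx$pairwise)
  # gene 1 is ~100% identical in both ANI-88 pairs -> its family is flagged
  fam1 <- fx$families$family_id[fx$families$gene_id == "ga_c1_1"]
  expect_equal(flagged, unique(fam1))
  # with no inter-species pairs the filter is inactive, with a warning
  pw_intra <- dplyr::mutate(fx$pairwise, ani = c(94, 93, 93))
  expect_warning(out <- flag_constraint_conserved(fx$families, fx$rbms, pw_intra),
                 "inactive")
  expect_length(out, 0)
})

test_that("recombinant calls require near-identity, different genomovars, and no constraint", {
  set.seed(32)
  fx <- toy_recomb_fixture()
  flagged <- flag_constraint_conserved(fx$families, fx$rbms, fx$pairwise)
  fams <- classify_families(fx$families, tibble::tibble(
    genome_id = c("ga", "gb", "gc"), genomovar = c("ga", "gb", "gc"),
    phylogroup = c("p", "p", "q"), species = c("s", "s", "t")), flagged)
  calls <- call_recombinant_genes(fx$rbms, fx$pairwise, flagged, fams)
  # 99.9 at ANI 94 is called; the constraint family (gene 1) is not,
  # even though it is 100% identical everywhere
  expect_true("ga_c1_1" %in% fx$rbms$gene_a[fx$rbms$identity >= 99.8])
  expect_false("ga_c1_1" %in% calls$gene_a)
  expect_setequal(calls$gene_a[calls$genome_b == "gb"], c("ga_c1_1", "ga_c1_5")[2])
  # same-genomovar pairs produce no calls
  pw_same <- dplyr::mutate(fx$pairwise, ani = c(99.0, 88, 88))
  calls2 <- call_recombinant_genes(fx$rbms, pw_same, flagged, fams)
  expect_false(any(calls2$genome_b == "gb"))
  # undefined ANI errors by default
  pw_na <- dplyr::mutate(fx$pairwise, ani = c(NA, 88, 88))
  expect_error(call_recombinant_genes(fx$rbms, pw_na, flagged, fams), "undefined ANI")
})

test_that("donor candidates are near-identical homologs outside the recipient's genomovar", {
  set.seed(33)
  fx <- toy_recomb_fixture()
  tiers <- tibble::tibble(genome_id = c("ga", "gb", "gc"),
                          genomovar = c("v1", "v1", "v2"),
                          phylogroup = "p", species = "s")
  calls <- call_recombinant_genes(fx$rbms, fx$pairwise, families = fx$families)
  calls <- find_donors(calls, fx$rbms, fx$families, tiers)
  # for ga gene 1 called vs gb: gc (different genomovar) is 100% identical
  row <- calls[calls$gene_a == "ga_c1_1" & calls$genome_b == "gb", ]
  expect_equal(row$donor_candidates[[1]], "gc")
  # gb is in ga's own genomovar, so it is excluded from ga-side donors
  expect_false("gb" %in% unlist(calls$donor_candidates[calls$genome_a == "ga"]))
})

test_that("cumulative recombined fraction counts union once and is monotone in partners", {
  set.seed(34)
  fx <- toy_recomb_fixture()
  calls <- tibble::tibble(
    genome_a = c("ga", "ga", "ga"), genome_b = c("gb", "gc", "gc"),
    gene_a = c("ga_c1_1", "ga_c1_1", "ga_c1_2"),
    gene_b = c("gb_c1_1", "gc_c1_1", "gc_c1_2"))
  # gene 1 called against both partners counts once
  expect_equal(cumulative_recombined_fraction(calls, fx$genes, "ga"), 2 / 6)
  f1 <- cumulative_recombined_fraction(calls, fx$genes, "ga", partners = "gb")
  f2 <- cumulative_recombined_fraction(calls, fx$genes, "ga", partners = c("gb", "gc"))
  expect_equal(f1, 1 / 6)
  expect_gte(f2, f1)
  expect_equal(cumulative_recombined_fraction(calls[0, ], fx$genes, "ga"), 0)
  expect_error(cumulative_recombined_fraction(calls, fx$genes, "zz"), "absent")
})

test_that("tracts are maximal runs of consecutive called genes with the documented span", {
  genes <- toy_genes("r", replicate(50, random_seq(900)))
  called_idx <- c(10, 11, 12, 40)
  calls <- tibble::tibble(
    genome_a = "r", genome_b = "p",
    gene_a = genes$gene_id[called_idx],
    gene_b = paste0("p_", called_idx))
  tr <- recombinant_tracts(calls, genes, "r", "p")
  expect_equal(nrow(tr), 2)
  expect_equal(tr$n_genes, c(3L, 1L))
  expect_equal(tr$first_gene_index, c(10L, 40L))
  expect_equal(tr$last_gene_index, c(12L, 40L))
  # three consecutive 900-bp genes with 100-bp spacers span 2900 bp
  expect_equal(tr$span_bp[1], 2900)
  expect_equal(nrow(recombinant_tracts(calls[0, ], genes, "r", "p")), 0)
})

test_that("the longest recombination-free gap uses midpoints and contig bounds", {
  genes <- tibble::tibble(
    gene_id = c("r_c1_1", "r_c1_2"), genome_id = "r", contig_id = "r_c1",
    start = c(99550L, 599550L), end = c(100450L, 600450L), strand = 1L,
    seq = replicate(2, random_seq(900)))
  gs <- genome_set(genes, tibble::tibble(contig_id = "r_c1", length = 1000000L))
  calls <- tibble::tibble(genome_a = "r", genome_b = "p",
                          gene_a = genes$gene_id, gene_b = c("p1", "p2"))
  expect_equal(max_recombination_free_gap(calls, gs, "r"), 500000)
  expect_equal(max_recombination_free_gap(calls[0, ], gs, "r"), 1000000)
})

test_that("the spatial uniformity test flags clustered calls and validates inputs", {
  set.seed(35)
  genes <- toy_genes("r", replicate(200, random_seq(900)))
  gs <- genome_set(genes)
  clustered <- tibble::tibble(genome_a = "r", genome_b = "p",
                              gene_a = genes$gene_id[1:20],
                              gene_b = paste0("p_", 1:20))
  p_clust <- spatial_uniformity_test(clustered, gs, "r", n_perm = 199, seed = 1)
  expect_lte(p_clust, 0.01)
  spread <- tibble::tibble(genome_a = "r", genome_b = "p",
                           gene_a = genes$gene_id[seq(5, 200, by = 10)],
                           gene_b = paste0("p_", 1:20))
  p_spread <- spatial_uniformity_test(spread, gs, "r", n_perm = 199, seed = 1)
  expect_gt(p_spread, 0.5)
  expect_error(spatial_uniformity_test(clustered, gs, "r", n_perm = 0), "n_perm")
  expect_warning(p_na <- spatial_uniformity_test(clustered[1, ], gs, "r", n_perm = 9),
                 "fewer than 2")
  expect_true(is.na(p_na))
})

test_that("spatial test p-values are roughly uniform under uniform placement", {
  set.seed(36)
  genes <- toy_genes("r", replicate(150, random_seq(600)))
  gs <- genome_set(genes)
  pvals <- vapply(1:40, function(i) {
    idx <- sample(150, 12)
    calls <- tibble::tibble(genome_a = "r", genome_b = "p",
                            gene_a = genes$gene_id[idx],
                            gene_b = paste0("p_", seq_along(idx)))
    spatial_uniformity_test(calls, gs, "r", n_perm = 99, seed = i)
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.05)
})

test_that("r/m follows the purged-substitution arithmetic", {
  # one called gene of 1000 bp with 0 mismatches on a 4% background
  genes <- dplyr::bind_rows(
    toy_genes("x", replicate(51, random_seq(1000))),
    toy_genes("y", replicate(51, random_seq(1000))))
  gx <- genes$gene_id[genes$genome_id == "x"]
  gy <- genes$gene_id[genes$genome_id == "y"]
  rbms <- tibble::tibble(
    genome_a = "x", genome_b = "y", gene_a = gx, gene_b = gy,
    identity = c(100, rep(96, 50)), aln_len = 1000L,
    mismatches = c(0L, rep(40L, 50)))
  calls <- tibble::tibble(genome_a = "x", genome_b = "y",
                          gene_a = gx[1], gene_b = gy[1])
  rm <- estimate_rm(rbms, calls, genes)
  expect_equal(rm$d_bg, 0.04)
  expect_equal(rm$r, 40)       # purged: 0.04 * 1000 - 0
  expect_equal(rm$m, 2000)     # 50 background genes x 40 mismatches
  expect_equal(rm$rm_purged, 40 / 2000)
  # no calls: r = 0
  rm0 <- estimate_rm(rbms, calls[0, ], genes)
  expect_equal(rm0$r, 0)
  expect_equal(rm0$rm_purged, 0)
})
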