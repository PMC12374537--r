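small_cfg <- function(n_genes = 60, ...) {
  sim_config(n_species = 2, genomes_per_species = 3,
             phylogroups = list(2, 1),
             phylogroup_half_divergence = c(0.027, 0.0455),
             n_genes = n_genes, ...)
}

test_that("generation is byte-reproducible under a fixed seed", {
  p1 <- generate_population(small_cfg(recomb_rate = 2, seed = 40))
  p2 <- generate_population(small_cfg(recomb_rate = 2, seed = 40))
  expect_identical(p1$genes, p2$genes)
  expect_identical(p1$truth, p2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_population(p1, d1); write_population(p2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  p3 <- generate_population(small_cfg(recomb_rate = 2, seed = 41))
  expect_false(identical(p1$genes$seq, p3$genes$seq))
})

test_that("measured ANI hits the configured targets within half a point", {
  pop <- generate_population(sim_pair_config(94, n_genes = 400, seed = 42))
  gs <- as_genome_set(pop)
  ani <- compute_ani(rbm_pair(gs, "s1_g01", "s1_g02")$identity)
  expect_equal(ani, 94, tolerance = 0.5 / 94)
  pop97 <- generate_population(sim_pair_config(97, n_genes = 400, seed = 43))
  ani97 <- compute_ani(rbm_pair(as_genome_set(pop97), "s1_g01", "s1_g02")$identity)
  expect_equal(ani97, 97, tolerance = 0.5 / 97)
})

test_that("realized divergence in the truth set matches the measurement when recombination is off", {
  pop <- generate_population(small_cfg(recomb_rate = 0, seed = 44, n_genes = 100))
  gs <- as_genome_set(pop)
  pw <- pairwise_summary(rbm_all_pairs(gs), min_rbm = 20)
  joined <- dplyr::left_join(pw, pop$truth$divergence, by = c("genome_a", "genome_b"))
  # within species RBM recovery is complete, so the truth divergence and the
  # measurement agree tightly; inter-species pairs additionally reflect the
  # RBM-formation filter and are compared loosely
  intra <- startsWith(joined$genome_a, "s1") == startsWith(joined$genome_b, "s1")
  expect_true(all(abs((1 - joined$ani / 100) - joined$d_realized)[intra] <= 0.005))
  expect_true(all(abs((1 - joined$ani / 100) - joined$d_realized) <= 0.02))
})

test_that("recombination injection replaces exactly the tract interval", {
  cfg <- small_cfg(recomb_rate = 0, seed = 45, n_genes = 100)
  pop <- generate_population(cfg)
  set.seed(45)
  pop2 <- inject_recombination(pop, n_events_per_species = 3,
                               tract_len_sampler = function(n) rep(2000, n))
  pop2 <- recombinr:::sim_finalise(pop2)
  ev <- pop2$truth$recomb
  expect_equal(nrow(ev), 6)
  expect_true(all(ev$end_bp - ev$start_bp == 2000))
  for (i in seq_len(nrow(ev))) {
    genes_in <- ev$genes_replaced[[i]]
    if (length(genes_in) == 0) next
    rec <- pop2$genes[pop2$genes$genome_id == ev$recipient[i] &
                        pop2$genes$gene_index %in% genes_in, ]
    don <- pop2$genes[pop2$genes$genome_id == ev$donor[i] &
                        pop2$genes$gene_index %in% genes_in, ]
    expect_identical(rec$seq, don$seq) # replaced genes are donor-identical
    # and the truth interval really contains them
    expect_true(all(rec$start >= ev$start_bp[i] & rec$end <= ev$end_bp[i]))
  }
  # rate 0 leaves the truth event list empty
  expect_equal(nrow(pop$truth$recomb), 0)
})

test_that("tract length mixture puts the modal bin at 1-3 kb", {
  cfg <- small_cfg(recomb_rate = 0, seed = 46)
  set.seed(46)
  lens <- cfg$tract_len_sampler(500)
  bins <- cut(lens / 1000, c(0, 1, 3, 5, 10, 20), right = FALSE)
  expect_equal(names(which.max(table(bins))), "[1,3)")
  expect_true(all(lens >= 1000 & lens <= 20000))
})

test_that("gene content is conserved through injections", {
  pop <- generate_population(small_cfg(recomb_rate = 3, seed = 47,
                                       sweep_ops = list(c(10, 3))))
  counts <- dplyr::count(pop$genes, genome_id)
  expect_true(all(counts$n == 60))
})

test_that("sweep injection spreads one allele at high identity across the species", {
  pop <- generate_population(small_cfg(recomb_rate = 0, seed = 48,
                                       sweep_ops = list(c(20, 3))))
  gs <- as_genome_set(pop)
  rbms <- rbm_all_pairs(gs)
  swept_ids <- pop$genes$gene_id[pop$genes$gene_index %in% 20:22]
  same_species <- startsWith(rbms$genome_a, "s1") == startsWith(rbms$genome_b, "s1")
  sw_intra <- rbms$identity[rbms$gene_a %in% swept_ids & same_species]
  expect_true(all(sw_intra >= 99.5))
  # an empty sweep list changes nothing
  p0 <- generate_population(small_cfg(recomb_rate = 0, seed = 48))
  p1 <- generate_population(small_cfg(recomb_rate = 0, seed = 48, sweep_ops = list()))
  expect_identical(p0$genes, p1$genes)
  # an operon over a constraint gene is rejected
  cfg_bad <- small_cfg(recomb_rate = 0, seed = 48, n_constraint_genes = 60,
                       sweep_ops = list(c(1, 2)))
  expect_error(generate_population(cfg_bad), "constraint")
})

test_that("ultra-conserved genes and exactly those genes are constraint-flagged", {
  cfg <- sim_config(n_species = 2, genomes_per_species = 2,
                    phylogroups = list(1, 1),
                    phylogroup_half_divergence = c(0.027, 0.0455),
                    n_genes = 120, n_constraint_genes = 3,
                    constraint_rate = 0, recomb_rate = 0, seed = 49)
  pop <- generate_population(cfg)
  gs <- as_genome_set(pop)
  rbms <- rbm_all_pairs(gs)
  pw <- pairwise_summary(rbms, min_rbm = 20)
  fams <- build_gene_families(rbms)
  flagged <- flag_constraint_conserved(fams, rbms, pw)
  truth_idx <- pop$truth$rates$gene_index[pop$truth$rates$constraint]
  truth_gene_ids <- pop$genes$gene_id[pop$genes$gene_index %in% truth_idx]
  truth_fams <- unique(fams$family_id[fams$gene_id %in% truth_gene_ids])
  # every planted zero-rate family is recovered ...
  expect_true(all(truth_fams %in% flagged))
  expect_equal(length(truth_fams), 3)
  # ... and anything else the filter flags is genuinely ultra-slow
  extra <- setdiff(flagged, truth_fams)
  if (length(extra) > 0) {
    extra_genes <- fams$gene_id[fams$family_id %in% extra]
    idx <- unique(pop$genes$gene_index[pop$genes$gene_id %in% extra_genes])
    expect_true(all(pop$truth$rates$rate[idx] < 0.05))
  }
})

test_that("completeness subsampling drops the configured gene fraction", {
  pop <- generate_population(small_cfg(recomb_rate = 0, seed = 50,
                                       completeness = 0.8))
  counts <- dplyr::count(pop$genes, genome_id)
  expect_true(all(counts$n == 60 - round(0.2 * 60)))
  expect_equal(nrow(pop$truth$dropped), 6 * round(0.2 * 60))
})

test_that("unattainable divergence targets are rejected with a clear message", {
  expect_error(invert_measured_ani(86), "attainable")
  cfg <- small_cfg(inter_species_ani = 86)
  expect_error(generate_population(cfg), "attainable")
})
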