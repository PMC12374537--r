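pw3 <- tibble::tibble(
  genome_a = c("g1", "g1", "g2"),
  genome_b = c("g2", "g3", "g3"),
  ani = c(99, 98, 99))

test_that("the ANI matrix is symmetric with 100 on the diagonal", {
  m <- ani_matrix(pw3)
  expect_equal(dim(m), c(3, 3))
  expect_equal(diag(m), setNames(rep(100, 3), c("g1", "g2", "g3")))
  expect_equal(m, t(m))
  expect_equal(m["g1", "g3"], 98)
})

test_that("single-linkage clustering obeys transitivity and treats NA as no edge", {
  m <- ani_matrix(pw3)
  cl <- cluster_at_threshold(m, 98.5)
  expect_equal(unname(cl), rep("g1", 3)) # g1-g2 and g2-g3 edges chain g3 in
  m2 <- m; m2[] <- 90; diag(m2) <- 100
  expect_equal(length(unique(cluster_at_threshold(m2, 98.5))), 3)
  m3 <- m; m3["g1", "g2"] <- NA; m3["g2", "g1"] <- NA; m3["g2", "g3"] <- NA; m3["g3", "g2"] <- NA
  expect_equal(length(unique(cluster_at_threshold(m3, 98.5))), 3)
})

test_that("tier assignments nest for random matrices", {
  set.seed(5)
  for (rep in 1:10) {
    n <- 8
    v <- matrix(runif(n * n, 85, 100), n)
    m <- (v + t(v)) / 2; diag(m) <- 100
    rownames(m) <- colnames(m) <- paste0("g", 1:n)
    tiers <- assign_tiers(m)
    agg <- dplyr::distinct(tiers, genomovar, phylogroup)
    expect_equal(anyDuplicated(agg$genomovar), 0)
    agg2 <- dplyr::distinct(tiers, phylogroup, species)
    expect_equal(anyDuplicated(agg2$phylogroup), 0)
  }
})

test_that("pair bands follow the half-open caption intervals", {
  expect_equal(assign_pair_group(97.3), "B")
  expect_equal(assign_pair_group(94.0), "C")
  expect_equal(assign_pair_group(96.5), "C") # boundary assigned downward
  expect_equal(assign_pair_group(98.5), "B")
  expect_equal(assign_pair_group(99.0), "A")
  expect_equal(assign_pair_group(91.0), "D")
  expect_true(is.na(assign_pair_group(90.0)))
  expect_error(assign_pair_group(NA_real_), "undefined")
})

test_that("group A agrees with genomovar clustering at 98.5", {
  set.seed(6)
  for (rep in 1:10) {
    n <- 6
    v <- matrix(runif(n * n, 90, 100), n)
    m <- (v + t(v)) / 2; diag(m) <- 100
    rownames(m) <- colnames(m) <- paste0("g", 1:n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (assign_pair_group(m[i, j]) %in% "A") {
        cl <- cluster_at_threshold(m, 98.5)
        expect_equal(unname(cl[i]), unname(cl[j]))
      }
    }
  }
})

test_that("the ANI gap detector finds an empty interior and rejects unimodality", {
  set.seed(10)
  vals <- rep(c(86, 87, 88, 92, 93, 94), each = 10) + rnorm(60, 0, 0.15)
  gap <- detect_ani_gap(vals)
  expect_s3_class(gap, "ani_gap")
  expect_gt(gap$lo, 88)
  expect_lt(gap$hi, 92)
  expect_lt(gap$lo, gap$hi)
  expect_null(detect_ani_gap(rnorm(100, 94, 1)))
  expect_error(detect_ani_gap(c(90, 95)), "at least 30")
})

test_that("gap detection ignores value order and sub-floor values", {
  set.seed(11)
  vals <- rep(c(87, 93), each = 25) + rnorm(50, 0, 0.2)
  g1 <- detect_ani_gap(vals)
  g2 <- detect_ani_gap(sample(vals))
  g3 <- detect_ani_gap(c(vals, runif(20, 40, 74.9)))
  expect_equal(tidy(g1), tidy(g2))
  expect_equal(tidy(g1), tidy(g3))
})

test_that("group profiles assign genomovars to their bands and count each gene once", {
  # two genomovars in band B, one in C, one in D
  tiers <- tibble::tibble(
    genome_id = c("r", "b1", "b2", "c1", "d1"),
    genomovar = c("r", "b1", "b2", "c1", "d1"),
    phylogroup = "p1", species = "s1")
  genes <- toy_genes("r", replicate(10, random_seq(50)))
  mk_rbm <- function(partner, ident_genes, bg = 97.2) {
    tibble::tibble(
      genome_a = "r", genome_b = partner,
      gene_a = genes$gene_id, gene_b = paste0(partner, "_", 1:10),
      identity = ifelse(seq_len(10) %in% ident_genes, 100, bg),
      aln_len = 50L, mismatches = 0L)
  }
  rbms <- dplyr::bind_rows(mk_rbm("b1", 1:4), mk_rbm("b2", 3:6),
                           mk_rbm("c1", 1:2, bg = 95), mk_rbm("d1", 1, bg = 92))
  pairwise <- tibble::tibble(genome_a = "r",
                             genome_b = c("b1", "b2", "c1", "d1"),
                             ani = c(97.5, 97.4, 95.0, 92.0))
  prof <- group_profiles(rbms, pairwise, tiers, "r", genes, tau = 99.8)
  expect_equal(sort(prof$fraction[prof$group == "B"]), c(0.4, 0.4))
  expect_equal(prof$genomovar[prof$group == "C"], "c1")
  expect_equal(prof$fraction[prof$group == "C"], 0.2)
  expect_equal(prof$genomovar[prof$group == "D"], "d1")
  expect_equal(prof$fraction[prof$group == "D"], 0.1)
  # E is the union over the B band only: genes 1..6, each counted once
  e_val <- prof$fraction[prof$group == "E"]
  expect_equal(e_val, 0.6)
  expect_gte(e_val, max(prof$fraction[prof$group == "B"]))
  # F is the union over the D band
  expect_equal(prof$fraction[prof$group == "F"], 0.1)
})
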