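# Population simulator: multi-species bacterial genome collections with
# tiered divergence structure, among-gene rate heterogeneity, homologous
# recombination tracts and operon-scale gene sweeps, plus machine-readable
# ground truth. Sequences are evolved on an explicit genealogy
# (root -> species -> phylogroup -> genomovar -> genome) by Jukes-Cantor-style
# substitutions: per gene and branch, Poisson(r_g * t * L_g) substitutions at
# distinct random sites, each to one of the three other bases; the rate
# multiplier r_g ~ gamma(alpha, mean 1) is a property of the gene, shared by
# the whole population (slow genes are slow everywhere).

#' Expected measured ANI for a substitution path length
#'
#' Maps a substitution divergence (expected substitutions per site summed
#' along the path between two genomes) to the gene-based ANI the pipeline
#' would measure, accounting for among-gene gamma rate heterogeneity, for
#' cross-branch substitution collisions, and for the reporting floor that
#' excludes gene identities below `floor` percent from the ANI mean.
#'
#' @param s Substitution path length (expected substitutions per site).
#' @param alpha Gamma shape of per-gene rates.
#' @param floor ANI reporting floor in percent identity.
#' @param gene_len Gene length governing the binomial spread of per-gene
#'   identities around their expectation.
#' @return Expected measured percent ANI.
#' @export
expected_measured_ani <- function(s, alpha = 0.88, floor = 75, gene_len = 900) {
  stopifnot(is_scalar_number(s), s >= 0)
  if (s == 0) return(100)
  # per-site mismatch probability for rate r: both branch halves hit
  # independently, a doubly-hit site still differs with probability 2/3;
  # per-gene identity is smeared binomially (normal approximation) around
  # its expectation, which matters for genes near the reporting floor
  parts <- function(r) {
    p <- pmin(r * s / 2, 1)
    q <- 2 * p - (4 / 3) * p^2
    mu <- 100 * (1 - q)
    sig <- pmax(100 * sqrt(q * (1 - q) / gene_len), 1e-9)
    z <- (mu - floor) / sig
    keep <- stats::pnorm(z)
    kept_mean <- mu + sig * stats::dnorm(z) / pmax(keep, 1e-12)
    list(keep = keep, contrib = kept_mean * keep)
  }
  upper <- stats::qgamma(1 - 1e-10, shape = alpha, rate = alpha)
  num <- integrate(function(r) parts(r)$contrib * dgamma(r, alpha, alpha),
                   0, upper, rel.tol = 1e-8)$value
  den <- integrate(function(r) parts(r)$keep * dgamma(r, alpha, alpha),
                   0, upper, rel.tol = 1e-8)$value
  if (den <= 0) return(NaN)
  num / den
}

# substitution path length that realises a target measured ANI; the measured
# scale saturates near 88 under heavy rate heterogeneity, hence the bound
invert_measured_ani <- function(target_ani, alpha = 0.88, floor = 75) {
  stopifnot(target_ani > floor, target_ani < 100)
  lo_attain <- expected_measured_ani(1.5, alpha, floor)
  if (target_ani <= lo_attain) {
    rb_abort(sprintf(
      "target ANI %.2f is below the attainable measured range (> %.2f) under gamma rate heterogeneity (alpha = %.3g) and the %.0f%% reporting floor",
      target_ani, lo_attain, alpha, floor))
  }
  uniroot(function(s) expected_measured_ani(s, alpha, floor) - target_ani,
          lower = 1e-8, upper = 1.5, tol = 1e-10)$root
}

#' Simulation configuration
#'
#' Defines the study conditions the simulator emulates: a multi-species
#' population with nested genomovar / phylogroup structure (intra-species
#' ANI spread ~92-99.5 with mode ~94, inter-species band ~86-88), among-gene
#' gamma rate heterogeneity, a few ultra-conserved rRNA-like genes,
#' recombination tracts of 1-20 kb (majority 1-3 kb) and optional
#' operon-scale sweeps. Divergence targets are given in measured-ANI space
#' and inverted internally to substitution branch lengths through
#' [expected_measured_ani()].
#'
#' @param n_species Number of species.
#' @param genomes_per_species Genomes per species; must match the phylogroup
#'   structure.
#' @param phylogroups List of integer vectors, one per phylogroup, giving the
#'   genomovar sizes within it (default `list(c(2, 2), 2, 1, 1)`: 8 genomes).
#' @param phylogroup_half_divergence Measured half-divergence of each
#'   phylogroup: a pair from phylogroups i and j targets ANI
#'   `100 * (1 - d_i - d_j)`.
#' @param genomovar_ani Target measured ANI within a genomovar.
#' @param phylogroup_ani Target measured ANI between genomovars of the same
#'   phylogroup.
#' @param inter_species_ani Target measured ANI between species.
#' @param n_genes Genes per genome.
#' @param gene_len_mean,gene_len_sd,gene_len_min Lognormal gene length model
#'   (natural-scale mean/sd, bp); `gene_len_sd = 0` gives fixed lengths.
#' @param spacer_len Intergenic spacer length in bp.
#' @param alpha Gamma shape of per-gene rate multipliers.
#' @param n_constraint_genes Number of ultra-conserved genes.
#' @param constraint_rate Rate multiplier of the ultra-conserved genes.
#' @param recomb_rate Recombination events per genome (events per species =
#'   `recomb_rate * genomes_per_species`).
#' @param tract_len_sampler Function `n -> tract lengths in bp`; default is
#'   the 80% Uniform(1, 3) kb + 20% Uniform(3, 20) kb mixture.
#' @param sweep_ops List of `c(start_gene_index, n_genes)` operons swept in
#'   every species.
#' @param sweep_residual_rate Residual substitution rate per site applied to
#'   each swept copy.
#' @param completeness Fraction of genes retained per genome (1 = complete).
#' @param ani_floor Reporting floor used by the measured-ANI inversion.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 2,
                       genomes_per_species = 8,
                       phylogroups = list(c(2, 2), 2, 1, 1),
                       phylogroup_half_divergence = c(0.027, 0.029, 0.0335, 0.0455),
                       genomovar_ani = 99.2,
                       phylogroup_ani = 97.0,
                       inter_species_ani = 88.5,
                       n_genes = 1400,
                       gene_len_mean = 900, gene_len_sd = 300, gene_len_min = 150,
                       spacer_len = 100,
                       alpha = 0.88,
                       n_constraint_genes = 3, constraint_rate = 0.01,
                       recomb_rate = 6.25,
                       tract_len_sampler = NULL,
                       sweep_ops = list(),
                       sweep_residual_rate = 5e-4,
                       completeness = 1,
                       ani_floor = 75,
                       seed = 1) {
  phylogroups <- purrr::map(phylogroups, as.integer)
  if (sum(unlist(phylogroups)) != genomes_per_species) {
    rb_abort("phylogroup genomovar sizes must sum to genomes_per_species")
  }
  if (length(phylogroup_half_divergence) != length(phylogroups)) {
    rb_abort("need one phylogroup_half_divergence per phylogroup")
  }
  stopifnot(alpha > 0, n_genes >= 1, gene_len_mean > 0, spacer_len >= 0,
            recomb_rate >= 0, completeness > 0, completeness <= 1,
            n_constraint_genes >= 0, n_constraint_genes <= n_genes)
  if (any(phylogroup_half_divergence <= 0 | phylogroup_half_divergence >= 0.125)) {
    rb_abort("phylogroup half-divergences must lie in (0, 0.125)")
  }
  if (is.null(tract_len_sampler)) {
    tract_len_sampler <- function(n) {
      ifelse(runif(n) < 0.8, runif(n, 1000, 3000), runif(n, 3000, 20000))
    }
  }
  structure(list(
    n_species = n_species, genomes_per_species = genomes_per_species,
    phylogroups = phylogroups,
    phylogroup_half_divergence = phylogroup_half_divergence,
    genomovar_ani = genomovar_ani, phylogroup_ani = phylogroup_ani,
    inter_species_ani = inter_species_ani,
    n_genes = n_genes, gene_len_mean = gene_len_mean,
    gene_len_sd = gene_len_sd, gene_len_min = gene_len_min,
    spacer_len = spacer_len, alpha = alpha,
    n_constraint_genes = n_constraint_genes, constraint_rate = constraint_rate,
    recomb_rate = recomb_rate, tract_len_sampler = tract_len_sampler,
    sweep_ops = sweep_ops, sweep_residual_rate = sweep_residual_rate,
    completeness = completeness, ani_floor = ani_floor, seed = seed
  ), class = "sim_config")
}

#' Two-genome configuration at a target ANI
#'
#' Convenience wrapper for null-calibration experiments: one species, two
#' genomes (each its own genomovar and phylogroup) at a target measured ANI.
#'
#' @param ani Target measured ANI of the pair.
#' @param n_genes Genes per genome.
#' @param gene_len_sd Lognormal sd (0 = fixed-length genes).
#' @param ... Further arguments to [sim_config()].
#' @export
sim_pair_config <- function(ani, n_genes = 600, gene_len_sd = 0, ...) {
  half <- (100 - ani) / 200
  sim_config(n_species = 1, genomes_per_species = 2,
             phylogroups = list(1, 1),
             phylogroup_half_divergence = c(half, half),
             n_genes = n_genes, gene_len_sd = gene_len_sd,
             recomb_rate = 0, n_constraint_genes = 0, ...)
}

# mutate a genome (list of integer gene vectors, bases 1..4) along one branch
mutate_branch <- function(genes, rates, lens, t) {
  if (t <= 0) return(genes)
  m <- rpois(length(genes), rates * t * lens)
  m <- pmin(m, lens)
  for (g in which(m > 0)) {
    sites <- sample.int(lens[g], m[g])
    shift <- sample.int(3, m[g], replace = TRUE)
    genes[[g]][sites] <- ((genes[[g]][sites] - 1L + shift) %% 4L) + 1L
  }
  genes
}

sim_branch_lengths <- function(cfg) {
  inv <- function(ani) invert_measured_ani(ani, cfg$alpha, cfg$ani_floor)
  multi_gv <- any(vapply(cfg$phylogroups, length, integer(1)) > 1)
  multi_genome_gv <- any(unlist(cfg$phylogroups) > 1)
  t_g <- if (multi_genome_gv) inv(cfg$genomovar_ani) / 2 else 0.002
  t_G <- if (multi_gv) inv(cfg$phylogroup_ani) / 2 - t_g else 0
  if (t_G < 0) rb_abort("phylogroup_ani is too low for genomovar_ani")
  S <- vapply(cfg$phylogroup_half_divergence,
              function(d) inv(100 - 200 * d) / 2, numeric(1))
  t_P <- S - t_G - t_g
  if (any(t_P < 0)) rb_abort("phylogroup half-divergence too small for the within-phylogroup targets")
  n_per_pg <- vapply(cfg$phylogroups, sum, integer(1))
  S_bar <- sum(S * n_per_pg) / sum(n_per_pg)
  t_sp <- if (cfg$n_species > 1) inv(cfg$inter_species_ani) / 2 - S_bar else 0
  if (t_sp < 0) rb_abort("inter_species_ani too high for the intra-species structure")
  list(t_g = t_g, t_G = t_G, t_P = t_P, t_sp = t_sp)
}

#' Generate a synthetic genome population with ground truth
#'
#' Evolves an ancestral gene complement down the configured genealogy,
#' applies recombination events and gene sweeps, and returns the population
#' with its truth set. Runs are byte-reproducible under a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `sim_population`: list with `genes` (gene
#'   tibble), `contigs`, `contig_seqs` (named character), `truth` (list:
#'   `genomes`, `rates`, `divergence`, `recomb`, `sweeps`, `dropped`) and
#'   `config`.
#' @export
generate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes

  lens <- if (cfg$gene_len_sd > 0) {
    sdlog <- sqrt(log(1 + (cfg$gene_len_sd / cfg$gene_len_mean)^2))
    meanlog <- log(cfg$gene_len_mean) - sdlog^2 / 2
    pmax(cfg$gene_len_min, round(rlnorm(n, meanlog, sdlog)))
  } else rep(cfg$gene_len_mean, n)
  lens <- as.integer(lens)
  strands <- sample(c(1L, -1L), n, replace = TRUE)
  rates <- rgamma(n, shape = cfg$alpha, rate = cfg$alpha)
  constraint_idx <- if (cfg$n_constraint_genes > 0) {
    sort(sample.int(n, cfg$n_constraint_genes))
  } else integer(0)
  rates[constraint_idx] <- cfg$constraint_rate

  ancestor <- purrr::map(lens, function(L) sample.int(4L, L, replace = TRUE))
  spacers <- purrr::map(seq_len(n + 1), function(i) sample.int(4L, cfg$spacer_len, replace = TRUE))
  starts <- cfg$spacer_len * seq_len(n) + c(0L, cumsum(lens))[seq_len(n)]
  starts <- as.integer(starts)
  ends <- starts + lens
  contig_len <- as.integer((n + 1) * cfg$spacer_len + sum(lens))

  bl <- sim_branch_lengths(cfg)
  genomes <- list()       # genome_id -> list of gene int vectors
  membership <- list()    # genome_id -> (species, phylogroup, genomovar)
  for (si in seq_len(cfg$n_species)) {
    sp_id <- paste0("s", si)
    sp_genes <- mutate_branch(ancestor, rates, lens, bl$t_sp)
    g_counter <- 0L
    for (pi in seq_along(cfg$phylogroups)) {
      pg_id <- sprintf("%s_p%d", sp_id, pi)
      pg_genes <- mutate_branch(sp_genes, rates, lens, bl$t_P[pi])
      for (vi in seq_along(cfg$phylogroups[[pi]])) {
        gv_id <- sprintf("%s_v%d", pg_id, vi)
        gv_genes <- mutate_branch(pg_genes, rates, lens, bl$t_G)
        for (gi in seq_len(cfg$phylogroups[[pi]][vi])) {
          g_counter <- g_counter + 1L
          genome_id <- sprintf("%s_g%02d", sp_id, g_counter)
          genomes[[genome_id]] <- mutate_branch(gv_genes, rates, lens, bl$t_g)
          membership[[genome_id]] <- tibble::tibble(
            genome_id = genome_id, species = sp_id, phylogroup = pg_id,
            genomovar = gv_id)
        }
      }
    }
  }
  truth <- list(
    genomes = dplyr::bind_rows(membership),
    rates = tibble::tibble(gene_index = seq_len(n), rate = rates,
                           length = lens, strand = strands,
                           constraint = seq_len(n) %in% constraint_idx),
    recomb = tibble::tibble(event_id = integer(), species = character(),
                            recipient = character(), donor = character(),
                            start_bp = integer(), end_bp = integer(),
                            tract_len = integer(), genes_replaced = list()),
    sweeps = tibble::tibble(species = character(), operon_start = integer(),
                            operon_len = integer(), gene_index = integer(),
                            source = character()),
    dropped = tibble::tibble(genome_id = character(), gene_index = integer())
  )

  pop <- structure(list(
    genomes_raw = genomes, ancestor = ancestor,
    lens = lens, starts = starts, ends = ends,
    strands = strands, spacers = spacers, contig_len = contig_len,
    truth = truth, config = cfg, genes = NULL, contigs = NULL,
    contig_seqs = NULL
  ), class = "sim_population")

  if (cfg$recomb_rate > 0) {
    n_events <- round(cfg$recomb_rate * cfg$genomes_per_species)
    pop <- inject_recombination(pop, n_events_per_species = n_events,
                                tract_len_sampler = cfg$tract_len_sampler)
  }
  for (op in cfg$sweep_ops) {
    pop <- inject_sweep(pop, operon = op)
  }
  pop <- sim_finalise(pop)
  pop
}

#' Inject homologous recombination events
#'
#' For each event a recipient and a donor are drawn uniformly from the same
#' species (any genomovar), a tract start is drawn uniformly on the contig
#' and the donor's homologous interval (identical coordinates: genomes share
#' the ancestral frame, there are no indels) replaces the recipient's, gene
#' content unchanged. Events are appended to the truth set with the list of
#' genes fully inside the tract.
#'
#' @param pop A `sim_population` (before [sim_finalise()]; [generate_population()]
#'   calls this internally when `recomb_rate > 0`).
#' @param n_events_per_species Number of events per species.
#' @param tract_len_sampler Function `n -> bp lengths`.
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return The updated `sim_population`.
#' @export
inject_recombination <- function(pop, n_events_per_species,
                                 tract_len_sampler = NULL, seed = NULL) {
  stopifnot(inherits(pop, "sim_population"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- pop$config
  tract_len_sampler <- tract_len_sampler %||% cfg$tract_len_sampler
  memb <- pop$truth$genomes
  ev_id <- nrow(pop$truth$recomb)
  new_events <- list()
  for (sp in unique(memb$species)) {
    ids <- memb$genome_id[memb$species == sp]
    if (length(ids) < 2) next
    for (e in seq_len(n_events_per_species)) {
      recipient <- sample(ids, 1)
      donor <- sample(setdiff(ids, recipient), 1)
      tl <- as.integer(round(tract_len_sampler(1)))
      if (tl >= pop$contig_len) rb_abort("recombination tract longer than the genome")
      a <- as.integer(floor(runif(1, 0, pop$contig_len - tl)))
      b <- a + tl
      full <- which(pop$starts >= a & pop$ends <= b)
      partial <- setdiff(which(pop$ends > a & pop$starts < b), full)
      for (g in full) pop$genomes_raw[[recipient]][[g]] <- pop$genomes_raw[[donor]][[g]]
      for (g in partial) {
        os <- max(a, pop$starts[g]); oe <- min(b, pop$ends[g])
        idx <- (os - pop$starts[g] + 1L):(oe - pop$starts[g])
        if (length(idx) > 0) {
          pop$genomes_raw[[recipient]][[g]][idx] <- pop$genomes_raw[[donor]][[g]][idx]
        }
      }
      ev_id <- ev_id + 1L
      new_events[[length(new_events) + 1]] <- tibble::tibble(
        event_id = ev_id, species = sp, recipient = recipient, donor = donor,
        start_bp = a, end_bp = b, tract_len = tl, genes_replaced = list(full))
    }
  }
  pop$truth$recomb <- dplyr::bind_rows(pop$truth$recomb, dplyr::bind_rows(new_events))
  pop
}

#' Inject an operon-scale gene sweep
#'
#' Copies one genome's allele of the operon genes into every member of each
#' species, with a small residual substitution load per copy, emulating the
#' spread of an advantageous allele through the species by recombination.
#'
#' @param pop A `sim_population`.
#' @param operon `c(start_gene_index, n_genes)`.
#' @param residual_rate Residual substitutions per site per copy.
#' @param seed Optional seed; `NULL` continues the RNG stream.
#' @return The updated `sim_population`.
#' @export
inject_sweep <- function(pop, operon, residual_rate = NULL, seed = NULL) {
  stopifnot(inherits(pop, "sim_population"), length(operon) == 2)
  if (!is.null(seed)) set.seed(seed)
  residual_rate <- residual_rate %||% pop$config$sweep_residual_rate
  idx <- seq.int(operon[1], length.out = operon[2])
  if (any(idx > pop$config$n_genes)) rb_abort("operon extends beyond the gene complement")
  constraint_idx <- pop$truth$rates$gene_index[pop$truth$rates$constraint]
  if (any(idx %in% constraint_idx)) {
    rb_abort("sweep operon overlaps a constraint-conserved gene")
  }
  memb <- pop$truth$genomes
  new_rows <- list()
  for (sp in unique(memb$species)) {
    ids <- memb$genome_id[memb$species == sp]
    source <- ids[1]
    for (gid in ids) {
      for (g in idx) {
        seq_g <- pop$genomes_raw[[source]][[g]]
        if (gid != source) {
          m <- min(rpois(1, residual_rate * length(seq_g)), length(seq_g))
          if (m > 0) {
            sites <- sample.int(length(seq_g), m)
            shift <- sample.int(3, m, replace = TRUE)
            seq_g[sites] <- ((seq_g[sites] - 1L + shift) %% 4L) + 1L
          }
        }
        pop$genomes_raw[[gid]][[g]] <- seq_g
      }
    }
    new_rows[[length(new_rows) + 1]] <- tibble::tibble(
      species = sp, operon_start = as.integer(operon[1]),
      operon_len = as.integer(operon[2]), gene_index = as.integer(idx),
      source = source)
  }
  pop$truth$sweeps <- dplyr::bind_rows(pop$truth$sweeps, dplyr::bind_rows(new_rows))
  pop
}

BASES <- c("A", "C", "G", "T")

# realised pairwise divergence measured directly from the final sequences,
# with the same >= floor identity filter the ANI computation applies
sim_realised_divergence <- function(pop) {
  ids <- names(pop$genomes_raw)
  lens <- pop$lens
  bounds <- c(0L, cumsum(lens))
  flat <- purrr::map(pop$genomes_raw, function(g) unlist(g, use.names = FALSE))
  floor_frac <- pop$config$ani_floor / 100
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  purrr::map(pairs, function(p) {
    neq <- cumsum(flat[[p[1]]] != flat[[p[2]]])
    at_ends <- neq[bounds[-1]]
    mism <- diff(c(0, at_ends))
    idf <- 1 - mism / lens
    keep <- idf >= floor_frac
    tibble::tibble(genome_a = p[1], genome_b = p[2],
                   d_realized = 1 - mean(idf[keep]),
                   frac_below_floor = mean(!keep))
  }) |>
    dplyr::bind_rows()
}

# materialise gene/contig tables and sequences; compute realised divergence
sim_finalise <- function(pop) {
  cfg <- pop$config
  n <- cfg$n_genes
  ids <- names(pop$genomes_raw)

  pop$truth$divergence <- sim_realised_divergence(pop)

  keep_idx <- purrr::map(ids, function(gid) {
    if (cfg$completeness < 1) {
      n_drop <- round((1 - cfg$completeness) * n)
      sort(setdiff(seq_len(n), sample.int(n, n_drop)))
    } else seq_len(n)
  })
  names(keep_idx) <- ids
  pop$truth$dropped <- purrr::imap(keep_idx, function(k, gid) {
    tibble::tibble(genome_id = gid, gene_index = setdiff(seq_len(n), k))
  }) |> dplyr::bind_rows()

  spacer_chr <- vapply(pop$spacers, function(s) paste(BASES[s], collapse = ""), character(1))
  gene_rows <- list()
  contig_rows <- list()
  contig_seqs <- character(0)
  for (gid in ids) {
    contig_id <- paste0(gid, "_c1")
    raw <- pop$genomes_raw[[gid]]
    gene_chr <- vapply(raw, function(s) paste(BASES[s], collapse = ""), character(1))
    embedded <- vapply(seq_len(n), function(g) {
      if (pop$strands[g] == 1L) gene_chr[g]
      else paste(BASES[5L - rev(raw[[g]])], collapse = "")
    }, character(1))
    contig_seqs[[contig_id]] <- paste0(
      paste0(vapply(seq_len(n), function(g) paste0(spacer_chr[g], embedded[g]), character(1)),
             collapse = ""),
      spacer_chr[n + 1])
    k <- keep_idx[[gid]]
    gene_rows[[gid]] <- tibble::tibble(
      gene_id = sprintf("%s_%d", contig_id, k),
      genome_id = gid, contig_id = contig_id,
      start = pop$starts[k], end = pop$ends[k],
      strand = pop$strands[k], seq = gene_chr[k], gene_index = k)
    contig_rows[[gid]] <- tibble::tibble(genome_id = gid, contig_id = contig_id,
                                         length = pop$contig_len)
  }
  pop$genes <- dplyr::bind_rows(gene_rows)
  pop$contigs <- dplyr::bind_rows(contig_rows)
  pop$contig_seqs <- contig_seqs
  pop
}

#' @export
print.sim_population <- function(x, ...) {
  cat("<sim_population> ", length(x$genomes_raw), " genomes x ",
      x$config$n_genes, " genes, ", nrow(x$truth$recomb), " recombination events, ",
      nrow(x$truth$sweeps), " sweep rows\n", sep = "")
  invisible(x)
}

#' Convert a simulated population to a genome set
#'
#' @param pop A `sim_population`.
#' @return A [genome_set()] over the population's genes.
#' @export
as_genome_set <- function(pop) {
  stopifnot(inherits(pop, "sim_population"))
  genome_set(dplyr::select(pop$genes, -"gene_index"), pop$contigs)
}

#' Write a simulated population to disk
#'
#' Emits per-genome gene FASTAs (Prodigal-style headers), whole-genome
#' FASTAs, and the truth tables as TSV.
#'
#' @param pop A `sim_population`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir) {
  stopifnot(inherits(pop, "sim_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_fasta(as_genome_set(pop), dir)
  for (gid in names(pop$genomes_raw)) {
    cid <- paste0(gid, "_c1")
    ss <- Biostrings::DNAStringSet(setNames(pop$contig_seqs[[cid]], cid))
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(gid, ".fna")), width = 80)
  }
  write_table_tsv(pop$truth$genomes, file.path(dir, "truth_genomes.tsv"))
  write_table_tsv(pop$truth$rates, file.path(dir, "truth_rates.tsv"))
  write_table_tsv(pop$truth$divergence, file.path(dir, "truth_divergence.tsv"))
  write_table_tsv(pop$truth$recomb, file.path(dir, "truth_recomb.tsv"))
  write_table_tsv(pop$truth$sweeps, file.path(dir, "truth_sweeps.tsv"))
  invisible(dir)
}
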