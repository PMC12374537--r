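#' Pipeline configuration
#'
#' All tunable thresholds of the analysis in one place. The tier thresholds
#' must be ordered genomovar > phylogroup > species.
#'
#' @param call_tau Near-identity threshold for recombination calls (percent).
#' @param f100_tau Identity threshold of the F100 numerator (percent).
#' @param genomovar,phylogroup,species Tier ANI thresholds (percent).
#' @param ani_floor RBM identity floor entering the ANI mean (percent).
#' @param min_rbm Minimum RBMs for a defined ANI.
#' @param alpha,mean_gene_len Null-model parameters ([null_model_params()]).
#' @param id_floor,min_cov RBM hit floor (percent identity / coverage of the
#'   shorter gene).
#' @param core_frac Core-gene presence threshold for family classification.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(call_tau = 99.8, f100_tau = 100,
                            genomovar = 98.5, phylogroup = 96.5, species = 91,
                            ani_floor = 75, min_rbm = 50,
                            alpha = 0.88, mean_gene_len = 900,
                            id_floor = 70, min_cov = 0.5, core_frac = 0.8) {
  if (!(genomovar > phylogroup && phylogroup > species)) {
    rb_abort("tier thresholds must satisfy genomovar > phylogroup > species")
  }
  structure(list(call_tau = call_tau, f100_tau = f100_tau,
                 genomovar = genomovar, phylogroup = phylogroup, species = species,
                 ani_floor = ani_floor, min_rbm = min_rbm,
                 alpha = alpha, mean_gene_len = mean_gene_len,
                 id_floor = id_floor, min_cov = min_cov, core_frac = core_frac),
            class = "pipeline_config")
}

#' Run the full recombination analysis
#'
#' Orchestrates the stages end-to-end: RBMs for all genome pairs, per-pair
#' ANI / F100 / excess test, tier clustering and ANI-gap detection,
#' constraint filtering and recombinant-gene calling with donors, tracts and
#' r/m, cumulative group profiles, and the gene-sweep scan.
#'
#' @param input A `genome_set`, a `sim_population`, or a directory of gene
#'   FASTA files.
#' @param config A [pipeline_config()].
#' @param verbose Progress messages.
#' @return An object of class `recomb_pipeline`: list with `genome_set`,
#'   `rbms`, `pairwise`, `tiers`, `gap`, `families`, `constraint`, `calls`,
#'   `tracts`, `rm`, `profiles`, `sweeps`, `config`.
#' @export
run_recombination_pipeline <- function(input, config = pipeline_config(),
                                       verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  gs <- if (inherits(input, "genome_set")) input
  else if (inherits(input, "sim_population")) as_genome_set(input)
  else if (is.character(input) && length(input) == 1 && dir.exists(input)) read_gene_dir(input)
  else rb_abort("input must be a genome_set, sim_population or directory")

  say <- function(...) if (verbose) message(...)
  params <- null_model_params(alpha = config$alpha,
                              mean_gene_len = config$mean_gene_len,
                              tau = config$f100_tau)

  say("stage rbm: all-vs-all reciprocal best matches")
  rbms <- rbm_all_pairs(gs, id_floor = config$id_floor, min_cov = config$min_cov,
                        verbose = verbose)
  say("stage pairwise: ANI / F100 / excess test")
  pairwise <- pairwise_summary(rbms, params, ani_floor = config$ani_floor,
                               min_rbm = config$min_rbm, f100_tau = config$f100_tau)
  say("stage tiers: clustering and gap detection")
  tiers <- assign_tiers(pairwise, genomovar = config$genomovar,
                        phylogroup = config$phylogroup, species = config$species)
  ani_values <- pairwise$ani[!is.na(pairwise$ani)]
  gap <- if (length(ani_values) >= 30) {
    detect_ani_gap(ani_values, lo_bound = config$ani_floor)
  } else NULL

  say("stage recomb: constraint filter and calls")
  families <- build_gene_families(rbms)
  constraint <- withCallingHandlers(
    flag_constraint_conserved(families, rbms, pairwise,
                              species_floor = config$species,
                              ident_tau = config$call_tau),
    warning = function(w) { say(conditionMessage(w)); invokeRestart("muffleWarning") })
  families <- classify_families(families, tiers, constraint,
                                core_frac = config$core_frac)
  calls <- call_recombinant_genes(rbms, pairwise, constraint, families,
                                  call_tau = config$call_tau,
                                  genomovar_threshold = config$genomovar,
                                  on_undefined = "drop")
  calls <- find_donors(calls, rbms, families, tiers, call_tau = config$call_tau)

  say("stage tracts and r/m")
  called_pairs <- dplyr::distinct(calls, .data$genome_a, .data$genome_b)
  tracts <- purrr::map2(called_pairs$genome_a, called_pairs$genome_b,
                        function(a, b) {
                          dplyr::bind_rows(
                            dplyr::mutate(recombinant_tracts(calls, gs, a, b), partner = b),
                            dplyr::mutate(recombinant_tracts(calls, gs, b, a), partner = a))
                        }) |> dplyr::bind_rows()
  rm_tbl <- estimate_rm(rbms, calls, gs)

  say("stage profiles: cumulative identical-gene fractions")
  profiles <- purrr::map(tiers$genome_id, function(g) {
    group_profiles(rbms, pairwise, tiers, g, gs, tau = config$call_tau)
  }) |> dplyr::bind_rows()

  say("stage sweeps")
  sweeps <- sweep_scan(families, rbms, pairwise, tiers,
                       allele_threshold = config$genomovar)

  structure(list(genome_set = gs, rbms = rbms, pairwise = pairwise,
                 tiers = tiers, gap = gap, families = families,
                 constraint = constraint, calls = calls, tracts = tracts,
                 rm = rm_tbl, profiles = profiles, sweeps = sweeps,
                 config = config),
            class = "recomb_pipeline")
}

#' @export
print.recomb_pipeline <- function(x, ...) {
  cat("<recomb_pipeline>\n")
  cat("  genomes:       ", nrow(x$tiers), "\n")
  cat("  genome pairs:  ", nrow(x$pairwise), "\n")
  cat("  species:       ", dplyr::n_distinct(x$tiers$species), "\n")
  cat("  genomovars:    ", dplyr::n_distinct(x$tiers$genomovar), "\n")
  if (!is.null(x$gap)) {
    cat(sprintf("  ANI gap:        %.1f%% - %.1f%%\n", x$gap$lo, x$gap$hi))
  } else cat("  ANI gap:        none detected\n")
  cat("  recomb calls:  ", nrow(x$calls), " gene-pair calls\n")
  cat("  sweeps:        ", sum(x$sweeps$swept), " swept families\n")
  invisible(x)
}

#' @describeIn run_recombination_pipeline per-pair summary joined with tier
#'   and band labels.
#' @param x A `recomb_pipeline`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.recomb_pipeline <- function(x, ...) {
  gv <- setNames(x$tiers$genomovar, x$tiers$genome_id)
  sp <- setNames(x$tiers$species, x$tiers$genome_id)
  n_calls <- x$calls |>
    dplyr::count(.data$genome_a, .data$genome_b, name = "n_calls")
  x$pairwise |>
    dplyr::left_join(n_calls, by = c("genome_a", "genome_b")) |>
    dplyr::mutate(n_calls = dplyr::coalesce(.data$n_calls, 0L),
                  same_species = sp[.data$genome_a] == sp[.data$genome_b],
                  same_genomovar = gv[.data$genome_a] == gv[.data$genome_b],
                  band = ifelse(is.na(.data$ani), NA_character_,
                                assign_pair_group(dplyr::coalesce(.data$ani, 0),
                                                  genomovar = x$config$genomovar,
                                                  phylogroup = x$config$phylogroup,
                                                  species = x$config$species)))
}

#' @describeIn run_recombination_pipeline one-row dataset overview.
#' @exportS3Method generics::glance
glance.recomb_pipeline <- function(x, ...) {
  tibble::tibble(
    n_genomes = nrow(x$tiers),
    n_pairs = nrow(x$pairwise),
    n_species = dplyr::n_distinct(x$tiers$species),
    n_phylogroups = dplyr::n_distinct(x$tiers$phylogroup),
    n_genomovars = dplyr::n_distinct(x$tiers$genomovar),
    ani_gap_lo = if (is.null(x$gap)) NA_real_ else x$gap$lo,
    ani_gap_hi = if (is.null(x$gap)) NA_real_ else x$gap$hi,
    n_calls = nrow(x$calls),
    n_swept_families = sum(x$sweeps$swept),
    median_f100_excess = median(
      x$pairwise$f100_observed - x$pairwise$f100_expected, na.rm = TRUE)
  )
}

#' Write all pipeline tables and a JSON summary to a directory
#'
#' Emits the TSV tables (`rbm`, `pairwise`, `tiers`, `calls`, `tracts`,
#' `rm`, `group_profiles`, `sweeps`) plus `summary.json`. Existing files are
#' kept unless `overwrite = TRUE`, so re-running over a populated directory
#' is a no-op.
#'
#' @param result A `recomb_pipeline`.
#' @param dir Output directory.
#' @param overwrite Replace existing files.
#' @return `dir`, invisibly.
#' @export
write_pipeline_tables <- function(result, dir, overwrite = FALSE) {
  stopifnot(inherits(result, "recomb_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    if (!file.exists(path) || overwrite) write_table_tsv(df, path)
  }
  emit(result$rbms, "rbm")
  emit(result$pairwise, "pairwise")
  emit(result$tiers, "tiers")
  emit(result$calls, "calls")
  emit(result$tracts, "tracts")
  emit(result$rm, "rm")
  emit(result$profiles, "group_profiles")
  emit(result$sweeps, "sweeps")
  json_path <- file.path(dir, "summary.json")
  if (!file.exists(json_path) || overwrite) {
    g <- glance(result)
    jsonlite::write_json(as.list(g), json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(dir)
}
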