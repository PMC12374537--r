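#' Read a gene FASTA with coordinate headers
#'
#' Reads a per-genome nucleotide FASTA of called genes whose headers carry
#' Prodigal-style coordinate fields, `>gene_id # start # end # strand [# ...]`,
#' with 1-based inclusive coordinates. Coordinates are converted to the
#' package-internal 0-based half-open convention and records are sorted by
#' contig and start position.
#'
#' The contig of each gene is inferred from the gene id by stripping the
#' trailing `_<number>` gene counter, following the gene-caller convention of
#' naming genes `<contig>_<n>`.
#'
#' @param path Path to a FASTA file.
#' @param genome_id Genome identifier to attach to every record.
#' @return A tibble of gene records with columns `gene_id`, `genome_id`,
#'   `contig_id`, `start`, `end` (0-based half-open), `strand` (+1/-1) and
#'   `seq` (upper-case nucleotides).
#' @examples
#' fa <- tempfile(fileext = ".fna")
#' writeLines(c(">g1_1 # 1 # 12 # 1", "ATGAAACCCGGG"), fa)
#' read_gene_fasta(fa, "g1")
#' @export
read_gene_fasta <- function(path, genome_id) {
  if (!file.exists(path)) rb_abort(paste0("file not found: ", path))
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) rb_abort(paste0("FASTA parse error in ", path, ": ",
                                                     conditionMessage(e))))
  if (length(ss) == 0) rb_abort(paste0("empty gene FASTA: ", path), "recombinr_empty_input")
  headers <- names(ss)
  fields <- stringr::str_split(headers, stringr::fixed(" # "))
  parse_one <- function(h, f, n) {
    if (length(f) < 4) {
      rb_abort(paste0("malformed gene header (need '# start # end # strand' fields): >", h))
    }
    start1 <- suppressWarnings(as.integer(f[[2]]))
    end1 <- suppressWarnings(as.integer(f[[3]]))
    strand <- suppressWarnings(as.integer(f[[4]]))
    if (is.na(start1) || is.na(end1) || is.na(strand) || !strand %in% c(1L, -1L)) {
      rb_abort(paste0("malformed coordinate fields in gene header: >", h))
    }
    if (end1 < start1) {
      rb_abort(paste0("gene header has end < start: >", h))
    }
    gene_id <- stringr::str_split_fixed(f[[1]], " ", 2)[, 1]
    c(gene_id = gene_id, start1 = start1, end1 = end1, strand = strand)
  }
  parsed <- purrr::map2(headers, fields, function(h, f) parse_one(h, f))
  gene_id <- purrr::map_chr(parsed, "gene_id")
  start1 <- as.integer(purrr::map_chr(parsed, "start1"))
  end1 <- as.integer(purrr::map_chr(parsed, "end1"))
  strand <- as.integer(purrr::map_chr(parsed, "strand"))

  seqs <- toupper(as.character(ss))
  genes <- tibble::tibble(
    gene_id = gene_id,
    genome_id = genome_id,
    contig_id = stringr::str_remove(gene_id, "_[0-9]+$"),
    start = start1 - 1L,
    end = end1,
    strand = strand,
    seq = unname(seqs)
  )
  bad_len <- nchar(genes$seq) != genes$end - genes$start
  if (any(bad_len)) {
    rb_abort(paste0("sequence length disagrees with coordinates for gene(s): ",
                    paste(utils::head(genes$gene_id[bad_len], 5), collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_id)) {
    rb_abort(paste0("duplicate gene ids within genome ", genome_id))
  }
  dplyr::arrange(genes, .data$contig_id, .data$start)
}

#' Read a whole-genome FASTA
#'
#' @param path Path to a FASTA file of contigs.
#' @return A tibble with columns `contig_id`, `length` and `seq`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) rb_abort(paste0("file not found: ", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0 || !startsWith(first, ">")) {
    rb_abort(paste0("not a FASTA file (no header line): ", path))
  }
  ss <- Biostrings::readDNAStringSet(path)
  ids <- stringr::str_split_fixed(names(ss), " ", 2)[, 1]
  if (anyDuplicated(ids)) rb_abort(paste0("duplicate contig ids in ", path))
  tibble::tibble(contig_id = ids,
                 length = Biostrings::width(ss),
                 seq = unname(toupper(as.character(ss))))
}

#' Bundle gene records (and contig lengths) into a validated genome set
#'
#' The genome set is the universal substrate consumed by all downstream
#' analyses: a gene table positioned on contigs, plus contig lengths. Gene
#' intervals on a contig may overlap by at most `overlap_slack` bp (gene
#' callers emit small overlaps at operon boundaries).
#'
#' @param genes Tibble of gene records as returned by [read_gene_fasta()],
#'   possibly row-bound across genomes.
#' @param contigs Optional tibble with `contig_id` and `length`. When absent,
#'   contig lengths are inferred as the maximal gene end per contig.
#' @param overlap_slack Maximum tolerated overlap between consecutive genes on
#'   a contig, in bp.
#' @return An object of class `genome_set`: a list with elements `genes` and
#'   `contigs`.
#' @export
genome_set <- function(genes, contigs = NULL, overlap_slack = 30) {
  assert_cols(genes, c("gene_id", "genome_id", "contig_id", "start", "end", "strand", "seq"),
              "genes")
  if (any(genes$end <= genes$start)) rb_abort("gene with end <= start")
  if (any(nchar(genes$seq) != genes$end - genes$start)) {
    rb_abort("gene sequence length disagrees with coordinates")
  }
  dup <- genes |>
    dplyr::count(.data$genome_id, .data$gene_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) rb_abort("duplicate gene ids within a genome")

  genes <- dplyr::arrange(genes, .data$genome_id, .data$contig_id, .data$start)
  overl <- genes |>
    dplyr::group_by(.data$genome_id, .data$contig_id) |>
    dplyr::mutate(prev_end = dplyr::lag(.data$end)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$prev_end), .data$prev_end - .data$start > overlap_slack)
  if (nrow(overl) > 0) {
    rb_abort(paste0("gene intervals overlap by more than ", overlap_slack,
                    " bp on contig ", overl$contig_id[1]))
  }

  if (is.null(contigs)) {
    contigs <- genes |>
      dplyr::group_by(.data$genome_id, .data$contig_id) |>
      dplyr::summarise(length = max(.data$end), .groups = "drop")
  } else {
    assert_cols(contigs, c("contig_id", "length"), "contigs")
    if (!"genome_id" %in% names(contigs)) {
      map <- dplyr::distinct(genes, .data$genome_id, .data$contig_id)
      contigs <- dplyr::left_join(contigs, map, by = "contig_id")
    }
    missing <- setdiff(unique(genes$contig_id), contigs$contig_id)
    if (length(missing) > 0) {
      rb_abort(paste0("gene contig absent from contig table: ", missing[1]))
    }
    beyond <- genes |>
      dplyr::left_join(contigs, by = c("genome_id", "contig_id")) |>
      dplyr::filter(.data$end > .data$length)
    if (nrow(beyond) > 0) rb_abort("gene extends beyond its contig length")
  }
  structure(list(genes = genes, contigs = contigs), class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("<genome_set> ", dplyr::n_distinct(x$genes$genome_id), " genomes, ",
      nrow(x$genes), " genes, ", nrow(x$contigs), " contigs\n", sep = "")
  invisible(x)
}

#' Read a directory of per-genome gene FASTAs into a genome set
#'
#' Every `*_genes.fna` (or `*.fna` when no `_genes` files exist) file in
#' `dir` is read with [read_gene_fasta()]; the genome id is the file name
#' minus the suffix.
#'
#' @param dir Directory containing gene FASTA files.
#' @param pattern Regular expression selecting gene FASTA files.
#' @return A `genome_set`.
#' @export
read_gene_dir <- function(dir, pattern = "_genes\\.(fna|fa|fasta)$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (length(files) == 0) rb_abort(paste0("no gene FASTA files in ", dir), "recombinr_empty_input")
  genes <- purrr::map(files, function(f) {
    gid <- sub(pattern, "", basename(f))
    read_gene_fasta(f, gid)
  })
  genome_set(dplyr::bind_rows(genes))
}

#' Write a tabular result to a TSV file
#'
#' Tab-separated, one header line, UTF-8, columns in their current order.
#' Numeric values keep full precision so a round-trip through
#' [read_table_tsv()] restores them exactly.
#'
#' @param records A data frame.
#' @param path Output path.
#' @export
write_table_tsv <- function(records, path) {
  if (!is.data.frame(records)) rb_abort("records must be a data frame")
  # drop list columns (serialised as comma-joined strings)
  records <- dplyr::mutate(records, dplyr::across(
    dplyr::where(is.list), ~ purrr::map_chr(.x, paste, collapse = ",")))
  readr::write_tsv(records, path, na = "NA")
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a genome set back to gene FASTA files
#'
#' Emits one `<genome_id>_genes.fna` per genome with Prodigal-style headers
#' (1-based inclusive coordinates), the inverse of [read_gene_fasta()].
#'
#' @param gs A `genome_set`.
#' @param dir Output directory (created if needed).
#' @export
write_gene_fasta <- function(gs, dir) {
  stopifnot(inherits(gs, "genome_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  split_genes <- split(gs$genes, gs$genes$genome_id)
  for (gid in names(split_genes)) {
    g <- split_genes[[gid]]
    ss <- Biostrings::DNAStringSet(g$seq)
    names(ss) <- sprintf("%s # %d # %d # %d # ID=%s", g$gene_id,
                         g$start + 1L, g$end, g$strand, g$gene_id)
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(gid, "_genes.fna")), width = 80)
  }
  invisible(dir)
}
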