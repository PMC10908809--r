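#' @title Tabular and sequence IO for virome pipelines
#' @description Readers and writers for the plain-text formats the pipeline
#'   consumes: UTF-8 TSV tables with mandatory headers and aligned FASTA (one
#'   file per entity, sample ids as record ids, wrapped at 80 columns). All
#'   readers validate headers, id uniqueness and alignment regularity and fail
#'   with file context.
#' @name virotrace-io
NULL

read_tsv_checked <- function(path, required, what, id_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, required, paste0(what, " (", path, ")"))
  if (!is.null(id_col) && anyDuplicated(df[[id_col]])) {
    dup <- unique(df[[id_col]][duplicated(df[[id_col]])])
    stop(sprintf("%s (%s): duplicate %s: %s", what, path, id_col,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write sample metadata
#'
#' @param path TSV file with columns `sample_id`, `individual_id`,
#'   `family_id`, `role`, `timepoint`, `age_days`, `source`, `library_size`,
#'   `dna_conc`.
#' @return data.frame of sample records.
#' @export
read_sample_metadata <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "individual_id", "family_id",
                                 "role", "timepoint", "age_days", "source",
                                 "library_size", "dna_conc"),
                         "sample metadata", id_col = "sample_id")
  if (!all(df$role %in% c("mother", "infant")))
    stop("role must be 'mother' or 'infant' (", path, ")", call. = FALSE)
  if (!all(df$source %in% c("VLP", "MGS", "TOTAL")))
    stop("source must be VLP, MGS or TOTAL (", path, ")", call. = FALSE)
  if (any(df$library_size <= 0))
    stop("library_size must be positive (", path, ")", call. = FALSE)
  df
}

#' @rdname read_sample_metadata
#' @param samples data.frame of sample records.
#' @export
write_sample_metadata <- function(samples, path) write_tsv(samples, path)

#' Read and write coverage tables
#'
#' @param path TSV with columns `scaffold_id`, `sample_id`, `read_count`,
#'   `breadth`, `scaffold_length`.
#' @return coverage data.frame.
#' @export
read_coverage_table <- function(path) {
  df <- read_tsv_checked(path, c("scaffold_id", "sample_id", "read_count",
                                 "breadth", "scaffold_length"),
                         "coverage table")
  if (any(df$breadth < 0 | df$breadth > 1))
    stop("breadth out of [0,1] (", path, ")", call. = FALSE)
  if (any(df$read_count < 0))
    stop("negative read counts (", path, ")", call. = FALSE)
  df
}

#' @rdname read_coverage_table
#' @param records coverage data.frame.
#' @export
write_coverage_table <- function(records, path) write_tsv(records, path)

#' Read and write abundance matrices
#'
#' Matrices are stored as TSV with an `entity_id` first column and one column
#' per sample.
#'
#' @param path TSV file path.
#' @return numeric matrix with entity rownames and sample colnames.
#' @export
read_abundance_matrix <- function(path) {
  df <- read_tsv_checked(path, "entity_id", "abundance matrix",
                         id_col = "entity_id")
  mat <- as.matrix(df[, setdiff(names(df), "entity_id"), drop = FALSE])
  rownames(mat) <- df$entity_id
  storage.mode(mat) <- "double"
  if (any(mat < 0)) stop("negative abundances (", path, ")", call. = FALSE)
  mat
}

#' @rdname read_abundance_matrix
#' @param mat abundance matrix.
#' @export
write_abundance_matrix <- function(mat, path) {
  df <- data.frame(entity_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read and write per-entity strain alignments (FASTA)
#'
#' One FASTA per entity; record ids are sample ids; all sequences must have
#' equal (aligned) length. Written FASTA is wrapped at 80 columns.
#'
#' @param path FASTA file path.
#' @return named character vector of aligned sequences.
#' @export
read_alignment_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(as.character(set), names(set))
  if (anyDuplicated(names(seqs)))
    stop("duplicate record ids in alignment ", path, call. = FALSE)
  if (length(unique(nchar(seqs))) > 1L)
    stop("ragged alignment lengths in ", path, " (",
         paste(range(nchar(seqs)), collapse = "-"), ")", call. = FALSE)
  toupper(seqs)
}

#' @rdname read_alignment_fasta
#' @param aln named character vector of aligned sequences.
#' @export
write_alignment_fasta <- function(aln, path) {
  set <- Biostrings::BStringSet(aln)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read and write the virus->host prediction map
#'
#' @param path TSV with columns `virus_id`, `host_id` and optionally
#'   `confidence`.
#' @return data.frame.
#' @export
read_host_map <- function(path) {
  read_tsv_checked(path, c("virus_id", "host_id"), "host map")
}

#' @rdname read_host_map
#' @param host_map data.frame.
#' @export
write_host_map <- function(host_map, path) write_tsv(host_map, path)

#' Read and write the planted-truth table of a synthetic cohort
#'
#' @param path TSV with columns `entity_id`, `kind`, `family_id`,
#'   `transmitted`, `coupled_host_id`.
#' @return data.frame.
#' @export
read_truth_table <- function(path) {
  df <- read_tsv_checked(path, c("entity_id", "kind", "family_id",
                                 "transmitted", "coupled_host_id"),
                         "truth table")
  df$transmitted <- as.logical(df$transmitted)
  df$coupled_host_id[df$coupled_host_id %in% c("", "NA")] <- NA_character_
  bad <- !is.na(df$coupled_host_id) & (!df$transmitted | df$kind != "virus")
  if (any(bad))
    stop("coupled_host_id may only be set for transmitted viruses (", path, ")",
         call. = FALSE)
  df
}

#' @rdname read_truth_table
#' @param truth data.frame.
#' @export
write_truth_table <- function(truth, path) write_tsv(truth, path)

#' Read scaffold annotation tables
#'
#' @param path TSV with the annotation fields consumed by
#'   [classify_viral()] and [vc_decontaminate()].
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_checked(path, c("scaffold_id", "length_bp", "circular",
                                 "virsorter_positive", "pvog_hits",
                                 "ribosomal_protein_genes", "rrna_hit",
                                 "refseq_viral_hit", "crass_hit", "nt_hit",
                                 "vc_id", "negctrl_cluster", "checkv_quality",
                                 "integrase", "recombinase", "ci_repressor"),
                         "annotation table", id_col = "scaffold_id")
  flag_cols <- c("circular", "virsorter_positive", "rrna_hit",
                 "refseq_viral_hit", "crass_hit", "nt_hit", "negctrl_cluster",
                 "integrase", "recombinase", "ci_repressor")
  for (cl in flag_cols) df[[cl]] <- as.logical(df[[cl]])
  df
}

#' @rdname read_annotations
#' @param annotations data.frame.
#' @export
write_annotations <- function(annotations, path) write_tsv(annotations, path)

#' Write a cohort bundle to a directory
#'
#' Serializes every component of a synthetic cohort in the same formats the
#' pipeline reads back: TSV tables plus one aligned FASTA per entity under
#' `alignments/virus/` and `alignments/bacteria/`.
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sample_metadata(cohort$samples, file.path(dir, "samples.tsv"))
  write_coverage_table(cohort$coverage, file.path(dir, "coverage.tsv"))
  write_abundance_matrix(cohort$abundance, file.path(dir, "abundance.tsv"))
  write_annotations(cohort$annotations, file.path(dir, "annotations.tsv"))
  write_host_map(cohort$host_map, file.path(dir, "host_map.tsv"))
  write_truth_table(cohort$truth, file.path(dir, "truth.tsv"))
  for (kind in c("virus", "bacteria")) {
    sub <- file.path(dir, "alignments", kind)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    for (e in names(cohort$alignments[[kind]]))
      write_alignment_fasta(cohort$alignments[[kind]][[e]],
                            file.path(sub, paste0(e, ".fasta")))
  }
  invisible(dir)
}

#' Read a cohort bundle from a directory written by [write_cohort()]
#'
#' @param dir directory path.
#' @return list with the same components as [generate_cohort()] output
#'   (minus `config` and `lifestyle`).
#' @export
read_cohort <- function(dir) {
  read_aln_dir <- function(sub) {
    files <- sort(list.files(sub, pattern = "\\.fasta$", full.names = TRUE))
    out <- lapply(files, read_alignment_fasta)
    stats::setNames(out, sub("\\.fasta$", "", basename(files)))
  }
  list(samples = read_sample_metadata(file.path(dir, "samples.tsv")),
       coverage = read_coverage_table(file.path(dir, "coverage.tsv")),
       abundance = read_abundance_matrix(file.path(dir, "abundance.tsv")),
       annotations = read_annotations(file.path(dir, "annotations.tsv")),
       host_map = read_host_map(file.path(dir, "host_map.tsv")),
       truth = read_truth_table(file.path(dir, "truth.tsv")),
       alignments = list(virus = read_aln_dir(file.path(dir, "alignments", "virus")),
                         bacteria = read_aln_dir(file.path(dir, "alignments", "bacteria"))))
}
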