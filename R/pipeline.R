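#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline with the study defaults:
#' breadth filter 0.75, presence breadth 0.95, persistence threshold 0.75,
#' candidate length 3000 bp, minimum 5 families, 100 bp alignment trimming,
#' 1000 permutation iterations, 999 Mantel permutations, alpha 0.05.
#'
#' @param input either a [cohort_config()] (synthetic mode) or a directory
#'   written by [write_cohort()].
#' @param breadth_threshold,presence_breadth,ppv_threshold,candidate_min_length,candidate_min_families,trim_bp,n_iter,n_perm,alpha
#'   stage thresholds (see module functions for semantics).
#' @param seed integer master seed.
#' @param out_dir optional output directory; when given, every stage writes
#'   its TSVs there and the configuration is serialized alongside.
#' @return list of class `run_config`.
#' @export
run_config <- function(input,
                       breadth_threshold = 0.75,
                       presence_breadth = 0.95,
                       ppv_threshold = 0.75,
                       candidate_min_length = 3000,
                       candidate_min_families = 5,
                       trim_bp = 100L,
                       n_iter = 1000L,
                       n_perm = 999L,
                       alpha = 0.05,
                       seed = 1L,
                       out_dir = NULL) {
  cfg <- list(input = input, breadth_threshold = breadth_threshold,
              presence_breadth = presence_breadth,
              ppv_threshold = ppv_threshold,
              candidate_min_length = candidate_min_length,
              candidate_min_families = candidate_min_families,
              trim_bp = as.integer(trim_bp), n_iter = as.integer(n_iter),
              n_perm = as.integer(n_perm), alpha = alpha,
              seed = as.integer(seed), out_dir = out_dir)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  in_range <- function(x, lo, hi) is.numeric(x) && length(x) == 1L &&
    is.finite(x) && x >= lo && x <= hi
  if (!in_range(cfg$breadth_threshold, 0, 1) || cfg$breadth_threshold == 0)
    stop("breadth_threshold must lie in (0, 1]", call. = FALSE)
  if (!in_range(cfg$presence_breadth, 0, 1))
    stop("presence_breadth must lie in [0, 1]", call. = FALSE)
  if (!in_range(cfg$ppv_threshold, 0, 1))
    stop("ppv_threshold must lie in [0, 1]", call. = FALSE)
  if (!in_range(cfg$alpha, 0, 1))
    stop("alpha must lie in [0, 1]", call. = FALSE)
  if (cfg$candidate_min_length < 0 || cfg$candidate_min_families < 1)
    stop("invalid candidate selection thresholds", call. = FALSE)
  if (cfg$trim_bp < 0 || cfg$n_iter < 1 || cfg$n_perm < 1)
    stop("trim_bp, n_iter and n_perm must be positive", call. = FALSE)
  if (!(inherits(cfg$input, "cohort_config") ||
        (is.character(cfg$input) && length(cfg$input) == 1L)))
    stop("input must be a cohort_config or a directory path", call. = FALSE)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file mirrors the arguments of [run_config()]; a `cohort` section
#' (arguments of [cohort_config()]) selects synthetic mode, an `input_dir`
#' entry selects file mode. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("cohort", "input_dir", "breadth_threshold", "presence_breadth",
             "ppv_threshold", "candidate_min_length", "candidate_min_families",
             "trim_bp", "n_iter", "n_perm", "alpha", "seed", "out_dir")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  input <- if (!is.null(y$cohort)) do.call(cohort_config, y$cohort)
           else if (!is.null(y$input_dir)) y$input_dir
           else stop("configuration needs either 'cohort' or 'input_dir'",
                     call. = FALSE)
  args <- y[setdiff(names(y), c("cohort", "input_dir"))]
  do.call(run_config, c(list(input = input), args))
}

#' Compare transmission calls against planted truth
#'
#' An entity counts as truly transmitted when the truth table flags it
#' transmitted in at least one family; it is called transmitted when its
#' BH-adjusted permutation p-value falls below `alpha`.
#'
#' @param results `results` table of a [transmission_analysis()].
#' @param truth truth table (per entity and family).
#' @param alpha FDR threshold (default 0.05).
#' @return list with the 2x2 `table`, `sensitivity`, `specificity`, `fdp`
#'   (false-discovery proportion among calls).
#' @export
transmission_confusion <- function(results, truth, alpha = 0.05) {
  truth_by_entity <- tapply(truth$transmitted, truth$entity_id, any)
  tested <- results[!is.na(results$q), ]
  is_true <- as.logical(truth_by_entity[tested$entity_id])
  called <- tested$q < alpha
  tp <- sum(called & is_true); fp <- sum(called & !is_true)
  fn <- sum(!called & is_true); tn <- sum(!called & !is_true)
  list(table = matrix(c(tp, fp, fn, tn), nrow = 2, byrow = TRUE,
                      dimnames = list(called = c("yes", "no"),
                                      truth = c("transmitted", "not"))),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       fdp = if (tp + fp > 0) fp / (tp + fp) else 0)
}

#' Run the full pipeline
#'
#' Executes curation, abundance construction, longitudinal dynamics, strain
#' distances, transmission inference and co-transmission linkage from one
#' configuration, and returns a run report accounting for every filtered
#' record. When the inputs carry a truth table, a confusion matrix for the
#' transmission calls is included. Outputs are identical for identical
#' configuration and seed.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_run` with `curated`, `abundance`,
#'   `dynamics`, `candidates`, `transmission`, `bacterial_transmission`,
#'   `cotransmission`, `truth_check`, and `report` (per-stage in/out counts).
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  cohort <- if (inherits(config$input, "cohort_config"))
    generate_cohort(config$input) else read_cohort(config$input)
  report <- list()

  ## curation
  ann <- cohort$annotations
  curated <- curate_scaffolds(ann)
  report$curation <- list(input = nrow(ann), retained = nrow(curated),
                          dropped = nrow(ann) - nrow(curated))

  ## abundance
  cov <- cohort$coverage[cohort$coverage$scaffold_id %in% curated$scaffold_id, ]
  filtered <- apply_breadth_filter(cov, config$breadth_threshold)
  lib <- stats::setNames(cohort$samples$library_size, cohort$samples$sample_id)
  abundance <- rpkm_transform(filtered, lib)
  report$abundance <- list(
    records = nrow(filtered),
    zeroed = sum(filtered$read_count == 0 & cov$read_count > 0))

  ## dynamics
  lifestyle <- stats::setNames(curated$lifestyle, curated$scaffold_id)
  nonzero <- colSums(abundance) > 0
  dyn_samples <- colnames(abundance)[nonzero]
  diversity <- data.frame(
    sample_id = dyn_samples,
    shannon = vapply(dyn_samples, function(s) shannon(abundance[, s]), numeric(1)),
    richness = colSums(abundance[, dyn_samples, drop = FALSE] > 0),
    temperate_fraction = temperate_fraction(
      abundance[, dyn_samples, drop = FALSE], lifestyle),
    stringsAsFactors = FALSE)
  meta <- cohort$samples
  vlp_meta <- meta[meta$source == "VLP" & meta$sample_id %in% dyn_samples, ]
  retention <- do.call(rbind, lapply(split(vlp_meta, vlp_meta$individual_id),
    function(df) {
      df <- df[order(df$age_days), ]
      if (nrow(df) < 2L) return(NULL)
      base <- abundance[, df$sample_id[1]]
      do.call(rbind, lapply(2:nrow(df), function(k) {
        rm <- retention_metrics(base, abundance[, df$sample_id[k]])
        data.frame(subject_id = df$individual_id[1],
                   baseline_label = df$timepoint[1],
                   later_label = df$timepoint[k],
                   n_retained = rm$n_retained,
                   pct_of_richness = rm$pct_of_richness,
                   cum_rel_abund = rm$cum_rel_abund,
                   stringsAsFactors = FALSE)
      }))
    }))
  rownames(retention) <- NULL
  persistence <- lapply(split(vlp_meta, vlp_meta$individual_id), function(df) {
    withCallingHandlers(
      persistence_partition(abundance[, df$sample_id, drop = FALSE],
                            config$ppv_threshold),
      warning = function(w) invokeRestart("muffleWarning"))
  })
  persistence <- Filter(Negate(is.null), persistence)
  dynamics <- list(diversity = diversity, retention = retention,
                   persistence = persistence)

  ## strain candidates + transmission
  candidates <- select_strain_candidates(
    cov, curated, meta, min_breadth = config$presence_breadth,
    min_length = config$candidate_min_length,
    min_families = config$candidate_min_families)
  v_aln <- cohort$alignments$virus[intersect(candidates,
                                             names(cohort$alignments$virus))]
  report$candidates <- list(curated_votus = nrow(curated),
                            candidates = length(candidates),
                            with_alignment = length(v_aln))
  transmission <- transmission_analysis(
    v_aln, meta, trim_bp = config$trim_bp, n_iter = config$n_iter,
    alpha = config$alpha, seed = child_seed(config$seed, 1L))
  bact_transmission <- transmission_analysis(
    cohort$alignments$bacteria, meta, trim_bp = config$trim_bp,
    n_iter = config$n_iter, alpha = config$alpha,
    seed = child_seed(config$seed, 2L))
  report$transmission <- list(
    tested = sum(!is.na(transmission$results$p_perm)),
    significant = sum(transmission$results$q < config$alpha, na.rm = TRUE))

  ## cotransmission
  cotrans <- cotransmission_analysis(
    transmission$details, bact_transmission$details, cohort$host_map, meta,
    n_perm = config$n_perm, alpha = config$alpha,
    seed = child_seed(config$seed, 3L))
  report$cotransmission <- list(
    pairs_tested = if (nrow(cotrans$results) > 0)
      sum(cotrans$results$status == "ok") else 0L,
    cotransmitted = if (nrow(cotrans$results) > 0)
      sum(cotrans$results$cotransmitted, na.rm = TRUE) else 0L)

  ## truth comparison (synthetic cohorts)
  truth_check <- NULL
  if (!is.null(cohort$truth)) {
    truth_check <- transmission_confusion(transmission$results, cohort$truth,
                                          config$alpha)
  }

  run <- structure(list(curated = curated, abundance = abundance,
                        dynamics = dynamics, candidates = candidates,
                        transmission = transmission,
                        bacterial_transmission = bact_transmission,
                        cotransmission = cotrans, truth_check = truth_check,
                        report = report, config = config),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) write_pipeline_outputs(run, cohort)
  run
}

write_pipeline_outputs <- function(run, cohort) {
  dir <- run$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_annotations(run$curated, file.path(dir, "curated_scaffolds.tsv"))
  write_abundance_matrix(run$abundance, file.path(dir, "abundance_rpkm.tsv"))
  write_tsv(run$dynamics$diversity, file.path(dir, "diversity.tsv"))
  if (!is.null(run$dynamics$retention))
    write_tsv(run$dynamics$retention, file.path(dir, "retention.tsv"))
  write_tsv(run$transmission$results, file.path(dir, "transmission.tsv"))
  write_tsv(run$bacterial_transmission$results,
            file.path(dir, "bacterial_transmission.tsv"))
  if (nrow(run$cotransmission$results) > 0)
    write_tsv(run$cotransmission$results, file.path(dir, "cotransmission.tsv"))
  cfg <- run$config
  cfg$input <- if (inherits(cfg$input, "cohort_config"))
    unclass(cfg$input) else cfg$input
  yaml::write_yaml(unclass(cfg), file.path(dir, "run_config.yaml"))
  jsonlite::write_json(run$report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
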