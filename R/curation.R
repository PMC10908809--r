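#' Classify scaffolds as putatively viral
#'
#' Applies six inclusion criteria to per-scaffold annotation features; a
#' scaffold >= 1 kbp is putatively viral if it satisfies at least one of:
#' \enumerate{
#'   \item a hit to the viral section of RefSeq (`refseq_viral_hit`),
#'   \item at least three ORFs with pVOG HMM hits and at least two hits per
#'     10 kb of scaffold length,
#'   \item VirSorter-positive (any of the six categories, including
#'     suggestive),
#'   \item a circular assembly,
#'   \item a hit to the Crassvirales reference set (`crass_hit`),
#'   \item longer than 3 kbp with no hit to the nt database.
#' }
#'
#' @param ann annotation data.frame (see [read_annotations()]). A missing
#'   `pvog_per_10kb` column is computed as `pvog_hits / (length_bp/1e4)`.
#' @return `ann` with added logical `is_viral` and character `criteria_hit`
#'   (comma-separated criterion numbers, e.g. `"3,4"`).
#' @export
classify_viral <- function(ann) {
  check_columns(ann, c("scaffold_id", "length_bp", "circular",
                       "virsorter_positive", "pvog_hits", "refseq_viral_hit",
                       "crass_hit", "nt_hit"), "annotation table")
  if (any(ann$length_bp < 1000))
    stop("scaffolds < 1 kbp must be removed before classification",
         call. = FALSE)
  if (is.null(ann$pvog_per_10kb))
    ann$pvog_per_10kb <- ann$pvog_hits / (ann$length_bp / 1e4)
  crit <- cbind(
    ann$refseq_viral_hit,
    ann$pvog_hits >= 3 & ann$pvog_per_10kb >= 2,
    ann$virsorter_positive,
    ann$circular,
    ann$crass_hit,
    ann$length_bp > 3000 & !ann$nt_hit)
  ann$is_viral <- rowSums(crit) > 0
  ann$criteria_hit <- apply(crit, 1, function(z) paste(which(z), collapse = ","))
  ann
}

#' Drop scaffolds whose dereplication cluster contains a negative control
#'
#' Scaffolds that co-cluster (99\% ANI) with scaffolds assembled from
#' negative-control libraries are treated as contamination and excluded.
#'
#' @param ann annotation data.frame with logical `negctrl_cluster`.
#' @return the retained rows.
#' @export
exclude_negative_control_clusters <- function(ann) {
  check_columns(ann, "negctrl_cluster", "annotation table")
  keep <- !ann$negctrl_cluster
  if (!any(keep)) warning("all scaffolds fell in negative-control clusters")
  ann[keep, , drop = FALSE]
}

#' Viral-cluster-level decontamination with member rescue
#'
#' Genus-level viral clusters (VCs) are condemned when any member (a) carries
#' an rRNA gene, (b) carries >= 1 ribosomal protein gene with < 3 pVOG hits
#' per 10 kb while being VirSorter-negative and non-circular, or (c) carries
#' more than 3 ribosomal protein genes. Members of condemned VCs are rescued
#' individually when (r1) circular with >= 1 pVOG hit, (r2) circular and
#' VirSorter-positive, or (r3) VirSorter-positive with no ribosomal protein
#' genes. Non-condemned VCs pass whole. Rescue takes precedence over
#' condemnation for the individual member.
#'
#' @param ann annotation data.frame; singletons/outliers/overlaps must carry
#'   their own `vc_id`.
#' @return the retained rows.
#' @export
vc_decontaminate <- function(ann) {
  check_columns(ann, c("vc_id", "rrna_hit", "ribosomal_protein_genes",
                       "virsorter_positive", "circular", "pvog_hits"),
                "annotation table")
  if (is.null(ann$pvog_per_10kb))
    ann$pvog_per_10kb <- ann$pvog_hits / (ann$length_bp / 1e4)
  condemning <- ann$rrna_hit |
    (ann$ribosomal_protein_genes >= 1 & ann$pvog_per_10kb < 3 &
       !ann$virsorter_positive & !ann$circular) |
    ann$ribosomal_protein_genes > 3
  vc_condemned <- tapply(condemning, ann$vc_id, any)
  condemned <- vc_condemned[ann$vc_id]
  rescued <- (ann$circular & ann$pvog_hits >= 1) |
    (ann$circular & ann$virsorter_positive) |
    (ann$virsorter_positive & ann$ribosomal_protein_genes == 0)
  ann[!condemned | rescued, , drop = FALSE]
}

#' Call phage lifestyle from gene content
#'
#' A vOTU is called temperate when it carries an integrase gene, or a
#' recombinase gene together with a CI-repressor-like protein gene; otherwise
#' it is called virulent.
#'
#' @param ann annotation data.frame with logical `integrase`, `recombinase`,
#'   `ci_repressor`.
#' @return character vector `"temperate"`/`"virulent"` named by scaffold id.
#' @export
call_lifestyle <- function(ann) {
  check_columns(ann, c("scaffold_id", "integrase", "recombinase",
                       "ci_repressor"), "annotation table")
  temperate <- ann$integrase | (ann$recombinase & ann$ci_repressor)
  stats::setNames(ifelse(temperate, "temperate", "virulent"), ann$scaffold_id)
}

#' Select vOTUs eligible for strain-level analysis
#'
#' Keeps vOTUs that satisfy all of: (1) a high-quality or complete genome by
#' CheckV, or a circularised genome; (2) sequence length >= 3 kbp; and (3)
#' presence in samples from at least `min_families` different families, where
#' presence means coverage breadth above `min_breadth` in both a maternal and
#' an infant sample of the family (the strain must be observable on both
#' sides of a potential transmission).
#'
#' @param coverage coverage table (post breadth computation, pre filtering).
#' @param annotations annotation table with `checkv_quality`, `circular`,
#'   `length_bp`.
#' @param metadata sample metadata.
#' @param min_breadth presence breadth cutoff (default 0.95, strict `>`).
#' @param min_length minimum scaffold length (default 3000).
#' @param min_families minimum number of mother-and-infant families
#'   (default 5).
#' @return character vector of candidate vOTU ids.
#' @export
select_strain_candidates <- function(coverage, annotations, metadata,
                                     min_breadth = 0.95, min_length = 3000,
                                     min_families = 5) {
  check_columns(coverage, c("scaffold_id", "sample_id", "breadth"),
                "coverage table")
  check_columns(annotations, c("scaffold_id", "checkv_quality", "circular",
                               "length_bp"), "annotation table")
  quality_ok <- annotations$checkv_quality %in% c("High-quality", "Complete") |
    annotations$circular
  length_ok <- annotations$length_bp >= min_length
  eligible <- annotations$scaffold_id[quality_ok & length_ok]

  cov <- coverage[coverage$breadth > min_breadth &
                    coverage$scaffold_id %in% eligible, ]
  m <- match(cov$sample_id, metadata$sample_id)
  cov$family_id <- metadata$family_id[m]
  cov$role <- metadata$role[m]
  fam_shared <- function(df) {
    roles <- tapply(df$role, df$family_id,
                    function(r) any(r == "mother") && any(r == "infant"))
    sum(roles, na.rm = TRUE)
  }
  n_fam <- vapply(split(cov, cov$scaffold_id), fam_shared, numeric(1))
  names(n_fam)[n_fam >= min_families]
}

#' Full scaffold curation stage
#'
#' Chains negative-control exclusion, the six-criteria viral classification
#' and VC-level decontamination, and annotates lifestyle calls.
#'
#' @param ann annotation data.frame.
#' @return data.frame of retained scaffolds with `criteria_hit` and
#'   `lifestyle` columns.
#' @export
curate_scaffolds <- function(ann) {
  ann <- exclude_negative_control_clusters(ann)
  ann <- classify_viral(ann)
  ann <- ann[ann$is_viral, , drop = FALSE]
  ann <- vc_decontaminate(ann)
  ann$lifestyle <- unname(call_lifestyle(ann))
  ann
}
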