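#' Zero out read counts with insufficient coverage breadth
#'
#' Spurious alignments inflate read counts for scaffolds that are only
#' patchily covered. Counts whose breadth of coverage is below the threshold
#' are set to zero; records at or above the threshold are untouched.
#'
#' @param records coverage table with columns `scaffold_id`, `sample_id`,
#'   `read_count`, `breadth`, `scaffold_length`.
#' @param threshold breadth cutoff in (0, 1]; default 0.75. The comparison is
#'   strict ("less than"), so records exactly at the threshold are retained.
#' @return the coverage table with filtered `read_count`.
#' @export
apply_breadth_filter <- function(records, threshold = 0.75) {
  stopifnot(threshold > 0, threshold <= 1)
  if (nrow(records) == 0L) return(records)
  check_columns(records, c("scaffold_id", "sample_id", "read_count",
                           "breadth", "scaffold_length"), "coverage table")
  if (any(records$breadth < 0 | records$breadth > 1))
    stop("breadth values must lie in [0, 1]", call. = FALSE)
  records$read_count[records$breadth < threshold] <- 0
  records
}

#' RPKM transform of a coverage table
#'
#' Converts breadth-filtered read counts into reads per kilobase of scaffold
#' per million mapped reads: `count / (length/1000) / (library_size/1e6)`.
#'
#' @param records coverage table (see [apply_breadth_filter()]).
#' @param library_sizes named numeric vector of per-sample mapped-read totals;
#'   names are sample ids.
#' @return numeric matrix, scaffolds x samples.
#' @export
#' @examples
#' rec <- data.frame(scaffold_id = "s1", sample_id = "a", read_count = 100,
#'                   breadth = 1, scaffold_length = 2000)
#' rpkm_transform(rec, c(a = 1e7))  # 5
rpkm_transform <- function(records, library_sizes) {
  check_columns(records, c("scaffold_id", "sample_id", "read_count",
                           "scaffold_length"), "coverage table")
  samples <- unique(records$sample_id)
  missing <- setdiff(samples, names(library_sizes))
  if (length(missing) > 0L)
    stop("missing library size for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(library_sizes[samples] <= 0))
    stop("library sizes must be positive", call. = FALSE)
  if (any(records$scaffold_length <= 0))
    stop("scaffold lengths must be positive", call. = FALSE)
  rpkm <- records$read_count / (records$scaffold_length / 1000) /
    (library_sizes[records$sample_id] / 1e6)
  entities <- unique(records$scaffold_id)
  mat <- matrix(0, length(entities), length(samples),
                dimnames = list(entities, samples))
  mat[cbind(match(records$scaffold_id, entities),
            match(records$sample_id, samples))] <- rpkm
  mat
}

#' Aggregate a vOTU abundance matrix by predicted host taxon
#'
#' Sums per-sample abundances over vOTUs that share a predicted host taxon.
#' vOTUs without a host assignment are collected under `"unassigned"`, so the
#' per-sample totals are conserved.
#'
#' @param matrix abundance matrix (vOTUs x samples).
#' @param host_map data.frame with columns `virus_id` and `host_id`
#'   (optionally `confidence`; when a vOTU has several hosts the single
#'   highest-confidence one is kept).
#' @return abundance matrix, host taxa x samples.
#' @export
aggregate_by_host <- function(matrix, host_map) {
  check_columns(host_map, c("virus_id", "host_id"), "host map")
  if ("confidence" %in% names(host_map) && anyDuplicated(host_map$virus_id)) {
    ord <- order(host_map$virus_id, -host_map$confidence)
    host_map <- host_map[ord, ]
    host_map <- host_map[!duplicated(host_map$virus_id), ]
  } else if (anyDuplicated(host_map$virus_id)) {
    stop("host map has duplicate virus ids and no confidence column to break ties",
         call. = FALSE)
  }
  absent <- setdiff(host_map$virus_id, rownames(matrix))
  if (length(absent) > 0L) {
    warning("host map entries absent from the matrix skipped: ",
            paste(absent, collapse = ", "))
    host_map <- host_map[!host_map$virus_id %in% absent, ]
  }
  host <- stats::setNames(host_map$host_id, host_map$virus_id)[rownames(matrix)]
  host[is.na(host)] <- "unassigned"
  groups <- rowsum(matrix, group = host)
  groups
}
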