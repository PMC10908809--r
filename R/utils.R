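#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`,
#' restoring the caller's RNG state afterwards, so that seeded operations do
#' not perturb an enclosing simulation.
#'
#' @param seed integer seed, or `NULL` to run with the current RNG state.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a parent seed and a counter.
# Keeps values in [0, 2^31 - 2] so they are valid R integer seeds.
child_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(counter) * 104729) %%
               (.Machine$integer.max - 1))
}

# Assert that a data.frame has the given columns, with file context in errors.
check_columns <- function(df, required, what = "table") {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Coerce an alignment (named character vector or Biostrings::DNAStringSet)
# to an n x L uppercase character matrix with sample ids as rownames.
alignment_matrix <- function(aln) {
  if (inherits(aln, "DNAStringSet")) aln <- as.character(aln)
  if (is.matrix(aln)) {
    mat <- toupper(aln)
  } else {
    if (is.null(names(aln)) || anyNA(names(aln)) || any(names(aln) == ""))
      stop("alignment records must be named by sample id", call. = FALSE)
    if (anyDuplicated(names(aln)))
      stop("duplicate sample ids in alignment: ",
           paste(unique(names(aln)[duplicated(names(aln))]), collapse = ", "),
           call. = FALSE)
    lens <- nchar(aln)
    if (length(unique(lens)) != 1L)
      stop("alignment has ragged sequence lengths (",
           paste(range(lens), collapse = "-"), ")", call. = FALSE)
    mat <- matrix(toupper(unlist(strsplit(aln, "", fixed = TRUE), use.names = FALSE)),
                  nrow = length(aln), byrow = TRUE,
                  dimnames = list(names(aln), NULL))
  }
  mat
}
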