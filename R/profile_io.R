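#' Read a functional abundance table
#'
#' Reads a tab-delimited table of molecular-function relative abundances
#' (e.g. KEGG Orthology profiles exported by functional-profiling tools)
#' into a profile matrix with samples as rows and function IDs as columns.
#'
#' Orientation is an explicit argument: many KO tables ship with functions
#' as rows and samples as columns (the default here), others the other way
#' around. No auto-detection is attempted, since a silently transposed
#' table is a correctness hazard. Empty cells are read as abundance 0;
#' function IDs are opaque strings and are preserved verbatim.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param orientation Either \code{"functions-as-rows"} (default) or
#'   \code{"samples-as-rows"}.
#' @param normalize If \code{TRUE} (default), each sample is rescaled to
#'   sum to 1 on load via \code{\link{normalize_profiles}}.
#' @return A numeric matrix (samples x functions) with unique sample IDs
#'   as row names and function IDs as column names.
#' @seealso \code{\link{write_profile_table}}, \code{\link{align_pairs}}
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, 2,
#'             dimnames = list(c("S1", "S2"), c("K00001", "K00002")))
#' write_profile_table(m, tf)
#' read_profile_table(tf, orientation = "samples-as-rows")
#' @export
read_profile_table <- function(path,
                               orientation = c("functions-as-rows",
                                               "samples-as-rows"),
                               normalize = TRUE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, row.names = NULL,
                      check.names = FALSE, stringsAsFactors = FALSE,
                      comment.char = ""),
    error = function(e) stopf("failed to parse header of %s: %s",
                              path, conditionMessage(e)))
  if (ncol(df) < 1L) stopf("malformed header in %s (line 1): no columns", path)
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(
    vapply(body, function(col) as.numeric(as.character(col)), numeric(nrow(body))))
  num <- matrix(num, nrow = nrow(body), ncol = ncol(body),
                dimnames = list(ids, colnames(body)))
  bad <- which(is.na(num) & !(is.na(body) | body == "" | body == "NA"),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stopf("non-numeric cell at row '%s', column '%s' in %s",
          rownames(num)[bad[1L, 1L]], colnames(num)[bad[1L, 2L]], path)
  num[is.na(num)] <- 0  # empty cells are absent functions
  m <- if (orientation == "functions-as-rows") t(num) else num
  validate_profile_table(m, source = path)
  if (normalize) m <- normalize_profiles(m) else m
}

validate_profile_table <- function(m, source = "table") {
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stopf("duplicated sample ID in %s: %s", source,
          paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (!is.null(colnames(m)) && anyDuplicated(colnames(m)))
    stopf("duplicated function ID in %s: %s", source,
          paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stopf("negative abundance for sample '%s', function '%s' in %s",
          rownames(m)[neg[1L, 1L]], colnames(m)[neg[1L, 2L]], source)
  invisible(m)
}

#' Rescale each sample to relative abundances summing to one
#'
#' Divides every sample's abundances by their total. All-zero samples are
#' left all-zero and reported with a warning. Idempotent and
#' zero-pattern-preserving.
#'
#' @param table A samples x functions abundance matrix.
#' @return The row-normalized matrix.
#' @export
normalize_profiles <- function(table) {
  table <- as.matrix(table)
  validate_profile_table(table)
  sums <- rowSums(table)
  zero <- sums == 0
  if (any(zero))
    warning("all-zero sample(s) left unnormalized: ",
            paste(rownames(table)[zero], collapse = ", "), call. = FALSE)
  sums[zero] <- 1
  table / sums
}

#' Align paired WGS and amplicon profile tables
#'
#' Matches samples of the same specimen sequenced by both shotgun WGS and
#' 16S amplicon, strictly by identical sample ID. Both tables are
#' projected onto the union of their function universes, with absent
#' functions filled as 0, so every pair shares one ordered function list.
#'
#' @param wgs,amplicon Samples x functions abundance matrices.
#' @return An object of class \code{"paired_profiles"}: a list with
#'   elements \code{wgs} and \code{amplicon} (matrices with identical
#'   dimnames, rows ordered by sample ID) and \code{sample_ids}.
#' @export
align_pairs <- function(wgs, amplicon) {
  wgs <- as.matrix(wgs); amplicon <- as.matrix(amplicon)
  validate_profile_table(wgs, "wgs table")
  validate_profile_table(amplicon, "amplicon table")
  ids <- sort(intersect(rownames(wgs), rownames(amplicon)))
  if (length(ids) == 0L)
    stop("zero pairs found: no sample IDs shared between the two tables",
         call. = FALSE)
  funs <- union(colnames(wgs), colnames(amplicon))
  project <- function(m) {
    out <- matrix(0, length(ids), length(funs), dimnames = list(ids, funs))
    out[, colnames(m)] <- m[ids, , drop = FALSE]
    out
  }
  structure(list(wgs = project(wgs), amplicon = project(amplicon),
                 sample_ids = ids),
            class = "paired_profiles")
}

#' @export
print.paired_profiles <- function(x, ...) {
  cat(sprintf("%d paired WGS:16S-amplicon profiles over %d functions\n",
              length(x$sample_ids), ncol(x$wgs)))
  invisible(x)
}

# Subset pairs by sample ID (used by the training-set selection driver).
subset_pairs <- function(pairs, ids) {
  structure(list(wgs = pairs$wgs[ids, , drop = FALSE],
                 amplicon = pairs$amplicon[ids, , drop = FALSE],
                 sample_ids = ids),
            class = "paired_profiles")
}

#' Write a functional abundance table
#'
#' Writes samples as rows and functions as columns, tab-delimited at full
#' precision, so that \code{read_profile_table(..., orientation =
#' "samples-as-rows", normalize = FALSE)} reproduces the matrix to within
#' 1e-12 per cell.
#'
#' @param table Samples x functions abundance matrix.
#' @param path Output path.
#' @export
write_profile_table <- function(table, path) {
  table <- as.matrix(table)
  df <- data.frame(sample_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopf("cannot write profile table to %s", path)
  invisible(path)
}

#' Read a two-column sample metadata table
#'
#' @param path Tab-delimited file with a header and two columns:
#'   sample ID and group label (e.g. body site or disease status).
#' @return A named character vector mapping sample ID to label.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 2L) stopf("metadata file %s needs two columns", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stopf("duplicated sample ID in metadata: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(as.character(df[[2L]]), ids)
}

#' Write a two-column sample metadata table
#'
#' @param metadata Named character vector (sample ID -> label).
#' @param path Output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(
    data.frame(sample_id = names(metadata), label = unname(metadata)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
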