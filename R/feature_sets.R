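# Gene-set collections: GMT parsing and resolution against an expression matrix.

#' Read a gene-set collection from a GMT file
#'
#' Parses the MSigDB GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description field is
#' discarded; duplicate gene symbols within a line are deduplicated (first
#' occurrence kept). Line order is preserved as the set order.
#'
#' @param path Path to a GMT file.
#' @return A `feature_set_collection`: a list with `names` (character vector
#'   of set identifiers), `members` (named list of character vectors of gene
#'   symbols), and `resolved` (FALSE until [resolve_sets()] is called).
#' @seealso [resolve_sets()]
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no sets: GMT file '", path, "' is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad) > 0L) {
    stop("malformed GMT line ", bad[1L], ": fewer than 3 tab-separated fields")
  }
  set_names <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(set_names)) {
    stop("duplicate set name in GMT: ",
         set_names[duplicated(set_names)][1L])
  }
  members <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(members) <- set_names
  new_feature_set_collection(set_names, members)
}

new_feature_set_collection <- function(names, members,
                                       resolved_indices = NULL,
                                       gene_names = NULL) {
  stopifnot(length(names) >= 1L, !anyDuplicated(names))
  structure(
    list(
      names = names,
      members = members,
      resolved_indices = resolved_indices,
      sizes = if (is.null(resolved_indices)) {
        lengths(members)
      } else {
        lengths(resolved_indices)
      },
      gene_names = gene_names,
      resolved = !is.null(resolved_indices)
    ),
    class = "feature_set_collection"
  )
}

#' Construct a gene-set collection in memory
#'
#' @param members Named list of character vectors of gene symbols; names are
#'   the set identifiers.
#' @return A `feature_set_collection`.
#' @export
feature_set_collection <- function(members) {
  stopifnot(is.list(members), !is.null(names(members)))
  new_feature_set_collection(names(members), lapply(members, unique))
}

#' Resolve gene-set members to columns of an expression matrix
#'
#' Intersects each set's gene symbols with `gene_names` (case-sensitive exact
#' match) and records, per set, the 1-based column indices of its surviving
#' genes. Sets resolving to fewer than `min_size` genes are dropped with a
#' warning. Resolution is idempotent and preserves set order.
#'
#' @param collection A `feature_set_collection`.
#' @param gene_names Character vector of unique gene symbols, in column order
#'   of the expression matrix.
#' @param min_size Minimum number of resolved genes a set must retain
#'   (default 1).
#' @return The collection with `resolved_indices`, `sizes` and `gene_names`
#'   filled in; dropped sets removed.
#' @export
resolve_sets <- function(collection, gene_names, min_size = 1L) {
  stopifnot(inherits(collection, "feature_set_collection"))
  if (length(gene_names) == 0L) stop("gene_names must be non-empty")
  if (anyDuplicated(gene_names)) stop("gene_names must be unique")
  idx <- lapply(collection$members, function(m) {
    i <- match(m, gene_names)
    i[!is.na(i)]
  })
  keep <- lengths(idx) >= min_size
  if (!any(keep)) stop("no usable feature sets after resolution")
  if (any(!keep)) {
    warning(sum(!keep), " feature set(s) dropped (fewer than ", min_size,
            " resolved genes): ",
            paste(collection$names[!keep], collapse = ", "))
  }
  members <- lapply(idx[keep], function(i) gene_names[i])
  new_feature_set_collection(collection$names[keep], members,
                             resolved_indices = idx[keep],
                             gene_names = gene_names)
}

#' @export
print.feature_set_collection <- function(x, ...) {
  cat("feature_set_collection with", length(x$names), "sets",
      if (x$resolved) "(resolved)" else "(unresolved)", "\n")
  cat("  sizes:", paste(utils::head(x$sizes, 10L), collapse = ", "),
      if (length(x$sizes) > 10L) "..." else "", "\n")
  invisible(x)
}

#' @export
length.feature_set_collection <- function(x) length(x$names)

#' Write a gene-set collection to a GMT file
#'
#' @param collection A `feature_set_collection`.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (default `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  stopifnot(inherits(collection, "feature_set_collection"))
  if (is.null(descriptions)) descriptions <- rep("na", length(collection$names))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, collection$names, descriptions, collection$members)
  writeLines(lines, path)
  invisible(path)
}
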