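# Species-by-category count matrices with per-species group labels.

#' Construct a species-by-category count matrix
#'
#' The central container for peptidase profile statistics: an integer matrix
#' of non-negative counts with species as rows and categories (catalytic types
#' or family codes) as columns, plus one growth-temperature group label per
#' species.
#'
#' @param counts Non-negative integer matrix with unique row names (species)
#'   and column names (categories).
#' @param group Character vector of group labels, one per row of `counts`,
#'   in row order (or named by species).
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `group` (named character vector).
#' @seealso [make_count_matrix()], [fungal_peptidase_counts()],
#'   [read_count_matrix()]
#' @export
#' @examples
#' m <- matrix(c(3, 2, 1, 4), 2, 2,
#'             dimnames = list(c("sp1", "sp2"), c("Aspartic", "Serine")))
#' count_matrix(m, c("mesophilic", "thermophilic"))
count_matrix <- function(counts, group) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("counts must have unique row names (species)")
  }
  if (is.null(colnames(counts))) {
    stop("counts must have column names (categories)")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  storage.mode(counts) <- "integer"
  group <- as.character(group)
  if (length(group) != nrow(counts)) {
    stop("need exactly one group label per species (",
         nrow(counts), " rows, ", length(group), " labels)")
  }
  if (is.null(names(group))) names(group) <- rownames(counts)
  group <- group[rownames(counts)]
  if (anyNA(group)) stop("every row must have a group label")
  structure(list(counts = counts, group = group), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " species x ", ncol(x$counts),
      " categories\n", sep = "")
  cat("groups: ", paste(sprintf("%s (n=%d)", names(table(x$group)),
                                table(x$group)), collapse = ", "), "\n",
      sep = "")
  print(x$counts, ...)
  invisible(x)
}

#' @export
as.data.frame.count_matrix <- function(x, ...) {
  data.frame(species = rownames(x$counts), group = unname(x$group),
             as.data.frame(x$counts), check.names = FALSE,
             row.names = NULL)
}

#' Read / write count matrices as TSV
#'
#' The on-disk layout is one row per species: a `species` column, a `group`
#' column, then one integer column per category.
#'
#' @param file Path to a tab-separated file.
#' @return `read_count_matrix()` returns a [count_matrix()];
#'   `write_count_matrix()` returns `file` invisibly.
#' @export
read_count_matrix <- function(file) {
  d <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("species", "group") %in% names(d))) {
    stop("count matrix TSV needs 'species' and 'group' columns: ", file)
  }
  cats <- setdiff(names(d), c("species", "group"))
  m <- as.matrix(d[, cats, drop = FALSE])
  rownames(m) <- d$species
  count_matrix(m, setNames(d$group, d$species))
}

#' @param x A [count_matrix()].
#' @rdname read_count_matrix
#' @export
write_count_matrix <- function(x, file) {
  stopifnot(inherits(x, "count_matrix"))
  write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

# Restrict a count matrix to the given groups (e.g. drop thermotolerant rows
# before a two-group comparison).
#' Subset a count matrix by group label
#'
#' @param x A [count_matrix()].
#' @param groups Character vector of group labels to keep.
#' @return A [count_matrix()] containing only species in `groups`.
#' @export
subset_groups <- function(x, groups) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- x$group %in% groups
  if (!any(keep)) stop("no species left after subsetting to: ",
                       paste(groups, collapse = ", "))
  count_matrix(x$counts[keep, , drop = FALSE], x$group[keep])
}
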