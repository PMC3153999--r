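#' Construct a gene set collection
#'
#' @param sets named list of character vectors of gene ids. Duplicate
#'   members within a set are removed.
#' @param description optional character vector of per-set descriptions
#'   (recycled; defaults to the set names).
#' @param universe optional character vector of gene ids present in the
#'   analysis.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL, universe = NULL) {
  if (length(sets) == 0) sets <- setNames(list(), character(0))
  .assert(is.list(sets) && (length(sets) == 0 ||
            (!is.null(names(sets)) && all(nzchar(names(sets))))),
          "sets must be a named list")
  .assert(!anyDuplicated(names(sets)), "set names must be unique")
  .assert(all(lengths(sets) > 0), "sets must be non-empty")
  sets <- lapply(sets, function(x) unique(as.character(x)))
  if (is.null(description)) description <- names(sets)
  description <- setNames(rep_len(as.character(description), length(sets)),
                          names(sets))
  structure(list(sets = sets, description = description,
                 universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  if (length(sz) == 0) {
    cat("gene_set_collection: 0 sets\n")
  } else {
    cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n",
                length(x$sets), min(sz), max(sz)))
  }
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a gene set collection from a GMT file
#'
#' GMT dialect: one set per line, tab-separated `name`, `description`,
#' then one or more gene ids. Lines with fewer than three fields are an
#' error reported with their line numbers; duplicated gene ids within a set
#' are collapsed.
#'
#' @param path GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  .assert(length(bad) == 0, "malformed GMT lines (< 3 fields): %s",
          paste(bad, collapse = ", "))
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  gene_set_collection(sets, description = desc)
}

#' Write a gene set collection to a GMT file
#'
#' @param collection a [gene_set_collection()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  .assert(inherits(collection, "gene_set_collection"),
          "collection must be a gene_set_collection")
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Filter gene sets for testability
#'
#' Retains a set only if (a) at least `coverage_min` of its members are
#' present among the analyzed genes and (b) the number of its analyzed
#' members lies within `size_range`. Retained sets have their members
#' restricted to the analyzed genes. These bounds avoid testing too
#' narrowly or too broadly defined categories and reduce the
#' multiple-testing burden.
#'
#' @param collection a [gene_set_collection()].
#' @param analyzed_genes character vector of gene ids present in the
#'   association analysis.
#' @param coverage_min minimum fraction of members covered (default 0.85).
#' @param size_range allowed size range (default `c(10, 200)`).
#' @param size_on `"analyzed"` applies `size_range` to the count of members
#'   present in the data (default); `"nominal"` applies it to the set's
#'   nominal size.
#' @return A filtered [gene_set_collection()] with `universe` set to
#'   `analyzed_genes` and a per-set `filter_report` data.frame attribute
#'   (`set_name`, `nominal_size`, `analyzed_size`, `coverage`, `retained`).
#' @export
filter_sets <- function(collection, analyzed_genes, coverage_min = 0.85,
                        size_range = c(10, 200),
                        size_on = c("analyzed", "nominal")) {
  .assert(inherits(collection, "gene_set_collection"),
          "collection must be a gene_set_collection")
  .assert(length(analyzed_genes) > 0, "analyzed_genes is empty")
  size_on <- match.arg(size_on)
  analyzed_genes <- unique(as.character(analyzed_genes))
  nominal <- lengths(collection$sets)
  inter <- lapply(collection$sets, intersect, y = analyzed_genes)
  n_in <- lengths(inter)
  coverage <- n_in / nominal
  size_basis <- if (size_on == "analyzed") n_in else nominal
  keep <- coverage >= coverage_min &
    size_basis >= size_range[1] & size_basis <= size_range[2]
  report <- data.frame(set_name = names(collection$sets),
                       nominal_size = nominal,
                       analyzed_size = n_in,
                       coverage = coverage,
                       retained = keep,
                       row.names = NULL,
                       stringsAsFactors = FALSE)
  out <- gene_set_collection(inter[keep],
                             description = collection$description[keep],
                             universe = analyzed_genes)
  attr(out, "filter_report") <- report
  out
}
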