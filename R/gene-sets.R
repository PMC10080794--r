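#' Named gene sets
#'
#' A `gene_set` is a named collection of unique gene identifiers, the currency
#' of all overlap / Venn / enrichment arithmetic downstream of m6A calling.
#'
#' @param name Non-empty set name.
#' @param members Character vector of gene ids; duplicates are removed.
#' @return An object of class `gene_set` with elements `name` and `members`.
#' @export
gene_set <- function(name, members) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    abort_value("gene set name must be a non-empty string")
  }
  members <- unique(as.character(members))
  members <- members[!is.na(members) & nzchar(members)]
  structure(list(name = name, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$members)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' Write a gene set to a text file
#'
#' Format: a `#name=<name>` header line, then one gene id per line.
#'
#' @param gs A `gene_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(gs, path) {
  stopifnot(inherits(gs, "gene_set"))
  writeLines(c(sprintf("#name=%s", gs$name), gs$members), path)
  invisible(path)
}

#' Read a gene set from a text file
#'
#' Duplicated ids are collapsed with a warning; a missing `#name=` header
#' defaults the set name to the file stem; an empty file yields an empty set
#' with a warning.
#'
#' @param path Path to a gene-set text file.
#' @return A `gene_set`.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path)
  name <- sub("\\.[^.]*$", "", basename(path))
  if (length(lines) > 0 && startsWith(lines[1], "#name=")) {
    name <- sub("^#name=", "", lines[1])
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    warning(sprintf("gene set file '%s' is empty", path))
  }
  if (anyDuplicated(lines)) {
    warning(sprintf("gene set file '%s' contains duplicated ids; deduplicated",
                    path))
  }
  gene_set(name, lines)
}

#' Region counts for a 2- or 3-set Venn diagram
#'
#' @param sets A list of 2 or 3 `gene_set` objects.
#' @return A tibble with one row per non-empty membership pattern of the
#'   2^k - 1 regions: logical membership columns (named after the sets), and
#'   `count`. Region counts sum to the size of the union.
#' @export
overlap_venn <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 3) {
    abort_value("overlap_venn supports 2 or 3 gene sets")
  }
  stopifnot(all(vapply(sets, inherits, logical(1), "gene_set")))
  nm <- vapply(sets, function(s) s$name, character(1))
  if (anyDuplicated(nm)) abort_value("gene set names must be distinct")
  universe <- unique(unlist(lapply(sets, function(s) s$members)))
  member <- vapply(sets, function(s) universe %in% s$members,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  colnames(member) <- nm
  k <- length(sets)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(patterns) <- nm
  counts <- apply(patterns, 1, function(p) {
    sum(colSums(t(member) == p) == k)
  })
  out <- tibble::as_tibble(patterns)
  out$count <- as.integer(counts)
  out
}

# Internal set helpers.
#' @noRd
set_intersect <- function(a, b, name = NULL) {
  gene_set(name %||% sprintf("%s_and_%s", a$name, b$name),
           intersect(a$members, b$members))
}

#' @noRd
set_diff <- function(a, b, name = NULL) {
  gene_set(name %||% sprintf("%s_not_%s", a$name, b$name),
           setdiff(a$members, b$members))
}

#' @importFrom rlang %||%
NULL
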