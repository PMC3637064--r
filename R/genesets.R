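#' Normalize gene symbols
#'
#' Gene symbols are compared case-insensitively throughout the package:
#' normalization uppercases each token and strips surrounding whitespace.
#' No alias mapping is attempted (symbol conversion services are out of
#' scope).  Normalization is idempotent.
#'
#' @param x character vector of raw gene symbols.
#' @return character vector of normalized symbols.
#' @examples
#' normalize_gene_symbols(c(" tp53 ", "Myc"))
#' @export
normalize_gene_symbols <- function(x) {
  if (!is.character(x)) stop("gene symbols must be character")
  out <- toupper(trimws(x))
  if (any(out == "")) stop("empty gene symbol after normalization")
  if (any(grepl("[\t ]", out))) stop("gene symbol contains internal whitespace")
  out
}

#' Construct a gene set
#'
#' A gene set is a functional term (pathway, transcription factor, cell
#' type, ...) together with the set of gene symbols annotated to it.
#' Duplicate symbols (after normalization) are collapsed to set semantics.
#'
#' @param term non-empty term label.
#' @param genes character vector of gene symbols (at least one).
#' @param description optional free-text description.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(term, genes, description = "") {
  if (!is.character(term) || length(term) != 1L || !nzchar(term))
    stop("term must be a non-empty string")
  genes <- unique(normalize_gene_symbols(genes))
  if (length(genes) < 1L) stop("gene set '", term, "' is empty")
  structure(list(term = term, description = as.character(description),
                 genes = genes),
            class = "gene_set")
}

#' Construct a gene-set library
#'
#' An ordered collection of gene sets with unique term labels.  The gene
#' universe defaults to the union of all member sets; a caller-supplied
#' universe (e.g. a whole-genome background) may override it for
#' cross-library consistency.
#'
#' @param sets list of [gene_set()] objects.
#' @param name library name.
#' @param category one of `"transcription"`, `"pathways"`, `"ontologies"`,
#'   `"diseases_drugs"`, `"cell_types"`, `"miscellaneous"`.
#' @param universe optional character vector overriding the derived universe.
#' @return object of class `gene_set_library`.
#' @export
gene_set_library <- function(sets, name = "library",
                             category = c("miscellaneous", "transcription",
                                          "pathways", "ontologies",
                                          "diseases_drugs", "cell_types"),
                             universe = NULL) {
  category <- match.arg(category)
  if (!is.list(sets)) stop("sets must be a list of gene_set objects")
  for (s in sets) {
    if (!inherits(s, "gene_set")) stop("all elements of sets must be gene_set")
  }
  terms <- vapply(sets, `[[`, "", "term")
  dup <- terms[duplicated(terms)]
  if (length(dup))
    stop("duplicate term label(s) in library: ", paste(unique(dup), collapse = ", "))
  if (!is.null(universe)) universe <- unique(normalize_gene_symbols(universe))
  structure(list(name = name, category = category, sets = sets,
                 universe_override = universe),
            class = "gene_set_library")
}

#' Gene universe of a library
#'
#' The union of all member sets, unless the library carries an explicit
#' universe override.
#'
#' @param library a [gene_set_library()].
#' @return character vector of gene symbols.
#' @export
library_universe <- function(library) {
  stopifnot(inherits(library, "gene_set_library"))
  if (!is.null(library$universe_override)) return(library$universe_override)
  unique(unlist(lapply(library$sets, `[[`, "genes"), use.names = FALSE)) %||% character()
}

#' @export
print.gene_set_library <- function(x, ...) {
  cat(sprintf("gene_set_library '%s' (%s): %d terms, %d genes in universe\n",
              x$name, x$category, length(x$sets), length(library_universe(x))))
  invisible(x)
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$term, length(x$genes)))
  invisible(x)
}

#' Terms of a library
#' @param library a [gene_set_library()].
#' @return character vector of term labels in library order.
#' @export
library_terms <- function(library) {
  vapply(library$sets, `[[`, "", "term")
}

#' Read a GMT gene-set library
#'
#' GMT is the standard tab-separated gene-set format: one set per line,
#' `term <TAB> description <TAB> gene1 <TAB> gene2 ...`.  Symbols are
#' normalized and duplicates within a line collapsed; line order is
#' preserved.  `\r\n` line endings are tolerated.
#'
#' @param source path to a GMT file, or a character vector of lines.
#' @param name library name (defaults to the file base name).
#' @param category library category, see [gene_set_library()].
#' @return a [gene_set_library()].
#' @export
read_gmt <- function(source, name = NULL, category = "miscellaneous") {
  if (length(source) == 1L && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    name <- name %||% tools::file_path_sans_ext(basename(source))
  } else {
    lines <- as.character(source)
    name <- name %||% "library"
  }
  lines <- sub("\r$", "", lines)
  sets <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line)) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, ": expected >= 3 tab-separated fields, got ",
           length(fields))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(trimws(genes))]
    if (!length(genes))
      stop("malformed GMT line ", i, ": no genes")
    sets[[length(sets) + 1L]] <- gene_set(fields[[1]], genes, fields[[2]])
  }
  gene_set_library(sets, name = name, category = category)
}

#' Write a GMT gene-set library
#'
#' Inverse of [read_gmt()]: the round trip reproduces the library's
#' term-to-gene-set mapping exactly.  Genes are written sorted
#' lexicographically within each line; an empty description is written as
#' an empty field (the 3-field GMT minimum), never omitted.  Output uses
#' UTF-8 and `\n` line endings.
#'
#' @param library a [gene_set_library()].
#' @param path output file path, or `NULL` to return the lines invisibly.
#' @return invisibly, the character vector of GMT lines.
#' @export
write_gmt <- function(library, path = NULL) {
  stopifnot(inherits(library, "gene_set_library"))
  lines <- vapply(library$sets, function(s) {
    paste(c(s$term, s$description %||% "", sort(s$genes)), collapse = "\t")
  }, "")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (length(lines)) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  invisible(lines)
}

#' Per-library summary statistics
#'
#' Term count, distinct-gene coverage and mean genes per term, the columns
#' of a library summary table.  An empty library yields all-zero stats.
#'
#' @param library a [gene_set_library()].
#' @return a one-row data.frame with columns `name`, `n_terms`,
#'   `gene_coverage`, `mean_genes_per_term`.
#' @export
library_stats <- function(library) {
  stopifnot(inherits(library, "gene_set_library"))
  sizes <- vapply(library$sets, function(s) length(s$genes), 0L)
  n <- length(sizes)
  data.frame(
    name = library$name,
    n_terms = n,
    gene_coverage = length(unique(unlist(lapply(library$sets, `[[`, "genes")))),
    mean_genes_per_term = if (n) sum(sizes) / n else 0,
    stringsAsFactors = FALSE
  )
}
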