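#' Input gene list
#'
#' A deduplicated, normalized set of gene symbols to be tested for
#' enrichment, with an optional free-text description and an optional
#' label naming the term expected to rank highly (used by
#' [benchmark_rank_recovery()]).
#'
#' @param genes character vector of gene symbols.
#' @param description optional description.
#' @param label optional expected-term label.
#' @return object of class `input_gene_list`.
#' @export
input_gene_list <- function(genes, description = "", label = NULL) {
  genes <- unique(normalize_gene_symbols(genes))
  if (!length(genes)) stop("input gene list is empty")
  structure(list(genes = genes, description = as.character(description),
                 label = label),
            class = "input_gene_list")
}

#' @export
print.input_gene_list <- function(x, ...) {
  cat(sprintf("input_gene_list: %d genes%s\n", length(x$genes),
              if (!is.null(x$label)) paste0(" (label: ", x$label, ")") else ""))
  invisible(x)
}

validate_contingency <- function(k, n, K, N) {
  if (any(N < 1) || any(K < 0) || any(n < 0) || any(k < 0))
    stop("contingency counts must be non-negative with N >= 1")
  if (any(K > N) || any(n > N)) stop("K and n must not exceed N")
  if (any(k > pmin(n, K))) stop("k must not exceed min(n, K)")
  invisible(TRUE)
}

#' One-sided Fisher exact (hypergeometric) p-value
#'
#' Upper-tail probability of observing at least `k` genes of an input list
#' of size `n` inside a term's gene set of size `K`, drawing without
#' replacement from a universe of `N` genes:
#' P(X >= k) with X ~ Hypergeometric(N, K, n).  `k = 0` yields exactly 1.
#' All arguments are vectorized.
#'
#' @param k overlap count.
#' @param n input-list size (restricted to the universe).
#' @param K term set size.
#' @param N universe size.
#' @return p-value(s) in (0, 1].
#' @examples
#' fisher_exact_p(2, 4, 5, 20)
#' @export
fisher_exact_p <- function(k, n, K, N) {
  validate_contingency(k, n, K, N)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  # guard against floating underflow just above the support boundary
  pmin(pmax(p, 0), 1)
}

# Total-order Fisher ranking used everywhere: p ascending, ties broken by
# larger overlap k, then lexicographic term.  Returns a permutation of
# 1..n_terms (competition-free: no shared ranks).
fisher_rank_order <- function(p, k, terms) {
  o <- order(p, -k, terms, method = "radix")
  r <- integer(length(p))
  r[o] <- seq_along(p)
  r
}

# Vectorized core: overlap counts, p-values and ranks for one input list.
enrich_core <- function(library, input_genes, universe) {
  terms <- library_terms(library)
  universe <- unique(universe)
  inp <- intersect(input_genes, universe)
  if (!length(inp))
    stop("input list shares no genes with the universe; ",
         "check that list and library/universe use the same symbol space")
  dropped <- length(input_genes) - length(inp)
  if (dropped > 0)
    message(dropped, " input gene(s) outside the universe dropped from n")
  N <- length(universe)
  n <- length(inp)
  K <- vapply(library$sets, function(s) sum(s$genes %in% universe), 0L)
  k <- vapply(library$sets, function(s) sum(s$genes %in% inp), 0L)
  p <- fisher_exact_p(k, n, K, N)
  list(terms = terms, k = k, K = K, n = n, N = N, p = p,
       rank = fisher_rank_order(p, k, terms),
       overlap = lapply(library$sets, function(s) intersect(s$genes, inp)))
}

#' Rank library terms by Fisher p-value
#'
#' Every term receives a one-sided Fisher p-value and a rank 1..n_terms
#' (ties broken deterministically by larger overlap, then term label).
#'
#' @param library a [gene_set_library()].
#' @param input an [input_gene_list()] or character vector of genes.
#' @param universe background gene universe; defaults to the library union.
#' @return data.frame with columns `term`, `overlap`, `set_size`,
#'   `p_value`, `fisher_rank`, ordered by rank.
#' @export
rank_by_p <- function(library, input, universe = NULL) {
  stopifnot(inherits(library, "gene_set_library"))
  if (!inherits(input, "input_gene_list")) input <- input_gene_list(input)
  universe <- universe %||% library_universe(library)
  core <- enrich_core(library, input$genes, universe)
  out <- data.frame(term = core$terms, overlap = core$k, set_size = core$K,
                    p_value = core$p, fisher_rank = core$rank,
                    stringsAsFactors = FALSE)
  out[order(out$fisher_rank), , drop = FALSE]
}

#' Rank-deviation z-score
#'
#' Standardizes a term's observed Fisher rank against its expected rank
#' distribution under random input lists: z = (observed - mean) / sd.
#' With this sign convention an enriched term (ranked earlier than
#' expected) gets z < 0.
#'
#' @param observed_rank observed Fisher rank(s).
#' @param mean_rank expected rank under random lists.
#' @param sd_rank standard deviation of the rank under random lists
#'   (must be > 0).
#' @return z-score(s).
#' @export
rank_zscore <- function(observed_rank, mean_rank, sd_rank) {
  if (any(sd_rank <= 0))
    stop("sd_rank must be > 0: rank variance undefined ",
         "(fall back to p-value ordering for such terms)")
  (observed_rank - mean_rank) / sd_rank
}

#' Combined enrichment score
#'
#' Multiplies the log Fisher p-value by the rank-deviation z-score:
#' c = ln(p) * z.  Under the package's sign convention (enriched terms
#' have z < 0 and ln(p) < 0) strongly enriched terms get large positive
#' c; tables sorted by combined score are sorted descending.  p is
#' clamped to >= 1e-300 before the log so scores stay finite.
#'
#' @param p Fisher p-value(s) in (0, 1].
#' @param z rank-deviation z-score(s).
#' @return combined score(s).
#' @examples
#' combined_score(0.01, -2)  # log(0.01) * -2 = 9.21034
#' @export
combined_score <- function(p, z) {
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]")
  log(pmax(p, 1e-300)) * z
}

#' Enrichment analysis of a gene list against a library
#'
#' Computes, for every term, the overlap with the input list, the
#' one-sided Fisher p-value, the Fisher rank, and -- when a calibrated
#' [calibrate_background()] object is supplied -- the rank-deviation
#' z-score and combined score c = ln(p) * z.  The table is sorted by the
#' requested mode: ascending p, ascending z (enriched terms are
#' negative), or descending combined score.  Terms whose background rank
#' variance is zero are given NA z/combined scores and sorted last, with
#' a warning.
#'
#' @param input an [input_gene_list()] or character vector.
#' @param library a [gene_set_library()].
#' @param background optional rank background from [calibrate_background()];
#'   required for the `z_score` and `combined` sort modes.
#' @param sort_mode `"p_value"`, `"z_score"` or `"combined"`.
#' @param universe background universe; defaults to the library union.
#' @return data.frame of class `enrichment_table` with one row per term.
#' @export
enrich <- function(input, library, background = NULL,
                   sort_mode = c("p_value", "z_score", "combined"),
                   universe = NULL) {
  sort_mode <- match.arg(sort_mode)
  stopifnot(inherits(library, "gene_set_library"))
  if (!inherits(input, "input_gene_list")) input <- input_gene_list(input)
  if (sort_mode != "p_value" && is.null(background))
    stop("sort_mode '", sort_mode, "' requires a calibrated background")
  universe <- universe %||% library_universe(library)
  core <- enrich_core(library, input$genes, universe)

  z <- rep(NA_real_, length(core$terms))
  cs <- rep(NA_real_, length(core$terms))
  if (!is.null(background)) {
    stopifnot(inherits(background, "rank_background"))
    missing <- setdiff(core$terms, background$terms)
    if (length(missing))
      stop("background does not cover library term(s): ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) " ...")
    bin <- nearest_bin(background, core$n)
    idx <- match(core$terms, background$terms)
    mu <- background$bins[[bin]]$mean_rank[idx]
    sdv <- background$bins[[bin]]$sd_rank[idx]
    ok <- sdv > 0
    if (any(!ok))
      warning(sum(!ok), " term(s) with zero background rank variance ",
              "excluded from z/combined scoring")
    z[ok] <- rank_zscore(core$rank[ok], mu[ok], sdv[ok])
    cs[ok] <- combined_score(core$p[ok], z[ok])
  }

  tab <- data.frame(term = core$terms, overlap = core$k, set_size = core$K,
                    p_value = core$p, fisher_rank = core$rank,
                    z_score = z, combined_score = cs,
                    stringsAsFactors = FALSE)
  tab$genes <- vapply(core$overlap, paste, "", collapse = ";")
  tab <- sort_enrichment(tab, sort_mode)
  structure(tab,
            class = c("enrichment_table", "data.frame"),
            library_name = library$name,
            description = input$description,
            sort_mode = sort_mode,
            n_input = core$n, universe_size = core$N)
}

sort_enrichment <- function(tab, sort_mode) {
  o <- switch(sort_mode,
    p_value = order(tab$p_value, -tab$overlap, tab$term, method = "radix"),
    z_score = order(is.na(tab$z_score), tab$z_score, tab$p_value, tab$term,
                    method = "radix"),
    combined = order(is.na(tab$combined_score), -xtfrm(tab$combined_score),
                     tab$p_value, tab$term, method = "radix"),
    stop("unknown sort_mode: ", sort_mode))
  out <- tab[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Re-sort an enrichment table
#'
#' Permutes (never drops) the records of an existing table into another
#' sort order.  Z/combined orders require the table to carry z-scores.
#'
#' @param table an `enrichment_table`.
#' @param sort_mode target order, see [enrich()].
#' @return the re-sorted `enrichment_table`.
#' @export
resort_enrichment <- function(table, sort_mode = c("p_value", "z_score", "combined")) {
  sort_mode <- match.arg(sort_mode)
  stopifnot(inherits(table, "enrichment_table"))
  if (sort_mode != "p_value" && all(is.na(table$z_score)))
    stop("table carries no z-scores; run enrich() with a background")
  at <- attributes(table)
  out <- sort_enrichment(as.data.frame(table), sort_mode)
  attributes(out) <- utils::modifyList(at, list(sort_mode = sort_mode,
                                                row.names = seq_len(nrow(out))))
  out
}

#' @export
print.enrichment_table <- function(x, n = 10L, ...) {
  cat(sprintf("enrichment_table: %s vs '%s', sorted by %s (top %d of %d)\n",
              attr(x, "description") %||% "input", attr(x, "library_name"),
              attr(x, "sort_mode"), min(n, nrow(x)), nrow(x)))
  print(utils::head(as.data.frame(x)[, c("term", "overlap", "set_size",
                                         "p_value", "z_score",
                                         "combined_score")], n), ...)
  invisible(x)
}

#' Export an enrichment table as TSV
#'
#' Writes the columns `Term`, `Overlap` (as k/K), `P-value`, `Z-score`,
#' `Combined Score` and `Genes` (semicolon-joined overlap genes).
#'
#' @param table an `enrichment_table`.
#' @param path output path, or `NULL` to return lines.
#' @return invisibly, the TSV lines.
#' @export
write_enrichment_tsv <- function(table, path = NULL) {
  stopifnot(inherits(table, "enrichment_table"))
  fmt <- function(x) ifelse(is.na(x), "NA", format(x, digits = 15, trim = TRUE,
                                                   scientific = NA))
  body <- paste(table$term,
                paste0(table$overlap, "/", table$set_size),
                fmt(table$p_value), fmt(table$z_score),
                fmt(table$combined_score), table$genes,
                sep = "\t")
  lines <- c(paste("Term", "Overlap (k/K)", "P-value", "Z-score",
                   "Combined Score", "Genes", sep = "\t"), body)
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  invisible(lines)
}

#' Export an enrichment table as JSON
#'
#' Lossless JSON serialization of the table records plus metadata
#' (library, sort mode, input size, universe size); see
#' [read_enrichment_json()] for the inverse.
#'
#' @param table an `enrichment_table`.
#' @param path output path, or `NULL` to return the JSON string.
#' @param seed seed to stamp into the artifact metadata.
#' @return invisibly, the JSON string.
#' @export
write_enrichment_json <- function(table, path = NULL, seed = 0L) {
  stopifnot(inherits(table, "enrichment_table"))
  payload <- list(
    meta = artifact_meta(seed, list(library = attr(table, "library_name"),
                                    sort_mode = attr(table, "sort_mode"))),
    library_name = attr(table, "library_name"),
    description = attr(table, "description") %||% "",
    sort_mode = attr(table, "sort_mode"),
    n_input = attr(table, "n_input"),
    universe_size = attr(table, "universe_size"),
    records = as.data.frame(table)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
  if (!is.null(path)) writeLines(json, path, useBytes = TRUE)
  invisible(as.character(json))
}

#' Read an enrichment table from JSON
#' @param source path or JSON string from [write_enrichment_json()].
#' @return the `enrichment_table`.
#' @export
read_enrichment_json <- function(source) {
  payload <- jsonlite::fromJSON(source)
  tab <- payload$records
  for (col in c("z_score", "combined_score"))
    tab[[col]] <- as.numeric(tab[[col]])
  structure(tab, class = c("enrichment_table", "data.frame"),
            library_name = payload$library_name,
            description = payload$description,
            sort_mode = payload$sort_mode,
            n_input = payload$n_input,
            universe_size = payload$universe_size)
}
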