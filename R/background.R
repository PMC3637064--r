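# Background rank calibration: the expected Fisher rank (mean, sd) of each
# term under random input lists, per list-length bin.

# Fisher ranks of every library term for many input lists at once.
# `lists` is a list of character vectors already inside `universe`.
# Returns a terms x lists integer matrix.  Vectorized through a logical
# membership matrix so calibration over thousands of lists stays fast.
rank_matrix_for_lists <- function(library, lists, universe) {
  terms <- library_terms(library)
  universe <- unique(universe)
  N <- length(universe)
  M <- membership_matrix(library, universe)           # terms x N, logical
  K <- vapply(library$sets, function(s) sum(s$genes %in% universe), 0L)
  storage.mode(M) <- "double"
  X <- matrix(0, nrow = N, ncol = length(lists))
  for (j in seq_along(lists)) {
    idx <- match(lists[[j]], universe)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) stop("list ", j, " shares no genes with the universe")
    X[idx, j] <- 1
  }
  kmat <- M %*% X                                      # overlaps, terms x lists
  n <- colSums(X)
  p <- stats::phyper(kmat - 1, K, N - K, matrix(n, nrow(kmat), ncol(kmat),
                                                byrow = TRUE),
                     lower.tail = FALSE)
  ranks <- matrix(0L, nrow(kmat), ncol(kmat), dimnames = list(terms, NULL))
  for (j in seq_len(ncol(kmat)))
    ranks[, j] <- fisher_rank_order(p[, j], kmat[, j], terms)
  ranks
}

#' Calibrate the expected-rank background of a library
#'
#' Runs Fisher-test enrichment for many random input gene lists and
#' records, for every term, the mean and standard deviation of its rank.
#' Backgrounds are stratified by input-list length (one bin per requested
#' length); at query time [enrich()] uses the bin nearest the input's
#' effective length.  All randomness flows from `seed`.
#'
#' @param library a [gene_set_library()] with at least 2 terms.
#' @param n_lists number of random lists per length bin (>= 2).
#' @param list_lengths input-list lengths to calibrate, e.g. `c(100, 300)`.
#' @param seed integer seed.
#' @param universe Fisher background universe; defaults to the library
#'   union (which, for noisy libraries, includes non-matchable symbols --
#'   exactly the situation the rank correction is designed for).
#' @param sample_from gene pool the random lists are drawn from; defaults
#'   to `universe`.  Pass the clean symbol space when the library itself
#'   carries noise symbols that real input lists can never contain.
#' @return object of class `rank_background`.
#' @export
calibrate_background <- function(library, n_lists = 1000L,
                                 list_lengths = 100L, seed = 1L,
                                 universe = NULL, sample_from = NULL) {
  stopifnot(inherits(library, "gene_set_library"))
  if (length(library$sets) < 2L)
    stop("rank calibration needs >= 2 terms (a 1-term library has no rank structure)")
  if (n_lists < 2L) stop("n_lists must be >= 2")
  if (!length(list_lengths)) stop("list_lengths must be non-empty")
  universe <- unique(universe %||% library_universe(library))
  sample_from <- unique(sample_from %||% universe)
  if (any(list_lengths > length(sample_from)))
    stop("list length exceeds the sampling pool size")

  terms <- library_terms(library)
  bins <- list()
  set.seed(split_seed(seed, "calibrate"))
  for (len in sort(unique(as.integer(list_lengths)))) {
    lists <- lapply(seq_len(n_lists),
                    function(i) sample(sample_from, len, replace = FALSE))
    ranks <- rank_matrix_for_lists(library, lists, universe)
    bins[[as.character(len)]] <- list(
      length = len,
      mean_rank = rowMeans(ranks),
      sd_rank = apply(ranks, 1, stats::sd)
    )
  }
  structure(list(library_name = library$name, terms = terms, bins = bins,
                 n_simulations = as.integer(n_lists),
                 list_length_bins = sort(unique(as.integer(list_lengths))),
                 universe_size = length(universe), seed = as.integer(seed)),
            class = "rank_background")
}

nearest_bin <- function(background, n) {
  lens <- background$list_length_bins
  as.character(lens[which.min(abs(lens - n))])
}

#' @export
print.rank_background <- function(x, ...) {
  cat(sprintf(
    "rank_background for '%s': %d terms, %d simulations, bins [%s], seed %d\n",
    x$library_name, length(x$terms), x$n_simulations,
    paste(x$list_length_bins, collapse = ", "), x$seed))
  invisible(x)
}

#' Write a rank background to versioned JSON
#' @param background a `rank_background`.
#' @param path output path, or `NULL` for the JSON string.
#' @return invisibly, the JSON string.
#' @export
write_background_json <- function(background, path = NULL) {
  stopifnot(inherits(background, "rank_background"))
  payload <- list(
    meta = artifact_meta(background$seed,
                         list(library = background$library_name,
                              bins = background$list_length_bins,
                              n_simulations = background$n_simulations)),
    library_name = background$library_name,
    terms = background$terms,
    n_simulations = background$n_simulations,
    list_length_bins = background$list_length_bins,
    universe_size = background$universe_size,
    seed = background$seed,
    bins = lapply(background$bins, function(b)
      list(length = b$length, mean_rank = unname(b$mean_rank),
           sd_rank = unname(b$sd_rank)))
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (!is.null(path)) writeLines(json, path, useBytes = TRUE)
  invisible(as.character(json))
}

#' Read a rank background written by [write_background_json()]
#' @param source path or JSON string.
#' @return the `rank_background`.
#' @export
read_background_json <- function(source) {
  payload <- jsonlite::fromJSON(source, simplifyVector = TRUE)
  bins <- lapply(payload$bins, function(b) {
    list(length = b$length,
         mean_rank = stats::setNames(b$mean_rank, payload$terms),
         sd_rank = stats::setNames(b$sd_rank, payload$terms))
  })
  structure(list(library_name = payload$library_name, terms = payload$terms,
                 bins = bins, n_simulations = payload$n_simulations,
                 list_length_bins = payload$list_length_bins,
                 universe_size = payload$universe_size,
                 seed = payload$seed),
            class = "rank_background")
}

#' Benchmark rank recovery of labeled gene lists
#'
#' For each labeled input list (e.g. from [planted_enrichment_list()] or a
#' knockdown-signature suite), computes the rank achieved by the expected
#' term under each of the three scoring methods.  Mirrors the evaluation
#' design in which differential lists after transcription-factor
#' knockdown should rank that factor's target set highly.
#'
#' @param library a [gene_set_library()].
#' @param perturbation_lists list of labeled [input_gene_list()] objects.
#' @param background a `rank_background` covering the library.
#' @param universe Fisher universe; defaults to the library union.
#' @return data.frame with one row per list (`label`, `rank_p`, `rank_z`,
#'   `rank_combined`) and a `mean_ranks` attribute with the per-method
#'   means.
#' @export
benchmark_rank_recovery <- function(library, perturbation_lists, background,
                                    universe = NULL) {
  stopifnot(inherits(library, "gene_set_library"),
            inherits(background, "rank_background"))
  labels <- vapply(perturbation_lists, function(l) l$label %||% "", "")
  if (any(labels == "")) stop("every perturbation list must carry a label")
  terms <- library_terms(library)
  missing <- setdiff(labels, terms)
  if (length(missing))
    stop("label(s) absent from library: ", paste(unique(missing), collapse = ", "))

  rows <- lapply(perturbation_lists, function(lst) {
    tab <- suppressMessages(
      enrich(lst, library, background = background, sort_mode = "p_value",
             universe = universe))
    i <- match(lst$label, tab$term)
    zr <- rank(tab$z_score, ties.method = "first", na.last = "keep")
    cr <- rank(-tab$combined_score, ties.method = "first", na.last = "keep")
    data.frame(label = lst$label,
               rank_p = tab$fisher_rank[i],
               rank_z = zr[i],
               rank_combined = cr[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, mean_ranks = c(p_value = mean(out$rank_p),
                                z_score = mean(out$rank_z),
                                combined = mean(out$rank_combined)))
}
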