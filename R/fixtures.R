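# Deterministic synthetic fixtures for every input the tool consumes.
# Each generator is a pure function of its spec + seed; one global seed
# fans out into per-component streams (see split_seed) so adding a
# generator never perturbs existing fixtures.

#' Specification for a random gene-set library fixture
#'
#' @param seed integer seed.
#' @param universe_size number of synthetic genes (`G0001`, ...).
#' @param n_terms number of terms.
#' @param min_size,max_size set-size range; sizes are drawn log-uniformly
#'   so small and large sets are both represented, as in real library
#'   collections whose set sizes span orders of magnitude.
#' @param noise_fraction fraction in [0, 1) of extra off-universe "noise"
#'   symbols appended to each set, emulating unmatchable gene identifiers
#'   in curated libraries.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, universe_size = 2000L, n_terms = 100L,
                         min_size = 10L, max_size = 200L,
                         noise_fraction = 0) {
  if (universe_size < 1L || n_terms < 1L) stop("counts must be positive")
  if (min_size < 1L || max_size < min_size) stop("bad set-size range")
  if (max_size > universe_size) stop("set size exceeds universe")
  if (noise_fraction < 0 || noise_fraction >= 1)
    stop("noise_fraction must be in [0, 1)")
  structure(list(seed = as.integer(seed),
                 universe_size = as.integer(universe_size),
                 n_terms = as.integer(n_terms),
                 min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 noise_fraction = noise_fraction),
            class = "fixture_spec")
}

synthetic_genes <- function(n, prefix = "G") {
  sprintf("%s%05d", prefix, seq_len(n))
}

#' Generate a random gene-set library
#'
#' Draws `n_terms` sets over a synthetic universe with log-uniform sizes
#' in `[min_size, max_size]`; when `noise_fraction > 0`, each set is
#' padded with that fraction of unique off-universe noise symbols
#' (`NOISE...`), so the library union is larger than the clean universe
#' -- the situation in which the Fisher test's set-size bias appears.
#'
#' @param spec a [fixture_spec()].
#' @return a [gene_set_library()]; the clean universe is available as
#'   `attr(, "clean_universe")`.
#' @export
random_library <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(split_seed(spec$seed, "library"))
  universe <- synthetic_genes(spec$universe_size)
  sizes <- round(exp(stats::runif(spec$n_terms, log(spec$min_size),
                                  log(spec$max_size))))
  sizes <- pmin(pmax(sizes, spec$min_size), spec$max_size)
  noise_counter <- 0L
  sets <- lapply(seq_len(spec$n_terms), function(i) {
    genes <- sample(universe, sizes[i], replace = FALSE)
    if (spec$noise_fraction > 0) {
      n_noise <- round(sizes[i] * spec$noise_fraction / (1 - spec$noise_fraction))
      if (n_noise > 0) {
        noise <- sprintf("NOISE%06d", noise_counter + seq_len(n_noise))
        noise_counter <<- noise_counter + n_noise
        genes <- c(genes, noise)
      }
    }
    gene_set(sprintf("TERM%04d", i), genes)
  })
  lib <- gene_set_library(sets, name = sprintf("fixture_seed%d", spec$seed))
  attr(lib, "clean_universe") <- universe
  lib
}

#' Draw a random input gene list
#'
#' Uniform sample without replacement from the universe; the building
#' block of background calibration.
#'
#' @param universe character vector of gene symbols.
#' @param length list length (1..|universe|).
#' @param seed integer seed.
#' @return an [input_gene_list()].
#' @export
random_gene_list <- function(universe, length, seed = 1L) {
  if (length < 1L) stop("list length must be >= 1")
  if (length > base::length(universe)) stop("length exceeds universe size")
  set.seed(split_seed(seed, "gene_list"))
  input_gene_list(sample(universe, length, replace = FALSE),
                  description = sprintf("random list (seed %d)", seed))
}

#' Plant an enrichment signal in a random gene list
#'
#' Builds a labeled input list whose overlap with one target term is
#' controlled: `ceiling(overlap_fraction * length)` genes are sampled
#' from the term's set, the remainder uniformly from the universe minus
#' that set -- a synthetic analogue of a differential list after
#' perturbing the term's factor.
#'
#' @param library a [gene_set_library()].
#' @param target_term term to plant.
#' @param overlap_fraction fraction in (0, 1] of the list taken from the
#'   target set.
#' @param length total list length.
#' @param seed integer seed.
#' @param universe pool for the non-signal remainder; defaults to the
#'   library's clean universe attribute, else its union.
#' @return an [input_gene_list()] with `label = target_term`.
#' @export
planted_enrichment_list <- function(library, target_term, overlap_fraction,
                                    length, seed = 1L, universe = NULL) {
  stopifnot(inherits(library, "gene_set_library"))
  if (overlap_fraction <= 0 || overlap_fraction > 1)
    stop("overlap_fraction must be in (0, 1]")
  idx <- match(target_term, library_terms(library))
  if (is.na(idx)) stop("term '", target_term, "' absent from library")
  target <- library$sets[[idx]]$genes
  universe <- universe %||% attr(library, "clean_universe") %||%
    library_universe(library)
  n_sig <- ceiling(overlap_fraction * length)
  if (n_sig > base::length(target))
    stop("target set smaller than requested signal size")
  rest_pool <- setdiff(universe, target)
  if (length - n_sig > base::length(rest_pool))
    stop("universe too small for the non-signal remainder")
  set.seed(split_seed(seed, "planted"))
  sig <- sample(target, n_sig, replace = FALSE)
  rest <- if (length - n_sig > 0)
    sample(rest_pool, length - n_sig, replace = FALSE) else character()
  input_gene_list(c(sig, rest),
                  description = sprintf("planted %s (overlap %.2f)",
                                        target_term, overlap_fraction),
                  label = target_term)
}

#' Toy corpus of every builder input with a ground-truth manifest
#'
#' Generates small, fully determined instances of each input format --
#' an expression matrix with planted |z| > 3 outliers (including a
#' duplicated probe), an interaction network with known hub degrees, a
#' peak set plus TSS annotation with known nearest genes, promoter
#' sequences with a motif planted in known windows, and a CuffDiff table
#' with known up/down counts -- together with a manifest recording every
#' planted fact.  With `dir` set, all components are written in their
#' standard formats (TSV, edge list, BED, FASTA, gene_exp.diff, JSON
#' manifest).
#'
#' @param seed integer seed.
#' @param dir optional directory to write the files into.
#' @return list with components `expression`, `network` (edge
#'   data.frame), `peaks`, `tss`, `promoters`, `cuffdiff`, `manifest`
#'   (and `paths` when written).
#' @export
toy_corpus <- function(seed = 1L, dir = NULL) {
  manifest <- list(seed = as.integer(seed))

  # --- expression matrix: 20 background genes + planted outliers ---
  # 12 samples: a single spike in an otherwise-flat row then reaches
  # z = sqrt(11) > 3 under the population sd (impossible with few samples)
  set.seed(split_seed(seed, "expr"))
  samples <- sprintf("CELL%02d", 1:12)
  genes <- sprintf("EXP%03d", 1:20)
  expr <- matrix(stats::rnorm(20 * 12, mean = 8, sd = 1), 20, 12,
                 dimnames = list(genes, samples))
  # planted outlier: huge value in one sample forces |z| > 3 there
  expr <- rbind(expr, OUTLIER1 = c(rep(8, 11), 60))
  # duplicate probe pair for MERGEME: the extreme probe must win the merge
  # (first probe alternates 7/9 so its z stays at +/-1 everywhere)
  expr <- rbind(expr, MERGEME = rep(c(7, 9), 6))
  expr <- rbind(expr, MERGEME = c(50, rep(8, 11)))
  manifest$expression <- list(
    outlier_gene = "OUTLIER1", outlier_sample = "CELL12",
    merged_gene = "MERGEME", merged_sample = "CELL01", threshold = 3)

  # --- interaction network: two hubs of known degree + a path ---
  set.seed(split_seed(seed, "ppi"))
  hub1_nb <- sprintf("PPI%03d", 1:5)     # HUBA degree 5
  hub2_nb <- sprintf("PPI%03d", 6:9)     # HUBB degree 4
  edges <- rbind(cbind("HUBA", hub1_nb), cbind("HUBB", hub2_nb),
                 cbind(c("PPI010", "PPI011"), c("PPI011", "PPI012")))
  network <- data.frame(a = edges[, 1], b = edges[, 2],
                        stringsAsFactors = FALSE)
  manifest$network <- list(
    hubs = list(HUBA = sort(hub1_nb), HUBB = sort(hub2_nb)),
    min_degree = 4)

  # --- peaks + TSS: known nearest gene per peak ---
  tss <- data.frame(
    gene = c("NEAR1", "NEAR2", "FAR1", "OTHER1"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    tss = c(1000L, 5000L, 40000L, 2000L),
    strand = c("+", "-", "+", "+"),
    stringsAsFactors = FALSE)
  peaks <- list(EXP_A = data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(950L, 5100L, 30000L, 2050L),
    end = c(1050L, 5200L, 30100L, 2150L),
    stringsAsFactors = FALSE))
  # midpoints 1000, 5150, 30050, 2100 -> NEAR1 (d 0), NEAR2 (d 150),
  # FAR1 (d 9950), OTHER1 (d 100)
  manifest$peaks <- list(
    experiment = "EXP_A", top2 = c("NEAR1", "OTHER1"),
    all_targets = c("NEAR1", "OTHER1", "NEAR2", "FAR1"))

  # --- promoters: motif planted in-window for 2 genes, out for 1 ---
  set.seed(split_seed(seed, "promoter"))
  motif <- "CACGTG"
  rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE, prob = c(.3, .2, .2, .3)),
                                collapse = "")
  window <- c(-2000L, 500L)
  win_len <- window[2] - window[1]
  plant <- function(pos_rel) {  # TSS-relative plant position
    s <- rand_dna(win_len + 200L)  # 200 nt beyond the window end
    at <- pos_rel - window[1] + 1L
    paste0(substr(s, 1, at - 1), motif,
           substr(s, at + nchar(motif), nchar(s)))
  }
  promoters <- c(
    MOTIF1 = plant(-100L),              # inside the window
    MOTIF2 = plant(400L),               # inside, downstream of TSS
    NOMOTIF = plant(win_len + window[1] + 60L),  # beyond +500, outside
    RANDOM1 = rand_dna(win_len + 200L))
  # scrub accidental matches from the window of the genes that must stay
  # negative (the motif is palindromic, so one pattern covers both
  # strands); iterate in case a substitution uncovers an overlapped match
  scrub <- function(s) {
    while (any(grepl("CACGTG", s))) s <- gsub("CACGTG", "CATGTG", s)
    s
  }
  in_win <- substr(promoters[c("NOMOTIF", "RANDOM1")], 1, win_len)
  promoters[c("NOMOTIF", "RANDOM1")] <-
    paste0(scrub(in_win),
           substr(promoters[c("NOMOTIF", "RANDOM1")], win_len + 1L,
                  nchar(promoters[c("NOMOTIF", "RANDOM1")])))
  manifest$promoters <- list(motif = motif, window = window,
                             hits = c("MOTIF1", "MOTIF2"),
                             misses = c("NOMOTIF", "RANDOM1"))

  # --- CuffDiff table: 3 up, 2 down, 4 not significant ---
  cd_gene <- c("UPA", "UPB", "UPC", "DOWNA", "DOWNB",
               "NSA", "NSB", "NSC", "NSD")
  lfc <- c(2.1, 1.4, 0.8, -1.9, -0.7, 1.2, -1.1, 0.1, -0.2)
  sig <- c("yes", "yes", "yes", "yes", "yes", "no", "no", "no", "no")
  cuffdiff <- data.frame(
    test_id = cd_gene, gene_id = cd_gene, gene = cd_gene,
    locus = sprintf("chr1:%d-%d", 1:9 * 1000, 1:9 * 1000 + 500),
    sample_1 = "q1", sample_2 = "q2", status = "OK",
    value_1 = 10, value_2 = round(10 * 2^lfc, 3),
    `log2(fold_change)` = lfc,
    test_stat = round(lfc * 2, 3), p_value = ifelse(sig == "yes", 1e-4, 0.4),
    q_value = ifelse(sig == "yes", 1e-3, 0.6), significant = sig,
    check.names = FALSE, stringsAsFactors = FALSE)
  manifest$cuffdiff <- list(n_up = 3, n_down = 2,
                            up = c("UPA", "UPB", "UPC"),
                            down = c("DOWNA", "DOWNB"))

  out <- list(expression = expr, network = network, peaks = peaks,
              tss = tss, promoters = promoters, cuffdiff = cuffdiff,
              manifest = manifest)
  if (!is.null(dir)) out$paths <- write_toy_corpus(out, dir)
  out
}

# Write every toy-corpus component in its standard on-disk format.
write_toy_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    network = file.path(dir, "network_edges.tsv"),
    peaks = file.path(dir, "peaks.bed"),
    tss = file.path(dir, "tss.tsv"),
    promoters = file.path(dir, "promoters.fa"),
    cuffdiff = file.path(dir, "gene_exp.diff"),
    manifest = file.path(dir, "manifest.json")
  )
  expr_df <- data.frame(gene = rownames(corpus$expression),
                        corpus$expression, check.names = FALSE)
  utils::write.table(expr_df, paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(corpus$network, paths$network, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  pk <- corpus$peaks[[1]]
  utils::write.table(cbind(pk, name = names(corpus$peaks)[1]), paths$peaks,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(corpus$tss, paths$tss, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(as.vector(rbind(paste0(">", names(corpus$promoters)),
                             unname(corpus$promoters))),
             paths$promoters)
  utils::write.table(corpus$cuffdiff, paths$cuffdiff, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(jsonlite::toJSON(corpus$manifest, auto_unbox = TRUE,
                              pretty = TRUE),
             paths$manifest)
  paths
}
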