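# Gene-set library construction procedures: expression z-score sets,
# interaction hubs, seed expansion, peak-to-TSS target sets, consensus
# promoter scanning and CuffDiff list extraction.

#' Gene sets of extreme expression per sample
#'
#' For each gene row, expression values are standardized against the
#' row's mean and standard deviation across all samples; duplicate
#' probes of one symbol are merged by keeping the value of highest
#' absolute z per sample.  Each sample (cell type, tissue, cell line)
#' becomes a term whose gene set holds the genes with |z| above the
#' threshold in that sample.  Constant rows (sd = 0) are skipped with a
#' warning.
#'
#' @param matrix numeric matrix, genes x samples; rownames are gene
#'   symbols (possibly duplicated probes), colnames are sample labels.
#' @param threshold absolute z cutoff (default 3, the conventional
#'   highly-expressed cutoff for these libraries).
#' @param sd_type `"population"` (divide by n) or `"sample"` (n - 1).
#' @param name,category passed to [gene_set_library()].
#' @return a [gene_set_library()]; samples whose set is empty are
#'   dropped.
#' @export
expression_zscore_sets <- function(matrix, threshold = 3,
                                   sd_type = c("population", "sample"),
                                   name = "expression_z",
                                   category = "cell_types") {
  sd_type <- match.arg(sd_type)
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (ncol(matrix) < 2L) stop("z-scores need >= 2 samples")
  if (threshold <= 0) stop("threshold must be > 0")
  if (any(!is.finite(matrix))) stop("expression values must be finite")

  mu <- rowMeans(matrix)
  n <- ncol(matrix)
  dev <- matrix - mu
  sdv <- sqrt(rowSums(dev^2) / if (sd_type == "population") n else n - 1L)
  keep <- sdv > 0
  if (any(!keep))
    warning(sum(!keep), " constant row(s) skipped (sd = 0, z undefined)")
  z <- dev[keep, , drop = FALSE] / sdv[keep]
  genes <- normalize_gene_symbols(rownames(matrix)[keep])

  # merge duplicate probes: per (gene, sample) keep the most extreme z
  ug <- unique(genes)
  zm <- matrix(0, length(ug), ncol(z), dimnames = list(ug, colnames(z)))
  for (g in ug) {
    rows <- z[genes == g, , drop = FALSE]
    pick <- apply(abs(rows), 2, which.max)
    zm[g, ] <- rows[cbind(pick, seq_len(ncol(rows)))]
  }

  sets <- list()
  for (s in colnames(zm)) {
    hit <- ug[abs(zm[, s]) > threshold]
    if (length(hit))
      sets[[length(sets) + 1L]] <- gene_set(s, hit,
                                            sprintf("|z| > %g genes", threshold))
  }
  gene_set_library(sets, name = name, category = category)
}

#' Interaction-hub gene sets
#'
#' Every node of an undirected interaction network with degree at or
#' above `min_degree` (inclusive, matching the "120 or more
#' interactions" rule) becomes a term; its gene set is the node's direct
#' neighbours.
#'
#' @param network an [igraph::graph] with gene-symbol vertex names, or an
#'   edge data.frame/matrix with two columns.
#' @param min_degree inclusive degree threshold (default 120).
#' @param name,category passed to [gene_set_library()].
#' @return a [gene_set_library()] (possibly empty).
#' @export
ppi_hub_sets <- function(network, min_degree = 120L, name = "ppi_hubs",
                         category = "pathways") {
  g <- as_interaction_graph(network)
  deg <- igraph::degree(g)
  hubs <- names(deg)[deg >= min_degree]
  sets <- lapply(sort(hubs), function(h) {
    nb <- names(igraph::neighbors(g, h))
    gene_set(h, nb, sprintf("direct interactors of %s", h))
  })
  gene_set_library(sets, name = name, category = category)
}

# normalize input into a simple undirected igraph with gene-symbol names
as_interaction_graph <- function(network) {
  if (igraph::is_igraph(network)) {
    g <- network
  } else {
    edges <- as.matrix(network)[, 1:2, drop = FALSE]
    edges[] <- normalize_gene_symbols(as.character(edges))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Seed-expansion gene sets
#'
#' For each named seed list (e.g. the genes of one disease), the
#' expanded set is the seeds plus every network protein, not itself a
#' seed, that directly interacts with at least two distinct seeds --
#' i.e. every intermediate on a length-2 path between two seeds.  Seeds
#' absent from the network are kept in the output set (they simply
#' contribute no paths) and reported via a message.
#'
#' @param seed_lists named list of character vectors of seed genes.
#' @param network interaction network, see [ppi_hub_sets()].
#' @param name,category passed to [gene_set_library()].
#' @return a [gene_set_library()] with one term per seed list.
#' @export
seed_expansion_sets <- function(seed_lists, network, name = "seed_expanded",
                                category = "diseases_drugs") {
  if (is.null(names(seed_lists)) || any(!nzchar(names(seed_lists))))
    stop("seed_lists must be a named list")
  g <- as_interaction_graph(network)
  vs <- igraph::V(g)$name
  sets <- lapply(names(seed_lists), function(term) {
    seeds <- unique(normalize_gene_symbols(seed_lists[[term]]))
    absent <- setdiff(seeds, vs)
    if (length(absent))
      message("term '", term, "': ", length(absent),
              " seed(s) absent from the network")
    present <- intersect(seeds, vs)
    inter <- character()
    if (length(present) >= 2L) {
      nb_count <- integer(length(vs)); names(nb_count) <- vs
      for (s in present) {
        nb <- names(igraph::neighbors(g, s))
        nb_count[nb] <- nb_count[nb] + 1L
      }
      inter <- names(nb_count)[nb_count >= 2L]
      inter <- setdiff(inter, seeds)
    }
    gene_set(term, c(seeds, inter), "seed-expanded sub-network")
  })
  gene_set_library(sets, name = name, category = category)
}

#' Peak-to-TSS target gene sets
#'
#' For each experiment's peak set, every peak is assigned the gene with
#' the nearest transcription start site on the same chromosome (distance
#' from peak midpoint to TSS; equidistant TSSs resolved upstream gene
#' first, then lexicographically).  Genes are ranked by their minimal
#' peak distance and the first `top_n` distinct genes form the
#' experiment's target set.
#'
#' @param peaks named list (one entry per experiment) of data.frames
#'   with columns `chrom`, `start`, `end` (0-based half-open, BED
#'   convention).
#' @param tss data.frame with columns `gene`, `chrom`, `tss` (1-based
#'   position), `strand`.
#' @param top_n number of target genes retained per experiment
#'   (default 2000).
#' @param name,category passed to [gene_set_library()].
#' @return a [gene_set_library()] with one term per experiment.
#' @export
peaks_to_target_sets <- function(peaks, tss, top_n = 2000L,
                                 name = "peak_targets",
                                 category = "transcription") {
  stopifnot(is.list(peaks), !is.null(names(peaks)))
  req <- c("gene", "chrom", "tss", "strand")
  if (!all(req %in% names(tss)))
    stop("tss annotation must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(tss[, c("gene", "tss")]))
    stop("duplicate (gene, tss) records in annotation")
  tss$gene <- normalize_gene_symbols(tss$gene)

  sets <- list()
  for (exp_name in names(peaks)) {
    pk <- peaks[[exp_name]]
    if (any(pk$start >= pk$end)) stop("peak with start >= end")
    shared <- intersect(unique(pk$chrom), unique(tss$chrom))
    if (!length(shared)) {
      warning("experiment '", exp_name,
              "': no chromosomes shared with the TSS annotation")
      next
    }
    assigned <- data.frame(gene = character(), dist = numeric())
    for (chr in shared) {
      mids <- (pk$start[pk$chrom == chr] + pk$end[pk$chrom == chr]) / 2
      ann <- tss[tss$chrom == chr, , drop = FALSE]
      for (mid in mids) {
        d <- abs(ann$tss - mid)
        best <- min(d)
        cand <- ann[d == best, , drop = FALSE]
        # tie rule: upstream (TSS before the peak midpoint), then name
        cand <- cand[order(cand$tss > mid, cand$gene), , drop = FALSE]
        assigned <- rbind(assigned,
                          data.frame(gene = cand$gene[1], dist = best))
      }
    }
    if (!nrow(assigned)) next
    mind <- tapply(assigned$dist, assigned$gene, min)
    ranked <- names(sort(mind))  # by minimal distance, ties by gene name
    targets <- utils::head(ranked, top_n)
    sets[[length(sets) + 1L]] <-
      gene_set(exp_name, targets, sprintf("top %d nearest-TSS targets", top_n))
  }
  gene_set_library(sets, name = name, category = category)
}

IUPAC_OK <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

#' Scan promoter windows for 100% consensus motif matches
#'
#' A gene is included in the output set iff its promoter window
#' (default -2000..+500 around the TSS) contains at least one exact
#' match to the IUPAC consensus on either strand; degenerate codes match
#' their standard nucleotide classes.  Sequences shorter than the window
#' are scanned as-is with a warning.
#'
#' @param promoters named character vector (or `Biostrings::DNAStringSet`)
#'   of promoter sequences keyed by gene; each sequence is assumed to
#'   start at the window's upstream edge relative to the TSS.
#' @param motif IUPAC consensus string (e.g. `"CACGTG"`, `"RRCGTG"`).
#' @param window c(upstream, downstream) offsets relative to the TSS.
#' @param label term label for the resulting set.
#' @return a [gene_set()] of the matching genes, or `NULL` if none match.
#' @export
consensus_promoter_scan <- function(promoters, motif,
                                    window = c(-2000L, 500L),
                                    label = motif) {
  motif <- toupper(motif)
  bad <- setdiff(strsplit(motif, "")[[1]], IUPAC_OK)
  if (length(bad))
    stop("invalid IUPAC character(s) in motif: ", paste(bad, collapse = ", "))
  if (inherits(promoters, "DNAStringSet")) {
    seqs <- promoters
  } else {
    if (is.null(names(promoters))) stop("promoters must be named by gene")
    seqs <- Biostrings::DNAStringSet(toupper(promoters))
  }
  win_len <- window[2] - window[1]
  short <- sum(Biostrings::width(seqs) < win_len)
  if (short > 0)
    warning(short, " promoter(s) shorter than the ", win_len,
            " nt window scanned as-is")
  seqs <- Biostrings::DNAStringSet(substr(as.character(seqs), 1, win_len))
  pat <- Biostrings::DNAString(motif)
  fwd <- Biostrings::vcountPattern(pat, seqs, fixed = FALSE)
  rev <- Biostrings::vcountPattern(Biostrings::reverseComplement(pat), seqs,
                                   fixed = FALSE)
  hits <- names(seqs)[fwd + rev > 0]
  if (!length(hits)) return(NULL)
  gene_set(label, hits,
           sprintf("100%% consensus matches in [%d, %+d] promoter window",
                   window[1], window[2]))
}

CUFFDIFF_COLUMNS <- c("test_id", "gene_id", "gene", "locus", "sample_1",
                      "sample_2", "status", "value_1", "value_2",
                      "log2(fold_change)", "test_stat", "p_value",
                      "q_value", "significant")

#' Extract up/down gene lists from a CuffDiff table
#'
#' Parses the 14-column `gene_exp.diff` dialect (extra columns are
#' ignored) and returns the significantly changed genes: up = rows
#' flagged `significant == "yes"` with positive log2 fold change, down =
#' flagged rows with negative log2 fold change.  Symbols are normalized
#' and deduplicated.
#'
#' @param path path to a `gene_exp.diff` file (or a data.frame already
#'   parsed with the dialect's column names).
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return an [input_gene_list()] for `"up"`/`"down"`, or a list with
#'   elements `up` and `down` for `"both"` (empty directions are `NULL`).
#' @export
cuffdiff_extract <- function(path, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (is.data.frame(path)) {
    tab <- path
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  }
  missing <- setdiff(CUFFDIFF_COLUMNS, names(tab))
  if (length(missing))
    stop("CuffDiff table missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!all(tab$significant %in% c("yes", "no")))
    stop("significant flag must be 'yes' or 'no'")
  lfc <- suppressWarnings(as.numeric(tab$`log2(fold_change)`))
  sig <- tab$significant == "yes"
  mk <- function(rows, tag) {
    genes <- unique(tab$gene[rows])
    genes <- genes[nzchar(trimws(genes)) & genes != "-"]
    if (!length(genes)) return(NULL)
    input_gene_list(genes, description = paste("CuffDiff", tag, "genes"))
  }
  up <- mk(which(sig & !is.na(lfc) & lfc > 0), "up")
  down <- mk(which(sig & !is.na(lfc) & lfc < 0), "down")
  switch(direction, up = up, down = down, both = list(up = up, down = down))
}
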