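test_that("expression z-score sets plant, merge and threshold correctly", {
  # one spike among 12 flat samples: z = sqrt(11) > 3 in the spiked sample
  m <- rbind(SPIKE = c(rep(5, 11), 50),
             FLAT1 = rep(c(4, 6), 6),
             FLAT2 = rep(c(3, 7), 6))
  colnames(m) <- sprintf("S%02d", 1:12)
  lib <- expression_zscore_sets(m)
  expect_identical(library_terms(lib), "S12")
  expect_identical(lib$sets[[1]]$genes, "SPIKE")

  # duplicate probes merge by max |z|: the 3.5-ish probe wins over 2.5-ish
  m2 <- rbind(G = c(rep(5, 11), 50),        # z = 3.317 in S12
              G = rep(c(4, 6), 6))          # z = +/-1 everywhere
  colnames(m2) <- colnames(m)
  lib2 <- expression_zscore_sets(m2)
  expect_identical(library_terms(lib2), "S12")
  expect_identical(lib2$sets[[1]]$genes, "G")

  # all-constant matrix -> warning, empty library
  const <- matrix(3, 2, 4, dimnames = list(c("A", "B"), sprintf("S%d", 1:4)))
  expect_warning(lib3 <- expression_zscore_sets(const), "constant")
  expect_length(lib3$sets, 0L)

  # monotone in threshold: lowering it never removes a gene
  m4 <- matrix(rnorm(30 * 12), 30, 12,
               dimnames = list(sprintf("g%02d", 1:30), colnames(m)))
  hi <- expression_zscore_sets(m4, threshold = 2)
  lo <- expression_zscore_sets(m4, threshold = 1.5)
  for (s in hi$sets) {
    mate <- lo$sets[[match(s$term, library_terms(lo))]]
    expect_true(all(s$genes %in% mate$genes))
  }
})

test_that("ppi hub sets use an inclusive degree threshold", {
  star <- cbind("HUB", sprintf("N%02d", 1:4))
  lib <- ppi_hub_sets(star, min_degree = 4)   # boundary: degree == threshold
  expect_identical(library_terms(lib), "HUB")
  expect_setequal(lib$sets[[1]]$genes, sprintf("N%02d", 1:4))
  # path graph has max degree 2
  path <- cbind(c("A", "B", "C"), c("B", "C", "D"))
  expect_length(ppi_hub_sets(path, min_degree = 3)$sets, 0L)
  # two hubs with hand-counted neighbourhoods
  edges <- rbind(cbind("H1", paste0("X", 1:4)), cbind("H2", paste0("Y", 1:5)))
  two <- ppi_hub_sets(edges, min_degree = 4)
  expect_identical(library_terms(two), c("H1", "H2"))
  expect_setequal(two$sets[[2]]$genes, paste0("Y", 1:5))
  # term count non-increasing in min_degree
  expect_gte(length(ppi_hub_sets(edges, min_degree = 4)$sets),
             length(ppi_hub_sets(edges, min_degree = 5)$sets))
})

test_that("seed expansion adds intermediates touching >= 2 seeds", {
  edges <- rbind(c("A", "X"), c("B", "X"), c("A", "Y"), c("Y", "Q"))
  lib <- seed_expansion_sets(list(D1 = c("A", "B")), edges)
  expect_setequal(lib$sets[[1]]$genes, c("A", "B", "X"))  # Y touches only A
  # no common neighbours -> just the seeds
  lib2 <- seed_expansion_sets(list(D2 = c("A", "Q")), edges)
  expect_setequal(lib2$sets[[1]]$genes, c("A", "Q", "Y"))
  lib3 <- seed_expansion_sets(list(D3 = c("X", "Q")), edges)
  expect_setequal(lib3$sets[[1]]$genes, c("X", "Q"))
  # seeds absent from the network are kept and logged
  expect_message(
    lib4 <- seed_expansion_sets(list(D4 = c("A", "B", "ZZ")), edges),
    "absent")
  expect_true("ZZ" %in% lib4$sets[[1]]$genes)
  # growth property on random graphs
  set.seed(44)
  g <- igraph::sample_gnp(40, 0.15)
  igraph::V(g)$name <- sprintf("P%02d", 1:40)
  seeds <- list(S = sprintf("P%02d", sample(40, 6)))
  out <- seed_expansion_sets(seeds, g)
  expect_true(all(seeds$S %in% out$sets[[1]]$genes))
})

test_that("peak-to-TSS assignment ranks genes by minimal distance", {
  tss <- data.frame(gene = c("G1", "G2", "G3"),
                    chrom = "chr1", tss = c(100L, 10000L, 3000L),
                    strand = "+", stringsAsFactors = FALSE)
  mk_peak <- function(mid) data.frame(chrom = "chr1", start = mid - 10,
                                      end = mid + 10)
  peaks <- list(E1 = do.call(rbind, list(mk_peak(110),    # G1, d 10
                                         mk_peak(15000),  # G2, d 5000
                                         mk_peak(3200)))) # G3, d 200
  lib <- peaks_to_target_sets(peaks, tss, top_n = 2)
  expect_identical(lib$sets[[1]]$genes, c("G1", "G3"))
  # top_n beyond the distinct targets returns all of them
  all3 <- peaks_to_target_sets(peaks, tss, top_n = 10)
  expect_setequal(all3$sets[[1]]$genes, c("G1", "G2", "G3"))
  # increasing top_n never drops a gene
  expect_true(all(lib$sets[[1]]$genes %in% all3$sets[[1]]$genes))
  # equidistant tie resolves to the upstream gene
  tss2 <- data.frame(gene = c("UP", "DN"), chrom = "chr1",
                     tss = c(900L, 1100L), strand = "+",
                     stringsAsFactors = FALSE)
  tie <- peaks_to_target_sets(list(E = mk_peak(1000)), tss2, top_n = 1)
  expect_identical(tie$sets[[1]]$genes, "UP")
  # disjoint chromosome naming warns and yields no set
  off <- list(E = data.frame(chrom = "chrX", start = 1L, end = 10L))
  expect_warning(empty <- peaks_to_target_sets(off, tss), "chromosome")
  expect_length(empty$sets, 0L)
})

test_that("consensus promoter scan honours IUPAC codes, strand and window", {
  win <- c(-50L, 10L)  # 60 nt window for compact fixtures
  base <- strrep("AT", 60)
  planted <- paste0(substr(base, 1, 20), "CACGTG", substr(base, 27, 120))
  proms <- c(HIT = planted, MISS = base)
  gs <- consensus_promoter_scan(proms, "CACGTG", window = win)
  expect_identical(gs$genes, "HIT")
  # empty sequence never matches (and is reported as shorter than the
  # window); NNNN matches any long-enough window
  expect_warning(
    expect_null(consensus_promoter_scan(c(EMPTY = ""), "CACGTG",
                                        window = win)),
    "shorter")
  all_match <- consensus_promoter_scan(proms, "NNNN", window = win)
  expect_setequal(all_match$genes, c("HIT", "MISS"))
  # degenerate code: RACGTG matches AACGTG (R = A/G)
  proms2 <- c(DEG = paste0(substr(base, 1, 20), "AACGTG",
                           substr(base, 27, 120)))
  expect_identical(consensus_promoter_scan(proms2, "RACGTG",
                                           window = win)$genes, "DEG")
  # reverse strand: plant the reverse complement of a non-palindrome
  proms3 <- c(RC = paste0(substr(base, 1, 20), "TTTCCC",
                          substr(base, 27, 120)))
  expect_identical(consensus_promoter_scan(proms3, "GGGAAA",
                                           window = win)$genes, "RC")
  expect_error(consensus_promoter_scan(proms, "CACGTJ", window = win),
               "IUPAC")
  # short sequences are scanned as-is with a warning
  expect_warning(
    consensus_promoter_scan(c(S = "CACGTG"), "CACGTG", window = win),
    "shorter")
})

test_that("cuffdiff extraction splits significant rows by direction", {
  tc <- toy_corpus(seed = 3)
  lists <- cuffdiff_extract(tc$cuffdiff)
  expect_setequal(lists$up$genes, tc$manifest$cuffdiff$up)
  expect_setequal(lists$down$genes, tc$manifest$cuffdiff$down)
  # all non-significant -> both empty (NULL)
  ns <- tc$cuffdiff
  ns$significant <- "no"
  both <- cuffdiff_extract(ns)
  expect_null(both$up)
  expect_null(both$down)
  # duplicate up rows collapse
  dup <- rbind(tc$cuffdiff, tc$cuffdiff[1, ])
  expect_length(cuffdiff_extract(dup, "up")$genes, 3L)
  # missing column is a parse error naming the column
  broken <- tc$cuffdiff
  broken$significant <- NULL
  expect_error(cuffdiff_extract(broken), "significant")
})

test_that("builder outputs pass library invariants and GMT round-trip", {
  tc <- toy_corpus(seed = 8)
  libs <- list(
    suppressWarnings(expression_zscore_sets(tc$expression)),
    ppi_hub_sets(tc$network, min_degree = 4),
    peaks_to_target_sets(tc$peaks, tc$tss, top_n = 3)
  )
  for (lib in libs) {
    expect_s3_class(lib, "gene_set_library")
    path <- withr::local_tempfile(fileext = ".gmt")
    write_gmt(lib, path)
    back <- read_gmt(path)
    expect_identical(library_terms(back), library_terms(lib))
    for (i in seq_along(lib$sets))
      expect_setequal(back$sets[[i]]$genes, lib$sets[[i]]$genes)
  }
})
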