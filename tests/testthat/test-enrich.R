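test_that("fisher_exact_p matches the enumeration oracle and its examples", {
  # frozen DERIVED example: N=20, K=5, n=4, k=2
  expect_equal(fisher_exact_p(2, 4, 5, 20), hyper_oracle(2, 4, 5, 20),
               tolerance = 1e-14)
  expect_equal(fisher_exact_p(2, 4, 5, 20), 0.2487100103199174,
               tolerance = 1e-12)
  # trivial identities
  expect_equal(fisher_exact_p(0, 7, 3, 20), 1)
  expect_equal(fisher_exact_p(4, 4, 20, 20), 1)   # K = N forces overlap
  # random spot agreement with the oracle
  set.seed(5)
  for (i in 1:50) {
    N <- sample(5:30, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(fisher_exact_p(k, n, K, N), hyper_oracle(k, n, K, N),
                 tolerance = 1e-12)
  }
  # monotone non-increasing in k at fixed (n, K, N)
  p <- fisher_exact_p(0:5, 8, 5, 40)
  expect_true(all(diff(p) <= 1e-15))
  # invariant violations are domain errors
  expect_error(fisher_exact_p(3, 2, 5, 20), "min")
  expect_error(fisher_exact_p(1, 2, 25, 20), "exceed")
})

test_that("rank_by_p assigns a deterministic full ranking", {
  lib <- tiny_library()
  tab <- rank_by_p(lib, c("C", "D", "E"))
  expect_setequal(tab$fisher_rank, 1:3)
  expect_identical(tab$term[1], "T3")  # contains the whole input
  # single term -> rank 1
  one <- gene_set_library(list(gene_set("S", c("A", "B"))))
  expect_equal(rank_by_p(one, "A", universe = LETTERS[1:5])$fisher_rank, 1L)
  # identical gene sets tie; order resolved lexicographically by term
  twin <- gene_set_library(list(gene_set("B_TERM", c("A", "B")),
                                gene_set("A_TERM", c("A", "B"))))
  tw <- rank_by_p(twin, "A", universe = LETTERS[1:6])
  expect_identical(tw$term, c("A_TERM", "B_TERM"))
  expect_identical(tw$fisher_rank, 1:2)
  # disjoint input errors with guidance
  expect_error(rank_by_p(lib, input_gene_list("ZZZ")), "universe")
})

test_that("rank_zscore and combined_score follow their contracts", {
  expect_equal(rank_zscore(150, 150, 10), 0)
  expect_equal(rank_zscore(130, 150, 10), -2)
  expect_error(rank_zscore(130, 150, 0), "sd_rank")

  expect_equal(combined_score(1, -5), 0)
  expect_equal(combined_score(0.3, 0), 0)
  expect_equal(combined_score(0.01, -2), log(0.01) * -2, tolerance = 1e-12)
  expect_error(combined_score(0, -1), "0, 1")
  expect_error(combined_score(1.2, -1), "0, 1")
  # floor keeps scores finite
  expect_true(is.finite(combined_score(1e-320, -3)))
})

test_that("calibrate_background is reproducible and symmetric", {
  # Two interchangeable disjoint terms.  The deterministic tie rule
  # (lexicographic term on equal p) systematically favours the earlier
  # label, so exchangeability is asserted after symmetrizing over the
  # two label orderings: the tie bias then cancels exactly.
  mk_pair <- function(first_label, second_label) {
    gene_set_library(list(gene_set(first_label, sprintf("A%02d", 1:10)),
                          gene_set(second_label, sprintf("B%02d", 1:10))))
  }
  bg_pq <- calibrate_background(mk_pair("P", "Q"), n_lists = 2000,
                                list_lengths = 4, seed = 3)
  bg_qp <- calibrate_background(mk_pair("Z_P", "A_Q"), n_lists = 2000,
                                list_lengths = 4, seed = 3)
  mr_p <- (bg_pq$bins[["4"]]$mean_rank[["P"]] +
             bg_qp$bins[["4"]]$mean_rank[["Z_P"]]) / 2
  mr_q <- (bg_pq$bins[["4"]]$mean_rank[["Q"]] +
             bg_qp$bins[["4"]]$mean_rank[["A_Q"]]) / 2
  expect_equal(mr_p, mr_q, tolerance = 0.05)
  # the two ranks always partition {1, 2}
  expect_equal(unname(sum(bg_pq$bins[["4"]]$mean_rank)), 3)

  bg2 <- calibrate_background(mk_pair("P", "Q"), n_lists = 2000,
                              list_lengths = 4, seed = 3)
  expect_identical(bg_pq, bg2)  # same seed -> bit-identical

  # 10 exchangeable disjoint terms: tie-symmetrized mean ranks ~ 5.5
  mk_ten <- function(labels) {
    gene_set_library(lapply(1:10, function(i)
      gene_set(labels[i], sprintf("G%02d_%02d", i, 1:8))))
  }
  fwd <- sprintf("S%02d", 1:10)
  rev_lab <- sprintf("S%02d", 10:1)
  bg_f <- calibrate_background(mk_ten(fwd), n_lists = 1500,
                               list_lengths = 5, seed = 9)
  bg_r <- calibrate_background(mk_ten(rev_lab), n_lists = 1500,
                               list_lengths = 5, seed = 9)
  mr <- (bg_f$bins[["5"]]$mean_rank[fwd] +
           bg_r$bins[["5"]]$mean_rank[rev_lab]) / 2
  se <- bg_f$bins[["5"]]$sd_rank[fwd] / sqrt(1500)
  expect_true(all(abs(mr - 5.5) < 3 * se + 0.2))
  expect_equal(unname(mean(bg_f$bins[["5"]]$mean_rank)), 5.5)

  expect_error(
    calibrate_background(gene_set_library(list(gene_set("S", "A")))),
    ">= 2 terms")
})

test_that("background JSON round-trips and binning picks the nearest length", {
  lib <- random_library(fixture_spec(seed = 2, universe_size = 200,
                                     n_terms = 12, min_size = 5,
                                     max_size = 30))
  bg <- calibrate_background(lib, n_lists = 50, list_lengths = c(10, 40),
                             seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_background_json(bg, path)
  back <- read_background_json(path)
  expect_equal(back$bins, bg$bins, tolerance = 1e-12)
  expect_identical(back$terms, bg$terms)
  expect_identical(enrichtk:::nearest_bin(bg, 12), "10")
  expect_identical(enrichtk:::nearest_bin(bg, 30), "40")
})

test_that("enrich produces coherent tables in all three sort modes", {
  spec <- fixture_spec(seed = 13, universe_size = 500, n_terms = 30,
                       min_size = 10, max_size = 60)
  lib <- random_library(spec)
  uni <- attr(lib, "clean_universe")
  bg <- calibrate_background(lib, n_lists = 400, list_lengths = 50,
                             seed = 17, sample_from = uni)
  lst <- planted_enrichment_list(lib, "TERM0005", 0.8, 50, seed = 19)

  # p_value mode needs no background
  tp <- suppressMessages(enrich(lst, lib))
  expect_s3_class(tp, "enrichment_table")
  expect_equal(nrow(tp), 30L)
  expect_true(!is.unsorted(tp$p_value))
  expect_identical(tp$term[1], "TERM0005")

  # z / combined modes require the background
  expect_error(enrich(lst, lib, sort_mode = "combined"), "background")
  for (mode in c("z_score", "combined")) {
    tm <- suppressMessages(enrich(lst, lib, background = bg, sort_mode = mode))
    expect_identical(tm$term[1], "TERM0005")  # strong planted signal wins
  }

  # re-sorting permutes but never drops records
  tz <- resort_enrichment(
    suppressMessages(enrich(lst, lib, background = bg)), "z_score")
  expect_setequal(tz$term, tp$term)
  expect_identical(attr(tz, "sort_mode"), "z_score")
  back_to_p <- resort_enrichment(tz, "p_value")
  expect_identical(back_to_p$term, tp$term)

  # background/library term mismatch is reported with the missing terms
  other <- gene_set_library(list(gene_set("ALPHA", uni[1:10]),
                                 gene_set("BETA", uni[11:20])))
  expect_error(
    suppressMessages(enrich(lst, other, background = bg,
                            sort_mode = "z_score")),
    "ALPHA")
})

test_that("input genes outside the universe are dropped from n", {
  lib <- tiny_library()
  expect_message(
    tab <- enrich(input_gene_list(c("A", "B", "XYZ")), lib),
    "1 input gene")
  expect_equal(attr(tab, "n_input"), 2L)
})

test_that("enrichment table TSV and JSON exports round-trip", {
  lib <- tiny_library()
  tab <- enrich(c("A", "B", "C"), lib)
  lines <- write_enrichment_tsv(tab)
  expect_identical(
    lines[1],
    "Term\tOverlap (k/K)\tP-value\tZ-score\tCombined Score\tGenes")
  expect_length(lines, 4L)
  expect_match(lines[2], "^T1\t2/2\t")

  path <- withr::local_tempfile(fileext = ".json")
  write_enrichment_json(tab, path, seed = 7)
  back <- read_enrichment_json(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  expect_identical(attr(back, "sort_mode"), attr(tab, "sort_mode"))
  expect_identical(attr(back, "library_name"), attr(tab, "library_name"))
})

test_that("benchmark_rank_recovery ranks labeled lists per method", {
  lib <- random_library(fixture_spec(seed = 23, universe_size = 400,
                                     n_terms = 20, min_size = 10,
                                     max_size = 40))
  uni <- attr(lib, "clean_universe")
  bg <- calibrate_background(lib, n_lists = 300, list_lengths = 20,
                             seed = 29, sample_from = uni)
  lists <- lapply(1:5, function(i) {
    # list identical in content to the term itself
    planted_enrichment_list(lib, sprintf("TERM%04d", i), 1.0,
                            length(lib$sets[[i]]$genes), seed = 100 + i)
  })
  res <- suppressMessages(benchmark_rank_recovery(lib, lists, bg))
  expect_equal(nrow(res), 5L)
  # a list identical in content to the term -> Fisher rank 1
  expect_true(all(res$rank_p == 1L))
  expect_named(attr(res, "mean_ranks"), c("p_value", "z_score", "combined"))
  # label missing from the library errors
  bad <- list(input_gene_list(uni[1:5], label = "NOPE"))
  expect_error(benchmark_rank_recovery(lib, bad, bg), "NOPE")
})

test_that("planted-term recovery by Fisher p succeeds in >= 95% of seeds", {
  lib <- random_library(fixture_spec(seed = 37, universe_size = 1000,
                                     n_terms = 100, min_size = 20,
                                     max_size = 80))
  terms <- library_terms(lib)
  sizes <- vapply(lib$sets, function(s) length(s$genes), 0L)
  eligible <- terms[sizes >= 40]
  wins <- vapply(1:100, function(i) {
    tgt <- eligible[(i - 1) %% length(eligible) + 1]
    lst <- planted_enrichment_list(lib, tgt, 0.8, 50, seed = 500 + i)
    tab <- suppressMessages(rank_by_p(lib, lst))
    tab$term[1] == tgt
  }, NA)
  expect_gte(mean(wins), 0.95)
})
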