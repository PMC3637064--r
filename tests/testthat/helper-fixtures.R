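# Shared helpers: independent oracles and tiny handcrafted fixtures.

# Independent hypergeometric upper-tail oracle: direct enumeration of
# C(K,i) C(N-K, n-i) / C(N, n).  For N <= 30 every binomial product fits
# exactly in a double, so the enumeration is exact rational arithmetic.
hyper_oracle <- function(k, n, K, N) {
  if (k == 0) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i) {
    choose(K, i) * choose(N - K, n - i)
  }, 0)) / choose(N, n)
}

# 3-set toy library used across modules
tiny_library <- function() {
  gene_set_library(list(
    gene_set("T1", c("A", "B")),
    gene_set("T2", c("B", "C")),
    gene_set("T3", c("C", "D", "E"))
  ), name = "tiny")
}

# grid_layout with a prescribed assignment (bypasses annealing)
manual_layout <- function(terms, width, height, assignment = NULL) {
  assignment <- assignment %||% c(seq_along(terms),
                                  rep(NA_integer_,
                                      width * height - length(terms)))
  structure(list(width = as.integer(width), height = as.integer(height),
                 terms = terms, assignment = assignment, fitness = NA_real_,
                 seed = 0L, schedule = annealing_schedule()),
            class = "grid_layout")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small enrichment table built directly (for termnet/export tests)
fake_table <- function(terms, p = NULL, z = NULL) {
  n <- length(terms)
  p <- p %||% seq(1e-6, 0.5, length.out = n)
  z <- z %||% rep(NA_real_, n)
  structure(
    data.frame(term = terms, overlap = rep(2L, n), set_size = rep(5L, n),
               p_value = p, fisher_rank = seq_len(n), z_score = z,
               combined_score = ifelse(is.na(z), NA_real_, log(p) * z),
               genes = rep("A;B", n), stringsAsFactors = FALSE),
    class = c("enrichment_table", "data.frame"),
    library_name = "fake", description = "fake", sort_mode = "p_value",
    n_input = 10L, universe_size = 100L)
}
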