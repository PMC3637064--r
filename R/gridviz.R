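# Toroidal-grid layout of library terms by gene-content similarity, and a
# permutation-based index for the spatial clustering of enriched terms.

#' Term-term gene-content similarity
#'
#' Default similarity is the Jaccard index of the terms' gene sets; the
#' measure is pluggable via `fun`, which must accept two character
#' vectors and return a scalar in [0, 1] (any co-occurrence measure can
#' be slotted in).  The result is symmetric with unit diagonal.
#'
#' @param library a [gene_set_library()] with >= 2 terms.
#' @param fun optional custom scorer `function(genes_a, genes_b)`.
#' @return symmetric numeric matrix with term dimnames, values in [0, 1].
#' @export
term_similarity <- function(library, fun = NULL) {
  stopifnot(inherits(library, "gene_set_library"))
  terms <- library_terms(library)
  if (length(terms) < 2L) stop("similarity needs >= 2 terms")
  sizes <- vapply(library$sets, function(s) length(s$genes), 0L)
  if (any(sizes == 0L)) stop("term with empty gene set")
  if (is.null(fun)) {
    genes <- unique(unlist(lapply(library$sets, `[[`, "genes")))
    M <- membership_matrix(library, genes)
    storage.mode(M) <- "double"
    inter <- M %*% t(M)
    un <- outer(sizes, sizes, "+") - inter
    S <- inter / un
  } else {
    n <- length(terms)
    S <- diag(1, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      v <- fun(library$sets[[i]]$genes, library$sets[[j]]$genes)
      S[i, j] <- S[j, i] <- v
    }
  }
  if (any(S < -1e-12) || any(S > 1 + 1e-12))
    stop("similarity values must lie in [0, 1]")
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  dimnames(S) <- list(terms, terms)
  S
}

#' Toroidal (wrap-around) Euclidean distance between grid cells
#'
#' Cells are 1-based `(row, col)` pairs on a `height` x `width` grid whose
#' edges wrap: per axis the displacement is `min(|d|, size - |d|)`.
#'
#' @param cell_a,cell_b integer vectors `c(row, col)`.
#' @param width,height grid dimensions.
#' @return non-negative distance.
#' @export
toroidal_distance <- function(cell_a, cell_b, width, height) {
  chk <- function(cell) {
    if (length(cell) != 2L || cell[1] < 1 || cell[1] > height ||
        cell[2] < 1 || cell[2] > width)
      stop("cell out of grid bounds")
  }
  chk(cell_a); chk(cell_b)
  dr <- abs(cell_a[1] - cell_b[1]); dr <- min(dr, height - dr)
  dc <- abs(cell_a[2] - cell_b[2]); dc <- min(dc, width - dc)
  sqrt(dr^2 + dc^2)
}

# Near-square grid dimensions: smallest w >= h >= 1 with w*h >= n and
# w - h <= 1.
grid_dims <- function(n_terms) {
  h <- max(1L, floor(sqrt(n_terms)))
  w <- as.integer(ceiling(n_terms / h))
  if (w - h > 1L) {
    h <- h + 1L
    w <- as.integer(ceiling(n_terms / h))
  }
  if (w < h) w <- h
  c(width = w, height = h)
}

# Cells are indexed 1..w*h in row-major order; cell_rc converts.
cell_rc <- function(cell, width) {
  r <- (cell - 1L) %/% width + 1L
  c <- (cell - 1L) %% width + 1L
  cbind(row = r, col = c)
}

# Edge list of the 4-neighbourhood torus: every cell contributes its
# right and down neighbour, so there are 2*w*h adjacency slots (a pair
# that is adjacent both ways on a width- or height-2 torus contributes
# twice); degenerate self-edges on 1-wide/1-tall grids are dropped.
torus_edges <- function(width, height) {
  n <- width * height
  cells <- seq_len(n)
  r <- (cells - 1L) %/% width
  c <- (cells - 1L) %% width
  right <- r * width + ((c + 1L) %% width) + 1L
  down <- ((r + 1L) %% height) * width + c + 1L
  e <- rbind(cbind(cells, right), cbind(cells, down))
  e[e[, 1] != e[, 2], , drop = FALSE]
}

#' Global fitness of a grid assignment
#'
#' The sum, over all toroidally adjacent cell pairs (4-neighbourhood),
#' of the similarity between the terms occupying the two cells.  Cells
#' holding no term (padding) contribute 0.  Annealing maximizes this.
#'
#' @param assignment integer vector over cells (row-major), each entry a
#'   term index into `rownames(similarity)` or `NA` for padding; every
#'   term must appear exactly once.
#' @param similarity matrix from [term_similarity()].
#' @param width,height grid dimensions with `width * height ==
#'   length(assignment)`.
#' @return scalar fitness.
#' @export
layout_fitness <- function(assignment, similarity, width, height) {
  if (length(assignment) != width * height)
    stop("assignment length must equal width * height")
  placed <- assignment[!is.na(assignment)]
  if (anyDuplicated(placed) || !setequal(placed, seq_len(nrow(similarity))))
    stop("every term must be placed exactly once")
  edges <- torus_edges(width, height)
  a <- assignment[edges[, 1]]
  b <- assignment[edges[, 2]]
  ok <- !is.na(a) & !is.na(b)
  sum(similarity[cbind(a[ok], b[ok])])
}

#' Annealing schedule
#'
#' Geometric cooling for [anneal_layout()]: temperature starts at
#' `initial_temperature` and is multiplied by `cooling_factor` after each
#' stage of `steps_per_temperature` proposed swaps (default 100 per
#' term); annealing stops after `stop_stages` consecutive stages with no
#' accepted move, or at `max_stages`.
#'
#' @param initial_temperature positive starting temperature.
#' @param cooling_factor in (0, 1).
#' @param steps_per_temperature proposals per stage, or `NULL` for
#'   100 x n_terms.
#' @param stop_stages consecutive zero-acceptance stages that end the run.
#' @param max_stages hard cap on stages.
#' @return object of class `annealing_schedule`.
#' @export
annealing_schedule <- function(initial_temperature = 1.0,
                               cooling_factor = 0.95,
                               steps_per_temperature = NULL,
                               stop_stages = 3L, max_stages = 150L) {
  if (initial_temperature <= 0) stop("initial_temperature must be > 0")
  if (cooling_factor <= 0 || cooling_factor >= 1)
    stop("cooling_factor must be in (0, 1)")
  structure(list(initial_temperature = initial_temperature,
                 cooling_factor = cooling_factor,
                 steps_per_temperature = steps_per_temperature,
                 stop_stages = as.integer(stop_stages),
                 max_stages = as.integer(max_stages)),
            class = "annealing_schedule")
}

#' Arrange library terms on a toroidal grid by simulated annealing
#'
#' Places all terms on the smallest near-square toroidal grid, starting
#' from a random arrangement and repeatedly proposing random pair swaps
#' (terms and padding cells alike), accepted with the Metropolis
#' probability min(1, exp(dF / T)) where dF is the fitness change.  The
#' best-so-far assignment is returned, so the final fitness never falls
#' below the initial one.  Fully reproducible from `seed`.
#'
#' @param similarity matrix from [term_similarity()].
#' @param schedule an [annealing_schedule()].
#' @param seed integer seed.
#' @return object of class `grid_layout`: `width`, `height`,
#'   `assignment` (cell to term index, `NA` = padding), `fitness`,
#'   `seed`, `schedule`.
#' @export
anneal_layout <- function(similarity, schedule = annealing_schedule(),
                          seed = 1L) {
  if (!inherits(schedule, "annealing_schedule")) stop("invalid schedule")
  n <- nrow(similarity)
  if (is.null(n) || n < 2L) stop("need >= 2 terms to lay out")
  dims <- grid_dims(n)
  w <- dims[["width"]]; h <- dims[["height"]]
  ncells <- w * h
  steps <- schedule$steps_per_temperature %||% (100L * n)

  set.seed(split_seed(seed, "anneal"))
  assignment <- rep(NA_integer_, ncells)
  assignment[sample.int(ncells, n)] <- sample.int(n, n)

  # per-cell incident edge list for O(1) swap deltas
  edges <- torus_edges(w, h)
  incident <- vector("list", ncells)
  for (e in seq_len(nrow(edges))) {
    incident[[edges[e, 1]]] <- c(incident[[edges[e, 1]]], e)
    incident[[edges[e, 2]]] <- c(incident[[edges[e, 2]]], e)
  }
  edge_sum <- function(assign, eidx) {
    a <- assign[edges[eidx, 1]]; b <- assign[edges[eidx, 2]]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) 0 else sum(similarity[cbind(a[ok], b[ok])])
  }

  fit <- layout_fitness(assignment, similarity, w, h)
  best <- assignment; best_fit <- fit
  temp <- schedule$initial_temperature
  idle_stages <- 0L

  for (stage in seq_len(schedule$max_stages)) {
    accepted <- 0L
    pair1 <- sample.int(ncells, steps, replace = TRUE)
    pair2 <- sample.int(ncells, steps, replace = TRUE)
    us <- stats::runif(steps)
    for (s in seq_len(steps)) {
      i <- pair1[s]; j <- pair2[s]
      if (i == j) next
      eidx <- unique(c(incident[[i]], incident[[j]]))
      before <- edge_sum(assignment, eidx)
      tmp <- assignment[i]; assignment[i] <- assignment[j]; assignment[j] <- tmp
      after <- edge_sum(assignment, eidx)
      dF <- after - before
      if (dF >= 0 || us[s] < exp(dF / temp)) {
        accepted <- accepted + 1L
        fit <- fit + dF
        if (fit > best_fit) { best_fit <- fit; best <- assignment }
      } else {  # revert
        tmp <- assignment[i]; assignment[i] <- assignment[j]; assignment[j] <- tmp
      }
    }
    idle_stages <- if (accepted == 0L) idle_stages + 1L else 0L
    if (idle_stages >= schedule$stop_stages) break
    temp <- temp * schedule$cooling_factor
  }

  structure(list(width = w, height = h, terms = rownames(similarity),
                 assignment = best, fitness = best_fit,
                 seed = as.integer(seed), schedule = schedule),
            class = "grid_layout")
}

#' @export
print.grid_layout <- function(x, ...) {
  cat(sprintf("grid_layout: %d terms on %dx%d torus, fitness %.4f, seed %d\n",
              sum(!is.na(x$assignment)), x$height, x$width, x$fitness, x$seed))
  invisible(x)
}

# (row, col) of each term on the layout
layout_positions <- function(layout) {
  cells <- which(!is.na(layout$assignment))
  rc <- cell_rc(cells, layout$width)
  idx <- layout$assignment[cells]
  out <- rc[order(idx), , drop = FALSE]
  rownames(out) <- layout$terms
  out
}

#' Significance of spatial clustering of enriched terms on the grid
#'
#' Statistic: mean pairwise toroidal distance among the cells of the
#' enriched terms (smaller = more clustered).  The null distribution is
#' sampled numerically by drawing the same number of occupied cells
#' uniformly without replacement `n_null` times; z = (observed - null
#' mean)/null sd and the one-sided p (small statistics) uses add-one
#' smoothing.  Clustering is flagged significant at p < 0.1.
#'
#' @param layout a `grid_layout` from [anneal_layout()].
#' @param enriched_terms character vector (>= 2) of placed term labels.
#' @param n_null number of null draws (>= 100).
#' @param seed integer seed.
#' @return object of class `clustering_result`: `statistic`, `z`, `p`,
#'   `significant`, `n_null`, `seed`.
#' @export
cluster_significance <- function(layout, enriched_terms, n_null = 1000L,
                                 seed = 1L) {
  stopifnot(inherits(layout, "grid_layout"))
  enriched_terms <- unique(enriched_terms)
  if (length(enriched_terms) < 2L) stop("need >= 2 enriched terms")
  if (n_null < 100L) stop("n_null must be >= 100")
  missing <- setdiff(enriched_terms, layout$terms)
  if (length(missing))
    stop("enriched term(s) not placed on the grid: ",
         paste(missing, collapse = ", "))

  pos <- layout_positions(layout)
  occupied <- pos  # all placed terms
  m <- length(enriched_terms)

  mean_pair_dist <- function(rc) {
    dr <- abs(outer(rc[, 1], rc[, 1], "-"))
    dr <- pmin(dr, layout$height - dr)
    dc <- abs(outer(rc[, 2], rc[, 2], "-"))
    dc <- pmin(dc, layout$width - dc)
    d <- sqrt(dr^2 + dc^2)
    mean(d[upper.tri(d)])
  }

  observed <- mean_pair_dist(pos[enriched_terms, , drop = FALSE])
  set.seed(split_seed(seed, "clusternull"))
  null_stats <- vapply(seq_len(n_null), function(i) {
    mean_pair_dist(occupied[sample.int(nrow(occupied), m), , drop = FALSE])
  }, 0)
  mu <- mean(null_stats); sdv <- stats::sd(null_stats)
  z <- if (sdv > 0) (observed - mu) / sdv else 0
  p <- (1 + sum(null_stats <= observed)) / (n_null + 1)
  structure(list(statistic = observed, z = z, p = p,
                 significant = p < 0.1, n_null = as.integer(n_null),
                 null_mean = mu, null_sd = sdv, seed = as.integer(seed)),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf(
    "clustering_result: statistic %.4f, z %.3f, p %.4f (%s at p < 0.1)\n",
    x$statistic, x$z, x$p,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Export a grid layout as a renderable payload
#'
#' Builds the per-cell payload for the two grid views: in
#' `p_value_view` the brightness of an enriched term's cell is its
#' -log10 p scaled to [0, 1] over the enriched set (all other cells 0);
#' in `grid_view` brightness is the mean similarity of a cell's term to
#' its toroidal neighbours, and enriched terms are flagged `circled`.
#'
#' @param layout a `grid_layout`.
#' @param table an `enrichment_table` covering the layout's terms.
#' @param mode `"p_value_view"` or `"grid_view"`.
#' @param similarity similarity matrix (required for `grid_view`).
#' @param enriched_terms terms treated as enriched; default top 10 of the
#'   table's sort order.
#' @param clustering optional `clustering_result` to embed.
#' @param seed seed stamped into the metadata.
#' @return list payload (cells + clustering), serializable with
#'   [write_grid_json()].
#' @export
export_grid <- function(layout, table, mode = c("p_value_view", "grid_view"),
                        similarity = NULL, enriched_terms = NULL,
                        clustering = NULL, seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(inherits(layout, "grid_layout"),
            inherits(table, "enrichment_table"))
  enriched_terms <- enriched_terms %||%
    utils::head(table$term, 10L)
  enriched_terms <- intersect(enriched_terms, layout$terms)
  pos <- layout_positions(layout)
  p <- table$p_value[match(rownames(pos), table$term)]

  if (mode == "p_value_view") {
    bright <- numeric(nrow(pos))
    is_enr <- rownames(pos) %in% enriched_terms
    if (any(is_enr)) {
      lg <- -log10(pmax(p[is_enr], 1e-300))
      top <- max(lg)
      bright[is_enr] <- if (top > 0) lg / top else 1
    }
  } else {
    if (is.null(similarity)) stop("grid_view requires the similarity matrix")
    edges <- torus_edges(layout$width, layout$height)
    assign <- layout$assignment
    bright_cell <- numeric(length(assign))
    cnt <- numeric(length(assign))
    a <- assign[edges[, 1]]; b <- assign[edges[, 2]]
    ok <- !is.na(a) & !is.na(b)
    for (e in which(ok)) {
      s <- similarity[a[e], b[e]]
      bright_cell[edges[e, 1]] <- bright_cell[edges[e, 1]] + s
      bright_cell[edges[e, 2]] <- bright_cell[edges[e, 2]] + s
      cnt[edges[e, 1]] <- cnt[edges[e, 1]] + 1
      cnt[edges[e, 2]] <- cnt[edges[e, 2]] + 1
    }
    mean_b <- ifelse(cnt > 0, bright_cell / cnt, 0)
    term_cells <- which(!is.na(assign))
    bright <- mean_b[term_cells][order(assign[term_cells])]
  }

  cells <- data.frame(term = rownames(pos), row = pos[, 1], col = pos[, 2],
                      brightness = round(pmin(pmax(bright, 0), 1), 10),
                      enriched = rownames(pos) %in% enriched_terms,
                      stringsAsFactors = FALSE)
  rownames(cells) <- NULL
  payload <- list(
    meta = artifact_meta(seed, list(mode = mode, width = layout$width,
                                    height = layout$height)),
    mode = mode, width = layout$width, height = layout$height,
    cells = cells
  )
  if (!is.null(clustering)) {
    stopifnot(inherits(clustering, "clustering_result"))
    payload$clustering <- list(statistic = clustering$statistic,
                               z = clustering$z, p = clustering$p,
                               significant = clustering$significant,
                               n_null = clustering$n_null,
                               seed = clustering$seed)
  }
  payload
}

#' Serialize a grid payload to JSON
#' @param payload from [export_grid()].
#' @param path output path, or `NULL` for the string.
#' @return invisibly, the JSON string.
#' @export
write_grid_json <- function(payload, path = NULL) {
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (!is.null(path)) writeLines(json, path, useBytes = TRUE)
  invisible(as.character(json))
}

#' Read a grid payload back from JSON
#' @param source path or JSON string.
#' @return the payload list.
#' @export
read_grid_json <- function(source) {
  jsonlite::fromJSON(source, simplifyVector = TRUE)
}
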