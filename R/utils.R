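# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic fan-out of one user seed into per-component stream seeds.
# Each component owns a fixed offset so adding a generator never perturbs
# the streams of existing ones.  Result kept strictly below 2^31.
split_seed <- function(seed, component) {
  offsets <- c(
    library   = 101L,
    gene_list = 211L,
    planted   = 307L,
    expr      = 401L,
    ppi       = 503L,
    peaks     = 601L,
    promoter  = 701L,
    cuffdiff  = 809L,
    anneal    = 907L,
    clusternull = 1009L,
    calibrate = 1103L
  )
  off <- offsets[[component]]
  if (is.null(off)) stop("unknown seed component: ", component)
  (as.integer(seed) %% 1000003L) * 2017L %% 2147483629L + off
}

# FNV-1a 32-bit hash of a character scalar; used to stamp artifacts with a
# config hash (no external hashing dependency available).
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor touches only the low byte (b < 256)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply via 16-bit halves (stays exact in doubles)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

tool_version <- function() {
  as.character(utils::packageVersion("enrichtk"))
}

# Standard metadata block embedded in JSON artifacts.
artifact_meta <- function(seed, config = list()) {
  cfg <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  list(
    tool = "enrichtk",
    version = tool_version(),
    seed = as.integer(seed),
    config_hash = fnv1a32(as.character(cfg))
  )
}

# Logical membership matrix (terms x genes) over `genes` columns.
membership_matrix <- function(library, genes = NULL) {
  genes <- genes %||% sort(library_universe(library))
  m <- matrix(FALSE, nrow = length(library$sets), ncol = length(genes),
              dimnames = list(vapply(library$sets, `[[`, "", "term"), genes))
  for (i in seq_along(library$sets)) {
    hit <- match(library$sets[[i]]$genes, genes)
    m[i, hit[!is.na(hit)]] <- TRUE
  }
  m
}
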