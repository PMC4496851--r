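# Internal helpers shared across modules.

# Canonical unordered pair key for two id vectors.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls never perturb user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# sample() without its size-1 surprise: sample_from(5L, 1) picks from c(5).
sample_from <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

# Parse "organism|group|serial" record ids into a node table.
parse_seq_ids <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  n <- lengths(parts)
  if (any(n < 2L)) {
    stopf("cannot derive organism labels from id '%s'; supply node_info explicitly",
          ids[which(n < 2L)[1L]])
  }
  data.frame(
    id = ids,
    organism = vapply(parts, `[`, character(1), 1L),
    group = vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, character(1)),
    stringsAsFactors = FALSE
  )
}
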