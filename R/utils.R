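# Internal helpers: condition constructors, seeded evaluation, coordinate
# reshaping between flat (x1,y1,z1,...) frame rows and n x 3 matrices.

dynsel_abort <- function(message, class) {
  stop(structure(
    class = c(class, "dynsel_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_invalid <- function(message) dynsel_abort(message, "dynsel_invalid_argument")
abort_parse <- function(message) dynsel_abort(message, "dynsel_parse_error")
abort_structural <- function(message) dynsel_abort(message, "dynsel_structural_error")
abort_selection <- function(message) dynsel_abort(message, "dynsel_selection_error")
abort_mapping <- function(message) dynsel_abort(message, "dynsel_mapping_error")
abort_state <- function(message) dynsel_abort(message, "dynsel_state_error")
abort_config <- function(message) dynsel_abort(message, "dynsel_config_error")
abort_fit <- function(message) dynsel_abort(message, "dynsel_fit_error")

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream.  All generator functions route their randomness through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_invalid("`seed` must be a single integer")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible substream seed from a root seed and a stage label;
# kept strictly below 2^31 so it is always a valid R integer.
substream_seed <- function(root, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(root) * 7919 + h) %% 2147483587)
}

# Flat frame row (x1,y1,z1,x2,...) -> n x 3 matrix and back.
frame_to_mat <- function(v) matrix(v, ncol = 3L, byrow = TRUE)
mat_to_frame <- function(m) as.numeric(t(m))

coord_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

`%||%` <- function(x, y) if (is.null(x)) y else x
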