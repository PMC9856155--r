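#' Specify an interatomic distance to monitor
#'
#' @param chain1,resid1,name1 Selector of the first atom.
#' @param chain2,resid2,name2 Selector of the second atom.
#' @param label Human-readable label (e.g. `"Arg296 P-Cz"`).
#' @return A `distance_spec`.
#' @export
distance_spec <- function(chain1, resid1, name1, chain2, resid2, name2,
                          label = NULL) {
  structure(
    list(a = list(chain = chain1, resid = resid1, name = name1),
         b = list(chain = chain2, resid = resid2, name = name2),
         label = label %||% sprintf("%s%d:%s-%s%d:%s", chain1, resid1, name1,
                                    chain2, resid2, name2)),
    class = "distance_spec"
  )
}

resolve_atom <- function(traj, sel) {
  hit <- which(traj$atoms$chain == sel$chain &
               traj$atoms$resid == sel$resid &
               traj$atoms$name == sel$name)
  if (length(hit) != 1L) {
    abort_selection(sprintf(
      "selector chain=%s resid=%s name=%s matched %d atoms (need exactly 1)",
      sel$chain, sel$resid, sel$name, length(hit)
    ))
  }
  hit
}

#' Per-frame Euclidean distance between two atoms
#'
#' @param traj A [trajectory()].
#' @param spec A [distance_spec()]; each selector must resolve to exactly
#'   one atom.
#' @return Data frame (`system`, `frame`, `distance_A`) with the spec
#'   label as attribute `label`.
#' @export
distance_series <- function(traj, spec) {
  i <- resolve_atom(traj, spec$a)
  j <- resolve_atom(traj, spec$b)
  ci <- (3L * i - 2L):(3L * i)
  cj <- (3L * j - 2L):(3L * j)
  d <- sqrt(rowSums((traj$xyz[, ci, drop = FALSE] -
                     traj$xyz[, cj, drop = FALSE])^2))
  out <- data.frame(system = traj$system, frame = seq_along(d),
                    distance_A = d, stringsAsFactors = FALSE)
  attr(out, "label") <- spec$label
  out
}

#' Histogram of a distance series
#'
#' Left-closed, right-open bins of fixed width; the mean is computed on
#' the raw series (bin-independent).  When the input carries system tags,
#' a frame-weighted pooled mean over systems is reported alongside the
#' per-call mean.
#'
#' @param series Numeric vector of distances, or the data frame from
#'   [distance_series()].
#' @param bin_width Bin width (Angstrom), > 0.
#' @param range Two-element numeric `[lo, hi)`; every value must fall in
#'   it.
#' @return A `distance_histogram`: `breaks`, `counts`, `mids`, `mean`,
#'   `n`.
#' @export
distance_histogram <- function(series, bin_width = 0.25, range = c(0, 20)) {
  x <- if (is.data.frame(series)) series$distance_A else as.numeric(series)
  if (length(x) == 0L) abort_invalid("empty distance series")
  if (bin_width <= 0) abort_invalid("bin_width must be positive")
  if (any(x < range[1L]) || any(x >= range[2L])) {
    abort_invalid("distances fall outside the histogram range")
  }
  breaks <- seq(range[1L], range[2L], by = bin_width)
  if (breaks[length(breaks)] < range[2L]) breaks <- c(breaks, range[2L])
  bin <- findInterval(x, breaks, rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  structure(
    list(breaks = breaks, counts = counts,
         mids = (breaks[-1L] + breaks[-length(breaks)]) / 2,
         mean = mean(x), n = length(x)),
    class = "distance_histogram"
  )
}

#' Frame-weighted pooled distance mean over several series
#'
#' The average distance over a set of simulations, pooling all frames
#' (so longer series weigh proportionally more).
#'
#' @param series_list List of distance series (vectors or data frames).
#' @return Single pooled mean (Angstrom).
#' @export
pooled_distance_mean <- function(series_list) {
  xs <- unlist(lapply(series_list, function(s) {
    if (is.data.frame(s)) s$distance_A else as.numeric(s)
  }), use.names = FALSE)
  if (length(xs) == 0L) abort_invalid("no distances to pool")
  mean(xs)
}
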