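# Interval arithmetic on 1-based inclusive coordinates, shared by the repeat
# mask, pan-genome partition and plasmid-loss stages.

#' Length of a set of 1-based inclusive intervals
#'
#' @param start,end integer vectors of equal length; `end >= start`.
#' @return Total number of positions covered, after merging overlaps.
#' @examples
#' interval_length(1215, 1823)  # 609
#' @export
interval_length <- function(start, end) {
  if (length(start) == 0L) return(0L)
  m <- merge_intervals(data.frame(start = start, end = end))
  sum(m$end - m$start + 1L)
}

#' Merge overlapping or adjacent intervals
#'
#' @param x data.frame with columns `start`, `end` (1-based inclusive).
#' @param adjacent merge intervals that touch (`end + 1 == start`)? Default TRUE.
#' @return data.frame of disjoint intervals sorted by `start`.
#' @export
merge_intervals <- function(x, adjacent = TRUE) {
  if (nrow(x) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  stopifnot(all(x$end >= x$start))
  x <- x[order(x$start, x$end), , drop = FALSE]
  slack <- if (adjacent) 1L else 0L
  grp <- cumsum(c(1L, as.integer(x$start[-1L] > cummax(x$end)[-nrow(x)] + slack)))
  data.frame(
    start = as.integer(tapply(x$start, grp, min)),
    end   = as.integer(tapply(x$end, grp, max)),
    row.names = NULL
  )
}

#' Complement of intervals within 1..len
#'
#' @param x data.frame with `start`, `end`.
#' @param len sequence length.
#' @return data.frame of the uncovered intervals.
#' @export
complement_intervals <- function(x, len) {
  m <- merge_intervals(x)
  if (nrow(m) == 0L) {
    if (len < 1L) return(data.frame(start = integer(0), end = integer(0)))
    return(data.frame(start = 1L, end = as.integer(len)))
  }
  starts <- c(1L, m$end + 1L)
  ends <- c(m$start - 1L, as.integer(len))
  keep <- ends >= starts
  data.frame(start = starts[keep], end = ends[keep])
}

# TRUE for each position in `pos` lying inside any interval of `x`.
positions_in_intervals <- function(pos, x) {
  if (nrow(x) == 0L || length(pos) == 0L) return(rep(FALSE, length(pos)))
  m <- merge_intervals(x)
  idx <- findInterval(pos, m$start)
  idx > 0L & pos <= m$end[pmax(idx, 1L)]
}

# Deterministic child seeds below 2^31, derived from a user seed.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483647)
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG so seeded operations compose without side effects.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
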