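#' Qualify sliding windows by TSP density
#'
#' A window qualifies when it holds at least `min_tsp` predicted TSPs. With
#' `strand_rule = "either"` (default) the threshold must be met on at least
#' one strand individually; with `"combined"` TSPs of both strands are pooled.
#' Windows are placed at every `step` bp ("every sliding window" of the island
#' definition corresponds to `step = 1`).
#'
#' @param track data.frame with columns `position` (1-based bp) and `strand`
#'   (`"+"`/`"-"`); row order is irrelevant.
#' @param genome_length genome extent in bp.
#' @param window window width in bp (default 100).
#' @param min_tsp minimal TSP count per window (default 8).
#' @param strand_rule `"either"` or `"combined"`.
#' @param step window start spacing in bp (default 1).
#' @return logical vector, one entry per window start
#'   `seq(1, genome_length - window + 1, by = step)`, with the start positions
#'   in attribute `"starts"`.
#' @export
qualify_windows <- function(track, genome_length, window = 100, min_tsp = 8,
                            strand_rule = c("either", "combined"), step = 1) {
  strand_rule <- match.arg(strand_rule)
  stopifnot(window >= 1, step >= 1, min_tsp >= 1)
  if (genome_length < window) stop("genome extent smaller than one window")
  stopifnot(is.data.frame(track), all(c("position", "strand") %in% names(track)))
  if (nrow(track) && (any(track$position < 1) ||
                      any(track$position > genome_length))) {
    stop("TSP position outside the genome")
  }
  starts <- seq.int(1L, genome_length - window + 1L, by = step)
  counts_for <- function(pos) {
    # per-bp occupancy, cumulated; window [w, w+window-1]
    occ <- tabulate(pos, nbins = genome_length)
    cs <- c(0, cumsum(occ))
    cs[starts + window] - cs[starts]
  }
  ok <- if (strand_rule == "combined") {
    counts_for(track$position) >= min_tsp
  } else {
    counts_for(track$position[track$strand == "+"]) >= min_tsp |
      counts_for(track$position[track$strand == "-"]) >= min_tsp
  }
  attr(ok, "starts") <- starts
  ok
}

#' Detect promoter islands from a TSP track
#'
#' Islands are maximal runs of consecutive qualifying window starts (see
#' [qualify_windows()]); each call spans from the first qualifying window's
#' start to the last qualifying window's end, and calls shorter than
#' `min_span` bp are discarded. With the defaults (window 100, >= 8 TSPs on a
#' strand, span >= 300 bp) this is the promoter-island criterion.
#'
#' @inheritParams qualify_windows
#' @param min_span minimal island length in bp (default 300).
#' @return data.frame with columns `start`, `end` (1-based inclusive),
#'   `length`, `n_tsp_top`, `n_tsp_bottom`, sorted and non-overlapping.
#' @examples
#' trk <- data.frame(position = 1:400, strand = "+")
#' detect_islands(trk, genome_length = 1000)
#' @export
detect_islands <- function(track, genome_length, window = 100, min_tsp = 8,
                           min_span = 300, strand_rule = c("either", "combined"),
                           step = 1) {
  strand_rule <- match.arg(strand_rule)
  ok <- qualify_windows(track, genome_length, window = window,
                        min_tsp = min_tsp, strand_rule = strand_rule,
                        step = step)
  starts <- attr(ok, "starts")
  ok <- as.vector(ok)
  empty <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                      n_tsp_top = numeric(0), n_tsp_bottom = numeric(0))
  if (!any(ok)) return(empty)
  r <- rle(ok)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  keep <- r$values
  s <- starts[idx_start[keep]]
  e <- starts[idx_end[keep]] + window - 1L
  len <- e - s + 1L
  sel <- len >= min_span
  if (!any(sel)) return(empty)
  s <- s[sel]; e <- e[sel]; len <- len[sel]
  top <- vapply(seq_along(s), function(i) {
    sum(track$position >= s[i] & track$position <= e[i] & track$strand == "+")
  }, numeric(1))
  bot <- vapply(seq_along(s), function(i) {
    sum(track$position >= s[i] & track$position <= e[i] & track$strand == "-")
  }, numeric(1))
  data.frame(start = as.integer(s), end = as.integer(e),
             length = as.integer(len), n_tsp_top = top, n_tsp_bottom = bot)
}
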