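#' Parse the packaged promoter-island annotation table
#'
#' Reads the machine-readable copy of the 78-island annotation (location,
#' flanking genes, genomic-island association marks A-E and H-NS evidence)
#' shipped in `inst/extdata/promoter_islands_table1.tsv`, and derives the
#' island interval as `[five_prime_end, five_prime_end + length - 1]`
#' (1-based inclusive, leftmost-base convention).
#'
#' @param path path to a table in the packaged schema; default is the
#'   packaged fixture.
#' @return data.frame with columns `five_prime_end`, `length`, `start`,
#'   `end`, `genes`, `assoc_A` ... `assoc_E` (logical), `n_assoc` (number of
#'   A-E marks present), `hns_mark` (`"G"`, `"K"`, `"O"` or `"A"`).
#' @examples
#' pis <- parse_island_table()
#' nrow(pis)          # 78
#' sum(pis$length)    # 33397
#' @export
parse_island_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "promoter_islands_table1.tsv",
                        package = "islandscape", mustWork = TRUE)
  }
  raw <- read.delim(path, comment.char = "#", colClasses = "character")
  need <- c("five_prime_end", "length", "genes", "A", "B", "C", "D", "E", "H")
  if (!all(need %in% names(raw))) {
    stop("island table must have columns: ", paste(need, collapse = ", "))
  }
  fp <- suppressWarnings(as.integer(raw$five_prime_end))
  len <- suppressWarnings(as.integer(raw$length))
  if (anyNA(fp) || anyNA(len) || any(len < 1)) {
    stop("malformed island row: non-numeric location or length")
  }
  marks <- vapply(raw[c("A", "B", "C", "D", "E")],
                  function(col) nzchar(trimws(col)), logical(length(fp)))
  if (length(fp) == 1) marks <- matrix(marks, nrow = 1)
  hns <- trimws(raw$H)
  if (any(!hns %in% c("G", "K", "O", "A", ""))) {
    stop("malformed H-NS mark (expected G, K, O or A)")
  }
  out <- data.frame(five_prime_end = fp, length = len,
                    start = fp, end = fp + len - 1L, genes = raw$genes)
  colnames(marks) <- paste0("assoc_", c("A", "B", "C", "D", "E"))
  out <- cbind(out, as.data.frame(marks))
  out$n_assoc <- rowSums(marks)
  out$hns_mark <- ifelse(nzchar(hns), hns, NA_character_)
  out
}

#' AT content of a sequence, in percent
#'
#' @param seq non-empty DNA sequence (character string).
#' @return `100 * (count A + count T) / length`.
#' @export
at_content <- function(seq) {
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop("empty sequence")
  assert_acgt(seq, "sequence")
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  100 * sum(b %in% c("A", "T")) / length(b)
}

#' Promoter search window for occupancy analysis
#'
#' Builds the genomic interval searched for protein-binding evidence:
#' islands use their own boundaries; single promoters (and promoters of alien
#' genes) use +/-150 bp around the TSP; regions with multiple promoters span
#' from 150 bp upstream of the first TSP to 150 bp downstream of the last.
#'
#' @param set_kind one of `"island"`, `"single"`, `"alien"`, `"multiple"`.
#' @param anchors for `"island"`: numeric length-2 `c(start, end)`; otherwise
#'   a vector of one or more TSP positions.
#' @param flank half-width of the search area in bp (default 150).
#' @return data.frame with `start`, `end` (clipped at 1).
#' @export
promoter_search_window <- function(set_kind = c("island", "single", "alien",
                                                "multiple"),
                                   anchors, flank = 150) {
  set_kind <- match.arg(set_kind)
  if (!length(anchors)) stop("no anchors supplied")
  if (set_kind == "island") {
    if (length(anchors) != 2 || anchors[1] > anchors[2]) {
      stop("island anchors must be c(start, end)")
    }
    return(data.frame(start = anchors[1], end = anchors[2]))
  }
  if (set_kind %in% c("single", "alien") && length(anchors) != 1) {
    stop("single/alien windows take exactly one TSP")
  }
  data.frame(start = max(1, min(anchors) - flank),
             end = max(anchors) + flank)
}

#' Decide whether a region is bound according to chip-on-chip evidence
#'
#' Two evidence modes mirror the published data formats:
#' * probe-ratio tracks: the region is bound iff it contains at least one
#'   probe with hybridization-signal ratio >= `ratio_threshold`;
#' * interval lists (one or more experimental series): the region is bound
#'   iff it overlaps a published site by at least `min_overlap` bp in at
#'   least one series.
#'
#' @param region data.frame row (or list) with `start`, `end`.
#' @param evidence either `list(mode = "probe", positions =, ratios =)` or
#'   `list(mode = "intervals", series = list(<data.frame start/end>, ...))`.
#' @param ratio_threshold probe-ratio cutoff (default 1.5).
#' @param min_overlap minimal overlap in bp for interval evidence (default 20).
#' @return logical scalar.
#' @export
is_bound <- function(region, evidence, ratio_threshold = 1.5,
                     min_overlap = 20) {
  stopifnot(!is.null(region$start), !is.null(region$end),
            region$start <= region$end)
  if (identical(evidence$mode, "probe")) {
    stopifnot(length(evidence$positions) == length(evidence$ratios))
    inside <- evidence$positions >= region$start &
      evidence$positions <= region$end
    return(any(evidence$ratios[inside] >= ratio_threshold))
  }
  if (identical(evidence$mode, "intervals")) {
    for (ser in evidence$series) {
      if (!nrow(ser)) next
      ov <- pmin(ser$end, region$end) - pmax(ser$start, region$start) + 1
      if (any(ov >= min_overlap)) return(TRUE)
    }
    return(FALSE)
  }
  stop("evidence$mode must be 'probe' or 'intervals'")
}

#' Relative occupancy of region sets, normalized to a reference set
#'
#' For each named region set, the percentage of regions bound under the given
#' evidence (see [is_bound()]) is expressed as fold ratio to the percentage
#' bound in the reference set (conventionally the multiple-promoter set).
#'
#' @param sets named list of region data.frames (`start`, `end`).
#' @param evidence a [is_bound()] evidence object, applied to all sets.
#' @param reference name of the reference set (default `"multiple"`).
#' @param ... passed to [is_bound()] (`ratio_threshold`, `min_overlap`).
#' @return list with `percent_bound` (named vector) and `fold_ratio`
#'   (named vector, reference = 1).
#' @export
relative_occupancy <- function(sets, evidence, reference = "multiple", ...) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (!reference %in% names(sets)) {
    stop("reference set '", reference, "' not present")
  }
  pct <- vapply(sets, function(regions) {
    assert_regions(regions)
    if (!nrow(regions)) return(NA_real_)
    bound <- vapply(seq_len(nrow(regions)), function(i) {
      is_bound(regions[i, ], evidence, ...)
    }, logical(1))
    100 * mean(bound)
  }, numeric(1))
  if (is.na(pct[reference]) || pct[reference] == 0) {
    stop("reference set has zero bound percentage; fold ratio undefined")
  }
  list(percent_bound = pct, fold_ratio = pct / pct[reference])
}

#' Monte-Carlo null model for region/feature overlap
#'
#' Estimates how much overlap (in bp) between a region set and a feature set
#' is expected by chance: each feature is independently shifted by a uniform
#' random offset around a circular genome (lengths preserved) and the
#' intersection with the regions is recomputed. Reports the observed overlap,
#' the null mean, and their ratio (fold enrichment).
#'
#' @param regions,features data.frames with `start`, `end` (1-based).
#' @param genome_length circular genome length in bp.
#' @param n_trials number of Monte-Carlo placements (>= 1).
#' @param seed integer seed.
#' @return list `observed_bp`, `expected_bp`, `fold_enrichment`,
#'   `null_overlaps` (numeric vector of length `n_trials`).
#' @export
overlap_null_model <- function(regions, features, genome_length,
                               n_trials = 1000, seed = NULL) {
  assert_regions(regions); assert_regions(features)
  stopifnot(n_trials >= 1, genome_length >= 1)
  if (nrow(features) &&
      any(features$end - features$start + 1 > genome_length)) {
    stop("feature longer than the genome")
  }
  reg <- IRanges::reduce(regions_to_iranges(regions))
  inter_bp <- function(f_start, f_len) {
    # wrap features around the circular genome, then intersect
    s <- ((f_start - 1L) %% genome_length) + 1L
    e <- s + f_len - 1L
    over <- e > genome_length
    ir <- IRanges::IRanges(start = c(s, rep(1L, sum(over))),
                           end = c(pmin(e, genome_length),
                                   e[over] - genome_length))
    sum(BiocGenerics::width(IRanges::intersect(reg, IRanges::reduce(ir))))
  }
  f_len <- if (nrow(features)) features$end - features$start + 1L else integer(0)
  observed <- if (nrow(features)) inter_bp(features$start, f_len) else 0
  with_seed(seed, {
    null <- vapply(seq_len(n_trials), function(i) {
      if (!length(f_len)) return(0)
      inter_bp(sample.int(genome_length, length(f_len), replace = TRUE), f_len)
    }, numeric(1))
    expected <- mean(null)
    list(observed_bp = observed,
         expected_bp = expected,
         fold_enrichment = if (expected > 0) observed / expected else NA_real_,
         null_overlaps = null)
  })
}
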