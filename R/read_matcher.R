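#' Build an exact-match genome index
#'
#' Holds the forward sequence and its reverse complement as
#' [Biostrings::DNAString] objects for exact substring queries on both
#' strands. Positions are always reported 1-based on the forward strand.
#'
#' @param genome single genome sequence: a character string, a
#'   [Biostrings::DNAString], or a path to a FASTA file with one record.
#' @return object of class `genome_index` with fields `fwd`, `rcp`, `length`.
#' @export
index_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome) &&
      grepl("\\.(fa|fasta|fna)$", genome, ignore.case = TRUE)) {
    genome <- read_genome_fasta(genome)
  }
  genome <- toupper(as.character(genome))
  assert_acgt(genome, "genome")
  fwd <- Biostrings::DNAString(genome)
  structure(list(fwd = fwd,
                 rcp = Biostrings::reverseComplement(fwd),
                 length = length(fwd)),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index:", x$length, "bp, both strands\n")
  invisible(x)
}

#' Query all genomic sites of an oligonucleotide
#'
#' Returns every exact occurrence of `pattern` on either strand. The reported
#' position is the forward-strand coordinate of the pattern's 5' base, i.e.
#' the leftmost matched base for `"+"` hits and the rightmost for `"-"` hits
#' (these reads are 5'-end tags, so the 5' base is the TSP proxy).
#'
#' @param index a [index_genome()] object.
#' @param pattern character string (A/C/G/T).
#' @return data.frame with columns `pos`, `strand`.
#' @export
query_sites <- function(index, pattern) {
  stopifnot(inherits(index, "genome_index"))
  assert_acgt(pattern, "query")
  k <- nchar(pattern)
  p <- Biostrings::DNAString(pattern)
  f <- BiocGenerics::start(Biostrings::matchPattern(p, index$fwd))
  r <- BiocGenerics::start(Biostrings::matchPattern(p, index$rcp))
  data.frame(pos = c(f, index$length - r + 1L),
             strand = rep(c("+", "-"), c(length(f), length(r))))
}

#' Stepwise maximal 5'-prefix matching of 44-nt reads
#'
#' Implements the stepwise maximal-prefix search: reads fully
#' identical to the genome (44 bases) are collected first; the remainder is
#' searched for a perfect 43-base 5' prefix, and so on down to `min_len`.
#' A read assigned at step k gets all genomic sites of its k-prefix, each
#' weighted 1/(number of sites). The base following the matched prefix is then
#' either a mismatch (a truncated transcript) or the start of the 3' adapter,
#' in which case the read is an adapter-confirmed short oligo.
#'
#' Adapter confirmation compares `min(nchar(adapter), 44 - k)` bases; reads
#' with fewer than `min_adapter_bases` comparable bases are never confirmed
#' (guards against spurious 1-3 base "confirmations" near k = 44).
#'
#' @param reads character vector of reads, all exactly 44 nt (names, if
#'   present, are used as read ids).
#' @param index a [index_genome()] object.
#' @param adapter 3'-adapter sequence (default `"GATCGTGACTG"`).
#' @param min_len smallest prefix length searched (default 9).
#' @param min_adapter_bases minimal comparable adapter bases for confirmation.
#' @return object of class `match_set`: a list with
#'   * `reads`: data.frame `read_id`, `prefix_len` (NA when unassigned),
#'     `n_sites`, `klass` (`full-match`/`short-oligo`/`truncated`/
#'     `unassigned`), `adapter_confirmed`;
#'   * `sites`: data.frame `read_id`, `prefix_len`, `pos`, `strand`, `weight`
#'     (one row per matching site, weights summing to 1 per assigned read).
#' @export
match_stepwise <- function(reads, index, adapter = "GATCGTGACTG", min_len = 9,
                           min_adapter_bases = 4) {
  stopifnot(inherits(index, "genome_index"), min_len >= 1)
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  assert_acgt(adapter, "adapter")
  n <- length(reads)
  if (n == 0) {
    return(structure(list(
      reads = data.frame(read_id = character(0), prefix_len = integer(0),
                         n_sites = integer(0), klass = character(0),
                         adapter_confirmed = logical(0)),
      sites = data.frame(read_id = character(0), prefix_len = integer(0),
                         pos = integer(0), strand = character(0),
                         weight = numeric(0))), class = "match_set"))
  }
  reads <- toupper(reads)
  if (any(nchar(reads) != 44)) stop("all reads must be exactly 44 nt long")
  assert_acgt(reads, "reads")
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%04d", seq_len(n))

  prefix_len <- rep(NA_integer_, n)
  n_sites <- rep(0L, n)
  site_rows <- vector("list", n)
  unassigned <- rep(TRUE, n)
  G <- index$length

  for (k in seq(44L, as.integer(min_len))) {
    if (!any(unassigned)) break
    idx_un <- which(unassigned)
    pref <- substr(reads[idx_un], 1L, k)
    upref <- unique(pref)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(upref))
    mf <- Biostrings::matchPDict(pd, index$fwd)
    mr <- Biostrings::matchPDict(pd, index$rcp)
    sf <- BiocGenerics::start(mf)
    sr <- BiocGenerics::start(mr)
    for (j in seq_along(upref)) {
      fpos <- sf[[j]]
      rpos <- sr[[j]]
      tot <- length(fpos) + length(rpos)
      if (tot == 0) next
      hit <- idx_un[pref == upref[j]]
      prefix_len[hit] <- k
      n_sites[hit] <- tot
      unassigned[hit] <- FALSE
      sites <- data.frame(
        pos = c(as.integer(fpos), G - as.integer(rpos) + 1L),
        strand = rep(c("+", "-"), c(length(fpos), length(rpos))),
        weight = 1 / tot)
      for (h in hit) {
        site_rows[[h]] <- cbind(read_id = ids[h], prefix_len = k, sites)
      }
    }
  }

  adapter_confirmed <- rep(FALSE, n)
  assigned <- !is.na(prefix_len)
  for (i in which(assigned)) {
    k <- prefix_len[i]
    ncmp <- min(nchar(adapter), 44L - k)
    if (ncmp >= min_adapter_bases &&
        substr(reads[i], k + 1L, k + ncmp) == substr(adapter, 1L, ncmp)) {
      adapter_confirmed[i] <- TRUE
    }
  }
  klass <- ifelse(!assigned, "unassigned",
           ifelse(prefix_len == 44L, "full-match",
           ifelse(adapter_confirmed, "short-oligo", "truncated")))

  sites <- if (any(assigned)) {
    do.call(rbind, site_rows[assigned])
  } else {
    data.frame(read_id = character(0), prefix_len = integer(0),
               pos = integer(0), strand = character(0), weight = numeric(0))
  }
  rownames(sites) <- NULL
  structure(list(
    reads = data.frame(read_id = ids, prefix_len = prefix_len,
                       n_sites = n_sites, klass = klass,
                       adapter_confirmed = adapter_confirmed),
    sites = sites), class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat("match_set:", nrow(x$reads), "reads;",
      sum(x$reads$klass == "full-match"), "full-match,",
      sum(x$reads$klass == "short-oligo"), "short-oligo,",
      sum(x$reads$klass == "truncated"), "truncated,",
      sum(x$reads$klass == "unassigned"), "unassigned\n")
  invisible(x)
}

#' Attribute matched reads to genomic regions
#'
#' Each matching site contributes its fractional weight (1/number of sites) to
#' every region containing the site's 5'-base position; regions are extended
#' by `flank` bp on both sides first. With `unique_only = TRUE`, reads with
#' more than one matching site are dropped (the uniquely matching subset).
#'
#' @param matches a [match_stepwise()] result.
#' @param regions data.frame with columns `start`, `end` (1-based inclusive)
#'   and optionally `name`.
#' @param flank symmetric region extension in bp.
#' @param unique_only drop multi-site reads.
#' @return data.frame `region`, `prefix_len`, `weight` (weighted count),
#'   one row per region x occupied prefix length.
#' @export
attribute_to_regions <- function(matches, regions, flank = 0,
                                 unique_only = FALSE) {
  stopifnot(inherits(matches, "match_set"))
  assert_regions(regions)
  nm <- if (!is.null(regions$name)) as.character(regions$name)
        else sprintf("region_%04d", seq_len(nrow(regions)))
  sites <- matches$sites
  if (unique_only && nrow(sites)) {
    multi <- matches$reads$read_id[matches$reads$n_sites > 1]
    sites <- sites[!(sites$read_id %in% multi), , drop = FALSE]
  }
  if (!nrow(sites) || !nrow(regions)) {
    return(data.frame(region = character(0), prefix_len = integer(0),
                      weight = numeric(0)))
  }
  ir <- regions_to_iranges(regions, flank)
  pts <- IRanges::IRanges(start = sites$pos, width = 1L)
  ov <- IRanges::findOverlaps(pts, ir)
  if (!length(ov)) {
    return(data.frame(region = character(0), prefix_len = integer(0),
                      weight = numeric(0)))
  }
  df <- data.frame(region = nm[S4Vectors::subjectHits(ov)],
                   prefix_len = sites$prefix_len[S4Vectors::queryHits(ov)],
                   weight = sites$weight[S4Vectors::queryHits(ov)])
  agg <- stats::aggregate(weight ~ region + prefix_len, data = df, FUN = sum)
  agg[order(agg$region, agg$prefix_len), , drop = FALSE]
}

#' Length-resolved normalized read-density profiles
#'
#' For every prefix length k from 9 to 44, the weighted read count falling in
#' a region set is normalized per the total weight assigned at that step and
#' per the set's share of the genome, so uniformly placed reads give 1.0 at
#' every step. Mirroring the original 36-step analysis, steps with k >=
#' `adapter_only_below` use all assigned reads while shorter steps use only
#' adapter-confirmed reads (short oligos).
#'
#' @param matches a [match_stepwise()] result.
#' @param region_sets named list of region data.frames (`start`, `end`).
#' @param genome_length forward-strand genome length in bp.
#' @param adapter_only_below steps below this prefix length use only
#'   adapter-confirmed reads (default 28, i.e. steps 18-36).
#' @param flank symmetric region extension in bp applied to every set.
#' @param unique_only drop multi-site reads first.
#' @param min_len smallest profiled prefix length (default 9).
#' @return numeric matrix, rows = prefix lengths `min_len:44` (rownames), one
#'   column per region set; 0 where a step has no eligible reads.
#' @export
profile_by_length <- function(matches, region_sets, genome_length,
                              adapter_only_below = 28, flank = 0,
                              unique_only = FALSE, min_len = 9) {
  stopifnot(inherits(matches, "match_set"), genome_length >= 1)
  if (!length(region_sets)) stop("region_sets must be non-empty")
  if (is.null(names(region_sets)) || any(!nzchar(names(region_sets)))) {
    stop("region_sets must be a named list")
  }
  set_len <- vapply(region_sets, function(r) {
    assert_regions(r)
    sum(BiocGenerics::width(IRanges::reduce(regions_to_iranges(r, flank))))
  }, numeric(1))
  if (any(set_len <= 0)) stop("region set with zero total length")

  sites <- matches$sites
  if (unique_only && nrow(sites)) {
    multi <- matches$reads$read_id[matches$reads$n_sites > 1]
    sites <- sites[!(sites$read_id %in% multi), , drop = FALSE]
  }
  conf <- matches$reads$read_id[matches$reads$adapter_confirmed]
  ks <- seq(as.integer(min_len), 44L)
  out <- matrix(0, nrow = length(ks), ncol = length(region_sets),
                dimnames = list(ks, names(region_sets)))
  for (ki in seq_along(ks)) {
    k <- ks[ki]
    sel <- sites$prefix_len == k
    if (k < adapter_only_below) sel <- sel & (sites$read_id %in% conf)
    st <- sites[sel, , drop = FALSE]
    tot <- sum(st$weight)
    if (tot <= 0) next
    pts <- IRanges::IRanges(start = st$pos, width = 1L)
    for (si in seq_along(region_sets)) {
      ir <- regions_to_iranges(region_sets[[si]], flank)
      ov <- IRanges::findOverlaps(pts, ir)
      w_in <- sum(st$weight[unique(S4Vectors::queryHits(ov))])
      out[ki, si] <- (w_in / tot) / (set_len[si] / genome_length)
    }
  }
  out
}
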