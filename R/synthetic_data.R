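#' Generate a random genome sequence
#'
#' Draws an i.i.d. base sequence with a prescribed expected GC fraction.
#' Identical arguments (including `seed`) always give the identical sequence.
#'
#' @param length genome length in bp (>= 1).
#' @param gc expected GC fraction in \[0, 1\].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return single character string over A/C/G/T of exactly `length` bases.
#' @examples
#' gen_genome(50, gc = 0.5, seed = 1)
#' @export
gen_genome <- function(length, gc = 0.5, seed = NULL) {
  if (!is.numeric(length) || length < 1) stop("length must be >= 1")
  if (!is.numeric(gc) || gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  with_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(BASES, as.integer(length), replace = TRUE, prob = p),
          collapse = "")
  })
}

#' Generate a TSP track with planted promoter islands
#'
#' Background TSPs follow a homogeneous Poisson process on each strand;
#' inside every planted island TSPs are placed at a regular spacing
#' `floor(100 / tsp_per_100bp)` so each sliding 100-bp window inside the
#' island is guaranteed to hold at least `tsp_per_100bp` TSPs on the planted
#' strand(s) by construction.
#'
#' @param genome_length genome extent in bp.
#' @param islands `NULL`, or a data.frame with columns `start` (1-based),
#'   `span` (bp), `tsp_per_100bp` (integer) and `strand_mode`
#'   (`"one-strand"` or `"both-strands"`). Islands must be disjoint and lie
#'   inside the genome.
#' @param background_rate expected background TSPs per kb per strand.
#' @param seed integer seed.
#' @return list with elements `track` (data.frame `position`, `strand`
#'   (`"+"`/`"-"`), `score`) sorted by position, and `islands` (the ground
#'   truth, with the planted strand in `strand`).
#' @export
gen_tsp_track <- function(genome_length, islands = NULL, background_rate = 0.5,
                          seed = NULL) {
  stopifnot(genome_length >= 1, background_rate >= 0)
  if (!is.null(islands) && nrow(islands)) {
    islands <- as.data.frame(islands)
    stopifnot(all(c("start", "span", "tsp_per_100bp") %in% names(islands)))
    if (is.null(islands$strand_mode)) islands$strand_mode <- "one-strand"
    ends <- islands$start + islands$span - 1
    if (any(islands$start < 1) || any(ends > genome_length)) {
      stop("planted island extends past the genome end")
    }
    o <- order(islands$start)
    if (nrow(islands) > 1 &&
        any(islands$start[o][-1] <= ends[o][-nrow(islands)])) {
      stop("planted islands overlap")
    }
  }
  with_seed(seed, {
    pos <- integer(0); str <- character(0)
    for (s in c("+", "-")) {
      n <- rpois(1, background_rate * genome_length / 1000)
      if (n > 0) {
        pos <- c(pos, sample.int(genome_length, n, replace = TRUE))
        str <- c(str, rep(s, n))
      }
    }
    truth_strand <- character(0)
    if (!is.null(islands) && nrow(islands)) {
      for (i in seq_len(nrow(islands))) {
        d <- as.integer(islands$tsp_per_100bp[i])
        if (d < 1) stop("tsp_per_100bp must be >= 1")
        spacing <- max(1L, min(100L %/% d, islands$span[i]))
        p <- seq(islands$start[i], islands$start[i] + islands$span[i] - 1L,
                 by = spacing)
        strands <- if (identical(islands$strand_mode[i], "both-strands")) {
          c("+", "-")
        } else sample(c("+", "-"), 1)
        truth_strand[i] <- paste(strands, collapse = "/")
        for (s in strands) {
          pos <- c(pos, p)
          str <- c(str, rep(s, length(p)))
        }
      }
    }
    track <- data.frame(position = as.integer(pos), strand = str,
                        score = round(rnorm(length(pos), mean = 5), 3))
    track <- track[order(track$position, track$strand), , drop = FALSE]
    rownames(track) <- NULL
    truth <- if (is.null(islands) || !nrow(islands)) {
      data.frame(start = integer(0), end = integer(0), strand = character(0))
    } else {
      data.frame(start = as.integer(islands$start),
                 end = as.integer(islands$start + islands$span - 1),
                 strand = truth_strand)
    }
    list(track = track, islands = truth)
  })
}

#' Generate a synthetic 44-nt 5'-end read set with ground truth
#'
#' Emulates a 5'-end-specific RNA-seq library of fixed 44-nt reads drawn from
#' both genome strands:
#' * `full`: verbatim genomic 44-mers (productive transcripts);
#' * `short`: a genomic k-prefix followed by the 3'-adapter and random fill
#'   (abortive short oligos); the (k+1)-prefix (genomic prefix plus the first
#'   adapter base) is rejection-sampled to be absent from both strands so the
#'   true maximal prefix length is exactly k;
#' * `mismatch`: a genomic k-prefix followed by a base chosen so the
#'   (k+1)-prefix is absent from both strands (truncated/erroneous reads);
#'   fill is regenerated if it would spuriously adapter-confirm;
#' * `multimap`: copies of one 44-mer planted at `multimap_sites` genomic
#'   locations. Planting edits the genome, so the possibly modified sequence
#'   is returned.
#'
#' @param genome genome sequence (single character string, A/C/G/T).
#' @param n_full,n_short,n_mismatch,n_multimap read counts per class.
#' @param k_range integer range of true genomic prefix lengths for the short
#'   and mismatch classes (drawn uniformly).
#' @param multimap_sites number of genomic copies of the multimap 44-mer.
#' @param adapter 3'-adapter sequence.
#' @param seed integer seed.
#' @return list with `reads` (named character vector of 44-nt reads),
#'   `truth` (data.frame `read_id`, `class`, `true_k`, `strand`, `origin_pos`
#'   (forward-strand coordinate of the 5' base), `n_sites`) and `genome`
#'   (the genome actually matching the truth; differs from the input only
#'   when multimap reads were planted).
#' @export
gen_read_set <- function(genome, n_full = 0, n_short = 0, n_mismatch = 0,
                         n_multimap = 0, k_range = c(9, 27),
                         multimap_sites = 3, adapter = "GATCGTGACTG",
                         seed = NULL) {
  assert_acgt(genome, "genome")
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  G <- nchar(genome)
  if (G < 44) stop("genome too short for 44-nt reads")
  with_seed(seed, {
    reads <- character(0)
    truth <- list()
    add <- function(read, class, k, strand, pos, n_sites) {
      id <- sprintf("read_%04d", length(reads) + 1L)
      reads[[id]] <<- read
      truth[[id]] <<- data.frame(read_id = id, class = class, true_k = k,
                                 strand = strand, origin_pos = pos,
                                 n_sites = n_sites)
    }
    count_sites <- function(pat) {
      nrow(find_prefix_sites(pat, genome))
    }
    rand_fill <- function(n) {
      if (n <= 0) "" else paste(sample(BASES, n, replace = TRUE), collapse = "")
    }
    draw_prefix <- function(k) {
      # genomic k-prefix from a random strand; returns prefix + origin info
      strand <- sample(c("+", "-"), 1)
      p <- sample.int(G - k + 1L, 1)
      sub <- substr(genome, p, p + k - 1L)
      if (strand == "+") {
        list(prefix = sub, strand = "+", pos = p)
      } else {
        list(prefix = revcomp(sub), strand = "-", pos = p + k - 1L)
      }
    }

    # multimap class: plant one 44-mer at m sites, then reads copy it
    if (n_multimap > 0) {
      m <- as.integer(multimap_sites)
      if (m < 1) stop("multimap_sites must be >= 1")
      if (G < 44 * (m + 1)) stop("genome too short for requested multimap sites")
      planted <- FALSE
      for (attempt in 1:100) {
        mer <- rand_fill(44)
        starts <- sort(sample.int(G - 43L, m))
        if (m > 1 && any(diff(starts) < 44)) next
        g2 <- genome
        for (s in starts) substr(g2, s, s + 43L) <- mer
        hits <- find_prefix_sites(mer, g2)
        if (nrow(hits) == m) {
          genome <- g2
          planted <- TRUE
          break
        }
      }
      if (!planted) stop("failed to plant a unique multimap 44-mer")
      for (i in seq_len(n_multimap)) {
        add(mer, "multimap", 44L, "+", starts[1], m)
      }
    }

    for (i in seq_len(n_full)) {
      strand <- sample(c("+", "-"), 1)
      p <- sample.int(G - 43L, 1)
      sub <- substr(genome, p, p + 43L)
      read <- if (strand == "+") sub else revcomp(sub)
      pos <- if (strand == "+") p else p + 43L
      add(read, "full", 44L, strand, pos, count_sites(read))
    }

    sample_k <- function() sample(seq(k_range[1], k_range[2]), 1)

    for (i in seq_len(n_short)) {
      repeat {
        k <- sample_k()
        pr <- draw_prefix(k)
        # true prefix length is k iff prefix+first adapter base never occurs
        if (count_sites(paste0(pr$prefix, substr(adapter, 1, 1))) == 0) break
      }
      body <- paste0(pr$prefix, adapter)
      read <- substr(paste0(body, rand_fill(44 - nchar(body))), 1, 44)
      add(read, "short", k, pr$strand, pr$pos, count_sites(pr$prefix))
    }

    for (i in seq_len(n_mismatch)) {
      repeat {
        k <- sample_k()
        pr <- draw_prefix(k)
        cand <- BASES[vapply(BASES, function(b) {
          count_sites(paste0(pr$prefix, b)) == 0
        }, logical(1))]
        if (length(cand)) break
      }
      b <- if (length(cand) == 1) cand else sample(cand, 1)
      repeat {
        read <- substr(paste0(pr$prefix, b, rand_fill(43 - k)), 1, 44)
        # must not look adapter-confirmed, or the class label would be wrong
        ncmp <- min(nchar(adapter), 44 - k)
        if (ncmp >= 4 &&
            substr(read, k + 1, k + ncmp) == substr(adapter, 1, ncmp)) next
        break
      }
      add(read, "mismatch", k, pr$strand, pr$pos, count_sites(pr$prefix))
    }

    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(read_id = character(0), class = character(0),
                 true_k = integer(0), strand = character(0),
                 origin_pos = integer(0), n_sites = integer(0))
    rownames(truth) <- NULL
    list(reads = reads, truth = truth, genome = genome)
  })
}

# all occurrences of `pat` as a 5'-end site table (pos of the 5' base, strand),
# scanning both strands of `genome`; overlapping occurrences count (lookahead),
# matching the behaviour of the exact-substring index
find_prefix_sites <- function(pat, genome) {
  G <- nchar(genome)
  la <- paste0("(?=", pat, ")")
  f <- gregexpr(la, genome, perl = TRUE)[[1]]
  fwd <- if (f[1] == -1) integer(0) else as.integer(f)
  r <- gregexpr(la, revcomp(genome), perl = TRUE)[[1]]
  rev <- if (r[1] == -1) integer(0) else G - as.integer(r) + 1L
  data.frame(pos = c(fwd, rev),
             strand = rep(c("+", "-"), c(length(fwd), length(rev))))
}

#' Generate random binding intervals
#'
#' Emulates a chip-on-chip binding-site list: `n` intervals with independent
#' uniform start positions, sorted by start. Intervals may overlap each other.
#'
#' @param genome_length genome extent in bp.
#' @param n number of intervals.
#' @param len interval length in bp; either a single value or a length-2
#'   range sampled uniformly per interval.
#' @param seed integer seed.
#' @return data.frame with `start`, `end` (1-based inclusive), `name`.
#' @export
gen_binding_intervals <- function(genome_length, n, len = 500, seed = NULL) {
  stopifnot(n >= 0, all(len >= 1), all(len <= genome_length))
  with_seed(seed, {
    if (n == 0) {
      return(data.frame(start = integer(0), end = integer(0),
                        name = character(0)))
    }
    L <- if (length(len) == 2) sample(seq(len[1], len[2]), n, replace = TRUE)
         else rep(as.integer(len), n)
    start <- vapply(L, function(l) sample.int(genome_length - l + 1L, 1),
                    integer(1))
    out <- data.frame(start = start, end = start + L - 1L,
                      name = sprintf("site_%04d", seq_len(n)))
    out <- out[order(out$start, out$end), , drop = FALSE]
    out$name <- sprintf("site_%04d", seq_len(n))
    rownames(out) <- NULL
    out
  })
}
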