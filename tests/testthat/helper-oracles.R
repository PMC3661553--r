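# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately naive: these implementations must not share
# code paths with the package functions they check.

# uniform step table: ideal straight B-helix (twist 36, no wedge)
uniform_table <- function(twist = 36, wedge = 0, direction = 0, rise = 3.4,
                          stacking = -5) {
  data.frame(
    dinucleotide = as.vector(outer(c("A", "C", "G", "T"),
                                   c("A", "C", "G", "T"), paste0)),
    twist = twist, wedge = wedge, direction = direction,
    rise = rise, stacking = stacking)
}

# naive per-window TSP recount (exhaustive oracle for qualify_windows)
oracle_qualify <- function(track, genome_length, window = 100, min_tsp = 8,
                           strand_rule = "either") {
  starts <- seq_len(genome_length - window + 1)
  vapply(starts, function(w) {
    lo <- w; hi <- w + window - 1
    inw <- track$position >= lo & track$position <= hi
    if (strand_rule == "combined") {
      sum(inw) >= min_tsp
    } else {
      sum(inw & track$strand == "+") >= min_tsp ||
        sum(inw & track$strand == "-") >= min_tsp
    }
  }, logical(1))
}

# naive maximal 5'-prefix search over both strands (oracle for match_stepwise)
oracle_max_prefix <- function(read, genome, min_len = 9) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(genome)))
  for (k in seq(nchar(read), min_len)) {
    p <- substr(read, 1, k)
    if (grepl(p, genome, fixed = TRUE) || grepl(p, rc, fixed = TRUE)) return(k)
  }
  NA_integer_
}

# naive double-strand substring scan (oracle for query_sites); reports the
# forward-strand coordinate of the pattern's 5' base; position-by-position
# comparison, so overlapping occurrences count
oracle_sites <- function(pattern, genome) {
  G <- nchar(genome)
  k <- nchar(pattern)
  hits <- function(subject) {
    which(vapply(seq_len(nchar(subject) - k + 1), function(i) {
      substr(subject, i, i + k - 1) == pattern
    }, logical(1)))
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(genome)))
  f <- hits(genome)
  r <- G - hits(rc) + 1L
  out <- data.frame(pos = c(f, r),
                    strand = rep(c("+", "-"), c(length(f), length(r))))
  out[order(out$pos, out$strand), , drop = FALSE]
}

# quaternion-based frame propagation (oracle for build_frames); same
# documented convention, fully independent arithmetic
oracle_frames <- function(seq, table, translation = "endstep") {
  qmul <- function(a, b) {
    c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
      a[1] * b[2:4] + b[1] * a[2:4] +
        c(a[3] * b[4] - a[4] * b[3],
          a[4] * b[2] - a[2] * b[4],
          a[2] * b[3] - a[3] * b[2]))
  }
  qrot <- function(axis, deg) {
    a <- deg * pi / 180
    axis <- axis / sqrt(sum(axis^2))
    c(cos(a / 2), sin(a / 2) * axis)
  }
  qapply <- function(q, v) {
    p <- qmul(qmul(q, c(0, v)), c(q[1], -q[2:4]))
    p[2:4]
  }
  b <- strsplit(toupper(seq), "")[[1]]
  L <- length(b)
  rownames(table) <- table$dinucleotide
  q <- c(1, 0, 0, 0)
  O <- matrix(0, L, 3)
  z_prev <- c(0, 0, 1)
  for (i in seq_len(L - 1)) {
    st <- table[paste0(b[i], b[i + 1]), ]
    half <- qrot(c(0, 0, 1), st$twist / 2)
    wax <- c(cos(st$direction * pi / 180), sin(st$direction * pi / 180), 0)
    qstep <- qmul(qmul(half, qrot(wax, st$wedge)), half)
    q <- qmul(q, qstep)
    z_new <- qapply(q, c(0, 0, 1))
    zdir <- if (translation == "endstep") z_new else {
      zm <- z_prev + z_new
      zm / sqrt(sum(zm^2))
    }
    O[i + 1, ] <- O[i, ] + st$rise * zdir
    z_prev <- z_new
  }
  O
}

# naive point-in-interval weighted count (oracle for attribute_to_regions)
oracle_attribute <- function(sites, regions, flank = 0) {
  vapply(seq_len(nrow(regions)), function(i) {
    lo <- regions$start[i] - flank
    hi <- regions$end[i] + flank
    sum(sites$weight[sites$pos >= lo & sites$pos <= hi])
  }, numeric(1))
}

# naive per-value binning loop (oracle for metric_histogram)
oracle_bin <- function(values, width, anchor) {
  counts <- integer(0)
  for (v in values) {
    j <- floor((v - anchor) / width) + 1
    if (j > length(counts)) counts[seq(length(counts) + 1, j)] <- 0L
    counts[j] <- counts[j] + 1L
  }
  counts
}

# plant a defined number of substitutions of each class into a copy of a
# sequence; returns donor/recipient rows plus the planted counts
plant_substitutions <- function(seq, n_inc = 5, n_dec = 4, n_neu = 3,
                                n_deam = 2, seed = 1) {
  stopifnot(n_deam <= n_inc)
  set.seed(seed)
  d <- strsplit(seq, "")[[1]]
  r <- d
  L <- length(d)
  pos <- sample.int(L, n_inc + n_dec + n_neu)
  i_inc <- pos[seq_len(n_inc)]
  i_dec <- pos[n_inc + seq_len(n_dec)]
  i_neu <- pos[n_inc + n_dec + seq_len(n_neu)]
  # deamination-compatible AT-increasing first (C->T / G->A), then other
  for (j in seq_along(i_inc)) {
    if (j <= n_deam) {
      d[i_inc[j]] <- sample(c("C", "G"), 1)
      r[i_inc[j]] <- if (d[i_inc[j]] == "C") "T" else "A"
    } else {
      d[i_inc[j]] <- sample(c("C", "G"), 1)
      r[i_inc[j]] <- if (d[i_inc[j]] == "C") "A" else "T"
    }
  }
  for (j in i_dec) {
    d[j] <- sample(c("A", "T"), 1)
    r[j] <- sample(c("G", "C"), 1)
  }
  for (j in i_neu) {
    d[j] <- sample(c("A", "G"), 1)
    r[j] <- if (d[j] == "A") "T" else "C"
  }
  list(donor = paste(d, collapse = ""), recipient = paste(r, collapse = ""),
       counts = list(inc = as.integer(n_inc), dec = as.integer(n_dec),
                     neu = as.integer(n_neu), deam = as.integer(n_deam)))
}
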