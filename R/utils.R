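BASES <- c("A", "C", "G", "T")

# complement lookup usable on split character vectors
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T only).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# abort unless sequence is plain A/C/G/T (no IUPAC ambiguity codes)
assert_acgt <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGT]", seq)
  if (any(bad)) {
    stop(what, " contains characters other than A/C/G/T ",
         "(ambiguity codes are not supported)", call. = FALSE)
  }
  invisible(seq)
}

# validate a regions data.frame (1-based inclusive start/end)
assert_regions <- function(regions) {
  stopifnot(is.data.frame(regions), all(c("start", "end") %in% names(regions)))
  if (nrow(regions) && any(regions$start > regions$end)) {
    stop("region start must be <= end", call. = FALSE)
  }
  invisible(regions)
}

# regions data.frame -> IRanges
regions_to_iranges <- function(regions, flank = 0) {
  assert_regions(regions)
  IRanges::IRanges(start = pmax(1L, as.integer(regions$start) - as.integer(flank)),
                   end = as.integer(regions$end) + as.integer(flank))
}

# with_seed: evaluate expr under a local RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}
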