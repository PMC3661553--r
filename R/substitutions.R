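#' Classify substitutions in a pairwise alignment
#'
#' Compares a putative donor sequence (row 1) with a recipient (row 2) in a
#' gapped pairwise alignment and tallies point substitutions by their effect
#' on AT content:
#' * AT-increasing: donor base G/C, recipient base A/T;
#' * AT-decreasing: donor base A/T, recipient base G/C;
#' * neutral: transversions within a class (A<->T, G<->C).
#'
#' Among the AT-increasing events, those explainable by cytosine deamination
#' (C->T, or G->A as its complementary-strand image) are counted as
#' deamination-compatible. Gap columns are tallied as insertion runs (gap in
#' the donor row) and deletion runs (gap in the recipient row).
#'
#' @param donor,recipient aligned rows of equal length; gaps as `"-"`.
#' @param subregion optional `c(start, end)` restriction in recipient
#'   (ungapped row 2) coordinates, 1-based inclusive.
#' @return list of counts: `total_substitutions`, `at_increasing`,
#'   `at_decreasing`, `neutral`, `deamination_compatible`, `insertions`,
#'   `deletions` (runs), plus `aligned_columns`.
#' @examples
#' classify_substitutions("ACGT", "ATGT")  # one C->T, AT-increasing
#' @export
classify_substitutions <- function(donor, recipient, subregion = NULL) {
  donor <- toupper(as.character(donor))
  recipient <- toupper(as.character(recipient))
  if (nchar(donor) != nchar(recipient)) {
    stop("alignment rows must have equal length")
  }
  d <- strsplit(donor, "", fixed = TRUE)[[1]]
  r <- strsplit(recipient, "", fixed = TRUE)[[1]]
  ok <- c("A", "C", "G", "T", "-")
  if (any(!d %in% ok) || any(!r %in% ok)) {
    stop("alignment rows may contain only A/C/G/T and '-'")
  }
  # recipient (ungapped) coordinate of every column; 0 before the first base
  rpos <- cumsum(r != "-")
  keep <- rep(TRUE, length(d))
  if (!is.null(subregion)) {
    stopifnot(length(subregion) == 2, subregion[1] <= subregion[2])
    keep <- rpos >= subregion[1] & rpos <= subregion[2] & r != "-"
    # deletion columns (recipient gap) inside the subregion span
    keep[r == "-" & rpos >= subregion[1] & rpos < subregion[2]] <- TRUE
  }
  sub <- keep & d != "-" & r != "-" & d != r
  at <- c("A", "T")
  inc <- sub & d %in% c("G", "C") & r %in% at
  dec <- sub & d %in% at & r %in% c("G", "C")
  neu <- sub & !inc & !dec
  deam <- inc & ((d == "C" & r == "T") | (d == "G" & r == "A"))
  run_count <- function(gap) {
    rl <- rle(gap & keep)
    sum(rl$values)
  }
  list(total_substitutions = sum(sub),
       at_increasing = sum(inc),
       at_decreasing = sum(dec),
       neutral = sum(neu),
       deamination_compatible = sum(deam),
       insertions = run_count(d == "-" & r != "-"),
       deletions = run_count(r == "-" & d != "-"),
       aligned_columns = sum(keep))
}
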