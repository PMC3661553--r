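#' Read a genome sequence from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @return character string (uppercase).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (!length(ss)) stop("no sequences in ", path)
  toupper(as.character(ss[[1]]))
}

#' Write a genome sequence to FASTA
#'
#' @param seq character string.
#' @param path output file.
#' @param name FASTA record name.
#' @export
write_genome_fasta <- function(seq, path, name = "synthetic_genome") {
  ss <- Biostrings::DNAStringSet(seq)
  names(ss) <- name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a 44-nt read set from FASTA or FASTQ
#'
#' @param path input file; FASTQ is assumed for `.fastq`/`.fq` extensions.
#' @return named character vector of read sequences.
#' @export
read_reads_fasta <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)$", path, ignore.case = TRUE)) "fastq"
         else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  setNames(toupper(as.character(ss)), names(ss))
}

#' Write a read set to FASTA
#'
#' @param reads named character vector.
#' @param path output file.
#' @export
write_reads_fasta <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads)
  if (is.null(names(ss))) names(ss) <- sprintf("read_%04d", seq_along(ss))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a stranded TSP track from BED6
#'
#' Single-base BED intervals; the 1-based interval start is the TSP position.
#'
#' @param path BED file.
#' @return data.frame `position`, `strand`, `score`.
#' @export
read_tsp_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(position = BiocGenerics::start(gr),
             strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-",
                             "-", "+"),
             score = if (!is.null(gr$score)) gr$score else NA_real_)
}

#' Write a stranded TSP track to BED6
#'
#' @param track data.frame `position`, `strand`, optionally `score`.
#' @param path output file.
#' @param chrom chromosome name used in column 1.
#' @export
write_tsp_bed <- function(track, path, chrom = "genome") {
  score <- if (!is.null(track$score)) track$score else 0
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = track$position, width = 1L),
    strand = track$strand,
    score = score,
    name = sprintf("tsp_%05d", seq_len(nrow(track))))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a region/interval set from BED
#'
#' @param path BED file (1-based inclusive coordinates on return).
#' @return data.frame `start`, `end`, `name`, `strand`.
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr),
             name = if (!is.null(gr$name)) gr$name
                    else sprintf("region_%04d", seq_along(gr)),
             strand = as.character(BiocGenerics::strand(gr)))
}

#' Write a region/interval set to BED
#'
#' @param regions data.frame `start`, `end`, optionally `name`, `score`,
#'   `strand`.
#' @param path output file.
#' @param chrom chromosome name used in column 1.
#' @export
write_regions_bed <- function(regions, path, chrom = "genome") {
  assert_regions(regions)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end),
    strand = if (!is.null(regions$strand)) regions$strand else "*",
    name = if (!is.null(regions$name)) regions$name
           else sprintf("region_%04d", seq_len(nrow(regions))))
  if (!is.null(regions$score)) gr$score <- regions$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Export a conformational chain as pseudo-atom PDB
#'
#' One pseudo-atom per vertex (C alpha records on one chain), connected in
#' order; intended for quick visual inspection in a molecular viewer.
#'
#' @param chain a [place_chain()] result.
#' @param path output file.
#' @export
write_chain_pdb <- function(chain, path) {
  stopifnot(inherits(chain, "conformational_chain"))
  V <- chain$vertices
  el <- if (chain$kind == "phosphorus") "P" else "C"
  lines <- vapply(seq_len(nrow(V)), function(i) {
    sprintf("ATOM  %5d %-4s PSA A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, el, i, V[i, 1], V[i, 2], V[i, 3], el)
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
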