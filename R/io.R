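## Plain-text writers for the standard interchange formats produced by a
## simulation/profiling run: FASTA references, paired FASTQ, BED truth
## segments and TSV tracks.

#' Write the two parental reference sequences to FASTA
#'
#' @param pair A `parental_pair`.
#' @param path Output FASTA path (two records, `parent_A` and `parent_B`).
#' @return The path, invisibly.
#' @export
write_parental_fasta <- function(pair, path) {
  stopifnot(inherits(pair, "parental_pair"))
  ss <- Biostrings::DNAStringSet(c(parent_A = pair$seq_a, parent_B = pair$seq_b))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write simulated paired reads to FASTQ
#'
#' Mates go to `<prefix>_1.fastq` and `<prefix>_2.fastq` with `/1` and
#' `/2` read-name suffixes and uniform placeholder qualities (the
#' simulator has no quality-score error model).
#'
#' @param reads Tibble from [simulate_reads()].
#' @param prefix Output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_reads_fastq <- function(reads, prefix) {
  paths <- paste0(prefix, "_", 1:2, ".fastq")
  for (m in 1:2) {
    r <- reads[reads$mate == m, ]
    qual <- strrep("I", nchar(r$seq[1]))
    lines <- as.vector(rbind(
      sprintf("@%s/%d", r$read_id, m), r$seq, "+", rep(qual, nrow(r))
    ))
    writeLines(lines, paths[m])
  }
  invisible(paths)
}

#' Write a hybrid plan (or any segment table) as BED
#'
#' 0-based half-open coordinates; extra columns go into the BED name field
#' as `key=value` pairs.
#'
#' @param segments Tibble with `start`, `end` and optional annotation
#'   columns; a `hybrid_plan` works directly.
#' @param path Output BED path.
#' @param chrom Chromosome label (default `"genome"`).
#' @return The path, invisibly.
#' @export
write_segments_bed <- function(segments, path, chrom = "genome") {
  seg <- as_tibble(segments)
  extra <- setdiff(names(seg), c("start", "end"))
  name <- if (length(extra)) {
    apply(seg[extra], 1, function(r) paste(extra, unname(r), sep = "=",
                                           collapse = ";"))
  } else "."
  writeLines(
    paste(chrom, format(seg$start, scientific = FALSE, trim = TRUE),
          format(seg$end, scientific = FALSE, trim = TRUE), name,
          sep = "\t"),
    path
  )
  invisible(path)
}
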