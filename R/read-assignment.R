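## Competitive assignment of reads to two parental reference genomes.
## Emulates the study design of aligning hybrid reads to both parents and
## discarding reads that align equally well to both ("ambiguous"): a read
## is informative about its subgenome of origin only if it overlaps at
## least one diagnostic site between the parents.

## exact k-mer seed positions of `seqs` in the k-mer table of one reference;
## returns candidate 1-based alignment starts (NA if no seed hit)
seed_starts <- function(seqs, kmer_table, offsets, k) {
  cand <- rep(NA_integer_, length(seqs))
  for (off in offsets) {
    need <- is.na(cand)
    if (!any(need)) break
    hit <- match(substring(seqs[need], off, off + k - 1L), kmer_table)
    cand[need] <- hit - off + 1L
  }
  cand
}

## Hamming mismatches of each read against the reference at given starts,
## chunked to bound memory; invalid/NA starts give NA
count_mismatches <- function(read_mat, starts, ref_chars, chunk = 20000L) {
  n <- nrow(read_mat)
  read_len <- ncol(read_mat)
  L <- length(ref_chars)
  out <- rep(NA_integer_, n)
  valid <- which(!is.na(starts) & starts >= 1L & starts + read_len - 1L <= L)
  for (grp in split(valid, ceiling(seq_along(valid) / chunk))) {
    idx <- outer(starts[grp], 0:(read_len - 1L), `+`)
    refm <- matrix(ref_chars[idx], nrow = length(grp))
    out[grp] <- as.integer(rowSums(refm != read_mat[grp, , drop = FALSE]))
  }
  out
}

#' Assign reads to parental subgenomes by competitive alignment
#'
#' Built-in aligner for duplicate-free, indel-free short reads: each read
#' (in both orientations) is seeded by exact k-mer lookup against both
#' references and scored by Hamming distance over its full length. A read
#' is `A_unique` if its best score against reference A beats reference B
#' (and is within the mismatch budget), symmetrically for `B_unique`;
#' equal best scores give `ambiguous` (the removal class), and no
#' acceptable placement gives `unmapped`. k-mer lookups return the first
#' occurrence, which is essentially unique for the k used here on
#' non-repetitive genomes.
#'
#' @param reads Tibble from [simulate_reads()] (needs `seq`; `read_id`,
#'   `mate` and truth columns are carried through), or a character vector
#'   of read sequences.
#' @param ref_a,ref_b Parental reference sequences (character strings), or
#'   pass a `parental_pair` as `ref_a` and omit `ref_b`.
#' @param k Seed length (default 31).
#' @param max_mismatch Maximum mismatches for an acceptable placement
#'   (default 10 on 150-bp reads).
#' @param seed_offsets Read offsets at which seeds are tried (default three
#'   evenly spaced positions, so a sequencing error in one seed rarely
#'   loses the read).
#' @return A `read_assignment` tibble: per read `label` in
#'   `A_unique`/`B_unique`/`ambiguous`/`unmapped`, `ref_start` (1-based on
#'   the assigned reference, NA otherwise), `strand`, `seq_fwd` (read
#'   oriented to the reference forward strand), `mismatches`, plus any
#'   carried truth columns. Attributes `ref_a`, `ref_b` keep the
#'   references for downstream coverage and pileup.
#' @export
assign_reads <- function(reads, ref_a, ref_b = NULL, k = 31,
                         max_mismatch = 10, seed_offsets = NULL) {
  if (inherits(ref_a, "parental_pair")) {
    ref_b <- ref_a$seq_b
    ref_a <- ref_a$seq_a
  }
  if (is.character(reads)) reads <- tibble(seq = reads)
  read_len <- unique(nchar(reads$seq))
  if (length(read_len) != 1L) abort("all reads must have equal length.")
  if (read_len < k) abort("reads shorter than the seed length k.")
  if (nchar(ref_a) < k || nchar(ref_b) < k) abort("references shorter than k.")
  if (is.null(seed_offsets)) {
    seed_offsets <- unique(pmax(1L, floor(c(1, (read_len - k) / 2, read_len - k + 1))))
  }

  kmers <- function(ref) {
    L <- nchar(ref)
    substring(ref, 1:(L - k + 1L), k:L)
  }
  tab_a <- kmers(ref_a)
  tab_b <- kmers(ref_b)
  chars_a <- seq_chars(ref_a)
  chars_b <- seq_chars(ref_b)

  fwd <- reads$seq
  rev <- revcomp(fwd)
  mat_f <- do.call(rbind, strsplit(fwd, "", fixed = TRUE))
  mat_r <- do.call(rbind, strsplit(rev, "", fixed = TRUE))

  score <- function(tab, chars) {
    s_f <- seed_starts(fwd, tab, seed_offsets, k)
    s_r <- seed_starts(rev, tab, seed_offsets, k)
    mm_f <- count_mismatches(mat_f, s_f, chars)
    mm_r <- count_mismatches(mat_r, s_r, chars)
    best_r <- !is.na(mm_r) & (is.na(mm_f) | mm_r < mm_f)
    list(
      mm = pmin(mm_f, mm_r, na.rm = TRUE),
      start = ifelse(best_r, s_r, s_f),
      strand = ifelse(best_r, "-", "+")
    )
  }
  sa <- score(tab_a, chars_a)
  sb <- score(tab_b, chars_b)
  mm_a <- ifelse(is.na(sa$mm) | sa$mm > max_mismatch, Inf, sa$mm)
  mm_b <- ifelse(is.na(sb$mm) | sb$mm > max_mismatch, Inf, sb$mm)

  label <- dplyr::case_when(
    is.infinite(mm_a) & is.infinite(mm_b) ~ "unmapped",
    mm_a < mm_b ~ "A_unique",
    mm_b < mm_a ~ "B_unique",
    TRUE ~ "ambiguous"
  )
  use_a <- label == "A_unique"
  use_b <- label == "B_unique"
  ref_start <- ifelse(use_a, sa$start, ifelse(use_b, sb$start, NA_integer_))
  strand <- ifelse(use_a, sa$strand, ifelse(use_b, sb$strand, NA_character_))
  seq_fwd <- ifelse(!is.na(strand) & strand == "-", rev, fwd)
  mism <- ifelse(use_a, sa$mm, ifelse(use_b, sb$mm, NA_integer_))

  out <- dplyr::bind_cols(
    reads,
    tibble(label = label, ref_start = as.integer(ref_start), strand = strand,
           seq_fwd = seq_fwd, mismatches = as.integer(mism))
  )
  structure(out,
            class = unique(c("read_assignment", class(out))),
            ref_a = ref_a, ref_b = ref_b, read_len = read_len)
}

#' Import read assignments from two SAM files
#'
#' Production path mirroring the built-in assigner's uniqueness rule on
#' pre-computed alignments: a read mapped in only one of the two
#' single-reference SAM files is unique to that reference; mapped in both
#' with different alignment scores (`AS` tag, or mismatch tag `NM` as
#' fallback) it goes to the better side; equal scores are `ambiguous`;
#' mapped in neither, `unmapped`. Assumes deduplicated input alignments.
#'
#' @param sam_a,sam_b SAM files of the same read set aligned to parent A
#'   and parent B respectively.
#' @param ref_a,ref_b The reference sequences (character strings), kept for
#'   downstream windowing.
#' @return A `read_assignment` tibble (columns as [assign_reads()]).
#' @export
read_sam_assignment <- function(sam_a, sam_b, ref_a = NULL, ref_b = NULL) {
  parse_sam <- function(path) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@")]
    if (!length(lines)) abort(sprintf("no alignment records in %s", path))
    f <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(f) < 11
    if (any(bad)) abort(sprintf("malformed SAM records in %s", path))
    flag <- as.integer(vapply(f, `[`, character(1), 2L))
    score <- vapply(f, function(x) {
      as_tag <- grep("^AS:i:", x[-(1:11)], value = TRUE)
      if (length(as_tag)) return(as.numeric(sub("AS:i:", "", as_tag[1])))
      nm_tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
      if (length(nm_tag)) return(-as.numeric(sub("NM:i:", "", nm_tag[1])))
      0
    }, numeric(1))
    tibble(
      read_id = vapply(f, `[`, character(1), 1L),
      mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
      mapped = bitwAnd(flag, 4L) == 0L,
      pos = as.integer(vapply(f, `[`, character(1), 4L)),
      strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
      seq = vapply(f, `[`, character(1), 10L),
      score = score
    )
  }
  a <- parse_sam(sam_a)
  b <- parse_sam(sam_b)
  j <- dplyr::full_join(a, b, by = c("read_id", "mate"),
                        suffix = c("_a", "_b"))
  map_a <- !is.na(j$mapped_a) & j$mapped_a
  map_b <- !is.na(j$mapped_b) & j$mapped_b
  sc_a <- ifelse(map_a, j$score_a, -Inf)
  sc_b <- ifelse(map_b, j$score_b, -Inf)
  label <- dplyr::case_when(
    !map_a & !map_b ~ "unmapped",
    map_a & (!map_b | sc_a > sc_b) ~ "A_unique",
    map_b & (!map_a | sc_b > sc_a) ~ "B_unique",
    TRUE ~ "ambiguous"
  )
  use_a <- label == "A_unique"
  use_b <- label == "B_unique"
  seqs <- ifelse(use_b, j$seq_b, j$seq_a)
  out <- tibble(
    read_id = j$read_id, mate = j$mate, seq = seqs, label = label,
    ref_start = as.integer(ifelse(use_a, j$pos_a, ifelse(use_b, j$pos_b, NA))),
    strand = ifelse(use_a, j$strand_a, ifelse(use_b, j$strand_b, NA)),
    seq_fwd = seqs,   # SAM stores SEQ already on the reference forward strand
    mismatches = NA_integer_
  )
  structure(out,
            class = unique(c("read_assignment", class(out))),
            ref_a = ref_a, ref_b = ref_b,
            read_len = unique(nchar(out$seq))[1])
}

#' Summarize an assignment into the four label classes
#'
#' @param assignment A `read_assignment`.
#' @return Tibble of label counts; the counts always sum to the total
#'   number of reads (the labels partition the read set).
#' @export
assignment_summary <- function(assignment) {
  out <- dplyr::count(as_tibble(assignment), .data$label, name = "n_reads")
  lv <- c("A_unique", "B_unique", "ambiguous", "unmapped")
  missing <- setdiff(lv, out$label)
  if (length(missing)) {
    out <- dplyr::bind_rows(out, tibble(label = missing, n_reads = 0L))
  }
  out[match(lv, out$label), ]
}
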