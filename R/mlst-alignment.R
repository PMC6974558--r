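## MLST marker alignments: IUPAC heterozygous-consensus handling,
## site counts, nucleotide diversity and multi-locus concatenation.
##
## A marker alignment is a tibble with columns `strain`, `species`, `seq`
## (equal-length aligned sequences over A/C/G/T, two-fold IUPAC codes
## R/Y/S/W/K/M for heterozygous positions, '-' gaps and 'N' missing) and a
## `locus` attribute.

#' Construct a marker alignment
#'
#' @param strain Character vector of strain identifiers.
#' @param seq Character vector of aligned sequences (equal lengths).
#' @param species Optional species label per strain.
#' @param locus Locus name.
#' @return A `marker_alignment` tibble.
#' @export
marker_alignment <- function(strain, seq, species = NA_character_,
                             locus = "locus") {
  seq <- toupper(seq)
  if (length(unique(nchar(seq))) != 1L) {
    abort("all sequences in an alignment must have equal length.")
  }
  if (nchar(seq[1]) == 0L) abort("locus length must be > 0.")
  bad <- grepl("[^ACGTRYSWKMN-]", seq)
  if (any(bad)) {
    abort(sprintf("unsupported characters in sequences of: %s",
                  paste(strain[bad], collapse = ", ")))
  }
  out <- tibble(strain = strain, species = species, seq = seq)
  structure(out, class = c("marker_alignment", class(out)), locus = locus)
}

#' Read one MLST locus alignment from FASTA
#'
#' Strain identifiers are taken from the FASTA headers (first whitespace
#' token). An optional species map (data frame with `strain`, `species`)
#' attaches species labels.
#'
#' @param path FASTA file of aligned sequences.
#' @param locus Locus name (defaults to the file name without extension).
#' @param species_map Optional data frame with columns `strain`, `species`.
#' @return A `marker_alignment` tibble.
#' @export
read_marker_alignment <- function(path, locus = NULL, species_map = NULL) {
  ss <- Biostrings::readBStringSet(path)
  strain <- sub("\\s.*$", "", names(ss))
  locus <- locus %||% sub("\\.[^.]*$", "", basename(path))
  species <- NA_character_
  if (!is.null(species_map)) {
    species <- species_map$species[match(strain, species_map$strain)]
  }
  marker_alignment(strain, unname(as.character(ss)), species, locus)
}

#' Write an alignment (or pseudo-haplotype expansion) to FASTA
#'
#' @param aln A `marker_alignment`.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_marker_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(setNames(aln$seq, aln$strain))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(m) <- aln$strain
  m
}

#' Collapse two haplotypes into an IUPAC-coded consensus
#'
#' Positions where the haplotypes agree pass through; positions where they
#' differ by a base pair are replaced by the two-fold IUPAC degeneracy code
#' (e.g. A/T -> W), the encoding used for heterozygous positions read off
#' Sanger chromatograms. Any `N` yields `N`; a gap in one haplotype only
#' also yields `N` (the diploid state is unresolved there), while a shared
#' gap stays a gap.
#'
#' @param hap1,hap2 Equal-length DNA strings over A/C/G/T/N/-.
#' @return The IUPAC consensus string (vectorized over pairs).
#' @export
#' @examples
#' encode_heterozygous_consensus("AAT", "ATT")
encode_heterozygous_consensus <- function(hap1, hap2) {
  if (length(hap1) != length(hap2)) abort("hap1 and hap2 lengths differ.")
  mapply(function(a, b) {
    if (nchar(a) != nchar(b)) abort("haplotype sequences differ in length.")
    ca <- seq_chars(toupper(a))
    cb <- seq_chars(toupper(b))
    out <- ca
    diff <- ca != cb
    out[ca == "N" | cb == "N"] <- "N"
    mix <- diff & ca != "N" & cb != "N"
    if (any(mix)) {
      gap <- mix & (ca == "-" | cb == "-")
      out[gap] <- "N"
      snp <- which(mix & !gap)
      if (length(snp)) {
        key <- paste0(pmin(ca[snp], cb[snp]), pmax(ca[snp], cb[snp]))
        code <- IUPAC2[key]
        if (anyNA(code)) abort("bases outside A/C/G/T/N/- in haplotypes.")
        out[snp] <- code
      }
    }
    paste(out, collapse = "")
  }, hap1, hap2, USE.NAMES = FALSE)
}

#' Expand IUPAC consensus sequences into two pseudo-haplotypes per strain
#'
#' Each strain yields two sequences: at every two-fold ambiguous position
#' the two constituent bases are split one per pseudo-haplotype
#' (alphabetically-first base to haplotype 1 — phase is not identifiable
#' from Sanger consensus, and the downstream statistics are
#' phase-invariant); unambiguous positions are duplicated. Inverse of
#' [encode_heterozygous_consensus()].
#'
#' @param aln A `marker_alignment` (only two-fold IUPAC codes allowed).
#' @return A `marker_alignment` with strains `<strain>_1`, `<strain>_2`.
#' @export
expand_biallelic <- function(aln) {
  stopifnot(inherits(aln, "marker_alignment"))
  if (any(grepl("[BDHV]", aln$seq))) {
    abort("3/4-fold IUPAC codes (B, D, H, V) are not supported.")
  }
  expand_one <- function(s) {
    ch <- seq_chars(s)
    amb <- ch %in% names(IUPAC2_SPLIT)
    h1 <- ch
    h2 <- ch
    if (any(amb)) {
      pairs <- IUPAC2_SPLIT[ch[amb]]
      h1[amb] <- vapply(pairs, `[`, character(1), 1L)
      h2[amb] <- vapply(pairs, `[`, character(1), 2L)
    }
    c(paste(h1, collapse = ""), paste(h2, collapse = ""))
  }
  haps <- vapply(aln$seq, expand_one, character(2), USE.NAMES = FALSE)
  marker_alignment(
    strain = as.vector(rbind(paste0(aln$strain, "_1"), paste0(aln$strain, "_2"))),
    seq = as.vector(haps),
    species = rep(aln$species, each = 2),
    locus = attr(aln, "locus")
  )
}

## columns kept for counting: no gap or N in any strain
usable_columns <- function(m) {
  colSums(m == "-" | m == "N") == 0
}

#' Count heterozygous and polymorphic sites in an alignment
#'
#' Columns containing a gap or `N` in any strain are excluded from all
#' counts. A retained column is heterozygous if at least one strain carries
#' a two-fold IUPAC ambiguity, and polymorphic if the union of constituent
#' alleles across strains (counting both alleles of an ambiguity) has at
#' least two distinct bases; a column that is variable only within a single
#' strain therefore counts as both. The polymorphic percentage is rounded
#' half-up to two decimals, the precision used in diversity tables.
#'
#' @param aln A `marker_alignment` with >= 2 sequences.
#' @return One-row tibble: `locus`, `n_sequences`, `n_total_sites`,
#'   `n_heterozygous_sites`, `n_polymorphic_sites`, `pct_polymorphic`.
#' @export
site_counts <- function(aln) {
  stopifnot(inherits(aln, "marker_alignment"))
  if (nrow(aln) < 2) abort("site counts need at least 2 sequences.")
  m <- aln_matrix(aln)
  keep <- usable_columns(m)
  m <- m[, keep, drop = FALSE]
  het <- colSums(matrix(m %in% names(IUPAC2_SPLIT), nrow = nrow(m))) > 0
  poly <- apply(m, 2, function(col) {
    alleles <- unique(unlist(c(col[!col %in% names(IUPAC2_SPLIT)],
                               IUPAC2_SPLIT[col[col %in% names(IUPAC2_SPLIT)]])))
    length(alleles) >= 2
  })
  tibble(
    locus = attr(aln, "locus"),
    n_sequences = nrow(aln),
    n_total_sites = ncol(m),
    n_heterozygous_sites = sum(het),
    n_polymorphic_sites = sum(poly),
    pct_polymorphic = round_half_up(100 * sum(poly) / ncol(m), 2)
  )
}

#' Nucleotide diversity of a marker alignment
#'
#' Expands the N strains into 2N pseudo-haplotypes and reports Pi, the mean
#' pairwise Hamming difference over all `choose(2N, 2)` haplotype pairs on
#' columns surviving the gap/missing filter (a per-locus count of
#' differences, not a per-site rate), plus its per-kb rescaling
#' `1000 * Pi / n_total_sites`.
#'
#' @param aln A `marker_alignment` with >= 2 strains.
#' @return One-row tibble: `locus`, `n_haplotypes`, `n_total_sites`, `Pi`,
#'   `pi_per_kb`.
#' @export
nucleotide_diversity <- function(aln) {
  stopifnot(inherits(aln, "marker_alignment"))
  if (nrow(aln) < 2) abort("nucleotide diversity is undefined for one strain.")
  haps <- expand_biallelic(aln)
  m <- aln_matrix(haps)
  keep <- usable_columns(m)
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  n_pairs <- choose(n, 2)
  ## per column: pairs differing = C(n,2) - sum_a C(n_a,2)
  diffs <- apply(m, 2, function(col) {
    n_pairs - sum(choose(table(col), 2))
  })
  tibble(
    locus = attr(aln, "locus"),
    n_haplotypes = n,
    n_total_sites = ncol(m),
    Pi = sum(diffs) / n_pairs,
    pi_per_kb = 1000 * sum(diffs) / n_pairs / ncol(m)
  )
}

#' Concatenate marker alignments across loci
#'
#' Keeps strains present in every locus; strains missing from any locus are
#' dropped with a warning (as happens when one allele of a hybrid marker
#' cannot be recovered). Optionally removes gap-containing columns per
#' locus before concatenation.
#'
#' @param alignments List of `marker_alignment` objects.
#' @param clean `"none"` (default) or `"gaps"` to drop columns containing a
#'   gap in any retained strain.
#' @return A `marker_alignment` of the concatenated sequences, with a
#'   `locus_widths` attribute giving per-locus contributions.
#' @export
concatenate_markers <- function(alignments, clean = c("none", "gaps")) {
  clean <- match.arg(clean)
  stopifnot(length(alignments) >= 1)
  strains <- purrr::map(alignments, "strain")
  shared <- Reduce(intersect, strains)
  if (!length(shared)) abort("no strains shared across all loci.")
  dropped <- setdiff(unique(unlist(strains)), shared)
  if (length(dropped)) {
    warn(sprintf("excluded from concatenation (missing >= 1 locus): %s",
                 paste(dropped, collapse = ", ")))
  }
  pieces <- purrr::map(alignments, function(a) {
    a <- a[match(shared, a$strain), ]
    s <- a$seq
    if (clean == "gaps") {
      m <- do.call(rbind, strsplit(s, "", fixed = TRUE))
      m <- m[, colSums(m == "-") == 0, drop = FALSE]
      s <- apply(m, 1, paste, collapse = "")
    }
    list(seq = s, species = a$species, width = nchar(s[1]))
  })
  seqs <- purrr::reduce(purrr::map(pieces, "seq"), paste0)
  out <- marker_alignment(
    strain = shared, seq = seqs, species = pieces[[1]]$species,
    locus = paste(purrr::map_chr(alignments, attr, "locus"), collapse = "+")
  )
  attr(out, "locus_widths") <- purrr::map_int(pieces, "width")
  out
}
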