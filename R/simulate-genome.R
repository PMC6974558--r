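## Synthetic two-parent genomes, hybrid chromosome complements and
## paired-end reads with full ground truth. These generators stand in for
## the study system: two diverged apiculate-yeast parental genomes and
## interspecific hybrids carrying a variable number of chromosome copies
## from each parent, with heterozygosity and LOH tracts on the subgenomes.

#' Simulate a pair of diverged parental genomes
#'
#' Generates one random chromosome and derives a second parental sequence
#' from it by substituting bases at a fixed per-site rate, emulating two
#' closely related parental species of an interspecific hybrid. No indels
#' are introduced: the divergent sites are the diagnostic SNPs that later
#' allow reads to be assigned to a subgenome.
#'
#' @param length Genome length in bp (>= 1000).
#' @param divergence_rate Per-site substitution probability between the two
#'   parents, in `[0, 0.2]`.
#' @param seed Integer seed; all randomness in the call derives from it
#'   (R's default Mersenne-Twister generator).
#' @return An object of class `parental_pair`: a list with `seq_a`, `seq_b`
#'   (character strings over ACGT), `divergence_map` (1-based positions
#'   where the parents differ), `divergence_rate` and `length`.
#' @export
#' @examples
#' pair <- simulate_parental_pair(2000, 0.02, seed = 1)
#' length(pair$divergence_map) / pair$length
simulate_parental_pair <- function(length, divergence_rate, seed) {
  check_scalar_number(length, "length", lower = 1000)
  check_scalar_number(divergence_rate, "divergence_rate", 0, 0.2)
  check_scalar_number(seed, "seed")
  set.seed(seed)
  length <- as.integer(length)
  a <- sample(DNA_BASES, length, replace = TRUE)
  b <- a
  div <- which(runif(length) < divergence_rate)
  if (length(div)) {
    ## substitute uniformly over the three alternative bases
    b[div] <- vapply(a[div], function(x) sample(setdiff(DNA_BASES, x), 1L),
                     character(1))
  }
  structure(
    list(
      seq_a = paste(a, collapse = ""),
      seq_b = paste(b, collapse = ""),
      divergence_map = div,
      divergence_rate = divergence_rate,
      length = length
    ),
    class = "parental_pair"
  )
}

#' @export
print.parental_pair <- function(x, ...) {
  cat(sprintf(
    "<parental_pair> %d bp, %d divergent sites (%.4f/site)\n",
    x$length, length(x$divergence_map), length(x$divergence_map) / x$length
  ))
  invisible(x)
}

#' Describe the chromosome-copy structure of a hybrid genome
#'
#' A hybrid plan tiles the genome with non-overlapping 0-based half-open
#' segments, each carrying `copies_a` chromosome copies from parent A and
#' `copies_b` from parent B (e.g. an allotriploid is a single segment with
#' 2 and 1). Segments flagged `loh` receive no planted heterozygosity,
#' emulating loss-of-heterozygosity tracts.
#'
#' @param segments Data frame with columns `start`, `end`, `copies_a`,
#'   `copies_b` and optionally `loh` (logical, default `FALSE`).
#' @param het_rate_a,het_rate_b Heterozygous sites planted per kb on the
#'   A and B subgenomes (only where the subgenome has >= 2 copies).
#' @return A `hybrid_plan` tibble with a `total_ploidy` attribute: the
#'   genome-length-weighted mean total copy number.
#' @export
#' @examples
#' hybrid_plan(data.frame(start = 0, end = 2e5, copies_a = 2, copies_b = 1),
#'             het_rate_a = 5)
hybrid_plan <- function(segments, het_rate_a = 0, het_rate_b = 0) {
  seg <- as_tibble(segments)
  if (!all(c("start", "end", "copies_a", "copies_b") %in% names(seg))) {
    abort("`segments` needs columns start, end, copies_a, copies_b.")
  }
  if (!"loh" %in% names(seg)) seg$loh <- FALSE
  seg <- dplyr::arrange(seg, .data$start)
  if (any(seg$end <= seg$start)) abort("segments must have end > start.")
  if (nrow(seg) > 1 && any(seg$start[-1] != seg$end[-nrow(seg)])) {
    abort("segments must tile the genome contiguously without overlap.")
  }
  if (seg$start[1] != 0) abort("segments must start at 0 (0-based half-open).")
  if (any(seg$copies_a + seg$copies_b <= 0)) {
    abort("every segment needs copies_a + copies_b > 0.")
  }
  if (any(seg$copies_a > 4 | seg$copies_b > 4 | seg$copies_a < 0 | seg$copies_b < 0)) {
    abort("copy numbers must be integers in 0..4.")
  }
  len <- sum(seg$end - seg$start)
  ploidy <- sum((seg$end - seg$start) * (seg$copies_a + seg$copies_b)) / len
  structure(seg,
            class = c("hybrid_plan", class(seg)),
            total_ploidy = ploidy,
            het_rate_a = het_rate_a,
            het_rate_b = het_rate_b)
}

## contiguous existence intervals of the i-th copy of one subgenome
copy_runs <- function(plan, copies_col, i) {
  present <- plan[[copies_col]] >= i
  runs <- rle(present)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  keep <- which(runs$values)
  tibble(start = plan$start[starts[keep]], end = plan$end[ends[keep]])
}

#' Build a hybrid genome with known ground truth
#'
#' Materializes the chromosome copies described by a [hybrid_plan()] from a
#' [simulate_parental_pair()] object and plants heterozygous positions on
#' the subgenomes: each planted site mutates exactly one copy of the
#' carrying subgenome (chosen uniformly), so an A subgenome with two copies
#' shows the canonical 50% allele balance at such sites. Sites are planted
#' only where the subgenome has at least two copies and the segment is not
#' flagged LOH.
#'
#' @param pair A `parental_pair`.
#' @param plan A `hybrid_plan` tiling `[0, pair$length)`.
#' @param seed Integer seed.
#' @return An object of class `hybrid_truth`: list with `copies` (tibble of
#'   contiguous copy pieces: `copy_id`, `subgenome`, `start`, `end`, `seq`),
#'   `planted_het` (tibble: `subgenome`, `pos` 1-based, `ref_base`,
#'   `alt_base`, `copy_id`), `plan`, and `pair`.
#' @export
simulate_hybrid_genome <- function(pair, plan, seed) {
  stopifnot(inherits(pair, "parental_pair"), inherits(plan, "hybrid_plan"))
  check_scalar_number(seed, "seed")
  if (max(plan$end) != pair$length) {
    abort("plan must tile [0, length) of the parental pair.")
  }
  set.seed(seed)

  pieces <- list()
  for (sub in c("A", "B")) {
    col <- if (sub == "A") "copies_a" else "copies_b"
    src <- if (sub == "A") pair$seq_a else pair$seq_b
    for (i in seq_len(max(plan[[col]]))) {
      runs <- copy_runs(plan, col, i)
      if (!nrow(runs)) next
      runs$copy_id <- sprintf("%s%d.%d", sub, i, seq_len(nrow(runs)))
      runs$subgenome <- sub
      runs$copy_index <- i
      runs$seq <- substring(src, runs$start + 1L, runs$end)
      pieces[[length(pieces) + 1L]] <- runs
    }
  }
  copies <- dplyr::bind_rows(pieces)

  ## plant heterozygous sites on one copy of the carrying subgenome,
  ## outside LOH tracts and only where >= 2 copies exist
  plant <- function(sub) {
    rate <- attr(plan, if (sub == "A") "het_rate_a" else "het_rate_b")
    col <- if (sub == "A") "copies_a" else "copies_b"
    elig <- plan[!plan$loh & plan[[col]] >= 2, , drop = FALSE]
    if (!nrow(elig) || rate <= 0) {
      return(tibble(subgenome = character(), pos = integer(),
                    ref_base = character(), alt_base = character(),
                    copy_id = character()))
    }
    src <- if (sub == "A") pair$seq_a else pair$seq_b
    out <- purrr::map_dfr(seq_len(nrow(elig)), function(j) {
      len <- elig$end[j] - elig$start[j]
      n <- rpois(1, rate * len / 1000)
      if (!n) return(NULL)
      pos <- sort(sample.int(len, min(n, len))) + elig$start[j]  # 1-based
      ref <- substring(src, pos, pos)
      alt <- vapply(ref, function(x) sample(setdiff(DNA_BASES, x), 1L),
                    character(1), USE.NAMES = FALSE)
      copy_idx <- sample.int(elig[[col]][j], length(pos), replace = TRUE)
      tibble(subgenome = sub, pos = pos, ref_base = ref, alt_base = alt,
             copy_index = copy_idx)
    })
    out
  }
  planted <- dplyr::bind_rows(plant("A"), plant("B"))

  ## apply planted alleles to the chosen copies
  if (nrow(planted)) {
    planted$copy_id <- NA_character_
    for (r in seq_len(nrow(planted))) {
      hit <- which(copies$subgenome == planted$subgenome[r] &
                     copies$copy_index == planted$copy_index[r] &
                     copies$start < planted$pos[r] &
                     copies$end >= planted$pos[r])
      stopifnot(length(hit) == 1L)
      off <- planted$pos[r] - copies$start[hit]
      substr(copies$seq[hit], off, off) <- planted$alt_base[r]
      planted$copy_id[r] <- copies$copy_id[hit]
    }
    planted$copy_index <- NULL
  }

  structure(
    list(copies = copies[, c("copy_id", "subgenome", "start", "end", "seq")],
         planted_het = planted, plan = plan, pair = pair),
    class = "hybrid_truth"
  )
}

#' @export
print.hybrid_truth <- function(x, ...) {
  cat(sprintf(
    "<hybrid_truth> %d copy pieces, %d planted het sites, total ploidy %.2f\n",
    nrow(x$copies), nrow(x$planted_het), attr(x$plan, "total_ploidy")
  ))
  invisible(x)
}

#' Simulate paired-end shotgun reads from a hybrid genome
#'
#' Draws sequencing fragments uniformly along every chromosome-copy piece of
#' the hybrid (Poisson fragment counts, so per-base depth over any single
#' copy is approximately Poisson at `coverage`), then reports the two mates
#' of each fragment with uniform substitution errors. Mate 1 is the forward
#' prefix of the fragment; mate 2 is the reverse complement of its suffix,
#' following the standard paired-end library convention.
#'
#' @param truth A `hybrid_truth` from [simulate_hybrid_genome()].
#' @param coverage Fold coverage per chromosome copy (> 0).
#' @param read_len Read length in bp (default 150).
#' @param insert_mean,insert_sd Fragment length distribution (default 400
#'   +/- 40 bp, a typical short-insert shotgun library).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @return Tibble with one row per read: `read_id`, `mate` (1/2), `seq`,
#'   and ground-truth columns `copy_id`, `subgenome`, `frag_start`,
#'   `frag_end` (1-based inclusive genome coordinates of the fragment).
#' @export
simulate_reads <- function(truth, coverage, read_len = 150, insert_mean = 400,
                           insert_sd = 40, error_rate = 0.001, seed = 1) {
  stopifnot(inherits(truth, "hybrid_truth"))
  check_scalar_number(coverage, "coverage", lower = 1e-9)
  check_scalar_number(error_rate, "error_rate", 0, 0.2)
  if (read_len >= insert_mean) abort("read_len must be < insert_mean.")
  set.seed(seed)

  copies <- truth$copies
  frags <- purrr::map_dfr(seq_len(nrow(copies)), function(i) {
    len <- copies$end[i] - copies$start[i]
    if (len < insert_mean) return(NULL)
    n <- rpois(1, len * coverage / (2 * read_len))
    if (!n) return(NULL)
    ins <- pmin(pmax(round(rnorm(n, insert_mean, insert_sd)), read_len + 10), len)
    s <- floor(runif(n, 1, len - ins + 2))  # 1-based within piece
    tibble(piece = i, s = as.integer(s), ins = as.integer(ins))
  })
  if (!nrow(frags)) abort("no fragments drawn; genome too short for the library.")

  piece_seq <- copies$seq[frags$piece]
  m1 <- substring(piece_seq, frags$s, frags$s + read_len - 1L)
  m2 <- revcomp(substring(piece_seq, frags$s + frags$ins - read_len,
                          frags$s + frags$ins - 1L))

  add_errors <- function(reads) {
    n_err <- rbinom(length(reads), read_len, error_rate)
    for (i in which(n_err > 0)) {
      pos <- sample.int(read_len, n_err[i])
      for (p in pos) {
        cur <- substr(reads[i], p, p)
        substr(reads[i], p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
      }
    }
    reads
  }
  if (error_rate > 0) {
    m1 <- add_errors(m1)
    m2 <- add_errors(m2)
  }

  ids <- sprintf("read%07d", seq_len(nrow(frags)))
  g_start <- copies$start[frags$piece] + frags$s       # 1-based genome coord
  g_end <- g_start + frags$ins - 1L
  out <- tibble(
    read_id = rep(ids, 2L),
    mate = rep(c(1L, 2L), each = nrow(frags)),
    seq = c(m1, m2),
    copy_id = rep(copies$copy_id[frags$piece], 2L),
    subgenome = rep(copies$subgenome[frags$piece], 2L),
    frag_start = rep(g_start, 2L),
    frag_end = rep(g_end, 2L)
  )
  dplyr::arrange(out, .data$read_id, .data$mate)
}
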