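## Variant sites on one parental reference: a simple pileup genotyper for
## the built-in path, VCF import for the production path, GATK-style hard
## filtering, allelic-state classification, windowed heterozygous-SNP
## density, LOH segment detection and minor-allele-balance windows.

variant_site_tibble <- function(scaffold, pos, ref, alt, gt, ad, depth,
                                qd = NA_real_, fs = NA_real_, sor = NA_real_,
                                mq = NA_real_, mq_rank_sum = NA_real_,
                                read_pos_rank_sum = NA_real_) {
  tibble(
    scaffold = scaffold, pos = as.integer(pos), ref = ref, alt = alt,
    gt = gt, ad = ad, depth = as.integer(depth),
    qd = qd, fs = fs, sor = sor, mq = mq,
    mq_rank_sum = mq_rank_sum, read_pos_rank_sum = read_pos_rank_sum
  )
}

#' Call variant sites from uniquely assigned reads (simple pileup caller)
#'
#' Piles the reads assigned uniquely to one subgenome onto its reference
#' (positions are 1-based, VCF convention) and emits a site wherever a
#' non-reference allele reaches `min_alt_fraction` of the reads at a
#' position with depth at least `min_depth`. The genotype lists every
#' allele above the threshold (`0/1` for ref+alt, `1/2` for two alternate
#' alleles, `1/1` for a fixed substitution). This is a deliberately simple
#' counting caller for simulated, indel-free reads: GATK-style annotation
#' fields are reported as missing rather than fabricated, and are only
#' populated on VCF import ([read_vcf_sites()]).
#'
#' @param assignment A `read_assignment` from [assign_reads()].
#' @param subgenome `"A"` or `"B"`: which unique-read set to pile up.
#' @param min_depth Minimum depth to emit a site (default 8).
#' @param min_alt_fraction Minimum allele fraction for an allele to enter
#'   the genotype (default 0.15).
#' @return A `variant_sites` tibble: `scaffold`, `pos`, `ref`, `alt`
#'   (comma-separated), `gt`, `ad` (list column of integer allele depths,
#'   ref first), `depth`, and NA annotation columns `qd`, `fs`, `sor`,
#'   `mq`, `mq_rank_sum`, `read_pos_rank_sum`. The reference length is
#'   kept in the `ref_length` attribute.
#' @export
pileup_genotype <- function(assignment, subgenome = c("A", "B"),
                            min_depth = 8, min_alt_fraction = 0.15) {
  stopifnot(inherits(assignment, "read_assignment"))
  subgenome <- match.arg(subgenome)
  ref <- attr(assignment, if (subgenome == "A") "ref_a" else "ref_b")
  read_len <- attr(assignment, "read_len")
  L <- nchar(ref)
  rows <- assignment[assignment$label == paste0(subgenome, "_unique"), ]
  empty <- variant_site_tibble(character(), integer(), character(),
                               character(), character(), list(), integer())
  if (!nrow(rows)) return(structure(empty, ref_length = L,
                                    class = c("variant_sites", class(empty))))

  ref_chars <- seq_chars(ref)
  depth <- depth_vector(rows$ref_start, read_len, L)

  ## mismatch observations (position, allele, count), chunked
  obs <- list()
  chunks <- split(seq_len(nrow(rows)), ceiling(seq_len(nrow(rows)) / 20000L))
  for (ch in chunks) {
    m <- do.call(rbind, strsplit(rows$seq_fwd[ch], "", fixed = TRUE))
    idx <- outer(rows$ref_start[ch], 0:(read_len - 1L), `+`)
    keep <- idx >= 1L & idx <= L
    ne <- keep & (matrix(ref_chars[pmin(pmax(idx, 1L), L)],
                         nrow = length(ch)) != m)
    if (any(ne)) {
      w <- which(ne)
      obs[[length(obs) + 1L]] <- tibble(pos = idx[w], allele = m[w])
    }
  }
  if (!length(obs)) {
    return(structure(empty, ref_length = L,
                     class = c("variant_sites", class(empty))))
  }
  alt_counts <- dplyr::count(dplyr::bind_rows(obs), .data$pos, .data$allele,
                             name = "count")

  sites <- alt_counts |>
    dplyr::group_by(.data$pos) |>
    dplyr::arrange(dplyr::desc(.data$count), .by_group = TRUE) |>
    dplyr::summarise(alts = list(.data$allele), counts = list(.data$count),
                     .groups = "drop")
  sites$depth <- depth[sites$pos]
  sites <- sites[sites$depth >= min_depth, ]
  if (!nrow(sites)) {
    return(structure(empty, ref_length = L,
                     class = c("variant_sites", class(empty))))
  }

  calls <- purrr::pmap_dfr(sites, function(pos, alts, counts, depth) {
    ref_count <- depth - sum(counts)
    frac <- counts / depth
    keep <- frac >= min_alt_fraction
    if (!any(keep)) return(NULL)
    alts <- alts[keep][seq_len(min(2L, sum(keep)))]
    counts <- counts[keep][seq_len(min(2L, sum(keep)))]
    gt_idx <- c(if (ref_count / depth >= min_alt_fraction) 0L, seq_along(alts))
    if (length(gt_idx) == 1L) gt_idx <- rep(gt_idx, 2L)  # fixed alt: 1/1
    variant_site_tibble(
      scaffold = subgenome, pos = pos, ref = ref_chars[pos],
      alt = paste(alts, collapse = ","),
      gt = paste(gt_idx, collapse = "/"),
      ad = list(as.integer(c(ref_count, counts))),
      depth = depth
    )
  })
  if (!nrow(calls)) calls <- empty
  structure(calls, ref_length = L,
            class = unique(c("variant_sites", class(calls))))
}

#' Import variant sites from a VCF file
#'
#' Reads the first sample's GT and AD fields and the INFO annotations used
#' by the hard filter (QD, FS, SOR, MQ, MQRankSum, ReadPosRankSum) into
#' the same tibble shape produced by [pileup_genotype()]. Assumes a
#' deduplicated, single-sample call set.
#'
#' @param path VCF 4.x file (plain text or bgzipped).
#' @return A `variant_sites` tibble.
#' @export
read_vcf_sites <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- unname(vcfR::extract.gt(v, element = "GT")[, 1])
  ad <- unname(vcfR::extract.gt(v, element = "AD")[, 1])
  info_num <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    suppressWarnings(as.numeric(x))
  }
  ad_list <- lapply(strsplit(ad, ",", fixed = TRUE), function(x) {
    suppressWarnings(as.integer(x))
  })
  out <- variant_site_tibble(
    scaffold = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT, gt = gsub("\\|", "/", gt), ad = ad_list,
    depth = vapply(ad_list, function(x) sum(x, na.rm = TRUE), integer(1)),
    qd = info_num("QD"), fs = info_num("FS"), sor = info_num("SOR"),
    mq = info_num("MQ"), mq_rank_sum = info_num("MQRankSum"),
    read_pos_rank_sum = info_num("ReadPosRankSum")
  )
  structure(out, class = unique(c("variant_sites", class(out))))
}

#' GATK-style hard filter for raw SNP calls
#'
#' Removes sites matching any of the classic hard-filter criteria:
#' `QD < 5.0`, `FS > 55`, `SOR > 2.0`, `MQ < 40`, `MQRankSum < -5.0`,
#' `ReadPosRankSum < -5.0`. A missing annotation means that criterion is
#' not applied (the site passes that check), so sites from the built-in
#' caller, which reports no annotations, pass through. Optionally retains
#' only biallelic genotypes afterwards, the final call-set convention for
#' heterozygosity maps.
#'
#' @param sites A `variant_sites` tibble.
#' @param max_fs,min_qd,max_sor,min_mq,min_mq_rank_sum,min_read_pos_rank_sum
#'   Filter thresholds (defaults as above).
#' @param biallelic_only Keep only sites classified biallelic by
#'   [classify_allelic_state()] (default `FALSE`).
#' @return The filtered `variant_sites` tibble.
#' @export
hard_filter <- function(sites, min_qd = 5.0, max_fs = 55, max_sor = 2.0,
                        min_mq = 40, min_mq_rank_sum = -5.0,
                        min_read_pos_rank_sum = -5.0,
                        biallelic_only = FALSE) {
  fails <- function(x, bad) !is.na(x) & bad
  drop <- fails(sites$qd, sites$qd < min_qd) |
    fails(sites$fs, sites$fs > max_fs) |
    fails(sites$sor, sites$sor > max_sor) |
    fails(sites$mq, sites$mq < min_mq) |
    fails(sites$mq_rank_sum, sites$mq_rank_sum < min_mq_rank_sum) |
    fails(sites$read_pos_rank_sum, sites$read_pos_rank_sum < min_read_pos_rank_sum)
  out <- sites[!drop, ]
  if (biallelic_only) {
    out <- out[classify_allelic_state(out)$allelic_state == "biallelic", ]
  }
  out
}

#' Classify sites as bi-allelic, tri-allelic or other
#'
#' Applies the GT/AD rule used for manual extraction of allelic states in
#' polyploid call sets: a `0/1` genotype is bi-allelic; a `1/2` genotype
#' is bi-allelic when fewer than `ref_threshold` (default 5%) of the total
#' reads support the reference allele, and tri-allelic when the reference
#' plus two alternative alleles are all supported (reference fraction at
#' or above the threshold). Everything else is `other`. The
#' classification depends only on depth ratios, so scaling all AD values
#' leaves it unchanged.
#'
#' @param sites A `variant_sites` tibble with GT and AD present.
#' @param ref_threshold Reference-read fraction below which a `1/2` site
#'   counts as bi-allelic (default 0.05).
#' @param strict_01 Alternative reading that applies the reference-fraction
#'   rule to `0/1` genotypes as well (a `0/1` site with reference fraction
#'   at or above the threshold becomes `other`). Default `FALSE`:
#'   `0/1` is bi-allelic unconditionally.
#' @return The input tibble with an `allelic_state` column.
#' @export
classify_allelic_state <- function(sites, ref_threshold = 0.05,
                                   strict_01 = FALSE) {
  if (any(vapply(sites$ad, function(x) !length(x) || anyNA(x), logical(1)))) {
    abort("AD field missing for some sites; cannot classify allelic state.")
  }
  ref_frac <- vapply(sites$ad, function(x) x[1] / sum(x), numeric(1))
  state <- dplyr::case_when(
    sites$gt == "0/1" & !strict_01 ~ "biallelic",
    sites$gt == "0/1" & strict_01 & ref_frac < ref_threshold ~ "biallelic",
    sites$gt == "0/1" ~ "other",
    sites$gt == "1/2" & ref_frac < ref_threshold ~ "biallelic",
    sites$gt == "1/2" ~ "triallelic",
    TRUE ~ "other"
  )
  dplyr::mutate(sites, allelic_state = state)
}

is_heterozygous_gt <- function(gt) {
  parts <- strsplit(gt, "/", fixed = TRUE)
  vapply(parts, function(p) length(unique(p)) >= 2, logical(1))
}

#' Heterozygous-SNP density in non-overlapping windows
#'
#' Counts filtered heterozygous sites in consecutive windows along the
#' reference, the track used to visualize heterozygosity and spot LOH
#' tracts, and reports the genome-wide heterozygosity percentage
#' (`100 * heterozygous sites / reference length`).
#'
#' @param sites A `variant_sites` tibble (ideally hard-filtered,
#'   biallelic).
#' @param window Window size in bp (default 10000).
#' @param ref_length Reference length; defaults to the `ref_length`
#'   attribute carried from [pileup_genotype()].
#' @return A `het_windows` tibble: `start`, `end` (0-based half-open),
#'   `n_het`. Attribute `pct_heterozygosity` carries the genome-wide
#'   percentage.
#' @export
het_density_windows <- function(sites, window = 10000, ref_length = NULL) {
  ref_length <- ref_length %||% attr(sites, "ref_length")
  if (is.null(ref_length)) abort("ref_length is required.")
  het_pos <- sites$pos[is_heterozygous_gt(sites$gt)]
  starts <- seq(0L, ref_length - 1L, by = window)
  ends <- pmin(starts + window, ref_length)
  n_het <- tabulate(findInterval(het_pos - 1L, starts), nbins = length(starts))
  out <- tibble(start = starts, end = ends, n_het = as.integer(n_het))
  structure(out,
            class = unique(c("het_windows", class(out))),
            pct_heterozygosity = 100 * length(het_pos) / ref_length,
            ref_length = ref_length, window = window)
}

#' Detect loss-of-heterozygosity segments from a density track
#'
#' Emits maximal runs of at least `min_windows` consecutive windows whose
#' heterozygous-SNP count does not exceed `max_het_per_window`, as
#' BED-style 0-based half-open segments. On an entirely homozygous track
#' this is a single segment spanning the reference.
#'
#' @param windows A `het_windows` tibble.
#' @param max_het_per_window Maximum count for a window to qualify
#'   (default 1).
#' @param min_windows Minimum run length in windows (default 5).
#' @return Tibble of segments: `start`, `end`, `n_windows`.
#' @export
detect_loh <- function(windows, max_het_per_window = 1, min_windows = 5) {
  low <- windows$n_het <= max_het_per_window
  r <- rle(low)
  ends_i <- cumsum(r$lengths)
  starts_i <- c(1L, head(ends_i, -1) + 1L)
  keep <- r$values & r$lengths >= min_windows
  tibble(
    start = windows$start[starts_i[keep]],
    end = windows$end[ends_i[keep]],
    n_windows = r$lengths[keep]
  )
}

#' Minor-allele balance in non-overlapping windows
#'
#' At each biallelic site the minor-allele fraction of the read depth is
#' `min(AD) / sum(AD)`; windowed means plus the global distribution mode
#' diagnose ploidy: heterozygous sites on one of two copies cluster at
#' 1/2, on one of three copies at 1/3.
#'
#' @param sites Biallelic `variant_sites` with AD.
#' @param window Window size in bp (default 2000).
#' @param ref_length Reference length; defaults to the attribute.
#' @return A tibble of windows (`start`, `end`, `n_sites`,
#'   `mean_minor_fraction`) with attributes `mode` (density peak of the
#'   per-site fractions), `interpretation` (`"diploid-like"`,
#'   `"triploid-like"` or `"indeterminate"`) and `site_fractions`.
#' @export
minor_allele_windows <- function(sites, window = 2000, ref_length = NULL) {
  ref_length <- ref_length %||% attr(sites, "ref_length")
  if (is.null(ref_length)) abort("ref_length is required.")
  if (!nrow(sites)) {
    out <- tibble(start = integer(), end = integer(), n_sites = integer(),
                  mean_minor_fraction = numeric())
    return(structure(out, mode = NA_real_, interpretation = "empty",
                     site_fractions = numeric()))
  }
  use_two <- function(x) sort(x, decreasing = TRUE)[1:2]
  frac <- vapply(sites$ad, function(x) {
    two <- use_two(x)
    min(two) / sum(two)
  }, numeric(1))
  starts <- seq(0L, ref_length - 1L, by = window)
  ends <- pmin(starts + window, ref_length)
  bin <- findInterval(sites$pos - 1L, starts)
  out <- tibble(
    start = starts, end = ends,
    n_sites = as.integer(tabulate(bin, nbins = length(starts))),
    mean_minor_fraction = as.numeric(tapply(frac, factor(bin, levels = seq_along(starts)),
                                            mean))
  )
  if (length(frac) >= 10) {
    ## reflect around 1/2 before the KDE: the folded minor fraction is
    ## bounded at 0.5, which would bias a naive mode estimate downward
    d <- density(c(frac, 1 - frac), from = 0.02, to = 0.98, bw = 0.02)
    peak <- d$x[which.max(d$y)]
    mode <- min(peak, 1 - peak)
  } else {
    mode <- median(frac)
  }
  interp <- dplyr::case_when(
    abs(mode - 0.5) <= 0.06 ~ "diploid-like",
    abs(mode - 1 / 3) <= 0.06 ~ "triploid-like",
    TRUE ~ "indeterminate"
  )
  structure(out, mode = mode, interpretation = interp, site_fractions = frac)
}
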