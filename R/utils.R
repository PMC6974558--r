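## Shared internal helpers.

DNA_BASES <- c("A", "C", "G", "T")

## IUPAC two-fold degeneracy codes for heterozygous Sanger consensus positions.
IUPAC2 <- c(
  "AG" = "R", "CT" = "Y", "CG" = "S", "AT" = "W", "GT" = "K", "AC" = "M"
)
IUPAC2_SPLIT <- list(
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
  W = c("A", "T"), K = c("G", "T"), M = c("A", "C")
)

#' Round half away from zero
#'
#' Fixed-precision rounding where `.5` always rounds up, matching how
#' percentages and rates are conventionally reported in diversity tables
#' (base R's `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(2.005, 10.2445), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## reverse complement of plain character DNA (vectorized)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## split one sequence into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

## truncated-geometric distribution of consecutive selfing generations:
## P(t) = (1 - s) s^t for t < t_max, with the full geometric tail mass
## s^t_max lumped at t_max (so the weights sum to one exactly and s = 1
## degenerates to a point mass at t_max)
selfing_t_weights <- function(s, t_max) {
  if (s >= 1) return(c(rep(0, t_max), 1))
  t <- 0:t_max
  w <- (1 - s) * s^t
  w[t_max + 1] <- s^t_max
  w
}

## reduce an integer ratio, e.g. c(4, 2) -> "2:1"
reduce_ratio <- function(a, b) {
  if (a == 0 && b == 0) return("0:0")
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  d <- g(max(a, b), min(a, b))
  if (d == 0) d <- 1
  paste0(a / d, ":", b / d)
}

## write a tabular file with '# key: value' provenance header lines
write_tsv_provenance <- function(x, path, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(provenance)) {
    writeLines(sprintf("# %s: %s", names(provenance),
                       vapply(provenance, paste, character(1), collapse = " ")),
               con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
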