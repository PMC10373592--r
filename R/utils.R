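# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over plain character vectors. Uses
#' [Biostrings::reverseComplement()] so IUPAC codes are handled.
#'
#' @param x character vector of DNA strings (A/C/G/T plus IUPAC codes).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substring by 0-based half-open interval [start, end)
substr0 <- function(x, start, end) substr(x, start + 1L, end)

# all 0-based start offsets of exact occurrences of `pattern` in `x`
find_all <- function(pattern, x) {
  if (nchar(pattern) == 0L || nchar(pattern) > nchar(x)) return(integer(0))
  m <- gregexpr(pattern, x, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  as.integer(m) - 1L
}

# round half away from zero at `digits` decimals (printed-table convention;
# base round() is banker's rounding)
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# percentage with the printed-precision rule: one decimal below 10, integer at
# or above 10
fmt_pct_value <- function(pct) {
  ifelse(is.na(pct), NA_real_,
         ifelse(abs(pct) < 10, round_half_up(pct, 1L), round_half_up(pct, 0L)))
}

# render "N (P)" cells used by variant-frequency tables
fmt_count_pct <- function(count, total) {
  pct <- 100 * count / total
  pct[rep_len(total <= 0, length(pct))] <- NA_real_
  v <- fmt_pct_value(pct)
  txt <- ifelse(is.na(v), "NA",
                ifelse(abs(v) < 10, sprintf("%.1f", v), sprintf("%d", as.integer(v))))
  sprintf("%d (%s)", as.integer(count), txt)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# a base different from `b`, deterministic under the current RNG
other_base <- function(b) sample(setdiff(DNA_BASES, b), 1L)

stop_locus <- function(file, line, msg) {
  stop(sprintf("%s%s%s", if (!is.null(file)) paste0(file, ":") else "",
               if (!is.null(line)) paste0(line, ": ") else "", msg), call. = FALSE)
}
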