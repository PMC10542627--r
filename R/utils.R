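#' @keywords internal
"_PACKAGE"

#' @importFrom stats pchisq rbinom rmultinom rnorm runif
#' @importFrom utils read.delim write.table
NULL

# Classed error constructor so callers/tests can match on condition class.
sr_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "spliceReporter_error")))
}

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over plain character vectors. `N` maps to `N`.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, either case).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# Fast substring of a single sequence over many 0-based half-open intervals.
substr0 <- function(seq, start0, end0) {
  substring(seq, start0 + 1L, end0)
}

# Validate 0-based half-open interval(s) within [0, len).
check_intervals <- function(start0, end0, len, what = "interval") {
  bad <- start0 < 0 | end0 > len | start0 > end0
  if (any(bad)) {
    sr_stop(sprintf("%s outside [0, %d) or inverted: [%d, %d)",
                    what, len, start0[bad][1], end0[bad][1]),
            "sr_validation_error")
  }
  invisible(TRUE)
}

# Probability-vector check (sums to 1 within 1e-9, non-negative).
check_prob <- function(p, name) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    sr_stop(sprintf("'%s' must be a non-negative vector summing to 1", name),
            "sr_config_error")
  }
  invisible(TRUE)
}

# Sample n random bases, uniform over ACGT (assumes caller set the RNG state).
random_bases <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# n random codons avoiding stop codons (and optionally ATG), as one string.
random_codons <- function(n, avoid_atg = FALSE) {
  if (n <= 0) return("")
  alphabet <- c("A", "C", "G", "T")
  codons <- expand.grid(alphabet, alphabet, alphabet, stringsAsFactors = FALSE)
  codons <- paste0(codons[[1]], codons[[2]], codons[[3]])
  drop <- STOP_CODONS
  if (avoid_atg) drop <- c(drop, "ATG")
  codons <- setdiff(codons, drop)
  paste(sample(codons, n, replace = TRUE), collapse = "")
}

# Split a string into codons starting at 0-based offset `from` (full codons only).
codon_split <- function(seq, from = 0L) {
  n <- (nchar(seq) - from) %/% 3L
  if (n <= 0) return(character(0))
  starts <- from + 3L * (seq_len(n) - 1L)
  substring(seq, starts + 1L, starts + 3L)
}
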