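#' Size-class / strand profile of a mapped small-RNA library
#'
#' Tabulates reads by (length, strand) and normalises to reads per million.
#' Reads with several equally good hit positions contribute weight
#' `1/n_hits` per hit so that every read counts exactly once in total.
#'
#' @param assignments alignment data.frame from [map_library()] (needs
#'   `read_len`, `strand`, `n_hits`).
#' @param library_size normalisation denominator; by default the number of
#'   reads passing the length filter (see the `library_size` element of
#'   [map_library()]'s result). Must be at least the number of assigned reads.
#' @param lengths length classes tabulated (zero-filled when absent).
#' @param sample sample label carried into the profile.
#' @return a `size_strand_profile`: data.frame with `length`, `strand`,
#'   `count`, `rpm`; attributes `sample` and `library_size`.
#' @export
size_strand_table <- function(assignments, library_size,
                              lengths = 18:30, sample = "sample") {
  if (library_size <= 0) {
    sr_stop("library_size must be positive for RPM normalisation",
            "sr_normalization_error")
  }
  n_reads <- length(unique(assignments$read_id))
  if (library_size < n_reads) {
    sr_stop("library_size smaller than the number of assigned reads",
            "sr_validation_error")
  }
  grid <- expand.grid(length = lengths, strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  w <- 1 / assignments$n_hits
  key <- paste(assignments$read_len, assignments$strand)
  agg <- tapply(w, key, sum)
  grid$count <- as.numeric(agg[paste(grid$length, grid$strand)])
  grid$count[is.na(grid$count)] <- 0
  grid$rpm <- grid$count * 1e6 / library_size
  structure(grid, class = c("size_strand_profile", "data.frame"),
            sample = sample, library_size = library_size)
}

#' Modal read length of a profile
#'
#' @param profile a `size_strand_profile`.
#' @return the length class with the highest total RPM (`NA` if empty).
#' @export
modal_length <- function(profile) {
  tot <- tapply(profile$rpm, profile$length, sum)
  if (all(tot == 0)) return(NA_integer_)
  as.integer(names(tot)[which.max(tot)])
}

#' Per-position coverage-per-million track
#'
#' Every hit adds `(1 / n_hits) * 1e6 / library_size` to each reference
#' position in its blocks (every aligned base counts, not just 5' ends),
#' optionally restricted to a length class and strand.
#'
#' @param assignments alignment data.frame from [map_library()].
#' @param locus a `reporter_locus`.
#' @param library_size RPM denominator.
#' @param length_class one of 21, 22, 24 or "all".
#' @param strand "+", "-" or "both".
#' @param sample sample label.
#' @return a `coverage_track`: list with `values` (numeric, one per locus
#'   position), `sample`, `length_class`, `strand`, `reference`.
#' @export
coverage_track <- function(assignments, locus, library_size,
                           length_class = "all", strand = "both",
                           sample = "sample") {
  if (library_size <= 0) {
    sr_stop("library_size must be positive for RPM normalisation",
            "sr_normalization_error")
  }
  L <- nchar(locus$sequence)
  validate_alignments(assignments, reference_length = L)
  sel <- rep(TRUE, nrow(assignments))
  if (!identical(length_class, "all")) {
    sel <- sel & assignments$read_len == as.integer(length_class)
  }
  if (strand != "both") sel <- sel & assignments$strand == strand
  a <- assignments[sel, , drop = FALSE]

  delta <- numeric(L + 1L)
  add <- function(s0, e0, w) {
    # delta-encoding: +w at block start, -w one past block end, then cumsum
    acc <- rowsum(c(w, -w), group = c(s0, e0))
    pos <- as.integer(rownames(acc)) + 1L
    delta[pos] <<- delta[pos] + acc[, 1]
  }
  if (nrow(a)) {
    w <- (1 / a$n_hits) * 1e6 / library_size
    add(a$start1, a$end1, w)
    split2 <- !is.na(a$start2)
    if (any(split2)) add(a$start2[split2], a$end2[split2], w[split2])
  }
  values <- cumsum(delta)[seq_len(L)]
  values[values < 0 & values > -1e-8] <- 0   # float dust from the cumsum
  structure(list(values = values, sample = sample,
                 length_class = as.character(length_class), strand = strand,
                 reference = locus$name),
            class = "coverage_track")
}

#' Compare two size/strand profiles
#'
#' Per-(length, strand) RPM ratios (`a / b`) and differences. Zero
#' denominators are flagged, never silently replaced: `infinite` when only
#' the denominator is zero, `undefined` when both sides are zero.
#'
#' @param profile_a,profile_b `size_strand_profile`s over the same key set.
#' @return data.frame with `length`, `strand`, `rpm_a`, `rpm_b`, `ratio`,
#'   `difference`, `flag`; attribute `total_ratio` (total RPM a / total
#'   RPM b).
#' @export
compare_profiles <- function(profile_a, profile_b) {
  key_a <- paste(profile_a$length, profile_a$strand)
  key_b <- paste(profile_b$length, profile_b$strand)
  if (!identical(sort(key_a), sort(key_b))) {
    sr_stop("profiles are keyed over different (length, strand) sets",
            "sr_validation_error")
  }
  b <- profile_b[match(key_a, key_b), , drop = FALSE]
  out <- data.frame(length = profile_a$length, strand = profile_a$strand,
                    rpm_a = profile_a$rpm, rpm_b = b$rpm,
                    stringsAsFactors = FALSE)
  out$ratio <- ifelse(out$rpm_b > 0, out$rpm_a / out$rpm_b, NA_real_)
  out$difference <- out$rpm_a - out$rpm_b
  out$flag <- ifelse(out$rpm_b > 0, "ok",
                     ifelse(out$rpm_a > 0, "infinite", "undefined"))
  tot_b <- sum(out$rpm_b)
  attr(out, "total_ratio") <- if (tot_b > 0) sum(out$rpm_a) / tot_b else NA_real_
  out
}
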