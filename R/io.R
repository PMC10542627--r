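#' Alignment data.frame constructor
#'
#' The pipeline's in-memory alignment container: one row per alignment, with
#' split alignments carried as up to two reference blocks. All coordinates
#' are 0-based half-open; conversion to 1-based happens only at the SAM
#' boundary.
#'
#' @param read_id character ids.
#' @param strand "+" or "-".
#' @param start1,end1 first (or only) reference block.
#' @param start2,end2 second block for split alignments (`NA` otherwise).
#' @param ... additional columns recycled to length (e.g. `sequence`,
#'   `mismatches`, `tier`, `mate`, `variant`).
#' @return a data.frame of class `c("sr_alignments", "data.frame")`.
#' @export
alignment_frame <- function(read_id, strand, start1, end1,
                            start2 = NA_integer_, end2 = NA_integer_, ...) {
  n <- length(read_id)
  if (length(start2) == 1L) start2 <- rep(start2, n)
  if (length(end2) == 1L) end2 <- rep(end2, n)
  df <- data.frame(read_id = as.character(read_id), strand = strand,
                   start1 = as.integer(start1), end1 = as.integer(end1),
                   start2 = as.integer(start2), end2 = as.integer(end2),
                   ..., stringsAsFactors = FALSE)
  validate_alignments(df)
  df
}

#' Validate an alignment data.frame
#'
#' @param alignments alignment data.frame.
#' @param reference_length optional; when given, blocks must lie within
#'   `[0, reference_length)`.
#' @return the input, invisibly; errors with class `sr_validation_error`.
#' @export
validate_alignments <- function(alignments, reference_length = NULL) {
  need <- c("read_id", "strand", "start1", "end1", "start2", "end2")
  miss <- setdiff(need, names(alignments))
  if (length(miss)) {
    sr_stop(paste("alignment frame missing columns:", paste(miss, collapse = ", ")),
            "sr_validation_error")
  }
  if (nrow(alignments) == 0) return(invisible(alignments))
  if (any(!alignments$strand %in% c("+", "-"))) {
    sr_stop("strand must be '+' or '-'", "sr_validation_error")
  }
  if (any(alignments$start1 >= alignments$end1)) {
    sr_stop("empty or inverted first block", "sr_validation_error")
  }
  split <- !is.na(alignments$start2)
  if (any(split & is.na(alignments$end2))) {
    sr_stop("start2 without end2", "sr_validation_error")
  }
  if (any(split & (alignments$end1 >= alignments$start2 |
                   alignments$start2 >= alignments$end2), na.rm = TRUE)) {
    sr_stop("blocks must be sorted and disjoint with a positive gap",
            "sr_validation_error")
  }
  if (!is.null(reference_length)) {
    hi <- pmax(alignments$end1, alignments$end2, na.rm = TRUE)
    if (any(alignments$start1 < 0 | hi > reference_length)) {
      sr_stop("alignment block outside the reference", "sr_validation_error")
    }
  }
  invisible(alignments)
}

#' Total aligned width per alignment row
#'
#' @param alignments alignment data.frame.
#' @return integer vector of summed block widths.
#' @export
aligned_width <- function(alignments) {
  w <- alignments$end1 - alignments$start1
  split <- !is.na(alignments$start2)
  w[split] <- w[split] + (alignments$end2[split] - alignments$start2[split])
  w
}

#' Read a FASTA file
#'
#' Thin wrapper over Biostrings that validates basic record structure first
#' (so malformed input is rejected with a line number, never silently
#' skipped) and preserves sequence text verbatim, including case.
#'
#' @param path file path.
#' @return named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) return(stats::setNames(character(0), character(0)))
  if (!startsWith(lines[nonblank[1]], ">")) {
    sr_stop(sprintf("malformed FASTA: line %d does not start a record",
                    nonblank[1]),
            "sr_parse_error")
  }
  set <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Write sequences as FASTA
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::BStringSet(records)
  names(set) <- names(records)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a FASTQ file (sequences only)
#'
#' @param path file path.
#' @return named character vector of sequences; qualities are not retained
#'   (the pipeline is quality-unaware).
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readBStringSet(path, format = "fastq")
  stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
}

#' Write sequences as FASTQ with uniform quality
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @param quality single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path, quality = "I") {
  lines <- as.vector(rbind(paste0("@", names(records)),
                           unname(records),
                           "+",
                           vapply(nchar(records),
                                  function(n) strrep(quality, n),
                                  character(1))))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a simulation configuration as YAML
#'
#' @param cfg a `sim_config`.
#' @param path file path.
#' @return `path` invisibly for the writer; a validated `sim_config` for the
#'   reader (unknown keys are rejected).
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  vecs <- c("variant_mix", "size_mix", "source_weights",
            "source_variant_weights")
  for (v in intersect(vecs, names(raw))) raw[[v]] <- unlist(raw[[v]])
  do.call(default_config, c(list(seed = raw$seed),
                            raw[setdiff(names(raw), "seed")]))
}

# CIGAR string for one alignment row (M blocks separated by an N gap).
cigar_of <- function(alignments) {
  w1 <- alignments$end1 - alignments$start1
  split <- !is.na(alignments$start2)
  cig <- paste0(w1, "M")
  cig[split] <- paste0(w1[split], "M",
                       alignments$start2[split] - alignments$end1[split], "N",
                       alignments$end2[split] - alignments$start2[split], "M")
  cig
}

#' Write alignments as SAM text
#'
#' Minimal single-reference SAM: split blocks become `M`-`N`-`M` CIGARs,
#' strand is FLAG bit 16, POS is 1-based (internal coordinates are 0-based
#' half-open). If the alignment frame carries `sequence` (read as sequenced),
#' SEQ is emitted in reference orientation, i.e. reverse-complemented for
#' minus-strand records; `mismatches` becomes an `NM:i` tag and `tier` an
#' `XT:i` tag.
#'
#' @param alignments alignment data.frame.
#' @param reference list with `name` and `length` (a `reporter_locus` works).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reference, path) {
  if (inherits(reference, "reporter_locus")) {
    reference <- list(name = reference$name, length = nchar(reference$sequence))
  }
  validate_alignments(alignments, reference_length = reference$length)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", reference$name, reference$length))
  n <- nrow(alignments)
  if (n == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  flag <- ifelse(alignments$strand == "-", 16L, 0L)
  seq <- rep("*", n)
  if (!is.null(alignments$sequence)) {
    seq <- alignments$sequence
    neg <- alignments$strand == "-"
    seq[neg] <- revcomp(seq[neg])
  }
  rec <- paste(alignments$read_id, flag, reference$name,
               alignments$start1 + 1L, 255L, cigar_of(alignments),
               "*", 0L, 0L, seq, "*", sep = "\t")
  if (!is.null(alignments$mismatches)) {
    rec <- paste0(rec, "\tNM:i:", alignments$mismatches)
  }
  if (!is.null(alignments$tier)) {
    rec <- paste0(rec, "\tXT:i:", alignments$tier)
  }
  writeLines(c(header, rec), path)
  invisible(path)
}

#' Read a SAM file into an alignment data.frame
#'
#' Inverse of [write_sam()] on the minimal SAM dialect the pipeline writes;
#' general CIGARs are resolved through GenomicAlignments, with at most one
#' `N` gap per record (more is rejected). Coordinates come back 0-based.
#'
#' @param path SAM file path.
#' @return alignment data.frame with a `reference` attribute
#'   (`list(name, length)`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_h <- startsWith(lines, "@")
  ref <- list(name = NA_character_, length = NA_integer_)
  sq <- lines[is_h & startsWith(lines, "@SQ")]
  if (length(sq)) {
    f <- strsplit(sq[1], "\t", fixed = TRUE)[[1]]
    ref$name <- sub("^SN:", "", f[grepl("^SN:", f)][1])
    ref$length <- as.integer(sub("^LN:", "", f[grepl("^LN:", f)][1]))
  }
  body_idx <- which(!is_h & nzchar(lines))
  if (length(body_idx) == 0) {
    out <- alignment_frame(character(0), character(0), integer(0), integer(0))
    attr(out, "reference") <- ref
    return(out)
  }
  parts <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    sr_stop(sprintf("malformed SAM record at line %d (%d fields)",
                    body_idx[which(nf < 11L)[1]], min(nf)),
            "sr_parse_error")
  }
  qname <- vapply(parts, `[[`, character(1), 1L)
  flag <- as.integer(vapply(parts, `[[`, character(1), 2L))
  pos <- as.integer(vapply(parts, `[[`, character(1), 4L))
  cigar <- vapply(parts, `[[`, character(1), 6L)
  seq <- vapply(parts, `[[`, character(1), 10L)
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")

  blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = c("M", "=", "X", "D"), reduce.ranges = TRUE)
  nb <- lengths(blocks)
  if (any(nb > 2L)) {
    sr_stop("SAM record with more than one splice gap is not supported",
            "sr_parse_error")
  }
  s1 <- vapply(seq_along(blocks), function(i) IRanges::start(blocks[[i]])[1], integer(1)) - 1L
  e1 <- vapply(seq_along(blocks), function(i) IRanges::end(blocks[[i]])[1], integer(1))
  s2 <- rep(NA_integer_, length(nb))
  e2 <- rep(NA_integer_, length(nb))
  two <- which(nb == 2L)
  s2[two] <- vapply(two, function(i) IRanges::start(blocks[[i]])[2], integer(1)) - 1L
  e2[two] <- vapply(two, function(i) IRanges::end(blocks[[i]])[2], integer(1))

  # SEQ back to as-sequenced orientation
  has_seq <- seq != "*"
  neg <- strand == "-" & has_seq
  seq[neg] <- revcomp(seq[neg])
  seq[!has_seq] <- NA_character_

  tag_val <- function(prefix) {
    vapply(parts, function(p) {
      hit <- p[grepl(prefix, p)]
      if (length(hit)) as.integer(sub(prefix, "", hit[1])) else NA_integer_
    }, integer(1))
  }
  out <- alignment_frame(qname, strand, s1, e1, s2, e2,
                         sequence = seq,
                         mismatches = tag_val("^NM:i:"),
                         tier = tag_val("^XT:i:"))
  attr(out, "reference") <- ref
  out
}

#' Write a coverage track as bedGraph
#'
#' Adjacent equal-value runs are merged and zero runs dropped (an all-zero
#' track yields an empty data section). 0-based half-open convention.
#'
#' @param track a `coverage_track` (see [coverage_track()]) or a bare numeric
#'   vector of per-position values.
#' @param path output path.
#' @param name reference sequence name (taken from the track if present).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, name = NULL) {
  values <- if (inherits(track, "coverage_track")) track$values else track
  if (is.null(name)) {
    name <- if (inherits(track, "coverage_track")) track$reference else "track"
  }
  if (any(values < 0)) {
    sr_stop("coverage values must be non-negative", "sr_validation_error")
  }
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  gr <- GenomicRanges::GRanges(
    seqnames = rep(name, sum(keep)),
    ranges = IRanges::IRanges(start = starts[keep] + 1L, end = ends[keep]),
    score = r$values[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path bedGraph path.
#' @param length optional track length; when given, the result is expanded to
#'   a per-position numeric vector (positions absent from the file are 0).
#' @return with `length`: numeric vector; otherwise a data.frame with
#'   0-based half-open `start`, `end` and `value`.
#' @export
read_bedgraph <- function(path, length = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   value = gr$score)
  if (is.null(length)) return(df)
  v <- numeric(length)
  for (i in seq_len(nrow(df))) {
    v[(df$start[i] + 1L):df$end[i]] <- df$value[i]
  }
  v
}

#' Write a pipeline table as TSV with a commented header
#'
#' @param df data.frame.
#' @param path output path.
#' @param what short description recorded in the comment line.
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(df, path, what = "table") {
  version <- as.character(utils::packageVersion("spliceReporter"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spliceReporter %s; %s; columns: %s",
                     version, what, paste(names(df), collapse = ", ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_commented()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_commented <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
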