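#' Read organelle-vs-nucleus alignment hits (BLAST tabular, outfmt 6)
#'
#' Parses the 12-column BLAST tabular dialect (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`) where the
#' query is the organelle genome and the subject is a nuclear chromosome.
#' Input coordinates are 1-based inclusive; they are converted to 0-based
#' half-open and reversed subject coordinates are normalized with strand
#' `"-"` (see [normalize_hits()]).
#'
#' @param path Path to a tab-separated hits file (lines starting with `#`
#'   are ignored).
#' @return Tibble with columns `source_id`, `chrom`, `identity`,
#'   `aln_length`, `mismatches`, `gap_opens`, `source_start`, `source_end`,
#'   `target_start`, `target_end`, `strand`, `evalue`, `bit_score`.
#' @export
read_blast_hits <- function(path) {
  cols <- c("source_id", "chrom", "identity", "aln_length", "mismatches",
            "gap_opens", "source_start", "source_end", "target_start",
            "target_end", "evalue", "bit_score")
  raw <- readr::read_tsv(
    path,
    col_names = cols,
    col_types = readr::cols(
      source_id = readr::col_character(),
      chrom = readr::col_character(),
      .default = readr::col_double()
    ),
    comment = "#",
    progress = FALSE
  )
  num <- setdiff(cols, c("source_id", "chrom"))
  for (cn in num) {
    bad <- which(!is.finite(raw[[cn]]))
    if (length(bad) > 0) {
      abort(paste0("non-numeric value in column '", cn, "' at line ", bad[1],
                   " of ", path))
    }
  }
  if (any(raw$identity < 0 | raw$identity > 100)) {
    abort(paste0("identity out of range [0,100] at line ",
                 which(raw$identity < 0 | raw$identity > 100)[1], " of ", path))
  }
  if (any(raw$aln_length < 1)) abort("alignment length must be >= 1")
  normalize_hits(raw)
}

#' Normalize alignment-hit coordinates
#'
#' Converts 1-based inclusive hit coordinates to the internal 0-based
#' half-open convention and folds reversed coordinate pairs into a strand
#' column. Idempotent: hits that already carry a `strand` column and
#' forward-ordered coordinates are returned unchanged, so normalizing twice
#' equals normalizing once.
#'
#' @param hits Tibble of alignment hits as read from BLAST tabular output.
#' @return Normalized tibble with `strand` in `{+,-}` and
#'   `start < end` on both the source and the target, 0-based half-open.
#' @export
normalize_hits <- function(hits) {
  h <- as_tibble(hits)
  if (!"strand" %in% names(h)) {
    # raw 1-based inclusive orientation-carrying coordinates
    rev_t <- h$target_start > h$target_end
    rev_s <- h$source_start > h$source_end
    h$strand <- ifelse(xor(rev_s, rev_t), "-", "+")
    ts <- pmin(h$target_start, h$target_end) - 1
    te <- pmax(h$target_start, h$target_end)
    ss <- pmin(h$source_start, h$source_end) - 1
    se <- pmax(h$source_start, h$source_end)
    h$target_start <- ts; h$target_end <- te
    h$source_start <- ss; h$source_end <- se
  }
  h
}

#' Write alignment hits as BLAST tabular (outfmt 6)
#'
#' Inverse of [read_blast_hits()]: internal 0-based half-open coordinates
#' are written 1-based inclusive and minus-strand hits are written with
#' reversed subject coordinates.
#'
#' @param hits Normalized hits tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_hits <- function(hits, path) {
  h <- normalize_hits(hits)
  minus <- h$strand == "-"
  ts1 <- h$target_start + 1
  te1 <- h$target_end
  out <- tibble(
    qseqid = h$source_id,
    sseqid = h$chrom,
    pident = h$identity,
    length = h$aln_length,
    mismatch = h$mismatches,
    gapopen = h$gap_opens,
    qstart = h$source_start + 1,
    qend = h$source_end,
    sstart = ifelse(minus, te1, ts1),
    send = ifelse(minus, ts1, te1),
    evalue = h$evalue,
    bitscore = h$bit_score
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
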