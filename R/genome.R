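#' Construct a genome object from named sequences
#'
#' A genome is an ordered set of named chromosome sequences together with
#' their lengths and the intervals of assembly gaps (maximal runs of `N`).
#' Sequences are upper-cased; IUPAC ambiguity codes other than `N` are kept
#' as literal bases and only `N` defines gaps.
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @return An object of class `genarch_genome`: a list with elements
#'   `seq` (named character), `lengths` (named integer) and `gaps`
#'   (tibble with `chrom`, `start`, `end`, 0-based half-open).
#' @examples
#' g <- genome(c(c1 = "ACGTNNNNACGT"))
#' genome_gaps(g)
#' @export
genome <- function(seqs) {
  if (!is.character(seqs) || length(seqs) == 0) {
    abort("`seqs` must be a non-empty named character vector")
  }
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) abort("all sequences must be named")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate id: ", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(seqs)
  gaps <- imap(seqs, function(s, id) {
    m <- gregexpr("N+", s)[[1]]
    if (m[1] == -1L) {
      return(tibble(chrom = character(), start = integer(), end = integer()))
    }
    tibble(
      chrom = id,
      start = as.integer(m) - 1L,
      end   = as.integer(m) - 1L + attr(m, "match.length")
    )
  }) |> list_rbind()
  structure(
    list(seq = seqs, lengths = nchar(seqs), gaps = gaps),
    class = "genarch_genome"
  )
}

#' @export
print.genarch_genome <- function(x, ...) {
  cat("<genarch_genome> ", length(x$seq), " sequence(s), ",
      format(sum(x$lengths), big.mark = ","), " bp total, ",
      nrow(x$gaps), " gap(s)\n", sep = "")
  lens <- x$lengths
  for (id in utils::head(names(lens), 12)) {
    cat("  ", id, ": ", format(lens[[id]], big.mark = ","), " bp\n", sep = "")
  }
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param g A `genarch_genome`.
#' @return Tibble with columns `chrom` and `length`.
#' @export
genome_lengths <- function(g) {
  stopifnot(inherits(g, "genarch_genome"))
  tibble(chrom = names(g$lengths), length = unname(g$lengths))
}

#' Assembly-gap intervals of a genome
#' @param g A `genarch_genome`.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @export
genome_gaps <- function(g) {
  stopifnot(inherits(g, "genarch_genome"))
  g$gaps
}

#' Read a genome from a FASTA file
#'
#' Reads with [Biostrings::readDNAStringSet()]; record ids are the first
#' whitespace-delimited token of each header. Duplicate ids and empty files
#' are errors. Gap intervals are computed from maximal `N` runs.
#'
#' @param path Path to a FASTA file.
#' @return A `genarch_genome`.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  names(seqs) <- ids
  genome(seqs)
}

#' Write a genome to a FASTA file (60-column wrap)
#' @param g A `genarch_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(g, path) {
  stopifnot(inherits(g, "genarch_genome"))
  ss <- Biostrings::DNAStringSet(g$seq)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Tile a genome into non-overlapping windows
#'
#' Tiles each chromosome `[0, L)` into `ceiling(L / window_size)` windows.
#' All windows have length `window_size` except possibly the last, which is
#' retained at its actual (shorter) length; per-window metrics downstream
#' are reported against the actual width.
#'
#' @param g A `genarch_genome`.
#' @param window_size Window size in bp (default 100 kb).
#' @return Tibble of class `genarch_grid` with `chrom`, `window` (1-based
#'   index within chromosome), `start`, `end`, `width`; attribute
#'   `window_size`.
#' @export
make_window_grid <- function(g, window_size = 1e5) {
  stopifnot(inherits(g, "genarch_genome"))
  if (!is.numeric(window_size) || length(window_size) != 1 || window_size < 1) {
    abort("`window_size` must be a single number >= 1")
  }
  window_size <- floor(window_size)
  grid <- imap(as.list(g$lengths), function(L, chrom) {
    starts <- seq(0, max(L - 1, 0), by = window_size)
    tibble(
      chrom = chrom,
      window = seq_along(starts),
      start = starts,
      end = pmin(starts + window_size, L)
    )
  }) |>
    list_rbind() |>
    mutate(width = .data$end - .data$start)
  attr(grid, "window_size") <- window_size
  class(grid) <- c("genarch_grid", class(grid))
  grid
}

# internal: window size of a grid (attribute survives most dplyr verbs we use)
grid_window_size <- function(grid) {
  ws <- attr(grid, "window_size")
  if (is.null(ws)) ws <- max(grid$width)
  ws
}

# internal: validate that a set of intervals refers to known chromosomes
check_chroms <- function(chroms, known, what = "interval") {
  bad <- setdiff(unique(chroms), known)
  if (length(bad) > 0) {
    abort(paste0("unknown chromosome in ", what, ": ", paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}
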