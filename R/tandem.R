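# Tandem-repeat monomer canonicalization and telomere/centromere calling.
#
# Repeat finders report the same tandem monomer phase-shifted (arbitrary
# rotation) and on either strand, so identical repeat families are split
# across records and their frequencies under-counted. The canonical form
# used throughout this module is the lexicographic minimum over all cyclic
# rotations of the monomer and of its reverse complement; merging records
# by canonical form restores family-level frequencies.

#' Reverse complement of nucleotide strings
#' @param x Character vector of ACGT(N) sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

#' Canonical form of a tandem-repeat monomer
#'
#' Returns the lexicographically smallest string among all cyclic rotations
#' of `x` and of its reverse complement (`2 * nchar(x)` candidates). The
#' canonical form identifies a repeat family regardless of the phase and
#' strand in which a repeat finder reported it; the operation is
#' idempotent.
#'
#' @param x Character vector of monomers (ACGT alphabet, non-empty).
#' @return Character vector of canonical monomers.
#' @examples
#' canonical_monomer("TTTAGGG") # telomere family -> "AAACCCT"
#' @export
canonical_monomer <- function(x) {
  if (length(x) == 0) return(character())
  if (any(is.na(x) | !nzchar(x))) abort("monomers must be non-empty")
  if (any(grepl("[^ACGT]", x))) {
    bad <- x[grepl("[^ACGT]", x)][1]
    abort(paste0("non-ACGT symbol in monomer: ", bad))
  }
  vapply(x, function(s) {
    n <- nchar(s)
    min(vapply(list(s, revcomp(s)), function(v) {
      d <- paste0(v, v)
      min(substring(d, seq_len(n), seq_len(n) + n - 1L))
    }, character(1)))
  }, character(1), USE.NAMES = FALSE)
}

#' Parse tandem-repeat records from a TRF .dat file
#'
#' Understands the Tandem Repeats Finder `.dat` dialect: `Sequence: <id>`
#' headers followed by space-separated records whose first four fields are
#' `start end period copy_number` (1-based inclusive) and whose 14th field
#' is the consensus monomer. Records with period above `max_period` are
#' dropped (a message reports how many); a record before any `Sequence:`
#' header is an error.
#'
#' @param path Path to a `.dat` file.
#' @param max_period Maximum monomer length retained (default 500 bp).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `period`, `copy_number`, `monomer`.
#' @export
parse_trf_dat <- function(path, max_period = 500) {
  lines <- readLines(path)
  out <- list()
  chrom <- NA_character_
  dropped <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "Sequence:")) {
      chrom <- trimws(sub("^Sequence:", "", ln))
      chrom <- sub("\\s.*$", "", chrom)
      next
    }
    if (startsWith(ln, "Parameters:")) next
    fields <- strsplit(ln, "\\s+")[[1]]
    if (!grepl("^[0-9]", fields[1])) next  # other header prose
    if (is.na(chrom)) {
      abort(paste0("record before any 'Sequence:' header at line ", i))
    }
    if (length(fields) < 14) {
      abort(paste0("malformed TRF record at line ", i, ": expected >= 14 fields"))
    }
    period <- as.numeric(fields[3])
    if (period > max_period) {
      dropped <- dropped + 1L
      next
    }
    out[[length(out) + 1]] <- tibble(
      chrom = chrom,
      start = as.numeric(fields[1]) - 1,
      end = as.numeric(fields[2]),
      period = period,
      copy_number = as.numeric(fields[4]),
      monomer = fields[14]
    )
  }
  if (dropped > 0) {
    inform(paste0("parse_trf_dat: dropped ", dropped,
                  " record(s) with period > ", max_period))
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  period = double(), copy_number = double(),
                  monomer = character()))
  }
  list_rbind(out)
}

#' Write tandem-repeat records in the TRF .dat dialect
#'
#' Counterpart of [parse_trf_dat()], used mainly by the synthetic-data
#' generator. Only the fields the parser consumes are meaningful; the
#' remaining numeric columns are filled with plausible placeholders.
#'
#' @param records Tibble with `chrom`, `start`, `end`, `period`,
#'   `copy_number`, `monomer` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trf_dat <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in unique(records$chrom)) {
    writeLines(paste0("Sequence: ", ch), con)
    rr <- records[records$chrom == ch, , drop = FALSE]
    writeLines(sprintf(
      "%d %d %d %.1f %d %d %d %d %d %d %d %d %.2f %s %s",
      as.integer(rr$start + 1), as.integer(rr$end), as.integer(rr$period),
      rr$copy_number, as.integer(rr$period), 100L, 0L,
      as.integer(2 * (rr$end - rr$start)),
      25L, 25L, 25L, 25L, 1.9, rr$monomer, rr$monomer
    ), con)
  }
  invisible(path)
}

#' Merge tandem-record frequencies by canonical monomer
#'
#' Collapses records whose monomers are rotations/strand-flips of the same
#' unit into one entry per canonical form, summing copy numbers. In
#' approximate mode, canonical forms of equal length whose normalized edit
#' distance is at most `max_dist` are additionally merged (greedily, into
#' the most frequent member).
#'
#' @param records Tibble from [parse_trf_dat()] (needs `monomer` and
#'   `copy_number`). Records with non-ACGT monomers are dropped with a
#'   message.
#' @param approximate Also merge near-identical canonical forms of equal
#'   length (default `FALSE`).
#' @param max_dist Normalized edit-distance threshold for approximate
#'   merging (default 0.1).
#' @return Tibble with `canonical`, `length`, `total_frequency`,
#'   `n_members`, `members` (list of observed monomer variants), sorted by
#'   `total_frequency` descending.
#' @export
merge_monomer_frequencies <- function(records, approximate = FALSE,
                                      max_dist = 0.1) {
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    return(tibble(canonical = character(), length = integer(),
                  total_frequency = double(), n_members = integer(),
                  members = list()))
  }
  ok <- !grepl("[^ACGT]", records$monomer)
  if (any(!ok)) {
    inform(paste0("merge_monomer_frequencies: dropped ", sum(!ok),
                  " record(s) with non-ACGT monomers"))
    records <- records[ok, , drop = FALSE]
  }
  records$canonical <- canonical_monomer(records$monomer)
  merged <- records |>
    group_by(.data$canonical) |>
    summarise(
      length = nchar(.data$canonical[1]),
      total_frequency = sum(.data$copy_number),
      members = list(sort(unique(.data$monomer))),
      .groups = "drop"
    )
  if (approximate && nrow(merged) > 1) {
    merged <- merged |> arrange(desc(.data$total_frequency))
    cluster <- rep(NA_integer_, nrow(merged))
    for (i in seq_len(nrow(merged))) {
      if (!is.na(cluster[i])) next
      cluster[i] <- i
      same_len <- which(is.na(cluster) & merged$length == merged$length[i])
      if (length(same_len) > 0) {
        d <- as.integer(adist(merged$canonical[i], merged$canonical[same_len]))
        hit <- same_len[d / merged$length[i] <= max_dist]
        cluster[hit] <- i
      }
    }
    merged <- merged |>
      mutate(cluster = cluster) |>
      group_by(.data$cluster) |>
      summarise(
        canonical = .data$canonical[1],
        length = .data$length[1],
        total_frequency = sum(.data$total_frequency),
        members = list(sort(unique(unlist(.data$members)))),
        .groups = "drop"
      ) |>
      select(-"cluster")
  }
  merged |>
    mutate(n_members = lengths(.data$members)) |>
    select("canonical", "length", "total_frequency", "n_members", "members") |>
    arrange(desc(.data$total_frequency), .data$canonical)
}

#' Call telomeric arrays at chromosome ends
#'
#' For each chromosome end, merges tandem records whose canonical monomer
#' equals the telomere family and whose locus overlaps the terminal
#' `end_zone`; the end is called present when the merged (union) span is at
#' least `min_array_bp`.
#'
#' @param records Tandem records ([parse_trf_dat()] output).
#' @param genome A `genarch_genome` (provides chromosome lengths).
#' @param motif_family Canonical monomer of the telomere family (default
#'   `"AAACCCT"`, the canonical form of the plant motif TTTAGGG).
#' @param end_zone Terminal zone width in bp (default 100 kb).
#' @param min_array_bp Minimum merged array span in bp (default 1 kb).
#' @return Tibble with `chrom`, `end` (`left`/`right`), `present`,
#'   `array_start`, `array_end` (`NA` when absent), `array_bp`.
#' @export
call_telomeres <- function(records, genome, motif_family = "AAACCCT",
                           end_zone = 1e5, min_array_bp = 1000) {
  stopifnot(inherits(genome, "genarch_genome"))
  rec <- as_tibble(records)
  if (nrow(rec) > 0) {
    rec <- rec[!grepl("[^ACGT]", rec$monomer), , drop = FALSE]
    rec <- rec[canonical_monomer(rec$monomer) == motif_family, , drop = FALSE]
  }
  out <- list()
  for (ch in names(genome$lengths)) {
    L <- genome$lengths[[ch]]
    rch <- rec[rec$chrom == ch, , drop = FALSE]
    for (side in c("left", "right")) {
      zone <- if (side == "left") c(0, min(end_zone, L)) else
        c(max(L - end_zone, 0), L)
      hit <- rch[rch$end > zone[1] & rch$start < zone[2], , drop = FALSE]
      if (nrow(hit) > 0) {
        red <- IRanges::reduce(as_iranges0(hit$start, hit$end))
        bp <- sum(IRanges::width(red))
        span <- c(min(hit$start), max(hit$end))
      } else {
        bp <- 0
        span <- c(NA_real_, NA_real_)
      }
      out[[length(out) + 1]] <- tibble(
        chrom = ch, end = side, present = bp >= min_array_bp,
        array_start = if (bp >= min_array_bp) span[1] else NA_real_,
        array_end = if (bp >= min_array_bp) span[2] else NA_real_,
        array_bp = bp
      )
    }
  }
  list_rbind(out)
}

#' Call centromeric satellite clusters
#'
#' Among tandem records whose canonical monomer length is in
#' `monomer_lengths`, finds per chromosome the `cluster_window` placement
#' maximizing the contained copy number (a record is contained when its
#' midpoint falls in the window; ties resolved leftmost). Copies outside
#' the chosen window are reported as scattered.
#'
#' @param records Tandem records ([parse_trf_dat()] output).
#' @param genome A `genarch_genome`; chromosomes without candidate records
#'   get a call with `NA` cluster coordinates.
#' @param monomer_lengths Candidate satellite monomer lengths in bp
#'   (default `c(79, 80)`).
#' @param cluster_window Cluster window width in bp (default 1 Mb).
#' @param per_family Also split calls by monomer length (default `FALSE`:
#'   families are pooled per chromosome).
#' @return Tibble with `chrom` (and `monomer_length` when `per_family`),
#'   `cluster_start`, `cluster_end`, `copies_in_cluster`,
#'   `scattered_copies`, `monomer_family` (canonical monomer of the
#'   highest-frequency member record in the cluster).
#' @export
call_centromeres <- function(records, genome, monomer_lengths = c(79, 80),
                             cluster_window = 1e6, per_family = FALSE) {
  stopifnot(inherits(genome, "genarch_genome"))
  records <- as_tibble(records)
  if (nrow(records) > 0) {
    records <- records[!grepl("[^ACGT]", records$monomer), , drop = FALSE]
  }
  cand <- records[nchar(records$monomer) %in% monomer_lengths, , drop = FALSE]
  if (nrow(cand) > 0) cand$canonical <- canonical_monomer(cand$monomer)

  one_call <- function(rch, ch, fam = NA) {
    base <- tibble(
      chrom = ch,
      cluster_start = NA_real_, cluster_end = NA_real_,
      copies_in_cluster = 0, scattered_copies = 0,
      monomer_family = NA_character_
    )
    if (!is.na(fam)) base <- mutate(base, monomer_length = fam, .after = "chrom")
    if (nrow(rch) == 0) return(base)
    mid <- (rch$start + rch$end) / 2
    o <- order(mid)
    mid <- mid[o]; w <- rch$copy_number[o]
    # candidate placements anchored at each record midpoint
    best_sum <- -Inf; best_i <- 1L
    for (i in seq_along(mid)) {
      inwin <- mid >= mid[i] & mid < mid[i] + cluster_window
      s <- sum(w[inwin])
      if (s > best_sum + 1e-9) { best_sum <- s; best_i <- i }
    }
    inwin <- mid >= mid[best_i] & mid < mid[best_i] + cluster_window
    members <- rch[o, , drop = FALSE][inwin, , drop = FALSE]
    base$cluster_start <- min(members$start)
    base$cluster_end <- max(members$end)
    base$copies_in_cluster <- sum(members$copy_number)
    base$scattered_copies <- sum(rch$copy_number) - base$copies_in_cluster
    base$monomer_family <-
      members$canonical[which.max(members$copy_number)]
    base
  }

  out <- list()
  for (ch in names(genome$lengths)) {
    rch <- cand[cand$chrom == ch, , drop = FALSE]
    if (per_family) {
      for (fam in monomer_lengths) {
        out[[length(out) + 1]] <-
          one_call(rch[nchar(rch$monomer) == fam, , drop = FALSE], ch, fam)
      }
    } else {
      out[[length(out) + 1]] <- one_call(rch, ch)
    }
  }
  list_rbind(out)
}

#' Find exact tandem arrays in a sequence
#'
#' Internal stand-in for an external tandem-repeat finder on synthetic,
#' mutation-free arrays: reports maximal runs where `s[i] == s[i + p]` for
#' a period `p <= max_period`, with the smallest period (runs that are
#' sub-runs of a smaller-period array are suppressed) and a copy count of
#' run length over period. Arrays are split at `N`.
#'
#' @param sequence A single ACGT(+N) string.
#' @param max_period Largest period searched (default 500).
#' @param min_copies Minimum copy number reported (default 3).
#' @param chrom Chromosome id used in the output (default `"seq"`).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `period`, `copy_number`, `monomer`.
#' @export
find_exact_tandem_arrays <- function(sequence, max_period = 500,
                                     min_copies = 3, chrom = "seq") {
  stopifnot(is.character(sequence), length(sequence) == 1)
  x <- strsplit(toupper(sequence), "")[[1]]
  n <- length(x)
  is_n <- x == "N"
  found <- list()
  covered <- list()  # per found array: c(start, end, period)
  for (p in seq_len(min(max_period, max(n - 1, 0)))) {
    if (n < 2 * p) break
    eq <- x[seq_len(n - p)] == x[seq_len(n - p) + p]
    eq[is_n[seq_len(n - p)] | is_n[seq_len(n - p) + p]] <- FALSE
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      run_len <- r$lengths[k] + p       # total array length in bp
      if (run_len / p < min_copies) next
      a0 <- starts[k] - 1               # 0-based array start
      a1 <- a0 + run_len                # half-open end
      contained <- any(vapply(covered, function(cv) {
        a0 >= cv[1] && a1 <= cv[2]
      }, logical(1)))
      if (contained) next
      found[[length(found) + 1]] <- tibble(
        chrom = chrom, start = a0, end = a1, period = p,
        copy_number = run_len / p,
        monomer = paste(x[(a0 + 1):(a0 + p)], collapse = "")
      )
      covered[[length(covered) + 1]] <- c(a0, a1, p)
    }
  }
  if (length(found) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  period = integer(), copy_number = double(),
                  monomer = character()))
  }
  list_rbind(found) |> arrange(.data$start, .data$period)
}
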