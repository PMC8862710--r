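# Per-window interval arithmetic shared by the landscape modules. Overlap
# and union math is delegated to IRanges per chromosome; everything else
# stays in the tibble frame.

# internal: IRanges from a 0-based half-open tibble subset (start, end)
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1, end = end)
}

#' Count intervals overlapping each window
#'
#' An interval contributes to every window it overlaps (no midpoint
#' assignment).
#'
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @param grid Window grid from [make_window_grid()].
#' @return `grid` with an added `n` column.
#' @export
count_overlaps_windows <- function(intervals, grid) {
  check_chroms(intervals$chrom, unique(grid$chrom), "interval")
  out <- as_tibble(grid)
  out$n <- 0L
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    wsel <- which(out$chrom == ch)
    hits <- IRanges::countOverlaps(
      as_iranges0(out$start[wsel], out$end[wsel]),
      as_iranges0(iv$start, iv$end)
    )
    out$n[wsel] <- as.integer(hits)
  }
  out
}

#' Base-pair coverage of intervals per window
#'
#' Computes, per window, the number of bases covered by the union of the
#' given intervals and the covered fraction of the actual window width.
#'
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @param grid Window grid from [make_window_grid()].
#' @return `grid` with added `covered_bp` and `fraction` columns.
#' @export
coverage_windows <- function(intervals, grid) {
  check_chroms(intervals$chrom, unique(grid$chrom), "interval")
  out <- as_tibble(grid)
  out$covered_bp <- 0
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    red <- IRanges::reduce(as_iranges0(iv$start, iv$end))
    wsel <- which(out$chrom == ch)
    win <- as_iranges0(out$start[wsel], out$end[wsel])
    ov <- IRanges::findOverlaps(win, red)
    if (length(ov) > 0) {
      inter_w <- pmin(IRanges::end(win)[S4Vectors::queryHits(ov)],
                      IRanges::end(red)[S4Vectors::subjectHits(ov)]) -
        pmax(IRanges::start(win)[S4Vectors::queryHits(ov)],
             IRanges::start(red)[S4Vectors::subjectHits(ov)]) + 1
      cov <- tapply(inter_w, S4Vectors::queryHits(ov), sum)
      out$covered_bp[wsel[as.integer(names(cov))]] <- as.numeric(cov)
    }
  }
  out$fraction <- out$covered_bp / out$width
  out
}

#' Count positions falling in each window
#' @param positions Tibble with `chrom`, `pos` (0-based).
#' @param grid Window grid.
#' @return `grid` with an added `n` column.
#' @export
count_positions_windows <- function(positions, grid) {
  if (nrow(positions) == 0) {
    out <- as_tibble(grid)
    out$n <- 0L
    return(out)
  }
  count_overlaps_windows(
    tibble(chrom = positions$chrom, start = positions$pos,
           end = positions$pos + 1),
    grid
  )
}

# internal: maximal runs of TRUE within each chromosome of a window table;
# returns tibble(chrom, start, end, n_windows, first, last) of runs
window_runs <- function(grid, flag) {
  stopifnot(length(flag) == nrow(grid))
  out <- list()
  for (ch in unique(grid$chrom)) {
    sel <- which(grid$chrom == ch)
    r <- rle(flag[sel])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    for (k in keep) {
      i0 <- sel[starts[k]]; i1 <- sel[ends[k]]
      out[[length(out) + 1]] <- tibble(
        chrom = ch,
        start = grid$start[i0],
        end = grid$end[i1],
        n_windows = ends[k] - starts[k] + 1L,
        first = i0, last = i1
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  n_windows = integer(), first = integer(), last = integer()))
  }
  list_rbind(out)
}
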