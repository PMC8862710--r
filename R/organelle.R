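# Nuclear insertions of organelle DNA (NUPTs/NUMTs): filtering of
# organelle-vs-nucleus alignment hits, merging into insertion events with
# length tiers, per-window counting, and detection of integration
# anomalies (end-proximal pairs, co-localized cp/mt windows, multi-Mb
# hotspots and tandem-like clusters).

INSERTION_TIERS <- c(100, 1000, 5000, 10000)

#' Filter organelle alignment hits
#'
#' Keeps hits with identity at or above `min_identity`, alignment length at
#' least `min_length` and e-value at most `max_evalue`.
#'
#' @param hits Normalized hits tibble ([read_blast_hits()]).
#' @param min_identity Identity floor in percent (default 95).
#' @param min_length Minimum alignment length in bp (default 100).
#' @param max_evalue E-value ceiling (default 1e-10).
#' @return Filtered hits tibble.
#' @export
filter_hits <- function(hits, min_identity = 95, min_length = 100,
                        max_evalue = 1e-10) {
  as_tibble(hits) |>
    filter(
      .data$identity >= min_identity,
      .data$aln_length >= min_length,
      .data$evalue <= max_evalue
    )
}

# internal: tier thresholds at or below a length
tiers_for_length <- function(len, tiers = INSERTION_TIERS) {
  lapply(len, function(l) tiers[tiers <= l])
}

#' Merge alignment hits into insertion events
#'
#' Hits of one organelle whose target intervals overlap or abut within
#' `max_gap` are merged into a single insertion event: the target span is
#' their union, source spans are collected, the event identity is the
#' maximum over members, and length tiers are assigned from the merged
#' target length.
#'
#' @param hits Filtered hits tibble; an `organelle` column (e.g. `cp`/`mt`)
#'   is carried through when present, otherwise `source_id` is used.
#' @param max_gap Maximum gap in bp between hits merged into one event
#'   (default 0: overlap or abutment only).
#' @param tiers Length-tier thresholds in bp.
#' @return Tibble with `organelle`, `chrom`, `start`, `end`, `length`,
#'   `n_hits`, `max_identity`, `tiers` (list of thresholds at or below the
#'   event length), `source_spans` (list of tibbles with `source_start`,
#'   `source_end`, `strand`).
#' @export
merge_hits_to_events <- function(hits, max_gap = 0, tiers = INSERTION_TIERS) {
  h <- as_tibble(hits)
  if (!"organelle" %in% names(h)) h$organelle <- h$source_id
  if (nrow(h) == 0) {
    return(tibble(organelle = character(), chrom = character(),
                  start = double(), end = double(), length = double(),
                  n_hits = integer(), max_identity = double(),
                  tiers = list(), source_spans = list()))
  }
  out <- list()
  for (org in unique(h$organelle)) {
    for (ch in unique(h$chrom[h$organelle == org])) {
      hh <- h |>
        filter(.data$organelle == org, .data$chrom == ch) |>
        arrange(.data$target_start, .data$target_end)
      # merge intervals allowing max_gap
      grp <- cumsum(c(1, hh$target_start[-1] >
                        cummax(hh$target_end)[-nrow(hh)] + max_gap))
      ev <- hh |>
        mutate(.grp = grp) |>
        group_by(.data$.grp) |>
        summarise(
          organelle = org, chrom = ch,
          start = min(.data$target_start), end = max(.data$target_end),
          n_hits = dplyr::n(),
          max_identity = max(.data$identity),
          source_spans = list(pick("source_id", "source_start",
                                   "source_end", "strand")),
          .groups = "drop"
        ) |>
        select(-".grp")
      out[[length(out) + 1]] <- ev
    }
  }
  list_rbind(out) |>
    mutate(length = .data$end - .data$start,
           tiers = tiers_for_length(.data$length, tiers)) |>
    select("organelle", "chrom", "start", "end", "length", "n_hits",
           "max_identity", "tiers", "source_spans") |>
    arrange(.data$organelle, .data$chrom, .data$start)
}

#' Count insertion events per window and length tier
#'
#' For each window, organelle and tier threshold, counts the events of at
#' least that length overlapping the window; an event spanning a window
#' boundary is counted in every window it overlaps.
#'
#' @param events Events tibble from [merge_hits_to_events()].
#' @param grid Window grid from [make_window_grid()].
#' @param tiers Tier thresholds in bp (default `c(100, 1000, 10000)`).
#' @return Long tibble with `chrom`, `window`, `start`, `end`, `width`,
#'   `organelle`, `tier`, `n`.
#' @export
count_events_per_window <- function(events, grid,
                                    tiers = c(100, 1000, 10000)) {
  check_chroms(events$chrom, unique(grid$chrom), "insertion event")
  if (nrow(events) == 0) {
    return(as_tibble(grid)[0, ] |>
             mutate(organelle = character(), tier = double(), n = integer()))
  }
  combos <- tidyr::expand_grid(
    organelle = unique(events$organelle),
    tier = tiers
  )
  out <- purrr::pmap(combos, function(organelle, tier) {
    ev <- events[events$organelle == organelle & events$length >= tier, ,
                 drop = FALSE]
    count_overlaps_windows(ev[c("chrom", "start", "end")], grid) |>
      mutate(organelle = organelle, tier = tier)
  }) |> list_rbind()
  out |>
    select("chrom", "window", "start", "end", "width", "organelle",
           "tier", "n")
}

#' Detect chromosome ends with insertions of both organelles
#'
#' Flags chromosome ends where at least one chloroplast and one
#' mitochondrial event both lie within `end_distance` of the terminus.
#'
#' @param events Events tibble (must contain both organelles of interest).
#' @param genome A `genarch_genome`.
#' @param end_distance Terminal distance in bp (default 500 kb).
#' @param organelles The two organelle labels required (default
#'   `c("cp", "mt")`).
#' @return Anomaly tibble with `type = "end_proximal"`, `chrom`, `end`,
#'   `start`, `end_pos` (the terminal zone) and per-organelle event counts.
#' @export
detect_end_proximal <- function(events, genome, end_distance = 5e5,
                                organelles = c("cp", "mt")) {
  stopifnot(inherits(genome, "genarch_genome"))
  out <- list()
  for (ch in names(genome$lengths)) {
    L <- genome$lengths[[ch]]
    for (side in c("left", "right")) {
      zone <- if (side == "left") c(0, min(end_distance, L)) else
        c(max(L - end_distance, 0), L)
      inzone <- events$chrom == ch &
        events$start < zone[2] & events$end > zone[1]
      n1 <- sum(inzone & events$organelle == organelles[1])
      n2 <- sum(inzone & events$organelle == organelles[2])
      if (n1 >= 1 && n2 >= 1) {
        out[[length(out) + 1]] <- tibble(
          type = "end_proximal", chrom = ch, side = side,
          start = zone[1], end = zone[2],
          n_cp = n1, n_mt = n2
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(type = character(), chrom = character(), side = character(),
                  start = double(), end = double(), n_cp = integer(),
                  n_mt = integer()))
  }
  list_rbind(out)
}

#' Detect windows where chloroplast and mitochondrial insertions co-localize
#'
#' Reports windows farther than `exclude_end_distance` from both
#' chromosome termini that contain at least one event of each organelle.
#'
#' @param events Events tibble with both organelles.
#' @param grid Window grid.
#' @param genome A `genarch_genome` (for chromosome lengths).
#' @param exclude_end_distance Terminal exclusion distance in bp (default
#'   500 kb).
#' @param organelles The two organelle labels (default `c("cp", "mt")`).
#' @return Anomaly tibble with `type = "co_localized"`, window coordinates
#'   and per-organelle counts.
#' @export
detect_co_localization <- function(events, grid, genome,
                                   exclude_end_distance = 5e5,
                                   organelles = c("cp", "mt")) {
  stopifnot(inherits(genome, "genarch_genome"))
  n1 <- count_overlaps_windows(
    events[events$organelle == organelles[1], c("chrom", "start", "end")], grid)$n
  n2 <- count_overlaps_windows(
    events[events$organelle == organelles[2], c("chrom", "start", "end")], grid)$n
  lens <- genome$lengths[grid$chrom]
  interior <- grid$start >= exclude_end_distance &
    grid$end <= lens - exclude_end_distance
  hit <- which(n1 >= 1 & n2 >= 1 & interior)
  tibble(
    type = rep("co_localized", length(hit)),
    chrom = grid$chrom[hit], start = grid$start[hit], end = grid$end[hit],
    n_cp = as.integer(n1[hit]), n_mt = as.integer(n2[hit])
  )
}

#' Detect organelle-integration hotspots
#'
#' Pools events of both organelles, computes the event-covered base
#' fraction per window, and reports maximal runs of consecutive windows
#' with coverage at or above `min_coverage_fraction` whose total span is at
#' least `min_span`. Evidence includes per-organelle covered bp.
#'
#' @param events Events tibble.
#' @param grid Window grid.
#' @param min_span Minimum hotspot span in bp (default 1 Mb).
#' @param min_coverage_fraction Per-window covered-fraction threshold
#'   (default 0.5).
#' @return Anomaly tibble with `type = "hotspot"`, `chrom`, `start`,
#'   `end`, `n_windows`, `covered_bp_cp`, `covered_bp_mt`,
#'   `mean_fraction`.
#' @export
detect_hotspot <- function(events, grid, min_span = 1e6,
                           min_coverage_fraction = 0.5) {
  cov <- coverage_windows(events[c("chrom", "start", "end")], grid)
  dense <- cov$fraction >= min_coverage_fraction
  runs <- window_runs(cov, dense)
  runs <- runs[runs$end - runs$start >= min_span, , drop = FALSE]
  if (nrow(runs) == 0) {
    return(tibble(type = character(), chrom = character(), start = double(),
                  end = double(), n_windows = integer(),
                  covered_bp_cp = double(), covered_bp_mt = double(),
                  mean_fraction = double()))
  }
  per_org <- function(org, r) {
    ev <- events[events$organelle == org & events$chrom == r$chrom &
                   events$start < r$end & events$end > r$start, ,
                 drop = FALSE]
    if (nrow(ev) == 0) return(0)
    red <- IRanges::reduce(as_iranges0(pmax(ev$start, r$start),
                                       pmin(ev$end, r$end)))
    sum(IRanges::width(red))
  }
  runs |>
    rowwise() |>
    mutate(
      type = "hotspot",
      covered_bp_cp = per_org("cp", pick(everything())),
      covered_bp_mt = per_org("mt", pick(everything())),
      mean_fraction = mean(cov$fraction[.data$first:.data$last])
    ) |>
    ungroup() |>
    select("type", "chrom", "start", "end", "n_windows",
           "covered_bp_cp", "covered_bp_mt", "mean_fraction")
}

# internal: reciprocal source-span overlap between two spans, as a
# fraction of the shorter span (0 when source ids differ)
source_overlap_fraction <- function(a, b) {
  ov <- pmin(a$source_end, b$source_end) - pmax(a$source_start, b$source_start)
  shorter <- pmin(a$source_end - a$source_start, b$source_end - b$source_start)
  frac <- pmax(ov, 0) / shorter
  frac[a$source_id != b$source_id] <- 0
  frac
}

#' Detect tandem-like organelle integrations
#'
#' Finds clusters of at least `min_events` events of one organelle whose
#' target positions lie within `neighborhood` of their cluster neighbours
#' and whose organelle source spans mutually overlap by at least
#' `min_source_overlap` (reciprocal, as a fraction of the shorter span) —
#' the signature of one organelle segment integrated repeatedly at nearby
#' positions. Within a positional cluster, the largest mutually compatible
#' group is reported (greedy, in positional order).
#'
#' @param events Events tibble of one organelle (other organelles are
#'   processed separately when present).
#' @param neighborhood Maximum target gap in bp between cluster neighbours
#'   (default 200 kb).
#' @param min_events Minimum cluster size (default 3).
#' @param min_source_overlap Reciprocal source-overlap threshold (default
#'   0.5).
#' @return Anomaly tibble with `type = "tandem_like"`, `organelle`,
#'   `chrom`, `start`, `end`, `n_events`, `min_pairwise_overlap`.
#' @export
detect_tandem_like <- function(events, neighborhood = 2e5, min_events = 3,
                               min_source_overlap = 0.5) {
  ev <- as_tibble(events)
  out <- list()
  for (org in unique(ev$organelle)) {
    for (ch in unique(ev$chrom[ev$organelle == org])) {
      e <- ev |>
        filter(.data$organelle == org, .data$chrom == ch) |>
        arrange(.data$start)
      if (nrow(e) < min_events) next
      # primary source span per event (longest member span)
      prim <- purrr::map(e$source_spans, function(ss) {
        ss[which.max(ss$source_end - ss$source_start), , drop = FALSE]
      }) |> list_rbind()
      gap <- e$start[-1] - e$end[-nrow(e)]
      cl <- cumsum(c(1, gap > neighborhood))
      for (k in unique(cl)) {
        idx <- which(cl == k)
        if (length(idx) < min_events) next
        # greedy mutually-compatible group in positional order
        grp <- integer()
        for (i in idx) {
          if (length(grp) == 0) { grp <- i; next }
          ok <- all(source_overlap_fraction(prim[rep(i, length(grp)), ],
                                            prim[grp, ]) >=
                      min_source_overlap)
          if (ok) grp <- c(grp, i)
        }
        if (length(grp) >= min_events) {
          pair_min <- min(vapply(seq_along(grp), function(a) {
            others <- grp[-a]
            if (length(others) == 0) return(1)
            min(source_overlap_fraction(prim[rep(grp[a], length(others)), ],
                                        prim[others, ]))
          }, numeric(1)))
          out[[length(out) + 1]] <- tibble(
            type = "tandem_like", organelle = org, chrom = ch,
            start = min(e$start[grp]), end = max(e$end[grp]),
            n_events = length(grp), min_pairwise_overlap = pair_min
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(type = character(), organelle = character(),
                  chrom = character(), start = double(), end = double(),
                  n_events = integer(), min_pairwise_overlap = double()))
  }
  list_rbind(out)
}
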