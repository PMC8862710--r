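# Organelle insertion events: hit filtering, merging, per-window counting
# and integration anomalies.

mk_hit <- function(chrom = "c1", ts, te, identity = 99, evalue = 1e-50,
                   org = "cp", ss = 0) {
  tibble::tibble(
    source_id = org, chrom = chrom, identity = identity,
    aln_length = te - ts, mismatches = 0, gap_opens = 0,
    source_start = ss, source_end = ss + (te - ts),
    target_start = ts, target_end = te, strand = "+",
    evalue = evalue, bit_score = 2 * (te - ts), organelle = org
  )
}

test_that("hit filtering applies identity, length and e-value floors", {
  hits <- dplyr::bind_rows(
    mk_hit(ts = 0, te = 500, identity = 94.9),
    mk_hit(ts = 1000, te = 1099, identity = 99),        # length 99
    mk_hit(ts = 2000, te = 56784, identity = 100),      # 54,784 bp
    mk_hit(ts = 60000, te = 60500, identity = 99, evalue = 1e-5),
    mk_hit(ts = 70000, te = 70100, identity = 95)       # boundary kept
  )
  kept <- filter_hits(hits)
  expect_equal(kept$target_start, c(2000, 70000))
  expect_true(all(kept$identity >= 95))
})

test_that("overlapping and abutting hits merge into one event with tiers", {
  hits <- dplyr::bind_rows(
    mk_hit(ts = 1000, te = 1500, identity = 96),
    mk_hit(ts = 1400, te = 1800, identity = 99.5),
    mk_hit(ts = 12000, te = 12150)
  )
  ev <- merge_hits_to_events(hits)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$start, c(1000, 12000))
  expect_equal(ev$end, c(1800, 12150))
  expect_equal(ev$length, c(800, 150))
  expect_equal(ev$max_identity[1], 99.5)
  expect_equal(nrow(ev$source_spans[[1]]), 2)
  expect_equal(ev$tiers[[1]], c(100))
  big <- merge_hits_to_events(mk_hit(ts = 0, te = 12000))
  expect_equal(big$tiers[[1]], c(100, 1000, 5000, 10000))
  # hits 10 kb apart stay separate at max_gap 0, merge with a larger gap
  far <- dplyr::bind_rows(mk_hit(ts = 0, te = 200),
                          mk_hit(ts = 10200, te = 10400))
  expect_equal(nrow(merge_hits_to_events(far)), 2)
  expect_equal(nrow(merge_hits_to_events(far, max_gap = 20000)), 1)
})

test_that("event identity bookkeeping respects the filter floor", {
  sim <- get_small_sim()
  ev <- merge_hits_to_events(filter_hits(sim$hits))
  expect_true(all(ev$max_identity >= 95))
})

test_that("window counts match a brute-force per-base oracle", {
  g <- flat_genome(c(c1 = 1000))
  grid <- make_window_grid(g, 100)
  ev <- merge_hits_to_events(dplyr::bind_rows(
    mk_hit(ts = 50, te = 180),    # spans windows 1-2
    mk_hit(ts = 250, te = 260),
    mk_hit(ts = 390, te = 720)    # spans windows 4-8
  ))
  prof <- count_events_per_window(ev, grid, tiers = c(10, 100))
  # oracle: an event counts in a window when any of its bases falls there
  oracle <- function(tier) {
    vapply(seq_len(nrow(grid)), function(w) {
      sum(vapply(seq_len(nrow(ev)), function(i) {
        ev$length[i] >= tier &&
          any(seq(ev$start[i], ev$end[i] - 1) %in%
                seq(grid$start[w], grid$end[w] - 1))
      }, logical(1)))
    }, numeric(1))
  }
  for (tier in c(10, 100)) {
    got <- prof[prof$tier == tier, ]
    expect_equal(got$n[order(got$window)], oracle(tier), label = tier)
  }
  expect_error(count_events_per_window(
    dplyr::mutate(ev, chrom = "nope"), grid), "unknown chromosome")
})

test_that("per-window tier counts are monotone in the tier threshold", {
  sim <- get_small_sim()
  ev <- merge_hits_to_events(filter_hits(sim$hits))
  prof <- count_events_per_window(ev, sim$grid, tiers = c(100, 1000, 10000))
  wide <- tidyr::pivot_wider(prof, names_from = "tier", values_from = "n",
                             names_prefix = "t")
  expect_true(all(wide$t10000 <= wide$t1000))
  expect_true(all(wide$t1000 <= wide$t100))
})

test_that("end-proximal detection requires both organelles near a terminus", {
  g <- flat_genome(c(c1 = 5e6))
  both <- dplyr::bind_rows(
    mk_hit(ts = 2e5, te = 2.01e5, org = "cp"),
    mk_hit(ts = 3e5, te = 3.01e5, org = "mt")
  ) |> merge_hits_to_events()
  hit <- detect_end_proximal(both, g)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$side, "left")
  only_cp <- merge_hits_to_events(mk_hit(ts = 2e5, te = 2.01e5, org = "cp"))
  expect_equal(nrow(detect_end_proximal(only_cp, g)), 0)
  far <- dplyr::bind_rows(
    mk_hit(ts = 6e5, te = 6.01e5, org = "cp"),
    mk_hit(ts = 7e5, te = 7.01e5, org = "mt")
  ) |> merge_hits_to_events()
  expect_equal(nrow(detect_end_proximal(far, g)), 0)
})

test_that("co-localized windows exclude the terminal zones", {
  g <- flat_genome(c(c1 = 5e6))
  grid <- make_window_grid(g, 1e5)
  ev <- dplyr::bind_rows(
    mk_hit(ts = 2.50e6, te = 2.501e6, org = "cp"),
    mk_hit(ts = 2.55e6, te = 2.551e6, org = "mt"),   # same interior window
    mk_hit(ts = 1.20e6, te = 1.201e6, org = "cp"),   # cp only
    mk_hit(ts = 4.95e6, te = 4.951e6, org = "cp"),   # terminal window
    mk_hit(ts = 4.96e6, te = 4.961e6, org = "mt")
  ) |> merge_hits_to_events()
  co <- detect_co_localization(ev, grid, g)
  expect_equal(nrow(co), 1)
  expect_equal(co$start, 2.5e6)
})

test_that("hotspots need sustained window coverage over a minimum span", {
  g <- flat_genome(c(c1 = 5e6))
  grid <- make_window_grid(g, 1e5)
  # 60% coverage in every window of a 2 Mb stretch
  dense <- purrr::map(0:19, function(w) {
    w0 <- 1e6 + w * 1e5
    dplyr::bind_rows(mk_hit(ts = w0, te = w0 + 4e4, org = "cp"),
                     mk_hit(ts = w0 + 5e4, te = w0 + 7e4, org = "mt"))
  }) |> purrr::list_rbind() |> merge_hits_to_events()
  hs <- detect_hotspot(dense, grid)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$start, 1e6)
  expect_equal(hs$end, 3e6)
  expect_true(hs$covered_bp_cp > hs$covered_bp_mt)
  # an isolated event is not a hotspot
  one <- merge_hits_to_events(mk_hit(ts = 1e6, te = 1.09e6))
  expect_equal(nrow(detect_hotspot(one, grid)), 0)
  # coverage below the threshold everywhere yields nothing
  sparse <- purrr::map(0:19, function(w) {
    w0 <- 1e6 + w * 1e5
    mk_hit(ts = w0, te = w0 + 4e4, org = "cp")
  }) |> purrr::list_rbind() |> merge_hits_to_events()
  expect_equal(nrow(detect_hotspot(sparse, grid)), 0)
})

test_that("tandem-like clusters require shared source spans", {
  same <- dplyr::bind_rows(
    mk_hit(ts = 1e5, te = 1.01e5, ss = 5000),
    mk_hit(ts = 1.6e5, te = 1.61e5, ss = 5000),
    mk_hit(ts = 2.2e5, te = 2.21e5, ss = 5000)
  ) |> merge_hits_to_events()
  tl <- detect_tandem_like(same)
  expect_equal(nrow(tl), 1)
  expect_equal(tl$n_events, 3)
  expect_equal(tl$min_pairwise_overlap, 1)
  disjoint <- dplyr::bind_rows(
    mk_hit(ts = 1e5, te = 1.01e5, ss = 0),
    mk_hit(ts = 1.6e5, te = 1.61e5, ss = 5000),
    mk_hit(ts = 2.2e5, te = 2.21e5, ss = 10000)
  ) |> merge_hits_to_events()
  expect_equal(nrow(detect_tandem_like(disjoint)), 0)
  two <- merge_hits_to_events(dplyr::bind_rows(
    mk_hit(ts = 1e5, te = 1.01e5, ss = 5000),
    mk_hit(ts = 1.6e5, te = 1.61e5, ss = 5000)
  ))
  expect_equal(nrow(detect_tandem_like(two)), 0)
})

test_that("planted events are recovered exactly from synthesized hits", {
  sim <- get_small_sim()
  ev <- merge_hits_to_events(filter_hits(sim$hits))
  tr <- sim$truth$insertions
  expect_equal(nrow(ev), nrow(tr))
  j <- dplyr::inner_join(ev, tr, by = c("organelle", "chrom", "start", "end"))
  expect_equal(nrow(j), nrow(tr))
  expect_true(all(purrr::map2_lgl(j$tiers.x, j$tiers.y, identical)))
  # the planted tandem-like cluster is detected
  tl <- detect_tandem_like(ev)
  planted <- tr[tr$note == "tandem_like", ]
  expect_true(any(tl$chrom == planted$chrom[1] &
                    tl$start <= min(planted$start) &
                    tl$end >= max(planted$end)))
})
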