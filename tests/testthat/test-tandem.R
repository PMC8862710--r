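# Monomer canonicalization, TRF parsing, frequency merging and
# telomere/centromere calling.

test_that("canonical monomer is the rotation/strand minimum", {
  expect_equal(canonical_monomer("TTTAGGG"), "AAACCCT")
  expect_equal(canonical_monomer("CCCTAAA"), "AAACCCT")  # strand symmetry
  expect_equal(canonical_monomer("A"), "A")
  # idempotent
  expect_equal(canonical_monomer(canonical_monomer("GATTACA")),
               canonical_monomer("GATTACA"))
  expect_error(canonical_monomer("ACGU"), "non-ACGT")
  expect_error(canonical_monomer(""), "non-empty")
})

test_that("canonical monomer agrees with the brute-force oracle", {
  set.seed(9)
  for (i in 1:200) {
    len <- sample(1:60, 1)
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    expect_equal(canonical_monomer(s), oracle_canonical(s), label = s)
  }
})

test_that("TRF .dat parsing converts coordinates and drops long periods", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c(
    "Sequence: chrZ",
    "Parameters: 2 7 7 80 10 50 500",
    paste("1 700 7 100.0 7 100 0 1400 25 25 25 25 1.9 TTTAGGG",
          "TTTAGGG"),
    paste("900 2103 501 2.4 501 95 0 2000 25 25 25 25 1.9",
          strrep("ACGT", 126), strrep("ACGT", 126))
  ), f)
  expect_message(rec <- parse_trf_dat(f), "dropped 1")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$start, 0)
  expect_equal(rec$end, 700)
  expect_equal(rec$chrom, "chrZ")

  f2 <- withr::local_tempfile(fileext = ".dat")
  writeLines("1 700 7 100.0 7 100 0 1400 25 25 25 25 1.9 TTTAGGG TTTAGGG",
             f2)
  expect_error(parse_trf_dat(f2), "Sequence")

  f3 <- withr::local_tempfile(fileext = ".dat")
  writeLines("Sequence: chrZ", f3)
  expect_equal(nrow(parse_trf_dat(f3)), 0)
})

test_that("monomer frequencies merge across rotation and strand", {
  rec <- tibble::tibble(
    chrom = "c", start = c(0, 1000), end = c(700, 1280), period = 7,
    copy_number = c(60, 40), monomer = c("TTTAGGG", "CCCTAAA")
  )
  m <- merge_monomer_frequencies(rec)
  expect_equal(nrow(m), 1)
  expect_equal(m$canonical, "AAACCCT")
  expect_equal(m$total_frequency, 100)
  expect_setequal(m$members[[1]], c("TTTAGGG", "CCCTAAA"))
  # unrelated monomers stay separate; frequencies are conserved
  rec2 <- dplyr::bind_rows(rec, tibble::tibble(
    chrom = "c", start = 2000, end = 2500, period = 5, copy_number = 17,
    monomer = "GGATC"
  ))
  m2 <- merge_monomer_frequencies(rec2)
  expect_equal(nrow(m2), 2)
  expect_equal(sum(m2$total_frequency), sum(rec2$copy_number))
  expect_equal(nrow(merge_monomer_frequencies(rec[0, ])), 0)
})

test_that("frequency conservation holds on random record sets", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(5:40, 1)
    rec <- tibble::tibble(
      chrom = "c", start = seq_len(n) * 100, end = seq_len(n) * 100 + 50,
      period = NA_real_,
      copy_number = runif(n, 1, 50),
      monomer = replicate(n, paste(sample(c("A", "C", "G", "T"),
                                          sample(2:12, 1), replace = TRUE),
                                   collapse = ""))
    )
    m <- merge_monomer_frequencies(rec)
    expect_equal(sum(m$total_frequency), sum(rec$copy_number))
    expect_true(all(diff(m$total_frequency) <= 0))
  }
})

test_that("approximate mode merges near-identical canonical forms", {
  rec <- tibble::tibble(
    chrom = "c", start = c(0, 100), end = c(50, 150), period = 10,
    copy_number = c(30, 20),
    monomer = c("AAAAACCCCC", "AAAAACCCCG")  # edit distance 1, length 10
  )
  expect_equal(nrow(merge_monomer_frequencies(rec)), 2)
  m <- merge_monomer_frequencies(rec, approximate = TRUE)
  expect_equal(nrow(m), 1)
  expect_equal(m$total_frequency, 50)
})

test_that("telomere calling recovers planted ends and only those", {
  sim <- get_small_sim()
  rec <- sim$trf_records[sim$trf_records$period <= 500, ]
  tel <- call_telomeres(rec, sim$genome, end_zone = 5e4, min_array_bp = 1000)
  truth <- sim$truth$telomeres
  called <- tel[tel$present, c("chrom", "end")]
  expect_equal(nrow(called), nrow(truth))
  expect_setequal(paste(called$chrom, called$end),
                  paste(truth$chrom, truth$side))
  # planted array sizes are matched
  j <- dplyr::inner_join(tel, truth, by = c("chrom", end = "side"))
  expect_true(all(j$array_bp.x >= j$array_bp.y))
})

test_that("telomere thresholds and zones behave as documented", {
  g <- flat_genome(c(c1 = 1e6))
  mid <- tibble::tibble(chrom = "c1", start = 5e5, end = 5e5 + 12000,
                        period = 7, copy_number = 12000 / 7,
                        monomer = "TTTAGGG")
  tel <- call_telomeres(mid, g)
  expect_false(any(tel$present))  # array in the middle is no telomere
  short <- tibble::tibble(chrom = "c1", start = 0, end = 500, period = 7,
                          copy_number = 500 / 7, monomer = "TTTAGGG")
  expect_false(any(call_telomeres(short, g, min_array_bp = 1000)$present))
  expect_true(call_telomeres(short, g, min_array_bp = 400)$present[1])
})

test_that("centromere clusters are recovered against an exhaustive oracle", {
  sim <- get_small_sim()
  rec <- sim$trf_records[sim$trf_records$period <= 500, ]
  cen <- call_centromeres(rec, sim$genome, cluster_window = 5e4)
  truth <- sim$truth$centromeres
  j <- dplyr::inner_join(cen, truth, by = "chrom",
                         suffix = c(".x", ".y"))
  expect_true(all(j$cluster_start.x < j$cluster_end.y &
                    j$cluster_end.x > j$cluster_start.y))
  expect_equal(j$copies_in_cluster, j$copies)
  expect_equal(j$scattered_copies.x, j$scattered_copies.y)

  # exhaustive scan oracle on a random candidate set
  set.seed(33)
  n <- 25
  rnd <- tibble::tibble(
    chrom = "c1", start = sort(sample.int(1e6, n)),
    period = 79, copy_number = sample(1:50, n, replace = TRUE)
  ) |>
    dplyr::mutate(end = start + 79 * 3,
                  monomer = strrep("A", 78) |> paste0("C"))
  W <- 1e5
  mids <- (rnd$start + rnd$end) / 2
  oracle_best <- max(vapply(mids, function(m) {
    sum(rnd$copy_number[mids >= m & mids < m + W])
  }, numeric(1)))
  cl <- call_centromeres(rnd, flat_genome(c(c1 = 1e6)),
                         monomer_lengths = 79, cluster_window = W)
  expect_equal(cl$copies_in_cluster, oracle_best)

  # tie -> leftmost; no candidates -> empty call
  two <- tibble::tibble(
    chrom = "c1", start = c(1e5, 8e5), end = c(1e5, 8e5) + 790,
    period = 79, copy_number = 10, monomer = strrep("G", 79)
  )
  tie <- call_centromeres(two, flat_genome(c(c1 = 1e6)),
                          monomer_lengths = 79, cluster_window = 1e4)
  expect_equal(tie$cluster_start, 1e5)
  none <- call_centromeres(two[0, ], flat_genome(c(c1 = 1e6)))
  expect_true(is.na(none$cluster_start))
})

test_that("the top-frequency canonical monomer is the telomere family", {
  sim <- get_small_sim()
  rec <- sim$trf_records[sim$trf_records$period <= 500, ]
  m <- merge_monomer_frequencies(rec)
  expect_equal(m$canonical[1], "AAACCCT")
})

test_that("exact tandem arrays are found with the smallest period", {
  a <- find_exact_tandem_arrays("ACGACGACG")
  expect_equal(a$period, 3)
  expect_equal(a$copy_number, 3)
  b <- find_exact_tandem_arrays("AAAAAA")
  expect_equal(b$period, 1)
  expect_equal(b$copy_number, 6)
  expect_equal(nrow(find_exact_tandem_arrays("ACGTACGAACGT", min_copies = 3)),
               0)
  # arrays are split at N
  d <- find_exact_tandem_arrays("ACACACACNNACACACAC", min_copies = 3)
  expect_equal(nrow(d), 2)
  expect_equal(d$start, c(0, 10))
  # recovers a planted array inside background sequence
  set.seed(2)
  bg <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
              collapse = "")
  s <- paste0(substr(bg, 1, 100), strrep("TTTAGGG", 20), substr(bg, 101, 300))
  arr <- find_exact_tandem_arrays(s, min_copies = 10)
  expect_true(any(arr$period == 7 & arr$start >= 95 & arr$start <= 101))
})
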