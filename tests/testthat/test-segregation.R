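# Segregation filtering and Mendelian-exclusion paternity.

mk_genotypes <- function(n_het, n_hom, n_missing = 0, locus = "l1",
                         contig = "ctg1", position = 100, depth = 40) {
  n <- n_het + n_hom + n_missing
  tibble::tibble(
    locus = locus, contig = contig, position = position,
    individual = sprintf("i%03d", seq_len(n)),
    genotype = rep(c("het", "hom", "missing"), c(n_het, n_hom, n_missing)),
    depth = depth
  )
}

test_that("the 1:1 chi-square follows the direct formula", {
  expect_equal(chi_square_1to1(100, 100), 0)
  expect_equal(chi_square_1to1(130, 70), 18)
  expect_equal(chi_square_1to1(60, 40), 4)
  expect_lt(chi_square_1to1(60, 40), 6.635)
  expect_error(chi_square_1to1(0, 0), "at least one")
})

test_that("the 1:1 chi-square agrees with the generic Pearson test", {
  set.seed(12)
  for (i in 1:200) {
    h <- sample(1:500, 1); m <- sample(1:500, 1)
    got <- chi_square_1to1(h, m)
    ref <- suppressWarnings(
      unname(stats::chisq.test(c(h, m), p = c(0.5, 0.5))$statistic))
    expect_equal(got, ref)
  }
})

test_that("the four filter steps act as documented", {
  g <- dplyr::bind_rows(
    mk_genotypes(80, 120, locus = "lowhet", contig = "c1", position = 100),
    mk_genotypes(130, 70, locus = "distorted", contig = "c2", position = 100),
    mk_genotypes(100, 100, locus = "good", contig = "c3", position = 100)
  )
  res <- four_step_filter(g)
  loci <- tidy(res)
  expect_false(loci$kept_step2[loci$locus == "lowhet"])   # 40% het
  expect_true(loci$kept_step2[loci$locus == "distorted"])
  expect_false(loci$kept_step3[loci$locus == "distorted"]) # chi2 = 18
  expect_equal(res$retained, "good")
  expect_true(all(diff(res$per_step_counts) <= 0))

  # step 1: a heterozygote below the depth floor is recoded homozygous
  g1 <- mk_genotypes(100, 100)
  g1$depth[g1$genotype == "het"][1:20] <- 19
  res1 <- four_step_filter(g1)
  expect_equal(tidy(res1)$n_het, 80)
  expect_equal(tidy(res1)$n_hom, 120)
  # ... or missing under the alternative interpretation
  res1m <- four_step_filter(g1, low_depth_to = "missing")
  expect_equal(tidy(res1m)$n_missing, 20)

  # step 4: fewest missing wins, ties by smallest position
  g4 <- dplyr::bind_rows(
    mk_genotypes(99, 96, n_missing = 5, locus = "m5", contig = "cX",
                 position = 100),
    mk_genotypes(100, 97, n_missing = 3, locus = "m3", contig = "cX",
                 position = 200)
  )
  expect_equal(four_step_filter(g4)$retained, "m3")
  g4tie <- dplyr::bind_rows(
    mk_genotypes(100, 97, n_missing = 3, locus = "p200", contig = "cX",
                 position = 200),
    mk_genotypes(100, 97, n_missing = 3, locus = "p100", contig = "cX",
                 position = 100)
  )
  expect_equal(four_step_filter(g4tie)$retained, "p100")

  expect_error(four_step_filter(g[0, ]), "zero individuals")
})

test_that("the population-denominator reading of step 2 is available", {
  g <- mk_genotypes(45, 30, n_missing = 25)
  expect_length(four_step_filter(g)$retained, 1)           # 45/75 = 0.6
  expect_length(four_step_filter(g, denominator = "population")$retained, 0)
})

test_that("filtering recovers exactly the planted 1:1 loci and is idempotent", {
  sim <- get_small_sim()
  res <- four_step_filter(sim$genotypes)
  expect_identical(sort(res$retained), sim$truth$seg_retained)
  expect_true(all(diff(res$per_step_counts) <= 0))
  again <- four_step_filter(
    dplyr::filter(sim$genotypes, locus %in% res$retained))
  expect_identical(sort(again$retained), sort(res$retained))
  gl <- glance(res)
  expect_equal(gl$n_retained, length(res$retained))
})

mk_marker <- function(id, ...) {
  g <- list(...)
  tibble::tibble(
    individual = id, locus = names(g),
    allele1 = purrr::map_chr(g, 1), allele2 = purrr::map_chr(g, 2)
  )
}

test_that("Mendelian exclusion assigns the only compatible father", {
  mom <- mk_marker("M", s1 = c("A", "A"))
  off <- mk_marker("o1", s1 = c("A", "B"))
  cands <- dplyr::bind_rows(mk_marker("BB", s1 = c("B", "B")),
                            mk_marker("AA", s1 = c("A", "A")))
  res <- assign_paternity(off, mom, cands)
  expect_equal(res$assigned_father, "BB")
  expect_equal(res$status, "assigned")
  mm <- tidy(res)
  expect_equal(mm$n_mismatch[mm$candidate == "AA"], 1)
  expect_equal(mm$n_mismatch[mm$candidate == "BB"], 0)
})

test_that("a heterozygous mother allows either offspring allele as paternal", {
  mom <- mk_marker("M", s1 = c("A", "B"))
  off <- mk_marker("o1", s1 = c("A", "B"))
  cands <- dplyr::bind_rows(mk_marker("CC", s1 = c("C", "C")),
                            mk_marker("AC", s1 = c("A", "C")))
  res <- assign_paternity(off, mom, cands)
  expect_equal(res$assigned_father, "AC")
  mm <- tidy(res)
  expect_equal(mm$n_mismatch[mm$candidate == "CC"], 1)
})

test_that("ties are ambiguous, never mis-assigned", {
  mom <- mk_marker("M", s1 = c("A", "A"))
  off <- mk_marker("o1", s1 = c("A", "B"))
  cands <- dplyr::bind_rows(mk_marker("B1", s1 = c("B", "B")),
                            mk_marker("B2", s1 = c("B", "C")))
  res <- assign_paternity(off, mom, cands)
  expect_equal(res$status, "ambiguous")
  expect_true(is.na(res$assigned_father))
})

test_that("disjoint locus sets give a warned unassigned result", {
  mom <- mk_marker("M", s1 = c("A", "A"))
  off <- mk_marker("o1", s2 = c("A", "B"))
  cands <- mk_marker("F", s3 = c("B", "B"))
  expect_warning(res <- assign_paternity(off, mom, cands), "no shared loci")
  expect_equal(res$status, "unassigned")
})

test_that("all simulated offspring are assigned to their true father", {
  sim <- get_small_sim()
  pat <- assign_paternity(sim$paternity$offspring, sim$paternity$mother,
                          sim$paternity$candidates)
  j <- dplyr::inner_join(pat, sim$truth$paternity, by = "offspring")
  expect_true(all(j$status == "assigned"))
  expect_equal(j$assigned_father, j$true_father)
  expect_true(all(j$n_informative >= 15))
})

test_that("unassignment grows with the genotyping error rate", {
  unassigned_frac <- function(e) {
    rates <- vapply(1:3, function(s) {
      cfg <- small_sim_config(seed = 100 + s)
      cfg$paternity$error_rate <- e
      sim <- suppressMessages(simulate_dataset(cfg))
      pat <- assign_paternity(sim$paternity$offspring, sim$paternity$mother,
                              sim$paternity$candidates)
      mean(pat$status != "assigned")
    }, numeric(1))
    mean(rates)
  }
  f0 <- unassigned_frac(0)
  f1 <- unassigned_frac(0.05)
  f2 <- unassigned_frac(0.2)
  expect_lte(f0, f1)
  expect_lte(f1, f2)
  expect_gt(f2, f0)
})

test_that("family and map summaries add up", {
  a <- tibble::tibble(
    offspring = c("o1", "o2", "o3", "o4"),
    assigned_father = c("F1", "F1", "F1", NA),
    status = c("assigned", "assigned", "assigned", "unassigned")
  )
  fam <- family_summary(a)
  expect_equal(nrow(fam), 1)
  expect_equal(fam$n_offspring, 3)
  expect_equal(attr(fam, "total"), 3)
  empty <- family_summary(a[a$status == "x", ])
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "total"), 0)

  ms <- map_summary(c(10, 20), c(3L, 4L))
  expect_equal(ms$total_cM, 30)
  expect_equal(ms$total_markers, 7)
  expect_error(map_summary(1:3, 1:2), "equal length")
})

test_that("the published family and linkage tables sum to the printed totals", {
  fam_tbl <- beech_fullsib_families()
  pseudo <- tibble::tibble(
    assigned_father = rep(fam_tbl$father, fam_tbl$family_size),
    status = "assigned"
  ) |>
    dplyr::mutate(offspring = paste0("o", dplyr::row_number()))
  fam <- family_summary(pseudo)
  expect_equal(attr(fam, "total"), 410)
  expect_equal(nrow(fam), 20)
  lg <- beech_linkage_groups()
  ms <- map_summary(lg$size_cM, lg$n_snps)
  expect_equal(ms$total_cM, 2213)
  expect_equal(ms$total_markers, 368)
})
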