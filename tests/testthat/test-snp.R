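# Allele-balance SNP classification and windowed density anomalies.

mk_site <- function(pos, ref, counts, chrom = "c1") {
  s <- tibble::tibble(chrom = chrom, pos = pos, ref = ref,
                      A = 0L, C = 0L, G = 0L, T = 0L)
  for (b in names(counts)) s[[b]] <- as.integer(counts[[b]])
  s
}

test_that("allele-balance thresholds are half-open as printed", {
  sites <- dplyr::bind_rows(
    mk_site(1, "A", list(A = 5, G = 5)),          # 0.5 -> het
    mk_site(2, "A", list(A = 15, G = 5)),         # 0.25 -> het (inclusive)
    mk_site(3, "A", list(A = 5, G = 15)),         # 0.75 -> hom (excluded from het)
    mk_site(4, "A", list(A = 4, G = 16)),         # 0.8 -> hom
    mk_site(5, "A", list(A = 2501, G = 7499)),    # 0.7499 -> het
    mk_site(6, "A", list(A = 16, G = 4)),         # 0.2 -> reference
    mk_site(7, "A", list(A = 9)),                 # depth 9 -> no_call
    mk_site(8, "A", list())                       # depth 0 -> no_call
  )
  calls <- classify_sites(sites)
  expect_equal(calls$state,
               c("heterozygous", "heterozygous", "homozygous_alt",
                 "homozygous_alt", "heterozygous", "reference",
                 "no_call", "no_call"))
  expect_equal(calls$reason[7:8], c("low_depth", "low_depth"))
  expect_equal(calls$alt_fraction[1], 0.5)
  # classification is a partition
  expect_equal(sum(table(calls$state)), nrow(sites))
})

test_that("gap flanks mask calls", {
  gaps <- tibble::tibble(chrom = "c1", start = 100, end = 200)
  sites <- dplyr::bind_rows(
    mk_site(98, "A", list(A = 10, G = 10)),   # 2 bp before the gap
    mk_site(202, "A", list(A = 10, G = 10)),  # 2 bp after
    mk_site(96, "A", list(A = 10, G = 10)),   # 4 bp away: called
    mk_site(150, "A", list(A = 10, G = 10))   # inside the gap
  )
  calls <- classify_sites(sites, gaps)
  expect_equal(calls$state, c("no_call", "no_call", "heterozygous",
                              "no_call"))
  expect_equal(calls$reason[c(1, 2, 4)], rep("near_gap", 3))
})

test_that("multi-allelic counts pool all non-reference bases", {
  calls <- classify_sites(mk_site(1, "A", list(A = 10, C = 3, G = 4, T = 3)))
  expect_equal(calls$alt, 10)
  expect_equal(calls$alt_fraction, 0.5)
  expect_equal(calls$state, "heterozygous")
})

test_that("the literal alt/ref ratio convention is selectable", {
  s <- mk_site(1, "A", list(A = 10, G = 10))
  expect_equal(classify_sites(s, ratio = "alt_ref")$state, "heterozygous")
  s2 <- mk_site(1, "A", list(A = 2, G = 18))
  expect_equal(classify_sites(s2, ratio = "alt_ref")$state, "homozygous_alt")
})

test_that("inter-individual SNPs need a homozygous first individual", {
  calls <- classify_sites(dplyr::bind_rows(
    mk_site(1, "A", list(G = 20)),            # hom alt G
    mk_site(2, "A", list(A = 10, G = 10)),    # het
    mk_site(3, "A", list(A = 5)),             # no_call
    mk_site(4, "A", list(A = 20))             # reference
  ))
  cons <- tibble::tibble(chrom = "c1", pos = c(1, 2, 3, 4),
                         base = c("T", "T", "T", "C"))
  inter <- call_inter_individual(calls, cons)
  expect_equal(inter$pos, c(1, 4))
  expect_equal(inter$kind, rep("homozygous_diff", 2))
  expect_message(
    call_inter_individual(calls,
                          tibble::tibble(chrom = "c1", pos = 1, base = "X")),
    "skipped")
})

test_that("window profiles split genic and intergenic counts", {
  g <- flat_genome(c(c1 = 300))
  grid <- make_window_grid(g, 100)
  genes <- tibble::tibble(chrom = "c1", start = 50, end = 80,
                          gene_id = "g1", duplicated = FALSE)
  calls <- classify_sites(dplyr::bind_rows(
    mk_site(10, "A", list(A = 10, G = 10)),
    mk_site(50, "A", list(A = 10, G = 10)),   # at gene start: genic
    mk_site(90, "A", list(A = 10, G = 10)),
    mk_site(150, "A", list(G = 20))
  ))
  prof <- profile_snp_windows(calls, grid, genes = genes)
  expect_equal(prof$het_count, c(3, 0, 0))
  expect_equal(prof$genic_het, c(1, 0, 0))
  expect_equal(prof$intergenic_het, c(2, 0, 0))
  expect_equal(prof$hom_count, c(0, 1, 0))
  # conservation
  expect_equal(sum(prof$het_count), sum(calls$state == "heterozygous"))
  expect_equal(prof$genic_het + prof$intergenic_het, prof$het_count)
})

test_that("window histograms conserve the window total", {
  prof <- tibble::tibble(chrom = "c1", window = 1:10, start = 0:9 * 100,
                         end = 1:10 * 100, width = 100,
                         het_count = rep(5L, 10),
                         hom_count = c(rep(2L, 6), rep(13L, 4)))
  h <- window_count_histogram(prof, binwidth = 10)
  expect_equal(h$n_windows[h$metric == "het"], 10)
  expect_equal(sum(h$n_windows[h$metric == "het"]),
               sum(h$n_windows[h$metric == "hom"]))
  expect_equal(nrow(window_count_histogram(prof[0, ])), 0)
})

test_that("low-heterozygosity regions are recovered with extended marks", {
  sim <- get_small_sim()
  calls <- classify_sites(sim$pileup, genome_gaps(sim$genome))
  prof <- profile_snp_windows(calls, sim$grid, genes = sim$genes)
  low <- detect_low_het_regions(prof, min_span = 5e4, flag_span = 7e4)
  truth <- sim$truth$snp_regions
  expect_equal(nrow(low), nrow(truth))
  j <- dplyr::inner_join(low, truth, by = "chrom")
  expect_equal(j$start.x, j$start.y)
  expect_equal(j$end.x, j$end.y)
  # the het-free + hom-free region is typed low_both, the others low_het
  expect_equal(low$type[low$chrom == "B"], "low_both")
  expect_true(all(low$type[low$chrom == "A"] == "low_het"))
  expect_true(all(low$extended == (low$end - low$start >= 7e4)))
})

test_that("uniform heterozygosity yields no low-het regions", {
  set.seed(8)
  prof <- tibble::tibble(
    chrom = "c1", window = 1:200, start = 0:199 * 1e5, end = 1:200 * 1e5,
    width = 1e5, het_count = rpois(200, 50), hom_count = rpois(200, 30)
  )
  expect_equal(nrow(detect_low_het_regions(prof)), 0)
  expect_error(detect_low_het_regions(prof[1:5, ]), "insufficient windows")
})

test_that("decoupled windows demand disagreement despite normal gene content", {
  g <- flat_genome(c(c1 = 2e6))
  grid <- make_window_grid(g, 1e5)
  genes <- tibble::tibble(chrom = "c1",
                          start = grid$start[-20] + 10,
                          end = grid$start[-20] + 20010,
                          gene_id = paste0("g", 1:19), duplicated = FALSE)
  prof <- tibble::tibble(
    chrom = grid$chrom, window = grid$window, start = grid$start,
    end = grid$end, width = grid$width,
    het_count = c(120L, rep(50L, 19)),
    genic_het = c(0L, rep(10L, 19)),
    hom_count = rep(30L, 20), genic_hom = rep(6L, 20)
  ) |>
    dplyr::mutate(intergenic_het = het_count - genic_het,
                  intergenic_hom = hom_count - genic_hom)
  dec <- detect_decoupled_windows(prof, genes, grid)
  expect_equal(nrow(dec), 1)
  expect_equal(dec$start, 0)
  expect_equal(dec$subtype, "conserved_genes")
  # a window without genes is never reported
  prof2 <- prof
  prof2$het_count[20] <- 200L; prof2$genic_het[20] <- 0L
  dec2 <- detect_decoupled_windows(prof2, genes, grid)
  expect_false(any(dec2$start == grid$start[20]))
  # a flat profile yields nothing
  prof3 <- dplyr::mutate(prof, het_count = 50L, genic_het = 10L,
                         hom_count = 30L, genic_hom = 6L)
  expect_equal(nrow(detect_decoupled_windows(prof3, genes, grid)), 0)
})

test_that("repeat-rich and duplicated-gene anomalies are recovered", {
  sim <- get_small_sim()
  rep_prof <- coverage_windows(sim$repeats, sim$grid)
  anom <- detect_repeat_gene_anomalies(
    rep_prof, sim$genes, sim$grid,
    min_span = 5e4, dup_min_span = 5e4)
  rich <- anom[anom$type == "repeat_rich", ]
  truth_r <- sim$truth$repeat_rich_regions
  expect_equal(nrow(rich), 1)
  ov <- min(rich$end, truth_r$end) - max(rich$start, truth_r$start)
  expect_gt(ov / (truth_r$end - truth_r$start), 0.85)
  dup <- anom[anom$type == "dup_gene_cluster", ]
  truth_d <- sim$truth$dup_gene_clusters
  expect_equal(nrow(dup), 1)
  expect_true(dup$start < truth_d$end & dup$end > truth_d$start)
  expect_gt(dup$evidence, 0.2)
})

test_that("a genome without planted anomalies reports none", {
  set.seed(14)
  g <- flat_genome(c(c1 = 3e6))
  grid <- make_window_grid(g, 1e5)
  reps <- tibble::tibble(chrom = "c1", start = grid$start,
                         end = grid$start + floor(runif(30, 0.3, 0.5) * 1e5))
  genes <- tibble::tibble(chrom = "c1", start = seq(1e3, 2.99e6, 1.5e4),
                          end = seq(1e3, 2.99e6, 1.5e4) + 3e3) |>
    dplyr::mutate(gene_id = paste0("g", dplyr::row_number()),
                  duplicated = dplyr::row_number() %% 20 == 0)
  anom <- detect_repeat_gene_anomalies(coverage_windows(reps, grid),
                                       genes, grid)
  expect_equal(nrow(anom), 0)
})

test_that("het recovery matches the binomial tail at depth 30", {
  set.seed(77)
  n <- 10000
  depth <- rpois(n, 30)
  alt <- rbinom(n, depth, 0.5)
  sites <- tibble::tibble(
    chrom = "c1", pos = seq_len(n) * 10, ref = "A",
    A = as.integer(depth - alt), C = 0L, G = as.integer(alt), T = 0L
  )
  calls <- classify_sites(sites)
  keep <- depth >= 10
  recall <- mean(calls$state[keep] == "heterozygous")
  # analytic oracle: P(0.25 <= X/d < 0.75) averaged over the observed depths
  tail_p <- function(d) {
    lo <- ceiling(0.25 * d)
    hi <- ceiling(0.75 * d) - 1  # X/d < 0.75
    pbinom(hi, d, 0.5) - pbinom(lo - 1, d, 0.5)
  }
  expected <- mean(vapply(depth[keep], tail_p, numeric(1)))
  mc_se <- sqrt(expected * (1 - expected) / sum(keep))
  expect_gt(recall, 0.99)
  expect_lt(abs(recall - expected), 4 * mc_se + 1e-4)
})
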