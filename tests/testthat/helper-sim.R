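# Shared fixtures: a scaled-down simulation config exercising every
# planted structure at unit-test size, plus a per-process cache so test
# files can share one simulated dataset.

small_sim_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed,
    chromosomes = c(A = 4e5, B = 3e5),
    window_size = 1e4,
    gaps = tibble::tibble(chrom = "A", start = 1.5e5, length = 1000),
    telomeres = tibble::tibble(
      chrom = c("A", "A", "B"), side = c("left", "right", "left"),
      array_bp = c(2000, 1500, 1200), motif = "TTTAGGG"
    ),
    centromeres = tibble::tibble(
      chrom = c("A", "B"), position = c(2e5, 1e5),
      monomer_length = c(79, 80), copies = 80,
      scattered = list(c(5e4, 3e5), c(2.4e5)),
      scattered_copies_each = 5
    ),
    organelles = c(cp = 30000, mt = 50000),
    insertions = tibble::tibble(
      organelle = c("cp", "cp", "mt", "cp", "cp", "cp"),
      chrom = c("A", "A", "A", "B", "B", "B"),
      position = c(4e4, 8e4, 1e5, 1.5e5, 1.6e5, 1.7e5),
      length = c(150, 2000, 11000, 1000, 1000, 1000),
      identity = c(97, 99.5, 99.8, 99.9, 99.9, 99.9),
      strand = c("+", "-", "+", "+", "+", "+"),
      source_start = c(NA, NA, NA, 5000, 5000, 5000),
      note = c("plain", "plain", "plain", "tandem_like", "tandem_like",
               "tandem_like")
    ),
    noise_hits = 4,
    snp = list(
      het_per_window = 20, hom_per_window = 10, ref_per_window = 5,
      depth_mean = 30,
      regions = tibble::tibble(
        chrom = c("A", "B"), start = c(2.2e5, 5e4), end = c(3.0e5, 1.1e5),
        het_per_window = 0, hom_per_window = c(25, 0),
        note = c("low_het", "low_both")
      ),
      decoupled = tibble::tibble(chrom = character(), start = double(),
                                 type = character())
    ),
    genes = list(
      offset = 2000, spacing = 6000, length = 2000, n_exons = 2,
      dup_background_every = 20,
      dup_cluster = tibble::tibble(chrom = "B", start = 2.2e5, end = 2.8e5)
    ),
    repeats = list(
      background_min = 0.3, background_max = 0.5,
      regions = tibble::tibble(chrom = "A", start = 1e4, end = 1.2e5,
                               fraction = 0.75, low_every = 30)
    ),
    mapping = list(
      n_offspring = 40, n_contigs_pair = 12, n_contigs_two = 6,
      n_contigs_distorted = 6, depth_mean = 40, depth_min = 20,
      max_missing = 4, error_rate = 0,
      het_fraction_low = 0.30, het_fraction_skewed = 0.80
    ),
    paternity = list(
      n_candidates = 8, n_loci = 25, n_offspring = 15, n_self = 1,
      n_alleles = 4, error_rate = 0
    ),
    ...
  )
}

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, maker) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- maker()
  .sim_cache[[key]]
}

get_small_sim <- function() {
  cached_sim("small", function() {
    suppressMessages(simulate_dataset(small_sim_config(seed = 11)))
  })
}

# toy genome helper for detector tests that need only coordinates
flat_genome <- function(lengths) {
  genome(vapply(lengths, function(L) strrep("A", L), character(1)))
}
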