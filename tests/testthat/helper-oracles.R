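# Independent brute-force oracles shared across test files.

# canonical monomer by explicit character-vector rotation of the sequence
# and its reverse complement
oracle_canonical <- function(s) {
  x <- strsplit(s, "")[[1]]
  n <- length(x)
  rc <- rev(chartr("ACGT", "TGCA", x))
  cands <- character(0)
  for (k in seq_len(n)) {
    idx <- c(k:n, seq_len(k - 1))
    cands <- c(cands, paste(x[idx], collapse = ""),
               paste(rc[idx], collapse = ""))
  }
  min(cands)
}

get_full_sim <- function() {
  cached_sim("full", function() {
    suppressMessages(simulate_dataset(sim_config(seed = 101)))
  })
}

# study-condition genome with no planted organelle/anomaly structure:
# uniform SNP density, background repeats, background gene duplication
featureless_sim_config <- function(seed = 1) {
  empty_ins <- tibble::tibble(
    organelle = character(), chrom = character(), position = double(),
    length = double(), identity = double(), strand = character(),
    source_start = double(), note = character()
  )
  sim_config(
    seed = seed,
    chromosomes = c(c1 = 2e6, c2 = 2e6),
    window_size = 1e5,
    gaps = tibble::tibble(chrom = character(), start = double(),
                          length = double()),
    telomeres = tibble::tibble(chrom = character(), side = character(),
                               array_bp = double(), motif = character()),
    centromeres = tibble::tibble(chrom = character(), position = double(),
                                 monomer_length = double(), copies = double(),
                                 scattered = list(),
                                 scattered_copies_each = double()),
    insertions = empty_ins,
    noise_hits = 4,
    snp = list(
      het_per_window = 50, hom_per_window = 30, ref_per_window = 10,
      depth_mean = 30,
      regions = tibble::tibble(chrom = character(), start = double(),
                               end = double(), het_per_window = double(),
                               hom_per_window = double(), note = character()),
      decoupled = tibble::tibble(chrom = character(), start = double(),
                                 type = character())
    ),
    repeats = list(
      background_min = 0.3, background_max = 0.5,
      regions = tibble::tibble(chrom = character(), start = double(),
                               end = double(), fraction = double(),
                               low_every = double())
    ),
    mapping = NULL, paternity = NULL
  )
}
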