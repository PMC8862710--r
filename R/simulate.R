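# Seeded synthetic-genome generator with planted ground truth.
#
# The generator plants, in an i.i.d. uniform ACGT background, every
# structure the analysis modules assume: telomeric TTTAGGG arrays at
# chromosome ends, 79/80 bp centromeric satellite clusters with scattered
# copies, assembly gaps, organelle fragments inserted at 95-100% identity
# across length tiers (including a multi-window integration hotspot, a
# tandem-like cluster, an end-proximal cp+mt pair and co-localized
# windows), SNP sites of known state with low-heterozygosity and
# decoupled-window regions, repeat-rich and duplicated-gene anomaly
# annotations, a half-sib genotype matrix mixing 1:1 and distorted loci,
# and a paternity panel with known fathers. Alignment hits are synthesized
# from the planted truth (coordinates plus the mutations applied to reach
# the target identity) rather than by running an aligner. Every draw is
# fixed by the config seed; identical seeds give byte-identical outputs.

SIM_BASES <- c("A", "C", "G", "T")

#' Mutate a fragment to a target identity
#'
#' Applies `round((1 - identity/100) * nchar(fragment))` substitutions at
#' distinct positions, never introducing `N` and always changing the base.
#'
#' @param fragment ACGT string.
#' @param identity Target identity in percent, in `(0, 100]`.
#' @param seed Optional seed; by default the current RNG stream is used.
#' @return The mutated fragment.
#' @export
mutate_to_identity <- function(fragment, identity, seed = NULL) {
  if (!is.numeric(identity) || identity <= 0 || identity > 100) {
    abort("identity must be in (0, 100]")
  }
  run <- function() {
    n <- nchar(fragment)
    k <- round((1 - identity / 100) * n)
    if (k > n) abort("required substitutions exceed fragment length")
    if (k == 0) return(fragment)
    x <- strsplit(fragment, "")[[1]]
    pos <- sample.int(n, k)
    for (i in pos) x[i] <- sample(setdiff(SIM_BASES, x[i]), 1)
    paste(x, collapse = "")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# rotate a monomer by k positions (phase shift)
rotate_monomer <- function(s, k) {
  n <- nchar(s)
  k <- k %% n
  if (k == 0) return(s)
  paste0(substring(s, k + 1, n), substring(s, 1, k))
}

#' Simulation configuration
#'
#' Returns the default simulation plan — the study conditions every
#' analysis module is validated against — with any component overridable
#' by name. Chromosome sizes are desk-scale (3 chromosomes of 12, 10 and
#' 8 Mb); the planted features and their magnitudes are documented in the
#' package vignette.
#'
#' @param seed Integer seed fixing every draw.
#' @param ... Named overrides of the default components (`chromosomes`,
#'   `window_size`, `gaps`, `telomeres`, `centromeres`, `organelles`,
#'   `insertions`, `snp`, `genes`, `repeats`, `mapping`, `paternity`,
#'   `noise_hits`).
#' @return A list of class `genarch_sim_config`.
#' @export
sim_config <- function(seed = 1, ...) {
  hotspot <- purrr::map(0:19, function(w) {
    w0 <- 6e6 + w * 1e5
    tibble(
      organelle = c("cp", "mt"), chrom = "chr2",
      position = c(w0 + 5000, w0 + 50000),
      length = c(40000, 20000), identity = c(99.5, 99),
      strand = "+", source_start = NA_real_, note = "hotspot"
    )
  }) |> list_rbind()

  cfg <- list(
    seed = seed,
    chromosomes = c(chr1 = 12e6, chr2 = 10e6, chr3 = 8e6),
    window_size = 1e5,
    gaps = tibble(
      chrom = c("chr1", "chr1", "chr2", "chr3"),
      start = c(1.75e6, 8.9e6, 4.5e6, 4.0e6),
      length = 5000
    ),
    telomeres = tibble(
      chrom = c("chr1", "chr1", "chr2", "chr2", "chr3"),
      side = c("left", "right", "left", "right", "left"),
      array_bp = c(12000, 6000, 3000, 3000, 5000),
      motif = "TTTAGGG"
    ),
    centromeres = tibble(
      chrom = c("chr1", "chr2", "chr3"),
      position = c(5e6, 3e6, 6.3e6),
      monomer_length = c(79, 80, 79),
      copies = 500,
      scattered = list(
        c(1.2e6, 2.6e6, 6.8e6, 10.0e6),
        c(0.8e6, 2.0e6, 5.0e6, 9.0e6),
        c(1.5e6, 3.0e6, 5.0e6, 7.6e6)
      ),
      scattered_copies_each = 5
    ),
    organelles = c(cp = 160000, mt = 420000),
    insertions = bind_rows(
      tibble(
        organelle = c("cp", "cp", "cp", "mt", "cp", "mt", "cp", "mt"),
        chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2", "chr3",
                  "chr3"),
        position = c(1.0e6, 3.5e6, 11.45e6, 6.5e6, 0.9e6, 2.8e6, 3.2e6,
                     5.5e6),
        length = c(150, 2000, 50000, 12000, 800, 300, 6000, 450),
        identity = c(97, 99.5, 100, 99.8, 96, 95.5, 99.2, 98),
        strand = c("+", "-", "+", "+", "+", "-", "+", "+"),
        source_start = NA_real_, note = "plain"
      ),
      tibble(
        organelle = "cp", chrom = "chr1",
        position = c(9.10e6, 9.17e6, 9.24e6),
        length = 2000, identity = 99.9, strand = "+",
        source_start = 40000, note = "tandem_like"
      ),
      tibble(
        organelle = c("cp", "mt"), chrom = "chr1",
        position = c(10.55e6, 10.58e6), length = c(500, 400),
        identity = c(97.5, 96), strand = "+", source_start = NA_real_,
        note = "co_localized"
      ),
      tibble(
        organelle = c("cp", "mt"), chrom = "chr3",
        position = c(2e5, 3e5), length = c(1200, 900),
        identity = c(98, 97), strand = "+", source_start = NA_real_,
        note = "end_proximal"
      ),
      hotspot
    ),
    noise_hits = 8,
    snp = list(
      het_per_window = 50, hom_per_window = 30, ref_per_window = 10,
      depth_mean = 30,
      regions = tibble(
        chrom = c("chr1", "chr2", "chr3"),
        start = c(2e6, 1.0e6, 1.0e6),
        end = c(8e6, 2.2e6, 3.0e6),
        het_per_window = 0,
        hom_per_window = c(60, 60, 0),
        note = c("low_het_extended", "low_het", "low_both")
      ),
      decoupled = tibble(
        chrom = "chr1", start = c(11.0e6, 11.3e6),
        type = c("conserved", "diversifying")
      )
    ),
    genes = list(
      offset = 50000, spacing = 15000, length = 3000, n_exons = 2,
      dup_background_every = 20,
      dup_cluster = tibble(chrom = "chr3", start = 6.5e6, end = 8.0e6)
    ),
    repeats = list(
      background_min = 0.3, background_max = 0.5,
      regions = tibble(chrom = "chr3", start = 2e5, end = 6.2e6,
                       fraction = 0.75, low_every = 30)
    ),
    mapping = list(
      n_offspring = 200, n_contigs_pair = 150, n_contigs_two = 75,
      n_contigs_distorted = 75, depth_mean = 40, depth_min = 20,
      max_missing = 10, error_rate = 0,
      het_fraction_low = 0.30, het_fraction_skewed = 0.80
    ),
    paternity = list(
      n_candidates = 19, n_loci = 36, n_offspring = 50, n_self = 3,
      n_alleles = 4, error_rate = 0
    )
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0) {
    abort(paste0("unknown sim_config component(s): ", paste(bad, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "genarch_sim_config")
}

# internal: all sequence-modifying feature intervals of a config, for
# collision checking and for excluding SNP placement
planned_feature_intervals <- function(cfg) {
  iv <- list()
  lens <- cfg$chromosomes
  if (nrow(cfg$telomeres %||% tibble()) > 0) {
    tl <- cfg$telomeres
    iv[[length(iv) + 1]] <- tibble(
      chrom = tl$chrom,
      start = ifelse(tl$side == "left", 0, lens[tl$chrom] - tl$array_bp),
      end = ifelse(tl$side == "left", tl$array_bp, lens[tl$chrom]),
      feature = paste0("telomere_", tl$chrom, "_", tl$side)
    )
  }
  if (nrow(cfg$gaps %||% tibble()) > 0) {
    iv[[length(iv) + 1]] <- tibble(
      chrom = cfg$gaps$chrom, start = cfg$gaps$start,
      end = cfg$gaps$start + cfg$gaps$length,
      feature = paste0("gap_", cfg$gaps$chrom, "_", cfg$gaps$start)
    )
  }
  if (nrow(cfg$centromeres %||% tibble()) > 0) {
    ce <- cfg$centromeres
    iv[[length(iv) + 1]] <- tibble(
      chrom = ce$chrom, start = ce$position,
      end = ce$position + ce$monomer_length * ce$copies,
      feature = paste0("centromere_", ce$chrom)
    )
    for (i in seq_len(nrow(ce))) {
      sc <- ce$scattered[[i]]
      if (length(sc) > 0) {
        iv[[length(iv) + 1]] <- tibble(
          chrom = ce$chrom[i], start = sc,
          end = sc + ce$monomer_length[i] * ce$scattered_copies_each[i],
          feature = paste0("centromere_scatter_", ce$chrom[i], "_", sc)
        )
      }
    }
  }
  if (nrow(cfg$insertions %||% tibble()) > 0) {
    ins <- cfg$insertions
    iv[[length(iv) + 1]] <- tibble(
      chrom = ins$chrom, start = ins$position,
      end = ins$position + ins$length,
      feature = paste0(ins$organelle, "_insertion_", ins$chrom, "_",
                       ins$position)
    )
  }
  if (length(iv) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  feature = character()))
  }
  list_rbind(iv)
}

check_plan_collisions <- function(cfg) {
  iv <- planned_feature_intervals(cfg)
  lens <- cfg$chromosomes
  check_chroms(iv$chrom, names(lens), "planted feature")
  oob <- iv$start < 0 | iv$end > lens[iv$chrom]
  if (any(oob)) {
    abort(paste0("planted feature out of bounds: ",
                 paste(iv$feature[oob], collapse = ", ")))
  }
  for (ch in unique(iv$chrom)) {
    v <- iv[iv$chrom == ch, , drop = FALSE]
    ov <- IRanges::findOverlaps(as_iranges0(v$start, v$end),
                                drop.self = TRUE, drop.redundant = TRUE)
    if (length(ov) > 0) {
      q <- S4Vectors::queryHits(ov)[1]; s <- S4Vectors::subjectHits(ov)[1]
      abort(paste0("planted features collide on ", ch, ": ",
                   v$feature[q], " overlaps ", v$feature[s]))
    }
  }
  iv
}

random_seq <- function(n) {
  paste(sample(SIM_BASES, n, replace = TRUE), collapse = "")
}

# sample up to `n` distinct positions in [w0, w1) avoiding `excluded`
# (IRanges, 0-based via as_iranges0) and optionally constrained to / away
# from the `genic` intervals (tibble start/end). When the admissible space
# holds fewer than `n` positions (e.g. a window fully covered by a planted
# feature), all admissible positions are returned — densely annotated
# windows simply carry fewer callable sites.
sample_positions <- function(n, w0, w1, excluded = NULL, genic = NULL,
                             genic_mode = c("any", "only", "avoid")) {
  genic_mode <- match.arg(genic_mode)
  if (n <= 0) return(numeric())
  admissible <- function(cand) {
    if (!is.null(excluded) && length(excluded) > 0) {
      hit <- IRanges::countOverlaps(as_iranges0(cand, cand + 1), excluded) > 0
      cand <- cand[!hit]
    }
    if (genic_mode != "any" && !is.null(genic)) {
      ing <- if (nrow(genic) > 0) {
        IRanges::countOverlaps(as_iranges0(cand, cand + 1),
                               as_iranges0(genic$start, genic$end)) > 0
      } else rep(FALSE, length(cand))
      cand <- if (genic_mode == "only") cand[ing] else cand[!ing]
    }
    cand
  }
  got <- numeric()
  for (try in 1:8) {
    got <- unique(c(got, admissible(unique(floor(runif(3 * n + 20, w0, w1))))))
    if (length(got) >= n) break
  }
  if (length(got) < n) {
    all_ok <- admissible(seq(w0, w1 - 1))
    got <- if (length(all_ok) <= n) all_ok else sample(all_ok, n)
  }
  sort(utils::head(got, n))
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Builds the genome, organelle genomes, alignment hits, tandem-repeat
#' records, gene and repeat annotations, pileup sites, genotype matrices
#' and a paternity panel described by `config`, together with a truth
#' table listing every planted feature. With `out_dir`, all components are
#' also written as plain-text files (FASTA, BLAST tabular, TRF .dat, GFF3,
#' BED, TSV and a truth JSON). Identical seeds give identical outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return An object of class `genarch_sim`; see Details in the vignette.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "genarch_sim_config"))
  features <- check_plan_collisions(config)
  sim <- withr::with_seed(config$seed, build_simulation(config, features))
  if (!is.null(out_dir)) write_simulation(sim, out_dir)
  sim
}

build_simulation <- function(cfg, features) {
  lens <- cfg$chromosomes
  truth <- list()

  ## background chromosomes
  seqs <- vapply(lens, random_seq, character(1))

  ## organelle genomes (circular; we only draw linear source spans)
  orgs <- vapply(cfg$organelles, random_seq, character(1))

  ## assembly gaps
  if (nrow(cfg$gaps %||% tibble()) > 0) {
    for (i in seq_len(nrow(cfg$gaps))) {
      ch <- cfg$gaps$chrom[i]; s0 <- cfg$gaps$start[i]; L <- cfg$gaps$length[i]
      substr(seqs[[ch]], s0 + 1, s0 + L) <- strrep("N", L)
    }
  }

  ## telomeres
  trf <- list()
  tl <- cfg$telomeres %||% tibble()
  if (nrow(tl) > 0) {
    for (i in seq_len(nrow(tl))) {
      ch <- tl$chrom[i]; bp <- tl$array_bp[i]; motif <- tl$motif[i]
      arr <- substr(strrep(motif, ceiling(bp / nchar(motif))), 1, bp)
      s0 <- if (tl$side[i] == "left") 0 else lens[[ch]] - bp
      substr(seqs[[ch]], s0 + 1, s0 + bp) <- arr
      # report the array as a repeat finder would: random phase and strand
      mono <- rotate_monomer(motif, sample.int(nchar(motif), 1) - 1)
      if (runif(1) < 0.5) mono <- revcomp(mono)
      trf[[length(trf) + 1]] <- tibble(
        chrom = ch, start = s0, end = s0 + bp, period = nchar(motif),
        copy_number = round(bp / nchar(motif), 1), monomer = mono
      )
    }
    truth$telomeres <- tibble(
      chrom = tl$chrom, side = tl$side,
      start = ifelse(tl$side == "left", 0, lens[tl$chrom] - tl$array_bp),
      end = ifelse(tl$side == "left", tl$array_bp, lens[tl$chrom]),
      array_bp = tl$array_bp
    )
  }

  ## centromeres: one satellite monomer per monomer length, shared by all
  ## chromosomes using that length
  ce <- cfg$centromeres %||% tibble()
  if (nrow(ce) > 0) {
    fam <- lapply(unique(ce$monomer_length), function(ml) random_seq(ml))
    names(fam) <- as.character(unique(ce$monomer_length))
    cent_truth <- list()
    for (i in seq_len(nrow(ce))) {
      ch <- ce$chrom[i]; ml <- ce$monomer_length[i]
      mono <- fam[[as.character(ml)]]
      n_cp <- ce$copies[i]
      s0 <- ce$position[i]
      arr <- strrep(mono, n_cp)
      substr(seqs[[ch]], s0 + 1, s0 + nchar(arr)) <- arr
      shift <- sample.int(ml, 1) - 1
      rep_mono <- rotate_monomer(mono, shift)
      if (runif(1) < 0.5) rep_mono <- revcomp(rep_mono)
      trf[[length(trf) + 1]] <- tibble(
        chrom = ch, start = s0, end = s0 + nchar(arr), period = ml,
        copy_number = n_cp, monomer = rep_mono
      )
      sc <- ce$scattered[[i]]
      n_each <- ce$scattered_copies_each[i]
      for (p in sc) {
        arr2 <- strrep(mono, n_each)
        substr(seqs[[ch]], p + 1, p + nchar(arr2)) <- arr2
        m2 <- rotate_monomer(mono, sample.int(ml, 1) - 1)
        if (runif(1) < 0.5) m2 <- revcomp(m2)
        trf[[length(trf) + 1]] <- tibble(
          chrom = ch, start = p, end = p + nchar(arr2), period = ml,
          copy_number = n_each, monomer = m2
        )
      }
      cent_truth[[i]] <- tibble(
        chrom = ch, cluster_start = s0, cluster_end = s0 + nchar(arr),
        monomer_length = ml, copies = n_cp,
        scattered_copies = length(sc) * n_each,
        monomer_canonical = canonical_monomer(mono)
      )
    }
    truth$centromeres <- list_rbind(cent_truth)
  }

  ## a few microsatellite decoys plus one over-long period record for the
  ## parser to drop
  decoy_ch <- names(lens)[1]
  trf[[length(trf) + 1]] <- tibble(
    chrom = decoy_ch, start = 4.2e5, end = 4.2e5 + 60, period = 2,
    copy_number = 30, monomer = "AT"
  )
  trf[[length(trf) + 1]] <- tibble(
    chrom = decoy_ch, start = 6.1e5, end = 6.1e5 + 90, period = 3,
    copy_number = 30, monomer = "AGC"
  )
  trf[[length(trf) + 1]] <- tibble(
    chrom = decoy_ch, start = 7.3e5, end = 7.3e5 + 1204, period = 602,
    copy_number = 2, monomer = strrep("ACGT", 151)
  )
  trf_records <- list_rbind(trf)

  ## organelle insertions: replace target spans with mutated fragments
  ins <- cfg$insertions %||% tibble()
  hit_rows <- list()
  ins_truth <- list()
  if (nrow(ins) > 0) {
    for (i in seq_len(nrow(ins))) {
      org <- ins$organelle[i]; ch <- ins$chrom[i]
      len <- ins$length[i]; tgt <- ins$position[i]
      src0 <- ins$source_start[i]
      if (is.na(src0)) {
        src0 <- floor(runif(1, 0, nchar(orgs[[org]]) - len))
      }
      frag <- substr(orgs[[org]], src0 + 1, src0 + len)
      k <- round((1 - ins$identity[i] / 100) * len)
      mut <- mutate_to_identity(frag, ins$identity[i])
      if (ins$strand[i] == "-") mut <- revcomp(mut)
      substr(seqs[[ch]], tgt + 1, tgt + len) <- mut
      pident <- 100 * (1 - k / len)
      hit_rows[[length(hit_rows) + 1]] <- tibble(
        source_id = org, chrom = ch, identity = round(pident, 3),
        aln_length = len, mismatches = k, gap_opens = 0,
        source_start = src0, source_end = src0 + len,
        target_start = tgt, target_end = tgt + len,
        strand = ins$strand[i], evalue = 1e-50, bit_score = round(1.9 * len),
        organelle = org
      )
      ins_truth[[length(ins_truth) + 1]] <- tibble(
        organelle = org, chrom = ch, start = tgt, end = tgt + len,
        length = len, identity = pident, source_start = src0,
        source_end = src0 + len, strand = ins$strand[i], note = ins$note[i],
        tiers = list(INSERTION_TIERS[INSERTION_TIERS <= len])
      )
    }
  }
  ## sub-threshold noise hits (filtered out downstream)
  n_noise <- cfg$noise_hits %||% 0
  if (n_noise > 0) {
    for (j in seq_len(n_noise)) {
      org <- sample(names(orgs), 1)
      ch <- sample(names(lens), 1)
      fail_mode <- j %% 3
      len <- if (fail_mode == 1) sample(40:99, 1) else sample(150:600, 1)
      idn <- if (fail_mode == 2) runif(1, 80, 94.9) else runif(1, 95, 99)
      ev <- if (fail_mode == 0) 10^runif(1, -8, -4) else 1e-30
      tgt <- floor(runif(1, 0, lens[[ch]] - len))
      src0 <- floor(runif(1, 0, nchar(orgs[[org]]) - len))
      hit_rows[[length(hit_rows) + 1]] <- tibble(
        source_id = org, chrom = ch, identity = round(idn, 2),
        aln_length = len, mismatches = round(len * (1 - idn / 100)),
        gap_opens = 0, source_start = src0, source_end = src0 + len,
        target_start = tgt, target_end = tgt + len, strand = "+",
        evalue = ev, bit_score = round(1.5 * len), organelle = org
      )
    }
  }
  hits <- if (length(hit_rows) > 0) list_rbind(hit_rows) else tibble()
  if (length(ins_truth) > 0) truth$insertions <- list_rbind(ins_truth)

  genome <- genome(seqs)
  grid <- make_window_grid(genome, cfg$window_size)

  ## gene models on a regular lattice
  gp <- cfg$genes
  genes <- NULL
  if (!is.null(gp)) {
    genes <- imap(as.list(lens), function(L, ch) {
      starts <- seq(gp$offset, L - gp$length, by = gp$spacing)
      k <- seq_along(starts) - 1
      dup <- (k %% gp$dup_background_every) == 0
      cl <- gp$dup_cluster[gp$dup_cluster$chrom == ch, , drop = FALSE]
      if (nrow(cl) > 0) {
        incl <- starts >= cl$start[1] & starts < cl$end[1]
        dup[incl] <- (k[incl] %% 5) < 2   # 40% flagged inside the cluster
      }
      exon_len <- floor(gp$length * 0.4)
      tibble(
        chrom = ch, start = starts, end = starts + gp$length,
        gene_id = sprintf("g_%s_%05d", ch, k + 1),
        duplicated = dup,
        exons = purrr::map(starts, function(s) {
          tibble(start = c(s, s + gp$length - exon_len),
                 end = c(s + exon_len, s + gp$length))
        })
      )
    }) |> list_rbind()
    dc <- gp$dup_cluster
    if (nrow(dc) > 0) truth$dup_gene_clusters <- dc
  }

  ## repeat annotation: one interval per window at a planned coverage
  rp <- cfg$repeats
  repeats <- NULL
  if (!is.null(rp)) {
    rep_rows <- list()
    for (ch in unique(grid$chrom)) {
      gw <- grid[grid$chrom == ch, , drop = FALSE]
      rg <- rp$regions[rp$regions$chrom == ch, , drop = FALSE]
      frac <- runif(nrow(gw), rp$background_min, rp$background_max)
      if (nrow(rg) > 0) {
        mid <- (gw$start + gw$end) / 2
        inr <- mid >= rg$start[1] & mid < rg$end[1]
        idx <- which(inr)
        frac[idx] <- rg$fraction[1]
        # a small minority of windows inside the region stay at background
        low <- idx[seq_along(idx) %% rg$low_every[1] == 0]
        frac[low] <- runif(length(low), rp$background_min, rp$background_max)
      }
      rep_rows[[length(rep_rows) + 1]] <- tibble(
        chrom = ch, start = gw$start,
        end = gw$start + floor(frac * gw$width),
        name = "repeat"
      )
    }
    repeats <- list_rbind(rep_rows)
    if (nrow(rp$regions) > 0) {
      truth$repeat_rich_regions <- rp$regions[c("chrom", "start", "end")]
    }
  }

  ## SNP sites (pileup) and second-individual consensus
  sp <- cfg$snp
  pileup <- NULL; consensus <- NULL
  if (!is.null(sp)) {
    excl <- list()
    gaps_tbl <- genome_gaps(genome)
    for (ch in names(lens)) {
      f <- features[features$chrom == ch, , drop = FALSE]
      g <- gaps_tbl[gaps_tbl$chrom == ch, , drop = FALSE]
      excl[[ch]] <- IRanges::reduce(c(
        as_iranges0(f$start, f$end),
        as_iranges0(pmax(g$start - 3, 0), g$end + 3)
      ))
    }
    site_rows <- list()
    for (wi in seq_len(nrow(grid))) {
      ch <- grid$chrom[wi]; w0 <- grid$start[wi]; w1 <- grid$end[wi]
      mid <- (w0 + w1) / 2
      rates <- c(het = sp$het_per_window, hom = sp$hom_per_window,
                 ref = sp$ref_per_window)
      rg <- sp$regions[sp$regions$chrom == ch & sp$regions$start <= mid &
                         sp$regions$end > mid, , drop = FALSE]
      if (nrow(rg) > 0) {
        rates["het"] <- rg$het_per_window[1]
        rates["hom"] <- rg$hom_per_window[1]
      }
      dec <- sp$decoupled[sp$decoupled$chrom == ch &
                            sp$decoupled$start == w0, , drop = FALSE]
      gch <- if (!is.null(genes)) {
        genes[genes$chrom == ch & genes$start < w1 & genes$end > w0,
              c("start", "end"), drop = FALSE]
      } else tibble(start = double(), end = double())
      draw <- function(lambda) rpois(1, lambda)
      if (nrow(dec) > 0 && dec$type[1] == "conserved") {
        n_het <- 120; het_mode <- "avoid"
        n_hom <- draw(rates["hom"]); hom_mode <- "any"
      } else if (nrow(dec) > 0 && dec$type[1] == "diversifying") {
        n_het <- draw(rates["het"]); het_mode <- "any"
        n_hom <- 15; hom_mode <- "only"
      } else {
        n_het <- draw(rates["het"]); het_mode <- "any"
        n_hom <- draw(rates["hom"]); hom_mode <- "any"
      }
      n_ref <- draw(rates["ref"])
      pos_het <- sample_positions(n_het, w0, w1, excl[[ch]], gch, het_mode)
      pos_hom <- sample_positions(n_hom, w0, w1, excl[[ch]], gch, hom_mode)
      pos_ref <- sample_positions(n_ref, w0, w1, excl[[ch]], gch, "any")
      # resolve cross-category duplicates
      pos_hom <- setdiff(pos_hom, pos_het)
      pos_ref <- setdiff(pos_ref, c(pos_het, pos_hom))
      site_rows[[length(site_rows) + 1]] <- tibble(
        chrom = ch,
        pos = c(pos_het, pos_hom, pos_ref),
        true_state = rep(c("het", "hom", "ref"),
                         c(length(pos_het), length(pos_hom), length(pos_ref))),
        near_gap = FALSE
      )
    }
    ## explicit near-gap heterozygous sites (expected no-calls)
    if (nrow(gaps_tbl) > 0) {
      site_rows[[length(site_rows) + 1]] <- tibble(
        chrom = rep(gaps_tbl$chrom, 2),
        pos = c(gaps_tbl$start - 2, gaps_tbl$end + 1),
        true_state = "het", near_gap = TRUE
      )
    }
    sites <- list_rbind(site_rows) |> arrange(.data$chrom, .data$pos)
    n <- nrow(sites)
    ref <- substring(genome$seq[sites$chrom],
                     sites$pos + 1, sites$pos + 1)
    # alternate base differs from reference
    alt_base <- map_chr(ref, function(r) sample(setdiff(SIM_BASES, r), 1))
    depth <- rpois(n, sp$depth_mean)
    alt <- integer(n)
    is_het <- sites$true_state == "het"
    is_hom <- sites$true_state == "hom"
    alt[is_het] <- rbinom(sum(is_het), depth[is_het], 0.5)
    alt[is_hom] <- depth[is_hom]
    cnt <- matrix(0L, nrow = n, ncol = 4,
                  dimnames = list(NULL, SIM_BASES))
    cnt[cbind(seq_len(n), match(ref, SIM_BASES))] <- depth - alt
    cnt[cbind(seq_len(n), match(alt_base, SIM_BASES))] <-
      cnt[cbind(seq_len(n), match(alt_base, SIM_BASES))] + alt
    pileup <- tibble(
      chrom = sites$chrom, pos = sites$pos, ref = ref,
      A = cnt[, "A"], C = cnt[, "C"], G = cnt[, "G"], T = cnt[, "T"]
    )
    # the second individual carries the reference allele everywhere: sites
    # where the pileup individual is homozygous-alternate are the
    # inter-individual (homozygous) SNPs
    consensus <- tibble(chrom = sites$chrom, pos = sites$pos, base = ref)
    truth$snp_sites <- sites |>
      mutate(depth = depth, alt = alt, alt_base = alt_base)
    truth$snp_regions <- sp$regions
    truth$decoupled_windows <- sp$decoupled |>
      mutate(end = .data$start + cfg$window_size)
  }

  ## half-sib mapping genotype matrix
  mp <- cfg$mapping
  genotypes <- NULL
  if (!is.null(mp)) {
    built <- build_mapping_matrix(mp)
    genotypes <- built$genotypes
    truth$seg_loci <- built$loci
    truth$seg_retained <- built$retained
  }

  ## paternity panel
  pp <- cfg$paternity
  paternity <- NULL
  if (!is.null(pp)) {
    paternity <- build_paternity_panel(pp)
    truth$paternity <- paternity$truth
  }

  structure(
    list(
      config = cfg, genome = genome, grid = grid, organelles = orgs,
      hits = if (nrow(hits) > 0) normalize_hits_presorted(hits) else hits,
      trf_records = trf_records, genes = genes, repeats = repeats,
      pileup = pileup, consensus = consensus, genotypes = genotypes,
      paternity = paternity[c("mother", "candidates", "offspring")],
      truth = truth
    ),
    class = "genarch_sim"
  )
}

# hits are built already normalized (0-based, start<end, strand recorded)
normalize_hits_presorted <- function(hits) {
  arrange(hits, .data$organelle, .data$chrom, .data$target_start)
}

build_mapping_matrix <- function(mp) {
  inds <- sprintf("hs%03d", seq_len(mp$n_offspring))
  contigs <- sprintf("ctg%04d",
                     seq_len(mp$n_contigs_pair + mp$n_contigs_two +
                               mp$n_contigs_distorted))
  plan <- list()
  add_locus <- function(contig, position, class) {
    plan[[length(plan) + 1]] <<- tibble(
      locus = paste0(contig, "_p", position),
      contig = contig, position = position, class = class,
      n_missing = sample(0:mp$max_missing, 1)
    )
  }
  i <- 0
  for (k in seq_len(mp$n_contigs_pair)) {
    i <- i + 1
    add_locus(contigs[i], 100, "mendelian_1to1")
    add_locus(contigs[i], 200,
              if (k %% 2 == 0) "distorted_low_het" else "distorted_skewed")
  }
  for (k in seq_len(mp$n_contigs_two)) {
    i <- i + 1
    add_locus(contigs[i], 100, "mendelian_1to1")
    add_locus(contigs[i], 200, "mendelian_1to1")
  }
  for (k in seq_len(mp$n_contigs_distorted)) {
    i <- i + 1
    add_locus(contigs[i], 100,
              if (k %% 2 == 0) "distorted_low_het" else "distorted_skewed")
  }
  loci <- list_rbind(plan)

  rows <- purrr::pmap(loci, function(locus, contig, position, class,
                                     n_missing) {
    miss <- sample(inds, n_missing)
    avail <- setdiff(inds, miss)
    n_av <- length(avail)
    n_het <- switch(class,
      mendelian_1to1 = ceiling(n_av / 2),
      distorted_low_het = round(mp$het_fraction_low * n_av),
      distorted_skewed = round(mp$het_fraction_skewed * n_av)
    )
    het_ind <- sample(avail, n_het)
    geno <- setNames(rep("hom", length(inds)), inds)
    geno[het_ind] <- "het"
    geno[miss] <- "missing"
    if (mp$error_rate > 0) {
      flip <- avail[runif(n_av) < mp$error_rate]
      geno[flip] <- ifelse(geno[flip] == "het", "hom", "het")
    }
    depth <- pmax(rpois(length(inds), mp$depth_mean), mp$depth_min)
    tibble(locus = locus, contig = contig, position = position,
           individual = inds, genotype = unname(geno), depth = depth)
  })
  genotypes <- list_rbind(rows)

  # expected retained set: per contig the 1:1 locus with fewest missing
  # genotypes (ties -> smallest position); contigs without a 1:1 locus
  # retain nothing
  retained <- loci |>
    filter(.data$class == "mendelian_1to1") |>
    group_by(.data$contig) |>
    arrange(.data$n_missing, .data$position, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    pull("locus")
  list(genotypes = genotypes, loci = loci, retained = sort(retained))
}

build_paternity_panel <- function(pp) {
  loci <- sprintf("snp%02d", seq_len(pp$n_loci))
  allele_pool <- lapply(loci, function(l) {
    sample(SIM_BASES, pp$n_alleles)
  })
  names(allele_pool) <- loci
  draw_geno <- function(id) {
    tibble(
      individual = id, locus = loci,
      allele1 = map_chr(allele_pool, ~ sample(.x, 1)),
      allele2 = map_chr(allele_pool, ~ sample(.x, 1))
    )
  }
  mother <- draw_geno("MOTHER")
  cand_ids <- sprintf("F%02d", seq_len(pp$n_candidates))
  candidates <- list_rbind(purrr::map(cand_ids, draw_geno))
  candidates <- bind_rows(candidates, mother)  # selfing: mother is a candidate

  off_ids <- sprintf("off%03d", seq_len(pp$n_offspring))
  fathers <- c(rep("MOTHER", pp$n_self),
               sample(cand_ids, pp$n_offspring - pp$n_self, replace = TRUE))
  fathers <- sample(fathers)  # shuffle selfed offspring among the rest
  all_parents <- bind_rows(mother, candidates) |> distinct()
  offspring <- purrr::map2(off_ids, fathers, function(id, f) {
    fa <- all_parents[all_parents$individual == f, , drop = FALSE]
    a_m <- ifelse(runif(pp$n_loci) < 0.5, mother$allele1, mother$allele2)
    a_p <- ifelse(runif(pp$n_loci) < 0.5, fa$allele1, fa$allele2)
    if (pp$error_rate > 0) {
      err <- runif(pp$n_loci) < pp$error_rate
      a_p[err] <- map_chr(allele_pool[err], ~ sample(.x, 1))
    }
    tibble(individual = id, locus = loci, allele1 = a_m, allele2 = a_p)
  }) |> list_rbind()

  list(
    mother = mother, candidates = candidates, offspring = offspring,
    truth = tibble(offspring = off_ids, true_father = fathers)
  )
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `genome.fa`, per-organelle FASTAs, `hits_cp.tsv`/`hits_mt.tsv`
#' (BLAST tabular), `arrays.dat` (TRF dialect), `genes.gff3`,
#' `repeats.bed`, `pileup.tsv`, `consensus.tsv`, `genotypes.tsv`, the
#' paternity panel TSVs and `truth.json`.
#'
#' @param sim A `genarch_sim` from [simulate_dataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "genarch_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_genome_fasta(sim$genome, p("genome.fa"))
  for (org in names(sim$organelles)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(sim$organelles[org], org)),
      p(paste0(org, ".fa")), width = 60L
    )
  }
  if (!is.null(sim$hits) && nrow(sim$hits) > 0) {
    for (org in unique(sim$hits$organelle)) {
      write_blast_hits(sim$hits[sim$hits$organelle == org, ],
                       p(paste0("hits_", org, ".tsv")))
    }
  }
  write_trf_dat(sim$trf_records, p("arrays.dat"))
  if (!is.null(sim$genes)) write_genes_gff3(sim$genes, p("genes.gff3"))
  if (!is.null(sim$repeats)) write_regions_bed(sim$repeats, p("repeats.bed"))
  if (!is.null(sim$pileup)) write_pileup_tsv(sim$pileup, p("pileup.tsv"))
  if (!is.null(sim$consensus)) {
    readr::write_tsv(sim$consensus, p("consensus.tsv"), progress = FALSE)
  }
  if (!is.null(sim$genotypes)) {
    write_genotypes_tsv(sim$genotypes, p("genotypes.tsv"))
  }
  if (!is.null(sim$paternity)) {
    write_markers_tsv(sim$paternity$mother, p("paternity_mother.tsv"))
    write_markers_tsv(sim$paternity$candidates, p("paternity_candidates.tsv"))
    write_markers_tsv(sim$paternity$offspring, p("paternity_offspring.tsv"))
  }
  jsonlite::write_json(sim$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @export
print.genarch_sim <- function(x, ...) {
  cat("<genarch_sim> seed", x$config$seed, "\n")
  print(x$genome)
  cat("planted:",
      nrow(x$truth$insertions %||% tibble()), "insertions,",
      nrow(x$truth$telomeres %||% tibble()), "telomere ends,",
      nrow(x$truth$snp_sites %||% tibble()), "SNP sites\n")
  invisible(x)
}
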