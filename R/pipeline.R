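# Pipeline orchestration: a single run configuration drives the stages in
# dependency order, writes per-stage TSV/BED/VCF artifacts plus one
# machine-readable JSON summary, and stamps every output with the config
# hash for provenance.

pipeline_defaults <- function() {
  list(
    window_size = 1e5,
    min_identity = 95, min_insertion_length = 100, max_evalue = 1e-10,
    max_gap = 0, tiers = c(100, 1000, 10000),
    telomere_motif = "AAACCCT", end_zone = 1e5, min_array_bp = 1000,
    centromere_lengths = c(79, 80), cluster_window = 1e6,
    min_depth = 10, gap_flank = 3,
    low_het_min_span = 1e6, het_quantile = 0.1, low_het_flag_span = 5e6,
    repeat_threshold = 0.7, repeat_window_fraction = 0.9,
    repeat_min_span = 5e6, dup_fraction = 0.2, dup_min_span = 1e6,
    end_distance = 5e5, hotspot_min_span = 1e6, hotspot_coverage = 0.5,
    tandem_neighborhood = 2e5, tandem_min_events = 3,
    tandem_source_overlap = 0.5,
    seg_min_depth = 20, seg_min_het_fraction = 0.5, seg_chi_sq_max = 6.635,
    max_mismatch = 0
  )
}

#' Read a pipeline run configuration from YAML
#'
#' The file may contain `seed`, `out_dir`, `stages` (any of `repeats`,
#' `organelle`, `snps`, `segregation`, `paternity`), an `inputs` block of
#' file paths (`genome`, `trf`, `hits_cp`, `hits_mt`, `genes`, `repeats`,
#' `pileup`, `consensus`, `genotypes`, `paternity_mother`,
#' `paternity_candidates`, `paternity_offspring`) and a `params` block
#' overriding analysis thresholds. Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A run-configuration list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "out_dir", "stages", "inputs", "params", "log_level")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  known_inputs <- c("genome", "trf", "hits_cp", "hits_mt", "genes",
                    "repeats", "pileup", "consensus", "genotypes",
                    "paternity_mother", "paternity_candidates",
                    "paternity_offspring")
  bad_in <- setdiff(names(cfg$inputs), known_inputs)
  if (length(bad_in) > 0) {
    abort(paste0("unknown inputs key(s): ", paste(bad_in, collapse = ", ")))
  }
  bad_p <- setdiff(names(cfg$params), names(pipeline_defaults()))
  if (length(bad_p) > 0) {
    abort(paste0("unknown params key(s): ", paste(bad_p, collapse = ", ")))
  }
  cfg
}

#' Run the landscape pipeline
#'
#' Executes the requested stages in dependency order over the configured
#' inputs, writing per-stage artifacts and a JSON summary into `out_dir`.
#' Every output file carries the config hash in a header comment; two runs
#' with identical configuration produce byte-identical summaries.
#'
#' @param config Run-configuration list (see [read_run_config()]) or a
#'   path to a YAML file.
#' @return Invisibly, a list with `summary` (the JSON-serialized list) and
#'   `paths` of written files.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  params <- modifyList(pipeline_defaults(), config$params %||% list())
  stages <- config$stages %||%
    c("repeats", "organelle", "snps", "segregation", "paternity")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- config$inputs %||% list()
  for (nm in names(inputs)) {
    if (!file.exists(inputs[[nm]])) {
      abort(paste0("missing input file for '", nm, "': ", inputs[[nm]]))
    }
  }
  cfg_hash <- rlang::hash(list(stages = stages, inputs = inputs,
                               params = params, seed = config$seed %||% NA))
  stamp <- paste0("config_hash: ", cfg_hash)
  p <- function(...) file.path(out_dir, ...)
  paths <- character()
  summary <- list(config_hash = cfg_hash, params = params, stages = stages)

  need <- function(nm, stage) {
    if (is.null(inputs[[nm]])) {
      abort(paste0("stage '", stage, "' requires input '", nm, "'"))
    }
    inputs[[nm]]
  }

  gen <- NULL; grid <- NULL
  if (any(stages %in% c("repeats", "organelle", "snps"))) {
    gen <- read_genome_fasta(need("genome", "landscape"))
    grid <- make_window_grid(gen, params$window_size)
  }
  genes <- if (!is.null(inputs$genes)) read_genes_gff3(inputs$genes) else NULL

  if ("repeats" %in% stages) {
    rec <- parse_trf_dat(need("trf", "repeats"))
    monomers <- merge_monomer_frequencies(rec)
    tel <- call_telomeres(rec, gen, motif_family = params$telomere_motif,
                          end_zone = params$end_zone,
                          min_array_bp = params$min_array_bp)
    cen <- call_centromeres(rec, gen,
                            monomer_lengths = params$centromere_lengths,
                            cluster_window = params$cluster_window)
    write_profile_tsv(monomers |> select(-"members"),
                      p("monomer_frequencies.tsv"), stamp)
    tel_bed <- tel |>
      filter(.data$present) |>
      transmute(chrom = .data$chrom, start = .data$array_start,
                end = .data$array_end,
                name = paste0("telomere_", .data$end))
    write_regions_bed(tel_bed, p("telomeres.bed"), gen)
    cen_bed <- cen |>
      filter(!is.na(.data$cluster_start)) |>
      transmute(chrom = .data$chrom, start = .data$cluster_start,
                end = .data$cluster_end, name = "centromere_cluster")
    write_regions_bed(cen_bed, p("centromeres.bed"), gen)
    paths <- c(paths, p(c("monomer_frequencies.tsv", "telomeres.bed",
                          "centromeres.bed")))
    summary$repeats <- list(
      n_records = nrow(rec), n_canonical_monomers = nrow(monomers),
      top_monomer = if (nrow(monomers) > 0) monomers$canonical[1] else NA,
      n_telomere_ends_present = sum(tel$present),
      n_centromere_clusters = sum(!is.na(cen$cluster_start))
    )
  }

  if ("organelle" %in% stages) {
    hits <- bind_rows(
      read_blast_hits(need("hits_cp", "organelle")) |> mutate(organelle = "cp"),
      read_blast_hits(need("hits_mt", "organelle")) |> mutate(organelle = "mt")
    )
    kept <- filter_hits(hits, params$min_identity,
                        params$min_insertion_length, params$max_evalue)
    events <- merge_hits_to_events(kept, max_gap = params$max_gap)
    prof <- count_events_per_window(events, grid, tiers = params$tiers)
    anomalies <- bind_rows(
      detect_end_proximal(events, gen, params$end_distance) |>
        mutate(name = paste0("end_proximal_", .data$side)),
      detect_co_localization(events, grid, gen, params$end_distance) |>
        mutate(name = "co_localized"),
      detect_hotspot(events, grid, params$hotspot_min_span,
                     params$hotspot_coverage) |>
        mutate(name = "hotspot"),
      detect_tandem_like(events, params$tandem_neighborhood,
                         params$tandem_min_events,
                         params$tandem_source_overlap) |>
        mutate(name = paste0("tandem_like_", .data$organelle))
    )
    write_profile_tsv(
      events |> select(-"tiers", -"source_spans") |>
        mutate(tiers = map_chr(events$tiers, paste, collapse = ",")),
      p("insertion_events.tsv"), stamp)
    write_profile_tsv(prof, p("insertion_windows.tsv"), stamp)
    write_regions_bed(anomalies[c("chrom", "start", "end", "name")],
                      p("organelle_anomalies.bed"), gen)
    paths <- c(paths, p(c("insertion_events.tsv", "insertion_windows.tsv",
                          "organelle_anomalies.bed")))
    summary$organelle <- list(
      n_hits = nrow(hits), n_hits_kept = nrow(kept),
      n_events = nrow(events),
      n_events_cp = sum(events$organelle == "cp"),
      n_events_mt = sum(events$organelle == "mt"),
      n_events_ge10kb = sum(events$length >= 10000),
      anomalies = as.list(table(anomalies$type))
    )
  }

  if ("snps" %in% stages) {
    sites <- read_pileup_tsv(need("pileup", "snps"))
    calls <- classify_sites(sites, genome_gaps(gen),
                            min_depth = params$min_depth,
                            gap_flank = params$gap_flank)
    inter <- NULL
    if (!is.null(inputs$consensus)) {
      cons <- readr::read_tsv(inputs$consensus, progress = FALSE,
                              show_col_types = FALSE)
      inter <- call_inter_individual(calls, cons)
    }
    prof <- profile_snp_windows(calls, grid, genes = genes)
    low <- detect_low_het_regions(prof, params$low_het_min_span,
                                  params$het_quantile,
                                  params$low_het_flag_span)
    dec <- if (!is.null(genes)) {
      detect_decoupled_windows(prof, genes, grid)
    } else NULL
    rep_anom <- NULL
    if (!is.null(inputs$repeats) && !is.null(genes)) {
      reps <- read_regions_bed(inputs$repeats)
      rep_prof <- coverage_windows(reps, grid)
      rep_anom <- detect_repeat_gene_anomalies(
        rep_prof, genes, grid, params$repeat_threshold,
        params$repeat_window_fraction, params$repeat_min_span,
        params$dup_fraction, params$dup_min_span)
    }
    write_snp_vcf(calls |> mutate(alt = .data$alt_base), p("snp_calls.vcf"),
                  genome = gen)
    write_profile_tsv(prof, p("snp_windows.tsv"), stamp)
    anom <- bind_rows(
      low |> transmute(chrom = .data$chrom, start = .data$start,
                       end = .data$end, name = .data$type),
      if (!is.null(dec)) dec |>
        transmute(chrom = .data$chrom, start = .data$start,
                  end = .data$end, name = .data$subtype),
      if (!is.null(rep_anom)) rep_anom |>
        transmute(chrom = .data$chrom, start = .data$start,
                  end = .data$end, name = .data$type)
    )
    write_regions_bed(anom, p("snp_anomalies.bed"), gen)
    paths <- c(paths, p(c("snp_calls.vcf", "snp_windows.tsv",
                          "snp_anomalies.bed")))
    st <- table(calls$state)
    summary$snps <- list(
      n_sites = nrow(calls),
      n_het = unname(st["heterozygous"] %||% 0),
      n_hom_alt = unname(st["homozygous_alt"] %||% 0),
      n_no_call = sum(calls$state == "no_call"),
      n_inter_individual = if (!is.null(inter)) nrow(inter) else NA,
      n_low_het_regions = nrow(low),
      n_low_both_regions = sum(low$type == "low_both"),
      n_extended_regions = sum(low$extended),
      n_decoupled_windows = if (!is.null(dec)) nrow(dec) else NA,
      n_repeat_rich = if (!is.null(rep_anom)) {
        sum(rep_anom$type == "repeat_rich")
      } else NA,
      n_dup_gene_clusters = if (!is.null(rep_anom)) {
        sum(rep_anom$type == "dup_gene_cluster")
      } else NA
    )
  }

  if ("segregation" %in% stages) {
    g <- read_genotypes_tsv(need("genotypes", "segregation"))
    seg <- four_step_filter(g, min_depth = params$seg_min_depth,
                            min_het_fraction = params$seg_min_het_fraction,
                            chi_sq_max = params$seg_chi_sq_max)
    write_profile_tsv(tidy(seg), p("segregation_loci.tsv"), stamp)
    paths <- c(paths, p("segregation_loci.tsv"))
    summary$segregation <- as.list(seg$per_step_counts)
  }

  if ("paternity" %in% stages) {
    mom <- read_markers_tsv(need("paternity_mother", "paternity"))
    cand <- read_markers_tsv(need("paternity_candidates", "paternity"))
    off <- read_markers_tsv(need("paternity_offspring", "paternity"))
    pat <- assign_paternity(off, mom, cand, max_mismatch = params$max_mismatch)
    fam <- family_summary(pat)
    write_profile_tsv(pat, p("paternity_assignments.tsv"), stamp)
    write_profile_tsv(fam, p("fullsib_families.tsv"), stamp)
    paths <- c(paths, p(c("paternity_assignments.tsv",
                          "fullsib_families.tsv")))
    summary$paternity <- c(as.list(glance(pat)),
                           list(total_in_families = attr(fam, "total")))
  }

  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  writeLines(c(
    paste0("# ", stamp),
    paste0("stages: ", paste(stages, collapse = ", ")),
    paste0("outputs: ", paste(basename(paths), collapse = ", "))
  ), p("report.txt"))
  paths <- c(paths, p(c("summary.json", "report.txt")))
  invisible(list(summary = summary, paths = paths))
}
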