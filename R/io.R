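# Readers and writers for the remaining plain-text formats the pipeline
# touches: BED, window-profile TSV, minimal VCF, pileup TSV, GFF3 gene
# models and mapping-population genotype matrices. BED and GFF3 go through
# rtracklayer; coordinates are converted between the internal 0-based
# half-open frame and each format's native convention at this boundary
# only.

regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end),
    strand = if ("strand" %in% names(regions)) {
      ifelse(regions$strand %in% c("+", "-"), regions$strand, "*")
    } else "*"
  )
}

#' Write genomic regions as BED
#'
#' Writes BED4 (or BED5/BED6 when `score`/`strand` columns are present);
#' BED is natively 0-based half-open, matching the internal convention.
#'
#' @param regions Tibble with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns.
#' @param path Output path.
#' @param genome Optional `genarch_genome`; when given, region chromosomes
#'   are validated against it and unknown chromosomes are an error.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path, genome = NULL) {
  regions <- as_tibble(regions)
  if (!is.null(genome)) {
    check_chroms(regions$chrom, names(genome$seq), "BED region")
  }
  if (nrow(regions) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  gr <- regions_to_granges(regions)
  if ("name" %in% names(regions)) names(gr) <- regions$name
  if ("score" %in% names(regions)) {
    GenomicRanges::mcols(gr)$score <- regions$score
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file into a regions tibble
#' @param path Path to a BED file.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand` (0-based half-open).
#' @export
read_regions_bed <- function(path) {
  if (length(readLines(path, n = 1)) == 0) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr)
  )
  mc <- GenomicRanges::mcols(gr)
  if ("name" %in% names(mc) && !all(is.na(mc$name))) out$name <- mc$name
  if ("score" %in% names(mc) && !all(is.na(mc$score))) out$score <- mc$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}

#' Write a per-window profile as TSV
#'
#' One row per window; column meanings are documented in `#`-prefixed
#' header comments, followed by a named header line. Provenance comments
#' (e.g. a config hash) can be prepended.
#'
#' @param profile Tibble with one row per window.
#' @param path Output path.
#' @param comments Character vector of comment lines (without leading `#`).
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path, comments = character()) {
  hdr <- c(
    paste0("# ", comments),
    "# coordinates are 0-based half-open; one row per window"
  )
  writeLines(hdr, path)
  readr::write_tsv(profile, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read a window-profile TSV written by [write_profile_tsv()]
#' @param path Path to the TSV.
#' @return Tibble with one row per window.
#' @export
read_profile_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", progress = FALSE,
                  show_col_types = FALSE)
}

#' Write SNP calls as a minimal VCF 4.2
#'
#' Emits variant sites only (heterozygous and homozygous-alternate calls)
#' with a single-sample `GT` field (`0/1` for heterozygous, `1/1` for
#' homozygous-alternate). Internal 0-based positions become 1-based VCF
#' `POS`.
#'
#' @param calls Tibble of SNP calls from [classify_sites()] (columns
#'   `chrom`, `pos`, `ref`, `alt`, `state`).
#' @param path Output path.
#' @param sample_name Sample column name in the VCF header.
#' @param genome Optional `genarch_genome` used to validate chromosomes and
#'   write contig header lines.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(calls, path, sample_name = "sample", genome = NULL) {
  calls <- as_tibble(calls)
  if (!is.null(genome)) check_chroms(calls$chrom, names(genome$seq), "VCF call")
  keep <- calls$state %in% c("heterozygous", "homozygous_alt")
  v <- calls[keep, , drop = FALSE]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=genarch",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(genome)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(genome$lengths), genome$lengths))
  }
  hdr <- c(hdr, paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                       sample_name))
  gt <- ifelse(v$state == "heterozygous", "0/1", "1/1")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                  v$chrom, as.integer(v$pos) + 1L, v$ref, v$alt, gt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a pileup table (per-site base counts) as TSV
#' @param sites Tibble with `chrom`, `pos` (0-based), `ref`, `A`, `C`,
#'   `G`, `T`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(sites, path) {
  readr::write_tsv(sites, path, progress = FALSE)
  invisible(path)
}

#' Read a pileup table written by [write_pileup_tsv()]
#' @param path Path to the TSV.
#' @return Tibble with `chrom`, `pos`, `ref`, `A`, `C`, `G`, `T`.
#' @export
read_pileup_tsv <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_double(),
      ref = readr::col_character(), .default = readr::col_integer()
    ),
    progress = FALSE
  )
}

#' Write gene models to GFF3
#'
#' Genes are written as `gene` features with `ID` and a `duplication=1`
#' attribute for members of multi-copy families; exons (when present as a
#' list-column) are written as child `exon` features.
#'
#' @param genes Tibble with `chrom`, `start`, `end`, `gene_id`,
#'   `duplicated` (logical) and optional `exons` list-column of tibbles
#'   with `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  genes <- as_tibble(genes)
  feats <- list(tibble(
    chrom = genes$chrom, start = genes$start, end = genes$end,
    type = "gene", id = genes$gene_id, parent = NA_character_,
    dup = genes$duplicated
  ))
  if ("exons" %in% names(genes)) {
    feats[[2]] <- purrr::map2(genes$exons, seq_len(nrow(genes)), function(ex, i) {
      if (is.null(ex) || nrow(ex) == 0) return(NULL)
      tibble(
        chrom = genes$chrom[i], start = ex$start, end = ex$end,
        type = "exon",
        id = paste0(genes$gene_id[i], ".exon", seq_len(nrow(ex))),
        parent = genes$gene_id[i], dup = NA
      )
    }) |> list_rbind()
  }
  ft <- list_rbind(feats)
  gr <- GenomicRanges::GRanges(
    seqnames = ft$chrom,
    ranges = IRanges::IRanges(start = ft$start + 1, end = ft$end),
    strand = "+"
  )
  GenomicRanges::mcols(gr)$type <- ft$type
  GenomicRanges::mcols(gr)$source <- "genarch"
  GenomicRanges::mcols(gr)$ID <- ft$id
  GenomicRanges::mcols(gr)$Parent <- ft$parent
  GenomicRanges::mcols(gr)$duplication <-
    ifelse(!is.na(ft$dup) & ft$dup, "1", NA_character_)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Reads `gene` features (with their `exon` children collected into an
#' `exons` list-column) and interprets the attribute `duplication=1` as the
#' multi-copy-family flag.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with `chrom`, `start`, `end`, `gene_id`, `duplicated`,
#'   `exons` (0-based half-open).
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  mc <- GenomicRanges::mcols(gr)
  is_gene <- as.character(mc$type) == "gene"
  genes <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene] - 1,
    end = GenomicRanges::end(gr)[is_gene],
    gene_id = as.character(mc$ID[is_gene]),
    duplicated = if ("duplication" %in% names(mc)) {
      !is.na(mc$duplication[is_gene]) & mc$duplication[is_gene] == "1"
    } else FALSE
  )
  is_exon <- as.character(mc$type) == "exon"
  if (any(is_exon)) {
    par <- as.character(unlist(mc$Parent[is_exon]))
    ex <- tibble(
      gene_id = par,
      start = GenomicRanges::start(gr)[is_exon] - 1,
      end = GenomicRanges::end(gr)[is_exon]
    )
    ex_by <- split(ex[c("start", "end")], ex$gene_id)
    genes$exons <- unname(ex_by[genes$gene_id])
  }
  genes
}

#' Write a mapping-population genotype matrix as TSV
#'
#' Rows are loci (with contig of origin and position), columns are
#' individuals; each cell is `genotype:depth` with genotype in
#' `{het,hom,missing}`.
#'
#' @param genotypes Long tibble with `locus`, `contig`, `position`,
#'   `individual`, `genotype`, `depth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  wide <- genotypes |>
    mutate(cell = paste0(.data$genotype, ":", .data$depth)) |>
    select("locus", "contig", "position", "individual", "cell") |>
    tidyr::pivot_wider(names_from = "individual", values_from = "cell")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a mapping-population genotype matrix written by
#' [write_genotypes_tsv()]
#' @param path Path to the TSV.
#' @return Long tibble with `locus`, `contig`, `position`, `individual`,
#'   `genotype`, `depth`.
#' @export
read_genotypes_tsv <- function(path) {
  wide <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  wide |>
    tidyr::pivot_longer(-c("locus", "contig", "position"),
                        names_to = "individual", values_to = "cell") |>
    tidyr::separate_wider_delim("cell", ":", names = c("genotype", "depth")) |>
    mutate(depth = as.integer(.data$depth))
}

#' Write diploid marker genotypes (paternity panel) as TSV
#' @param markers Tibble with `individual`, `locus`, `allele1`, `allele2`
#'   (`NA` alleles denote a missing genotype).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markers_tsv <- function(markers, path) {
  readr::write_tsv(markers, path, progress = FALSE)
  invisible(path)
}

#' Read diploid marker genotypes written by [write_markers_tsv()]
#' @param path Path to the TSV.
#' @return Tibble with `individual`, `locus`, `allele1`, `allele2`.
#' @export
read_markers_tsv <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
}
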