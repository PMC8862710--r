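# Mapping-population computations: the four-step segregation filter with
# the 1:1 heterozygote:homozygote chi-square rule, Mendelian-exclusion
# paternity assignment for half-sib progenies, and family / linkage-map
# summary arithmetic.

#' Chi-square statistic for a 1:1 genotype ratio
#'
#' Pearson chi-square against equal expected heterozygote and homozygote
#' counts (`exp = (n_het + n_hom) / 2` for both classes, 1 d.f., no
#' continuity correction). The conventional critical value used by the
#' segregation filter is 6.635, the upper 1% point of chi-square with one
#' degree of freedom (`qchisq(0.99, 1)`), although it is sometimes
#' mislabelled as a 90% confidence threshold.
#'
#' @param n_het,n_hom Non-negative counts (vectorized).
#' @return Numeric chi-square statistic(s).
#' @examples
#' chi_square_1to1(130, 70) # 18
#' @export
chi_square_1to1 <- function(n_het, n_hom) {
  if (any(n_het + n_hom < 1)) {
    abort("chi_square_1to1 requires at least one observation")
  }
  e <- (n_het + n_hom) / 2
  (n_het - e)^2 / e + (n_hom - e)^2 / e
}

#' Four-step segregation filter for mapping-population SNPs
#'
#' Implements the genotype filter for a half-sib mapping population whose
#' informative loci are heterozygous in the mother and monomorphic in the
#' fathers (expected 1:1 het:hom segregation):
#' 1. heterozygous genotypes with depth below `min_depth` are set to
#'    homozygous (`low_depth_to = "hom"`, the default) or to missing;
#' 2. loci are kept when the heterozygote fraction is at least
#'    `min_het_fraction` (denominator: non-missing individuals by
#'    default, or the full population with
#'    `denominator = "population"`);
#' 3. loci are kept when [chi_square_1to1()] is strictly below
#'    `chi_sq_max`;
#' 4. per contig, only the surviving locus with fewest missing genotypes
#'    is retained (ties broken by smallest position).
#'
#' @param genotypes Long tibble with `locus`, `contig`, `position`,
#'   `individual`, `genotype` (`het`/`hom`/`missing`), `depth`.
#' @param min_depth Depth threshold of step 1 (default 20).
#' @param min_het_fraction Heterozygote-fraction threshold of step 2
#'   (default 0.5).
#' @param chi_sq_max Chi-square threshold of step 3 (default 6.635).
#' @param low_depth_to What a low-depth heterozygote becomes (default
#'   `"hom"`).
#' @param denominator Step-2 denominator convention.
#' @return An object of class `genarch_segfilter`: list with `loci`
#'   (per-locus tibble with counts, chi-square and per-step keep flags),
#'   `per_step_counts` (named vector, non-increasing), `retained`
#'   (character vector of locus ids) and `params`.
#' @export
four_step_filter <- function(genotypes, min_depth = 20,
                             min_het_fraction = 0.5, chi_sq_max = 6.635,
                             low_depth_to = c("hom", "missing"),
                             denominator = c("non_missing", "population")) {
  low_depth_to <- match.arg(low_depth_to)
  denominator <- match.arg(denominator)
  g <- as_tibble(genotypes)
  n_pop <- dplyr::n_distinct(g$individual)
  if (n_pop == 0) abort("zero individuals in genotype matrix")

  # step 1: low-depth heterozygotes become monomorphic (or missing)
  g <- g |>
    mutate(genotype = ifelse(.data$genotype == "het" & .data$depth < min_depth,
                             low_depth_to, .data$genotype))

  loci <- g |>
    group_by(.data$locus, .data$contig, .data$position) |>
    summarise(
      n_het = sum(.data$genotype == "het"),
      n_hom = sum(.data$genotype == "hom"),
      n_missing = sum(.data$genotype == "missing"),
      .groups = "drop"
    ) |>
    mutate(
      denom = if (denominator == "non_missing") .data$n_het + .data$n_hom
              else n_pop,
      het_fraction = ifelse(.data$denom > 0, .data$n_het / .data$denom, 0),
      kept_step2 = .data$het_fraction >= min_het_fraction,
      chi_square = ifelse(.data$n_het + .data$n_hom >= 1,
                          chi_square_1to1_safe(.data$n_het, .data$n_hom),
                          NA_real_),
      kept_step3 = .data$kept_step2 & !is.na(.data$chi_square) &
        .data$chi_square < chi_sq_max
    )

  step4 <- loci |>
    filter(.data$kept_step3) |>
    group_by(.data$contig) |>
    arrange(.data$n_missing, .data$position, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  loci <- loci |>
    mutate(kept_step4 = .data$locus %in% step4$locus) |>
    arrange(.data$contig, .data$position)

  counts <- c(
    input = nrow(loci),
    step1_depth_recode = nrow(loci),
    step2_het_fraction = sum(loci$kept_step2),
    step3_chi_square = sum(loci$kept_step3),
    step4_one_per_contig = sum(loci$kept_step4)
  )
  structure(
    list(
      loci = loci,
      per_step_counts = counts,
      retained = loci$locus[loci$kept_step4],
      params = list(min_depth = min_depth,
                    min_het_fraction = min_het_fraction,
                    chi_sq_max = chi_sq_max, low_depth_to = low_depth_to,
                    denominator = denominator, n_individuals = n_pop)
    ),
    class = "genarch_segfilter"
  )
}

# internal: vectorized chi-square tolerating zero totals (NA)
chi_square_1to1_safe <- function(n_het, n_hom) {
  tot <- n_het + n_hom
  e <- tot / 2
  ifelse(tot >= 1, (n_het - e)^2 / e + (n_hom - e)^2 / e, NA_real_)
}

#' @export
print.genarch_segfilter <- function(x, ...) {
  cat("<genarch_segfilter>\n")
  print(x$per_step_counts)
  cat("retained:", length(x$retained), "loci\n")
  invisible(x)
}

#' @rdname four_step_filter
#' @param x A `genarch_segfilter` object.
#' @param ... Unused.
#' @export
tidy.genarch_segfilter <- function(x, ...) {
  x$loci
}

#' @rdname four_step_filter
#' @export
glance.genarch_segfilter <- function(x, ...) {
  as_tibble(as.list(x$per_step_counts)) |>
    mutate(n_individuals = x$params$n_individuals,
           n_retained = length(x$retained))
}

#' Assign fathers by Mendelian exclusion
#'
#' For each offspring and candidate father, counts mismatching loci: a
#' locus mismatches when no candidate allele can serve as the paternal
#' allele given the mother and offspring genotypes. The paternal allele
#' set consists of the offspring alleles whose partner allele is carried
#' by the mother (both offspring alleles when the mother carries both).
#' Loci with missing genotypes in mother, offspring or candidate are
#' skipped for that comparison, as are loci where the offspring is
#' incompatible with the mother. An offspring is `assigned` when exactly
#' one candidate attains the minimum mismatch count and that minimum is at
#' most `max_mismatch`; several such candidates give `ambiguous`, none
#' `unassigned`. Self-pollination is accommodated simply by listing the
#' mother among the candidates.
#'
#' @param offspring Tibble with `individual`, `locus`, `allele1`,
#'   `allele2` (NA = missing) for the offspring.
#' @param mother Same layout for the mother (single individual).
#' @param candidates Same layout for the candidate fathers.
#' @param max_mismatch Maximum mismatches tolerated for assignment
#'   (default 0).
#' @return Tibble of class `genarch_paternity` with `offspring`,
#'   `assigned_father` (`NA` unless assigned), `status`
#'   (`assigned`/`ambiguous`/`unassigned`), `min_mismatch`,
#'   `n_candidates_at_min`, `n_informative`; attribute `mismatches` holds
#'   the full offspring x candidate mismatch table.
#' @export
assign_paternity <- function(offspring, mother, candidates,
                             max_mismatch = 0) {
  off <- as_tibble(offspring)
  mom <- as_tibble(mother) |> select("locus", m1 = "allele1", m2 = "allele2")
  cand <- as_tibble(candidates)

  shared <- intersect(unique(off$locus), intersect(unique(mom$locus),
                                                   unique(cand$locus)))
  if (length(shared) == 0) {
    warn("assign_paternity: no shared loci; all offspring unassigned")
    res <- tibble(
      offspring = unique(off$individual),
      assigned_father = NA_character_, status = "unassigned",
      min_mismatch = NA_integer_, n_candidates_at_min = 0L,
      n_informative = 0L
    )
    class(res) <- c("genarch_paternity", class(res))
    attr(res, "mismatches") <- tibble()
    return(res)
  }

  trio <- off |>
    filter(.data$locus %in% shared) |>
    inner_join(mom, by = "locus") |>
    mutate(
      a1_maternal = !is.na(.data$allele1) &
        (.data$allele1 == .data$m1 | .data$allele1 == .data$m2),
      a2_maternal = !is.na(.data$allele2) &
        (.data$allele2 == .data$m1 | .data$allele2 == .data$m2),
      p1 = ifelse(.data$a2_maternal, .data$allele1, NA_character_),
      p2 = ifelse(.data$a1_maternal, .data$allele2, NA_character_),
      informative = !is.na(.data$allele1) & !is.na(.data$allele2) &
        !is.na(.data$m1) & !(is.na(.data$p1) & is.na(.data$p2))
    ) |>
    filter(.data$informative)

  mm <- trio |>
    inner_join(cand |> rename(candidate = "individual", c1 = "allele1",
                              c2 = "allele2"),
               by = "locus", relationship = "many-to-many") |>
    mutate(
      cand_missing = is.na(.data$c1) | is.na(.data$c2),
      mismatch = !.data$cand_missing & !(
        (!is.na(.data$p1) & (.data$c1 == .data$p1 | .data$c2 == .data$p1)) |
        (!is.na(.data$p2) & (.data$c1 == .data$p2 | .data$c2 == .data$p2))
      )
    ) |>
    group_by(offspring = .data$individual, .data$candidate) |>
    summarise(
      n_mismatch = sum(.data$mismatch),
      n_compared = sum(!.data$cand_missing),
      .groups = "drop"
    )

  res <- mm |>
    group_by(.data$offspring) |>
    summarise(
      min_mismatch = min(.data$n_mismatch),
      n_candidates_at_min = sum(.data$n_mismatch == min(.data$n_mismatch)),
      best_candidate = .data$candidate[which.min(.data$n_mismatch)],
      .groups = "drop"
    ) |>
    mutate(
      assigned_father = ifelse(
        .data$min_mismatch <= max_mismatch & .data$n_candidates_at_min == 1,
        .data$best_candidate, NA_character_)
    ) |>
    mutate(status = dplyr::case_when(
      !is.na(.data$assigned_father) ~ "assigned",
      .data$min_mismatch <= max_mismatch ~ "ambiguous",
      TRUE ~ "unassigned"
    )) |>
    left_join(
      trio |> count(.data$individual, name = "n_informative"),
      by = c(offspring = "individual")
    ) |>
    select("offspring", "assigned_father", "status", "min_mismatch",
           "n_candidates_at_min", "n_informative")
  class(res) <- c("genarch_paternity", class(res))
  attr(res, "mismatches") <- mm
  res
}

#' @rdname assign_paternity
#' @param x A `genarch_paternity` result.
#' @param ... Unused.
#' @export
tidy.genarch_paternity <- function(x, ...) {
  attr(x, "mismatches")
}

#' @rdname assign_paternity
#' @export
glance.genarch_paternity <- function(x, ...) {
  tibble(
    n_offspring = nrow(x),
    n_assigned = sum(x$status == "assigned"),
    n_ambiguous = sum(x$status == "ambiguous"),
    n_unassigned = sum(x$status == "unassigned")
  )
}

#' Full-sib family summary from paternity assignments
#'
#' Counts assigned offspring per father. The total across families is
#' attached as the `total` attribute (and returned by
#' `sum(result$n_offspring)`).
#'
#' @param assignments Paternity result ([assign_paternity()]) or any
#'   tibble with `assigned_father` and `status` columns.
#' @return Tibble with `father`, `n_offspring`, sorted by father;
#'   attribute `total`.
#' @export
family_summary <- function(assignments) {
  fam <- as_tibble(assignments) |>
    filter(.data$status == "assigned") |>
    count(father = .data$assigned_father, name = "n_offspring") |>
    arrange(.data$father)
  attr(fam, "total") <- sum(fam$n_offspring)
  fam
}

#' Linkage-map totals
#'
#' Sums per-linkage-group genetic sizes and marker counts.
#'
#' @param sizes_cM Numeric vector of linkage-group sizes in centimorgans.
#' @param marker_counts Integer vector of SNP markers per linkage group
#'   (same length).
#' @return Tibble with `n_linkage_groups`, `total_cM`, `total_markers`.
#' @export
map_summary <- function(sizes_cM, marker_counts) {
  if (length(sizes_cM) != length(marker_counts)) {
    abort("sizes_cM and marker_counts must have equal length")
  }
  tibble(
    n_linkage_groups = length(sizes_cM),
    total_cM = sum(sizes_cM),
    total_markers = sum(marker_counts)
  )
}

#' Published beech full-sib family sizes
#'
#' The full-sib family sizes recovered by pedigree reconstruction in a
#' European Beech open-pollinated progeny trial (one mother, 19
#' neighbouring candidate fathers plus selfing), shipped as a plain-text
#' table for summary arithmetic and examples.
#'
#' @return Tibble with `father`, `family_size`.
#' @export
beech_fullsib_families <- function() {
  readr::read_tsv(
    system.file("extdata", "beech_fullsib_families.tsv", package = "genarch"),
    col_types = "ci", progress = FALSE
  )
}

#' Published beech linkage-group summary
#'
#' Genetic sizes (cM) and SNP marker counts of the 13 linkage groups of a
#' combined maternal beech linkage map, shipped as a plain-text table for
#' summary arithmetic and examples.
#'
#' @return Tibble with `lg`, `size_cM`, `n_snps`.
#' @export
beech_linkage_groups <- function() {
  readr::read_tsv(
    system.file("extdata", "beech_linkage_groups.tsv", package = "genarch"),
    col_types = "cii", progress = FALSE
  )
}
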