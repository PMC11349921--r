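# The two variant-filter pipelines and the carrier statistics built on them.
#
# Known-variant screen: ClinVar P/LP + cohort MAF < 0.0015 + mean depth
# > 20x, over the 13-gene panel.
# Candidate discovery: cohort MAF < 0.001 + depth > 20x + CADD Phred > 20 +
# complete (100%) disease penetrance, over variants not already classified
# P/LP.

CLINVAR_LEVELS <- c("PATHOGENIC", "LIKELY_PATHOGENIC",
                    "UNCERTAIN_RISK_ALLELE", "VUS", "LIKELY_BENIGN",
                    "BENIGN")

#' Read a variant annotation table
#'
#' Tab-separated with header columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#' `hgvs_c`, `hgvs_p`, `rsid`, `clinvar_significance`, `cadd_phred`,
#' `mean_depth`, `impute_info`, `external_af` (the last optional). Empty
#' strings are missing. `clinvar_significance` must use the fixed
#' vocabulary `PATHOGENIC`, `LIKELY_PATHOGENIC`, `UNCERTAIN_RISK_ALLELE`,
#' `VUS`, `LIKELY_BENIGN`, `BENIGN`.
#'
#' @param path Path to a TSV file.
#' @return An annotation tibble with an added `variant_id` key column.
#' @export
read_annotations <- function(path) {
  tbl <- readr::read_tsv(path, na = c("", "NA"), show_col_types = FALSE,
                         progress = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "gene", "clinvar_significance",
                "cadd_phred", "mean_depth")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop("annotation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(stats::na.omit(unique(tbl$clinvar_significance)),
                 CLINVAR_LEVELS)
  if (length(bad) > 0) {
    stop("unknown clinvar_significance value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(tbl$ref == tbl$alt, na.rm = TRUE)) {
    stop("annotation rows with ref == alt are invalid", call. = FALSE)
  }
  mutate(tbl, variant_id = variant_key(.data$chrom, .data$pos, .data$ref,
                                       .data$alt))
}

is_plp <- function(significance) {
  significance %in% c("PATHOGENIC", "LIKELY_PATHOGENIC")
}

annotate_maf <- function(annotations, genotypes) {
  maf <- compute_cohort_maf(
    semi_join(genotypes, annotations, by = "variant_id"))
  left_join(annotations, maf[, c("variant_id", "maf")], by = "variant_id")
}

new_mody_screen <- function(variants, stages, thresholds, pipeline) {
  structure(list(variants = variants, stages = stages,
                 thresholds = thresholds, pipeline = pipeline),
            class = "mody_screen")
}

#' Screen for previously reported pathogenic MODY variants
#'
#' Retains panel variants classified pathogenic or likely pathogenic in
#' ClinVar whose cohort minor allele frequency is below `maf_max` and whose
#' mean sequencing depth exceeds `depth_min`. Thresholds are fractions and
#' reads, respectively.
#'
#' @param annotations Annotation tibble from [read_annotations()] (panel
#'   variants).
#' @param genotypes Long genotype table covering the annotated variants.
#' @param maf_max Cohort MAF upper bound (exclusive); default 0.0015.
#' @param depth_min Mean-depth lower bound (exclusive); default 20.
#' @param panel Panel table; annotations are restricted to its genes.
#' @return A `mody_screen` object; `$variants` holds one row per surviving
#'   variant ordered by (chrom, pos), `$stages` the filtering waterfall.
#'   Use [generics::tidy()] / [generics::glance()] to extract tibbles.
#' @export
screen_known_variants <- function(annotations, genotypes, maf_max = 0.0015,
                                  depth_min = 20, panel = mody_panel()) {
  ann <- filter(annotations, .data$gene %in% panel$gene)
  ann <- annotate_maf(ann, genotypes)
  s1 <- filter(ann, is_plp(.data$clinvar_significance))
  s2 <- filter(s1, !is.na(.data$maf) & .data$maf < maf_max)
  s3 <- filter(s2, !is.na(.data$mean_depth) & .data$mean_depth > depth_min)
  out <- arrange(s3, .data$chrom, .data$pos)
  stages <- tibble(
    stage = c("panel", "clinvar_plp", "maf", "depth"),
    n = c(nrow(ann), nrow(s1), nrow(s2), nrow(out))
  )
  new_mody_screen(out, stages,
                  list(maf_max = maf_max, depth_min = depth_min), "known")
}

#' Per-variant carrier report with penetrance
#'
#' Penetrance is the share of carriers with a diabetic phenotype among all
#' carriers, including carriers with unknown glycemic status in the
#' denominator (N = total carriers).
#'
#' @param carriers Character vector of carrier ids (nonempty).
#' @param statuses Named character vector of lifetime glycemic statuses.
#' @param pedigree Optional `mody_pedigree` for the family count.
#' @param variant Variant id carried into the output.
#' @return One-row tibble: `variant_id`, `n_carriers`, `n_families`,
#'   `n_dm`, `n_pre_dm`, `n_nd`, `n_na`, `penetrance_pct`, and a `carriers`
#'   list-column.
#' @export
#' @examples
#' st <- c(rep("DIABETIC", 8), rep("PRE_DIABETIC", 8),
#'         rep("NON_DIABETIC", 3), rep("UNKNOWN", 2))
#' names(st) <- paste0("P", 1:21)
#' compute_penetrance(names(st), st)$penetrance_pct  # 100 * 8/21
compute_penetrance <- function(carriers, statuses, pedigree = NULL,
                               variant = NA_character_) {
  if (length(carriers) == 0) {
    stop("penetrance undefined for an empty carrier set", call. = FALSE)
  }
  st <- statuses[carriers]
  st[is.na(st)] <- "UNKNOWN"
  n <- length(carriers)
  n_dm <- sum(st == "DIABETIC")
  tibble(
    variant_id = variant,
    n_carriers = n,
    n_families = if (is.null(pedigree)) NA_integer_
                 else carrier_families(pedigree, carriers),
    n_dm = n_dm,
    n_pre_dm = sum(st == "PRE_DIABETIC"),
    n_nd = sum(st == "NON_DIABETIC"),
    n_na = sum(st == "UNKNOWN"),
    penetrance_pct = 100 * n_dm / n,
    carriers = list(sort(carriers))
  )
}

#' Carrier reports for a set of variants
#'
#' Vectorised wrapper around [compute_penetrance()]; variants without
#' carriers yield a zero row with undefined penetrance.
#'
#' @param variant_ids Variant ids present in `genotypes`.
#' @inheritParams discover_candidates
#' @param pedigree Optional pedigree for family counts.
#' @return Tibble with one row per variant.
#' @export
carrier_reports_for <- function(variant_ids, genotypes, statuses,
                                pedigree = NULL) {
  if (length(variant_ids) == 0) {
    return(tibble(variant_id = character(), n_carriers = integer(),
                  n_families = integer(), n_dm = integer(),
                  n_pre_dm = integer(), n_nd = integer(), n_na = integer(),
                  penetrance_pct = numeric(), carriers = list()))
  }
  purrr::map_dfr(variant_ids, function(v) {
    carr <- carriers_of(genotypes, v)
    if (length(carr) == 0) {
      return(tibble(variant_id = v, n_carriers = 0L,
                    n_families = if (is.null(pedigree)) NA_integer_ else 0L,
                    n_dm = 0L, n_pre_dm = 0L, n_nd = 0L, n_na = 0L,
                    penetrance_pct = NA_real_,
                    carriers = list(character())))
    }
    compute_penetrance(carr, statuses, pedigree, variant = v)
  })
}

#' Discover candidate MODY variants
#'
#' Four-stage pipeline over the panel: (1) restrict to panel variants not
#' already classified P/LP (the known screen owns those); (2) cohort
#' MAF < `maf_max` and mean depth > `depth_min`; (3) CADD Phred >
#' `cadd_min` (missing CADD fails); (4) penetrance equal to
#' `penetrance_required` percent. The stages are a conjunction, so their
#' order does not change the survivors; intermediate counts are logged in
#' `$stages`.
#'
#' @param annotations Annotation tibble (panel variants).
#' @param genotypes Long genotype table.
#' @param statuses Named character vector of lifetime glycemic statuses.
#' @param maf_max,depth_min,cadd_min,penetrance_required Thresholds;
#'   defaults 0.001, 20, 20, 100.
#' @param exclude_plp Drop ClinVar P/LP variants from the candidate pool
#'   (default `TRUE`); set `FALSE` to rank every panel variant.
#' @param pedigree Optional pedigree for family counts in the reports.
#' @param panel Panel table.
#' @return A `mody_screen` object whose `$variants` rows carry the carrier
#'   report columns (`n_carriers`, `penetrance_pct`, ...).
#' @export
discover_candidates <- function(annotations, genotypes, statuses,
                                maf_max = 0.001, depth_min = 20,
                                cadd_min = 20, penetrance_required = 100,
                                exclude_plp = TRUE, pedigree = NULL,
                                panel = mody_panel()) {
  ann <- filter(annotations, .data$gene %in% panel$gene)
  s1 <- if (exclude_plp) {
    filter(ann, !is_plp(.data$clinvar_significance))
  } else {
    ann
  }
  s1 <- annotate_maf(s1, genotypes)
  s2 <- filter(s1, !is.na(.data$maf) & .data$maf < maf_max &
                 !is.na(.data$mean_depth) & .data$mean_depth > depth_min)
  s3 <- filter(s2, !is.na(.data$cadd_phred) & .data$cadd_phred > cadd_min)
  rep3 <- carrier_reports_for(s3$variant_id, genotypes, statuses, pedigree)
  s4 <- inner_join(s3, rep3, by = "variant_id") |>
    filter(.data$n_carriers > 0,
           abs(.data$penetrance_pct - penetrance_required) < 1e-9) |>
    arrange(.data$chrom, .data$pos)
  stages <- tibble(
    stage = c("panel", "not_plp", "maf_depth", "cadd", "penetrance"),
    n = c(nrow(ann), nrow(s1), nrow(s2), nrow(s3), nrow(s4))
  )
  new_mody_screen(s4, stages,
                  list(maf_max = maf_max, depth_min = depth_min,
                       cadd_min = cadd_min,
                       penetrance_required = penetrance_required,
                       exclude_plp = exclude_plp),
                  "discovery")
}

#' Pool the carriers of a set of screened variants
#'
#' @param genotypes Long genotype table.
#' @param variant_ids Variant ids to pool.
#' @return Character vector: union of carrier ids.
#' @export
pooled_carriers <- function(genotypes, variant_ids) {
  sort(unique(unlist(lapply(variant_ids, carriers_of,
                            genotypes = genotypes))))
}

#' Carrier prevalence among diabetic participants
#'
#' Distinct carriers of the given variants divided by the number of
#' diabetic participants. Following the source convention, the numerator
#' counts *all* carriers regardless of their own glycemic status; set
#' `carriers_only_diabetic = TRUE` to restrict it to diabetic carriers.
#'
#' @param carriers Character vector of (pooled) carrier ids.
#' @param diabetic_ids Nonempty character vector of diabetic participant
#'   ids.
#' @param carriers_only_diabetic Restrict numerator to diabetic carriers.
#' @return Percentage (0-100).
#' @export
#' @examples
#' prevalence_among_diabetics(paste0("c", 1:45), paste0("d", 1:3043))
prevalence_among_diabetics <- function(carriers, diabetic_ids,
                                       carriers_only_diabetic = FALSE) {
  if (length(diabetic_ids) == 0) {
    stop("prevalence undefined for an empty diabetic set", call. = FALSE)
  }
  num <- unique(carriers)
  if (carriers_only_diabetic) num <- intersect(num, diabetic_ids)
  100 * length(num) / length(unique(diabetic_ids))
}

#' Per-variant share of the detected MODY spectrum
#'
#' Each variant's carriers as a percentage of all carriers across the
#' reported variant set, sorted descending.
#'
#' @param reports Tibble with `variant_id` and `n_carriers` columns (e.g.
#'   `tidy()` of a screen, or [compute_penetrance()] rows).
#' @return `reports` with an added `spectrum_share_pct` column, sorted by
#'   share.
#' @export
spectrum_report <- function(reports) {
  stopifnot(nrow(reports) >= 1)
  total <- sum(reports$n_carriers)
  reports |>
    mutate(spectrum_share_pct = 100 * .data$n_carriers / total) |>
    arrange(dplyr::desc(.data$spectrum_share_pct))
}

#' Overlap between clinical MODY suspects and P/LP carriers
#'
#' @param suspects Nonempty character vector of clinically suspected
#'   participant ids (see [flag_mody_suspects()]).
#' @param carriers Character vector of pooled P/LP carrier ids.
#' @return One-row tibble: `n_suspects`, `n_with_plp`, `percent`.
#' @export
suspect_overlap <- function(suspects, carriers) {
  if (length(suspects) == 0) {
    stop("suspect set is empty", call. = FALSE)
  }
  n_overlap <- length(intersect(unique(suspects), unique(carriers)))
  tibble(n_suspects = length(unique(suspects)),
         n_with_plp = n_overlap,
         percent = 100 * n_overlap / length(unique(suspects)))
}

#' @exportS3Method base::print
print.mody_screen <- function(x, ...) {
  cat("<mody_screen:", x$pipeline, "pipeline>\n")
  cat("thresholds:",
      paste(names(x$thresholds), unlist(x$thresholds), sep = "=",
            collapse = ", "), "\n")
  cat("waterfall:",
      paste(x$stages$stage, x$stages$n, sep = ":", collapse = " -> "), "\n")
  cat(nrow(x$variants), "surviving variant(s)\n")
  if (nrow(x$variants) > 0) {
    cols <- intersect(c("variant_id", "gene", "clinvar_significance",
                        "maf", "cadd_phred", "n_carriers",
                        "penetrance_pct"), names(x$variants))
    print(x$variants[, cols])
  }
  invisible(x)
}

#' Tidy a screen result into a per-variant tibble
#'
#' @param x A `mody_screen` object.
#' @param ... Unused.
#' @return Tibble with one row per surviving variant.
#' @export
tidy.mody_screen <- function(x, ...) {
  out <- x$variants
  out$carriers <- NULL
  as_tibble(out)
}

#' One-row summary of a screen run
#'
#' @param x A `mody_screen` object.
#' @param ... Unused.
#' @return One-row tibble: pipeline, input/output sizes and thresholds.
#' @export
glance.mody_screen <- function(x, ...) {
  dplyr::bind_cols(
    tibble(pipeline = x$pipeline,
           n_input = x$stages$n[1],
           n_survivors = x$stages$n[nrow(x$stages)]),
    as_tibble(x$thresholds)
  )
}
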