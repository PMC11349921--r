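# Cohort-, variant- and carrier-level summary reports mirroring the usual
# presentation of family-cohort MODY screens: a demographic table by
# glycemic stratum, a per-variant table with penetrance and diagnosis
# breakdown, and a per-subtype clinical profile of the carriers.

mean_sd <- function(x, sd_single = c("na", "zero")) {
  sd_single <- match.arg(sd_single)
  x <- x[!is.na(x)]
  if (length(x) == 0) return(c(mean = NA_real_, sd = NA_real_))
  s <- if (length(x) == 1) {
    if (sd_single == "zero") 0 else NA_real_
  } else {
    stats::sd(x)
  }
  c(mean = mean(x), sd = s)
}

#' Cohort demographic and clinical summary by glycemic stratum
#'
#' One row per stratum (`ALL`, `DIABETIC`, `PRE_DIABETIC`, `NON_DIABETIC`)
#' with counts, percentages, and mean/SD of age, BMI and available
#' laboratory fields, plus the number of diabetics on glucose-lowering
#' treatment.
#'
#' @param phenotypes Visit tibble (see [read_phenotypes()]).
#' @param sd_single How to report SD for single-observation strata:
#'   `"na"` (default) or `"zero"`.
#' @return A tibble with one row per stratum.
#' @export
cohort_summary <- function(phenotypes, sd_single = c("na", "zero")) {
  sd_single <- match.arg(sd_single)
  if (nrow(phenotypes) == 0) {
    stop("phenotype table is empty", call. = FALSE)
  }
  participants <- classify_participants(phenotypes)
  lab_cols <- intersect(c("fpg", "ogtt_2h", "tg", "chol", "hdl", "ldl",
                          "sbp", "dbp"), names(phenotypes))
  last_visit <- phenotypes |>
    arrange(.data$participant_id, .data$exam_age) |>
    group_by(.data$participant_id) |>
    dplyr::slice_tail(n = 1) |>
    ungroup()
  dat <- left_join(participants, last_visit, by = "participant_id")

  n_total <- nrow(dat)
  one_stratum <- function(label, rows) {
    stats_tbl <- purrr::map(c(age = "exam_age", bmi = "bmi.y", lab_cols |>
                                setNames(lab_cols)),
                            function(col) mean_sd(rows[[col]], sd_single))
    out <- tibble(stratum = label, n = nrow(rows),
                  pct = 100 * nrow(rows) / n_total)
    for (nm in names(stats_tbl)) {
      out[[paste0(nm, "_mean")]] <- stats_tbl[[nm]][["mean"]]
      out[[paste0(nm, "_sd")]] <- stats_tbl[[nm]][["sd"]]
    }
    out$n_treated <- sum(rows$glucose_lowering_agent &
                           !rows$metformin_non_diabetic, na.rm = TRUE)
    out
  }
  strata <- c("DIABETIC", "PRE_DIABETIC", "NON_DIABETIC")
  bind_rows(
    one_stratum("ALL", dat),
    purrr::map_dfr(strata, function(s) {
      one_stratum(s, dat[dat$lifetime_status == s, ])
    })
  )
}

#' Per-variant report with penetrance and diagnosis breakdown
#'
#' Joins a screen result with carrier reports: identifiers, HGVS, cohort
#' MAF, CADD, ClinVar class, carrier and family counts, diagnosis
#' breakdown and penetrance.
#'
#' @param screen A `mody_screen` object (from [screen_known_variants()] or
#'   [discover_candidates()]).
#' @param genotypes Long genotype table.
#' @param statuses Named character vector of lifetime statuses.
#' @param pedigree Optional pedigree for family counts.
#' @return Tibble, one row per surviving variant; discovery rows carry
#'   `candidate = TRUE`.
#' @export
variant_report <- function(screen, genotypes, statuses, pedigree = NULL) {
  stopifnot(inherits(screen, "mody_screen"))
  base <- tidy(screen)
  if (nrow(base) == 0) return(base)
  rep_cols <- c("n_carriers", "n_families", "n_dm", "n_pre_dm", "n_nd",
                "n_na", "penetrance_pct")
  if (!all(rep_cols %in% names(base))) {
    reports <- carrier_reports_for(base$variant_id, genotypes, statuses,
                                   pedigree)
    reports$carriers <- NULL
    base <- left_join(base, reports, by = "variant_id")
  }
  mutate(base, candidate = screen$pipeline == "discovery")
}

#' Clinical profile of carriers, per variant
#'
#' For each variant: carrier/family counts, sex split, mean/SD of age,
#' BMI and labs at the carriers' latest visit, BMI-category percentages,
#' glycemic-status breakdown, family history of diabetes among diabetic
#' carriers (first and second degree), and treatment counts. Variants
#' without carriers are omitted with a warning. Single-carrier subtypes
#' report `NA` SDs.
#'
#' @param variant_ids Variants to profile.
#' @param genotypes Long genotype table.
#' @param phenotypes Visit tibble.
#' @param pedigree A `mody_pedigree`.
#' @return Tibble with one row per variant that has carriers.
#' @export
carrier_clinical_report <- function(variant_ids, genotypes, phenotypes,
                                    pedigree) {
  participants <- classify_participants(phenotypes)
  statuses <- setNames(participants$lifetime_status,
                       participants$participant_id)
  sex_of <- setNames(pedigree$sex, pedigree$id)
  last_visit <- phenotypes |>
    arrange(.data$participant_id, .data$exam_age) |>
    group_by(.data$participant_id) |>
    dplyr::slice_tail(n = 1) |>
    ungroup()
  rel <- relative_table(pedigree, max_degree = 2)
  lab_cols <- intersect(c("fpg", "ogtt_2h", "tg", "chol", "hdl", "ldl"),
                        names(phenotypes))

  purrr::map_dfr(variant_ids, function(v) {
    carr <- carriers_of(genotypes, v)
    if (length(carr) == 0) {
      warning("variant without carriers omitted from report: ", v,
              call. = FALSE)
      return(NULL)
    }
    rows <- last_visit[last_visit$participant_id %in% carr, ]
    part <- participants[participants$participant_id %in% carr, ]
    st <- statuses[carr]
    st[is.na(st)] <- "UNKNOWN"
    bmic <- part$bmi_category
    dm_carr <- carr[st == "DIABETIC"]
    fh_degree <- function(ids, deg) {
      sum(vapply(ids, function(id) {
        rls <- rel$relative[rel$id == id & rel$degree == deg]
        any(statuses[rls] == "DIABETIC", na.rm = TRUE)
      }, logical(1)))
    }
    age <- mean_sd(rows$exam_age)
    bmi <- mean_sd(part$bmi)
    out <- tibble(
      variant_id = v,
      n_carriers = length(carr),
      n_families = carrier_families(pedigree, carr),
      n_female = sum(sex_of[carr] == "F", na.rm = TRUE),
      age_mean = age[["mean"]], age_sd = age[["sd"]],
      bmi_mean = bmi[["mean"]], bmi_sd = bmi[["sd"]],
      pct_underweight = 100 * mean(bmic == "UNDERWEIGHT"),
      pct_normal = 100 * mean(bmic == "NORMAL"),
      pct_overweight = 100 * mean(bmic == "OVERWEIGHT"),
      pct_obese = 100 * mean(bmic == "OBESE"),
      n_dm = sum(st == "DIABETIC"),
      n_pre_dm = sum(st == "PRE_DIABETIC"),
      n_nd = sum(st == "NON_DIABETIC"),
      n_na = sum(st == "UNKNOWN"),
      fh_first_degree = fh_degree(dm_carr, 1L),
      fh_second_degree = fh_degree(dm_carr, 2L),
      n_treated = sum(rows$glucose_lowering_agent &
                        !rows$metformin_non_diabetic, na.rm = TRUE)
    )
    for (col in lab_cols) {
      ms <- mean_sd(rows[[col]])
      out[[paste0(col, "_mean")]] <- ms[["mean"]]
      out[[paste0(col, "_sd")]] <- ms[["sd"]]
    }
    out
  })
}

#' Write a screen result as TSV plus a JSON run log
#'
#' The JSON log carries the pipeline name, thresholds and the filtering
#' waterfall (variants in/out per stage), sufficient to reconstruct the
#' run; the TSV holds the per-variant table. Output is byte-stable for
#' identical inputs.
#'
#' @param screen A `mody_screen` object.
#' @param dir Output directory.
#' @param name Basename for the two files (default the pipeline name).
#' @return Paths of the written files, invisibly.
#' @export
write_screen_report <- function(screen, dir, name = screen$pipeline) {
  stopifnot(inherits(screen, "mody_screen"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, paste0(name, ".tsv"))
  json <- file.path(dir, paste0(name, "_log.json"))
  readr::write_tsv(tidy(screen), tsv, na = "", progress = FALSE)
  jsonlite::write_json(
    list(pipeline = screen$pipeline, thresholds = screen$thresholds,
         waterfall = screen$stages),
    json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}
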