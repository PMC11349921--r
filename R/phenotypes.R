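# Glycemic phenotype classification under the ADA rules:
#   diabetic       FPG >= 126 mg/dl, or 2h-OGTT >= 200 mg/dl, or use of
#                  glucose-lowering agents (metformin taken for non-diabetic
#                  purposes does not count)
#   pre-diabetic   FPG in [100, 125] or OGTT in [140, 199]
#   non-diabetic   every available measure below its pre-diabetic cutoff
# A visit with no biomarker and no medication record is UNKNOWN.

FPG_DIABETIC <- 126
FPG_PREDIABETIC <- 100
OGTT_DIABETIC <- 200
OGTT_PREDIABETIC <- 140

#' Read a longitudinal phenotype table
#'
#' Reads a tab-separated phenotype table with one row per participant visit.
#' Expected columns: `participant_id`, `exam_age`, `fpg`, `ogtt_2h`,
#' `glucose_lowering_agent`, `metformin_non_diabetic`, `bmi`, and optionally
#' `sbp`, `dbp`, `tg`, `chol`, `hdl`, `ldl`, `creatinine`,
#' `self_reported_onset`, `insulin_resistance`. Empty strings are missing.
#'
#' @param path Path to a TSV file.
#' @return A tibble of visits.
#' @export
read_phenotypes <- function(path) {
  tbl <- readr::read_tsv(path, na = c("", "NA"), show_col_types = FALSE,
                         progress = FALSE)
  required <- c("participant_id", "exam_age", "fpg", "ogtt_2h",
                "glucose_lowering_agent", "metformin_non_diabetic")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop("phenotype table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl$participant_id <- as.character(tbl$participant_id)
  tbl$glucose_lowering_agent <- as.logical(tbl$glucose_lowering_agent)
  tbl$metformin_non_diabetic <- as.logical(tbl$metformin_non_diabetic)
  tbl
}

#' Classify glycemic status of each visit
#'
#' Applies the ADA thresholds to every row of a visit table. Closed
#' thresholds as published: FPG 126 / OGTT 200 themselves classify diabetic,
#' FPG 100 / OGTT 140 pre-diabetic. Medication dominates biomarkers; a
#' metformin-for-non-diabetic-purposes flag cancels the medication criterion
#' for that visit.
#'
#' @param visits A data frame with columns `fpg`, `ogtt_2h`,
#'   `glucose_lowering_agent`, `metformin_non_diabetic` (missing values
#'   allowed everywhere; missing medication flags are treated as `FALSE`).
#' @param strict_nondiabetic If `TRUE`, non-diabetic requires *both*
#'   biomarkers present and below their pre-diabetic cutoffs; by default a
#'   visit is non-diabetic when all *available* measures are below cutoff.
#' @return `visits` with an added character column `visit_status`, one of
#'   `"DIABETIC"`, `"PRE_DIABETIC"`, `"NON_DIABETIC"`, `"UNKNOWN"`.
#' @export
#' @examples
#' classify_visits(tibble::tibble(
#'   fpg = c(126, 99, 95, NA), ogtt_2h = c(NA, 139, 150, NA),
#'   glucose_lowering_agent = c(FALSE, FALSE, FALSE, TRUE),
#'   metformin_non_diabetic = FALSE))
classify_visits <- function(visits, strict_nondiabetic = FALSE) {
  stopifnot(is.data.frame(visits))
  fpg <- visits$fpg
  ogtt <- visits$ogtt_2h
  if (any(fpg < 0, na.rm = TRUE) || any(ogtt < 0, na.rm = TRUE)) {
    stop("negative glucose biomarker values are invalid", call. = FALSE)
  }
  meds <- visits$glucose_lowering_agent %||% rep(FALSE, nrow(visits))
  met_nd <- visits$metformin_non_diabetic %||% rep(FALSE, nrow(visits))
  meds[is.na(meds)] <- FALSE
  met_nd[is.na(met_nd)] <- FALSE

  diabetic <- (!is.na(fpg) & fpg >= FPG_DIABETIC) |
    (!is.na(ogtt) & ogtt >= OGTT_DIABETIC) |
    (meds & !met_nd)
  pre <- (!is.na(fpg) & fpg >= FPG_PREDIABETIC & fpg < FPG_DIABETIC) |
    (!is.na(ogtt) & ogtt >= OGTT_PREDIABETIC & ogtt < OGTT_DIABETIC)
  fpg_low <- !is.na(fpg) & fpg < FPG_PREDIABETIC
  ogtt_low <- !is.na(ogtt) & ogtt < OGTT_PREDIABETIC
  non <- if (strict_nondiabetic) {
    fpg_low & ogtt_low
  } else {
    (fpg_low | ogtt_low) & (is.na(fpg) | fpg_low) & (is.na(ogtt) | ogtt_low)
  }

  status <- dplyr::case_when(
    diabetic ~ "DIABETIC",
    pre ~ "PRE_DIABETIC",
    non ~ "NON_DIABETIC",
    TRUE ~ "UNKNOWN"
  )
  dplyr::mutate(as_tibble(visits), visit_status = status)
}

#' Categorise body-mass index by the WHO cutoffs
#'
#' @param bmi Numeric vector of BMI values in kg/m^2; `NA` allowed.
#' @return Character vector: `<18.5` UNDERWEIGHT, `[18.5,25)` NORMAL,
#'   `[25,30)` OVERWEIGHT, `>=30` OBESE, missing UNKNOWN.
#' @export
#' @examples
#' bmi_category(c(22.73, 32.2, 25, NA))
bmi_category <- function(bmi) {
  if (any(bmi <= 0, na.rm = TRUE)) {
    stop("BMI must be strictly positive", call. = FALSE)
  }
  dplyr::case_when(
    is.na(bmi) ~ "UNKNOWN",
    bmi < 18.5 ~ "UNDERWEIGHT",
    bmi < 25 ~ "NORMAL",
    bmi < 30 ~ "OVERWEIGHT",
    TRUE ~ "OBESE"
  )
}

#' Reduce visit classifications to lifetime participant records
#'
#' Collapses a longitudinal visit table to one row per participant:
#' lifetime glycemic status is the severity maximum over visits
#' (DIABETIC > PRE_DIABETIC > NON_DIABETIC > UNKNOWN), onset age is the exam
#' age of the earliest diabetic visit unless a self-reported onset age is
#' supplied (which takes precedence), and BMI category comes from the latest
#' visit with a recorded BMI.
#'
#' @param visits Visit table; columns as for [classify_visits()] plus
#'   `participant_id`, `exam_age`, and optionally `bmi`,
#'   `self_reported_onset`, `insulin_resistance`.
#' @param strict_nondiabetic Passed to [classify_visits()].
#' @return One-row-per-participant tibble with `participant_id`,
#'   `lifetime_status`, `onset_age`, `bmi`, `bmi_category`,
#'   `insulin_resistance`, `n_visits`.
#' @export
classify_participants <- function(visits, strict_nondiabetic = FALSE) {
  stopifnot(is.data.frame(visits), nrow(visits) > 0)
  if (!"participant_id" %in% names(visits)) {
    stop("visit table needs a participant_id column", call. = FALSE)
  }
  cls <- classify_visits(visits, strict_nondiabetic = strict_nondiabetic)
  cls$.sev <- match(cls$visit_status, .STATUS_LEVELS)
  if (!"bmi" %in% names(cls)) cls$bmi <- NA_real_
  if (!"self_reported_onset" %in% names(cls)) {
    cls$self_reported_onset <- NA_real_
  }
  if (!"insulin_resistance" %in% names(cls)) cls$insulin_resistance <- FALSE
  cls$insulin_resistance[is.na(cls$insulin_resistance)] <- FALSE

  cls |>
    arrange(.data$participant_id, .data$exam_age) |>
    group_by(.data$participant_id) |>
    summarise(
      lifetime_status = .STATUS_LEVELS[max(.data$.sev)],
      first_diabetic_age = if (any(.data$visit_status == "DIABETIC")) {
        min(.data$exam_age[.data$visit_status == "DIABETIC"])
      } else {
        NA_real_
      },
      self_reported_onset = if (all(is.na(.data$self_reported_onset))) {
        NA_real_
      } else {
        min(.data$self_reported_onset, na.rm = TRUE)
      },
      bmi = if (all(is.na(.data$bmi))) NA_real_ else {
        .data$bmi[!is.na(.data$bmi)][sum(!is.na(.data$bmi))]
      },
      insulin_resistance = any(.data$insulin_resistance),
      n_visits = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(
      onset_age = dplyr::if_else(
        .data$lifetime_status == "DIABETIC",
        dplyr::coalesce(.data$self_reported_onset, .data$first_diabetic_age),
        NA_real_
      ),
      bmi_category = bmi_category(.data$bmi)
    ) |>
    select("participant_id", "lifetime_status", "onset_age", "bmi",
           "bmi_category", "insulin_resistance", "n_visits")
}

#' Determine age at diabetes onset for one participant
#'
#' Self-reported onset age takes precedence over the exam age of the first
#' visit classified diabetic (follow-up visits bound the true onset only
#' coarsely).
#'
#' @param visits Visit rows of a single diabetic participant.
#' @return Onset age in years, or `NA` if no diabetic visit and no
#'   self-report exists.
#' @export
determine_onset_age <- function(visits) {
  rec <- classify_participants(visits)
  if (nrow(rec) != 1) {
    stop("determine_onset_age expects visits of a single participant",
         call. = FALSE)
  }
  if (rec$lifetime_status != "DIABETIC") {
    stop("onset age is only defined for diabetic participants", call. = FALSE)
  }
  rec$onset_age
}

#' Flag participants with a clinically suspected MODY phenotype
#'
#' A participant is flagged as a clinical MODY suspect when all three hold:
#' diabetes onset before age 25; a family history of diabetes (a diabetic
#' relative of the configured degree); and no evidence of type 1 or type 2
#' diabetes, operationalised as normal or under body weight with no
#' insulin-resistance marker.
#'
#' @param participants Output of [classify_participants()].
#' @param pedigree A [read_ped()] pedigree. Participants absent from the
#'   pedigree get `family_history = FALSE` (with a warning).
#' @param degree Relationship degree(s) that count towards family history;
#'   default first-degree only.
#' @return `participants` with added logical columns `onset_under_25`,
#'   `family_history`, `no_t1d_t2d_evidence`, `is_suspect`.
#' @export
flag_mody_suspects <- function(participants, pedigree, degree = 1) {
  stopifnot(is.data.frame(participants))
  statuses <- setNames(participants$lifetime_status,
                       participants$participant_id)
  in_ped <- participants$participant_id %in% pedigree$id
  if (!all(in_ped)) {
    warning(sum(!in_ped), " participant(s) absent from pedigree; ",
            "family history taken as FALSE for them", call. = FALSE)
  }

  # Family history is only decidable (and only matters) for diabetics with
  # a pedigree entry; avoids relative lookups for the whole cohort.
  fh <- rep(FALSE, nrow(participants))
  need <- which(in_ped & participants$lifetime_status == "DIABETIC")
  rel_map <- relative_table(pedigree, max_degree = max(degree))
  for (i in need) {
    id <- participants$participant_id[i]
    rels <- rel_map$relative[rel_map$id == id & rel_map$degree %in% degree]
    fh[i] <- any(statuses[rels] == "DIABETIC", na.rm = TRUE)
  }

  participants |>
    mutate(
      onset_under_25 = !is.na(.data$onset_age) & .data$onset_age < 25,
      family_history = fh,
      no_t1d_t2d_evidence =
        .data$bmi_category %in% c("NORMAL", "UNDERWEIGHT") &
        !.data$insulin_resistance,
      is_suspect = .data$onset_under_25 & .data$family_history &
        .data$no_t1d_t2d_evidence
    )
}
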