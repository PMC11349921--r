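# Shared fixtures, built once per test run.

.cache <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.cache$fx)) .cache$fx <- tcgs_fixture()
  .cache$fx
}

get_participants <- function() {
  if (is.null(.cache$participants)) {
    .cache$participants <- classify_participants(get_fixture()$phenotypes)
  }
  .cache$participants
}

get_statuses <- function() {
  p <- get_participants()
  stats::setNames(p$lifetime_status, p$participant_id)
}

# one-visit helper
visit <- function(fpg = NA_real_, ogtt = NA_real_, meds = FALSE,
                  met_nd = FALSE, age = 40, id = "p1", bmi = NA_real_,
                  self_onset = NA_real_) {
  tibble::tibble(participant_id = id, exam_age = age, fpg = fpg,
                 ogtt_2h = ogtt, glucose_lowering_agent = meds,
                 metformin_non_diabetic = met_nd, bmi = bmi,
                 self_reported_onset = self_onset)
}

# trio pedigree: father F1, mother M1, child C1
trio_ped <- function() {
  as_pedigree(tibble::tibble(
    family_id = "T1", id = c("F1", "M1", "C1"),
    father_id = c(NA, NA, "F1"), mother_id = c(NA, NA, "M1"),
    sex = c("M", "F", "M")))
}

# large single-couple pedigree for transmission-ratio checks
couple_with_children <- function(n_children) {
  kids <- sprintf("K%05d", seq_len(n_children))
  as_pedigree(tibble::tibble(
    family_id = "BIG",
    id = c("DAD", "MUM", kids),
    father_id = c(NA, NA, rep("DAD", n_children)),
    mother_id = c(NA, NA, rep("MUM", n_children)),
    sex = c("M", "F", rep(c("M", "F"), length.out = n_children))))
}

# unrelated founders only (for penetrance-recovery checks)
founder_cohort <- function(n) {
  ids <- sprintf("U%05d", seq_len(n))
  as_pedigree(tibble::tibble(
    family_id = ids, id = ids, father_id = NA_character_,
    mother_id = NA_character_, sex = rep(c("M", "F"), length.out = n)))
}

random_annotation_table <- function(n) {
  panel <- mody_panel()
  g <- sample(nrow(panel), n, replace = TRUE)
  pos <- panel$start[g] + sample.int(1000, n, replace = TRUE)
  tibble::tibble(
    chrom = panel$chrom[g], pos = pos,
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("AA", "CC", "GG", "TT"), n, replace = TRUE),
    gene = panel$gene[g],
    clinvar_significance = sample(
      c("PATHOGENIC", "LIKELY_PATHOGENIC", "VUS", "BENIGN",
        "UNCERTAIN_RISK_ALLELE"), n, replace = TRUE),
    cadd_phred = round(runif(n, 0, 40), 2),
    mean_depth = round(runif(n, 5, 40), 1),
    variant_id = paste0("V", seq_len(n))
  )
}

random_genotypes <- function(annotation, n_samples, p_alt = 0.05,
                             p_missing = 0.05) {
  tidyr::expand_grid(variant_id = annotation$variant_id,
                     sample_id = sprintf("S%04d", seq_len(n_samples))) |>
    dplyr::mutate(
      dosage = sample(c(0L, 1L, 2L, NA_integer_),
                      dplyr::n(), replace = TRUE,
                      prob = c(1 - p_alt - p_missing, p_alt * 0.8,
                               p_alt * 0.2, p_missing)))
}
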