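# Deterministic validation cohort ("TCGS-like fixture"). Counts are
# constructed, not simulated, so every published tally is exact:
#   - 20,005 participants: 3,043 diabetic + 5,835 pre-diabetic +
#     11,124 non-diabetic + 3 with all-missing glycemic data
#   - seven panel variants with the published carrier/family/diagnosis
#     configuration (45 P/LP carriers in 24 families; 49 carriers in 25
#     families including the uncertain-risk-allele candidate)
#   - three decoy variants that each fail exactly one screen predicate
#   - three fully-encoded pedigrees for the HNF4A / HNF1A / HNF1B families
#   - 25 clinical MODY suspects, 3 of them P/LP carriers
# No RNG is used anywhere; biomarkers are placed deterministically inside
# the ADA band of the intended status.

FIXTURE_VARIANTS <- list(
  hnf4a = "chr20:44413696:G:A",
  gck = "chr7:44149764:G:C",
  hnf1a = "chr12:120994313:C:CC",
  hnf1b_516 = "chr17:37739468:G:A",
  hnf1b_1025 = "chr17:37731615:G:A",
  cel = "chr9:133071270:C:CC",
  ins = "chr11:2160956:G:A",
  decoy_benign = "chr7:44150000:A:G",
  decoy_maf = "chr11:2161000:C:T",
  decoy_depth = "chr12:120995000:G:T"
)

fixture_annotations <- function() {
  v <- FIXTURE_VARIANTS
  tbl <- tibble::tribble(
    ~variant_id, ~gene, ~hgvs_c, ~hgvs_p, ~rsid,
    ~clinvar_significance, ~cadd_phred, ~mean_depth, ~impute_info,
    ~external_af, ~consequence,
    v$hnf4a, "HNF4A", "NM_175914.5:c.322G>A", "p.Val108Ile",
    "rs377476335", "PATHOGENIC", 22.2, 32.5, 0.853567, 9.932e-6,
    "missense",
    v$gck, "GCK", "NM_000162.5:c.675C>G", "p.Ile225Met",
    "rs772754004", "PATHOGENIC", 6.324, 28.4, 0.879049, 6.196e-7,
    "missense",
    v$hnf1a, "HNF1A", "NM_000545.8:c.863_864insC", "p.Pro289fs",
    "rs766191969", "PATHOGENIC", NA, 30.1, 0.992043, 9.529e-5,
    "frameshift",
    v$hnf1b_516, "HNF1B", "NM_000458.4:c.516C>T", "p.Tyr172=",
    "rs764561297", "PATHOGENIC", 9.416, 25.6, 0.954562, 1.487e-5,
    "synonymous",
    v$hnf1b_1025, "HNF1B", "NM_000458.4:c.1025C>T", "p.Ser342Phe",
    "rs780035561", "UNCERTAIN_RISK_ALLELE", 20.7, 30.0, 0.851708,
    4.091e-5, "missense",
    v$cel, "CEL", "NM_001807.6:c.1776dup", "p.Val593fs",
    "rs193922638", "LIKELY_PATHOGENIC", 17.15, 26.3, 0.98107, 4.028e-6,
    "frameshift",
    v$ins, "INS", "NM_000207.3:c.16C>T", "p.Arg6Cys",
    "rs121908278", "PATHOGENIC", 21.2, 27.8, 0.869638, 1.365e-5,
    "missense",
    v$decoy_benign, "GCK", "NM_000162.5:c.900A>G", "p.=",
    "rs900000001", "BENIGN", 3.2, 30.0, 0.97, 1.2e-3, "synonymous",
    v$decoy_maf, "INS", "NM_000207.3:c.100C>T", "p.Arg34Cys",
    "rs900000002", "PATHOGENIC", 25.0, 31.0, 0.96, 2.0e-3, "missense",
    v$decoy_depth, "HNF1A", "NM_000545.8:c.1200G>T", "p.Trp400Cys",
    "rs900000003", "PATHOGENIC", 24.0, 15.0, 0.95, 3.0e-6, "missense"
  )
  parts <- stringr::str_split_fixed(tbl$variant_id, ":", 4)
  tbl |>
    mutate(chrom = parts[, 1], pos = as.numeric(parts[, 2]),
           ref = parts[, 3], alt = parts[, 4]) |>
    select("chrom", "pos", "ref", "alt", "gene", "hgvs_c", "hgvs_p",
           "rsid", "clinvar_significance", "cadd_phred", "mean_depth",
           "impute_info", "external_af", "consequence", "variant_id")
}

# one member row for the explicit families
fm <- function(family, id, father = NA, mother = NA, sex, status,
               exam_age, bmi, onset = NA_real_, meds = FALSE,
               carrier = NA_character_, genotyped = TRUE,
               fpg = NA_real_, ogtt = NA_real_) {
  tibble(family_id = family, id = id,
         father_id = as.character(father), mother_id = as.character(mother),
         sex = sex, status = status, exam_age = exam_age, bmi = bmi,
         self_reported_onset = onset, meds = meds, carrier = carrier,
         genotyped = genotyped, fpg_fix = fpg, ogtt_fix = ogtt)
}

fixture_families <- function() {
  v <- FIXTURE_VARIANTS
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- fm(...)

  # -- HNF4A family (three generations; maternal transmission) -----------
  add("FAM0001", "A_GF", sex = "M", status = "NON_DIABETIC", exam_age = 82,
      bmi = 24.1)
  add("FAM0001", "A_GM", sex = "F", status = "NON_DIABETIC", exam_age = 80,
      bmi = 23.6)
  add("FAM0001", "A_MO", "A_GF", "A_GM", sex = "F", status = "DIABETIC",
      exam_age = 58, bmi = 23.0, onset = 20, meds = TRUE,
      genotyped = FALSE)
  add("FAM0001", "A_AU1", "A_GF", "A_GM", sex = "F", status = "DIABETIC",
      exam_age = 55, bmi = 22.4, onset = 21, meds = TRUE)
  add("FAM0001", "A_AU2", "A_GF", "A_GM", sex = "F", status = "DIABETIC",
      exam_age = 52, bmi = 23.8, onset = 22, meds = TRUE)
  add("FAM0001", "A_FA", sex = "M", status = "NON_DIABETIC", exam_age = 60,
      bmi = 26.0)
  add("FAM0001", "A_PRO", "A_FA", "A_MO", sex = "F", status = "DIABETIC",
      exam_age = 33, bmi = 19.05, onset = 22, carrier = v$hnf4a,
      fpg = 130, ogtt = 256)
  add("FAM0001", "A_BRO", "A_FA", "A_MO", sex = "M", status = "DIABETIC",
      exam_age = 36, bmi = 24.2, onset = 28)

  # -- HNF1A family (proband + insulin-treated maternal line) ------------
  add("FAM0002", "B_GF", sex = "M", status = "NON_DIABETIC", exam_age = 84,
      bmi = 25.2)
  add("FAM0002", "B_GM", sex = "F", status = "DIABETIC", exam_age = 81,
      bmi = 23.2, onset = 16, meds = TRUE)
  add("FAM0002", "B_MO", "B_GF", "B_GM", sex = "F", status = "DIABETIC",
      exam_age = 50, bmi = 23.5, onset = 17, meds = TRUE,
      genotyped = FALSE)
  add("FAM0002", "B_U1", "B_GF", "B_GM", sex = "M", status = "DIABETIC",
      exam_age = 56, bmi = 23.1, onset = 16, meds = TRUE)
  add("FAM0002", "B_U2", "B_GF", "B_GM", sex = "M", status = "DIABETIC",
      exam_age = 54, bmi = 24.0, onset = 17, meds = TRUE)
  add("FAM0002", "B_U3", "B_GF", "B_GM", sex = "M", status = "DIABETIC",
      exam_age = 52, bmi = 24.6, onset = 18, meds = TRUE)
  add("FAM0002", "B_FA", sex = "M", status = "NON_DIABETIC", exam_age = 52,
      bmi = 27.0)
  add("FAM0002", "B_PRO", "B_FA", "B_MO", sex = "F", status = "DIABETIC",
      exam_age = 24, bmi = 22.73, onset = 13, carrier = v$hnf1a,
      fpg = 171, ogtt = 260)

  # -- HNF1B candidate family (grandmother, two children, grandson) ------
  add("FAM0003", "C_GM", sex = "F", status = "DIABETIC", exam_age = 76,
      bmi = 30.5, onset = 40, meds = TRUE, carrier = v$hnf1b_1025)
  add("FAM0003", "C_GF", sex = "M", status = "NON_DIABETIC", exam_age = 78,
      bmi = 25.4)
  add("FAM0003", "C_C1", "C_GF", "C_GM", sex = "F", status = "DIABETIC",
      exam_age = 55, bmi = 27.0, onset = 35, meds = TRUE,
      carrier = v$hnf1b_1025)
  add("FAM0003", "C_C1SP", sex = "M", status = "NON_DIABETIC",
      exam_age = 57, bmi = 26.2)
  add("FAM0003", "C_C2", "C_GF", "C_GM", sex = "M", status = "DIABETIC",
      exam_age = 52, bmi = 31.0, onset = 38, meds = TRUE,
      carrier = v$hnf1b_1025)
  add("FAM0003", "C_C2SP", sex = "F", status = "NON_DIABETIC",
      exam_age = 50, bmi = 24.8)
  add("FAM0003", "C_GS", "C_C1SP", "C_C1", sex = "M", status = "DIABETIC",
      exam_age = 34, bmi = 26.0, onset = 30, meds = TRUE,
      carrier = v$hnf1b_1025)
  add("FAM0003", "C_X", "C_C2", "C_C2SP", sex = "F", status = "DIABETIC",
      exam_age = 30, bmi = 28.0, onset = 27)

  # -- GCK families: 13 carriers {3 DM, 5 PreDM, 4 ND, 1 NA} in 7 fams ---
  gck_status <- list(
    c("DIABETIC", "DIABETIC"), c("DIABETIC", "PRE_DIABETIC"),
    c("PRE_DIABETIC", "PRE_DIABETIC"), c("PRE_DIABETIC", "PRE_DIABETIC"),
    c("NON_DIABETIC", "NON_DIABETIC"), c("NON_DIABETIC", "NON_DIABETIC"),
    "UNKNOWN")
  for (i in seq_along(gck_status)) {
    fam <- sprintf("FAM%04d", 3 + i)
    st <- gck_status[[i]]
    a <- paste0("G", i, "_A")
    add(fam, a, sex = "F", status = st[1], exam_age = 60 + i,
        bmi = 26 + i * 0.4, carrier = v$gck,
        onset = if (st[1] == "DIABETIC") 38 + i else NA_real_,
        meds = st[1] == "DIABETIC" && i == 1)
    if (length(st) == 2) {
      sp <- paste0("G", i, "_SP")
      ch <- paste0("G", i, "_C")
      add(fam, sp, sex = "M", status = "NON_DIABETIC", exam_age = 61 + i,
          bmi = 25.0)
      add(fam, ch, sp, a, sex = if (i %% 2 == 0) "F" else "M",
          status = st[2], exam_age = 32 + i, bmi = 25.5 + i * 0.3,
          carrier = v$gck,
          onset = if (st[2] == "DIABETIC") 29 else NA_real_)
    }
  }

  # -- HNF1B c.516C>T families: 8 carriers {1 DM, 5 PreDM, 2 ND} in 3 ----
  h_status <- list(c("DIABETIC", "PRE_DIABETIC", "PRE_DIABETIC"),
                   c("PRE_DIABETIC", "PRE_DIABETIC", "PRE_DIABETIC"),
                   c("NON_DIABETIC", "NON_DIABETIC"))
  for (i in seq_along(h_status)) {
    fam <- sprintf("FAM%04d", 10 + i)
    st <- h_status[[i]]
    a <- paste0("H", i, "_A")
    add(fam, a, sex = "F", status = st[1], exam_age = 58 + i, bmi = 25.8,
        carrier = v$hnf1b_516,
        onset = if (st[1] == "DIABETIC") 50 else NA_real_,
        meds = st[1] == "DIABETIC")
    sp <- paste0("H", i, "_SP")
    add(fam, sp, sex = "M", status = "NON_DIABETIC", exam_age = 60 + i,
        bmi = 24.4)
    for (k in seq_len(length(st) - 1)) {
      add(fam, paste0("H", i, "_C", k), sp, a,
          sex = if (k %% 2 == 0) "F" else "M", status = st[k + 1],
          exam_age = 30 + k, bmi = 24 + k, carrier = v$hnf1b_516)
    }
  }

  # -- CEL: single pre-diabetic obese carrier ----------------------------
  add("FAM0014", "CEL_A", sex = "F", status = "PRE_DIABETIC",
      exam_age = 43, bmi = 32.2, carrier = v$cel, fpg = 101, ogtt = 138)

  # -- INS families: 21 carriers {8 DM, 8 PreDM, 3 ND, 2 NA} in 11 -------
  ins_status <- list(
    c("DIABETIC", "DIABETIC"),            # child is the clinical suspect
    c("DIABETIC", "DIABETIC"), c("DIABETIC", "PRE_DIABETIC"),
    c("DIABETIC", "PRE_DIABETIC"), c("DIABETIC", "PRE_DIABETIC"),
    c("DIABETIC", "PRE_DIABETIC"), c("PRE_DIABETIC", "PRE_DIABETIC"),
    c("PRE_DIABETIC", "PRE_DIABETIC"), c("NON_DIABETIC", "NON_DIABETIC"),
    c("NON_DIABETIC", "UNKNOWN"), "UNKNOWN")
  for (i in seq_along(ins_status)) {
    fam <- sprintf("FAM%04d", 14 + i)
    st <- ins_status[[i]]
    a <- paste0("N", i, "_A")
    add(fam, a, sex = if (i %% 2 == 0) "F" else "M", status = st[1],
        exam_age = 55 + i, bmi = 28 + (i %% 5), carrier = v$ins,
        onset = if (st[1] == "DIABETIC") 33 + i else NA_real_,
        meds = st[1] == "DIABETIC" && i == 2)
    if (length(st) == 2) {
      sp <- paste0("N", i, "_SP")
      ch <- paste0("N", i, "_C")
      add(fam, sp, sex = if (i %% 2 == 0) "M" else "F",
          status = "NON_DIABETIC", exam_age = 56 + i, bmi = 24.0)
      add(fam, ch, if (i %% 2 == 0) sp else a,
          if (i %% 2 == 0) a else sp, sex = "F", status = st[2],
          exam_age = if (i == 1) 26 else 31 + i,
          bmi = if (i == 1) 23.0 else 26 + (i %% 4),
          carrier = v$ins,
          onset = if (st[2] == "DIABETIC") {
            if (i == 1) 22 else 28 + i
          } else NA_real_)
    }
  }

  # -- 14 background suspect trios (young-onset lean diabetic child with
  #    a diabetic obese parent) ------------------------------------------
  for (i in seq_len(14)) {
    fam <- sprintf("FAM%04d", 25 + i)
    p1 <- paste0("S", i, "_P1"); p2 <- paste0("S", i, "_P2")
    ch <- paste0("S", i, "_C")
    add(fam, p1, sex = "M", status = "DIABETIC", exam_age = 50 + i,
        bmi = 31.0, onset = 30 + i, meds = TRUE)
    add(fam, p2, sex = "F", status = "NON_DIABETIC", exam_age = 49 + i,
        bmi = 24.0)
    add(fam, ch, p1, p2, sex = if (i %% 2 == 0) "F" else "M",
        status = "DIABETIC", exam_age = 28, bmi = 22 + i * 0.1,
        onset = 18 + (i %% 7))
  }

  bind_rows(rows)
}

#' Build the deterministic validation cohort
#'
#' Constructs a 20,005-participant family cohort whose classification
#' counts, carrier configuration, penetrances, family counts and clinical
#' suspect overlap reproduce the published tallies exactly (see the
#' package vignette). Fully deterministic; no random number generation.
#'
#' @return List with elements `pedigree` (a `mody_pedigree`), `genotypes`
#'   (long tibble), `phenotypes` (visit tibble) and `annotations`.
#' @export
#' @examples
#' \donttest{
#' fx <- tcgs_fixture()
#' table(classify_participants(fx$phenotypes)$lifetime_status)
#' }
tcgs_fixture <- function() {
  fams <- fixture_families()

  n_dm <- 3043L - sum(fams$status == "DIABETIC")
  n_pre <- 5835L - sum(fams$status == "PRE_DIABETIC")
  n_nd <- 11124L - sum(fams$status == "NON_DIABETIC")
  stopifnot(n_dm > 0, n_pre > 0, n_nd > 0,
            sum(fams$status == "UNKNOWN") == 3L)

  n_bg <- n_dm + n_pre + n_nd
  i <- seq_len(n_bg)
  bg_status <- rep(c("DIABETIC", "PRE_DIABETIC", "NON_DIABETIC"),
                   times = c(n_dm, n_pre, n_nd))
  bg <- tibble(
    family_id = sprintf("BG%05d", i),
    id = sprintf("B%05d", i),
    father_id = NA_character_, mother_id = NA_character_,
    sex = if_else(i %% 2 == 0, "F", "M"),
    status = bg_status,
    exam_age = dplyr::case_when(
      bg_status == "DIABETIC" ~ 30 + (i %% 46),
      TRUE ~ 20 + (i %% 60)
    ),
    bmi = 20 + (i %% 14) + 0.3,
    self_reported_onset = NA_real_,
    meds = bg_status == "DIABETIC" & i %% 3 == 0,
    carrier = NA_character_,
    genotyped = TRUE,
    fpg_fix = NA_real_, ogtt_fix = NA_real_
  )

  all_rows <- bind_rows(fams, bg)
  stopifnot(nrow(all_rows) == 20005L)

  pedigree <- as_pedigree(
    all_rows[, c("family_id", "id", "father_id", "mother_id", "sex")])

  # biomarker realization inside the ADA band of the assigned status
  j <- seq_len(nrow(all_rows))
  st <- all_rows$status
  fpg <- dplyr::case_when(
    st == "DIABETIC" ~ 126 + (j %% 100),
    st == "PRE_DIABETIC" ~ 100 + (j %% 26),
    st == "NON_DIABETIC" ~ 70 + (j %% 30),
    TRUE ~ NA_real_
  )
  ogtt <- dplyr::case_when(
    st == "DIABETIC" ~ 200 + (j %% 120),
    st == "PRE_DIABETIC" ~ 140 + (j %% 60),
    st == "NON_DIABETIC" ~ 80 + (j %% 60),
    TRUE ~ NA_real_
  )
  fpg <- dplyr::coalesce(all_rows$fpg_fix, fpg)
  ogtt <- dplyr::coalesce(all_rows$ogtt_fix, ogtt)

  phenotypes <- tibble(
    participant_id = all_rows$id,
    exam_age = all_rows$exam_age,
    fpg = fpg,
    ogtt_2h = ogtt,
    glucose_lowering_agent = all_rows$meds & st != "UNKNOWN",
    metformin_non_diabetic = FALSE,
    bmi = if_else(st == "UNKNOWN", NA_real_, all_rows$bmi),
    sbp = round(105 + (j %% 30) + if_else(st == "DIABETIC", 12, 0), 0),
    dbp = round(68 + (j %% 18), 0),
    tg = round(100 + (j %% 120) + if_else(st == "DIABETIC", 30, 0), 0),
    chol = round(150 + (j %% 70), 0),
    hdl = round(38 + (j %% 22), 0),
    ldl = round(80 + (j %% 45), 0),
    self_reported_onset = all_rows$self_reported_onset
  )

  genotypes <- fixture_genotypes(all_rows)
  list(pedigree = pedigree, genotypes = genotypes,
       phenotypes = phenotypes, annotations = fixture_annotations())
}

fixture_genotypes <- function(all_rows) {
  v <- FIXTURE_VARIANTS
  ids <- all_rows$id
  untyped <- ids[!all_rows$genotyped]

  carrier_sets <- split(all_rows$id[!is.na(all_rows$carrier)],
                        all_rows$carrier[!is.na(all_rows$carrier)])
  # decoy carriers drawn from background non-diabetic singletons
  bg_nd <- all_rows$id[all_rows$status == "NON_DIABETIC" &
                         startsWith(all_rows$id, "B")]
  carrier_sets[[v$decoy_maf]] <- bg_nd[1:100]
  carrier_sets[[v$decoy_depth]] <- bg_nd[101:102]
  carrier_sets[[v$decoy_benign]] <- bg_nd[103:105]

  purrr::map_dfr(unname(unlist(FIXTURE_VARIANTS)), function(vid) {
    dosage <- rep(0L, length(ids))
    dosage[ids %in% carrier_sets[[vid]]] <- 1L
    dosage[ids %in% untyped] <- NA_integer_
    tibble(variant_id = vid, sample_id = ids, dosage = dosage)
  })
}
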