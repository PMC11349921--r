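# Pedigree loading, relationship degrees and transmission assessment.

test_that("PED round trip keeps founders and links", {
  path <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("T1 F1 0 0 1 0", "T1 M1 0 0 2 0", "T1 C1 F1 M1 1 2"), path)
  ped <- read_ped(path)
  expect_s3_class(ped, "mody_pedigree")
  expect_setequal(founders(ped), c("F1", "M1"))
  expect_equal(nrow(ped), 3)
})

test_that("malformed pedigrees are rejected with informative errors", {
  base <- tibble::tibble(family_id = "T1", id = c("F1", "M1", "C1"),
                         father_id = c(NA, NA, "F1"),
                         mother_id = c(NA, NA, "M1"),
                         sex = c("M", "F", "M"))
  self <- base; self$father_id[3] <- "C1"
  expect_error(as_pedigree(self), "own parent")
  dup <- dplyr::bind_rows(base, base[3, ])
  expect_error(as_pedigree(dup), "duplicated")
  swap <- base; swap$father_id[3] <- "M1"; swap$mother_id[3] <- "F1"
  expect_error(as_pedigree(swap), "sex-inconsistent|father and mother")
  cyc <- tibble::tibble(family_id = "T1", id = c("A", "B"),
                        father_id = c("B", "A"), mother_id = NA_character_,
                        sex = "M")
  expect_error(as_pedigree(cyc), "cycle|father and mother")
})

test_that("relationship degrees follow the genetic convention", {
  # three generations: GF+GM -> (MO, AU) ; FA+MO -> (PRO, SIB)
  ped <- as_pedigree(tibble::tibble(
    family_id = "F",
    id = c("GF", "GM", "MO", "AU", "FA", "PRO", "SIB", "HB"),
    father_id = c(NA, NA, "GF", "GF", NA, "FA", "FA", "FA"),
    mother_id = c(NA, NA, "GM", "GM", NA, "MO", "MO", "AU"),
    sex = c("M", "F", "F", "F", "M", "F", "M", "M")))
  expect_setequal(relatives_of(ped, "PRO", 1), c("FA", "MO", "SIB"))
  expect_setequal(relatives_of(ped, "PRO", 2),
                  c("GF", "GM", "AU", "HB"))  # incl. half-brother
  # symmetry of degree-1 and disjointness of the two degrees
  for (id in ped$id) {
    d1 <- relatives_of(ped, id, 1)
    d2 <- relatives_of(ped, id, 2)
    expect_length(intersect(d1, d2), 0)
    for (r in d1) expect_true(id %in% relatives_of(ped, r, 1))
  }
  expect_error(relatives_of(ped, "NOBODY"), "unknown")
})

test_that("the encoded proband families expose the published kinship", {
  ped <- get_fixture()$pedigree
  # young-onset proband: mother at degree 1; maternal grandmother and the
  # three maternal uncles at degree 2
  expect_true("B_MO" %in% relatives_of(ped, "B_PRO", 1))
  expect_true(all(c("B_GM", "B_U1", "B_U2", "B_U3") %in%
                    relatives_of(ped, "B_PRO", 2)))
})

test_that("founders with no kin have empty relative sets", {
  ped <- as_pedigree(tibble::tibble(
    family_id = "L", id = "LONER", father_id = NA_character_,
    mother_id = NA_character_, sex = "M"))
  expect_length(relatives_of(ped, "LONER", 1), 0)
  expect_length(relatives_of(ped, "LONER", 2), 0)
})

test_that("carrier family counting is exact and monotone under union", {
  ped <- get_fixture()$pedigree
  gt <- get_fixture()$genotypes
  expect_equal(carrier_families(ped, character(0)), 0L)
  ins <- carriers_of(gt, "chr11:2160956:G:A")
  gck <- carriers_of(gt, "chr7:44149764:G:C")
  expect_equal(carrier_families(ped, ins), 11L)
  expect_equal(carrier_families(ped, gck), 7L)
  expect_gte(carrier_families(ped, union(ins, gck)),
             max(carrier_families(ped, ins), carrier_families(ped, gck)))
  expect_error(carrier_families(ped, "NOT_THERE"), "not in pedigree")
})

test_that("a carrier child of two genotyped non-carriers breaks Mendelian consistency", {
  ped <- trio_ped()
  gt <- tibble::tibble(variant_id = "v1",
                       sample_id = c("F1", "M1", "C1"),
                       dosage = c(0L, 0L, 1L))
  st <- c(F1 = "NON_DIABETIC", M1 = "NON_DIABETIC", C1 = "DIABETIC")
  tr <- assess_transmission(ped, gt, "v1", st)
  expect_false(tr$mendelian_consistent)
  expect_error(assess_transmission(ped, gt, "nope", st), "not found")
})

test_that("an isolated carrier yields no informative trio and unresolved lineage", {
  ped <- trio_ped()
  gt <- tibble::tibble(variant_id = "v1", sample_id = c("F1", "M1", "C1"),
                       dosage = c(1L, 0L, 0L))
  st <- c(F1 = "DIABETIC", M1 = "NON_DIABETIC", C1 = "NON_DIABETIC")
  tr <- assess_transmission(ped, gt, "v1", st)
  expect_true(tr$mendelian_consistent)
  expect_equal(tr$transmission_lineage, "UNRESOLVED")
  expect_equal(tr$cosegregation_fraction, 1)  # the lone carrier is diabetic
})

test_that("full co-segregation through three generations is AD compatible", {
  fx <- get_fixture()
  tr <- assess_transmission(fx$pedigree, fx$genotypes,
                            "chr17:37731615:G:A", get_statuses())
  expect_equal(nrow(tr), 1)
  expect_true(tr$ad_compatible)
  expect_true(tr$mendelian_consistent)
  expect_equal(tr$cosegregation_fraction, 1.0)
  expect_equal(tr$transmission_lineage, "MATERNAL")
})

test_that("a genotyped non-carrier between two carriers defeats AD compatibility", {
  # grandmother carrier, mother genotyped non-carrier, child carrier:
  # Mendelian-consistent only if the married-in father is untyped, but the
  # variant cannot have travelled through the non-carrier mother
  ped <- as_pedigree(tibble::tibble(
    family_id = "F", id = c("GM", "GF", "MO", "FA", "CH"),
    father_id = c(NA, NA, "GF", NA, "FA"),
    mother_id = c(NA, NA, "GM", NA, "MO"),
    sex = c("F", "M", "F", "M", "M")))
  gt <- tibble::tibble(variant_id = "v1",
                       sample_id = c("GM", "GF", "MO", "FA", "CH"),
                       dosage = c(1L, 0L, 0L, NA, 1L))
  st <- c(GM = "DIABETIC", CH = "DIABETIC")
  tr <- assess_transmission(ped, gt, "v1", st)
  expect_true(tr$mendelian_consistent)
  expect_false(tr$ad_compatible)

  # untyped mother instead: compatible (obligate carrier inference)
  gt2 <- dplyr::mutate(gt, dosage = dplyr::if_else(sample_id == "MO",
                                                   NA_integer_, dosage))
  expect_true(assess_transmission(ped, gt2, "v1", st)$ad_compatible)
})
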