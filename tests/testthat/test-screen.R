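# MAF computation, the two filter pipelines, and carrier statistics.

test_that("cohort MAF equals a naive per-sample allele tally", {
  # worked examples
  gt <- tibble::tibble(variant_id = "v", sample_id = as.character(1:1000),
                       dosage = c(1L, rep(0L, 999)))
  expect_equal(compute_cohort_maf(gt)$maf, 0.0005)
  gt2 <- tibble::tibble(variant_id = "v",
                        sample_id = as.character(1:16226),
                        dosage = c(rep(1L, 21), rep(0L, 16205)))
  expect_equal(compute_cohort_maf(gt2)$maf, 21 / (2 * 16226))
  # folding: all homozygous alternate folds to 0
  gt3 <- tibble::tibble(variant_id = "v", sample_id = as.character(1:10),
                        dosage = 2L)
  expect_equal(compute_cohort_maf(gt3)$maf, 0)
  # all-missing is an error
  gt4 <- tibble::tibble(variant_id = "v", sample_id = "s",
                        dosage = NA_integer_)
  expect_error(compute_cohort_maf(gt4), "undefined")

  # randomized equivalence against an independent tally
  set.seed(7)
  for (rep in 1:10) {
    ann <- random_annotation_table(5)
    g <- random_genotypes(ann, 50)
    got <- compute_cohort_maf(g)
    for (v in ann$variant_id) {
      d <- g$dosage[g$variant_id == v]
      alt <- 0L; tot <- 0L
      for (x in d) {
        if (!is.na(x)) { alt <- alt + x; tot <- tot + 2L }
      }
      expect_equal(got$maf[got$variant_id == v], min(alt / tot, 1 - alt / tot))
    }
  }
})

test_that("the known-variant screen keeps exactly the six P/LP variants", {
  fx <- get_fixture()
  sc <- screen_known_variants(fx$annotations, fx$genotypes)
  td <- tidy(sc)
  expect_equal(nrow(td), 6)
  expect_setequal(td$gene, c("HNF4A", "GCK", "HNF1A", "HNF1B", "CEL", "INS"))
  expect_false("chr17:37731615:G:A" %in% td$variant_id)  # the URA
  expect_true(all(td$clinvar_significance %in%
                    c("PATHOGENIC", "LIKELY_PATHOGENIC")))
  # ordering stable by (chrom, pos)
  expect_equal(td$variant_id,
               td$variant_id[order(td$chrom, td$pos)])
  # stage log reconstructs the waterfall
  expect_equal(sc$stages$n[length(sc$stages$n)], 6)

  # all-decoy input gives an empty, well-formed result
  decoys <- dplyr::filter(fx$annotations, grepl("rs9000000", rsid))
  empty <- screen_known_variants(decoys, fx$genotypes)
  expect_equal(nrow(tidy(empty)), 0)
})

test_that("each decoy fails exactly one screen predicate", {
  fx <- get_fixture()
  ann <- dplyr::left_join(fx$annotations, compute_cohort_maf(fx$genotypes),
                          by = "variant_id")
  decoy <- function(rs) ann[ann$rsid == rs, ]
  d_ben <- decoy("rs900000001")   # benign: fails significance only
  expect_false(d_ben$clinvar_significance %in%
                 c("PATHOGENIC", "LIKELY_PATHOGENIC"))
  expect_lt(d_ben$maf, 0.0015); expect_gt(d_ben$mean_depth, 20)
  d_maf <- decoy("rs900000002")   # common: fails MAF only
  expect_equal(d_maf$clinvar_significance, "PATHOGENIC")
  expect_gte(d_maf$maf, 0.0015); expect_gt(d_maf$mean_depth, 20)
  d_dep <- decoy("rs900000003")   # shallow: fails depth only
  expect_equal(d_dep$clinvar_significance, "PATHOGENIC")
  expect_lt(d_dep$maf, 0.0015); expect_lte(d_dep$mean_depth, 20)
})

test_that("penetrance uses the all-carriers denominator", {
  st <- c(rep("DIABETIC", 8), rep("PRE_DIABETIC", 8),
          rep("NON_DIABETIC", 3), rep("UNKNOWN", 2))
  names(st) <- paste0("P", seq_along(st))
  r <- compute_penetrance(names(st), st)
  expect_equal(r$penetrance_pct, 100 * 8 / 21)
  expect_equal(r$penetrance_pct, 38.1, tolerance = 0.01)
  expect_equal(c(r$n_dm, r$n_pre_dm, r$n_nd, r$n_na), c(8L, 8L, 3L, 2L))

  all_dm <- stats::setNames(rep("DIABETIC", 4), paste0("Q", 1:4))
  expect_equal(compute_penetrance(names(all_dm), all_dm)$penetrance_pct, 100)
  one_pre <- c(Z1 = "PRE_DIABETIC")
  expect_equal(compute_penetrance("Z1", one_pre)$penetrance_pct, 0)
  expect_error(compute_penetrance(character(0), st), "empty carrier set")
  # statuses missing from the map count as unknown but stay in N
  r2 <- compute_penetrance(c("P1", "nowhere"), st)
  expect_equal(r2$penetrance_pct, 50)
  expect_equal(r2$n_na, 1L)
})

test_that("penetrance is bounded and 100 only when every carrier is diabetic", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(1:30, 1)
    st <- stats::setNames(sample(glycemic_levels(), n, replace = TRUE),
                          paste0("I", seq_len(n)))
    r <- compute_penetrance(names(st), st)
    expect_gte(r$penetrance_pct, 0)
    expect_lte(r$penetrance_pct, 100)
    expect_equal(r$penetrance_pct == 100, all(st == "DIABETIC"))
  }
})

test_that("discovery returns the single complete-penetrance candidate", {
  fx <- get_fixture()
  st <- get_statuses()
  dc <- discover_candidates(fx$annotations, fx$genotypes, st,
                            pedigree = fx$pedigree)
  td <- tidy(dc)
  expect_equal(nrow(td), 1)
  expect_equal(td$variant_id, "chr17:37731615:G:A")
  expect_equal(td$gene, "HNF1B")
  expect_equal(td$cadd_phred, 20.7)
  expect_equal(td$n_carriers, 4L)
  expect_equal(td$penetrance_pct, 100)
  expect_equal(td$clinvar_significance, "UNCERTAIN_RISK_ALLELE")

  # raising the CADD floor above 20.7 empties the result
  none <- discover_candidates(fx$annotations, fx$genotypes, st,
                              cadd_min = 21)
  expect_equal(nrow(tidy(none)), 0)

  # sub-complete penetrance is excluded at stage 4
  relaxed <- discover_candidates(fx$annotations, fx$genotypes, st,
                                 penetrance_required = 12.5)
  expect_false("chr17:37731615:G:A" %in% tidy(relaxed)$variant_id)
})

test_that("tightening any threshold can only shrink the survivor set", {
  set.seed(23)
  for (rep in 1:5) {
    ann <- random_annotation_table(40)
    gt <- random_genotypes(ann, 60)
    st <- stats::setNames(
      sample(c("DIABETIC", "PRE_DIABETIC", "NON_DIABETIC"), 60,
             replace = TRUE), sprintf("S%04d", 1:60))
    base_known <- tidy(screen_known_variants(ann, gt, maf_max = 0.3,
                                             depth_min = 10))$variant_id
    for (mm in c(0.2, 0.1, 0.02)) {
      sub <- tidy(screen_known_variants(ann, gt, maf_max = mm,
                                        depth_min = 10))$variant_id
      expect_true(all(sub %in% base_known))
      base_known <- sub
    }
    base_disc <- tidy(discover_candidates(ann, gt, st, maf_max = 0.3,
                                          depth_min = 10, cadd_min = 5,
                                          penetrance_required = 100)
                      )$variant_id
    tighter <- tidy(discover_candidates(ann, gt, st, maf_max = 0.3,
                                        depth_min = 20, cadd_min = 25,
                                        penetrance_required = 100)
                    )$variant_id
    expect_true(all(tighter %in% base_disc))
  }
})

test_that("the pipelines equal a brute-force predicate conjunction", {
  set.seed(31)
  ann <- random_annotation_table(50)
  gt <- random_genotypes(ann, 40)
  st <- stats::setNames(
    sample(c("DIABETIC", "PRE_DIABETIC", "NON_DIABETIC", "UNKNOWN"), 40,
           replace = TRUE), sprintf("S%04d", 1:40))
  maf_tbl <- compute_cohort_maf(gt)
  maf <- stats::setNames(maf_tbl$maf, maf_tbl$variant_id)

  expected_known <- character(0)
  expected_disc <- character(0)
  for (i in seq_len(nrow(ann))) {
    v <- ann$variant_id[i]
    plp <- ann$clinvar_significance[i] %in% c("PATHOGENIC",
                                              "LIKELY_PATHOGENIC")
    if (plp && maf[v] < 0.05 && ann$mean_depth[i] > 20) {
      expected_known <- c(expected_known, v)
    }
    carr <- gt$sample_id[gt$variant_id == v & !is.na(gt$dosage) &
                           gt$dosage >= 1]
    pen <- if (length(carr) > 0) {
      100 * sum(st[carr] == "DIABETIC", na.rm = TRUE) / length(carr)
    } else {
      NA_real_
    }
    if (!plp && maf[v] < 0.05 && ann$mean_depth[i] > 20 &&
        !is.na(ann$cadd_phred[i]) && ann$cadd_phred[i] > 15 &&
        !is.na(pen) && pen == 100) {
      expected_disc <- c(expected_disc, v)
    }
  }
  got_known <- tidy(screen_known_variants(ann, gt, maf_max = 0.05,
                                          depth_min = 20))$variant_id
  got_disc <- tidy(discover_candidates(ann, gt, st, maf_max = 0.05,
                                       depth_min = 20, cadd_min = 15)
                   )$variant_id
  expect_setequal(got_known, expected_known)
  expect_setequal(got_disc, expected_disc)
})

test_that("prevalence, spectrum shares and suspect overlap match hand counts", {
  expect_equal(prevalence_among_diabetics(paste0("c", 1:45),
                                          paste0("d", 1:3043)),
               100 * 45 / 3043)
  expect_equal(prevalence_among_diabetics(paste0("c", 1:4),
                                          paste0("d", 1:3043)),
               100 * 4 / 3043)
  expect_equal(prevalence_among_diabetics(character(0), paste0("d", 1:10)), 0)
  expect_error(prevalence_among_diabetics("c1", character(0)), "empty")
  # diabetic-carriers-only variant
  expect_equal(prevalence_among_diabetics(c("d1", "x1"), paste0("d", 1:10),
                                          carriers_only_diabetic = TRUE), 10)

  reports <- tibble::tibble(variant_id = c("ins", "gck", "other"),
                            n_carriers = c(21L, 13L, 11L))
  sp <- spectrum_report(reports)
  expect_equal(sp$spectrum_share_pct[sp$variant_id == "ins"], 100 * 21 / 45)
  expect_equal(sp$spectrum_share_pct[sp$variant_id == "gck"], 100 * 13 / 45)
  expect_equal(sp$variant_id[1], "ins")  # sorted descending
  expect_equal(sum(sp$spectrum_share_pct), 100)
  single <- spectrum_report(reports[1, ])
  expect_equal(single$spectrum_share_pct, 100)

  ov <- suspect_overlap(paste0("s", 1:25), c(paste0("s", 1:3), "zzz"))
  expect_equal(ov$percent, 12)
  expect_equal(suspect_overlap("a", "b")$percent, 0)
  expect_equal(suspect_overlap(c("a", "b"), c("a", "b", "c"))$percent, 100)
  expect_error(suspect_overlap(character(0), "x"), "empty")
})

test_that("screen objects expose tidy, glance, print and autoplot", {
  fx <- get_fixture()
  sc <- screen_known_variants(fx$annotations, fx$genotypes)
  g <- glance(sc)
  expect_equal(g$pipeline, "known")
  expect_equal(g$n_survivors, 6)
  expect_equal(g$maf_max, 0.0015)
  expect_output(print(sc), "known pipeline")
  dc <- discover_candidates(fx$annotations, fx$genotypes, get_statuses())
  expect_s3_class(autoplot(dc), "ggplot")
})
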