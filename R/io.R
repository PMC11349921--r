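# Writers for the cohort bundle. Outputs are plain text: VCF v4.2, 6-column
# PED, and TSVs for phenotypes/annotations; re-reading reproduces the
# in-memory objects.

#' Write a cohort bundle (VCF, PED, phenotype and annotation TSVs)
#'
#' @param pedigree A `mody_pedigree`; PED row and VCF sample-column order
#'   follow its row order.
#' @param genotypes Long genotype table; variant ids must be
#'   `chrom:pos:ref:alt` keys.
#' @param phenotypes Visit tibble.
#' @param annotations Annotation tibble.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(pedigree, genotypes, phenotypes, annotations, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             ped = file.path(dir, "cohort.ped"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             annotations = file.path(dir, "annotations.tsv"))

  write_ped(pedigree, paths["ped"])
  write_vcf(genotypes, pedigree$id, paths["vcf"])
  readr::write_tsv(phenotypes, paths["phenotypes"], na = "", progress = FALSE)
  readr::write_tsv(annotations, paths["annotations"], na = "",
                   progress = FALSE)
  invisible(paths)
}

write_ped <- function(pedigree, path) {
  out <- tibble(
    fam = pedigree$family_id, id = pedigree$id,
    father = dplyr::coalesce(pedigree$father_id, "0"),
    mother = dplyr::coalesce(pedigree$mother_id, "0"),
    sex = dplyr::recode(pedigree$sex, M = "1", F = "2", .missing = "0"),
    phenotype = "0"
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_vcf <- function(genotypes, sample_ids, path) {
  variants <- genotypes |>
    distinct(.data$variant_id) |>
    tidyr::separate_wider_delim(
      "variant_id", ":", names = c("chrom", "pos", "ref", "alt"),
      cols_remove = FALSE) |>
    mutate(pos = as.numeric(.data$pos)) |>
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt)

  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##reference=GRCh38",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  dosage_wide <- genotypes |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "dosage")
  dosage_mat <- as.matrix(dosage_wide[, sample_ids])
  rownames(dosage_mat) <- dosage_wide$variant_id
  body <- vapply(seq_len(nrow(variants)), function(i) {
    d <- dosage_mat[variants$variant_id[i], ]
    gt <- if_else(is.na(d), "./.", gt_code[d + 1L])
    paste(c(variants$chrom[i], format(variants$pos[i], scientific = FALSE),
            ".", variants$ref[i], variants$alt[i], ".", "PASS", ".", "GT",
            gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
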