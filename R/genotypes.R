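# Genotype tables are long tibbles: one row per (variant, sample) with an
# alternate-allele dosage in {0, 1, 2, NA}. Variant ids are
# "chrom:pos:ref:alt" strings (GRCh38, 1-based).

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Load cohort genotypes from a VCF restricted to the MODY panel
#'
#' Reads a VCF (v4.2+, GRCh38 contig names), keeps records falling inside
#' the panel gene regions, splits multi-allelic sites into biallelic
#' records, and returns alternate-allele dosages per sample. Missing calls
#' (`./.`) are preserved as `NA`.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param panel Data frame of gene regions with columns `gene`, `chrom`,
#'   `start`, `end`; defaults to [mody_panel()].
#' @return A long tibble (`variant_id`, `sample_id`, `dosage`) with
#'   attribute `variants`: a tibble of `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `gene`.
#' @export
read_cohort_vcf <- function(path, panel = mody_panel()) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(vcf)
  if (is.null(dim(fixm))) fixm <- t(fixm)  # single-record VCF
  fix <- as_tibble(as.data.frame(fixm, stringsAsFactors = FALSE))
  if (nrow(fix) == 0) stop("VCF contains no variant records", call. = FALSE)
  fix$POS <- as.numeric(fix$POS)
  if (any(is.na(fix$POS))) {
    stop("malformed VCF: non-numeric POS encountered", call. = FALSE)
  }
  if (!any(fix$CHROM %in% panel$chrom)) {
    stop("no VCF contig matches the panel (expected GRCh38 'chr*' names)",
         call. = FALSE)
  }
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt_raw)

  rows <- purrr::map_dfr(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    gene_hit <- panel$gene[panel$chrom == fix$CHROM[i] &
                             panel$start <= fix$POS[i] &
                             panel$end >= fix$POS[i]]
    if (length(gene_hit) == 0) return(NULL)
    purrr::map_dfr(seq_along(alts), function(k) {
      tibble(row = i, alt_index = k, chrom = fix$CHROM[i], pos = fix$POS[i],
             ref = fix$REF[i], alt = alts[k], gene = gene_hit[1])
    })
  })
  if (nrow(rows) == 0) {
    return(structure(
      tibble(variant_id = character(), sample_id = character(),
             dosage = integer()),
      variants = tibble(variant_id = character(), chrom = character(),
                        pos = numeric(), ref = character(),
                        alt = character(), gene = character())))
  }
  rows$variant_id <- variant_key(rows$chrom, rows$pos, rows$ref, rows$alt)

  calls <- purrr::map_dfr(seq_len(nrow(rows)), function(j) {
    g <- gt_raw[rows$row[j], ]
    dosage <- gt_dosage(g, rows$alt_index[j])
    tibble(variant_id = rows$variant_id[j], sample_id = samples,
           dosage = dosage)
  })
  attr(calls, "variants") <-
    rows[, c("variant_id", "chrom", "pos", "ref", "alt", "gene")]
  calls
}

# Dosage of alt allele `k` from GT strings ("0/1", "1|1", "./.", NA).
gt_dosage <- function(gt, k = 1) {
  vapply(gt, function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles == as.character(k))
  }, integer(1), USE.NAMES = FALSE)
}

#' Cohort minor allele frequency of each variant
#'
#' Alternate-allele count over twice the number of non-missing calls,
#' folded to the minor allele (values above 0.5 are reflected).
#'
#' @param genotypes Long genotype table (`variant_id`, `sample_id`,
#'   `dosage`).
#' @return Tibble with `variant_id`, `n_genotyped`, `alt_count`, `maf`.
#' @export
#' @examples
#' gt <- tibble::tibble(variant_id = "v", sample_id = as.character(1:1000),
#'                      dosage = c(1, rep(0, 999)))
#' compute_cohort_maf(gt)  # 1 / 2000
compute_cohort_maf <- function(genotypes) {
  out <- genotypes |>
    group_by(.data$variant_id) |>
    summarise(
      n_genotyped = sum(!is.na(.data$dosage)),
      alt_count = sum(.data$dosage, na.rm = TRUE),
      .groups = "drop"
    )
  if (any(out$n_genotyped == 0)) {
    stop("allele frequency undefined: variant(s) with no non-missing call: ",
         paste(head(out$variant_id[out$n_genotyped == 0], 3), collapse = ", "),
         call. = FALSE)
  }
  out |>
    mutate(maf = pmin(.data$alt_count / (2 * .data$n_genotyped),
                      1 - .data$alt_count / (2 * .data$n_genotyped)))
}

#' Carriers of a variant
#'
#' A carrier holds at least one alternate allele (heterozygous or
#' homozygous), matching dominant-acting variant semantics.
#'
#' @param genotypes Long genotype table.
#' @param variant Variant id.
#' @return Character vector of carrier sample ids.
#' @export
carriers_of <- function(genotypes, variant) {
  g <- filter(genotypes, .data$variant_id == .env$variant)
  if (nrow(g) == 0) stop("variant not in genotype table: ", variant,
                         call. = FALSE)
  sort(g$sample_id[!is.na(g$dosage) & g$dosage >= 1])
}
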