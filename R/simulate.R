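# Synthetic family-cohort generator: multi-generation pedigrees, founder
# variant placement with Mendelian gene dropping, and
# penetrance-parameterised phenotype realization whose biomarker values
# land inside the ADA band of the intended status (so classification
# recovers the simulated status exactly).

#' Simulation configuration
#'
#' Background glycemic rates default to a large family-based population
#' cohort profile: 15.2% diabetic, 29.1% pre-diabetic, remainder
#' non-diabetic.
#'
#' @param n_families Number of independent families.
#' @param generations Pedigree depth (>= 1).
#' @param mean_sibship Mean number of children per couple (> 0).
#' @param background_diabetes_rate,background_prediabetes_rate Marginal
#'   status probabilities for non-carriers; must sum to at most 1.
#' @param variant_specs List of [variant_spec()] entries.
#' @param seed Integer seed; a fixed seed makes every output byte-identical.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_families = 100, generations = 3, mean_sibship = 2.4,
                       background_diabetes_rate = 0.152,
                       background_prediabetes_rate = 0.291,
                       variant_specs = list(), seed = 1L) {
  stopifnot(n_families >= 1, generations >= 1, mean_sibship > 0)
  if (background_diabetes_rate < 0 || background_prediabetes_rate < 0 ||
      background_diabetes_rate + background_prediabetes_rate > 1) {
    stop("background rates must be non-negative and sum to at most 1",
         call. = FALSE)
  }
  structure(list(
    n_families = as.integer(n_families),
    generations = as.integer(generations),
    mean_sibship = mean_sibship,
    background_diabetes_rate = background_diabetes_rate,
    background_prediabetes_rate = background_prediabetes_rate,
    variant_specs = variant_specs,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Specification of one simulated variant
#'
#' @param variant_id Variant key, `chrom:pos:ref:alt`.
#' @param n_founder_carriers Founders made heterozygous.
#' @param target_penetrance Probability that a carrier is diabetic, in
#'   `[0, 1]`.
#' @param onset_mean,onset_sd Carrier onset-age distribution in years;
#'   defaults mirror young-onset monogenic diabetes (23.9 +/- 5).
#' @param missing_status_rate Share of carriers enrolled with all-missing
#'   biomarkers.
#' @return A `variant_spec` list.
#' @export
variant_spec <- function(variant_id, n_founder_carriers = 1,
                         target_penetrance = 1, onset_mean = 23.9,
                         onset_sd = 5, missing_status_rate = 0) {
  stopifnot(target_penetrance >= 0, target_penetrance <= 1,
            missing_status_rate >= 0, missing_status_rate < 1)
  structure(list(variant_id = variant_id,
                 n_founder_carriers = as.integer(n_founder_carriers),
                 target_penetrance = target_penetrance,
                 onset_mean = onset_mean, onset_sd = onset_sd,
                 missing_status_rate = missing_status_rate),
            class = "variant_spec")
}

# Deterministic derived seed per operation so call order cannot leak
# randomness between stages.
substream_seed <- function(seed, offset) {
  (as.integer(seed) * 97L + as.integer(offset)) %% .Machine$integer.max
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate multi-generation family pedigrees
#'
#' Each family starts from a founder couple; every couple draws a sibship
#' size from a zero-truncated Poisson with the configured mean, and
#' children in non-final generations marry in unrelated founder spouses.
#'
#' @param config A [sim_config()].
#' @return A `mody_pedigree` tibble.
#' @export
simulate_pedigrees <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, 1L), {
    rows <- purrr::map_dfr(seq_len(config$n_families), function(f) {
      fam <- sprintf("F%04d", f)
      counter <- 0L
      nid <- function() {
        counter <<- counter + 1L
        sprintf("%s_I%03d", fam, counter)
      }
      out <- list()
      add <- function(id, father, mother, sex) {
        out[[length(out) + 1L]] <<-
          tibble(family_id = fam, id = id, father_id = father,
                 mother_id = mother, sex = sex)
      }
      pa <- nid(); ma <- nid()
      add(pa, NA, NA, "M"); add(ma, NA, NA, "F")
      couples <- list(c(pa, ma))
      for (g in seq_len(config$generations - 1)) {
        next_couples <- list()
        for (cp in couples) {
          n_kids <- rtpois(1, config$mean_sibship)
          for (k in seq_len(n_kids)) {
            kid <- nid()
            sex <- if (runif(1) < 0.5) "M" else "F"
            add(kid, cp[1], cp[2], sex)
            if (g < config$generations - 1) {
              sp <- nid()
              add(sp, NA, NA, if (sex == "M") "F" else "M")
              next_couples[[length(next_couples) + 1L]] <-
                if (sex == "M") c(kid, sp) else c(sp, kid)
            }
          }
        }
        couples <- next_couples
        if (length(couples) == 0) break
      }
      bind_rows(out)
    })
    new_pedigree(rows)
  })
}

# zero-truncated Poisson draw
rtpois <- function(n, lambda) {
  x <- rpois(n, lambda)
  while (any(x == 0)) {
    x[x == 0] <- rpois(sum(x == 0), lambda)
  }
  x
}

#' Drop a variant through a pedigree
#'
#' Selected founders are made heterozygous; every non-founder inherits one
#' allele from each parent uniformly at random (parents outside the
#' pedigree contribute reference alleles). The result is
#' Mendelian-consistent by construction.
#'
#' @param pedigree A `mody_pedigree`.
#' @param spec A [variant_spec()].
#' @param seed Integer seed.
#' @return Long genotype tibble (`variant_id`, `sample_id`, `dosage`).
#' @export
gene_drop <- function(pedigree, spec, seed = 1L) {
  fo <- founders(pedigree)
  if (spec$n_founder_carriers > length(fo)) {
    stop("more founder carriers requested (", spec$n_founder_carriers,
         ") than founders available (", length(fo), ")", call. = FALSE)
  }
  with_seed(substream_seed(seed, 2L), {
    alleles <- matrix(0L, nrow = nrow(pedigree), ncol = 2,
                      dimnames = list(pedigree$id, NULL))
    carrier_founders <- sample(fo, spec$n_founder_carriers)
    alleles[carrier_founders, 1] <- 1L

    # process in generation order: peel from founders downward
    order_ids <- topo_order(pedigree)
    father <- setNames(pedigree$father_id, pedigree$id)
    mother <- setNames(pedigree$mother_id, pedigree$id)
    for (id in order_ids) {
      f <- father[[id]]; m <- mother[[id]]
      if (is.na(f) && is.na(m)) next
      pat <- if (is.na(f)) 0L else alleles[f, sample(1:2, 1)]
      mat <- if (is.na(m)) 0L else alleles[m, sample(1:2, 1)]
      alleles[id, ] <- c(pat, mat)
    }
    tibble(variant_id = spec$variant_id, sample_id = pedigree$id,
           dosage = as.integer(rowSums(alleles)))
  })
}

topo_order <- function(pedigree) {
  remaining <- pedigree$id
  father <- setNames(pedigree$father_id, pedigree$id)
  mother <- setNames(pedigree$mother_id, pedigree$id)
  placed <- character(0)
  while (length(remaining) > 0) {
    ready <- remaining[
      (is.na(father[remaining]) | !(father[remaining] %in% remaining)) &
        (is.na(mother[remaining]) | !(mother[remaining] %in% remaining))]
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

#' Simulate a longitudinal phenotype table for a pedigree
#'
#' Carriers of each simulated variant become diabetic with their spec's
#' target penetrance (onset age from the spec's onset distribution);
#' everyone else draws a status from the background rates. Statuses are
#' realized as concrete FPG/OGTT values inside the matching ADA band
#' (diabetic FPG ~ U\[126, 250\], pre-diabetic U\[100, 125.99\],
#' non-diabetic U\[70, 99.9\]; OGTT analogous), so [classify_visits()]
#' recovers the simulated status. A `missing_status_rate` share of carriers
#' are enrolled with all biomarkers missing.
#'
#' @param pedigree A `mody_pedigree`.
#' @param genotypes Long genotype table covering the pedigree (may hold
#'   several variants).
#' @param config A [sim_config()]; its `variant_specs` drive the carrier
#'   model.
#' @param seed Integer seed.
#' @return Visit tibble (one visit per individual) with an attribute
#'   `true_status` (named character vector) recording the simulated status.
#' @export
simulate_phenotypes <- function(pedigree, genotypes, config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(seed, 3L), {
    ids <- pedigree$id
    n <- length(ids)
    p_bg <- c(config$background_diabetes_rate,
              config$background_prediabetes_rate)
    status <- sample(c("DIABETIC", "PRE_DIABETIC", "NON_DIABETIC"), n,
                     replace = TRUE,
                     prob = c(p_bg, 1 - sum(p_bg)))
    names(status) <- ids
    onset <- setNames(rep(NA_real_, n), ids)
    missing_bio <- setNames(rep(FALSE, n), ids)

    for (spec in config$variant_specs) {
      carr <- carriers_of(genotypes, spec$variant_id)
      carr <- intersect(carr, ids)
      if (length(carr) == 0) next
      is_dm <- runif(length(carr)) < spec$target_penetrance
      residual <- sample(c("PRE_DIABETIC", "NON_DIABETIC"), length(carr),
                         replace = TRUE, prob = c(0.5, 0.5))
      status[carr] <- if_else(is_dm, "DIABETIC", residual)
      onset[carr[is_dm]] <- pmax(
        5, rnorm(sum(is_dm), spec$onset_mean, spec$onset_sd))
      if (spec$missing_status_rate > 0) {
        miss <- runif(length(carr)) < spec$missing_status_rate
        missing_bio[carr[miss]] <- TRUE
        status[carr[miss]] <- "UNKNOWN"
      }
    }

    exam_age <- round(runif(n, 20, 80), 1)
    dm <- status == "DIABETIC"
    exam_age[dm] <- pmax(exam_age[dm],
                         if_else(is.na(onset[dm]), 25, onset[dm]) + 0.5)
    # band upper bounds leave headroom so rounding to 1 decimal cannot
    # cross the next ADA threshold
    fpg <- dplyr::case_when(
      status == "DIABETIC" ~ runif(n, 126, 250),
      status == "PRE_DIABETIC" ~ runif(n, 100, 125.9),
      status == "NON_DIABETIC" ~ runif(n, 70, 99.4),
      TRUE ~ NA_real_
    )
    ogtt <- dplyr::case_when(
      status == "DIABETIC" ~ runif(n, 200, 400),
      status == "PRE_DIABETIC" ~ runif(n, 140, 199.4),
      status == "NON_DIABETIC" ~ runif(n, 80, 139.4),
      TRUE ~ NA_real_
    )
    out <- tibble(
      participant_id = ids,
      exam_age = exam_age,
      fpg = round(fpg, 1),
      ogtt_2h = round(ogtt, 1),
      glucose_lowering_agent = FALSE,
      metformin_non_diabetic = FALSE,
      bmi = round(runif(n, 18, 35), 1),
      self_reported_onset = round(onset, 1)
    )
    attr(out, "true_status") <- status
    out
  })
}

#' Simulate a complete synthetic family cohort
#'
#' Convenience wrapper: pedigrees, gene dropping for every variant spec,
#' and phenotypes, all derived deterministically from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with elements `pedigree`, `genotypes`, `phenotypes`.
#' @export
simulate_cohort <- function(config) {
  ped <- simulate_pedigrees(config)
  genotypes <- purrr::map_dfr(seq_along(config$variant_specs), function(i) {
    gene_drop(ped, config$variant_specs[[i]],
              seed = substream_seed(config$seed, 100L + i))
  })
  phen <- simulate_phenotypes(ped, genotypes, config, seed = config$seed)
  list(pedigree = ped, genotypes = genotypes, phenotypes = phen)
}
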