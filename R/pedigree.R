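# Family graphs from 6-column PED records. A pedigree is a tibble with one
# row per individual (family_id, id, father_id, mother_id, sex) where NA
# marks an unknown parent; founders are rows with both parents unknown.

new_pedigree <- function(tbl) {
  tbl <- as_tibble(tbl)
  needed <- c("family_id", "id", "father_id", "mother_id", "sex")
  stopifnot(all(needed %in% names(tbl)))
  validate_pedigree(tbl)
  class(tbl) <- c("mody_pedigree", class(tbl))
  tbl
}

validate_pedigree <- function(tbl) {
  dup <- tbl$id[duplicated(tbl$id)]
  if (length(dup) > 0) {
    stop("duplicated individual id(s) in pedigree: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (any(tbl$father_id == tbl$id | tbl$mother_id == tbl$id, na.rm = TRUE)) {
    bad <- tbl$id[which(tbl$father_id == tbl$id | tbl$mother_id == tbl$id)]
    stop("individual listed as own parent: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sex <- setNames(tbl$sex, tbl$id)
  fathers <- unique(stats::na.omit(tbl$father_id))
  mothers <- unique(stats::na.omit(tbl$mother_id))
  bad_f <- fathers[!is.na(sex[fathers]) & sex[fathers] == "F"]
  bad_m <- mothers[!is.na(sex[mothers]) & sex[mothers] == "M"]
  if (length(bad_f) > 0 || length(bad_m) > 0) {
    stop("sex-inconsistent parenthood for: ",
         paste(c(bad_f, bad_m), collapse = ", "), call. = FALSE)
  }
  both <- intersect(fathers, mothers)
  if (length(both) > 0) {
    stop("individual(s) recorded as both father and mother: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  # acyclicity: iteratively peel individuals whose in-pedigree parents are
  # all peeled; leftovers lie on a cycle
  remaining <- tbl$id
  parents <- list(f = setNames(tbl$father_id, tbl$id),
                  m = setNames(tbl$mother_id, tbl$id))
  repeat {
    pf <- parents$f[remaining]
    pm <- parents$m[remaining]
    free <- (is.na(pf) | !(pf %in% remaining)) &
      (is.na(pm) | !(pm %in% remaining))
    if (all(!free)) break
    remaining <- remaining[!free]
    if (length(remaining) == 0) break
  }
  if (length(remaining) > 0) {
    stop("pedigree contains an ancestry cycle involving: ",
         paste(head(remaining, 5), collapse = ", "), call. = FALSE)
  }
  invisible(tbl)
}

#' Read a 6-column PED pedigree file
#'
#' Whitespace-delimited, columns family, individual, father, mother, sex
#' (1 = male, 2 = female, other = unknown), phenotype. `0` marks a missing
#' parent. The phenotype column is ignored: glycemic statuses come from the
#' phenotype table via [classify_participants()].
#'
#' @param path Path to a PED file.
#' @return A `mody_pedigree` tibble with columns `family_id`, `id`,
#'   `father_id`, `mother_id`, `sex`.
#' @export
read_ped <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(raw) < 5) stop("PED file needs at least 5 columns", call. = FALSE)
  as_pedigree(tibble(
    family_id = raw[[1]],
    id = raw[[2]],
    father_id = raw[[3]],
    mother_id = raw[[4]],
    sex = raw[[5]]
  ))
}

#' Coerce a data frame of PED-style records to a pedigree
#'
#' @param tbl Data frame with columns `family_id`, `id`, `father_id`,
#'   `mother_id`, `sex`; parents `"0"`/`NA` are unknown; sex coded
#'   `1`/`"M"` male, `2`/`"F"` female.
#' @return A validated `mody_pedigree` tibble.
#' @export
as_pedigree <- function(tbl) {
  tbl <- as_tibble(tbl)
  tbl <- mutate(tbl,
    across(c("family_id", "id", "father_id", "mother_id", "sex"),
           as.character),
    father_id = dplyr::na_if(.data$father_id, "0"),
    mother_id = dplyr::na_if(.data$mother_id, "0"),
    sex = dplyr::case_when(
      .data$sex %in% c("1", "M") ~ "M",
      .data$sex %in% c("2", "F") ~ "F",
      TRUE ~ NA_character_
    )
  )
  missing_parents <- setdiff(
    c(stats::na.omit(tbl$father_id), stats::na.omit(tbl$mother_id)), tbl$id)
  if (length(missing_parents) > 0) {
    stop("parent id(s) not present as individuals: ",
         paste(head(missing_parents, 5), collapse = ", "), call. = FALSE)
  }
  new_pedigree(tbl)
}

#' Founders of a pedigree
#'
#' @param pedigree A `mody_pedigree`.
#' @return Character vector of ids with no recorded parent.
#' @export
founders <- function(pedigree) {
  pedigree$id[is.na(pedigree$father_id) & is.na(pedigree$mother_id)]
}

# All (id, relative, degree) pairs up to max_degree, computed with joins.
# Degree 1: parents, children, full siblings. Degree 2: grandparents,
# grandchildren, aunts/uncles, nieces/nephews, half-siblings.
relative_table <- function(pedigree, max_degree = 2) {
  ped <- as_tibble(pedigree)[, c("id", "father_id", "mother_id")]
  par <- bind_rows(
    tibble(id = ped$id, parent = ped$father_id),
    tibble(id = ped$id, parent = ped$mother_id)
  ) |> filter(!is.na(.data$parent))

  parents <- tibble(id = par$id, relative = par$parent)
  children <- tibble(id = par$parent, relative = par$id)

  # siblings: share at least one parent; full = share both known parents
  sib_pairs <- inner_join(par, par, by = "parent",
                          relationship = "many-to-many") |>
    filter(.data$id.x != .data$id.y) |>
    count(id = .data$id.x, relative = .data$id.y, name = "shared")
  pk <- ped |>
    mutate(n_known = (!is.na(.data$father_id)) + (!is.na(.data$mother_id)))
  nk <- setNames(pk$n_known, pk$id)
  full_sibs <- sib_pairs |>
    filter(.data$shared == 2, nk[.data$id] == 2, nk[.data$relative] == 2) |>
    select("id", "relative")
  half_sibs <- sib_pairs |>
    anti_join(full_sibs, by = c("id", "relative")) |>
    select("id", "relative")

  d1 <- bind_rows(parents, children, full_sibs) |>
    distinct() |>
    mutate(degree = 1L)
  if (max_degree < 2) return(d1)

  gp <- inner_join(parents, parents, by = c("relative" = "id"),
                   relationship = "many-to-many") |>
    select(id = "id", relative = "relative.y")
  gc <- tibble(id = gp$relative, relative = gp$id)
  avunc <- inner_join(parents, full_sibs, by = c("relative" = "id"),
                      relationship = "many-to-many") |>
    select(id = "id", relative = "relative.y")
  nieces <- tibble(id = avunc$relative, relative = avunc$id)

  d2 <- bind_rows(gp, gc, avunc, nieces, half_sibs) |>
    distinct() |>
    filter(.data$id != .data$relative) |>
    anti_join(d1, by = c("id", "relative")) |>
    mutate(degree = 2L)
  bind_rows(d1, d2)
}

#' Relatives of an individual by relationship degree
#'
#' Degree 1 covers parents, children and full siblings; degree 2 covers
#' grandparents, grandchildren, aunts/uncles, nieces/nephews and
#' half-siblings (the standard genetic-relatedness convention).
#'
#' @param pedigree A `mody_pedigree`.
#' @param id Individual id.
#' @param degree 1 or 2.
#' @return Character vector of relative ids (exactly the requested degree).
#' @export
relatives_of <- function(pedigree, id, degree = 1) {
  stopifnot(degree %in% c(1L, 2L))
  if (!id %in% pedigree$id) {
    stop("unknown individual id: ", id, call. = FALSE)
  }
  rel <- relative_table(pedigree, max_degree = degree)
  sort(rel$relative[rel$id == id & rel$degree == degree])
}

#' Number of distinct families among a carrier set
#'
#' @param pedigree A `mody_pedigree`.
#' @param carriers Character vector of carrier ids (must be in the
#'   pedigree).
#' @return Integer count of distinct `family_id` values; 0 for an empty set.
#' @export
carrier_families <- function(pedigree, carriers) {
  if (length(carriers) == 0) return(0L)
  unknown <- setdiff(carriers, pedigree$id)
  if (length(unknown) > 0) {
    stop("carrier id(s) not in pedigree: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  dplyr::n_distinct(pedigree$family_id[pedigree$id %in% carriers])
}

#' Assess variant transmission within carrier families
#'
#' For each family containing at least one carrier of `variant_id`, checks
#' Mendelian consistency (no carrier child with both parents genotyped
#' non-carrier), counts informative genotyped trios, computes the
#' co-segregation fraction (diabetic carriers over carriers with known
#' glycemic status), tests autosomal-dominant compatibility (every pair of
#' carriers connected by a pedigree path free of genotyped non-carriers;
#' ungenotyped individuals on such paths are treated as obligate carriers),
#' and infers the transmission lineage where the carrier parental side is
#' genotyped or deducible.
#'
#' @param pedigree A `mody_pedigree`.
#' @param genotypes Long genotype table (`variant_id`, `sample_id`,
#'   `dosage`), as from [read_cohort_vcf()] or [gene_drop()].
#' @param variant_id Variant identifier present in `genotypes`.
#' @param statuses Named character vector of lifetime glycemic statuses
#'   (names = participant ids), e.g. from [classify_participants()].
#' @return A tibble with one row per carrier family: `variant_id`,
#'   `family_id`, `n_carriers`, `mendelian_consistent`,
#'   `n_informative_trios`, `cosegregation_fraction`, `ad_compatible`,
#'   `transmission_lineage` (`"MATERNAL"`, `"PATERNAL"` or `"UNRESOLVED"`).
#' @export
assess_transmission <- function(pedigree, genotypes, variant_id, statuses) {
  gt <- filter(genotypes, .data$variant_id == .env$variant_id)
  if (nrow(gt) == 0) {
    stop("variant not found in genotype table: ", variant_id, call. = FALSE)
  }
  dosage <- setNames(gt$dosage, gt$sample_id)
  carriers <- names(dosage)[!is.na(dosage) & dosage >= 1]
  fam_of <- setNames(pedigree$family_id, pedigree$id)
  fams <- sort(unique(stats::na.omit(fam_of[carriers])))

  purrr::map_dfr(fams, function(fam) {
    ped_f <- pedigree[pedigree$family_id == fam, ]
    carr_f <- intersect(carriers, ped_f$id)
    geno_status <- function(ids) {
      # "carrier", "noncarrier" or "untyped" per individual
      d <- dosage[ids]
      dplyr::case_when(is.na(d) ~ "untyped", d >= 1 ~ "carrier",
                       TRUE ~ "noncarrier")
    }
    father <- setNames(ped_f$father_id, ped_f$id)
    mother <- setNames(ped_f$mother_id, ped_f$id)

    # Mendelian check: carrier child, both parents genotyped non-carrier
    mendel_ok <- TRUE
    for (id in carr_f) {
      ps <- c(father[[id]], mother[[id]])
      ps <- ps[!is.na(ps)]
      if (length(ps) == 2 && all(geno_status(ps) == "noncarrier")) {
        mendel_ok <- FALSE
      }
    }

    trio_child <- ped_f$id[!is.na(father[ped_f$id]) &
                             !is.na(mother[ped_f$id])]
    informative <- vapply(trio_child, function(id) {
      trio <- c(id, father[[id]], mother[[id]])
      all(geno_status(trio) != "untyped") && any(trio %in% carr_f)
    }, logical(1))
    n_trios <- sum(informative)

    st <- statuses[carr_f]
    known <- !is.na(st) & st != "UNKNOWN"
    coseg <- if (any(known)) sum(st[known] == "DIABETIC") / sum(known)
    else NA_real_

    ad_ok <- ad_compatible(ped_f, carr_f, geno_status)
    lineage <- lineage_of(carr_f, father, mother, geno_status)

    tibble(
      variant_id = variant_id, family_id = fam,
      n_carriers = length(carr_f),
      mendelian_consistent = mendel_ok,
      n_informative_trios = n_trios,
      cosegregation_fraction = coseg,
      ad_compatible = ad_ok,
      transmission_lineage = lineage
    )
  })
}

# Connectivity of each carrier pair through parent-child edges avoiding
# genotyped non-carriers (ungenotyped intermediates allowed as obligate
# carriers). Families are small, so BFS per pair is fine.
ad_compatible <- function(ped_f, carr_f, geno_status) {
  if (length(carr_f) < 2) return(TRUE)
  edges <- bind_rows(
    tibble(a = ped_f$id, b = ped_f$father_id),
    tibble(a = ped_f$id, b = ped_f$mother_id)
  ) |> filter(!is.na(.data$b))
  edges <- bind_rows(edges, tibble(a = edges$b, b = edges$a))
  passable <- setNames(geno_status(ped_f$id) != "noncarrier", ped_f$id)
  for (i in seq_len(length(carr_f) - 1)) {
    src <- carr_f[i]
    tgt <- carr_f[(i + 1):length(carr_f)]
    seen <- src
    frontier <- src
    while (length(frontier) > 0) {
      nxt <- unique(edges$b[edges$a %in% frontier])
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, nxt)
      # expand only through passable nodes (endpoints may be reached anyway)
      frontier <- nxt[passable[nxt]]
    }
    if (!all(tgt %in% seen)) return(FALSE)
  }
  TRUE
}

lineage_of <- function(carr_f, father, mother, geno_status) {
  sides <- purrr::map_chr(carr_f, function(id) {
    f <- father[[id]]
    m <- mother[[id]]
    if (is.na(f) && is.na(m)) return(NA_character_)
    fs <- if (is.na(f)) "absent" else geno_status(f)
    ms <- if (is.na(m)) "absent" else geno_status(m)
    if (ms == "carrier" && fs != "carrier") return("MATERNAL")
    if (fs == "carrier" && ms != "carrier") return("PATERNAL")
    if (fs == "noncarrier" && ms %in% c("untyped", "absent")) {
      return("MATERNAL")
    }
    if (ms == "noncarrier" && fs %in% c("untyped", "absent")) {
      return("PATERNAL")
    }
    NA_character_
  })
  sides <- unique(stats::na.omit(sides))
  if (length(sides) == 1) sides else "UNRESOLVED"
}
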