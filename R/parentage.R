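#' @title Paternity assignment by multi-locus exclusion
#' @description
#' Candidate sires for an infant are the sampled males older than 1250
#' days at the infant's birth and present on the island for at least the
#' 200 days preceding it (one gestation plus margin). Mismatches are
#' counted per shared locus: in trio mode against the paternal alleles
#' consistent with the mother-offspring pair, in dyad mode (mother
#' unsampled) by simple allele sharing with the offspring. Assignment
#' rules, applied to candidates genotyped on enough shared loci: best
#' candidate 0 mismatches and runner-up >= 2 (strict), runner-up exactly 1
#' (relaxed), or best 1 mismatch with runner-up >= 3 (one-mismatch gap-3).
#' Anything else — including ties at the top — stays unassigned
#' (likelihood arbitration is out of scope).
#' @name parentage
NULL

#' Genotype container
#'
#' @param calls named list: locus -> character vector of exactly 2 alleles
#'   (homozygotes repeat the allele).
#' @param id individual id.
#' @return a `genotype` object.
#' @export
genotype <- function(id, calls) {
  bad <- names(calls)[vapply(calls, length, integer(1)) != 2]
  if (length(bad)) {
    stop("locus call(s) without exactly 2 alleles: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(id = id, calls = lapply(calls, as.character),
                 n_loci = length(calls)), class = "genotype")
}

#' Build genotype objects from a long-format genotype table
#' @param df genotype table (`id`, `locus`, `allele1`, `allele2`).
#' @return named list of [genotype()] objects.
#' @export
genotypes_from_table <- function(df) {
  out <- lapply(split(df, df$id), function(g) {
    calls <- Map(c, g$allele1, g$allele2)
    names(calls) <- g$locus
    genotype(g$id[1], calls)
  })
  out[unique(df$id)]
}

#' Eligible candidate sires for an infant
#'
#' @param infant one row of the individual table (needs `birth_day`).
#' @param males individual table of sampled males.
#' @param memberships membership table; any group counts as island
#'   presence.
#' @param min_age_days minimum age at the infant's birth (default 1250).
#' @param presence_days required continuous presence immediately before
#'   the birth (default 200).
#' @return character vector of eligible male ids (possibly empty).
#' @export
candidate_sires <- function(infant, males, memberships,
                            min_age_days = 1250, presence_days = 200) {
  b <- infant$birth_day[1]
  old_enough <- (b - males$birth_day) > min_age_days
  present <- vapply(males$id, function(m) {
    mm <- memberships[memberships$id == m, , drop = FALSE]
    .ck_interval_intersection(mm$start_day, mm$end_day,
                              b - presence_days, b) >= presence_days
  }, logical(1))
  males$id[old_enough & present]
}

#' Count paternal mismatches between an offspring and a candidate
#'
#' Trio mode (mother given): at each locus shared by offspring and
#' candidate, the offspring's possible paternal alleles are those whose
#' complementary allele the mother carries; a mismatch is a locus where
#' the candidate carries none of them. If mother and offspring are
#' themselves incompatible at a locus, the locus falls back to dyad logic.
#' Dyad mode (`mother = NULL`): a mismatch is a shared locus where the
#' candidate shares no allele with the offspring.
#'
#' @param offspring,candidate [genotype()] objects.
#' @param mother [genotype()] or `NULL`.
#' @return list with `mismatches` and `shared_loci`.
#' @export
count_mismatches <- function(offspring, mother = NULL, candidate) {
  shared <- intersect(names(offspring$calls), names(candidate$calls))
  if (!length(shared)) stop("zero shared loci", call. = FALSE)
  mm <- 0L
  for (loc in shared) {
    o <- offspring$calls[[loc]]
    cand <- candidate$calls[[loc]]
    pat <- unique(o)
    if (!is.null(mother) && loc %in% names(mother$calls)) {
      mo <- mother$calls[[loc]]
      poss <- character(0)
      if (o[1] %in% mo) poss <- c(poss, o[2])
      if (o[2] %in% mo) poss <- c(poss, o[1])
      if (length(poss)) pat <- unique(poss)
      # else: mother-offspring mismatch at locus; dyad fallback
    }
    if (!any(pat %in% cand)) mm <- mm + 1L
  }
  list(mismatches = mm, shared_loci = length(shared))
}

#' Assign paternity by the exclusion rules
#'
#' Candidates sharing fewer than `min_shared_loci` loci with the offspring
#' are dropped with a warning. Remaining candidates are ordered by
#' mismatch count; the rule fired depends on the best and second-best
#' counts: `0 / >=2` strict, `0 / 1` relaxed, `1 / >=3` one-mismatch
#' gap-3; everything else (including ties at the best count) is
#' unassigned. A single candidate needs 0 mismatches for a strict
#' assignment.
#'
#' @param offspring [genotype()].
#' @param mother [genotype()] or `NULL` (dyad mode).
#' @param candidates list of [genotype()] objects.
#' @param min_shared_loci minimum shared loci for a candidate to be
#'   compared (default 12).
#' @return list with `offspring_id`, `assigned_sire` (id or `NA`), `rule`
#'   (`"strict"`, `"relaxed"`, `"one_mismatch_gap3"` or `"unassigned"`),
#'   `tie` flag, and named vectors `mismatch_counts`, `shared_loci`.
#' @export
assign_paternity <- function(offspring, mother = NULL, candidates,
                             min_shared_loci = 12) {
  if (!length(candidates)) stop("no candidates", call. = FALSE)
  counts <- integer(0); shared <- integer(0)
  for (cand in candidates) {
    cm <- count_mismatches(offspring, mother, cand)
    counts[cand$id] <- cm$mismatches
    shared[cand$id] <- cm$shared_loci
  }
  eligible <- names(counts)[shared >= min_shared_loci]
  dropped <- setdiff(names(counts), eligible)
  if (length(dropped)) {
    warning("candidate(s) below ", min_shared_loci, " shared loci dropped: ",
            paste(dropped, collapse = ", "))
  }
  res <- list(offspring_id = offspring$id, assigned_sire = NA_character_,
              rule = "unassigned", tie = FALSE,
              mismatch_counts = counts, shared_loci = shared)
  if (!length(eligible)) return(res)
  ec <- counts[eligible]
  o <- order(ec)
  best <- ec[o[1]]
  second <- if (length(ec) > 1) ec[o[2]] else Inf
  if (length(ec) > 1 && second == best) {
    res$tie <- TRUE
    return(res)
  }
  rule <- if (best == 0 && second >= 2) "strict"
          else if (best == 0 && second == 1) "relaxed"
          else if (best == 1 && second >= 3) "one_mismatch_gap3"
          else "unassigned"
  if (rule != "unassigned") {
    res$assigned_sire <- names(ec)[o[1]]
    res$rule <- rule
  }
  res
}

#' Assign paternity for a set of offspring
#'
#' Convenience wrapper: derives each offspring's candidate set with
#' [candidate_sires()] and applies [assign_paternity()] in trio mode when
#' the mother is genotyped, dyad mode otherwise.
#'
#' @param offspring_ids ids to assign.
#' @param individuals individual table.
#' @param memberships membership table.
#' @param genotypes named list from [genotypes_from_table()].
#' @param min_shared_loci,min_age_days,presence_days thresholds.
#' @return data.frame (`offspring_id`, `assigned_sire`, `rule`, `tie`,
#'   `n_candidates`).
#' @export
paternity_table <- function(offspring_ids, individuals, memberships,
                            genotypes, min_shared_loci = 12,
                            min_age_days = 1250, presence_days = 200) {
  males <- individuals[individuals$sex == "male" &
                         individuals$id %in% names(genotypes), , drop = FALSE]
  rows <- lapply(offspring_ids, function(oid) {
    ind <- individuals[individuals$id == oid, , drop = FALSE]
    cand_ids <- candidate_sires(ind, males, memberships,
                                min_age_days, presence_days)
    cand_ids <- setdiff(cand_ids, oid)
    if (!length(cand_ids) || is.null(genotypes[[oid]])) {
      return(data.frame(offspring_id = oid, assigned_sire = NA_character_,
                        rule = "unassigned", tie = FALSE,
                        n_candidates = length(cand_ids),
                        stringsAsFactors = FALSE))
    }
    mom <- ind$mother_id[1]
    mother_g <- if (!is.na(mom)) genotypes[[mom]] else NULL
    a <- assign_paternity(genotypes[[oid]], mother_g,
                          genotypes[cand_ids], min_shared_loci)
    data.frame(offspring_id = oid, assigned_sire = a$assigned_sire,
               rule = a$rule, tie = a$tie, n_candidates = length(cand_ids),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
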