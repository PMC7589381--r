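#' Expected transgene segregation ratio in selfed progeny
#'
#' Under independent assortment, a plant hemizygous at `n` unlinked T-DNA
#' insertion loci yields selfed offspring that carry at least one insertion
#' in (4^n - 1) of 4^n cases: each insertion is transmitted to 3/4 of
#' offspring, so the transgenic:non-transgenic ratio is (4^n - 1):1.
#'
#' @param n_unlinked_insertions Number of hemizygous insertion loci (>= 0).
#' @return Named numeric vector c(transgenic=, nontransgenic=).
#' @export
expected_segregation <- function(n_unlinked_insertions) {
  n <- as.integer(n_unlinked_insertions)
  if (n < 0L) stop("n must be >= 0")
  c(transgenic = 4^n - 1, nontransgenic = 1)
}

#' Chi-square test of a Mendelian segregation ratio
#'
#' Pearson chi-square goodness of fit (1 degree of freedom, no continuity
#' correction) of observed transgenic/non-transgenic counts against an
#' expected ratio. The observed segregation is called consistent with the
#' ratio iff p >= alpha.
#'
#' @param n_pos Observed transgenic count.
#' @param n_neg Observed non-transgenic count.
#' @param ratio Expected ratio, default `c(3, 1)`.
#' @param alpha Significance level (default 0.05).
#' @return A `segregation_result`: observed counts, expected counts,
#'   chi_square, df, p_value, consistent.
#' @export
segregation_test <- function(n_pos, n_neg, ratio = c(3, 1), alpha = 0.05) {
  n <- n_pos + n_neg
  if (n < 1L) stop("zero total count")
  expected <- n * ratio / sum(ratio)
  chi2 <- sum((c(n_pos, n_neg) - expected)^2 / expected)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(
    list(
      observed = c(transgenic = n_pos, nontransgenic = n_neg),
      expected = expected, ratio = ratio,
      chi_square = chi2, df = 1L, p_value = p, alpha = alpha,
      consistent = p >= alpha
    ),
    class = "segregation_result"
  )
}

#' @export
print.segregation_result <- function(x, ...) {
  cat("<segregation_result>", x$observed[1], ":", x$observed[2],
      "vs", paste(x$ratio, collapse = ":"),
      sprintf("chi^2 = %.3f, p = %.4f ->", x$chi_square, x$p_value),
      if (x$consistent) "consistent" else "inconsistent", "\n")
  invisible(x)
}

#' Classify allele transmission across a pedigree
#'
#' For every offspring allele, reports whether it was inherited (present in
#' the parent's somatic allele set -- for chimeric parents the clone-derived
#' set), de novo (absent from the parent; expected only while the transgene
#' and hence Cas9 is still present) or anomalous (absent from the parent in
#' a non-transgenic offspring). Parental mutant alleles found in no
#' offspring of a parent are reported as lost, the signature of mutations
#' confined to somatic sectors outside the germ line.
#'
#' @param pedigree A `pedigree` from [simulate_pedigree()] (or a compatible
#'   list with a `plants` element).
#' @return List: `alleles` (data.frame plant_id, locus, allele, class),
#'   `lost` (data.frame parent_id, locus, allele), `n_de_novo`,
#'   `n_anomalous`.
#' @export
track_alleles <- function(pedigree) {
  plants <- pedigree$plants
  gens <- vapply(plants, `[[`, character(1), "generation")
  if (length(unique(gens)) < 2L) stop("pedigree needs at least 2 generations")
  rows <- list()
  offspring_of <- split(
    names(plants),
    vapply(plants, function(p) ifelse(is.na(p$parent_id), "", p$parent_id), character(1))
  )
  for (pid in names(plants)) {
    p <- plants[[pid]]
    if (is.na(p$parent_id)) next
    parent <- plants[[p$parent_id]]
    if (is.null(parent)) stop("orphan node: ", pid, " has unknown parent ", p$parent_id)
    for (l in names(p$alleles)) {
      for (a in p$alleles[[l]]) {
        cls <- if (a %in% parent$alleles[[l]]) {
          "inherited"
        } else if (any(p$transgene_copies > 0L)) {
          "de novo"
        } else {
          "anomalous"
        }
        rows[[length(rows) + 1L]] <- data.frame(
          plant_id = pid, locus = l, allele = a, class = cls,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  alleles <- do.call(rbind, rows)
  lost <- list()
  for (pid in names(offspring_of)) {
    if (pid == "" || is.null(plants[[pid]])) next
    kids <- offspring_of[[pid]]
    if (!length(kids)) next
    parent <- plants[[pid]]
    for (l in names(parent$alleles)) {
      mut <- setdiff(parent$alleles[[l]][!grepl("h$", parent$alleles[[l]])], NA)
      if (!length(mut)) next
      seen <- unique(unlist(lapply(kids, function(k) plants[[k]]$alleles[[l]])))
      for (a in setdiff(mut, seen)) {
        lost[[length(lost) + 1L]] <- data.frame(
          parent_id = pid, locus = l, allele = a, stringsAsFactors = FALSE
        )
      }
    }
  }
  lost <- if (length(lost)) do.call(rbind, lost) else data.frame(
    parent_id = character(0), locus = character(0), allele = character(0),
    stringsAsFactors = FALSE
  )
  list(
    alleles = alleles, lost = lost,
    n_de_novo = sum(alleles$class == "de novo"),
    n_anomalous = sum(alleles$class == "anomalous")
  )
}

#' Select homozygous (optionally non-transgenic) multi-mutant plants
#'
#' @param plants A `pedigree`, or a list of `plant_genotype` objects.
#' @param required_homozygous_loci Loci that must be homozygous mutant
#'   (two identical, non-wild-type alleles).
#' @param require_nontransgenic Drop plants still carrying the transgene.
#' @param generation Optional generation label filter (e.g. `"T4"`).
#' @return data.frame of selected plants (plant_id, generation, one column
#'   per required locus, transgenic), ordered by plant_id. Zero rows carry a
#'   `diagnostic` attribute explaining the failure.
#' @export
select_candidates <- function(plants, required_homozygous_loci,
                              require_nontransgenic = TRUE,
                              generation = NULL) {
  if (inherits(plants, "pedigree")) plants <- plants$plants
  rows <- list()
  n_transgenic_blocked <- 0L
  for (p in plants) {
    if (!is.null(generation) && p$generation != generation) next
    hom <- vapply(required_homozygous_loci, function(l) {
      a <- p$alleles[[l]]
      !is.null(a) && length(a) <= 2L && length(unique(a)) == 1L && !grepl("h$", a[1])
    }, logical(1))
    if (!all(hom)) next
    tg <- any(p$transgene_copies > 0L)
    if (require_nontransgenic && tg) {
      n_transgenic_blocked <- n_transgenic_blocked + 1L
      next
    }
    row <- data.frame(plant_id = p$plant_id, generation = p$generation,
                      stringsAsFactors = FALSE)
    for (l in required_homozygous_loci) row[[l]] <- p$alleles[[l]][1]
    row$transgenic <- tg
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(out)) {
    out <- data.frame(plant_id = character(0), generation = character(0),
                      transgenic = logical(0), stringsAsFactors = FALSE)
    attr(out, "diagnostic") <- if (n_transgenic_blocked > 0L) {
      paste0(n_transgenic_blocked,
             " plant(s) homozygous at all required loci but still transgenic")
    } else {
      "no plant homozygous mutant at all required loci"
    }
    return(out)
  }
  out <- out[order(out$plant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
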