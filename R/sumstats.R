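# Cohort summary surface: demographics, phenotype and variant-type
# frequencies, and truncating/nontruncating phenotype strata per level.

# Half-away-from-zero rounding to one decimal, for report parity with the
# conventional presentation of percentages.
.round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.age_block <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) {
    return(list(n = 0L, mean = NA_real_, median = NA_real_,
                range = c(NA_real_, NA_real_)))
  }
  list(n = length(x), mean = mean(x), median = stats::median(x),
       range = range(x))
}

.freq_block <- function(counts, denom) {
  data.frame(count = as.integer(counts),
             denominator = as.integer(denom),
             percent = .round_half_up(100 * counts / denom),
             row.names = names(counts))
}

#' Summarize a cohort at every analysis level
#'
#' Computes the standard summary surface: unit counts per level, patient
#' sex and de novo counts, the three age statistics (each with its pairwise
#' deletion denominator), per-phenotype and per-variant-type frequencies,
#' and the per-phenotype counts within the truncating and nontruncating
#' strata. Phenotype percentages can sum past 100 because units carry
#' several phenotypes.
#'
#' @param cohort a \code{\linkS4class{VHLCohort}}.
#' @param phenotypes phenotype groups to tabulate (default the 7 analyzed).
#' @return nested list: one entry per level (\code{patient}, \code{family},
#'   \code{variant}) with \code{n}, \code{phenotype}, \code{variant_type}
#'   and \code{by_group} frequency tables; the patient entry additionally
#'   carries \code{sex}, \code{de_novo} and \code{ages}.
#' @export
cohortSummary <- function(cohort, phenotypes = vhlPhenotypes()) {
  views <- list(patient = patients(cohort), family = families(cohort),
                variant = variantUnits(cohort))
  out <- lapply(names(views), function(level) {
    units <- views[[level]]
    n <- nrow(units)
    phe_counts <- vapply(phenotypes, function(p)
      sum(vapply(units$phenotypes, function(s) p %in% s, logical(1))),
      integer(1))
    vt_counts <- vapply(VARIANT_TYPES, function(v)
      sum(units$variant_type == v, na.rm = TRUE), integer(1))
    by_group <- lapply(c(truncating = "truncating",
                         nontruncating = "nontruncating"), function(g) {
      sub <- units[units$group == g, , drop = FALSE]
      cnt <- vapply(phenotypes, function(p)
        sum(vapply(sub$phenotypes, function(s) p %in% s, logical(1))),
        integer(1))
      .freq_block(cnt, nrow(sub))
    })
    block <- list(n = n,
                  phenotype = .freq_block(phe_counts, n),
                  variant_type = .freq_block(vt_counts, n),
                  by_group = by_group)
    if (level == "patient") {
      sex_n <- sum(units$sex %in% c("male", "female"))
      block$sex <- .freq_block(
        c(male = sum(units$sex == "male"),
          female = sum(units$sex == "female")), sex_n)
      block$de_novo <- sum(units$de_novo == "confirmed", na.rm = TRUE)
      block$ages <- list(age_onset = .age_block(units$age_onset),
                         age_death = .age_block(units$age_death),
                         last_known_age = .age_block(units$last_known_age))
    }
    block
  })
  names(out) <- names(views)
  out
}
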