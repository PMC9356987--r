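# Age-related penetrance from isolated-phenotype patients, and all-pairs
# two-sample Kolmogorov-Smirnov testing with Bonferroni correction.

#' Onset ages of patients with an isolated phenotype
#'
#' A patient contributes iff it carries exactly one phenotype group and has
#' an onset age (pairwise deletion: patients missing the age are skipped,
#' not imputed). Phenotypes with fewer than \code{min_n} contributing
#' patients are dropped with a warning, mirroring the exclusion of
#' undersampled manifestations from the penetrance analysis.
#'
#' @param patient_units patient-level analysis units.
#' @param min_n minimum sample size to retain a phenotype (default 5).
#' @return named list of numeric onset-age vectors, one per retained
#'   phenotype; dropped phenotypes recorded in attribute "dropped".
#' @export
isolatedOnsetAges <- function(patient_units, min_n = 5) {
  iso <- lengths(patient_units$phenotypes) == 1L &
    !is.na(patient_units$age_onset)
  sub <- patient_units[iso, , drop = FALSE]
  phe <- vapply(sub$phenotypes, `[`, "", 1L)
  ages <- split(sub$age_onset, phe)
  small <- names(ages)[lengths(ages) < min_n]
  if (length(small))
    warning("dropping undersampled phenotype(s): ",
            paste(small, collapse = ", "))
  out <- ages[lengths(ages) >= min_n]
  attr(out, "dropped") <- small
  out
}

#' Empirical penetrance curves
#'
#' Builds, per phenotype, the onset-age empirical CDF among
#' isolated-phenotype patients, and reads off the first age at which the
#' CDF reaches 0.5 (the "50% patient threshold").
#'
#' @param age_map named list of onset-age vectors (see
#'   \code{\link{isolatedOnsetAges}}).
#' @param min_n minimum sample size recorded in the object.
#' @return a \code{\linkS4class{PenetranceCurves}}.
#' @export
penetranceCurves <- function(age_map, min_n = 5) {
  ages <- lapply(age_map, function(x) sort(as.numeric(x)))
  med <- vapply(ages, function(x) {
    if (length(x) < min_n) return(NA_real_)
    Fn <- stats::ecdf(x)
    x[which(Fn(x) >= 0.5)[1L]]
  }, numeric(1))
  methods::new("PenetranceCurves", ages = ages,
               n = vapply(ages, length, integer(1)),
               median_age = med, min_n = min_n,
               dropped = as.character(attr(age_map, "dropped") %||%
                                        character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' All-pairs two-sample Kolmogorov-Smirnov grid
#'
#' Two-sided two-sample KS test for each unordered pair of phenotype onset
#' distributions, Bonferroni-corrected over the m = k(k-1)/2 pairs. Exact
#' p-values are used when the product of the sample sizes is at most 1e4
#' and the pooled sample is tie-free; the asymptotic distribution is used
#' otherwise (onset ages are integer years, so ties are expected at scale).
#' Pairs where either sample has fewer than two observations are reported
#' untested.
#'
#' @param age_map named list of onset-age vectors.
#' @param alpha nominal family-wise level.
#' @return a \code{\linkS4class{KSGrid}}.
#' @export
pairwiseKS <- function(age_map, alpha = 0.05) {
  k <- length(age_map)
  if (k < 2) stop("pairwise KS needs at least two phenotypes")
  phe <- names(age_map)
  m <- k * (k - 1) / 2
  D <- p <- matrix(NA_real_, k, k, dimnames = list(phe, phe))
  tested <- matrix(FALSE, k, k, dimnames = list(phe, phe))
  diag(D) <- 0; diag(p) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- age_map[[i]]; y <- age_map[[j]]
    if (length(x) < 2 || length(y) < 2) next
    exact <- length(x) * length(y) <= 1e4 &&
      !anyDuplicated(c(x, y))
    ht <- suppressWarnings(stats::ks.test(x, y, exact = exact))
    D[i, j] <- D[j, i] <- unname(ht$statistic)
    p[i, j] <- p[j, i] <- ht$p.value
    tested[i, j] <- tested[j, i] <- TRUE
  }
  sig <- !is.na(p) & p <= alpha / m & tested
  methods::new("KSGrid", D = D, p = p, significant = sig, tested = tested,
               alpha = alpha, m = m)
}

setMethod("show", "PenetranceCurves", function(object) {
  cat("PenetranceCurves (isolated-phenotype onset ages)\n")
  for (phe in names(object@ages)) {
    cat(sprintf("  %-5s n = %4d  50%% threshold = %s years\n", phe,
                object@n[[phe]],
                format(object@median_age[[phe]])))
  }
  if (length(object@dropped))
    cat("  dropped (n <", object@min_n, "):",
        paste(object@dropped, collapse = ", "), "\n")
})

setMethod("show", "KSGrid", function(object) {
  cat(sprintf("KSGrid: %d phenotypes, %d pairs, corrected alpha = %.3g\n",
              nrow(object@D), object@m, object@alpha / object@m))
  cat("D statistics:\n")
  print(round(object@D, 3))
  sig <- which(object@significant & upper.tri(object@significant),
               arr.ind = TRUE)
  if (nrow(sig)) {
    cat("significant pairs:",
        paste(sprintf("%s-%s", rownames(object@D)[sig[, 1]],
                      colnames(object@D)[sig[, 2]]), collapse = ", "),
        "\n")
  } else cat("no significant pairs\n")
})
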