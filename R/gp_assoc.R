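# Genotype-phenotype contingency analyses: truncating/nontruncating by
# phenotype, pairwise post hocs, and structural/functional domain tests.

#' Build the phenotype-by-variant-group contingency table
#'
#' One row per phenotype, columns truncating and nontruncating. A unit
#' carrying k phenotypes contributes k cell increments (one per phenotype
#' row); units with group "excluded" do not contribute.
#'
#' @param units analysis-unit data.frame.
#' @param phenotypes phenotype rows (default the 7 analyzed groups).
#' @return integer matrix, phenotypes x c(truncating, nontruncating).
#' @export
buildGroupTable <- function(units, phenotypes = vhlPhenotypes()) {
  units <- units[units$group %in% c("truncating", "nontruncating"), ,
                 drop = FALSE]
  if (!nrow(units)) stop("empty table: no truncating/nontruncating units")
  tab <- vapply(c("truncating", "nontruncating"), function(g) {
    sub <- units[units$group == g, , drop = FALSE]
    vapply(phenotypes, function(p)
      sum(vapply(sub$phenotypes, function(s) p %in% s, logical(1))),
      integer(1))
  }, integer(length(phenotypes)))
  matrix(tab, nrow = length(phenotypes),
         dimnames = list(phenotypes, c("truncating", "nontruncating")))
}

#' Pearson chi-square test without continuity correction
#'
#' @param table count matrix (all expected counts must be positive).
#' @param alpha nominal level recorded in the result.
#' @param posthoc logical: run all pairwise 2x2 row comparisons with a
#'   Bonferroni-corrected level alpha / C(rows, 2).
#' @return a \code{\linkS4class{ContingencyResult}}.
#' @examples
#' chi2Test(rbind(PPGL = c(72, 688), CHB = c(519, 676)))
#' @export
chi2Test <- function(table, alpha = 0.05, posthoc = FALSE) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0))
    stop("zero row marginal: ",
         paste(rownames(table)[rowSums(table) == 0], collapse = ", "))
  if (any(colSums(table) == 0))
    stop("zero column marginal: ",
         paste(colnames(table)[colSums(table) == 0], collapse = ", "))
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  ph <- if (posthoc && nrow(table) >= 2) posthocPairwise(table, alpha) else
    data.frame()
  methods::new("ContingencyResult", table = table,
               expected = ht$expected,
               statistic = unname(ht$statistic), df = unname(ht$parameter),
               p.value = ht$p.value, posthoc = ph, alpha = alpha)
}

#' Pairwise post hoc comparisons between phenotype rows
#'
#' For each unordered pair of rows, a 2-column chi-square compares the two
#' phenotypes' splits; significance is Bonferroni-corrected at
#' alpha / C(rows, 2). Degenerate pairs (a zero marginal in the 2x2) are
#' reported untested.
#'
#' @param table count matrix with >= 2 rows.
#' @param alpha nominal level.
#' @return data.frame with columns a, b, chi2, p, significant, tested.
#' @export
posthocPairwise <- function(table, alpha = 0.05) {
  table <- as.matrix(table)
  k <- nrow(table)
  if (k < 2) stop("post hoc needs at least two phenotype rows")
  m <- choose(k, 2)
  rows <- rownames(table)
  if (is.null(rows)) rows <- as.character(seq_len(k))
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sub <- table[c(i, j), , drop = FALSE]
    ok <- all(rowSums(sub) > 0) && all(colSums(sub) > 0)
    if (ok) {
      ht <- suppressWarnings(stats::chisq.test(sub, correct = FALSE))
      out[[length(out) + 1L]] <- data.frame(
        a = rows[i], b = rows[j], chi2 = unname(ht$statistic),
        p = ht$p.value, significant = ht$p.value <= alpha / m,
        tested = TRUE, stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        a = rows[i], b = rows[j], chi2 = NA_real_, p = NA_real_,
        significant = FALSE, tested = FALSE, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "m") <- m
  attr(res, "corrected_alpha") <- alpha / m
  res
}

#' Domain distribution tests
#'
#' Builds two phenotype-by-region tables over units with a codon position:
#' the structural table (alpha-domain 156-204 vs beta-domain 63-143) and
#' the functional table (HIF-alpha binding site vs Elongin B/C binding
#' site; codon 79 belongs to both sites and counts in both columns). Units
#' in neither region of a table are tallied separately, not tested. Each
#' table gets the Pearson chi-square plus pairwise post hocs.
#'
#' @param units analysis-unit data.frame.
#' @param phenotypes phenotype rows.
#' @param alpha nominal level.
#' @return list with \code{structural} and \code{functional} results
#'   (each a \code{\linkS4class{ContingencyResult}}, or a list with the
#'   reduced table and \code{untested = TRUE} when the table is
#'   degenerate) and \code{outside} counts (units outside both regions of
#'   each table).
#' @export
domainTests <- function(units, phenotypes = vhlPhenotypes(), alpha = 0.05) {
  coding <- units[!is.na(units$codon), , drop = FALSE]
  if (!nrow(coding)) stop("no units with codon positions")
  dom <- annotateDomains(coding$codon)
  count_tab <- function(in_a, in_b, names_ab) {
    tab <- vapply(list(in_a, in_b), function(flag) {
      sub <- coding[flag, , drop = FALSE]
      vapply(phenotypes, function(p)
        sum(vapply(sub$phenotypes, function(s) p %in% s, logical(1))),
        integer(1))
    }, integer(length(phenotypes)))
    matrix(tab, nrow = length(phenotypes),
           dimnames = list(phenotypes, names_ab))
  }
  structural <- count_tab(dom$in_alpha, dom$in_beta, c("alpha", "beta"))
  functional <- count_tab(dom$in_hif, dom$in_elongin, c("hif", "elongin"))
  # phenotypes absent from both regions of a table cannot be tested there
  run_test <- function(tab) {
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2 || any(colSums(tab) == 0))
      return(list(table = tab, untested = TRUE))
    chi2Test(tab, alpha, posthoc = TRUE)
  }
  list(structural = run_test(structural),
       functional = run_test(functional),
       outside = c(structural = sum(!dom$in_alpha & !dom$in_beta),
                   functional = sum(!dom$in_hif & !dom$in_elongin)))
}

setMethod("show", "ContingencyResult", function(object) {
  cat(sprintf("ContingencyResult: chi2 = %.4g, df = %d, p = %.3g\n",
              object@statistic, as.integer(object@df), object@p.value))
  print(object@table)
  if (nrow(object@posthoc)) {
    sig <- object@posthoc[object@posthoc$significant, , drop = FALSE]
    cat(sprintf("post hoc: %d/%d pairs significant at alpha/m = %.3g\n",
                nrow(sig), nrow(object@posthoc),
                attr(object@posthoc, "corrected_alpha")))
  }
})
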