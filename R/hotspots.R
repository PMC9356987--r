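# Per-codon missense recurrence tests against an even-distribution null:
# exact one-tailed binomial on raw counts, and a continuous-tail variant on
# BLOSUM90-weighted cumulative scores.

#' Tally missense observations per codon
#'
#' Only units classified missense with a codon position contribute; all
#' other variant types are ignored.
#'
#' @param units analysis-unit data.frame.
#' @return list with \code{counts} (integer vector of length 213, named by
#'   codon) and \code{n_total}.
#' @export
codonCounts <- function(units) {
  mis <- units[!is.na(units$variant_type) &
                 units$variant_type == "missense" &
                 !is.na(units$codon), , drop = FALSE]
  counts <- tabulate(mis$codon, nbins = VHL_N_CODONS)
  names(counts) <- seq_len(VHL_N_CODONS)
  list(counts = counts, n_total = sum(counts))
}

#' One-tailed binomial hotspot test per codon
#'
#' Under the null that the n_total missense observations fall evenly over
#' the 213 codons, each codon count is Binomial(n_total, 1/213). The exact
#' upper tail P(X >= count) is tested per codon at the Bonferroni-corrected
#' level alpha/213; codons at p <= (alpha/213) * 1e-4 (four orders of
#' magnitude below the corrected level) are flagged highly significant.
#'
#' @param counts integer vector of per-codon counts (length 213).
#' @param n_total total missense observations (defaults to
#'   \code{sum(counts)}).
#' @param alpha nominal family-wise level (default 0.05).
#' @return data.frame with columns codon, count, p_raw, significant,
#'   highly_significant.
#' @export
binomialHotspotTest <- function(counts, n_total = sum(counts),
                                alpha = 0.05) {
  if (n_total < 1) stop("no missense observations: empty hotspot test")
  stopifnot(length(counts) == VHL_N_CODONS)
  p0 <- 1 / VHL_N_CODONS
  p_raw <- stats::pbinom(counts - 1L, n_total, p0, lower.tail = FALSE)
  cutoff <- alpha / VHL_N_CODONS
  data.frame(codon = seq_len(VHL_N_CODONS), count = as.integer(counts),
             p_raw = p_raw,
             significant = p_raw <= cutoff,
             highly_significant = p_raw <= cutoff * 1e-4)
}

#' Read a substitution matrix in NCBI plain-text format
#'
#' @param path matrix file (default: the bundled BLOSUM90, 20 standard
#'   amino acids).
#' @return symmetric numeric matrix with amino-acid dimnames.
#' @export
readBlosum <- function(path = system.file("extdata", "BLOSUM90.txt",
                                          package = "vhlgp")) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  aas <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  mat <- t(vapply(rows, function(r) as.numeric(r[-1]),
                  numeric(length(aas))))
  dimnames(mat) <- list(vapply(rows, `[`, "", 1L), aas)
  if (!isTRUE(all.equal(mat, t(mat))))
    stop("substitution matrix is not symmetric")
  mat
}

#' Radicality weights for missense observations under BLOSUM90
#'
#' Each missense observation (ref -> alt) is weighted by its substitution
#' radicality w = (b(ref, ref) - b(ref, alt)) / Wbar, where b is the
#' BLOSUM90 entry and Wbar is the mean of b(r, r) - b(r, a) over all 380
#' ordered non-identical amino-acid pairs. The normalization makes the
#' cohort-average weight approximately 1, so cumulative scores are
#' commensurate with raw counts. Conservative substitutions weigh less
#' than radical ones.
#'
#' @param ref_aa,alt_aa one-letter amino acids (vectors).
#' @param blosum substitution matrix from \code{\link{readBlosum}}.
#' @return numeric vector of weights.
#' @export
blosumWeight <- function(ref_aa, alt_aa, blosum = readBlosum()) {
  aas <- rownames(blosum)
  if (any(!ref_aa %in% aas) || any(!alt_aa %in% aas))
    stop("amino acid outside the 20-letter alphabet ",
         "(stop-gain observations are not missense)")
  if (any(ref_aa == alt_aa))
    stop("identical ref and alt amino acids are not missense")
  pairs <- expand.grid(r = aas, a = aas, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$r != pairs$a, ]
  wbar <- mean(blosum[cbind(pairs$r, pairs$r)] -
                 blosum[cbind(pairs$r, pairs$a)])
  (blosum[cbind(ref_aa, ref_aa)] - blosum[cbind(ref_aa, alt_aa)]) / wbar
}

#' Cumulative BLOSUM90-adjusted codon scores
#'
#' @param observations data.frame with columns \code{codon},
#'   \code{ref_aa}, \code{alt_aa} (one row per missense observation).
#' @param blosum substitution matrix.
#' @return list with \code{scores} (numeric vector of length 213) and
#'   \code{s_total}.
#' @export
blosumAdjust <- function(observations, blosum = readBlosum()) {
  scores <- numeric(VHL_N_CODONS)
  names(scores) <- seq_len(VHL_N_CODONS)
  if (nrow(observations)) {
    if (any(is.na(observations$codon) | observations$codon < 1 |
              observations$codon > VHL_N_CODONS))
      stop("observation codons must lie in 1..", VHL_N_CODONS)
    w <- blosumWeight(observations$ref_aa, observations$alt_aa, blosum)
    agg <- tapply(w, factor(observations$codon,
                            levels = seq_len(VHL_N_CODONS)), sum)
    scores <- ifelse(is.na(agg), 0, agg)
    names(scores) <- seq_len(VHL_N_CODONS)
  }
  list(scores = scores, s_total = sum(scores))
}

#' Continuous one-tailed test on BLOSUM-adjusted codon scores
#'
#' Extends the one-tailed binomial tail to non-integer cumulative scores:
#' under an even distribution the expected score per codon is
#' lambda = s_total / 213, and the upper tail of a Poisson(lambda) count is
#' continued in its argument via the gamma distribution,
#' p = P(Gamma(shape = score) <= lambda) (equal to the Poisson upper tail
#' P(X >= score) at integer scores; p = 1 at score 0). The same Bonferroni
#' threshold as the raw test applies.
#'
#' @param scores per-codon cumulative scores (length 213, non-negative).
#' @param s_total total score (defaults to \code{sum(scores)}).
#' @param alpha nominal family-wise level.
#' @return data.frame with columns codon, blosum_score, p_blosum,
#'   significant_blosum.
#' @export
blosumHotspotTest <- function(scores, s_total = sum(scores),
                              alpha = 0.05) {
  stopifnot(length(scores) == VHL_N_CODONS)
  if (any(scores < 0)) stop("negative BLOSUM-adjusted scores")
  if (s_total <= 0) stop("no missense observations: empty hotspot test")
  lambda <- s_total / VHL_N_CODONS
  p <- ifelse(scores <= 0, 1,
              stats::pgamma(lambda, shape = scores, lower.tail = TRUE))
  cutoff <- alpha / VHL_N_CODONS
  data.frame(codon = seq_len(VHL_N_CODONS), blosum_score = as.numeric(scores),
             p_blosum = p, significant_blosum = p <= cutoff)
}

#' Full per-codon hotspot analysis for one analysis level
#'
#' Combines the raw exact-binomial test and the BLOSUM90-adjusted
#' continuous test over the missense observations of the given units.
#'
#' @param units analysis-unit data.frame (patient or family level).
#' @param alpha nominal family-wise level.
#' @param blosum substitution matrix.
#' @return a \code{\linkS4class{HotspotResult}}.
#' @export
hotspotAnalysis <- function(units, alpha = 0.05, blosum = readBlosum()) {
  cc <- codonCounts(units)
  raw <- binomialHotspotTest(cc$counts, cc$n_total, alpha)
  mis <- units[!is.na(units$variant_type) &
                 units$variant_type == "missense" &
                 !is.na(units$codon) & !is.na(units$ref_aa) &
                 !is.na(units$alt_aa), c("codon", "ref_aa", "alt_aa")]
  adj <- blosumAdjust(mis, blosum)
  bl <- blosumHotspotTest(adj$scores, adj$s_total, alpha)
  tab <- data.frame(codon = raw$codon, count = raw$count,
                    blosum_score = bl$blosum_score, p_raw = raw$p_raw,
                    p_blosum = bl$p_blosum,
                    significant = raw$significant,
                    highly_significant = raw$highly_significant,
                    significant_blosum = bl$significant_blosum)
  methods::new("HotspotResult", table = tab, n_total = cc$n_total,
               s_total = adj$s_total, alpha = alpha,
               m = as.numeric(VHL_N_CODONS))
}

setMethod("show", "HotspotResult", function(object) {
  tb <- object@table
  cat(sprintf(
    "HotspotResult: %d missense observations over %d codons (alpha = %g)\n",
    as.integer(object@n_total), as.integer(object@m), object@alpha))
  sig <- tb[tb$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat(sprintf("  significant codons (p <= %.3g): %s\n",
                object@alpha / object@m,
                paste(sig$codon, collapse = ", ")))
    hs <- sig$codon[sig$highly_significant]
    if (length(hs))
      cat("  highly significant:", paste(hs, collapse = ", "), "\n")
  } else cat("  no significant codons\n")
})
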