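#' @import methods
NULL

#' VHLCohort: a curated cohort resolved into the three analysis views
#'
#' Container for a loaded, classified and filtered cohort. The three views
#' mirror the three resolutions of the analysis: one row per patient, one row
#' per family (kindred within one source), and one row per unique variant.
#' Each view is a data.frame of analysis units with a list-column
#' \code{phenotypes} (character vectors of phenotype-group codes) and the
#' variant annotation columns (\code{hgvs_c}, \code{hgvs_p},
#' \code{variant_type}, \code{codon}, \code{ref_aa}, \code{alt_aa},
#' \code{group}). Records dropped on the way in are retained in
#' \code{exclusions} with a reason code, so input records are conserved.
#'
#' @slot patients data.frame of patient-level analysis units.
#' @slot families data.frame of family-level analysis units.
#' @slot variants data.frame of unique-variant analysis units.
#' @slot exclusions data.frame ledger of dropped records (case_id, level,
#'   reason).
#'
#' @exportClass VHLCohort
setClass("VHLCohort",
  representation(
    patients   = "data.frame",
    families   = "data.frame",
    variants   = "data.frame",
    exclusions = "data.frame"
  )
)

setValidity("VHLCohort", function(object) {
  msg <- character()
  need <- c("unit_id", "phenotypes", "group")
  for (sl in c("patients", "families", "variants")) {
    df <- slot(object, sl)
    miss <- setdiff(need, names(df))
    if (length(miss))
      msg <- c(msg, sprintf("%s view lacks column(s): %s", sl,
                            paste(miss, collapse = ", ")))
    if ("phenotypes" %in% names(df) && nrow(df) &&
        any(lengths(df$phenotypes) == 0))
      msg <- c(msg, sprintf("%s view contains units with no phenotype", sl))
  }
  if (nrow(object@exclusions) &&
      !all(c("case_id", "reason") %in% names(object@exclusions)))
    msg <- c(msg, "exclusions ledger needs case_id and reason columns")
  if (length(msg)) msg else TRUE
})

#' CooccurrenceMatrix: pairwise phenotype co-occurrence
#'
#' Raw pair counts, conditional ratios, per-manifestation min-max scaled
#' ratios and low/moderate/high bands.
#'
#' @slot phenotypes character vector of analyzed phenotype groups.
#' @slot counts symmetric matrix of raw pair counts (diagonal = marginal
#'   counts).
#' @slot conditional matrix of conditional ratios r[a,b] = C[a,b]/C[a,a].
#' @slot scaled matrix of row-wise min-max scaled ratios in [0,1]
#'   (diagonal NA).
#' @slot band character matrix of bands ("low", "moderate", "high").
#' @slot degenerate character vector of phenotypes whose ratio row was
#'   constant (scaled row set to 0).
#'
#' @exportClass CooccurrenceMatrix
setClass("CooccurrenceMatrix",
  representation(
    phenotypes  = "character",
    counts      = "matrix",
    conditional = "matrix",
    scaled      = "matrix",
    band        = "matrix",
    degenerate  = "character"
  )
)

setValidity("CooccurrenceMatrix", function(object) {
  C <- object@counts
  if (!isTRUE(all.equal(C, t(C)))) return("counts matrix must be symmetric")
  r <- object@conditional
  off <- r[row(r) != col(r)]
  if (any(off < -1e-12 | off > 1 + 1e-12, na.rm = TRUE))
    return("conditional ratios must lie in [0, 1]")
  TRUE
})

#' HotspotResult: per-codon missense recurrence test
#'
#' One row per codon of the 213-residue VHL protein with the raw missense
#' count, the cumulative BLOSUM90-adjusted score, one-tailed p-values under
#' the even-distribution null, and Bonferroni-corrected significance flags.
#'
#' @slot table data.frame with columns codon, count, blosum_score, p_raw,
#'   p_blosum, significant, highly_significant, significant_blosum.
#' @slot n_total total missense observations entering the raw test.
#' @slot s_total total cumulative BLOSUM-adjusted score.
#' @slot alpha nominal family-wise significance level.
#' @slot m number of tests (213 codons).
#'
#' @exportClass HotspotResult
setClass("HotspotResult",
  representation(
    table   = "data.frame",
    n_total = "numeric",
    s_total = "numeric",
    alpha   = "numeric",
    m       = "numeric"
  )
)

setValidity("HotspotResult", function(object) {
  tb <- object@table
  if (nrow(tb) != object@m) return("table must have one row per codon")
  if (abs(sum(tb$count) - object@n_total) > 1e-9)
    return("counts must sum to n_total")
  if (any(tb$p_raw <= 0 | tb$p_raw > 1))
    return("p-values must lie in (0, 1]")
  if (any(tb$highly_significant & !tb$significant))
    return("highly significant codons must be significant")
  TRUE
})

#' ContingencyResult: a chi-square contingency analysis with post hocs
#'
#' @slot table labeled count matrix.
#' @slot expected expected counts under independence.
#' @slot statistic Pearson chi-square statistic (no continuity correction).
#' @slot df degrees of freedom, (rows-1)(cols-1).
#' @slot p.value upper-tail chi-square p-value.
#' @slot posthoc data.frame of pairwise 2xC comparisons (row pair, chi2, p,
#'   significant at alpha/m), possibly empty.
#' @slot alpha nominal significance level.
#'
#' @exportClass ContingencyResult
setClass("ContingencyResult",
  representation(
    table     = "matrix",
    expected  = "matrix",
    statistic = "numeric",
    df        = "numeric",
    p.value   = "numeric",
    posthoc   = "data.frame",
    alpha     = "numeric"
  )
)

setValidity("ContingencyResult", function(object) {
  if (any(object@table < 0)) return("cells must be non-negative")
  d <- (nrow(object@table) - 1L) * (ncol(object@table) - 1L)
  if (object@df != d) return("df must equal (rows-1)(cols-1)")
  TRUE
})

#' PenetranceCurves: onset-age empirical CDFs for isolated phenotypes
#'
#' @slot ages named list of sorted integer onset ages per phenotype.
#' @slot n named integer vector of sample sizes.
#' @slot median_age named numeric vector: first age at which the empirical
#'   CDF reaches 0.5 (NA below the inclusion threshold).
#' @slot min_n minimum sample size for a phenotype to be retained.
#' @slot dropped character vector of phenotypes dropped for small n.
#'
#' @exportClass PenetranceCurves
setClass("PenetranceCurves",
  representation(
    ages       = "list",
    n          = "integer",
    median_age = "numeric",
    min_n      = "numeric",
    dropped    = "character"
  )
)

#' KSGrid: all-pairs two-sample Kolmogorov-Smirnov tests
#'
#' @slot D symmetric matrix of KS statistics.
#' @slot p symmetric matrix of p-values.
#' @slot significant logical matrix, p <= alpha/m.
#' @slot tested logical matrix (FALSE where a sample had n < 2).
#' @slot alpha nominal level.
#' @slot m number of unordered pairs tested, k(k-1)/2.
#'
#' @exportClass KSGrid
setClass("KSGrid",
  representation(
    D           = "matrix",
    p           = "matrix",
    significant = "matrix",
    tested      = "matrix",
    alpha       = "numeric",
    m           = "numeric"
  )
)

setValidity("KSGrid", function(object) {
  if (any(object@D < -1e-12 | object@D > 1 + 1e-12, na.rm = TRUE))
    return("D must lie in [0, 1]")
  if (!isTRUE(all.equal(object@D, t(object@D))))
    return("D grid must be symmetric")
  TRUE
})

#' ClusterModel: phenotype-similarity spectral clustering of patients
#'
#' Jaccard affinity over phenotype sets, the ascending spectrum of the
#' symmetric normalized Laplacian, the two eigengap estimates of the number
#' of clusters, label assignments at each estimate, and per-cluster
#' genotype/phenotype profiles. Genotype information enters only the
#' profiles, never the clustering itself.
#'
#' @slot unit_ids character ids of the clustered patients.
#' @slot affinity symmetric Jaccard similarity matrix.
#' @slot eigenvalues ascending normalized-Laplacian spectrum.
#' @slot k_candidates two integers from the two largest eigengaps.
#' @slot labels named list of integer label vectors, one per candidate K.
#' @slot seed integer seed used for k-means.
#' @slot profiles named list (per K) of per-cluster profile lists.
#'
#' @exportClass ClusterModel
setClass("ClusterModel",
  representation(
    unit_ids     = "character",
    affinity     = "matrix",
    eigenvalues  = "numeric",
    k_candidates = "integer",
    labels       = "list",
    seed         = "integer",
    profiles     = "list"
  )
)

setValidity("ClusterModel", function(object) {
  A <- object@affinity
  if (nrow(A) && !isTRUE(all.equal(unname(diag(A)), rep(1, nrow(A)))))
    return("affinity diagonal must be 1")
  if (any(A < -1e-12 | A > 1 + 1e-12)) return("affinity must lie in [0, 1]")
  ev <- object@eigenvalues
  if (length(ev) && (min(ev) < -1e-8 || max(ev) > 2 + 1e-8))
    return("normalized-Laplacian eigenvalues must lie in [0, 2]")
  TRUE
})
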