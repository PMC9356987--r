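# Phenotype-similarity spectral clustering: Jaccard affinity over patient
# phenotype sets, symmetric normalized Laplacian, eigengap model selection
# (two candidates), Ng-Jordan-Weiss clustering, per-cluster profiling.
# Genotype information enters only the profiles, never the clustering.

#' Jaccard affinity between phenotype sets
#'
#' A[i, j] = |S_i intersect S_j| / |S_i union S_j|. Every set must be
#' non-empty (patients without any VHL-related phenotype are omitted from
#' cluster analysis upstream).
#'
#' @param phenotype_sets list of character vectors.
#' @return symmetric numeric matrix with unit diagonal.
#' @examples
#' jaccardAffinity(list(c("CHB", "RA"), "CHB", "PPGL"))
#' @export
jaccardAffinity <- function(phenotype_sets) {
  if (any(lengths(phenotype_sets) == 0L))
    stop("empty phenotype set: omit such patients before clustering")
  sets <- lapply(phenotype_sets, unique)
  phe <- sort(unique(unlist(sets)))
  M <- vapply(sets, function(s) phe %in% s, logical(length(phe)))
  M <- matrix(as.numeric(M), nrow = length(phe))
  inter <- crossprod(M)
  sizes <- colSums(M)
  un <- outer(sizes, sizes, "+") - inter
  A <- inter / un
  dimnames(A) <- NULL
  A
}

# Symmetric normalized Laplacian L = I - D^{-1/2} A D^{-1/2}
.normalized_laplacian <- function(A) {
  deg <- rowSums(A)
  if (any(deg <= 0))
    stop("isolated node (zero degree): remove it before clustering")
  dh <- 1 / sqrt(deg)
  diag(nrow(A)) - (dh * A) * rep(dh, each = nrow(A))
}

#' Eigengap estimates of the number of clusters
#'
#' Computes the ascending spectrum of the symmetric normalized Laplacian
#' and the gaps g_i = lambda_{i+1} - lambda_i for i in 2..k_max (a
#' one-cluster answer is excluded as uninformative). The indices of the two
#' largest gaps, in descending gap order with ties broken toward smaller K,
#' are the two candidate cluster counts.
#'
#' @param affinity symmetric affinity matrix (n >= 3).
#' @param k_max largest K considered (default 15).
#' @return list with \code{k1}, \code{k2} (integer candidates) and
#'   \code{spectrum} (ascending eigenvalues).
#' @export
eigengapK <- function(affinity, k_max = 15) {
  n <- nrow(affinity)
  if (n < 3) stop("eigengap estimation needs at least 3 units")
  L <- .normalized_laplacian(affinity)
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  k_max <- min(k_max, n - 1L)
  idx <- 2:k_max
  gaps <- ev[idx + 1L] - ev[idx]
  ord <- order(-gaps, idx)  # largest gap first, ties toward smaller K
  list(k1 = as.integer(idx[ord[1L]]), k2 = as.integer(idx[ord[2L]]),
       spectrum = ev)
}

#' Spectral clustering (Ng-Jordan-Weiss)
#'
#' Takes the bottom-K eigenvectors of the symmetric normalized Laplacian,
#' unit-normalizes the rows of the eigenvector matrix, and runs k-means
#' with a fixed seed and multiple restarts. Deterministic given
#' (affinity, K, seed).
#'
#' @param affinity symmetric affinity matrix.
#' @param K number of clusters, 2 <= K <= n-1.
#' @param seed integer seed for k-means.
#' @param nstart k-means restarts (default 10).
#' @return integer label vector in 1..K.
#' @export
spectralCluster <- function(affinity, K, seed = 1L, nstart = 10) {
  n <- nrow(affinity)
  if (K < 2 || K > n - 1) stop("K must lie in 2..n-1")
  L <- .normalized_laplacian(affinity)
  es <- eigen(L, symmetric = TRUE)
  U <- es$vectors[, n - seq_len(K) + 1L, drop = FALSE]  # bottom-K
  norms <- sqrt(rowSums(U^2))
  norms[norms == 0] <- 1
  U <- U / norms
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  # Lloyd iterations: stable on the heavily duplicated rows that tied
  # phenotype sets produce (Hartigan-Wong warns on them); random restarts
  # that land on an empty cluster are discarded among the nstart tries
  km <- withCallingHandlers(
    stats::kmeans(U, centers = K, nstart = nstart, iter.max = 200,
                  algorithm = "Lloyd"),
    warning = function(w) {
      if (grepl("empty cluster|Quick-TRANSfer", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  as.integer(km$cluster)
}

#' Per-cluster genotype and phenotype profiles
#'
#' For each cluster: the fraction of patients carrying each phenotype, the
#' share of each phenotype among all phenotype occurrences, truncating and
#' nontruncating counts, alpha-domain / beta-domain / neither counts, and
#' the per-codon histogram. Because only phenotype information was used in
#' clustering, any genotype trend across clusters reflects
#' genotype-phenotype structure in the data, not the algorithm.
#'
#' @param labels integer cluster labels aligned to \code{units}.
#' @param units patient-level analysis units.
#' @return named list of per-cluster profile lists (size, phenotype
#'   fractions, phenotype occurrence shares, group counts, domain counts,
#'   codon histogram).
#' @export
profileClusters <- function(labels, units) {
  stopifnot(length(labels) == nrow(units))
  phe_all <- sort(unique(unlist(units$phenotypes)))
  d <- vhlDomains()
  out <- lapply(sort(unique(labels)), function(cl) {
    sub <- units[labels == cl, , drop = FALSE]
    n <- nrow(sub)
    carrier <- vapply(phe_all, function(p)
      sum(vapply(sub$phenotypes, function(s) p %in% s, logical(1))),
      integer(1))
    occ <- table(factor(unlist(sub$phenotypes), levels = phe_all))
    grp <- table(factor(sub$group,
                        levels = c("truncating", "nontruncating",
                                   "excluded")))
    codons <- sub$codon[!is.na(sub$codon)]
    dom <- c(alpha = sum(codons %in% d$alpha),
             beta = sum(codons %in% d$beta),
             neither = sum(!codons %in% d$alpha & !codons %in% d$beta))
    list(n = n,
         phenotype_fraction = carrier / n,
         phenotype_occurrence_share =
           as.numeric(occ) / max(sum(occ), 1L),
         group_counts = c(grp),
         domain_counts = dom,
         codon_hist = tabulate(codons, nbins = VHL_N_CODONS))
  })
  names(out) <- paste0("cluster", sort(unique(labels)))
  out
}

#' Full phenotype-similarity cluster analysis of patients
#'
#' Builds the Jaccard affinity over patient phenotype sets, estimates the
#' number of clusters with the eigengap method (two candidates), clusters
#' at each candidate K, and profiles the clusters.
#'
#' @param patient_units patient-level analysis units (non-empty phenotype
#'   sets).
#' @param seed integer seed for k-means.
#' @param k_max largest K considered by the eigengap.
#' @return a \code{\linkS4class{ClusterModel}}.
#' @export
clusterAnalysis <- function(patient_units, seed = 1L, k_max = 15) {
  A <- jaccardAffinity(patient_units$phenotypes)
  eg <- eigengapK(A, k_max)
  ks <- unique(c(eg$k1, eg$k2))
  labels <- lapply(ks, function(K)
    spectralCluster(A, K, seed = seed))
  names(labels) <- paste0("K", ks)
  profiles <- lapply(labels, profileClusters, units = patient_units)
  methods::new("ClusterModel", unit_ids = patient_units$unit_id,
               affinity = A, eigenvalues = eg$spectrum,
               k_candidates = c(eg$k1, eg$k2), labels = labels,
               seed = as.integer(seed), profiles = profiles)
}

#' @describeIn ClusterModel the two eigengap candidates for K
#' @param x a \code{ClusterModel}
#' @export
kCandidates <- function(x) x@k_candidates

#' @describeIn ClusterModel label assignments (list, one per candidate K)
#' @export
clusterLabels <- function(x) x@labels

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: %d patients, eigengap K candidates = %s\n",
              length(object@unit_ids),
              paste(object@k_candidates, collapse = ", ")))
  for (nm in names(object@labels)) {
    sizes <- table(object@labels[[nm]])
    cat(sprintf("  %s cluster sizes: %s\n", nm,
                paste(sizes, collapse = ", ")))
  }
})
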