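# Jaccard affinity, normalized-Laplacian spectra, eigengap selection,
# spectral clustering and cluster profiling

test_that("Jaccard affinity matches set arithmetic", {
  A <- jaccardAffinity(list(c("CHB", "RA"), c("CHB", "RA"), "CHB",
                            "PPGL"))
  expect_equal(A[1, 2], 1)
  expect_equal(A[1, 3], 0.5)
  expect_equal(A[1, 4], 0)
  expect_equal(diag(A), rep(1, 4))
  expect_error(jaccardAffinity(list("CHB", character())), "empty")
})

test_that("affinity equals brute-force set arithmetic on random cohorts", {
  set.seed(13)
  phe <- vhlPhenotypes()
  for (rep in 1:5) {
    sets <- replicate(sample(4:15, 1),
                      sample(phe, sample(1:4, 1)), simplify = FALSE)
    A <- jaccardAffinity(sets)
    for (i in seq_along(sets)) for (j in seq_along(sets)) {
      expect_equal(A[i, j],
                   length(intersect(sets[[i]], sets[[j]])) /
                     length(union(sets[[i]], sets[[j]])))
    }
  }
})

test_that("normalized-Laplacian spectra stay in [0, 2] and the zero
          eigenvalue multiplicity counts connected components", {
  set.seed(21)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    sizes <- sample(3:10, k, replace = TRUE)
    # disjoint complete blocks: affinity 1 within, 0 across
    labels <- rep(seq_len(k), sizes)
    A <- outer(labels, labels, "==") * 1
    diag(A) <- 1
    eg <- eigengapK(A, k_max = min(12, sum(sizes) - 1))
    ev <- eg$spectrum
    expect_gte(min(ev), -1e-9)
    expect_lte(max(ev), 2 + 1e-9)
    expect_equal(sum(ev < 1e-8), k)
    if (k >= 2) expect_equal(eg$k1, k)
  }
})

test_that("block-diagonal affinities yield the component count as k1", {
  A3 <- as.matrix(Matrix::bdiag(matrix(1, 4, 4), matrix(1, 5, 5),
                                matrix(1, 3, 3)))
  eg <- eigengapK(A3)
  expect_equal(eg$k1, 3)
  A2 <- as.matrix(Matrix::bdiag(matrix(1, 4, 4), matrix(1, 4, 4)))
  expect_equal(eigengapK(A2)$k1, 2)
})

test_that("perfect two-block affinity is split exactly at K = 2", {
  sets <- c(rep(list("PPGL"), 6), rep(list(c("CHB", "RA")), 7))
  A <- jaccardAffinity(sets)
  labels <- spectralCluster(A, K = 2, seed = 4)
  truth <- rep(1:2, c(6, 7))
  expect_equal(mclust::adjustedRandIndex(labels, truth), 1)
  expect_error(spectralCluster(A, K = 1), "2..n-1")
})

test_that("labels are equivariant under permutation of input order", {
  set.seed(31)
  planted <- make_planted_sets(40, list("PPGL", "CHB", c("RA", "RCC")),
                               noise = 0)
  A <- jaccardAffinity(planted$sets)
  lab <- spectralCluster(A, 3, seed = 9)
  perm <- sample(40)
  lab_p <- spectralCluster(A[perm, perm], 3, seed = 9)
  expect_equal(mclust::adjustedRandIndex(lab[perm], lab_p), 1)
})

test_that("clustering is deterministic given affinity, K and seed", {
  set.seed(17)
  planted <- make_planted_sets(50, list("PPGL", "CHB"), noise = 0.1)
  A <- jaccardAffinity(planted$sets)
  expect_identical(spectralCluster(A, 2, seed = 3),
                   spectralCluster(A, 2, seed = 3))
})

test_that("cluster profiles summarize phenotypes and genotypes per group", {
  u <- make_units(list("PPGL", "PPGL", "CHB", "CHB"),
                  variant_type = c("missense", "missense", "stop_gained",
                                   "stop_gained"),
                  codon = c(167L, 161L, 98L, 82L),
                  ref_aa = "R", alt_aa = "W")
  labels <- c(1L, 1L, 2L, 2L)
  prof <- profileClusters(labels, u)
  expect_equal(prof$cluster1$phenotype_fraction[["PPGL"]], 1)
  expect_equal(unname(prof$cluster1$group_counts["nontruncating"]), 2L)
  expect_equal(unname(prof$cluster1$domain_counts["alpha"]), 2)
  expect_equal(unname(prof$cluster2$domain_counts["beta"]), 2)
  expect_equal(sum(prof$cluster1$codon_hist), 2)
})

test_that("end-to-end cluster analysis returns a coherent model", {
  set.seed(55)
  planted <- make_planted_sets(60, list("PPGL", c("CHB", "RA")),
                               noise = 0.05)
  u <- make_units(planted$sets, variant_type = "missense", codon = 167L,
                  ref_aa = "R", alt_aa = "W")
  cm <- clusterAnalysis(u, seed = 2)
  expect_s4_class(cm, "ClusterModel")
  expect_equal(length(cm@eigenvalues), 60)
  expect_true(2 %in% cm@k_candidates)
  lab <- cm@labels[["K2"]]
  expect_gte(mclust::adjustedRandIndex(lab, planted$truth), 0.9)
})
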