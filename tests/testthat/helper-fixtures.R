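# Shared fixtures and independent oracles. Fixtures are built in code; the
# oracles are deliberately naive (enumeration / log-space summation) and
# independent of the implementation paths they check.

# analysis-unit data.frame from a list of phenotype sets (+ optional
# variant fields)
make_units <- function(phenotype_sets, variant_type = NA_character_,
                       codon = NA_integer_, ref_aa = NA_character_,
                       alt_aa = NA_character_, group = NULL,
                       age_onset = NA_real_) {
  n <- length(phenotype_sets)
  units <- data.frame(
    unit_id = sprintf("U%03d", seq_len(n)),
    level = "patient",
    variant_type = rep_len(variant_type, n),
    codon = rep_len(as.integer(codon), n),
    ref_aa = rep_len(ref_aa, n),
    alt_aa = rep_len(alt_aa, n),
    age_onset = rep_len(age_onset, n),
    stringsAsFactors = FALSE)
  units$group <- if (is.null(group)) groupVariant(units$variant_type) else
    rep_len(group, n)
  units$phenotypes <- phenotype_sets
  units
}

# exact binomial upper tail by log-space pmf summation, no pbinom/dbinom
log_binom_tail <- function(n, c, p) {
  if (c <= 0) return(1)
  k <- c:n
  logs <- lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)
  m <- max(logs)
  exp(m) * sum(exp(logs - m))
}

# closed-form 2x2 Pearson chi-square
chi2_2x2_closed <- function(tab) {
  tab <- matrix(as.numeric(tab), 2)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  N <- a + b + c + d
  N * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# brute-force pair counting for the co-occurrence matrix
cooccur_brute <- function(sets, phenotypes) {
  k <- length(phenotypes)
  C <- matrix(0, k, k, dimnames = list(phenotypes, phenotypes))
  for (s in sets) {
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (phenotypes[a] %in% s && phenotypes[b] %in% s)
        C[a, b] <- C[a, b] + 1
    }
  }
  C
}

# brute-force two-sample KS statistic on the pooled step functions
ks_stat_brute <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(vapply(grid, function(t) mean(x <= t) - mean(y <= t),
                 numeric(1))))
}

# exact permutation p-value for the two-sample KS test (tie-free samples):
# enumerate all assignments of the pooled values to the two groups
ks_perm_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  obs <- ks_stat_brute(x, y)
  splits <- utils::combn(length(pooled), n1)
  ds <- apply(splits, 2, function(idx)
    ks_stat_brute(pooled[idx], pooled[-idx]))
  mean(ds >= obs - 1e-12)
}

# planted-cluster phenotype sets: K classes with characteristic sets, a
# noise fraction of patients have one phenotype membership flipped
make_planted_sets <- function(n, class_sets, noise = 0.1) {
  universe <- vhlPhenotypes()
  truth <- rep_len(seq_along(class_sets), n)
  sets <- lapply(truth, function(k) class_sets[[k]])
  flip <- which(stats::runif(n) < noise)
  for (i in flip) {
    p <- sample(universe, 1L)
    s <- sets[[i]]
    s <- if (p %in% s) setdiff(s, p) else union(s, p)
    if (length(s)) sets[[i]] <- s
  }
  list(sets = sets, truth = truth)
}
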