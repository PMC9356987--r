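# One-shot reproducible run over a datasheet: cohort assembly plus every
# analysis stage, with file outputs carrying the run configuration.

#' Run the full analysis pipeline
#'
#' Executes load, exclusions, aggregation, summary statistics,
#' co-occurrence, hotspot tests, contingency analyses, penetrance and
#' clustering, and (optionally) writes the results as TSV/JSON files whose
#' provenance records the configuration and seed. Deterministic given the
#' input, configuration and seed.
#'
#' @param input datasheet path or records data.frame.
#' @param outdir output directory (NULL: no files, results only).
#' @param levels analysis levels to run (subset of patient/family/variant).
#' @param alpha nominal significance level for every test family.
#' @param seed integer seed (k-means).
#' @param min_n minimum per-phenotype sample size for penetrance.
#' @param k_max largest K considered by the eigengap.
#' @param phenotypes phenotype groups to analyze.
#' @return named list: \code{cohort}, \code{summary}, and per-level
#'   \code{cooccurrence}, \code{hotspots}, \code{group_test},
#'   \code{domain_tests}; patient-level \code{penetrance}, \code{ks} and
#'   \code{clusters}.
#' @export
runAll <- function(input, outdir = NULL,
                   levels = c("patient", "family", "variant"),
                   alpha = 0.05, seed = 1L, min_n = 5, k_max = 15,
                   phenotypes = vhlPhenotypes()) {
  levels <- match.arg(levels, c("patient", "family", "variant"),
                      several.ok = TRUE)
  cohort <- buildCohort(input)
  views <- list(patient = patients(cohort), family = families(cohort),
                variant = variantUnits(cohort))[levels]
  res <- list(cohort = cohort,
              summary = cohortSummary(cohort, phenotypes),
              config = list(levels = levels, alpha = alpha, seed = seed,
                            min_n = min_n, k_max = k_max,
                            phenotypes = phenotypes))
  for (lv in levels) {
    units <- views[[lv]]
    res[[lv]] <- list(
      cooccurrence = cooccurrence(units, phenotypes),
      hotspots = tryCatch(hotspotAnalysis(units, alpha),
                          error = function(e) e$message),
      group_test = tryCatch(
        chi2Test(buildGroupTable(units, phenotypes), alpha,
                 posthoc = TRUE),
        error = function(e) e$message),
      domain_tests = tryCatch(domainTests(units, phenotypes, alpha),
                              error = function(e) e$message))
  }
  if ("patient" %in% levels) {
    ages <- suppressWarnings(isolatedOnsetAges(views$patient, min_n))
    res$patient$penetrance <- penetranceCurves(ages, min_n)
    res$patient$ks <- if (length(ages) >= 2) pairwiseKS(ages, alpha) else
      NULL
    res$patient$clusters <- if (nrow(views$patient) >= 3)
      clusterAnalysis(views$patient, seed = seed, k_max = k_max) else NULL
  }
  if (!is.null(outdir)) .write_outputs(res, outdir)
  invisible(res)
}

.write_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  header <- sprintf("# vhlgp run: %s", jsonlite::toJSON(res$config,
                                                        auto_unbox = TRUE))
  write_tsv <- function(x, file) {
    path <- file.path(outdir, file)
    writeLines(header, path)
    suppressWarnings(utils::write.table(x, path, sep = "\t",
                                        quote = FALSE, append = TRUE,
                                        col.names = NA))
    path
  }
  write_tsv(exclusions(res$cohort), "exclusions.tsv")
  for (lv in intersect(names(res), c("patient", "family", "variant"))) {
    blk <- res[[lv]]
    if (methods::is(blk$cooccurrence, "CooccurrenceMatrix")) {
      write_tsv(blk$cooccurrence@conditional,
                sprintf("cooccurrence_%s_conditional.tsv", lv))
      write_tsv(blk$cooccurrence@scaled,
                sprintf("cooccurrence_%s_scaled.tsv", lv))
      write_tsv(blk$cooccurrence@band,
                sprintf("cooccurrence_%s_band.tsv", lv))
    }
    if (methods::is(blk$hotspots, "HotspotResult"))
      write_tsv(blk$hotspots@table, sprintf("hotspots_%s.tsv", lv))
    if (methods::is(blk$group_test, "ContingencyResult")) {
      gt <- blk$group_test
      jsonlite::write_json(
        list(table = gt@table, chi2 = gt@statistic, df = gt@df,
             p = gt@p.value, posthoc = gt@posthoc),
        file.path(outdir, sprintf("group_test_%s.json", lv)),
        auto_unbox = TRUE, digits = NA)
    }
  }
  if (!is.null(res$patient$ks)) {
    write_tsv(res$patient$ks@p, "ks_p_values.tsv")
    write_tsv(res$patient$ks@D, "ks_statistics.tsv")
  }
  if (!is.null(res$patient$clusters)) {
    cm <- res$patient$clusters
    lab <- data.frame(unit_id = cm@unit_ids, check.names = FALSE)
    for (nm in names(cm@labels)) lab[[nm]] <- cm@labels[[nm]]
    write_tsv(lab, "cluster_labels.tsv")
    write_tsv(data.frame(eigenvalue = cm@eigenvalues), "spectrum.tsv")
    jsonlite::write_json(cm@profiles,
                         file.path(outdir, "cluster_profiles.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(res$summary,
                       file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}
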