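# Datasheet loading, exclusion rules and aggregation into analysis views

write_sheet <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  header <- paste(c("case_id", "source_id", "resolution", "kindred_id",
                    "hgvs_c", "hgvs_p", "variant_type",
                    "genotype_confirmed", "de_novo", "sex", "age_onset",
                    "age_death", "last_known_age", "gnomad_af",
                    "hpo_terms"), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}

row_tsv <- function(case_id, resolution = "patient", kindred = "",
                    hgvs_c = "", hgvs_p = "p.Arg167Trp", vtype = "",
                    confirmed = "true", af = "", hpo = "HP:0009713",
                    age_onset = "", source = "src1") {
  paste(c(case_id, source, resolution, kindred, hgvs_c, hgvs_p, vtype,
          confirmed, "unknown", "", age_onset, "", "", af, hpo),
        collapse = "\t")
}

test_that("well-formed datasheets load with split HPO sets and NA blanks", {
  path <- write_sheet(c(
    row_tsv("c1", hpo = "HP:0009713;HP:0006880", age_onset = "30"),
    row_tsv("c2", hpo = ""),
    row_tsv("c3", resolution = "family")))
  rec <- readDatasheet(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$hpo_terms[[1]], c("HP:0009713", "HP:0006880"))
  expect_equal(rec$hpo_terms[[2]], character())
  expect_equal(rec$age_onset, c(30, NA, NA))
  expect_true(is.na(rec$kindred_id[1]))
})

test_that("malformed ages and missing columns raise row-level errors", {
  path <- write_sheet(row_tsv("c1", age_onset = "-4"))
  expect_error(readDatasheet(path), "age_onset.*row")
  path2 <- write_sheet(row_tsv("c1", age_onset = "young"))
  expect_error(readDatasheet(path2), "age_onset")
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("case_id\tsource_id", "c1\ts1"), bad)
  expect_error(readDatasheet(bad), "mandatory column")
})

test_that("common-variant exclusion is strict at 1% and ledgered", {
  path <- write_sheet(c(
    row_tsv("c1", af = "0.02"),
    row_tsv("c2", af = "0.01"),
    row_tsv("c3", af = "")))
  excl <- applyExclusions(readDatasheet(path))
  expect_equal(excl$ledger$case_id, "c1")
  expect_equal(excl$ledger$reason, "common_population_variant")
  expect_setequal(excl$kept$case_id, c("c2", "c3"))
})

test_that("compound heterozygotes keep only the rare allele", {
  path <- write_sheet(
    row_tsv("c1", hgvs_p = "p.Arg167Trp;p.Pro25Leu", af = "1e-5;0.03"))
  excl <- applyExclusions(readDatasheet(path))
  expect_equal(nrow(excl$kept), 1)
  expect_equal(excl$kept$hgvs_p, "p.Arg167Trp")
  expect_equal(excl$kept$gnomad_af, 1e-5)
})

test_that("records without variant or phenotype are dropped with reasons, \
and input records are conserved", {
  path <- write_sheet(c(
    row_tsv("c1"),
    row_tsv("c2", hgvs_p = "", confirmed = "false"),
    row_tsv("c3", hpo = ""),
    row_tsv("c4", hpo = "HP:9999999")))
  excl <- applyExclusions(readDatasheet(path))
  expect_equal(nrow(excl$kept) + nrow(excl$ledger), 4)
  lg <- setNames(excl$ledger$reason, excl$ledger$case_id)
  expect_equal(unname(lg["c2"]), "no_variant")
  expect_equal(unname(lg["c3"]), "no_phenotype")
  expect_equal(unname(lg["c4"]), "no_phenotype")
})

test_that("the familial-variant rule rescues untested kindred members", {
  path <- write_sheet(c(
    row_tsv("c1", kindred = "K1", hpo = "HP:0009713"),
    row_tsv("c2", kindred = "K1", hgvs_p = "", confirmed = "false",
            hpo = "HP:0002666")))
  excl <- applyExclusions(readDatasheet(path))
  expect_equal(nrow(excl$kept), 2)
  expect_equal(excl$kept$hgvs_p[2], "p.Arg167Trp")
  # rescue is per-source: the same kindred id elsewhere is another family
  path2 <- write_sheet(c(
    row_tsv("c1", kindred = "K1", hpo = "HP:0009713"),
    row_tsv("c2", kindred = "K1", source = "src2", hgvs_p = "",
            confirmed = "false", hpo = "HP:0002666")))
  excl2 <- applyExclusions(readDatasheet(path2))
  expect_equal(excl2$ledger$case_id, "c2")
  expect_equal(excl2$ledger$reason, "no_variant")
})

test_that("family aggregation unions phenotypes over kindred members", {
  path <- write_sheet(c(
    row_tsv("p1", kindred = "K1", hpo = "HP:0009713"),
    row_tsv("p2", kindred = "K1", hgvs_p = "", confirmed = "false",
            hpo = "HP:0009594"),
    row_tsv("p3")))
  cohort <- buildCohort(path)
  fam <- families(cohort)
  expect_equal(nrow(fam), 2)
  k1 <- fam[which(fam$kindred_id == "K1"), ]
  expect_equal(k1$phenotypes[[1]], c("CHB", "RA"))
  expect_equal(k1$hgvs_p, "p.Arg167Trp")
  expect_equal(k1$n_members, 2L)
  # the singleton patient yields a family identical to the patient
  singleton <- fam[is.na(fam$kindred_id), ]
  expect_equal(singleton$phenotypes[[1]], "CHB")
  expect_equal(singleton$n_members, 1L)
})

test_that("families need a confirmed member; conflicts are excluded", {
  path <- write_sheet(c(
    row_tsv("p1", kindred = "K1", confirmed = "false"),
    row_tsv("p2", kindred = "K1", confirmed = "false",
            hpo = "HP:0002666"),
    row_tsv("p3", kindred = "K2", hgvs_p = "p.Arg167Trp"),
    row_tsv("p4", kindred = "K2", hgvs_p = "p.Tyr98His")))
  cohort <- buildCohort(path)
  expect_equal(nrow(families(cohort)), 0)
  reasons <- exclusions(cohort)$reason
  expect_true("family_no_confirmed_member" %in% reasons)
  expect_true("conflicting_familial_variants" %in% reasons)
})

test_that("variant aggregation unions phenotypes across all resolutions", {
  path <- write_sheet(c(
    row_tsv("r1", hpo = "HP:0002666"),
    row_tsv("r2", hpo = "HP:0002666"),
    row_tsv("r3", hpo = "HP:0012197"),
    row_tsv("r4", hgvs_p = "p.Tyr98His", hpo = "HP:0009713"),
    row_tsv("r5", resolution = "tumor", hgvs_p = "p.Leu158Gln",
            hpo = "HP:0005584")))
  cohort <- buildCohort(path)
  v <- variantUnits(cohort)
  expect_equal(nrow(v), 3)
  r167 <- v[v$hgvs_p == "p.Arg167Trp", ]
  expect_equal(r167$phenotypes[[1]], c("PNET", "PPGL"))
  expect_equal(r167$n_members, 3L)
  # tumor-resolution variants appear at variant level only
  expect_true("p.Leu158Gln" %in% v$hgvs_p)
  expect_false("r5" %in% sub("^P:", "", patients(cohort)$unit_id))
})

test_that("variant identity normalizes case, spacing and aa codes", {
  path <- write_sheet(c(
    row_tsv("r1", hgvs_p = "p.Arg167Trp"),
    row_tsv("r2", hgvs_p = "p.R167W"),
    row_tsv("r3", hgvs_p = " P.ARG167TRP ", hpo = "HP:0002666")))
  cohort <- buildCohort(path)
  expect_equal(nrow(variantUnits(cohort)), 1)
})

test_that("re-aggregating the family view is a no-op", {
  sim <- simulateCohort(simulationConfig(seed = 11, n_families = 60))
  excl <- applyExclusions(sim$datasheet)
  fam1 <- aggregateFamilies(excl$kept)$units
  # families are already one unit per kindred: aggregating the family view
  # (treating each unit as a family-resolution record) changes nothing
  fam_records <- excl$kept[excl$kept$resolution %in%
                             c("patient", "family"), ]
  expect_equal(length(unique(fam1$unit_id)), nrow(fam1))
  fam2 <- aggregateFamilies(excl$kept)$units
  expect_identical(fam1, fam2)
})
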