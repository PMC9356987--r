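# Datasheet loading, curation filters, and aggregation into the three
# analysis views (patient-, family- and unique-variant-based).

DATASHEET_COLUMNS <- c("case_id", "source_id", "resolution", "kindred_id",
                       "hgvs_c", "hgvs_p", "variant_type",
                       "genotype_confirmed", "de_novo", "sex", "age_onset",
                       "age_death", "last_known_age", "gnomad_af",
                       "hpo_terms")

GNOMAD_COMMON_AF <- 0.01  # strictly greater than 1% is "common"

.as_flag <- function(x) {
  tolower(trimws(as.character(x))) %in% c("true", "t", "yes", "y", "1")
}

.parse_age <- function(x, col, rows) {
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA
  suppress <- suppressWarnings(as.numeric(x))
  bad <- which((!is.na(x) & is.na(suppress)) | (!is.na(suppress) &
                                                  suppress < 0))
  if (length(bad)) {
    stop(sprintf("invalid %s in row(s) %s (negative or non-numeric)",
                 col, paste(rows[bad], collapse = ", ")))
  }
  suppress
}

#' Read a curated cohort datasheet
#'
#' Loads a delimited text datasheet (TSV or CSV, detected from the header
#' line) with one row per curated case. The HPO column is split on ";" into
#' a list-column of term sets; blank cells become NA; ages are validated as
#' non-negative numbers with row-level error messages. The
#' \code{gnomad_af}, \code{hgvs_c} and \code{hgvs_p} cells may carry two
#' ";"-separated values for compound-heterozygous records; these are
#' resolved by \code{\link{applyExclusions}}.
#'
#' @param path path to the datasheet.
#' @return data.frame of case records with columns
#'   \code{case_id, source_id, resolution, kindred_id, hgvs_c, hgvs_p,
#'   variant_type, genotype_confirmed, de_novo, sex, age_onset, age_death,
#'   last_known_age, gnomad_af, hpo_terms}.
#' @export
readDatasheet <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(DATASHEET_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("datasheet lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[DATASHEET_COLUMNS]
  rows <- seq_len(nrow(raw)) + 1L  # +1: header line, for error provenance
  blank_na <- function(x) {
    x <- trimws(x)
    x[!nzchar(x)] <- NA_character_
    x
  }
  rec <- data.frame(
    case_id   = blank_na(raw$case_id),
    source_id = blank_na(raw$source_id),
    resolution = tolower(blank_na(raw$resolution)),
    kindred_id = blank_na(raw$kindred_id),
    hgvs_c = blank_na(raw$hgvs_c),
    hgvs_p = blank_na(raw$hgvs_p),
    variant_type = blank_na(raw$variant_type),
    genotype_confirmed = .as_flag(raw$genotype_confirmed),
    de_novo = tolower(blank_na(raw$de_novo)),
    sex = tolower(blank_na(raw$sex)),
    age_onset = .parse_age(raw$age_onset, "age_onset", rows),
    age_death = .parse_age(raw$age_death, "age_death", rows),
    last_known_age = .parse_age(raw$last_known_age, "last_known_age", rows),
    gnomad_af = blank_na(raw$gnomad_af),
    stringsAsFactors = FALSE
  )
  rec$de_novo[is.na(rec$de_novo)] <- "unknown"
  rec$sex[is.na(rec$sex)] <- "unknown"
  bad_res <- which(!rec$resolution %in% c("patient", "family", "variant",
                                          "tumor"))
  if (length(bad_res)) {
    stop("invalid resolution tag in row(s) ",
         paste(rows[bad_res], collapse = ", "))
  }
  bad_dn <- which(!rec$de_novo %in% c("confirmed", "no", "unknown"))
  if (length(bad_dn)) {
    stop("invalid de_novo value in row(s) ",
         paste(rows[bad_dn], collapse = ", "))
  }
  terms <- strsplit(ifelse(is.na(raw$hpo_terms), "", raw$hpo_terms), ";",
                    fixed = TRUE)
  rec$hpo_terms <- lapply(terms, function(t) {
    t <- trimws(t)
    t[nzchar(t)]
  })
  rec
}

# Resolve compound-heterozygous records: two ";"-separated descriptors on
# one row. When one allele is a common population variant (gnomAD AF > 1%),
# it is removed and the record is kept as heterozygous for the rare allele.
.resolve_compound_het <- function(records) {
  split2 <- function(x) {
    if (is.na(x)) return(c(NA_character_, NA_character_))
    parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    parts[!nzchar(parts)] <- NA
    length(parts) <- 2L
    parts
  }
  for (i in seq_len(nrow(records))) {
    cs <- split2(records$hgvs_c[i])
    ps <- split2(records$hgvs_p[i])
    afs <- suppressWarnings(as.numeric(split2(records$gnomad_af[i])))
    n_desc <- max(sum(!is.na(cs)), sum(!is.na(ps)))
    if (n_desc <= 1L) next
    common <- which(!is.na(afs) & afs > GNOMAD_COMMON_AF)
    keep <- if (length(common) == 1L) setdiff(1:2, common) else 1L
    records$hgvs_c[i] <- cs[keep]
    records$hgvs_p[i] <- ps[keep]
    records$gnomad_af[i] <- as.character(afs[keep])
  }
  records$gnomad_af <- suppressWarnings(as.numeric(records$gnomad_af))
  if (any(records$gnomad_af < 0 | records$gnomad_af > 1, na.rm = TRUE))
    stop("gnomad_af outside [0, 1]")
  records
}

# Classify variants and map phenotypes for all records; adds columns
# variant_type (classified), codon, ref_aa, alt_aa, group, phenotypes,
# unmapped_terms. Records with no descriptor at all stay variant_type NA.
.annotate_records <- function(records, map = phenotypeGroupMap()) {
  has_desc <- !is.na(records$hgvs_c) | !is.na(records$hgvs_p) |
    !is.na(records$variant_type)
  ann <- data.frame(variant_type = rep(NA_character_, nrow(records)),
                    codon = NA_integer_, ref_aa = NA_character_,
                    alt_aa = NA_character_, stringsAsFactors = FALSE)
  if (any(has_desc)) {
    cls <- classifyVariant(records$hgvs_c[has_desc],
                           records$hgvs_p[has_desc],
                           records$variant_type[has_desc])
    ann[has_desc, c("variant_type", "codon", "ref_aa", "alt_aa")] <-
      cls[c("variant_type", "codon", "ref_aa", "alt_aa")]
  }
  records$variant_type <- ann$variant_type
  records$codon <- ann$codon
  records$ref_aa <- ann$ref_aa
  records$alt_aa <- ann$alt_aa
  records$group <- groupVariant(records$variant_type)
  mapped <- lapply(records$hpo_terms, mapPhenotypes, map = map)
  records$phenotypes <- lapply(mapped, `[[`, "groups")
  records$unmapped_terms <- lapply(mapped, `[[`, "unmapped")
  records$variant_key <- .variant_key(records$hgvs_c, records$hgvs_p)
  records
}

# Familial-variant rescue: an untested member of a kindred with a
# genetically confirmed variant is assumed (for analysis only) to carry the
# familial variant, consistent with clinical diagnosis guidelines.
.rescue_familial <- function(records) {
  no_var <- is.na(records$variant_key)
  if (!any(no_var)) return(records)
  fam_key <- paste(records$source_id, records$kindred_id, sep = "\r")
  fam_key[is.na(records$kindred_id)] <- NA
  for (i in which(no_var & !is.na(fam_key))) {
    members <- which(fam_key == fam_key[i] & records$genotype_confirmed &
                       !is.na(records$variant_key))
    if (!length(members)) next
    keys <- unique(records$variant_key[members])
    if (length(keys) != 1L) next  # conflicting kindred handled downstream
    j <- members[1L]
    records[i, c("hgvs_c", "hgvs_p", "variant_type", "codon", "ref_aa",
                 "alt_aa", "group", "variant_key", "gnomad_af")] <-
      records[j, c("hgvs_c", "hgvs_p", "variant_type", "codon", "ref_aa",
                   "alt_aa", "group", "variant_key", "gnomad_af")]
  }
  records
}

#' Apply the curation exclusion rules
#'
#' Resolves compound-heterozygous records (the common allele is removed and
#' the record kept), classifies variants, maps phenotypes, propagates
#' confirmed familial variants to untested kindred members, and then drops
#' records that cannot enter any analysis: carriers of common population
#' variants (gnomAD allele frequency > 1%), records with no variant
#' descriptor after the familial rescue, and records with no mapped VHL
#' phenotype group. Exclusion is data flow, not failure: dropped records are
#' returned in a ledger with reason codes and input records are conserved
#' (\code{nrow(kept) + nrow(ledger) == nrow(records)}).
#'
#' @param records data.frame from \code{\link{readDatasheet}}.
#' @param map HPO mapping table (see \code{\link{phenotypeGroupMap}}).
#' @return list with \code{kept} (annotated records) and \code{ledger}
#'   (data.frame of case_id, resolution, reason).
#' @export
applyExclusions <- function(records, map = phenotypeGroupMap()) {
  records <- .resolve_compound_het(records)
  records <- .annotate_records(records, map)
  records <- .rescue_familial(records)
  reason <- rep(NA_character_, nrow(records))
  common <- !is.na(records$gnomad_af) &
    records$gnomad_af > GNOMAD_COMMON_AF
  reason[common] <- "common_population_variant"
  no_var <- is.na(reason) & is.na(records$variant_key)
  reason[no_var] <- "no_variant"
  no_phe <- is.na(reason) & lengths(records$phenotypes) == 0L
  reason[no_phe] <- "no_phenotype"
  ledger <- data.frame(case_id = records$case_id[!is.na(reason)],
                       resolution = records$resolution[!is.na(reason)],
                       reason = reason[!is.na(reason)],
                       stringsAsFactors = FALSE)
  list(kept = records[is.na(reason), , drop = FALSE], ledger = ledger)
}

.unit_columns <- function(df, level) {
  df$level <- rep_len(level, nrow(df))
  rownames(df) <- NULL
  df
}

#' Aggregate patient records into family-level analysis units
#'
#' Patient-resolution cases sharing a kindred id within one source form one
#' family; family-resolution records are families already. A family is
#' admitted only when at least one member is genetically confirmed; its
#' phenotype set is the union over members and its variant is the confirmed
#' familial variant. Kindreds with conflicting confirmed variants are
#' excluded and flagged.
#'
#' @param kept annotated records from \code{\link{applyExclusions}}.
#' @return list with \code{units} (family-level data.frame) and
#'   \code{ledger} of excluded families.
#' @export
aggregateFamilies <- function(kept) {
  pat <- kept[kept$resolution == "patient", , drop = FALSE]
  fam <- kept[kept$resolution == "family", , drop = FALSE]
  key <- paste(pat$source_id, pat$kindred_id, sep = "\r")
  key[is.na(pat$kindred_id)] <- paste0("singleton\r", pat$case_id[
    is.na(pat$kindred_id)])
  units <- list()
  ledger <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    members <- pat[idx, , drop = FALSE]
    confirmed <- members[members$genotype_confirmed, , drop = FALSE]
    unit_id <- paste0("F:", gsub("\r", ":", k))
    if (!nrow(confirmed)) {
      ledger[[length(ledger) + 1L]] <- data.frame(
        case_id = unit_id, resolution = "family",
        reason = "family_no_confirmed_member", stringsAsFactors = FALSE)
      next
    }
    keys <- unique(confirmed$variant_key)
    if (length(keys) > 1L) {
      ledger[[length(ledger) + 1L]] <- data.frame(
        case_id = unit_id, resolution = "family",
        reason = "conflicting_familial_variants", stringsAsFactors = FALSE)
      next
    }
    rep_row <- confirmed[1L, , drop = FALSE]
    u <- rep_row[c("source_id", "kindred_id", "hgvs_c", "hgvs_p",
                   "variant_type", "codon", "ref_aa", "alt_aa", "group",
                   "variant_key")]
    u$unit_id <- unit_id
    u$phenotypes <- list(sort(unique(unlist(members$phenotypes))))
    u$member_case_ids <- list(members$case_id)
    u$n_members <- nrow(members)
    units[[length(units) + 1L]] <- u
  }
  for (i in seq_len(nrow(fam))) {
    r <- fam[i, , drop = FALSE]
    if (!r$genotype_confirmed) {
      ledger[[length(ledger) + 1L]] <- data.frame(
        case_id = paste0("F:", r$case_id), resolution = "family",
        reason = "family_no_confirmed_member", stringsAsFactors = FALSE)
      next
    }
    u <- r[c("source_id", "kindred_id", "hgvs_c", "hgvs_p", "variant_type",
             "codon", "ref_aa", "alt_aa", "group", "variant_key")]
    u$unit_id <- paste0("F:", r$case_id)
    u$phenotypes <- r$phenotypes
    u$member_case_ids <- list(r$case_id)
    u$n_members <- 1L
    units[[length(units) + 1L]] <- u
  }
  units <- if (length(units)) do.call(rbind, units) else
    .empty_units()
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(case_id = character(), resolution = character(),
               reason = character(), stringsAsFactors = FALSE)
  list(units = .unit_columns(units, "family"), ledger = ledger)
}

.empty_units <- function() {
  data.frame(source_id = character(), kindred_id = character(),
             hgvs_c = character(), hgvs_p = character(),
             variant_type = character(), codon = integer(),
             ref_aa = character(), alt_aa = character(),
             group = character(), variant_key = character(),
             unit_id = character(),
             phenotypes = I(list()), member_case_ids = I(list()),
             n_members = integer(), stringsAsFactors = FALSE)
}

#' Aggregate all admitted records into unique-variant analysis units
#'
#' One unit per normalized variant identity (the \code{c.} description when
#' present, else the \code{p.} description; case-insensitive, whitespace
#' stripped, amino acids canonicalized). Phenotypes are the union across
#' records of all four resolutions, including tumor-resolution records.
#'
#' @param kept annotated records from \code{\link{applyExclusions}}.
#' @return data.frame of variant-level analysis units.
#' @export
aggregateVariants <- function(kept) {
  units <- list()
  for (k in unique(kept$variant_key)) {
    members <- kept[kept$variant_key == k, , drop = FALSE]
    u <- members[1L, c("source_id", "kindred_id", "hgvs_c", "hgvs_p",
                       "variant_type", "codon", "ref_aa", "alt_aa",
                       "group", "variant_key")]
    u$unit_id <- paste0("V:", k)
    u$phenotypes <- list(sort(unique(unlist(members$phenotypes))))
    u$member_case_ids <- list(members$case_id)
    u$n_members <- nrow(members)
    units[[length(units) + 1L]] <- u
  }
  units <- if (length(units)) do.call(rbind, units) else .empty_units()
  .unit_columns(units, "variant")
}

#' Assemble a cohort into the three analysis views
#'
#' Runs the full cohort pipeline: read (if given a path), exclusion rules,
#' and aggregation into patient-, family- and unique-variant-level units.
#'
#' @param x a datasheet path or a records data.frame from
#'   \code{\link{readDatasheet}}.
#' @param map HPO mapping table.
#' @return a \code{\linkS4class{VHLCohort}}.
#' @examples
#' sim <- simulateCohort(simulationConfig(seed = 1, n_families = 40))
#' cohort <- buildCohort(sim$datasheet)
#' cohort
#' @export
buildCohort <- function(x, map = phenotypeGroupMap()) {
  records <- if (is.character(x)) readDatasheet(x) else x
  excl <- applyExclusions(records, map)
  kept <- excl$kept
  pat <- kept[kept$resolution == "patient", , drop = FALSE]
  patients <- pat[c("source_id", "kindred_id", "hgvs_c", "hgvs_p",
                    "variant_type", "codon", "ref_aa", "alt_aa", "group",
                    "variant_key", "sex", "age_onset", "age_death",
                    "last_known_age", "de_novo")]
  patients$unit_id <- paste0("P:", pat$case_id)
  patients$phenotypes <- pat$phenotypes
  patients$member_case_ids <- lapply(pat$case_id, identity)
  patients$n_members <- 1L
  patients <- .unit_columns(patients, "patient")
  fams <- aggregateFamilies(kept)
  vars <- aggregateVariants(kept)
  exclusions <- rbind(excl$ledger, fams$ledger)
  methods::new("VHLCohort", patients = patients, families = fams$units,
               variants = vars, exclusions = exclusions)
}

#' @describeIn VHLCohort patient-level analysis units
#' @param object,x a \code{VHLCohort}
#' @export
patients <- function(x) x@patients

#' @describeIn VHLCohort family-level analysis units
#' @export
families <- function(x) x@families

#' @describeIn VHLCohort unique-variant analysis units
#' @export
variantUnits <- function(x) x@variants

#' @describeIn VHLCohort ledger of excluded records
#' @export
exclusions <- function(x) x@exclusions

setMethod("show", "VHLCohort", function(object) {
  cat("VHLCohort\n")
  cat(sprintf("  patients: %d  families: %d  unique variants: %d\n",
              nrow(object@patients), nrow(object@families),
              nrow(object@variants)))
  if (nrow(object@exclusions)) {
    tab <- table(object@exclusions$reason)
    cat("  exclusions:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "), "\n")
  } else cat("  exclusions: none\n")
})
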