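# HGVS-lite variant classification against NM_000551.3 (VHL, 213 codons).
# Regular-grammar parsing only: p. substitutions / frameshifts / in-frame
# indels / extensions, and c. intronic, UTR and indel patterns. No
# transcript-sequence validation is attempted.

VHL_N_CODONS <- 213L

VARIANT_TYPES <- c("missense", "stop_gained", "frameshift", "deletion",
                   "exon_loss", "splice_site", "inframe_indel", "delins",
                   "synonymous", "intron", "utr", "start_lost", "stop_lost",
                   "unknown")

AA3TO1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
            Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
            Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
            Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
            Ter = "*", Sec = "U")

AA1TO3 <- stats::setNames(names(AA3TO1), unname(AA3TO1))

# accept 3-letter codes, 1-letter codes, "Ter", "*" or "X"; return 1-letter
.aa1 <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NA_character_)
  if (x %in% names(AA3TO1)) return(unname(AA3TO1[x]))
  if (x %in% c("*", "X", "Ter")) return("*")
  if (nchar(x) == 1 && toupper(x) %in% AA3TO1) return(toupper(x))
  NA_character_
}

.aa_pat <- "(?:[A-Z][a-z]{2}|[A-Z]|\\*)"

# Normalize declared variant-type strings from heterogeneous datasheets
.normalize_declared <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NA_character_)
  key <- gsub("[ _-]+", "_", tolower(trimws(x)))
  key <- sub("_variant$", "", key)
  map <- c(missense = "missense", stop_gained = "stop_gained",
           nonsense = "stop_gained", frameshift = "frameshift",
           deletion = "deletion", exon_loss = "exon_loss",
           splice_site = "splice_site", splice = "splice_site",
           inframe_indel = "inframe_indel",
           inframe_deletion = "inframe_indel",
           inframe_insertion = "inframe_indel",
           delins = "delins", synonymous = "synonymous",
           intron = "intron", intronic = "intron",
           utr = "utr", utr_region = "utr",
           start_lost = "start_lost", stop_lost = "stop_lost",
           unknown = "unknown")
  if (key %in% names(map)) unname(map[key]) else NA_character_
}

# Parse one p. description -> list(type, codon, ref, alt) or NULL
.parse_p <- function(p) {
  p <- trimws(p)
  p <- sub("^p\\.", "", p)
  p <- gsub("[()]", "", p)
  if (!nzchar(p)) return(NULL)

  # frameshift: Arg82GlyfsTer10, L89fs, Arg82fs*10
  m <- regmatches(p, regexec(sprintf("^(%s)(\\d+)(?:%s)?fs", .aa_pat, .aa_pat),
                             p, perl = TRUE))[[1]]
  if (length(m)) {
    return(list(type = "frameshift", codon = as.integer(m[3]),
                ref = .aa1(m[2]), alt = NA_character_))
  }
  # extension past the stop codon: Ter214GlnextTer17 -> stop_lost; the
  # affected residue is the stop codon itself, outside the 1..213 protein,
  # so no codon position is recorded
  if (grepl("ext", p)) {
    return(list(type = "stop_lost", codon = NA_integer_,
                ref = NA_character_, alt = NA_character_))
  }
  # delins: Cys157_Leu158delinsTrp
  if (grepl("delins", p)) {
    m <- regmatches(p, regexec(sprintf("^(%s)(\\d+)", .aa_pat), p, perl = TRUE))[[1]]
    return(list(type = "delins",
                codon = if (length(m)) as.integer(m[3]) else NA_integer_,
                ref = if (length(m)) .aa1(m[2]) else NA_character_,
                alt = NA_character_))
  }
  # in-frame deletion / duplication / insertion: Phe76del, Gly93_Gln96del
  m <- regmatches(p, regexec(
    sprintf("^(%s)(\\d+)(?:_(%s)(\\d+))?(del|dup|ins)", .aa_pat, .aa_pat),
    p, perl = TRUE))[[1]]
  if (length(m)) {
    c1 <- as.integer(m[3])
    c2 <- if (nzchar(m[5])) as.integer(m[5]) else c1
    # extended multi-codon loss is reported as a deletion proper
    type <- if (!is.na(c2) && c2 - c1 + 1L > 20L) "deletion" else
      "inframe_indel"
    return(list(type = type, codon = c1, ref = .aa1(m[2]),
                alt = NA_character_))
  }
  # synonymous written with "=": Arg167=
  m <- regmatches(p, regexec(sprintf("^(%s)(\\d+)=$", .aa_pat), p, perl = TRUE))[[1]]
  if (length(m)) {
    return(list(type = "synonymous", codon = as.integer(m[3]),
                ref = .aa1(m[2]), alt = .aa1(m[2])))
  }
  # substitution: Arg167Trp, Arg161Ter, R167W, Met1Leu
  m <- regmatches(p, regexec(sprintf("^(%s)(\\d+)(%s)$", .aa_pat, .aa_pat),
                             p, perl = TRUE))[[1]]
  if (length(m)) {
    ref <- .aa1(m[2]); alt <- .aa1(m[4]); codon <- as.integer(m[3])
    if (is.na(ref) || is.na(alt)) return(NULL)
    type <- if (identical(alt, "*")) "stop_gained"
            else if (identical(ref, alt)) "synonymous"
            else if (codon == 1L && ref == "M") "start_lost"
            else "missense"
    return(list(type = type, codon = codon, ref = ref, alt = alt))
  }
  # unknown consequence at a known residue: Met1?
  m <- regmatches(p, regexec(sprintf("^(%s)(\\d+)\\?$", .aa_pat), p, perl = TRUE))[[1]]
  if (length(m)) {
    codon <- as.integer(m[3]); ref <- .aa1(m[2])
    type <- if (codon == 1L && identical(ref, "M")) "start_lost" else
      "unknown"
    return(list(type = type, codon = codon, ref = ref,
                alt = NA_character_))
  }
  NULL
}

# Parse one c. description -> list(type, codon=NA, ref=NA, alt=NA) or NULL
.parse_c <- function(cdna) {
  cdna <- trimws(cdna)
  cdna <- sub("^c\\.", "", cdna)
  if (!nzchar(cdna)) return(NULL)
  res <- function(type) list(type = type, codon = NA_integer_,
                             ref = NA_character_, alt = NA_character_)
  if (grepl("^[-*]", cdna)) return(res("utr"))
  # intronic offsets: 340+1G>A, 341-2A>G, 463+8C>T
  m <- regmatches(cdna, regexec("^\\d+([+-])(\\d+)", cdna, perl = TRUE))[[1]]
  if (length(m)) {
    off <- as.integer(m[3])
    return(res(if (off <= 2L) "splice_site" else "intron"))
  }
  # whole-exon scale deletions spelled at c. level: 341-?_463+?del
  if (grepl("[-+]\\?", cdna) && grepl("del", cdna)) return(res("exon_loss"))
  if (grepl("delins", cdna)) {
    # frame determined by deleted vs inserted length is unknown here
    return(res("delins"))
  }
  m <- regmatches(cdna, regexec("^(\\d+)(?:_(\\d+))?(del|dup)", cdna, perl = TRUE))[[1]]
  if (length(m)) {
    p1 <- as.integer(m[2])
    p2 <- if (nzchar(m[3])) as.integer(m[3]) else p1
    len <- p2 - p1 + 1L
    if (len %% 3L != 0L) return(res("frameshift"))
    return(res(if (len > 60L) "deletion" else "inframe_indel"))
  }
  m <- regmatches(cdna, regexec("^(\\d+)_(\\d+)ins([A-Z]+)", cdna, perl = TRUE))[[1]]
  if (length(m)) {
    return(res(if (nchar(m[4]) %% 3L == 0L) "inframe_indel" else
      "frameshift"))
  }
  if (grepl("^\\d+[ACGT]>[ACGT]$", cdna)) {
    # coding substitution: consequence needs the p. description
    return(NULL)
  }
  NULL
}

#' Classify variants from HGVS descriptions
#'
#' Infers the variant type, affected codon and amino-acid change from the
#' protein-level (\code{p.}) description when parseable, falling back to
#' coding-level (\code{c.}) patterns (intronic/splice offsets, UTR prefixes,
#' indel frame arithmetic) and finally to a declared type from the
#' datasheet. The parser is deliberately a regular-grammar subset of HGVS;
#' descriptions it cannot interpret yield \code{variant_type = "unknown"}
#' rather than an error, unless a declared type rescues them.
#'
#' @param hgvs_c character vector of \code{c.} descriptions (NA allowed).
#' @param hgvs_p character vector of \code{p.} descriptions (NA allowed).
#' @param declared_type character vector of datasheet-declared types
#'   (NA allowed); used as a fallback and cross-check.
#'
#' @return data.frame with columns \code{hgvs_c}, \code{hgvs_p},
#'   \code{variant_type}, \code{codon}, \code{ref_aa}, \code{alt_aa}.
#'   Missense rows always carry codon, ref and alt amino acids.
#'
#' @examples
#' classifyVariant(hgvs_p = "p.Arg167Trp")
#' classifyVariant(hgvs_c = "c.340+1G>A")
#' @export
classifyVariant <- function(hgvs_c = NA_character_, hgvs_p = NA_character_,
                            declared_type = NA_character_) {
  n <- max(length(hgvs_c), length(hgvs_p), length(declared_type))
  hgvs_c <- rep_len(as.character(hgvs_c), n)
  hgvs_p <- rep_len(as.character(hgvs_p), n)
  declared_type <- rep_len(as.character(declared_type), n)
  out <- data.frame(hgvs_c = hgvs_c, hgvs_p = hgvs_p,
                    variant_type = "unknown", codon = NA_integer_,
                    ref_aa = NA_character_, alt_aa = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pc <- hgvs_c[i]; pp <- hgvs_p[i]; dt <- .normalize_declared(
      declared_type[i])
    has_p <- !is.na(pp) && nzchar(trimws(pp))
    has_c <- !is.na(pc) && nzchar(trimws(pc))
    if (!has_p && !has_c && is.na(dt)) {
      stop(sprintf(
        "row %d: no variant descriptor (hgvs_c, hgvs_p or declared type)",
        i))
    }
    ann <- NULL
    if (has_p) ann <- .parse_p(pp)
    if (is.null(ann) && has_c) ann <- .parse_c(pc)
    if (is.null(ann)) {
      ann <- list(type = if (!is.na(dt)) dt else "unknown",
                  codon = NA_integer_, ref = NA_character_,
                  alt = NA_character_)
    } else if (!is.na(dt) && dt != ann$type &&
               # declared whole-gene/exon deletions outrank a c.-level guess
               dt %in% c("exon_loss", "deletion") &&
               ann$type %in% c("deletion", "exon_loss", "inframe_indel")) {
      ann$type <- dt
    }
    if (!is.na(ann$codon) && (ann$codon < 1L || ann$codon > VHL_N_CODONS)) {
      stop(sprintf("row %d (%s): codon %d outside 1..%d", i,
                   if (has_p) pp else pc, ann$codon, VHL_N_CODONS))
    }
    out$variant_type[i] <- ann$type
    out$codon[i] <- ann$codon
    out$ref_aa[i] <- ann$ref
    out$alt_aa[i] <- ann$alt
  }
  stopifnot(all(out$variant_type %in% VARIANT_TYPES))
  out
}

#' Group variant types into truncating / nontruncating / excluded
#'
#' Truncating: stop-gained, frameshift, deletion, exon loss, splice site and
#' start-lost variants. Nontruncating: missense, in-frame indels, in-frame
#' delins and stop-lost. Synonymous, UTR, intronic and unparseable variants
#' are excluded from the grouping.
#'
#' @param variant_type character vector of variant types (see
#'   \code{\link{classifyVariant}}).
#' @return character vector in \code{c("truncating", "nontruncating",
#'   "excluded")}.
#' @examples
#' groupVariant(c("stop_gained", "missense", "synonymous"))
#' @export
groupVariant <- function(variant_type) {
  bad <- setdiff(unique(variant_type), c(VARIANT_TYPES, NA))
  if (length(bad))
    stop("unknown variant type(s): ", paste(bad, collapse = ", "))
  truncating <- c("stop_gained", "frameshift", "deletion", "exon_loss",
                  "splice_site", "start_lost")
  nontrunc <- c("missense", "inframe_indel", "delins", "stop_lost")
  out <- rep("excluded", length(variant_type))
  out[variant_type %in% truncating] <- "truncating"
  out[variant_type %in% nontrunc] <- "nontruncating"
  out[is.na(variant_type)] <- NA_character_
  out
}

# Normalized identity key for a variant: prefer c., else p.; lower-case,
# whitespace stripped, 3-letter amino acids canonicalized to 1-letter.
.variant_key <- function(hgvs_c, hgvs_p) {
  norm <- function(x) {
    x <- gsub("\\s+", "", x)
    for (a in names(AA3TO1))
      x <- gsub(a, AA3TO1[a], x, ignore.case = TRUE)
    tolower(x)
  }
  key <- ifelse(!is.na(hgvs_c) & nzchar(hgvs_c), norm(hgvs_c),
                ifelse(!is.na(hgvs_p) & nzchar(hgvs_p), norm(hgvs_p),
                       NA_character_))
  key
}
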