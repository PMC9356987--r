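# Phenotype-group mapping and VHL protein domain annotation.

#' The seven phenotype groups entering the correlation analyses
#'
#' CNS hemangioblastoma (CHB), retinal angioma (RA),
#' pheochromocytoma/paraganglioma (PPGL), renal cell carcinoma (RCC),
#' pancreatic neuroendocrine tumor (PNET), pancreatic cysts or tumors (PCT)
#' and renal cysts or tumors (RCT). Rarer groups (ELST, epididymal and
#' ovarian cysts/tumors) are mapped and carried but not analyzed by default.
#'
#' @return character vector of group codes.
#' @export
vhlPhenotypes <- function() {
  c("PNET", "PPGL", "CHB", "RA", "RCC", "RCT", "PCT")
}

#' Bundled HPO term to phenotype-group mapping
#'
#' Reads the versioned seed mapping shipped with the package (a two-column
#' TSV plus a human-readable label). Each HPO id belongs to exactly one
#' group. Users can pass an extended table to the mapping functions.
#'
#' @param path path to a mapping TSV (default: the bundled table).
#' @return data.frame with columns \code{hpo_id}, \code{group},
#'   \code{label}.
#' @export
phenotypeGroupMap <- function(path = system.file("extdata",
                                                 "hpo_phenotype_groups.tsv",
                                                 package = "vhlgp")) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  stopifnot(all(c("hpo_id", "group") %in% names(map)))
  if (anyDuplicated(map$hpo_id))
    stop("mapping table assigns an HPO id to more than one group")
  map
}

#' Map HPO terms to VHL phenotype groups
#'
#' Collapses a set of HPO identifiers onto the combined phenotype groups.
#' Unrecognized terms are returned separately, never silently dropped; the
#' result is a set (duplicates collapse, order is irrelevant).
#'
#' @param hpo_terms character vector of HPO ids (possibly empty).
#' @param map mapping table from \code{\link{phenotypeGroupMap}}.
#' @return list with \code{groups} (sorted character vector of group codes)
#'   and \code{unmapped} (sorted character vector of unrecognized ids).
#' @examples
#' mapPhenotypes(c("HP:0009713", "HP:0006880"))
#' @export
mapPhenotypes <- function(hpo_terms, map = phenotypeGroupMap()) {
  hpo_terms <- unique(hpo_terms[!is.na(hpo_terms) & nzchar(hpo_terms)])
  hit <- match(hpo_terms, map$hpo_id)
  list(groups = sort(unique(map$group[hit[!is.na(hit)]])),
       unmapped = sort(hpo_terms[is.na(hit)]))
}

#' Structural and functional regions of the VHL protein
#'
#' Inclusive codon intervals and sets: the alpha-domain (156-204), the
#' beta-domain (63-143), the HIF-alpha binding site, the Elongin B/C binding
#' site (codon 79 belongs to both functional sites) and the (GXEEX)8 tandem
#' repeat (14-53).
#'
#' @return named list of integer codon vectors: \code{alpha}, \code{beta},
#'   \code{hif}, \code{elongin}, \code{gxeex}.
#' @export
vhlDomains <- function() {
  list(alpha   = 156:204,
       beta    = 63:143,
       hif     = c(67L, 69L, 75L, 77L, 78L, 79L, 88L, 91L, 98L, 99L,
                   105:112, 115L, 117L),
       elongin = c(79L, 153L, 159L, 161L, 162L, 163L, 165L, 166L, 174L,
                   177L, 178L, 184L),
       gxeex   = 14:53)
}

#' Annotate codons with domain membership
#'
#' @param codon integer vector of codon positions in 1..213.
#' @return data.frame of logical flags \code{in_alpha}, \code{in_beta},
#'   \code{in_hif}, \code{in_elongin}, \code{in_repeat}. All five flags may
#'   be FALSE for codons outside every region.
#' @examples
#' annotateDomains(c(167, 79, 30))
#' @export
annotateDomains <- function(codon) {
  codon <- as.integer(codon)
  if (any(is.na(codon) | codon < 1L | codon > VHL_N_CODONS))
    stop("codon positions must lie in 1..", VHL_N_CODONS)
  d <- vhlDomains()
  data.frame(codon = codon,
             in_alpha   = codon %in% d$alpha,
             in_beta    = codon %in% d$beta,
             in_hif     = codon %in% d$hif,
             in_elongin = codon %in% d$elongin,
             in_repeat  = codon %in% d$gxeex)
}
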