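# Pairwise phenotype co-occurrence ratios, scaled per manifestation.

#' Phenotype co-occurrence matrix
#'
#' Counts, for every ordered pair of phenotypes (a, b), the number of units
#' carrying both, and expresses it as the conditional ratio
#' r[a,b] = C[a,b] / C[a,a] (the fraction of a-units that also carry b).
#' Each row of r (the diagonal excluded) is then min-max scaled to [0, 1]
#' per manifestation, and banded: low [0, 0.33], moderate (0.33, 0.66],
#' high (0.66, 1]. A row with constant off-diagonal ratios cannot be
#' scaled; its scaled row is set to 0 and the phenotype flagged degenerate.
#'
#' @param units analysis-unit data.frame (any level) with a non-empty
#'   \code{phenotypes} list-column.
#' @param phenotypes phenotype groups to analyze; groups with zero units
#'   are dropped with a warning.
#' @return a \code{\linkS4class{CooccurrenceMatrix}}.
#' @examples
#' units <- data.frame(unit_id = as.character(1:4))
#' units$phenotypes <- list(c("CHB", "RA"), "CHB", c("CHB", "RCC"),
#'                          c("CHB", "RCC"))
#' cooccurrence(units, phenotypes = c("CHB", "RA", "RCC"))
#' @export
cooccurrence <- function(units, phenotypes = vhlPhenotypes()) {
  sets <- units$phenotypes
  if (any(lengths(sets) == 0L))
    stop("co-occurrence requires units with non-empty phenotype sets")
  member <- vapply(phenotypes, function(p)
    vapply(sets, function(s) p %in% s, logical(1)),
    logical(length(sets)))
  member <- matrix(member, nrow = length(sets),
                   dimnames = list(NULL, phenotypes))
  empty <- colSums(member) == 0L
  if (any(empty)) {
    warning("dropping phenotype(s) with zero units: ",
            paste(phenotypes[empty], collapse = ", "))
    phenotypes <- phenotypes[!empty]
    member <- member[, !empty, drop = FALSE]
  }
  C <- crossprod(member)  # C[a,b] = units with both; diagonal = marginals
  storage.mode(C) <- "double"
  r <- C / diag(C)
  s <- matrix(NA_real_, nrow(C), ncol(C), dimnames = dimnames(C))
  band <- matrix(NA_character_, nrow(C), ncol(C), dimnames = dimnames(C))
  degenerate <- character()
  for (a in seq_len(nrow(r))) {
    off <- setdiff(seq_len(ncol(r)), a)
    row <- r[a, off]
    if (length(row) == 0L) next
    rng <- range(row)
    if (diff(rng) < .Machine$double.eps) {
      s[a, off] <- 0
      degenerate <- c(degenerate, phenotypes[a])
    } else {
      s[a, off] <- (row - rng[1]) / diff(rng)
    }
    band[a, off] <- as.character(cut(s[a, off],
                                     breaks = c(-Inf, 0.33, 0.66, Inf),
                                     labels = c("low", "moderate", "high")))
  }
  methods::new("CooccurrenceMatrix", phenotypes = phenotypes, counts = C,
               conditional = r, scaled = s, band = band,
               degenerate = degenerate)
}

setMethod("show", "CooccurrenceMatrix", function(object) {
  cat(sprintf("CooccurrenceMatrix over %d phenotypes (%s)\n",
              length(object@phenotypes),
              paste(object@phenotypes, collapse = ", ")))
  cat("scaled ratios (rows = manifestation):\n")
  print(round(object@scaled, 2))
  if (length(object@degenerate))
    cat("degenerate rows (constant ratios, scaled to 0):",
        paste(object@degenerate, collapse = ", "), "\n")
})
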