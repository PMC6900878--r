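#' The standard genetic code with degeneracy and optimal-codon annotation
#'
#' Builds the lookup structure used throughout the package: the standard
#' genetic code (via [Biostrings::GENETIC_CODE]), the degeneracy of each
#' amino acid (how many sense codons encode it), and a configurable set of
#' "optimal" codons — the preferentially used synonymous codon(s) per amino
#' acid, whose loss through a synonymous change can lower translation
#' efficiency.
#'
#' The default optimal set is the highest-frequency human codon per amino
#' acid, with the top two codons for leucine and serine; under this set
#' arginine has exactly one optimal codon while leucine and serine have two.
#' Supply `optimal` (a data frame with columns `aa`, `codon`, or a path to
#' such a TSV) to use a different assignment; every codon must encode its
#' stated amino acid under the standard code.
#'
#' @param optimal `NULL` for the packaged default, a data frame with columns
#'   `aa` (one-letter amino acid) and `codon`, or the path to a tab-separated
#'   file with those columns.
#'
#' @return An object of class `codon_table`: a list with elements
#'   `code` (named character, codon -> amino acid, `"*"` for stop),
#'   `degeneracy` (named integer, amino acid -> number of sense codons) and
#'   `optimal` (character vector of optimal codons).
#' @examples
#' tab <- codon_table()
#' tab$degeneracy[c("L", "M", "R")]
#' @export
codon_table <- function(optimal = NULL) {
  code <- Biostrings::GENETIC_CODE
  sense <- code[code != "*"]
  degeneracy <- vapply(split(names(sense), sense), length, integer(1))

  if (is.null(optimal)) {
    optimal <- system.file("extdata", "optimal_codons.tsv",
                           package = "synsig", mustWork = TRUE)
  }
  if (is.character(optimal) && length(optimal) == 1) {
    optimal <- readr::read_tsv(optimal, col_types = readr::cols(.default = "c"),
                               progress = FALSE)
  }
  stopifnot(is.data.frame(optimal), all(c("aa", "codon") %in% names(optimal)))
  opt <- toupper(optimal$codon)
  bad <- opt[is.na(code[opt]) | code[opt] != optimal$aa]
  if (length(bad) > 0) {
    stop("optimal codons not encoding their stated amino acid: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(opt)) stop("duplicated optimal codons", call. = FALSE)

  structure(
    list(code = code, degeneracy = degeneracy, optimal = unname(opt)),
    class = "codon_table"
  )
}

#' @export
print.codon_table <- function(x, ...) {
  cat("<codon_table> standard genetic code;",
      length(x$code[x$code != "*"]), "sense codons,",
      length(x$optimal), "optimal codons\n")
  invisible(x)
}

#' Translate codons under the standard genetic code
#'
#' @param codon Character vector of 3-mers over `{A,C,G,T}`.
#' @param table A [codon_table()].
#' @return One-letter amino acids; `"*"` for stop codons.
#' @examples
#' translate_codon(c("CTT", "ATG", "TAA"))
#' @export
translate_codon <- function(codon, table = codon_table()) {
  codon <- toupper(codon)
  aa <- unname(table$code[codon])
  if (anyNA(aa)) {
    stop("not a codon over {A,C,G,T}: ",
         paste(unique(codon[is.na(aa)]), collapse = ", "), call. = FALSE)
  }
  aa
}

#' Classify the optimal-codon status of a synonymous codon change
#'
#' For a synonymous pair of codons, reports whether the change preserves,
#' gains or loses membership of the optimal-codon set — the transitions that
#' matter for translation efficiency.
#'
#' @param ref_codon,alt_codon Character vectors of synonymous codon pairs.
#' @param table A [codon_table()].
#' @return Character vector over
#'   `{"opt->opt", "opt->nonopt", "nonopt->opt", "nonopt->nonopt"}`.
#' @export
optimal_change <- function(ref_codon, alt_codon, table = codon_table()) {
  ref_codon <- toupper(ref_codon)
  alt_codon <- toupper(alt_codon)
  aa_ref <- translate_codon(ref_codon, table)
  aa_alt <- translate_codon(alt_codon, table)
  bad <- aa_ref != aa_alt | aa_ref == "*"
  if (any(bad)) {
    stop("optimal_change() requires synonymous sense codon pairs; offending: ",
         paste(unique(paste0(ref_codon[bad], "/", alt_codon[bad])),
               collapse = ", "), call. = FALSE)
  }
  r <- ifelse(ref_codon %in% table$optimal, "opt", "nonopt")
  a <- ifelse(alt_codon %in% table$optimal, "opt", "nonopt")
  paste0(r, "->", a)
}
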