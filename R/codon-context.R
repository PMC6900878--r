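BASES <- c("A", "C", "G", "T")

#' The 12 ordered single-base substitution patterns
#' @return Character vector `"A>C"`, `"A>G"`, ... in lexicographic order.
#' @export
substitution_patterns <- function() {
  grid <- expand.grid(ref = BASES, alt = BASES, stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  sort(paste0(grid$ref, ">", grid$alt))
}

#' The six sequence-context mutation subtypes
#'
#' A:T-reference transitions/transversions (`ATts`, `ATtv`) and
#' G:C-reference transitions/transversions split by CpG dinucleotide context
#' (`C_GCts`, `C_GCtv` within CpG; `NC_GCts`, `NC_GCtv` outside).
#' @return Character vector of the six subtype labels.
#' @export
context_subtypes <- function() {
  c("ATts", "ATtv", "C_GCts", "C_GCtv", "NC_GCts", "NC_GCtv")
}

check_bases <- function(x, what) {
  bad <- !(x %in% BASES)
  if (any(bad)) {
    stop(what, " must be one of A, C, G, T; got: ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
}

#' Classify a substitution as transition or transversion
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine exchanges
#' (A<->G, C<->T); the other eight ordered substitutions are transversions.
#'
#' @param ref,alt Reference and alternate base vectors over `{A,C,G,T}`.
#' @return Logical vector, `TRUE` for transitions.
#' @export
is_transition <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  check_bases(ref, "ref"); check_bases(alt, "alt")
  if (any(ref == alt)) stop("ref == alt is not a substitution", call. = FALSE)
  purine <- function(b) b %in% c("A", "G")
  purine(ref) == purine(alt)
}

#' Name the ordered substitution pattern of a base change
#'
#' @inheritParams is_transition
#' @return Character vector of patterns such as `"C>T"` (one of 12).
#' @examples
#' classify_pattern("C", "T")
#' @export
classify_pattern <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  check_bases(ref, "ref"); check_bases(alt, "alt")
  if (any(ref == alt)) stop("ref == alt is not a substitution", call. = FALSE)
  paste0(ref, ">", alt)
}

#' Is a C or G site in CpG dinucleotide context?
#'
#' A site is in CpG context when its reference base is C followed by G, or G
#' preceded by C, on the coding sequence. A missing neighbour at a sequence
#' end counts as non-CpG on that side. CpG status is undefined for A/T sites
#' and asking for one is an error.
#'
#' @param cds A single coding sequence string.
#' @param pos 1-based positions within `cds`.
#' @return Logical vector.
#' @export
is_cpg_site <- function(cds, pos) {
  cds <- toupper(cds)
  stopifnot(length(cds) == 1)
  len <- nchar(cds)
  if (any(pos < 1 | pos > len)) stop("position outside the CDS", call. = FALSE)
  base <- stringr::str_sub(cds, pos, pos)
  if (any(base %in% c("A", "T"))) {
    stop("CpG context is undefined for A/T reference sites", call. = FALSE)
  }
  nxt <- ifelse(pos < len, stringr::str_sub(cds, pos + 1, pos + 1), "")
  prv <- ifelse(pos > 1, stringr::str_sub(cds, pos - 1, pos - 1), "")
  (base == "C" & nxt == "G") | (base == "G" & prv == "C")
}

#' Assign a substitution to one of the six sequence-context subtypes
#'
#' A/T-reference changes split by transition status only (`cpg` must be `NA`
#' for them); C/G-reference changes additionally split by CpG dinucleotide
#' context, which must be supplied.
#'
#' @inheritParams is_transition
#' @param cpg Logical vector: CpG context for C/G reference sites, `NA` for
#'   A/T sites.
#' @return Character vector over [context_subtypes()].
#' @examples
#' classify_subtype("C", "T", cpg = FALSE) # "NC_GCts"
#' classify_subtype("A", "G", cpg = NA)    # "ATts"
#' @export
classify_subtype <- function(ref, alt, cpg = NA) {
  ref <- toupper(ref); alt <- toupper(alt)
  ts <- is_transition(ref, alt)
  n <- length(ref)
  cpg <- rep_len(cpg, n)
  at_ref <- ref %in% c("A", "T")
  if (any(at_ref & !is.na(cpg))) {
    stop("cpg must not be supplied for A/T reference bases", call. = FALSE)
  }
  if (any(!at_ref & is.na(cpg))) {
    stop("cpg is required for C/G reference bases", call. = FALSE)
  }
  ifelse(at_ref,
         ifelse(ts, "ATts", "ATtv"),
         paste0(ifelse(cpg, "C_", "NC_"), ifelse(ts, "GCts", "GCtv")))
}

#' Annotate mutation records with codon, context and synonymy information
#'
#' Joins each single-nucleotide variant to its gene's coding sequence and
#' derives: the amino-acid position (`codon_index`), position within the
#' codon (`codon_pos`), reference and alternate codons, the encoded amino
#' acid, whether the change is synonymous, the ordered substitution
#' `pattern`, CpG dinucleotide context (`cpg`, `NA` for A/T sites), the
#' sequence-context `subtype`, and for synonymous sense changes the
#' optimal-codon transition class (`optimal_change`).
#'
#' The reference base of every record must match the CDS; a mismatch or a
#' position beyond the CDS is an error naming the offending site. CpG
#' context is evaluated on the reference CDS only.
#'
#' @param muts A data frame of mutation records with columns `sample_id`,
#'   `cancer_type`, `gene_id`, `cds_pos`, `ref`, `alt` (see
#'   [read_mutation_table()]).
#' @param genes A gene table with columns `gene_id`, `cds` (see
#'   [read_cds_fasta()]).
#' @param table A [codon_table()].
#' @return A tibble: the input columns plus `codon_index`, `codon_pos`,
#'   `ref_codon`, `alt_codon`, `aa`, `synonymous`, `pattern`, `cpg`,
#'   `subtype`, `optimal_change`.
#' @export
annotate_mutations <- function(muts, genes, table = codon_table()) {
  stopifnot(is.data.frame(muts), is.data.frame(genes))
  absent <- setdiff(unique(muts$gene_id), genes$gene_id)
  if (length(absent) > 0) {
    stop("genes in the mutation table but not in the gene set: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  x <- dplyr::left_join(
    tibble::as_tibble(muts),
    dplyr::select(genes, "gene_id", "cds"),
    by = "gene_id"
  )
  x$ref <- toupper(x$ref)
  x$alt <- toupper(x$alt)
  len <- nchar(x$cds)
  beyond <- which(x$cds_pos < 1 | x$cds_pos > len)
  if (length(beyond) > 0) {
    stop("cds_pos outside the CDS at: ",
         paste(paste0(x$gene_id[beyond], ":", x$cds_pos[beyond]),
               collapse = ", "), call. = FALSE)
  }
  cds_ref <- stringr::str_sub(x$cds, x$cds_pos, x$cds_pos)
  mismatch <- which(cds_ref != x$ref)
  if (length(mismatch) > 0) {
    stop("reference base does not match the CDS at: ",
         paste(head(paste0(x$gene_id[mismatch], ":", x$cds_pos[mismatch],
                           " (CDS has ", cds_ref[mismatch], ", record has ",
                           x$ref[mismatch], ")"), 5), collapse = ", "),
         call. = FALSE)
  }

  codon_index <- (x$cds_pos - 1) %/% 3 + 1
  codon_pos <- (x$cds_pos - 1) %% 3 + 1
  start <- (codon_index - 1) * 3 + 1
  ref_codon <- stringr::str_sub(x$cds, start, start + 2)
  alt_codon <- ref_codon
  stringr::str_sub(alt_codon, codon_pos, codon_pos) <- x$alt

  aa_ref <- translate_codon(ref_codon, table)
  aa_alt <- translate_codon(alt_codon, table)
  synonymous <- aa_ref == aa_alt

  nxt <- ifelse(x$cds_pos < len,
                stringr::str_sub(x$cds, x$cds_pos + 1, x$cds_pos + 1), "")
  prv <- ifelse(x$cds_pos > 1,
                stringr::str_sub(x$cds, x$cds_pos - 1, x$cds_pos - 1), "")
  cpg <- ifelse(x$ref %in% c("C", "G"),
                (x$ref == "C" & nxt == "G") | (x$ref == "G" & prv == "C"),
                NA)

  opt <- rep(NA_character_, nrow(x))
  idx <- which(synonymous & aa_ref != "*")
  if (length(idx) > 0) {
    opt[idx] <- optimal_change(ref_codon[idx], alt_codon[idx], table)
  }

  out <- dplyr::mutate(
    dplyr::select(x, -"cds"),
    codon_index = codon_index,
    codon_pos = codon_pos,
    ref_codon = ref_codon,
    alt_codon = alt_codon,
    aa = aa_ref,
    synonymous = synonymous,
    pattern = classify_pattern(x$ref, x$alt),
    cpg = cpg,
    subtype = classify_subtype(x$ref, x$alt, cpg),
    optimal_change = opt
  )
  out
}

#' Keep synonymous sense-codon mutations only
#'
#' Drops non-synonymous records and synonymous changes between stop codons
#' (the analyses are defined on amino acids only), reporting the counts.
#'
#' @param ann Output of [annotate_mutations()].
#' @param strict Error instead of dropping when non-synonymous rows are
#'   present.
#' @return Filtered tibble.
#' @export
filter_synonymous <- function(ann, strict = FALSE) {
  n_in <- nrow(ann)
  nonsyn <- sum(!ann$synonymous)
  if (strict && nonsyn > 0) {
    stop(nonsyn, " non-synonymous record(s) in a synonymous-only analysis",
         call. = FALSE)
  }
  out <- dplyr::filter(ann, .data$synonymous, .data$aa != "*")
  message("filter_synonymous: ", n_in, " in, ", nrow(out), " kept (",
          nonsyn, " non-synonymous, ", n_in - nonsyn - nrow(out),
          " stop-codon) dropped")
  out
}
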