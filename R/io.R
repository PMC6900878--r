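#' Column mapping for mutation-table dialects
#'
#' Catalog exports name their columns differently; a dialect maps the
#' column names found in a file's header onto the fields the package uses.
#' The defaults match the tables this package writes.
#'
#' @param sample,cancer_type,gene,cds_pos,ref,alt Header names of the
#'   required columns.
#' @param pathogenic Optional header name of a logical per-mutation
#'   pathogenicity-label column.
#' @return A named list of class `mutation_dialect`.
#' @export
mutation_dialect <- function(sample = "sample", cancer_type = "cancer_type",
                             gene = "gene", cds_pos = "cds_pos",
                             ref = "ref", alt = "alt", pathogenic = NULL) {
  structure(list(sample = sample, cancer_type = cancer_type, gene = gene,
                 cds_pos = cds_pos, ref = ref, alt = alt,
                 pathogenic = pathogenic),
            class = "mutation_dialect")
}

read_tsv_chr <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  na = c("", "."), progress = FALSE)
}

stop_rows <- function(rows, msg) {
  # header occupies line 1, so data row i is file line i + 1
  stop(msg, " at line(s): ", paste(head(rows + 1, 5), collapse = ", "),
       if (length(rows) > 5) " ..." else "", call. = FALSE)
}

#' Read a mutation catalog
#'
#' Reads a tab-separated mutation table (one single-nucleotide variant per
#' row; header row required) into the package's record layout. Columns are
#' located by name through a [mutation_dialect()]; extra columns are
#' dropped. Row order and duplicate rows are preserved — recurrence of the
#' same change in several samples is exactly the signal the hotspot test
#' uses. Malformed rows are hard errors naming the file line.
#'
#' @param path File path.
#' @param dialect A [mutation_dialect()].
#' @return A tibble with columns `sample_id`, `cancer_type`, `gene_id`,
#'   `cds_pos` (1-based position in the coding sequence), `ref`, `alt`,
#'   and `pathogenic` if the dialect names a label column.
#' @export
read_mutation_table <- function(path, dialect = mutation_dialect()) {
  raw <- read_tsv_chr(path)
  need <- unlist(dialect[c("sample", "cancer_type", "gene", "cds_pos",
                           "ref", "alt")])
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = raw[[dialect$sample]],
    cancer_type = raw[[dialect$cancer_type]],
    gene_id = raw[[dialect$gene]],
    cds_pos = suppressWarnings(as.integer(raw[[dialect$cds_pos]])),
    ref = toupper(raw[[dialect$ref]]),
    alt = toupper(raw[[dialect$alt]])
  )
  bad <- which(is.na(out$cds_pos) | out$cds_pos < 1)
  if (length(bad) > 0) stop_rows(bad, "non-integer or non-positive cds_pos")
  bad <- which(!(out$ref %in% BASES) | !(out$alt %in% BASES))
  if (length(bad) > 0) stop_rows(bad, "malformed ref/alt base")
  bad <- which(out$ref == out$alt)
  if (length(bad) > 0) stop_rows(bad, "ref equals alt")
  bad <- which(is.na(out$sample_id) | is.na(out$gene_id) |
                 is.na(out$cancer_type))
  if (length(bad) > 0) stop_rows(bad, "missing sample/cancer_type/gene")
  if (!is.null(dialect$pathogenic)) {
    if (!dialect$pathogenic %in% names(raw)) {
      stop("missing pathogenicity column ", dialect$pathogenic, call. = FALSE)
    }
    out$pathogenic <- as.logical(raw[[dialect$pathogenic]])
  }
  out
}

#' Write a mutation table in the package's TSV dialect
#' @param muts Tibble as returned by [read_mutation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(muts, path) {
  out <- tibble::tibble(sample = muts$sample_id,
                        cancer_type = muts$cancer_type,
                        gene = muts$gene_id, cds_pos = muts$cds_pos,
                        ref = muts$ref, alt = muts$alt)
  if ("pathogenic" %in% names(muts)) out$pathogenic <- muts$pathogenic
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read coding sequences from FASTA
#'
#' The FASTA header token up to the first whitespace is the gene id.
#' Sequences are uppercased and validated as clean coding sequences: length
#' a positive multiple of 3, no internal stop codon (a trailing stop codon
#' is permitted), bases over `{A,C,G,T}`, no duplicate ids.
#'
#' @param path FASTA file path.
#' @return A tibble with columns `gene_id`, `cds`, `protein_length`
#'   (`nchar(cds)/3`).
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  cds <- toupper(as.character(seqs))
  validate_gene_table(tibble::tibble(gene_id = ids, cds = unname(cds)))
}

validate_gene_table <- function(genes) {
  len <- nchar(genes$cds)
  bad <- which(len == 0 | len %% 3 != 0)
  if (length(bad) > 0) {
    stop("CDS length not a positive multiple of 3 for: ",
         paste(genes$gene_id[bad], collapse = ", "), call. = FALSE)
  }
  if (any(grepl("[^ACGT]", genes$cds))) {
    stop("CDS contains non-ACGT characters", call. = FALSE)
  }
  code <- Biostrings::GENETIC_CODE
  internal_stop <- vapply(genes$cds, function(s) {
    n_cod <- nchar(s) / 3
    if (n_cod < 2) return(FALSE)
    starts <- seq(1, by = 3, length.out = n_cod - 1) # exclude trailing codon
    any(code[substring(s, starts, starts + 2)] == "*")
  }, logical(1), USE.NAMES = FALSE)
  if (any(internal_stop)) {
    stop("internal stop codon in: ",
         paste(genes$gene_id[internal_stop], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(gene_id = genes$gene_id, cds = genes$cds,
                 protein_length = as.integer(len / 3))
}

#' Write coding sequences to FASTA
#' @param genes Tibble with `gene_id`, `cds`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(genes, path) {
  x <- Biostrings::DNAStringSet(setNames(genes$cds, genes$gene_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a protein-domain interval table
#'
#' Tab-separated with header columns `gene`, `domain_acc`, `domain_name`,
#' `aa_start`, `aa_end`; amino-acid coordinates are 1-based and inclusive.
#' When a gene table is supplied, intervals must lie within the protein.
#'
#' @param path File path.
#' @param genes Optional gene tibble from [read_cds_fasta()] for bounds
#'   checking.
#' @return A tibble `gene_id`, `domain_acc`, `domain_name`, `aa_start`,
#'   `aa_end`.
#' @export
read_domain_table <- function(path, genes = NULL) {
  raw <- read_tsv_chr(path)
  need <- c("gene", "domain_acc", "domain_name", "aa_start", "aa_end")
  if (length(setdiff(need, names(raw))) > 0) {
    stop("domain table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    gene_id = raw$gene,
    domain_acc = raw$domain_acc,
    domain_name = raw$domain_name,
    aa_start = suppressWarnings(as.integer(raw$aa_start)),
    aa_end = suppressWarnings(as.integer(raw$aa_end))
  )
  bad <- which(is.na(out$aa_start) | is.na(out$aa_end) |
                 out$aa_start < 1 | out$aa_end < out$aa_start)
  if (length(bad) > 0) stop_rows(bad, "invalid domain interval")
  if (!is.null(genes)) {
    chk <- dplyr::left_join(out, dplyr::select(genes, "gene_id",
                                               "protein_length"),
                            by = "gene_id")
    bad <- which(is.na(chk$protein_length) | chk$aa_end > chk$protein_length)
    if (length(bad) > 0) stop_rows(bad, "domain interval outside the protein")
  }
  out
}

#' Write a protein-domain interval table
#' @param domains Tibble as returned by [read_domain_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(domains, path) {
  out <- tibble::tibble(gene = domains$gene_id, domain_acc = domains$domain_acc,
                        domain_name = domains$domain_name,
                        aa_start = domains$aa_start, aa_end = domains$aa_end)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a per-site conservation-score track
#'
#' Tab-separated with header columns `gene`, `cds_pos`, `rs_score` holding
#' rejected-substitution conservation scores per nucleotide site of the
#' coding sequence. At most one score per `(gene, cds_pos)` site.
#'
#' @param path File path.
#' @return A tibble `gene_id`, `cds_pos`, `rs_score`.
#' @export
read_score_track <- function(path) {
  raw <- read_tsv_chr(path)
  need <- c("gene", "cds_pos", "rs_score")
  if (length(setdiff(need, names(raw))) > 0) {
    stop("score track must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    gene_id = raw$gene,
    cds_pos = suppressWarnings(as.integer(raw$cds_pos)),
    rs_score = suppressWarnings(as.numeric(raw$rs_score))
  )
  bad <- which(is.na(out$cds_pos) | is.na(out$rs_score) | out$cds_pos < 1)
  if (length(bad) > 0) stop_rows(bad, "invalid score row")
  dup <- which(duplicated(out[, c("gene_id", "cds_pos")]))
  if (length(dup) > 0) stop_rows(dup, "duplicate (gene, cds_pos) score")
  out
}

#' Write a conservation-score track
#' @param track Tibble as returned by [read_score_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path) {
  out <- tibble::tibble(gene = track$gene_id, cds_pos = track$cds_pos,
                        rs_score = track$rs_score)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
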