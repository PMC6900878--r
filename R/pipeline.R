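#' Read a pathogenicity-label table
#'
#' Tab-separated with header columns `gene`, `aa_pos`, `pathogenic`
#' (logical), one row per labelled amino-acid position.
#'
#' @param path File path.
#' @return A tibble `gene_id`, `aa_pos`, `pathogenic`.
#' @export
read_pathogenicity_table <- function(path) {
  raw <- read_tsv_chr(path)
  need <- c("gene", "aa_pos", "pathogenic")
  if (length(setdiff(need, names(raw))) > 0) {
    stop("pathogenicity table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    gene_id = raw$gene,
    aa_pos = suppressWarnings(as.integer(raw$aa_pos)),
    pathogenic = as.logical(raw$pathogenic))
  bad <- which(is.na(out$aa_pos) | is.na(out$pathogenic))
  if (length(bad) > 0) stop_rows(bad, "invalid pathogenicity row")
  out
}

#' Run the full analysis and write a directory of report tables
#'
#' Wires the stages together: annotation of both cohorts (non-synonymous
#' and stop-codon rows dropped with logged counts, or an error under
#' `strict`), substitution/amino-acid/degeneracy spectra and per-sample
#' loads, hotspot calling, and — when at least one hotspot is reported —
#' the three-way comparison (conservation t-tests, per-set amino-acid
#' distributions, domain overlap). Every table is written as TSV into
#' `out_dir`.
#'
#' @param tumor,neutral Mutation tibbles ([read_mutation_table()] layout).
#' @param genes Gene tibble ([read_cds_fasta()] layout).
#' @param out_dir Output directory.
#' @param scores Optional score track ([read_score_track()]).
#' @param domains Optional domain table ([read_domain_table()]).
#' @param pathogenicity Optional label table
#'   ([read_pathogenicity_table()]).
#' @param alpha,min_count,pool Passed to [call_hotspots()].
#' @param strict Error on non-synonymous input rows instead of dropping.
#' @param table A [codon_table()].
#' @return Invisibly, a list with the computed objects (`tumor_ann`,
#'   `neutral_ann`, `spectra`, `hotspots`, and when available `sets`,
#'   `conservation`, `aa_by_set`, `domains`).
#' @export
run_report <- function(tumor, neutral, genes, out_dir,
                       scores = NULL, domains = NULL, pathogenicity = NULL,
                       alpha = 0.05, min_count = 2,
                       pool = "global", strict = FALSE,
                       table = codon_table()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) readr::write_tsv(x, file.path(out_dir, name),
                                            progress = FALSE)

  tumor_ann <- filter_synonymous(
    annotate_mutations(tumor, genes, table), strict = strict)
  neutral_ann <- filter_synonymous(
    annotate_mutations(neutral, genes, table), strict = strict)
  tsv(tumor_ann, "tumor_annotated.tsv")
  tsv(neutral_ann, "neutral_annotated.tsv")

  spectra <- list(
    tumor_patterns = pattern_spectrum(tumor_ann),
    tumor_patterns_by_pos = pattern_spectrum(tumor_ann,
                                             by_codon_pos = TRUE),
    neutral_patterns = pattern_spectrum(neutral_ann),
    tumor_aa = aa_spectrum(tumor_ann, "cancer_type", table),
    neutral_aa = aa_spectrum(neutral_ann, NULL, table),
    tumor_degeneracy = degeneracy_spectrum(tumor_ann, "cancer_type", table),
    tumor_load = per_sample_load(tumor_ann),
    degeneracy_correlation = dplyr::bind_rows(
      tumor = degeneracy_correlation(tumor_ann, table),
      neutral = degeneracy_correlation(neutral_ann, table),
      .id = "cohort"))
  for (nm in names(spectra)) tsv(spectra[[nm]], paste0(nm, ".tsv"))

  calls <- call_hotspots(tumor_ann, genes, alpha = alpha,
                         min_count = min_count,
                         pathogenicity = pathogenicity, pool = pool,
                         table = table)
  tsv(tibble::as_tibble(calls), "hotspot_calls.tsv")
  tsv(glance(calls), "hotspot_summary.tsv")

  out <- list(tumor_ann = tumor_ann, neutral_ann = neutral_ann,
              spectra = spectra, hotspots = calls)

  if (any(calls$reported)) {
    sets <- build_control_sets(tumor_ann, neutral_ann, calls)
    tsv(sets, "comparison_sets.tsv")
    out$sets <- sets
    out$aa_by_set <- aa_distribution_by_set(sets, table)
    tsv(out$aa_by_set, "aa_by_set.tsv")
    if (!is.null(scores)) {
      # one score observation per distinct mutated site, not per recurrence
      site_sets <- dplyr::distinct(sets, .data$set, .data$gene_id,
                                   .data$cds_pos)
      sc <- attach_scores(site_sets, scores)
      by_set <- split(sc$rs_score, sc$set)
      pairs <- list(c("hotspot", "neutral"), c("hotspot", "non_hotspot"))
      cons <- dplyr::bind_rows(lapply(pairs, function(p) {
        dplyr::mutate(conservation_test(by_set[[p[1]]], by_set[[p[2]]]),
                      set_a = p[1], set_b = p[2], .before = 1)
      }))
      tsv(cons, "conservation_tests.tsv")
      out$conservation <- cons
    }
    if (!is.null(domains)) {
      ov <- domain_overlap(sets, domains)
      tsv(ov$accessions, "domain_accessions.tsv")
      tsv(ov$venn, "domain_venn.tsv")
      tsv(ov$shared, "domain_shared_proportions.tsv")
      out$domains <- ov
    }
  } else {
    message("run_report: no hotspot reported; comparative stage skipped")
  }
  invisible(out)
}
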