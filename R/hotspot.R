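#' Enumerate every synonymous single-base change in a set of genes
#'
#' Walks each coding sequence and lists every (site, alternate base) pair
#' whose substitution leaves the encoded amino acid unchanged, classified
#' by sequence-context subtype using the CpG dinucleotide context of the
#' reference CDS. Synonymous exchanges between stop codons are excluded.
#' This table is both the sampling space of the cohort generator and the
#' denominator of the hotspot background model.
#'
#' @param genes Gene tibble from [read_cds_fasta()] (columns `gene_id`,
#'   `cds`).
#' @param table A [codon_table()].
#' @return A tibble with one row per synonymous opportunity: `gene_id`,
#'   `cds_pos`, `aa_pos`, `codon_pos`, `ref`, `alt`, `aa`, `pattern`,
#'   `cpg`, `subtype`.
#' @export
opportunity_sites <- function(genes, table = codon_table()) {
  stopifnot(is.data.frame(genes), nrow(genes) > 0)
  len <- nchar(genes$cds)
  gene_id <- rep(genes$gene_id, len)
  cds <- rep(genes$cds, len)
  pos <- sequence(len)
  glen <- rep(len, len)
  ref <- stringr::str_sub(cds, pos, pos)
  nxt <- ifelse(pos < glen, stringr::str_sub(cds, pos + 1, pos + 1), "")
  prv <- ifelse(pos > 1, stringr::str_sub(cds, pos - 1, pos - 1), "")
  cpg <- ifelse(ref %in% c("C", "G"),
                (ref == "C" & nxt == "G") | (ref == "G" & prv == "C"), NA)

  # expand each site to its three alternate bases
  altmat <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
  i <- rep(seq_along(pos), each = 3)
  alt <- as.vector(t(altmat[ref, , drop = FALSE]))

  aa_pos <- (pos[i] - 1) %/% 3 + 1
  codon_pos <- (pos[i] - 1) %% 3 + 1
  start <- (aa_pos - 1) * 3 + 1
  ref_codon <- stringr::str_sub(cds[i], start, start + 2)
  alt_codon <- ref_codon
  stringr::str_sub(alt_codon, codon_pos, codon_pos) <- alt

  aa_ref <- unname(table$code[ref_codon])
  aa_alt <- unname(table$code[alt_codon])
  keep <- aa_ref == aa_alt & aa_ref != "*"

  ref_k <- ref[i][keep]
  alt_k <- alt[keep]
  cpg_k <- cpg[i][keep]
  tibble::tibble(
    gene_id = gene_id[i][keep],
    cds_pos = pos[i][keep],
    aa_pos = aa_pos[keep],
    codon_pos = codon_pos[keep],
    ref = ref_k,
    alt = alt_k,
    aa = aa_ref[keep],
    pattern = paste0(ref_k, ">", alt_k),
    cpg = cpg_k,
    subtype = classify_subtype(ref_k, alt_k, cpg_k)
  )
}

#' Per-position synonymous opportunity counts by subtype
#'
#' Aggregates [opportunity_sites()] to the amino-acid position level: for
#' each gene, position and sequence-context subtype, the number of
#' (site, alternate base) pairs within the codon whose change is synonymous
#' and of that subtype. Each count lies in 0..9 (three sites times three
#' alternates); zero-count combinations are omitted.
#'
#' @inheritParams opportunity_sites
#' @return A tibble `gene_id`, `aa_pos`, `subtype`, `opp`.
#' @export
synonymous_opportunities <- function(genes, table = codon_table()) {
  dplyr::count(opportunity_sites(genes, table),
               .data$gene_id, .data$aa_pos, .data$subtype, name = "opp")
}

#' Upper-tail Poisson probability
#'
#' `P(X >= k)` for `X ~ Poisson(lam)`; equals 1 at `k = 0`.
#'
#' @param k Non-negative integer observed counts.
#' @param lam Non-negative Poisson means.
#' @return Probabilities in `[0, 1]`.
#' @export
poisson_tail <- function(k, lam) {
  if (any(k < 0) || any(k != floor(k))) {
    stop("k must be a non-negative integer", call. = FALSE)
  }
  if (any(lam < 0)) stop("lam must be non-negative", call. = FALSE)
  ppois(k - 1, lam, lower.tail = FALSE)
}

#' Fisher's combined probability test
#'
#' Combines independent p-values via `-2 * sum(log(p))` referred to a
#' chi-squared distribution with `2 * length(p)` degrees of freedom.
#' Zero p-values are an error: floor them (see `p_floor` in
#' [call_hotspots()]) before combining.
#'
#' @param p Non-empty vector of p-values in `(0, 1]`.
#' @return The combined p-value.
#' @export
fisher_combine <- function(p) {
  if (length(p) == 0) stop("no p-values to combine", call. = FALSE)
  if (any(p <= 0)) stop("p-values must be > 0 (apply a floor)", call. = FALSE)
  if (any(p > 1)) stop("p-values must be <= 1", call. = FALSE)
  chi2 <- -2 * sum(log(p))
  pchisq(chi2, df = 2 * length(p), lower.tail = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity, returned in the
#' input order (wraps [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p Vector of p-values.
#' @return Adjusted q-values in `[0, 1]`.
#' @export
bh_fdr <- function(p) {
  p.adjust(p, method = "BH")
}

#' Per-position Poisson background expectations
#'
#' For each gene, cancer type, amino-acid position and subtype, the expected
#' synonymous mutation count under the background model: the observed
#' per-gene, per-cancer-type, per-subtype total is spread over positions in
#' proportion to each position's synonymous opportunity of that subtype,
#' `lambda[p, s] = N[g, c, s] * opp[p, s] / opp_total[g, s]`. Summed over
#' positions the expectations return the observed totals exactly.
#'
#' @param ann Annotated synonymous mutations ([annotate_mutations()] output,
#'   already restricted to synonymous sense changes).
#' @param genes Gene tibble covering every mutated gene.
#' @param positions Optional tibble `gene_id`, `cancer_type`, `aa_pos`
#'   restricting the output; `NULL` for all positions with any opportunity.
#' @param table A [codon_table()].
#' @return A tibble `gene_id`, `cancer_type`, `aa_pos`, `subtype`, `opp`,
#'   `opp_total`, `n_gcs` (the gene/cancer/subtype total), `lambda`, `obs`.
#' @export
hotspot_background <- function(ann, genes, positions = NULL,
                               table = codon_table()) {
  absent <- setdiff(unique(ann$gene_id), genes$gene_id)
  if (length(absent) > 0) {
    stop("mutated genes missing from the gene set: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  used <- dplyr::filter(genes, .data$gene_id %in% unique(ann$gene_id))
  opp_tbl <- synonymous_opportunities(used, table)
  opp_tot <- dplyr::summarise(
    dplyr::group_by(opp_tbl, .data$gene_id, .data$subtype),
    opp_total = sum(.data$opp), .groups = "drop")

  n_gcs <- dplyr::count(ann, .data$gene_id, .data$cancer_type, .data$subtype,
                        name = "n_gcs")
  obs <- dplyr::count(ann, .data$gene_id, .data$cancer_type,
                      aa_pos = .data$codon_index, .data$subtype, name = "obs")

  gc_pairs <- dplyr::distinct(ann, .data$gene_id, .data$cancer_type)
  bg <- dplyr::inner_join(gc_pairs, opp_tbl, by = "gene_id",
                          relationship = "many-to-many")
  if (!is.null(positions)) {
    bg <- dplyr::semi_join(bg, positions,
                           by = c("gene_id", "cancer_type", "aa_pos"))
  }
  bg <- dplyr::left_join(bg, opp_tot, by = c("gene_id", "subtype"))
  bg <- dplyr::left_join(bg, n_gcs,
                         by = c("gene_id", "cancer_type", "subtype"))
  bg <- dplyr::left_join(bg, obs,
                         by = c("gene_id", "cancer_type", "aa_pos", "subtype"))
  dplyr::mutate(bg,
                n_gcs = dplyr::coalesce(.data$n_gcs, 0L),
                obs = dplyr::coalesce(.data$obs, 0L),
                lambda = .data$n_gcs * .data$opp / .data$opp_total)
}

#' Call synonymous hotspot mutations
#'
#' Detects amino-acid positions whose synonymous mutation counts exceed the
#' background expected from the gene, the cancer type and the six
#' sequence-context subtypes. Per tested position, each subtype with
#' non-zero opportunity contributes an upper-tail Poisson p-value against
#' its background expectation ([hotspot_background()]); these are combined
#' with Fisher's method and adjusted by Benjamini-Hochberg FDR across all
#' tested positions. A position is `reported` when its q-value is below
#' `alpha` and, if a pathogenicity-label table is supplied, it is labelled
#' pathogenic.
#'
#' Only positions observed at least `min_count` times (summed over
#' subtypes) within a gene/cancer-type stratum are tested: a hotspot is a
#' recurrent change, and the gate keeps the multiple-testing burden to
#' positions that could possibly qualify.
#'
#' @inheritParams hotspot_background
#' @param alpha FDR threshold for reporting (default 0.05).
#' @param min_count Minimum observed count for a position to be tested
#'   (default 2).
#' @param p_floor Floor applied to per-subtype p-values before the log
#'   transform of Fisher's statistic (default 1e-300).
#' @param pathogenicity Optional tibble `gene_id`, `aa_pos`, `pathogenic`;
#'   positions absent from it count as not pathogenic. `NULL` disables the
#'   filter.
#' @param pool `"global"` (default) adjusts p-values across all tested
#'   positions in the run; `"per_cancer"` adjusts within each cancer type.
#' @return A tibble of class `syn_hotspots`, one row per tested position:
#'   `gene_id`, `cancer_type`, `aa_pos`, `total_obs`, per-subtype `obs_*`,
#'   `lambda_*` and `p_*` columns, `p_combined`, `q`, `pathogenic`,
#'   `reported`. Attributes record `alpha`, `min_count` and `pool`.
#' @export
call_hotspots <- function(ann, genes, alpha = 0.05, min_count = 2,
                          p_floor = 1e-300, pathogenicity = NULL,
                          pool = c("global", "per_cancer"),
                          table = codon_table()) {
  pool <- match.arg(pool)
  stopifnot(all(c("gene_id", "cancer_type", "codon_index", "subtype",
                  "synonymous", "aa") %in% names(ann)))
  syn <- dplyr::filter(ann, .data$synonymous, .data$aa != "*")

  obs_pos <- dplyr::count(syn, .data$gene_id, .data$cancer_type,
                          aa_pos = .data$codon_index, name = "total_obs")
  tested <- dplyr::filter(obs_pos, .data$total_obs >= min_count)
  empty <- tibble::tibble(gene_id = character(), cancer_type = character(),
                          aa_pos = integer(), total_obs = integer(),
                          p_combined = double(), q = double(),
                          pathogenic = logical(), reported = logical())
  if (nrow(tested) == 0) {
    return(structure(empty, class = c("syn_hotspots", class(empty)),
                     alpha = alpha, min_count = min_count, pool = pool,
                     n_tested = 0L))
  }

  bg <- hotspot_background(syn, genes, positions = tested, table = table)
  bg <- dplyr::mutate(bg, p_subtype = poisson_tail(.data$obs, .data$lambda))

  calls <- dplyr::summarise(
    dplyr::group_by(bg, .data$gene_id, .data$cancer_type, .data$aa_pos),
    p_combined = fisher_combine(pmax(.data$p_subtype, .env$p_floor)),
    .groups = "drop")
  calls <- dplyr::left_join(tested, calls,
                            by = c("gene_id", "cancer_type", "aa_pos"))

  if (pool == "global") {
    calls$q <- bh_fdr(calls$p_combined)
  } else {
    calls <- dplyr::mutate(dplyr::group_by(calls, .data$cancer_type),
                           q = bh_fdr(.data$p_combined))
    calls <- dplyr::ungroup(calls)
  }

  if (is.null(pathogenicity)) {
    calls$pathogenic <- NA
  } else {
    stopifnot(all(c("gene_id", "aa_pos", "pathogenic") %in%
                    names(pathogenicity)))
    calls <- dplyr::left_join(
      calls, dplyr::distinct(pathogenicity, .data$gene_id, .data$aa_pos,
                             .data$pathogenic),
      by = c("gene_id", "aa_pos"))
    calls$pathogenic <- dplyr::coalesce(calls$pathogenic, FALSE)
  }
  calls$reported <- calls$q < alpha &
    (is.na(calls$pathogenic) | calls$pathogenic)

  # per-subtype observation/expectation/p columns, wide
  wide <- tidyr::pivot_wider(
    dplyr::select(bg, "gene_id", "cancer_type", "aa_pos", "subtype",
                  "obs", "lambda", "p_subtype"),
    names_from = "subtype",
    values_from = c("obs", "lambda", "p_subtype"),
    names_glue = "{.value}_{subtype}", values_fill = NA)
  names(wide) <- sub("^p_subtype_", "p_", names(wide))
  out <- dplyr::left_join(calls, wide,
                          by = c("gene_id", "cancer_type", "aa_pos"))
  out <- dplyr::arrange(out, .data$gene_id, .data$cancer_type, .data$aa_pos)
  message("call_hotspots: ", nrow(obs_pos), " mutated positions, ",
          nrow(tested), " tested (min_count=", min_count, "), ",
          sum(out$reported), " reported at FDR ", alpha)
  structure(out, class = c("syn_hotspots", class(out)),
            alpha = alpha, min_count = min_count, pool = pool,
            n_tested = nrow(tested))
}

#' @export
print.syn_hotspots <- function(x, ...) {
  cat("<syn_hotspots> ", attr(x, "n_tested"), " tested positions, ",
      sum(x$reported), " reported at FDR ", attr(x, "alpha"), "\n", sep = "")
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a hotspot call set
#'
#' One row per tested amino-acid position with the headline statistics,
#' ordered by q-value.
#'
#' @param x A `syn_hotspots` object from [call_hotspots()].
#' @param ... Unused.
#' @return A plain tibble `gene_id`, `cancer_type`, `aa_pos`, `total_obs`,
#'   `p_combined`, `q`, `pathogenic`, `reported`.
#' @export
tidy.syn_hotspots <- function(x, ...) {
  out <- dplyr::select(tibble::as_tibble(x), "gene_id", "cancer_type",
                       "aa_pos", "total_obs", "p_combined", "q",
                       "pathogenic", "reported")
  dplyr::arrange(out, .data$q, .data$gene_id, .data$aa_pos)
}

#' One-row summary of a hotspot call set
#'
#' @inheritParams tidy.syn_hotspots
#' @return A one-row tibble: `n_tested`, `n_reported`, `n_hmcg` (genes with
#'   at least one reported hotspot), `n_cancer_types`, `alpha`, `min_count`,
#'   `pool`.
#' @export
glance.syn_hotspots <- function(x, ...) {
  rep <- dplyr::filter(tibble::as_tibble(x), .data$reported)
  tibble::tibble(
    n_tested = attr(x, "n_tested"),
    n_reported = nrow(rep),
    n_hmcg = dplyr::n_distinct(rep$gene_id),
    n_cancer_types = dplyr::n_distinct(rep$cancer_type),
    alpha = attr(x, "alpha"),
    min_count = attr(x, "min_count"),
    pool = attr(x, "pool")
  )
}
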