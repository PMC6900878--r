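#' Build the three comparison sets around a hotspot call set
#'
#' Given annotated synonymous mutations from the tumor and neutral cohorts
#' and a hotspot call set, labels three disjoint mutation sets restricted
#' to the hotspot-mutation-containing genes (HMCGs — genes with at least
#' one reported hotspot): `hotspot` (tumor mutations at reported
#' amino-acid positions), `non_hotspot` (the remaining tumor mutations in
#' HMCGs) and `neutral` (neutral-cohort mutations in HMCGs; membership is
#' by cohort, so a neutral mutation at a hotspot position stays neutral).
#'
#' @param tumor_ann,neutral_ann Annotated synonymous mutations of the two
#'   cohorts.
#' @param calls A `syn_hotspots` object from [call_hotspots()] with at
#'   least one reported hotspot.
#' @return A tibble: the mutation rows of the three sets stacked, with a
#'   `set` column; attribute `hmcg` lists the HMCG gene ids.
#' @export
build_control_sets <- function(tumor_ann, neutral_ann, calls) {
  assert_synonymous(tumor_ann)
  assert_synonymous(neutral_ann)
  rep_calls <- dplyr::filter(tibble::as_tibble(calls), .data$reported)
  if (nrow(rep_calls) == 0) stop("no hotspots called", call. = FALSE)
  hot_pos <- dplyr::distinct(rep_calls, .data$gene_id, .data$aa_pos)
  hmcg <- unique(hot_pos$gene_id)

  tumor_hmcg <- dplyr::filter(tumor_ann, .data$gene_id %in% hmcg)
  is_hot <- dplyr::mutate(tumor_hmcg, aa_pos = .data$codon_index)
  hot <- dplyr::semi_join(is_hot, hot_pos, by = c("gene_id", "aa_pos"))
  non_hot <- dplyr::anti_join(is_hot, hot_pos, by = c("gene_id", "aa_pos"))
  neutral <- dplyr::mutate(
    dplyr::filter(neutral_ann, .data$gene_id %in% hmcg),
    aa_pos = .data$codon_index)

  out <- dplyr::bind_rows(
    dplyr::mutate(hot, set = "hotspot"),
    dplyr::mutate(non_hot, set = "non_hotspot"),
    dplyr::mutate(neutral, set = "neutral"))
  message("build_control_sets: ", length(hmcg), " HMCGs; hotspot=",
          nrow(hot), ", non_hotspot=", nrow(non_hot), ", neutral=",
          nrow(neutral))
  structure(out, hmcg = hmcg)
}

#' Attach conservation scores to mutations
#'
#' Looks up each mutation's rejected-substitution score at its own
#' nucleotide site. Sites missing from the track are dropped with a
#' reported count; if every site is missing that is an error.
#'
#' @param muts Mutation tibble with `gene_id`, `cds_pos`.
#' @param track Score tibble from [read_score_track()].
#' @return `muts` with an `rs_score` column, missing-score rows removed.
#' @export
attach_scores <- function(muts, track) {
  out <- dplyr::left_join(muts,
                          dplyr::select(track, "gene_id", "cds_pos",
                                        "rs_score"),
                          by = c("gene_id", "cds_pos"))
  n_missing <- sum(is.na(out$rs_score))
  if (n_missing == nrow(out)) {
    stop("no mutation site has a conservation score", call. = FALSE)
  }
  if (n_missing > 0) {
    message("attach_scores: ", n_missing, " of ", nrow(out),
            " sites lack a score and were dropped")
  }
  dplyr::filter(out, !is.na(.data$rs_score))
}

#' One-tailed unpaired t-test between two score sets
#'
#' Tests whether the mean conservation score of set A exceeds that of set B
#' with an unpaired t-test, Welch (unequal-variance) form by default; set
#' `var_equal = TRUE` for the pooled-variance form.
#'
#' @param a,b Numeric score vectors (at least two values each).
#' @param alternative Direction of the test (default `"greater"`: mean of
#'   `a` exceeds mean of `b`).
#' @param var_equal Use the pooled-variance (equal-variance) form.
#' @return A one-row tibble `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`.
#' @export
conservation_test <- function(a, b, alternative = "greater",
                              var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least two scores per set", call. = FALSE)
  }
  tt <- t.test(a, b, alternative = alternative, var.equal = var_equal)
  tibble::tibble(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b))
}

#' Amino-acid distributions of the three comparison sets
#'
#' @param sets Output of [build_control_sets()].
#' @param table A [codon_table()].
#' @return An [aa_spectrum()] tibble grouped by `set`.
#' @export
aa_distribution_by_set <- function(sets, table = codon_table()) {
  aa_spectrum(sets, group_by = "set", table = table)
}

#' Protein-domain overlap of the three comparison sets
#'
#' Maps each mutation to the domain intervals covering its amino-acid
#' position (closed intervals; a mutation inside overlapping intervals of
#' the same accession counts once per distinct accession) and summarises:
#' the distinct domain accessions hit by each set, the seven Venn-region
#' counts of those three accession sets, and — for accessions hit by all
#' three sets — the proportion of that domain's mutations contributed by
#' each set.
#'
#' @param sets Output of [build_control_sets()].
#' @param domains Domain tibble from [read_domain_table()].
#' @return A list with tibbles `accessions` (`set`, `domain_acc`), `venn`
#'   (`region`, `n_domains`) and `shared` (`domain_acc`, `set`, `n`,
#'   `prop`).
#' @export
domain_overlap <- function(sets, domains) {
  stopifnot(all(c("set", "gene_id", "aa_pos") %in% names(sets)))
  muts <- dplyr::mutate(sets, .row = dplyr::row_number())
  hits <- dplyr::inner_join(
    dplyr::select(muts, ".row", "set", "gene_id", "aa_pos"),
    dplyr::select(domains, "gene_id", "domain_acc", "aa_start", "aa_end"),
    by = "gene_id", relationship = "many-to-many")
  hits <- dplyr::filter(hits, .data$aa_pos >= .data$aa_start,
                        .data$aa_pos <= .data$aa_end)
  hits <- dplyr::distinct(hits, .data$.row, .data$set, .data$domain_acc)

  accessions <- dplyr::distinct(hits, .data$set, .data$domain_acc)
  membership <- dplyr::summarise(
    dplyr::group_by(accessions, .data$domain_acc),
    region = paste(sort(unique(.data$set)), collapse = "&"),
    .groups = "drop")
  venn <- dplyr::count(membership, .data$region, name = "n_domains")

  shared_acc <- membership$domain_acc[
    membership$region == "hotspot&neutral&non_hotspot"]
  shared <- dplyr::count(
    dplyr::filter(hits, .data$domain_acc %in% shared_acc),
    .data$domain_acc, .data$set, name = "n")
  if (nrow(shared) > 0) {
    shared <- tidyr::complete(shared, .data$domain_acc,
                              set = c("hotspot", "neutral", "non_hotspot"),
                              fill = list(n = 0L))
    shared <- dplyr::ungroup(
      dplyr::mutate(dplyr::group_by(shared, .data$domain_acc),
                    prop = .data$n / sum(.data$n)))
  } else {
    shared$prop <- double()
  }
  list(accessions = accessions, venn = venn, shared = shared)
}
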