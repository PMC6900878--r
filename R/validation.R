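#' Default study conditions of the hotspot-recovery harness
#'
#' A single-cancer-type tumor cohort sized so that each planted 20-fold
#' hotspot expects at least eight mutations: 50 genes, 120 samples with a
#' Poisson mean of 100 synonymous mutations each, 8 planted hotspots.
#'
#' @param ... Overrides forwarded to [simulate_config()].
#' @return A [simulate_config()].
#' @export
recovery_config <- function(...) {
  simulate_config(cancer_types = "SKCA", n_samples = 120, mean_load = 100,
                  n_hotspots = 8, fold_enrichment = 20, ...)
}

#' Null-cohort conditions for false-positive-rate checks
#'
#' 50 genes and roughly 5,000 tumor mutations with no planted hotspot.
#'
#' @inheritParams recovery_config
#' @return A [simulate_config()].
#' @export
null_config <- function(...) {
  simulate_config(cancer_types = "SKCA", n_samples = 50, mean_load = 100,
                  n_hotspots = 0, ...)
}

#' Planted-hotspot recovery across seeded replicates
#'
#' For each seed: simulate a study, run annotation and [call_hotspots()],
#' and compare the reported positions against the planted ground truth.
#' Sensitivity is assessed over planted hotspots whose analytic expected
#' mutation count is at least `min_expected` (a hotspot expecting fewer
#' hits carries too little signal to be a fair recovery target).
#'
#' @param config A [simulate_config()]; default [recovery_config()].
#' @param seeds Integer vector of replicate seeds.
#' @param min_expected Minimum expected hit count for a planted hotspot to
#'   enter the sensitivity denominator.
#' @param alpha,min_count Passed to [call_hotspots()].
#' @return A tibble, one row per replicate: `seed`, `n_planted`,
#'   `n_eligible`, `n_recovered`, `n_reported`, `sensitivity`.
#' @export
hotspot_recovery <- function(config = recovery_config(), seeds = 1:25,
                             min_expected = 8, alpha = 0.05,
                             min_count = 2) {
  res <- lapply(seeds, function(s) {
    st <- simulate_study(config, seed = s)
    ann <- suppressMessages(filter_synonymous(
      annotate_mutations(st$tumor, st$genes)))
    calls <- suppressMessages(call_hotspots(ann, st$genes, alpha = alpha,
                                            min_count = min_count))
    rep_pos <- dplyr::distinct(
      dplyr::filter(tibble::as_tibble(calls), .data$reported),
      .data$gene_id, .data$aa_pos)
    eligible <- dplyr::filter(st$planted,
                              .data$expected_hits >= min_expected)
    hit <- dplyr::semi_join(eligible, rep_pos, by = c("gene_id", "aa_pos"))
    tibble::tibble(seed = s, n_planted = nrow(st$planted),
                   n_eligible = nrow(eligible), n_recovered = nrow(hit),
                   n_reported = nrow(rep_pos),
                   sensitivity = nrow(hit) / max(nrow(eligible), 1))
  })
  dplyr::bind_rows(res)
}

#' Hotspot false-positive behaviour on null cohorts
#'
#' Simulates cohorts with no planted hotspot and records how many
#' positions [call_hotspots()] reports in each replicate.
#'
#' @param config A [simulate_config()] with `n_hotspots = 0`; default
#'   [null_config()].
#' @inheritParams hotspot_recovery
#' @return A tibble `seed`, `n_tested`, `n_reported`.
#' @export
hotspot_null_rate <- function(config = null_config(), seeds = 1:25,
                              alpha = 0.05, min_count = 2) {
  stopifnot(config$n_hotspots == 0)
  res <- lapply(seeds, function(s) {
    genes <- generate_genes(config, s)
    sites <- opportunity_sites(genes)
    muts <- generate_cohort(genes, config, "tumor", seed = s, sites = sites)
    ann <- suppressMessages(filter_synonymous(
      annotate_mutations(muts, genes)))
    calls <- suppressMessages(call_hotspots(ann, genes, alpha = alpha,
                                            min_count = min_count))
    tibble::tibble(seed = s, n_tested = attr(calls, "n_tested"),
                   n_reported = sum(calls$reported))
  })
  dplyr::bind_rows(res)
}

#' Conservation-shift detection across seeded replicates
#'
#' For each seed: generate genes, plant hotspot codons, draw a score track
#' with mean shift `config$rs_delta` at hotspot sites, and run the
#' one-tailed unpaired t-test of hotspot-site scores against an equal-sized
#' random sample of other sites.
#'
#' @inheritParams hotspot_recovery
#' @param n_background Number of non-hotspot sites sampled per replicate.
#' @return A tibble `seed`, `delta`, `statistic`, `p_value`.
#' @export
conservation_recovery <- function(config = recovery_config(), seeds = 1:25,
                                  n_background = 200) {
  res <- lapply(seeds, function(s) {
    genes <- generate_genes(config, s)
    sites <- opportunity_sites(genes)
    planted <- plant_hotspots(genes, config, s, sites = sites)
    track <- generate_scores(genes, config, planted, s)
    hot_key <- paste(rep(planted$gene_id, each = 3),
                     rep((planted$aa_pos - 1) * 3, each = 3) + 1:3)
    is_hot <- paste(track$gene_id, track$cds_pos) %in% hot_key
    hot_scores <- track$rs_score[is_hot]
    bg_pool <- track$rs_score[!is_hot]
    bg <- withr::with_seed(stream_seed(s, "cons_background"),
                           sample(bg_pool, n_background))
    tt <- conservation_test(hot_scores, bg)
    tibble::tibble(seed = s, delta = config$rs_delta,
                   statistic = tt$statistic, p_value = tt$p_value)
  })
  dplyr::bind_rows(res)
}
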