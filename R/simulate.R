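#' Configuration for the synthetic-cohort generator
#'
#' Bundles every knob of the simulator with defaults chosen to mirror the
#' statistical structure the analysis assumes: a tumor cohort whose
#' substitution weights lean toward C:G->T:A changes (transitions at G:C
#' reference sites dominate, strongest in CpG context) and a neutral cohort
#' leaning toward T:A->C:G transitions; per-sample mutation counts Poisson;
#' planted hotspot positions up-weighted by a stated fold enrichment;
#' conservation scores Normal with a mean shift at hotspot codons; random
#' non-overlapping domain intervals drawn from a shared accession pool so
#' that accessions recur across genes.
#'
#' @param n_genes Number of genes.
#' @param cds_length_range Range of CDS lengths in nucleotides (multiples
#'   of 3 are drawn within it).
#' @param gc_content Target GC fraction of the coding sequences.
#' @param cancer_types Cancer-type codes of the tumor cohort.
#' @param n_samples Tumor samples per cancer type.
#' @param mean_load Poisson mean of synonymous mutations per tumor sample.
#' @param neutral_label Cohort code used in the neutral table's
#'   `cancer_type` column.
#' @param neutral_n_samples,neutral_mean_load Sample count and per-sample
#'   Poisson mean of the neutral cohort.
#' @param tumor_weights,neutral_weights Named non-negative relative
#'   sampling weights over the six [context_subtypes()].
#' @param n_hotspots Number of planted hotspot positions (tumor cohort
#'   only).
#' @param fold_enrichment Multiplier (>= 1) applied to the sampling weight
#'   of every synonymous opportunity in a planted hotspot's codon.
#' @param rs_mean,rs_sd Baseline Normal parameters of the conservation
#'   score track.
#' @param rs_delta Mean shift added at the three sites of each planted
#'   hotspot codon.
#' @param n_domains_per_gene Domain intervals per gene.
#' @param domain_pool Number of distinct domain accessions shared across
#'   genes.
#' @param pathogenic_flip_prob Probability of flipping a planted hotspot's
#'   pathogenicity label to `FALSE`.
#' @param nonsyn_prop Proportion of non-synonymous contaminant rows to add
#'   to the tumor table (0 disables; used to exercise upstream filtering).
#' @return A list of class `sim_config`.
#' @export
simulate_config <- function(n_genes = 50,
                            cds_length_range = c(300, 3000),
                            gc_content = 0.5,
                            cancer_types = c("BRCA", "LUAD", "SKCA"),
                            n_samples = 40,
                            mean_load = 100,
                            neutral_label = "NEUT",
                            neutral_n_samples = 80,
                            neutral_mean_load = 50,
                            tumor_weights = c(ATts = 1.2, ATtv = 0.5,
                                              C_GCts = 8, C_GCtv = 0.9,
                                              NC_GCts = 5.5, NC_GCtv = 1.1),
                            neutral_weights = c(ATts = 4, ATtv = 0.8,
                                                C_GCts = 2, C_GCtv = 0.8,
                                                NC_GCts = 2, NC_GCtv = 0.8),
                            n_hotspots = 10,
                            fold_enrichment = 20,
                            rs_mean = 0, rs_sd = 1, rs_delta = 2,
                            n_domains_per_gene = 2,
                            domain_pool = 12,
                            pathogenic_flip_prob = 0,
                            nonsyn_prop = 0) {
  stopifnot(length(cds_length_range) == 2,
            cds_length_range[1] >= 9,
            fold_enrichment >= 1,
            all(names(tumor_weights) == context_subtypes()),
            all(names(neutral_weights) == context_subtypes()),
            all(tumor_weights >= 0), any(tumor_weights > 0),
            all(neutral_weights >= 0), any(neutral_weights > 0))
  structure(as.list(environment()), class = "sim_config")
}

# one RNG stream per generated artifact, keyed by (master seed, name), so
# adding an artifact never perturbs the others
stream_seed <- function(seed, name) {
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 65536 * 1000003 + h) %% 2147483647)
}

#' Generate random valid coding sequences
#'
#' Each gene starts with ATG, ends with a stop codon, contains no internal
#' stop, and has interior codons drawn from the 61 sense codons with
#' probabilities proportional to the product of per-base probabilities at
#' the target GC content.
#'
#' @param config A [simulate_config()].
#' @param seed Integer seed (deterministic byte-identical output).
#' @return A gene tibble (`gene_id`, `cds`, `protein_length`).
#' @export
generate_genes <- function(config, seed) {
  withr::with_seed(stream_seed(seed, "genes"), {
    code <- Biostrings::GENETIC_CODE
    sense <- names(code)[code != "*"]
    gc <- config$gc_content
    p_base <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    w <- vapply(strsplit(sense, ""), function(b) prod(p_base[b]), double(1))
    stops <- c("TAA", "TAG", "TGA")
    w_stop <- vapply(strsplit(stops, ""), function(b) prod(p_base[b]),
                     double(1))
    n_cod <- sample(seq(config$cds_length_range[1] %/% 3,
                        config$cds_length_range[2] %/% 3),
                    config$n_genes, replace = TRUE)
    cds <- vapply(n_cod, function(k) {
      paste0("ATG",
             paste(sample(sense, k - 2, replace = TRUE, prob = w),
                   collapse = ""),
             sample(stops, 1, prob = w_stop))
    }, character(1))
    validate_gene_table(tibble::tibble(
      gene_id = sprintf("g%03d", seq_len(config$n_genes)), cds = cds))
  })
}

# choose planted hotspot codons among positions with a G:C transition
# opportunity (the dominant context of real hotspot calls), and record the
# expected mutation count per cancer-type stratum under the sampling model
plant_hotspots <- function(genes, config, seed, sites = NULL) {
  if (config$n_hotspots == 0) {
    return(tibble::tibble(gene_id = character(), aa_pos = integer(),
                          fold = double(), expected_hits = double()))
  }
  if (is.null(sites)) sites <- opportunity_sites(genes)
  withr::with_seed(stream_seed(seed, "hotspots"), {
    cand <- dplyr::distinct(
      dplyr::filter(sites, .data$subtype %in% c("C_GCts", "NC_GCts")),
      .data$gene_id, .data$aa_pos)
    stopifnot(nrow(cand) >= config$n_hotspots)
    picked <- cand[sample.int(nrow(cand), config$n_hotspots), ]
    picked$fold <- config$fold_enrichment

    w <- unname(config$tumor_weights[sites$subtype])
    hot_key <- paste(picked$gene_id, picked$aa_pos)
    site_key <- paste(sites$gene_id, sites$aa_pos)
    is_hot <- site_key %in% hot_key
    w_eff <- w * ifelse(is_hot, config$fold_enrichment, 1)
    m_per_cancer <- config$n_samples * config$mean_load
    codon_w <- vapply(hot_key, function(k) sum(w_eff[site_key == k]),
                      double(1))
    picked$expected_hits <- m_per_cancer * codon_w / sum(w_eff)
    dplyr::arrange(picked, .data$gene_id, .data$aa_pos)
  })
}

#' Generate a mutation cohort over synonymous opportunities
#'
#' Draws each sample's mutation count from a Poisson distribution, then
#' draws mutations over the genes' synonymous (site, alternate) pairs with
#' probability proportional to the cohort's subtype weight; in the tumor
#' cohort, opportunities inside planted hotspot codons are up-weighted by
#' the fold enrichment. Only synonymous records are emitted unless
#' `nonsyn_prop > 0` asks for contaminant rows.
#'
#' @param genes Gene tibble.
#' @param config A [simulate_config()].
#' @param cohort `"tumor"` or `"neutral"`.
#' @param planted Planted-hotspot tibble (`gene_id`, `aa_pos`, `fold`);
#'   ignored for the neutral cohort.
#' @param seed Integer seed.
#' @param sites Precomputed [opportunity_sites()] of `genes`, to avoid
#'   re-enumeration.
#' @return A mutation tibble (`sample_id`, `cancer_type`, `gene_id`,
#'   `cds_pos`, `ref`, `alt`).
#' @export
generate_cohort <- function(genes, config, cohort = c("tumor", "neutral"),
                            planted = NULL, seed = 1, sites = NULL) {
  cohort <- match.arg(cohort)
  if (is.null(sites)) sites <- opportunity_sites(genes)
  weights <- if (cohort == "tumor") config$tumor_weights else
    config$neutral_weights
  w <- unname(weights[sites$subtype])
  if (cohort == "tumor" && !is.null(planted) && nrow(planted) > 0) {
    bad <- dplyr::anti_join(planted, sites, by = c("gene_id", "aa_pos"))
    if (nrow(bad) > 0) {
      stop("planted hotspot at a position with no synonymous opportunity: ",
           paste(paste0(bad$gene_id, ":", bad$aa_pos), collapse = ", "),
           call. = FALSE)
    }
    key <- paste(sites$gene_id, sites$aa_pos)
    hot <- match(key, paste(planted$gene_id, planted$aa_pos))
    w <- w * ifelse(is.na(hot), 1, planted$fold[hot])
  }
  groups <- if (cohort == "tumor") {
    tibble::tibble(cancer_type = rep(config$cancer_types,
                                     each = config$n_samples),
                   sample_id = paste0(rep(config$cancer_types,
                                          each = config$n_samples), "_s",
                                      sprintf("%03d", sequence(
                                        rep(config$n_samples,
                                            length(config$cancer_types))))),
                   load = config$mean_load)
  } else {
    tibble::tibble(cancer_type = config$neutral_label,
                   sample_id = sprintf("%s_s%03d", config$neutral_label,
                                       seq_len(config$neutral_n_samples)),
                   load = config$neutral_mean_load)
  }
  withr::with_seed(stream_seed(seed, paste0("cohort_", cohort)), {
    counts <- rpois(nrow(groups), groups$load)
    total <- sum(counts)
    idx <- sample.int(nrow(sites), total, replace = TRUE, prob = w)
    out <- tibble::tibble(
      sample_id = rep(groups$sample_id, counts),
      cancer_type = rep(groups$cancer_type, counts),
      gene_id = sites$gene_id[idx],
      cds_pos = sites$cds_pos[idx],
      ref = sites$ref[idx],
      alt = sites$alt[idx])
    if (cohort == "tumor" && config$nonsyn_prop > 0) {
      out <- dplyr::bind_rows(out, nonsyn_contaminants(genes, groups, config))
    }
    out
  })
}

# contaminant non-synonymous rows for exercising upstream filters
nonsyn_contaminants <- function(genes, groups, config) {
  n_extra <- max(1, round(config$nonsyn_prop * config$mean_load *
                            nrow(groups)))
  code <- Biostrings::GENETIC_CODE
  rows <- list()
  got <- 0
  while (got < n_extra) {
    gi <- sample.int(nrow(genes), 1)
    len <- nchar(genes$cds[gi])
    pos <- sample.int(len, 1)
    ref <- substr(genes$cds[gi], pos, pos)
    alt <- sample(setdiff(BASES, ref), 1)
    ci <- (pos - 1) %/% 3 + 1
    cp <- (pos - 1) %% 3 + 1
    rc <- substr(genes$cds[gi], (ci - 1) * 3 + 1, ci * 3)
    ac <- rc
    substr(ac, cp, cp) <- alt
    if (code[rc] != code[ac]) {
      g <- groups[sample.int(nrow(groups), 1), ]
      got <- got + 1
      rows[[got]] <- tibble::tibble(sample_id = g$sample_id,
                                    cancer_type = g$cancer_type,
                                    gene_id = genes$gene_id[gi],
                                    cds_pos = pos, ref = ref, alt = alt)
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a conservation-score track
#'
#' Every CDS site receives a Normal score; the three sites of each planted
#' hotspot codon receive an additional mean shift of `rs_delta`.
#'
#' @inheritParams generate_cohort
#' @return A score tibble (`gene_id`, `cds_pos`, `rs_score`).
#' @export
generate_scores <- function(genes, config, planted = NULL, seed = 1) {
  len <- nchar(genes$cds)
  track <- tibble::tibble(gene_id = rep(genes$gene_id, len),
                          cds_pos = sequence(len))
  shift <- rep(0, nrow(track))
  if (!is.null(planted) && nrow(planted) > 0) {
    hot_sites <- tidyr::uncount(planted, 3, .id = "off")
    hot_sites$cds_pos <- (hot_sites$aa_pos - 1) * 3 + hot_sites$off
    shift[paste(track$gene_id, track$cds_pos) %in%
            paste(hot_sites$gene_id, hot_sites$cds_pos)] <- config$rs_delta
  }
  withr::with_seed(stream_seed(seed, "scores"), {
    track$rs_score <- rnorm(nrow(track), config$rs_mean + shift,
                            config$rs_sd)
  })
  track
}

#' Generate random protein-domain intervals
#'
#' Places `n_domains_per_gene` non-overlapping closed intervals per gene
#' (one inside each equal slice of the protein), drawing accessions from a
#' small shared pool so that the same accession recurs across genes.
#'
#' @inheritParams generate_cohort
#' @return A domain tibble (`gene_id`, `domain_acc`, `domain_name`,
#'   `aa_start`, `aa_end`).
#' @export
generate_domains <- function(genes, config, seed = 1) {
  withr::with_seed(stream_seed(seed, "domains"), {
    pool <- sprintf("PF%05d", sample.int(99999, config$domain_pool))
    per_gene <- lapply(seq_len(nrow(genes)), function(i) {
      p_len <- nchar(genes$cds[i]) / 3
      k <- config$n_domains_per_gene
      chunk <- p_len %/% k
      if (chunk < 12) return(NULL)
      starts <- ends <- integer(k)
      for (j in seq_len(k)) {
        d_len <- sample(8:min(60, chunk - 4), 1)
        s0 <- (j - 1) * chunk
        starts[j] <- s0 + sample.int(chunk - d_len, 1)
        ends[j] <- starts[j] + d_len - 1
      }
      acc <- sample(pool, k, replace = FALSE)
      tibble::tibble(gene_id = genes$gene_id[i], domain_acc = acc,
                     domain_name = paste0("dom_", sub("PF", "", acc)),
                     aa_start = starts, aa_end = ends)
    })
    dplyr::bind_rows(per_gene)
  })
}

#' Generate pathogenicity labels for planted hotspots
#'
#' Labels every planted hotspot position pathogenic, flipping each label
#' to `FALSE` independently with `pathogenic_flip_prob`.
#'
#' @inheritParams generate_cohort
#' @return A tibble (`gene_id`, `aa_pos`, `pathogenic`).
#' @export
generate_pathogenicity <- function(planted, config, seed = 1) {
  withr::with_seed(stream_seed(seed, "pathogenicity"), {
    tibble::tibble(
      gene_id = planted$gene_id, aa_pos = planted$aa_pos,
      pathogenic = stats::runif(nrow(planted)) >= config$pathogenic_flip_prob)
  })
}

#' Simulate a complete study: genes, cohorts, scores, domains, labels
#'
#' Runs every generator under per-artifact seed streams derived from one
#' master seed and returns all pipeline inputs together with a
#' ground-truth manifest (planted hotspots with their analytic expected
#' hit counts, the subtype weights, the conservation shift).
#'
#' @param config A [simulate_config()].
#' @param seed Master integer seed.
#' @return A list `genes`, `tumor`, `neutral`, `scores`, `domains`,
#'   `pathogenicity`, `planted`, `manifest`.
#' @export
simulate_study <- function(config = simulate_config(), seed = 1) {
  genes <- generate_genes(config, seed)
  sites <- opportunity_sites(genes)
  planted <- plant_hotspots(genes, config, seed, sites = sites)
  tumor <- generate_cohort(genes, config, "tumor", planted, seed,
                           sites = sites)
  neutral <- generate_cohort(genes, config, "neutral", seed = seed,
                             sites = sites)
  scores <- generate_scores(genes, config, planted, seed)
  domains <- generate_domains(genes, config, seed)
  pathogenicity <- generate_pathogenicity(planted, config, seed)
  manifest <- list(
    seed = seed,
    rng = "Mersenne-Twister via withr::with_seed, one stream per artifact",
    n_genes = config$n_genes,
    tumor_weights = as.list(config$tumor_weights),
    neutral_weights = as.list(config$neutral_weights),
    fold_enrichment = config$fold_enrichment,
    rs_delta = config$rs_delta,
    planted = lapply(seq_len(nrow(planted)), function(i)
      as.list(planted[i, ]))
  )
  list(genes = genes, tumor = tumor, neutral = neutral, scores = scores,
       domains = domains, pathogenicity = pathogenicity, planted = planted,
       manifest = manifest)
}

#' Write a simulated study to a directory
#'
#' Emits exactly the formats the readers consume: `genes.fasta`,
#' `tumor.tsv`, `neutral.tsv`, `scores.tsv`, `domains.tsv`,
#' `pathogenicity.tsv`, plus `manifest.yaml` with the ground truth.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cds_fasta(study$genes, file.path(dir, "genes.fasta"))
  write_mutation_table(study$tumor, file.path(dir, "tumor.tsv"))
  write_mutation_table(study$neutral, file.path(dir, "neutral.tsv"))
  write_score_track(study$scores, file.path(dir, "scores.tsv"))
  write_domain_table(study$domains, file.path(dir, "domains.tsv"))
  readr::write_tsv(tibble::tibble(gene = study$pathogenicity$gene_id,
                                  aa_pos = study$pathogenicity$aa_pos,
                                  pathogenic = study$pathogenicity$pathogenic),
                   file.path(dir, "pathogenicity.tsv"), progress = FALSE)
  yaml::write_yaml(study$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
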