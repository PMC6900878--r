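test_that("opportunity counts match a brute-force mutate-and-retranslate", {
  # GGG codon away from any CpG neighbour: pos3 G->A is a transition,
  # G->C / G->T are transversions, all synonymous (Gly is 4-fold)
  genes <- make_genes(g1 = "ATGAAAGGGAAATAA")
  opp <- synonymous_opportunities(genes)
  g3 <- opp[opp$aa_pos == 3, ]
  expect_equal(g3$opp[g3$subtype == "NC_GCts"], 1L)
  expect_equal(g3$opp[g3$subtype == "NC_GCtv"], 2L)

  # Met admits no synonymous change
  expect_false(1 %in% opp$aa_pos)

  # random gene: totals equal the independent oracle's
  cds <- random_cds(80, seed = 21)
  got <- as.data.frame(synonymous_opportunities(make_genes(g1 = cds)))
  want <- oracle_opportunities(cds)
  got <- got[order(got$aa_pos, got$subtype), c("aa_pos", "subtype", "opp")]
  want <- want[order(want$aa_pos, want$subtype), ]
  expect_equal(got$aa_pos, want$aa_pos)
  expect_equal(got$subtype, want$subtype)
  expect_equal(got$opp, want$opp)
  expect_true(all(got$opp >= 0 & got$opp <= 9))
})

test_that("poisson_tail matches the series oracle and is monotone", {
  expect_equal(poisson_tail(0, 3.0), 1.0)
  lam <- c(0.1, 1, 2.5, 7)
  expect_equal(poisson_tail(1, lam), 1 - exp(-lam), tolerance = 1e-12)
  for (k in c(2, 5, 12)) {
    for (l in lam) {
      expect_equal(poisson_tail(k, l), oracle_poisson_tail(k, l),
                   tolerance = 1e-12)
    }
  }
  # non-increasing in k, non-decreasing in lam
  expect_true(all(diff(poisson_tail(0:10, 2)) <= 0))
  expect_true(all(diff(poisson_tail(3, seq(0.1, 5, by = 0.1))) >= 0))
  expect_error(poisson_tail(2, -1), "non-negative")
  expect_error(poisson_tail(-1, 1), "non-negative")
})

test_that("fisher_combine matches the even-df chi-squared closed form", {
  expect_equal(fisher_combine(c(1, 1, 1)), 1.0)
  for (p in c(0.9, 0.3, 0.01)) {
    expect_equal(fisher_combine(p), p, tolerance = 1e-12) # single-p identity
  }
  chi <- -2 * (log(0.05) + log(0.05))
  expect_equal(fisher_combine(c(0.05, 0.05)),
               oracle_chisq_sf_even(chi, 4), tolerance = 1e-12)

  # permutation-invariant; monotone in each argument
  p <- c(0.2, 0.8, 0.05)
  expect_equal(fisher_combine(p), fisher_combine(rev(p)))
  expect_lt(fisher_combine(c(0.1, 0.5)), fisher_combine(c(0.2, 0.5)))
  expect_error(fisher_combine(c(0, 0.5)), "floor")
  expect_error(fisher_combine(numeric(0)), "no p-values")
})

test_that("BH adjustment reproduces the hand-executed step-up", {
  # p * n / rank = (.04, .04, .04, .04) after monotonicity
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # order restored to input order
  expect_equal(bh_fdr(c(0.04, 0.01, 0.02, 0.03)), rep(0.04, 4))
})

test_that("background expectations conserve the observed subtype totals", {
  genes <- make_genes(g1 = random_cds(120, seed = 31),
                      g2 = random_cds(60, seed = 32))
  sites <- opportunity_sites(genes)
  withr::local_seed(33)
  idx <- sample(nrow(sites), 400, replace = TRUE)
  muts <- make_muts(sites$gene_id[idx], sites$cds_pos[idx],
                    sites$ref[idx], sites$alt[idx],
                    sample_id = sample(paste0("s", 1:10), 400, replace = TRUE),
                    cancer_type = sample(c("SKCA", "LUAD"), 400,
                                         replace = TRUE))
  ann <- suppressMessages(filter_synonymous(annotate_mutations(muts, genes)))
  bg <- hotspot_background(ann, genes)
  sums <- dplyr::summarise(
    dplyr::group_by(bg, .data$gene_id, .data$cancer_type, .data$subtype),
    lambda_sum = sum(.data$lambda), n_gcs = .data$n_gcs[1],
    .groups = "drop")
  expect_equal(sums$lambda_sum, as.numeric(sums$n_gcs), tolerance = 1e-9)
  # and observed counts decompose the same totals
  obs_sums <- dplyr::summarise(
    dplyr::group_by(bg, .data$gene_id, .data$cancer_type, .data$subtype),
    obs_sum = sum(.data$obs), n_gcs = .data$n_gcs[1], .groups = "drop")
  expect_equal(obs_sums$obs_sum, obs_sums$n_gcs)
})

test_that("an extreme single-position pile-up is reported", {
  genes <- make_genes(g1 = random_cds(102, seed = 41))
  sites <- opportunity_sites(genes)
  # background: one mutation at each of 100 distinct positions
  withr::local_seed(42)
  spread_pos <- sites[!duplicated(sites$aa_pos), ]
  spread_pos <- spread_pos[seq_len(min(100, nrow(spread_pos))), ]
  # pile-up: 15 recurrences of one opportunity
  hot <- sites[sites$aa_pos == spread_pos$aa_pos[5], ][1, ]
  pile <- hot[rep(1, 15), ]
  all_sites <- rbind(spread_pos, pile)
  muts <- make_muts(all_sites$gene_id, all_sites$cds_pos, all_sites$ref,
                    all_sites$alt,
                    sample_id = paste0("s", seq_len(nrow(all_sites))))
  ann <- suppressMessages(filter_synonymous(annotate_mutations(muts, genes)))
  calls <- suppressMessages(call_hotspots(ann, genes))
  rep_pos <- calls$aa_pos[calls$reported]
  expect_true(hot$aa_pos %in% rep_pos)

  # uniform mutations, one per position: nothing is even tested
  muts_null <- make_muts(spread_pos$gene_id, spread_pos$cds_pos,
                         spread_pos$ref, spread_pos$alt,
                         sample_id = paste0("s", seq_len(nrow(spread_pos))))
  ann_null <- suppressMessages(filter_synonymous(
    annotate_mutations(muts_null, genes)))
  calls_null <- suppressMessages(call_hotspots(ann_null, genes))
  expect_equal(sum(calls_null$reported), 0L)
  expect_equal(attr(calls_null, "n_tested"), 0L)
})

test_that("the pathogenicity filter gates reporting after the statistics", {
  genes <- make_genes(g1 = random_cds(102, seed = 51))
  sites <- opportunity_sites(genes)
  spread <- sites[!duplicated(sites$aa_pos), ][1:80, ]
  hot <- sites[sites$aa_pos == spread$aa_pos[7], ][1, ]
  rows <- rbind(spread, hot[rep(1, 15), ])
  muts <- make_muts(rows$gene_id, rows$cds_pos, rows$ref, rows$alt,
                    sample_id = paste0("s", seq_len(nrow(rows))))
  ann <- suppressMessages(filter_synonymous(annotate_mutations(muts, genes)))

  labels_yes <- tibble::tibble(gene_id = "g1", aa_pos = hot$aa_pos,
                               pathogenic = TRUE)
  labels_no <- dplyr::mutate(labels_yes, pathogenic = FALSE)
  with_yes <- suppressMessages(call_hotspots(ann, genes,
                                             pathogenicity = labels_yes))
  with_no <- suppressMessages(call_hotspots(ann, genes,
                                            pathogenicity = labels_no))
  expect_true(hot$aa_pos %in% with_yes$aa_pos[with_yes$reported])
  expect_false(hot$aa_pos %in% with_no$aa_pos[with_no$reported])
  # the statistics themselves are unchanged by the filter
  expect_equal(with_yes$q, with_no$q)
})

test_that("alpha = 1 with min_count = 1 reports every tested position", {
  genes <- make_genes(g1 = random_cds(40, seed = 61))
  sites <- opportunity_sites(genes)
  rows <- sites[!duplicated(sites$aa_pos), ][1:10, ]
  muts <- make_muts(rows$gene_id, rows$cds_pos, rows$ref, rows$alt)
  ann <- suppressMessages(filter_synonymous(annotate_mutations(muts, genes)))
  calls <- suppressMessages(call_hotspots(ann, genes, alpha = 1,
                                          min_count = 1))
  expect_equal(attr(calls, "n_tested"), 10L)
  expect_true(all(calls$reported))
})

test_that("tidy and glance summarise a call set", {
  genes <- make_genes(g1 = random_cds(102, seed = 71))
  sites <- opportunity_sites(genes)
  hot <- sites[sites$aa_pos == 9, ][1, ]
  spread <- sites[!duplicated(sites$aa_pos), ][1:60, ]
  rows <- rbind(spread, hot[rep(1, 12), ])
  muts <- make_muts(rows$gene_id, rows$cds_pos, rows$ref, rows$alt,
                    sample_id = paste0("s", seq_len(nrow(rows))))
  ann <- suppressMessages(filter_synonymous(annotate_mutations(muts, genes)))
  calls <- suppressMessages(call_hotspots(ann, genes))
  td <- tidy(calls)
  expect_true(all(c("gene_id", "aa_pos", "p_combined", "q", "reported")
                  %in% names(td)))
  expect_equal(td$q, sort(td$q)) # ordered by q
  gl <- glance(calls)
  expect_equal(gl$n_reported, sum(calls$reported))
  expect_equal(gl$n_tested, attr(calls, "n_tested"))
})
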