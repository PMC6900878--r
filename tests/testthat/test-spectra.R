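syn_fixture <- function(n_per_group, patterns, groups) {
  # hand-built annotated rows: only the columns the spectra need
  rows <- do.call(rbind, lapply(seq_along(groups), function(i) {
    data.frame(sample_id = paste0(groups[i], "_s", seq_len(n_per_group[i])),
               cancer_type = groups[i],
               pattern = patterns[[i]],
               codon_pos = 3L, aa = "L", synonymous = TRUE)
  }))
  tibble::as_tibble(rows)
}

test_that("pattern proportions and the All average row behave as defined", {
  one <- syn_fixture(10, list(rep("C>T", 10)), "SKCA")
  sp <- pattern_spectrum(one)
  expect_equal(sp$prop[sp$group == "SKCA" & sp$pattern == "C>T"], 1)
  expect_equal(sum(sp$prop[sp$group == "SKCA"]), 1)

  # two groups at 0.4 and 0.6 for C>T -> All = 0.5 (unweighted mean)
  two <- syn_fixture(c(10, 20),
                     list(c(rep("C>T", 4), rep("G>A", 6)),
                          c(rep("C>T", 12), rep("G>A", 8))),
                     c("A1", "B1"))
  sp2 <- pattern_spectrum(two)
  expect_equal(sp2$prop[sp2$group == "All" & sp2$pattern == "C>T"], 0.5)

  # proportions are invariant to row order and sample relabeling
  shuf <- two[sample.int(nrow(two)), ]
  shuf$sample_id <- paste0("x", seq_len(nrow(shuf)))
  expect_equal(pattern_spectrum(shuf), sp2)

  expect_error(pattern_spectrum(dplyr::mutate(one, synonymous = FALSE)),
               "synonymous")
})

test_that("realized proportions track multinomial generating weights", {
  withr::local_seed(202)
  w <- c("C>T" = 0.5, "G>A" = 0.25, "T>C" = 0.15, "A>G" = 0.1)
  n <- 4000
  draws <- sample(names(w), n, replace = TRUE, prob = w)
  ann <- tibble::tibble(sample_id = "s1", cancer_type = "CT",
                        pattern = draws, codon_pos = 3L, aa = "L",
                        synonymous = TRUE)
  sp <- pattern_spectrum(ann, include_all = FALSE)
  for (p in names(w)) {
    se <- sqrt(w[p] * (1 - w[p]) / n)
    expect_lt(abs(sp$prop[sp$pattern == p] - w[p]), 3 * se)
  }
})

test_that("the codon-position split refines the pattern spectrum", {
  ann <- tibble::tibble(
    sample_id = "s", cancer_type = "CT",
    pattern = c("C>T", "C>T", "T>C", "A>C"),
    codon_pos = c(3L, 3L, 1L, 3L), aa = "L", synonymous = TRUE)
  split <- pattern_spectrum(ann, by_codon_pos = TRUE)
  flat <- pattern_spectrum(ann, include_all = FALSE)
  recovered <- dplyr::summarise(
    dplyr::group_by(split, .data$group, .data$pattern),
    prop = sum(.data$prop), .groups = "drop")
  expect_equal(dplyr::arrange(recovered, pattern)$prop,
               dplyr::arrange(flat, pattern)$prop)

  bad <- dplyr::mutate(ann, codon_pos = c(3L, 2L, 1L, 3L))
  expect_error(pattern_spectrum(bad, by_codon_pos = TRUE), "position 1 or 3")
})

test_that("per-sample load divides mutations by observed samples", {
  muts <- tibble::tibble(sample_id = c("a", "a", "b", "b", "c", "c"),
                         cancer_type = "CT")
  expect_equal(per_sample_load(muts)$per_sample_mean, 2)

  # Poisson(100) per-sample counts: mean load within 3 SE of 100
  withr::local_seed(77)
  n_samp <- 60
  counts <- rpois(n_samp, 100)
  muts2 <- tibble::tibble(
    sample_id = rep(paste0("s", seq_len(n_samp)), counts),
    cancer_type = "CT")
  load <- per_sample_load(muts2)
  se <- sqrt(100 / n_samp)
  expect_lt(abs(load$per_sample_mean - 100), 3 * se)
})

test_that("one-sample t-test matches the closed form and its edge cases", {
  r <- one_sample_ttest(c(1, 2, 3), 2)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r2 <- one_sample_ttest(c(1, 2, 3), 0)
  expect_equal(r2$statistic, oracle_t1(c(1, 2, 3), 0))
  expect_equal(r2$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r2$df, 2)

  expect_error(one_sample_ttest(c(2, 2, 2), 2), "zero variance")
  expect_error(one_sample_ttest(1, 0), "at least two")
})

test_that("amino-acid and degeneracy spectra cover the degenerate alphabet", {
  ann <- tibble::tibble(sample_id = "s", cancer_type = "CT",
                        pattern = "C>T", codon_pos = 3L,
                        aa = c("L", "L", "A", "K"), synonymous = TRUE)
  sp <- aa_spectrum(ann)
  expect_equal(nrow(sp), 18L)
  expect_equal(sum(sp$prop), 1)
  expect_equal(sp$prop[sp$aa == "L"], 0.5)
  expect_false(any(c("M", "W") %in% sp$aa))
  expect_error(aa_spectrum(dplyr::mutate(ann, aa = "M")), "Met or Trp")

  dg <- degeneracy_spectrum(ann)
  expect_equal(sort(dg$degeneracy), c(2L, 3L, 4L, 6L))
  expect_equal(sum(dg$prop), 1)
  expect_equal(dg$prop[dg$degeneracy == 6], 0.5) # L
  expect_equal(dg$prop[dg$degeneracy == 2], 0.25) # K
})

test_that("degeneracy correlation is 1 for proportional counts, errors flat", {
  tab <- codon_table()
  degen <- tab$degeneracy[tab$degeneracy >= 2]
  # counts exactly proportional to codon number
  ann <- tibble::tibble(
    sample_id = "s", cancer_type = "CT", pattern = "C>T", codon_pos = 3L,
    aa = rep(names(degen), degen), synonymous = TRUE)
  expect_equal(degeneracy_correlation(ann)$r_squared, 1)

  flat <- tibble::tibble(
    sample_id = "s", cancer_type = "CT", pattern = "C>T", codon_pos = 3L,
    aa = names(degen), synonymous = TRUE)
  expect_error(degeneracy_correlation(flat), "constant")
})

test_that("degeneracy correlation degrades monotonically with noise", {
  tab <- codon_table()
  degen <- tab$degeneracy[tab$degeneracy >= 2]
  r2_at_noise <- vapply(c(0, 2, 20), function(noise) {
    withr::with_seed(55, {
      w <- degen + noise * stats::runif(18)
      n <- 3000
      aa <- sample(names(degen), n, replace = TRUE, prob = w)
      ann <- tibble::tibble(sample_id = "s", cancer_type = "CT",
                            pattern = "C>T", codon_pos = 3L, aa = aa,
                            synonymous = TRUE)
      degeneracy_correlation(ann)$r_squared
    })
  }, double(1))
  expect_true(all(diff(r2_at_noise) < 0))
  expect_gt(r2_at_noise[1], 0.95)
})

test_that("per-pattern t-tests against a reference cohort run per pattern", {
  withr::local_seed(9)
  groups <- paste0("ct", 1:6)
  pats <- substitution_patterns()
  w <- stats::setNames(rep(1, 12), pats)
  w["C>T"] <- 12 # strongly C>T-biased cohort
  ann <- tibble::tibble(
    sample_id = "s", cancer_type = rep(groups, each = 200),
    pattern = unlist(lapply(groups, function(g)
      sample(pats, 200, replace = TRUE, prob = w))),
    codon_pos = 3L, aa = "L", synonymous = TRUE)
  props <- pattern_spectrum(ann)
  ref <- tibble::tibble(pattern = pats, prop = 1 / 12)
  res <- pattern_ttest(props, ref)
  expect_equal(nrow(res), 12L)
  ct <- res[res$pattern == "C>T", ]
  expect_equal(ct$hypothetical, 1 / 12)
  expect_lt(ct$p_value, 0.05) # groups center near 0.5, far from 1/12
})
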