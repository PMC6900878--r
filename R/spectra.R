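assert_synonymous <- function(ann) {
  stopifnot(is.data.frame(ann))
  if (!all(c("pattern", "aa", "synonymous") %in% names(ann))) {
    stop("expected annotated mutations (see annotate_mutations())",
         call. = FALSE)
  }
  if (any(!ann$synonymous) || any(ann$aa == "*")) {
    stop("spectrum summaries are defined on synonymous sense mutations; ",
         "apply filter_synonymous() first", call. = FALSE)
  }
  invisible(ann)
}

group_sym <- function(group_by) {
  if (is.null(group_by)) NULL else rlang::sym(group_by)
}

#' Substitution-pattern spectrum per group
#'
#' Proportions of the 12 ordered single-base substitution patterns within
#' each group (cancer type by default), optionally split by codon position.
#' The `"All"` row is the unweighted mean of the per-group proportions, so
#' that small and large groups contribute equally to the cohort-level
#' signature.
#'
#' @param ann Annotated synonymous mutations.
#' @param group_by Grouping column name (default `"cancer_type"`).
#' @param by_codon_pos Split proportions by codon position (1 or 3; a
#'   synonymous change at position 2 is impossible and its presence is an
#'   error). Within a group the split proportions sum to the unsplit ones.
#' @param include_all Append the `"All"` average row (never for the split
#'   spectrum).
#' @return A tibble `group`, (`codon_pos`,) `pattern`, `n`, `prop`.
#' @export
pattern_spectrum <- function(ann, group_by = "cancer_type",
                             by_codon_pos = FALSE, include_all = TRUE) {
  assert_synonymous(ann)
  g <- group_sym(group_by)
  pats <- substitution_patterns()
  if (by_codon_pos) {
    if (!all(ann$codon_pos %in% c(1L, 3L))) {
      stop("synonymous changes must lie at codon position 1 or 3",
           call. = FALSE)
    }
    counts <- dplyr::count(ann, group = !!g, .data$codon_pos, .data$pattern)
    counts <- tidyr::complete(counts, .data$group,
                              codon_pos = c(1L, 3L), pattern = pats,
                              fill = list(n = 0L))
    out <- dplyr::mutate(dplyr::group_by(counts, .data$group),
                         prop = .data$n / sum(.data$n))
    return(dplyr::ungroup(out))
  }
  counts <- dplyr::count(ann, group = !!g, .data$pattern)
  counts <- tidyr::complete(counts, .data$group, pattern = pats,
                            fill = list(n = 0L))
  out <- dplyr::ungroup(
    dplyr::mutate(dplyr::group_by(counts, .data$group),
                  prop = .data$n / sum(.data$n)))
  if (include_all) {
    all_row <- dplyr::summarise(dplyr::group_by(out, .data$pattern),
                                n = sum(.data$n), prop = mean(.data$prop),
                                .groups = "drop")
    all_row$group <- "All"
    out <- dplyr::bind_rows(out, all_row[names(out)])
  }
  out
}

#' Amino-acid spectrum of synonymous mutations
#'
#' Proportions of mutations per amino acid over the 18 degenerate amino
#' acids (methionine and tryptophan have a single codon, admit no
#' synonymous change, and must be absent).
#'
#' @param ann Annotated synonymous mutations.
#' @param group_by Optional grouping column name (`NULL` for one overall
#'   spectrum).
#' @param table A [codon_table()].
#' @return A tibble (`group`,) `aa`, `degeneracy`, `n`, `prop`.
#' @export
aa_spectrum <- function(ann, group_by = NULL, table = codon_table()) {
  assert_synonymous(ann)
  if (any(ann$aa %in% c("M", "W"))) {
    stop("synonymous mutations cannot occur at Met or Trp", call. = FALSE)
  }
  degen_aa <- sort(names(table$degeneracy[table$degeneracy >= 2]))
  g <- group_sym(group_by)
  counts <- if (is.null(g)) {
    dplyr::count(dplyr::mutate(ann, group = "all"), .data$group, .data$aa)
  } else {
    dplyr::count(ann, group = !!g, .data$aa)
  }
  counts <- tidyr::complete(counts, .data$group, aa = degen_aa,
                            fill = list(n = 0L))
  out <- dplyr::ungroup(
    dplyr::mutate(dplyr::group_by(counts, .data$group),
                  prop = .data$n / sum(.data$n)))
  out$degeneracy <- unname(table$degeneracy[out$aa])
  if (is.null(g)) out$group <- NULL
  out
}

#' Degeneracy-class spectrum of synonymous mutations
#'
#' Proportions of mutations falling at amino acids of each degeneracy class
#' (2-, 3-, 4- or 6-fold degenerate codon families).
#'
#' @inheritParams aa_spectrum
#' @return A tibble (`group`,) `degeneracy`, `n`, `prop`.
#' @export
degeneracy_spectrum <- function(ann, group_by = NULL, table = codon_table()) {
  assert_synonymous(ann)
  g <- group_sym(group_by)
  x <- dplyr::mutate(ann, degeneracy = unname(table$degeneracy[.data$aa]))
  counts <- if (is.null(g)) {
    dplyr::count(dplyr::mutate(x, group = "all"), .data$group,
                 .data$degeneracy)
  } else {
    dplyr::count(x, group = !!g, .data$degeneracy)
  }
  counts <- tidyr::complete(counts, .data$group,
                            degeneracy = c(2L, 3L, 4L, 6L),
                            fill = list(n = 0L))
  out <- dplyr::ungroup(
    dplyr::mutate(dplyr::group_by(counts, .data$group),
                  prop = .data$n / sum(.data$n)))
  if (is.null(g)) out$group <- NULL
  out
}

#' Mean mutation load per sample
#'
#' Total mutations divided by the number of distinct samples observed in
#' the table, per group. Samples with zero mutations do not appear in a
#' mutation table and therefore cannot enter the denominator.
#'
#' @param muts A mutation or annotated-mutation tibble with `sample_id`.
#' @param group_by Grouping column name (default `"cancer_type"`).
#' @return A tibble `group`, `n_mutations`, `n_samples`, `per_sample_mean`.
#' @export
per_sample_load <- function(muts, group_by = "cancer_type") {
  g <- group_sym(group_by)
  dplyr::summarise(
    dplyr::group_by(muts, group = !!g),
    n_mutations = dplyr::n(),
    n_samples = dplyr::n_distinct(.data$sample_id),
    per_sample_mean = dplyr::n() / dplyr::n_distinct(.data$sample_id),
    .groups = "drop")
}

#' One-sample t-test against a hypothetical mean
#'
#' Classical one-sample t-test of a vector of per-group proportions against
#' a fixed hypothetical value (such as the neutral cohort's mean proportion
#' of the same substitution), two-sided.
#'
#' @param x Numeric vector (at least two values, non-zero variance).
#' @param mu The hypothetical mean.
#' @return A one-row tibble `estimate`, `statistic`, `df`, `p_value`.
#' @export
one_sample_ttest <- function(x, mu) {
  if (length(x) < 2) stop("need at least two values", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("zero variance across groups; the t statistic is undefined",
         call. = FALSE)
  }
  tt <- t.test(x, mu = mu)
  tibble::tibble(estimate = unname(tt$estimate),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value)
}

#' Compare per-group substitution proportions against a reference cohort
#'
#' Runs [one_sample_ttest()] per substitution pattern, using the reference
#' cohort's mean proportion of that pattern as the hypothetical value —
#' the comparison used to contrast a tumor cohort's spectrum against a
#' neutral one.
#'
#' @param props A [pattern_spectrum()] tibble (the `"All"` row is ignored).
#' @param reference A tibble `pattern`, `prop` of reference proportions
#'   (e.g. the neutral cohort's `"All"` row).
#' @return A tibble `pattern`, `hypothetical`, `estimate`, `statistic`,
#'   `df`, `p_value`.
#' @export
pattern_ttest <- function(props, reference) {
  stopifnot(all(c("group", "pattern", "prop") %in% names(props)),
            all(c("pattern", "prop") %in% names(reference)))
  props <- dplyr::filter(props, .data$group != "All")
  ref <- setNames(reference$prop, reference$pattern)
  res <- lapply(split(props, props$pattern), function(d) {
    mu <- unname(ref[d$pattern[1]])
    cbind(tibble::tibble(pattern = d$pattern[1], hypothetical = mu),
          one_sample_ttest(d$prop, mu))
  })
  tibble::as_tibble(do.call(rbind, res))
}

#' Correlation between amino-acid mutation percentages and codon counts
#'
#' Pearson correlation, over the 18 degenerate amino acids, between the
#' percentage of synonymous mutations at each amino acid and the number of
#' codons encoding it.
#'
#' @inheritParams aa_spectrum
#' @return A one-row tibble `r`, `r_squared`.
#' @export
degeneracy_correlation <- function(ann, table = codon_table()) {
  sp <- aa_spectrum(ann, group_by = NULL, table = table)
  if (stats::sd(sp$prop) == 0) {
    stop("amino-acid percentages are constant; correlation undefined",
         call. = FALSE)
  }
  r <- cor(sp$prop, sp$degeneracy)
  tibble::tibble(r = r, r_squared = r^2)
}
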