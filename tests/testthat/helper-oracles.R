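# Independent oracles and tiny fixtures shared across tests.
# These deliberately avoid the package's own code paths (and, for the
# statistical kernels, the distribution functions the package calls).

# upper Poisson tail by direct term-by-term series summation
oracle_poisson_tail <- function(k, lam) {
  if (k == 0) return(1)
  if (lam == 0) return(0)
  term <- exp(-lam + k * log(lam) - lgamma(k + 1))
  total <- 0
  i <- k
  while (term > 1e-18 * (1 + total) || i < k + 10) {
    total <- total + term
    term <- term * lam / (i + 1)
    i <- i + 1
    if (i > k + 1e6) break
  }
  min(total, 1)
}

# chi-squared survival function for even df = 2m, closed (Erlang) form
oracle_chisq_sf_even <- function(x, df) {
  stopifnot(df %% 2 == 0)
  m <- df / 2
  j <- 0:(m - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

# closed-form one-sample t statistic
oracle_t1 <- function(x, mu) (mean(x) - mu) / (sd(x) / sqrt(length(x)))

# brute-force synonymous-opportunity census for one gene: mutate every
# site to every alternate base, re-translate, classify by hand
oracle_opportunities <- function(cds) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  res <- list()
  for (pos in seq_len(nchar(cds))) {
    ref <- substr(cds, pos, pos)
    ci <- (pos - 1) %/% 3 + 1
    rc <- substr(cds, (ci - 1) * 3 + 1, ci * 3)
    for (alt in setdiff(bases, ref)) {
      ac <- rc
      substr(ac, (pos - 1) %% 3 + 1, (pos - 1) %% 3 + 1) <- alt
      if (code[rc] != code[ac] || code[rc] == "*") next
      ts <- paste0(ref, alt) %in% c("AG", "GA", "CT", "TC")
      if (ref %in% c("A", "T")) {
        sub <- if (ts) "ATts" else "ATtv"
      } else {
        nxt <- if (pos < nchar(cds)) substr(cds, pos + 1, pos + 1) else ""
        prv <- if (pos > 1) substr(cds, pos - 1, pos - 1) else ""
        cpg <- (ref == "C" && nxt == "G") || (ref == "G" && prv == "C")
        sub <- paste0(if (cpg) "C_" else "NC_", if (ts) "GCts" else "GCtv")
      }
      res[[length(res) + 1]] <- data.frame(aa_pos = ci, subtype = sub)
    }
  }
  df <- do.call(rbind, res)
  aggregate(list(opp = rep(1, nrow(df))), df[c("aa_pos", "subtype")], sum)
}

make_genes <- function(...) {
  cds <- toupper(c(...))
  tibble::tibble(gene_id = if (is.null(names(cds)))
    paste0("g", seq_along(cds)) else names(cds),
    cds = unname(cds), protein_length = nchar(cds) %/% 3L)
}

# a random clean CDS built codon-by-codon, independent of the generator
random_cds <- function(n_codons, seed) {
  withr::with_seed(seed, {
    code <- Biostrings::GENETIC_CODE
    sense <- names(code)[code != "*"]
    paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                        collapse = ""), "TAA")
  })
}

make_muts <- function(gene_id, cds_pos, ref, alt, sample_id = NULL,
                      cancer_type = "SKCA") {
  n <- length(cds_pos)
  tibble::tibble(
    sample_id = sample_id %||% paste0("s", seq_len(n)),
    cancer_type = rep_len(cancer_type, n),
    gene_id = rep_len(gene_id, n),
    cds_pos = as.integer(cds_pos),
    ref = rep_len(ref, n), alt = rep_len(alt, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
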