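# independent oracles and small fixture builders used across test files

# plain-loop indicator value statistic (Dufrene-Legendre single group):
# returns per-taxon list(stat, group)
indval_oracle <- function(counts, groups) {
  glev <- sort(unique(groups))
  t(apply(counts, 1, function(x) {
    a_num <- sapply(glev, function(g) mean(x[groups == g]))
    a <- if (sum(a_num) > 0) a_num / sum(a_num) else rep(0, length(glev))
    b <- sapply(glev, function(g) mean(x[groups == g] > 0))
    iv <- a * b
    c(stat = max(iv), group = unname(which.max(iv)))
  }))
}

# exhaustive permutation p-value over all distinct relabelings
indval_exhaustive_p <- function(counts, groups) {
  obs <- indval_oracle(counts, groups)[, "stat"]
  perms <- unique(combn(seq_along(groups), sum(groups == groups[1]),
                        simplify = FALSE))
  stats <- sapply(perms, function(idx) {
    g <- rep("B", length(groups))
    g[idx] <- "A"
    indval_oracle(counts, g)[, "stat"]
  })
  if (is.null(dim(stats))) stats <- matrix(stats, nrow = 1)
  rowMeans(stats >= obs - 1e-12)
}

# a tiny three-archetype cohort used by several files
small_cohort <- function(seed = 42, n_each = 3, decoy_rate = 0) {
  mix <- stats::setNames(rep(n_each, 3),
                         c("AOA_prototroph", "SAR11_HMP_aux",
                           "Flavobacteria_salvage"))
  generate_genome_set(mix, seed = seed, decoy_rate = decoy_rate)
}

# run the annotate -> genotype chain on an in-memory genome set
genotype_cohort <- function(gs, catalog = b1_gene_catalog(),
                            alpha = 0.05) {
  hits <- filter_hits(gs$hits, catalog)
  pm <- build_presence_matrix(hits, catalog, gs$meta$genome_id)
  classify_b1_genotypes(pm, gs$meta, alpha = alpha)
}

# named presence row over the full vocabulary
presence_row <- function(...) {
  v <- c(...)
  stats::setNames(as.numeric(v), names(v))
}

bact_meta <- function(completeness = 1, contamination = 0,
                      domain = "bacteria") {
  data.frame(genome_id = "g1", domain = domain,
             taxonomy = "Bacteria;P;C;O;F", completeness = completeness,
             contamination = contamination, stringsAsFactors = FALSE)
}
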