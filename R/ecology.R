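# amplicon community summaries: relative abundance, diversity,
# dissimilarity + UPGMA clustering, rank tests, indicator species analysis

#' Relative abundance per sample
#'
#' Normalizes a taxa-by-samples count matrix to per-sample proportions,
#' optionally collapsing rows that share a taxonomy prefix at a given rank
#' before normalizing.
#'
#' @param counts Numeric matrix (taxa x samples), non-negative.
#' @param taxonomy Optional character vector of semicolon-delimited
#'   taxonomy strings, one per row of `counts` (required when collapsing).
#' @param collapse_rank Optional 1-based rank index at which to collapse.
#' @return Matrix of proportions; every column sums to one.
#' @export
relative_abundance <- function(counts, taxonomy = NULL,
                               collapse_rank = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(collapse_rank)) {
    if (is.null(taxonomy)) stop("taxonomy required to collapse")
    ranks <- strsplit(taxonomy, ";", fixed = TRUE)
    grp <- vapply(ranks, function(r) {
      paste(trimws(r[seq_len(min(collapse_rank, length(r)))]),
            collapse = ";")
    }, character(1))
    counts <- rowsum(counts, grp)
  }
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    stop("all-zero sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(counts, 2, totals, "/")
}

#' Remove chloroplast-classified taxa
#'
#' @param counts Taxa-by-samples count matrix.
#' @param taxonomy Taxonomy strings, one per row.
#' @return The count matrix without rows whose taxonomy contains
#'   "chloroplast" (case-insensitive).
#' @export
drop_chloroplast_asvs <- function(counts, taxonomy) {
  keep <- !grepl("chloroplast", taxonomy, ignore.case = TRUE)
  counts[keep, , drop = FALSE]
}

#' Shannon diversity index
#'
#' `H = -sum(p * log(p))` over nonzero entries, natural log by default.
#'
#' @param proportions Numeric vector of proportions summing to one
#'   (tolerance 1e-9).
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon index, in `[0, log(richness)]`.
#' @export
shannon_index <- function(proportions, base = exp(1)) {
  if (any(proportions < 0)) stop("proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1")
  }
  p <- proportions[proportions > 0]
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity
#'
#' `BC = 1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`.
#'
#' @param x,y Non-negative abundance vectors of equal length, not both
#'   all-zero.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("Bray-Curtis undefined for two all-zero vectors")
  1 - 2 * sum(pmin(x, y)) / tot
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' @param counts Taxa-by-samples abundance matrix.
#' @return Symmetric samples-by-samples dissimilarity matrix.
#' @export
bray_curtis_matrix <- function(counts) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- bray_curtis(counts[, i], counts[, j])
    }
  }
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerates the pair of clusters with the smallest arithmetic mean of
#' the original pairwise dissimilarities between their members. Ties are
#' broken deterministically by the lexicographically smallest pair of
#' smallest member labels. The result is also a valid `hclust` object, so
#' `plot()` and `cutree()` work; [as_newick()] exports an ultrametric
#' Newick string in which leaf-to-node path lengths equal half the merge
#' heights.
#'
#' @param d Symmetric numeric matrix with zero diagonal and non-negative
#'   entries; dimnames supply the sample labels.
#' @param tol Tolerance for the symmetry check (default 1e-9).
#' @return Object of class `c("upgma_tree", "hclust")` with `merge`,
#'   `height`, `order`, `labels`.
#' @export
average_linkage <- function(d, tol = 1e-9) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d)) stop("dissimilarity matrix must be square")
  if (n < 2) stop("need at least two samples")
  if (max(abs(d - t(d))) > tol) stop("dissimilarity matrix is asymmetric")
  if (any(d < 0)) stop("dissimilarities must be non-negative")
  if (any(abs(diag(d)) > tol)) stop("diagonal must be zero")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("S", seq_len(n))

  # active clusters: list of member indices; id: hclust code
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)
  min_label <- labels
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(members)
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        h <- mean(d[members[[i]], members[[j]]])
        lab <- sort(c(min_label[i], min_label[j]))
        cand <- list(i = i, j = j, h = h, lab = lab)
        if (is.null(best) || h < best$h - tol ||
            (abs(h - best$h) <= tol &&
             (lab[1] < best$lab[1] ||
              (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- cand
        }
      }
    }
    a <- ids[best$i]; b <- ids[best$j]
    merge[step, ] <- sort(c(a, b))
    height[step] <- best$h
    members[[best$i]] <- c(members[[best$i]], members[[best$j]])
    min_label[best$i] <- min(min_label[best$i], min_label[best$j])
    ids[best$i] <- step
    members[[best$j]] <- NULL
    ids <- ids[-best$j]
    min_label <- min_label[-best$j]
  }
  tree <- list(merge = merge, height = height,
               order = tree_leaf_order(merge), labels = labels,
               method = "average", call = match.call(),
               dist.method = "user-supplied")
  class(tree) <- c("upgma_tree", "hclust")
  tree
}

tree_leaf_order <- function(merge) {
  leaves <- function(node) {
    if (node < 0) return(-node)
    c(leaves(merge[node, 1]), leaves(merge[node, 2]))
  }
  leaves(nrow(merge))
}

#' Export a UPGMA tree as a Newick string
#'
#' Branch lengths are differences of half merge heights, so root-to-leaf
#' path lengths equal half the root height (the ultrametric convention for
#' UPGMA dendrograms).
#'
#' @param tree Object from [average_linkage()].
#' @param digits Significant digits for branch lengths.
#' @return Newick string terminated by `;`.
#' @export
as_newick <- function(tree, digits = 10) {
  fmt <- function(x) format(x, digits = digits, trim = TRUE,
                            scientific = FALSE)
  node_str <- function(node, parent_h) {
    if (node < 0) {
      paste0(tree$labels[-node], ":", fmt(parent_h / 2))
    } else {
      h <- tree$height[node]
      paste0("(", node_str(tree$merge[node, 1], h), ",",
             node_str(tree$merge[node, 2], h), "):",
             fmt((parent_h - h) / 2))
    }
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  paste0("(", node_str(tree$merge[root, 1], h), ",",
         node_str(tree$merge[root, 2], h), ");")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA (average linkage) clustering of", length(x$labels),
      "samples\n")
  cat("Merge heights:", paste(signif(x$height, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Rank-based group comparison tests
#'
#' Thin wrapper over [stats::kruskal.test()] and [stats::wilcox.test()]
#' (two-sided, asymptotic null with mid-rank tie correction). Degenerate
#' input in which every value is identical returns statistic 0 and p-value
#' 1 for either test.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length as `values`.
#' @param test `"kruskal_wallis"` (>= 2 groups) or `"wilcoxon_rank_sum"`
#'   (exactly 2 groups).
#' @return List with `statistic` and `p_value`.
#' @export
grouped_rank_test <- function(values, groups,
                              test = c("kruskal_wallis",
                                       "wilcoxon_rank_sum")) {
  test <- match.arg(test)
  groups <- as.factor(as.character(groups))
  if (any(table(groups) == 0) || nlevels(groups) < 2) {
    stop("each group must contain at least one observation and there ",
         "must be at least two groups")
  }
  if (length(values) != length(groups)) stop("length mismatch")
  if (length(unique(values)) == 1) {
    return(list(statistic = 0, p_value = 1))
  }
  if (test == "kruskal_wallis") {
    res <- stats::kruskal.test(values, groups)
  } else {
    if (nlevels(groups) != 2) {
      stop("wilcoxon_rank_sum requires exactly 2 groups")
    }
    res <- stats::wilcox.test(values[groups == levels(groups)[1]],
                              values[groups == levels(groups)[2]],
                              exact = FALSE, correct = TRUE)
  }
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Indicator species analysis (IndVal)
#'
#' Single-group Dufrene-Legendre indicator values. For taxon i and group j,
#' specificity `A = mean abundance in j / sum over groups of mean
#' abundances` and fidelity `B = fraction of samples of j in which the
#' taxon is present`; the indicator statistic is `max_j A*B` with the
#' maximizing group reported. Significance is assessed by permuting sample
#' group labels (fixed group sizes): `p = (1 + #permuted >= observed) /
#' (1 + n_permutations)`.
#'
#' @param counts Taxa-by-samples abundance matrix.
#' @param groups Group labels, one per sample column.
#' @param n_permutations Number of label permutations (>= 99).
#' @param seed Integer seed; the same seed gives bit-identical output.
#' @return Data frame (`taxon`, `group`, `stat`, `p_value`,
#'   `n_permutations`), one row per taxon.
#' @export
indval <- function(counts, groups, n_permutations = 999, seed = 1) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  if (length(groups) != ncol(counts)) {
    stop("one group label per sample column required")
  }
  glev <- sort(unique(groups))
  if (length(glev) < 2) stop("need at least two groups")
  if (n_permutations < 99) {
    stop("n_permutations must be at least 99 for usable p resolution")
  }
  stat_fun <- function(g) {
    gmat <- outer(g, glev, "==") * 1  # samples x groups
    gn <- colSums(gmat)
    means <- counts %*% sweep(gmat, 2, gn, "/")
    tot <- rowSums(means)
    a <- means / ifelse(tot > 0, tot, 1)
    a[tot == 0, ] <- 0
    b <- (counts > 0) %*% sweep(gmat, 2, gn, "/")
    a * b
  }
  obs <- stat_fun(groups)
  best <- apply(obs, 1, which.max)
  obs_stat <- obs[cbind(seq_len(nrow(obs)), best)]

  exceed <- integer(nrow(counts))
  run_seeded(seed, {
    for (p in seq_len(n_permutations)) {
      perm <- stat_fun(sample(groups))
      perm_max <- do.call(pmax, as.data.frame(perm))
      exceed <- exceed + (perm_max >= obs_stat - 1e-12)
    }
  })
  data.frame(taxon = if (is.null(rownames(counts)))
               paste0("taxon", seq_len(nrow(counts))) else rownames(counts),
             group = glev[best],
             stat = unname(obs_stat),
             p_value = (1 + exceed) / (1 + n_permutations),
             n_permutations = n_permutations,
             stringsAsFactors = FALSE)
}

# evaluate expr under a fixed RNG state, restoring the caller's stream
run_seeded <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Assign a pelagic depth layer
#'
#' Epipelagic (0-200 m), mesopelagic (200-1000 m), bathypelagic (> 1000 m);
#' boundary depths belong to the shallower layer.
#'
#' @param depth_m Numeric depths in meters (>= 0).
#' @return Character vector of layer labels.
#' @export
assign_depth_layer <- function(depth_m) {
  if (any(depth_m < 0)) stop("depth must be non-negative")
  ifelse(depth_m <= 200, "epipelagic",
         ifelse(depth_m <= 1000, "mesopelagic", "bathypelagic"))
}

#' Prototroph share of relative amplicon abundance
#'
#' Summed relative abundance per sample of taxa whose genotype maps to
#' PROTOTROPH. Taxa not present in the map are kept in the denominator
#' (the proportions) but excluded from the numerator.
#'
#' @param rel_abundance Taxa-by-samples matrix of proportions.
#' @param genotype_map Named character vector mapping taxon to genotype
#'   category.
#' @return Named numeric vector, one share in \[0, 1\] per sample.
#' @export
prototroph_share <- function(rel_abundance, genotype_map) {
  cats <- genotype_map[rownames(rel_abundance)]
  proto <- !is.na(cats) & cats == "PROTOTROPH"
  colSums(rel_abundance[proto, , drop = FALSE])
}
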