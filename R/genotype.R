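# B1 genotype classification with incompleteness-aware confidence

B1_CATEGORIES <- c("PROTOTROPH", "AUX_HMP", "AUX_HET", "AUX_DUAL",
                   "SALVAGE_ONLY", "NO_PATHWAY", "INDETERMINATE")

#' Probability that absent genes are unobserved by incompleteness alone
#'
#' Under a model in which each encoded gene is recovered in the assembly
#' independently with probability equal to the genome's completeness, the
#' chance that `k_absent` encoded genes are all missing from the assembly is
#' `(1 - completeness)^k_absent`. This is the confidence weight used to
#' decide whether a gene-absence call on a MAG is trustworthy.
#'
#' @param completeness Estimated genome completeness, fraction in \[0, 1\].
#' @param k_absent Number of genes called absent (non-negative integer).
#' @return Probability in \[0, 1\]; `1` when `k_absent = 0`.
#' @examples
#' absence_confidence(0.9, 2)  # 0.01
#' @export
absence_confidence <- function(completeness, k_absent) {
  if (any(!is.finite(completeness)) ||
      any(completeness < 0) || any(completeness > 1)) {
    stop("completeness must lie in [0, 1]")
  }
  if (any(k_absent < 0) || any(k_absent != round(k_absent))) {
    stop("k_absent must be a non-negative integer")
  }
  (1 - completeness)^k_absent
}

#' Classify the B1 genotype of one genome
#'
#' Classification follows the three-function rule for de novo thiamine
#' biosynthesis: the pyrimidine branch (PYR: `thiC`), the thiazole branch
#' (THZ: `thiG` or `thi4`), and the condensation step (CND: `thiE`, or
#' `thiDN` for archaea). A genome carrying all three functions is a
#' tentative PROTOTROPH; missing PYR only gives a pyrimidine (HMP) auxotroph,
#' missing THZ only a thiazole (HET) auxotroph, missing both a dual
#' auxotroph. Without the condensation step the genome is SALVAGE_ONLY if it
#' carries salvage or transporter genes (`thiL`, `thiM`, `tenA`, `thiD`, or
#' any thiamine/precursor transporter), else NO_PATHWAY.
#'
#' Any category that asserts gene absence is trusted only if the absence is
#' unlikely to be an assembly artifact: `p_chance`, the probability under
#' [absence_confidence()] that all missing synthesis functions are
#' unobserved due to incompleteness alone, must be strictly below `alpha`;
#' otherwise the call is downgraded to INDETERMINATE.
#'
#' @param row Named numeric vector of gene copy counts for one genome
#'   (names restricted to the catalog vocabulary).
#' @param meta One-row data frame (or named list) with at least `genome_id`,
#'   `domain` ("bacteria"/"archaea"), `completeness`, `contamination`.
#' @param alpha Significance level for trusting an absence call
#'   (default 0.05).
#' @param thiDN_archaea_only If `TRUE` (default), `thiDN` satisfies the
#'   condensation step only for archaeal genomes, reflecting the archaeal
#'   thiD-thiN fusion.
#' @return A one-row data frame with fields `genome_id`, `category`,
#'   `absent_required` (comma-joined), `p_chance`, `salvage_flags`,
#'   `chemoautotrophy_flags`, `quality_tier`.
#' @export
classify_b1_genotype <- function(row, meta, alpha = 0.05,
                                 thiDN_archaea_only = TRUE) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  unknown <- setdiff(names(row), GENE_VOCABULARY)
  if (length(unknown) > 0) {
    stop("unknown gene symbol(s) in presence row: ",
         paste(unknown, collapse = ", "))
  }
  meta <- as.list(meta)
  domain <- match.arg(meta$domain, c("bacteria", "archaea"))
  completeness <- as.numeric(meta$completeness)
  contamination <- as.numeric(meta$contamination)

  has <- function(sym) {
    present <- row[names(row) %in% sym]
    length(present) > 0 && any(present > 0)
  }
  cnd_symbols <- if (domain == "archaea" || !thiDN_archaea_only) {
    c("thiE", "thiDN")
  } else "thiE"
  pyr <- has("thiC")
  thz <- has(c("thiG", "thi4"))
  cnd <- has(cnd_symbols)
  salvage_capable <- has(SALVAGE_CAPABLE_SYMBOLS)

  category <- if (pyr && thz && cnd) {
    "PROTOTROPH"
  } else if (!pyr && thz && cnd) {
    "AUX_HMP"
  } else if (pyr && !thz && cnd) {
    "AUX_HET"
  } else if (!pyr && !thz && cnd) {
    "AUX_DUAL"
  } else if (salvage_capable) {
    "SALVAGE_ONLY"
  } else {
    "NO_PATHWAY"
  }

  # symbols that would be needed to complete the de novo pathway; p_chance
  # counts missing *functions* (either thiazole gene would do), not symbols
  absent_syms <- character()
  k_absent <- 0L
  if (!pyr) { absent_syms <- c(absent_syms, "thiC"); k_absent <- k_absent + 1L }
  if (!thz) {
    absent_syms <- c(absent_syms, "thiG", "thi4"); k_absent <- k_absent + 1L
  }
  if (!cnd) {
    absent_syms <- c(absent_syms, cnd_symbols); k_absent <- k_absent + 1L
  }
  if (category == "PROTOTROPH") {
    p_chance <- 0
  } else {
    p_chance <- absence_confidence(completeness, k_absent)
    if (p_chance >= alpha) category <- "INDETERMINATE"
  }

  salvage_flags <- c(
    intersect(c("thiL", "thiM", "tenA", "thiD"),
              names(row)[row > 0]),
    if (has(B1_TRANSPORTER_SYMBOLS)) "transporter"
  )
  quality_tier <- if (completeness >= 0.5 && contamination < 0.05) {
    "high"
  } else if (completeness >= 0.5 && contamination <= 0.10) {
    "medium"
  } else {
    "below_threshold"
  }
  data.frame(genome_id = as.character(meta$genome_id),
             category = category,
             absent_required = paste(absent_syms, collapse = ","),
             p_chance = p_chance,
             salvage_flags = paste(salvage_flags, collapse = ","),
             chemoautotrophy_flags = paste(annotate_chemoautotrophy(row),
                                           collapse = ","),
             quality_tier = quality_tier,
             stringsAsFactors = FALSE)
}

#' Classify all genomes of a presence matrix
#'
#' @param presence Genome-by-gene matrix from [build_presence_matrix()].
#' @param meta Data frame of genome metadata (`genome_id`, `domain`,
#'   `taxonomy`, `completeness`, `contamination`), one row per genome of
#'   `presence`.
#' @inheritParams classify_b1_genotype
#' @return Data frame of calls, one row per genome.
#' @export
classify_b1_genotypes <- function(presence, meta, alpha = 0.05,
                                  thiDN_archaea_only = TRUE) {
  idx <- match(rownames(presence), meta$genome_id)
  if (anyNA(idx)) {
    stop("metadata missing for genome(s): ",
         paste(rownames(presence)[is.na(idx)], collapse = ", "))
  }
  calls <- lapply(seq_len(nrow(presence)), function(i) {
    classify_b1_genotype(presence[i, ], meta[idx[i], , drop = FALSE],
                         alpha = alpha,
                         thiDN_archaea_only = thiDN_archaea_only)
  })
  do.call(rbind, calls)
}

#' Chemoautotrophy marker flags for one genome
#'
#' Flags energy-metabolism and carbon-fixation markers: ammonia oxidation
#' (`amoA`), nitrite oxidation (`nxr`), sulfur oxidation (`aprA`/`aprB`/
#' `dsrA`), and Calvin-Benson-Bassham carbon fixation (`rbcL`).
#'
#' @param row Named numeric vector of gene copy counts.
#' @return Character vector (possibly empty) of flags.
#' @export
annotate_chemoautotrophy <- function(row) {
  unknown <- setdiff(names(row), GENE_VOCABULARY)
  if (length(unknown) > 0) {
    stop("unknown gene symbol(s): ", paste(unknown, collapse = ", "))
  }
  has <- function(sym) {
    present <- row[names(row) %in% sym]
    length(present) > 0 && any(present > 0)
  }
  c(if (has("amoA")) "ammonia_oxidation",
    if (has("nxr")) "nitrite_oxidation",
    if (has(c("aprA", "aprB", "dsrA"))) "sulfur_oxidation",
    if (has("rbcL")) "cbb_fixation")
}

#' Summarize genotype calls by taxon and domain
#'
#' Counts and fractions of each genotype category per taxon at the requested
#' taxonomy rank, within each domain, among genomes passing a quality gate.
#' Fractions are computed within domain so they sum to one per domain.
#'
#' @param calls Data frame from [classify_b1_genotypes()].
#' @param meta Genome metadata data frame (must include `taxonomy` as
#'   semicolon-delimited ranks and `domain`).
#' @param rank 1-based taxonomy rank index to aggregate at, or `NULL` for
#'   domain-level totals only.
#' @param quality Which quality tiers to include: `"medium"` (medium +
#'   high, the default), `"high"`, or `"all"`.
#' @return Data frame with `domain`, `taxon`, `category`, `count`,
#'   `fraction` (fraction within domain).
#' @export
genotype_summary <- function(calls, meta, rank = NULL,
                             quality = c("medium", "high", "all")) {
  quality <- match.arg(quality)
  if (nrow(calls) == 0) {
    return(data.frame(domain = character(), taxon = character(),
                      category = character(), count = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  idx <- match(calls$genome_id, meta$genome_id)
  if (anyNA(idx)) stop("metadata missing for some genomes in calls")
  keep <- switch(quality,
                 all = rep(TRUE, nrow(calls)),
                 medium = calls$quality_tier %in% c("high", "medium"),
                 high = calls$quality_tier == "high")
  calls <- calls[keep, , drop = FALSE]
  idx <- idx[keep]
  if (nrow(calls) == 0) {
    return(data.frame(domain = character(), taxon = character(),
                      category = character(), count = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  domain <- meta$domain[idx]
  taxon <- if (is.null(rank)) {
    rep("all", nrow(calls))
  } else {
    ranks <- strsplit(meta$taxonomy[idx], ";", fixed = TRUE)
    too_shallow <- lengths(ranks) < rank
    if (any(too_shallow)) {
      stop("taxonomy shallower than requested rank for genome(s): ",
           paste(calls$genome_id[too_shallow], collapse = ", "))
    }
    trimws(vapply(ranks, `[[`, character(1), rank))
  }
  tab <- as.data.frame(table(domain = domain, taxon = taxon,
                             category = factor(calls$category,
                                               levels = B1_CATEGORIES)),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "count"
  tab <- tab[tab$count > 0 | TRUE, , drop = FALSE]
  domain_totals <- tapply(tab$count, tab$domain, sum)
  tab$fraction <- tab$count / as.numeric(domain_totals[tab$domain])
  tab <- tab[order(tab$domain, tab$taxon, tab$category), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Read genome metadata
#'
#' Completeness and contamination are accepted either as fractions or as
#' percentages; values above 1 anywhere in a column mean the column is in
#' percent and it is rescaled to fractions.
#'
#' @param path TSV with columns `genome_id`, `domain`, `taxonomy`,
#'   `completeness`, `contamination`.
#' @return Data frame of genome metadata with fractions in \[0, 1\].
#' @export
read_genome_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("genome_id", "domain", "taxonomy", "completeness",
                "contamination")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    stop("genome metadata missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (colname in c("completeness", "contamination")) {
    v <- as.numeric(meta[[colname]])
    if (any(v > 1, na.rm = TRUE)) v <- v / 100
    meta[[colname]] <- v
  }
  meta
}
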