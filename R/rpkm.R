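# ORF-level count normalization (RPKM) and depth-resolved gene/transcript
# profiles

#' Normalize ORF counts to RPKM
#'
#' Reads per kilobase of ORF per million mapped reads:
#' `rpkm = count / ((length_bp / 1000) * (library_size / 1e6))`. Library
#' sizes default to column sums of the count matrix, but externally supplied
#' totals of mapped reads take precedence when available.
#'
#' @param counts Numeric matrix of mapped-read counts (ORFs x samples).
#' @param orf_meta Data frame with `orf_id` and `length_bp` (positive bp)
#'   for every row of `counts`; extra columns (e.g. `genome_id`,
#'   `gene_symbol`, `taxon_class`, `domain`) are carried by downstream
#'   profile functions.
#' @param library_sizes Optional named numeric vector of per-sample library
#'   sizes (total mapped reads); names must cover all columns of `counts`.
#' @return Numeric matrix of RPKM values with the same dimnames as
#'   `counts`; attribute `library_sizes` records the sizes used and
#'   attribute `library_size_source` whether they were `"supplied"` or
#'   `"column_sums"`.
#' @export
compute_rpkm <- function(counts, orf_meta, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  lens <- orf_meta$length_bp[match(rownames(counts), orf_meta$orf_id)]
  if (anyNA(lens)) {
    stop("missing ORF length for: ",
         paste(rownames(counts)[is.na(lens)], collapse = ", "))
  }
  if (any(lens <= 0)) stop("ORF lengths must be positive")
  if (is.null(library_sizes)) {
    library_sizes <- colSums(counts)
    source <- "column_sums"
  } else {
    miss <- setdiff(colnames(counts), names(library_sizes))
    if (length(miss) > 0) {
      stop("library size missing for sample(s): ",
           paste(miss, collapse = ", "))
    }
    library_sizes <- library_sizes[colnames(counts)]
    source <- "supplied"
  }
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0)) {
    stop("library sizes must be positive")
  }
  rpkm <- sweep(counts / (lens / 1000), 2, library_sizes / 1e6, "/")
  attr(rpkm, "library_sizes") <- library_sizes
  attr(rpkm, "library_size_source") <- source
  rpkm
}

#' Depth profile of summed gene RPKM by group
#'
#' Sums RPKM over ORFs annotated with each requested gene symbol within
#' each group (domain, taxon class, or genome). With `group_by = "domain"`
#' the archaea:bacteria RPKM ratio is also reported per sample and symbol
#' (`NA` where the bacterial total is zero).
#'
#' @param rpkm RPKM matrix from [compute_rpkm()].
#' @param orf_meta ORF annotation data frame (`orf_id`, `gene_symbol`, and
#'   the grouping column).
#' @param gene_symbols Non-empty character vector of gene symbols.
#' @param group_by One of `"domain"`, `"taxon_class"`, `"genome"`.
#' @return Long data frame (`sample_id`, `group`, `gene_symbol`, `rpkm`);
#'   with `group_by = "domain"` an attribute `domain_ratio` holds a data
#'   frame (`sample_id`, `gene_symbol`, `archaea_bacteria_ratio`).
#' @export
gene_depth_profile <- function(rpkm, orf_meta,
                               gene_symbols,
                               group_by = c("domain", "taxon_class",
                                            "genome")) {
  group_by <- match.arg(group_by)
  if (length(gene_symbols) == 0) stop("gene_symbols must be non-empty")
  group_col <- switch(group_by, domain = "domain",
                      taxon_class = "taxon_class", genome = "genome_id")
  if (!group_col %in% names(orf_meta)) {
    stop("orf_meta lacks column: ", group_col)
  }
  idx <- match(rownames(rpkm), orf_meta$orf_id)
  sym <- orf_meta$gene_symbol[idx]
  grp <- orf_meta[[group_col]][idx]
  keep <- !is.na(sym) & sym %in% gene_symbols
  groups <- sort(unique(grp[keep]))
  out <- expand.grid(sample_id = colnames(rpkm), group = groups,
                     gene_symbol = sort(unique(gene_symbols)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$rpkm <- 0
  if (any(keep)) {
    sub <- rpkm[keep, , drop = FALSE]
    key <- paste(grp[keep], sym[keep], sep = "\r")
    sums <- rowsum(sub, key)
    hit <- match(paste(out$group, out$gene_symbol, sep = "\r"),
                 rownames(sums))
    pos <- !is.na(hit)
    out$rpkm[pos] <- sums[cbind(hit[pos], match(out$sample_id[pos],
                                                colnames(sums)))]
  }
  if (group_by == "domain") {
    ratio <- unique(out[, c("sample_id", "gene_symbol")])
    g <- function(dom) {
      m <- match(paste(ratio$sample_id, dom, ratio$gene_symbol),
                 paste(out$sample_id, out$group, out$gene_symbol))
      v <- out$rpkm[m]
      v[is.na(v)] <- 0
      v
    }
    arch <- g("archaea"); bact <- g("bacteria")
    ratio$archaea_bacteria_ratio <- ifelse(bact > 0, arch / bact, NA_real_)
    rownames(ratio) <- NULL
    attr(out, "domain_ratio") <- ratio
  }
  out
}

#' Per-group shares of summed thiamine-gene RPKM
#'
#' Within each sample, the share of RPKM summed over the requested gene
#' symbols attributed to each taxon group. Shares sum to one per sample
#' where defined; samples with zero total RPKM over the requested genes get
#' `NA` shares (undefined, not zero).
#'
#' @inheritParams gene_depth_profile
#' @param group_by Column of `orf_meta` to group by (default
#'   `"taxon_class"`).
#' @return Long data frame (`sample_id`, `group`, `share`).
#' @export
transcript_shares <- function(rpkm, orf_meta, gene_symbols,
                              group_by = "taxon_class") {
  prof <- gene_depth_profile(rpkm, orf_meta, gene_symbols,
                             group_by = if (group_by == "genome_id")
                               "genome" else group_by)
  tot_by_group <- rowsum(prof$rpkm, paste(prof$sample_id, prof$group,
                                          sep = "\r"))
  keys <- strsplit(rownames(tot_by_group), "\r", fixed = TRUE)
  out <- data.frame(sample_id = vapply(keys, `[[`, character(1), 1),
                    group = vapply(keys, `[[`, character(1), 2),
                    rpkm = as.numeric(tot_by_group),
                    stringsAsFactors = FALSE)
  sample_tot <- tapply(out$rpkm, out$sample_id, sum)
  denom <- as.numeric(sample_tot[out$sample_id])
  out$share <- ifelse(denom > 0, out$rpkm / denom, NA_real_)
  out$rpkm <- NULL
  out <- out[order(out$sample_id, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}
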