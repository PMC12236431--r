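# end-to-end orchestration from a single config: annotate -> genotype ->
# rpkm/profiles -> ecology -> trc, with a combined JSON summary

#' Build a run configuration
#'
#' @param hits,genome_meta Paths to the hit table and genome metadata
#'   (required for the genotyping stages).
#' @param catalog Optional path to a gene-family catalog TSV (default:
#'   shipped catalog).
#' @param asv_counts,asv_taxonomy,sample_meta Optional paths for the
#'   community-ecology stage (ASV count TSV: first column taxon id,
#'   remaining columns samples; taxonomy TSV: `taxon`, `taxonomy`; sample
#'   TSV: `sample_id`, `depth_m`).
#' @param orf_counts,orf_meta Optional paths for the RPKM stage (ORF count
#'   TSV: first column orf_id; metadata TSV per [compute_rpkm()]).
#' @param trc,ctd Optional paths for the TRC stage.
#' @param out_dir Output directory.
#' @param general_evalue,strict_evalue Tiered e-value cutoffs.
#' @param alpha Absence-confidence level for genotyping.
#' @param omz_do,omz_core_do Dissolved-oxygen cutoffs (umol/kg).
#' @param depth_tol CTD join tolerance (m).
#' @param indval_permutations Permutations for indicator species analysis.
#' @param profile_genes Gene symbols for depth profiles.
#' @param seed Integer seed for all stochastic steps.
#' @return A validated `run_config` list.
#' @export
run_config <- function(hits, genome_meta, out_dir, catalog = NULL,
                       asv_counts = NULL, asv_taxonomy = NULL,
                       sample_meta = NULL, orf_counts = NULL,
                       orf_meta = NULL, trc = NULL, ctd = NULL,
                       general_evalue = 1e-10, strict_evalue = 1e-15,
                       alpha = 0.05, omz_do = 30, omz_core_do = 10,
                       depth_tol = 5, indval_permutations = 999,
                       profile_genes = c("thiC", "thiG", "thi4", "thiE"),
                       seed = 1) {
  cfg <- list(hits = hits, genome_meta = genome_meta, out_dir = out_dir,
              catalog = catalog, asv_counts = asv_counts,
              asv_taxonomy = asv_taxonomy, sample_meta = sample_meta,
              orf_counts = orf_counts, orf_meta = orf_meta, trc = trc,
              ctd = ctd, general_evalue = general_evalue,
              strict_evalue = strict_evalue, alpha = alpha,
              omz_do = omz_do, omz_core_do = omz_core_do,
              depth_tol = depth_tol,
              indval_permutations = indval_permutations,
              profile_genes = profile_genes, seed = seed)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (cfg$strict_evalue > cfg$general_evalue ||
      cfg$strict_evalue <= 0 || cfg$general_evalue <= 0) {
    stop("config error: e-value tiers must satisfy 0 < strict <= general")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("config error: alpha must lie in (0, 1)")
  }
  if (cfg$omz_core_do > cfg$omz_do) {
    stop("config error: OMZ core cutoff must not exceed the OMZ cutoff")
  }
  if (cfg$indval_permutations < 99) {
    stop("config error: indval_permutations must be >= 99")
  }
  for (p in c("hits", "genome_meta")) {
    if (!file.exists(cfg[[p]])) stop("config error: missing file: ",
                                     cfg[[p]])
  }
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

#' @rdname read_run_config
#' @param cfg A `run_config` object.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write a commented configuration template
#'
#' @param path Destination path for the YAML template.
#' @export
write_config_template <- function(path) {
  writeLines(c(
    "# b1profiler run configuration",
    "hits: hits.domtbl          # homology-search hit table (domtbl or TSV)",
    "genome_meta: genomes.tsv   # genome_id, domain, taxonomy, completeness, contamination",
    "out_dir: results",
    "# catalog: families.tsv    # optional; defaults to the shipped catalog",
    "# asv_counts: asv.tsv      # optional community-ecology stage",
    "# asv_taxonomy: tax.tsv",
    "# sample_meta: samples.tsv",
    "# orf_counts: orf.tsv      # optional RPKM stage",
    "# orf_meta: orfmeta.tsv",
    "# trc: trc.tsv             # optional TRC stage",
    "# ctd: ctd.tsv",
    "general_evalue: 1.0e-10    # general annotation tier",
    "strict_evalue: 1.0e-15     # B1/nitrification/carbon-fixation tier",
    "alpha: 0.05                # absence-confidence level",
    "omz_do: 30                 # OMZ dissolved-oxygen cutoff, umol/kg",
    "omz_core_do: 10            # OMZ core cutoff, umol/kg",
    "depth_tol: 5               # CTD join tolerance, m",
    "indval_permutations: 999",
    "seed: 1"), path)
  invisible(path)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(cfg), tf)
  unname(tools::md5sum(tf))
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Run the full pipeline from a configuration
#'
#' Executes annotate -> genotype, then (when inputs are configured) the
#' RPKM/profile, community-ecology and TRC stages, writing per-stage TSVs,
#' a combined `summary.json` (genotype category counts, per-layer
#' prototroph shares, domain RPKM ratios, TRC fold changes and local
#' maxima) and a `run_log.txt` recording package version, config hash and
#' seed. Reruns with an identical config and inputs are identical.
#'
#' @param cfg A `run_config` (or path to a YAML config).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  logf <- function(...) cat(paste0(format(Sys.time(), "%H:%M:%S "), ...,
                                   "\n"), file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("b1profiler ",
       as.character(utils::packageVersion("b1profiler")),
       " | config hash ", config_hash(cfg), " | seed ", cfg$seed)
  summary <- list(config_hash = config_hash(cfg), seed = cfg$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste("FAILED at stage:", name),
                 file.path(cfg$out_dir, "FAILED"))
      logf("stage ", name, " failed: ", conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- annotate ---
  catalog <- stage("annotate", {
    if (is.null(cfg$catalog)) b1_gene_catalog()
    else b1_gene_catalog(cfg$catalog)
  })
  meta <- stage("annotate", read_genome_meta(cfg$genome_meta))
  presence <- stage("annotate", {
    hits <- parse_hit_table(cfg$hits)
    hits <- filter_hits(hits, catalog, cfg$general_evalue,
                        cfg$strict_evalue)
    build_presence_matrix(hits, catalog, meta$genome_id)
  })
  write_presence_matrix(presence, file.path(cfg$out_dir, "presence.tsv"))
  logf("annotate: ", nrow(presence), " genomes x ", ncol(presence),
       " gene symbols")

  # --- genotype ---
  calls <- stage("genotype",
                 classify_b1_genotypes(presence, meta, alpha = cfg$alpha))
  utils::write.table(calls, file.path(cfg$out_dir, "genotype_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$genotype_counts <- as.list(table(calls$category))
  logf("genotype: ", nrow(calls), " calls")

  # --- rpkm / profiles ---
  if (!is.null(cfg$orf_counts)) {
    prof <- stage("rpkm", {
      counts <- read_matrix_tsv(cfg$orf_counts)
      orf_meta <- utils::read.delim(cfg$orf_meta,
                                    stringsAsFactors = FALSE)
      rpkm <- compute_rpkm(counts, orf_meta)
      gene_depth_profile(rpkm, orf_meta, cfg$profile_genes,
                         group_by = "domain")
    })
    utils::write.table(prof, file.path(cfg$out_dir, "gene_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ratio <- attr(prof, "domain_ratio")
    utils::write.table(ratio, file.path(cfg$out_dir, "domain_ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$mean_domain_ratio <- stats::aggregate(
      archaea_bacteria_ratio ~ gene_symbol, ratio, mean,
      na.action = stats::na.omit)
    logf("rpkm: profiles for ",
         length(unique(prof$gene_symbol)), " gene symbols")
  }

  # --- ecology ---
  if (!is.null(cfg$asv_counts)) {
    eco <- stage("ecology", {
      counts <- read_matrix_tsv(cfg$asv_counts)
      tax <- utils::read.delim(cfg$asv_taxonomy,
                               stringsAsFactors = FALSE)
      samples <- utils::read.delim(cfg$sample_meta,
                                   stringsAsFactors = FALSE)
      taxonomy <- tax$taxonomy[match(rownames(counts), tax$taxon)]
      counts <- drop_chloroplast_asvs(counts, taxonomy)
      taxonomy <- tax$taxonomy[match(rownames(counts), tax$taxon)]
      rel <- relative_abundance(counts)
      layer <- assign_depth_layer(
        samples$depth_m[match(colnames(counts), samples$sample_id)])
      shannon <- apply(rel, 2, shannon_index)
      bc <- bray_curtis_matrix(counts)
      tree <- average_linkage(bc)
      iv <- indval(counts, layer,
                   n_permutations = cfg$indval_permutations,
                   seed = cfg$seed)
      gm <- genotype_map_from_calls(calls, meta)
      proto <- prototroph_share_by_taxonomy(rel, taxonomy, gm)
      list(rel = rel, shannon = shannon, tree = tree, indval = iv,
           prototroph = proto, layer = layer)
    })
    utils::write.table(
      data.frame(sample_id = names(eco$shannon), layer = eco$layer,
                 shannon = eco$shannon,
                 prototroph_share = eco$prototroph),
      file.path(cfg$out_dir, "ecology_samples.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(eco$indval, file.path(cfg$out_dir, "indval.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(as_newick(eco$tree),
               file.path(cfg$out_dir, "dendrogram.nwk"))
    summary$prototroph_share_by_layer <- as.list(
      tapply(eco$prototroph, eco$layer, mean))
    summary$shannon_by_layer <- as.list(tapply(eco$shannon, eco$layer,
                                               mean))
    logf("ecology: ", ncol(eco$rel), " samples")
  }

  # --- trc ---
  if (!is.null(cfg$trc)) {
    trc_res <- stage("trc", {
      trc <- read_trc_table(cfg$trc)
      ctd <- read_ctd_table(cfg$ctd)
      prof <- replicate_stats(trc)
      prof <- assign_oxygen_layers(prof, ctd, depth_tol = cfg$depth_tol,
                                   omz_threshold = cfg$omz_do,
                                   core_threshold = cfg$omz_core_do)
      prof
    })
    utils::write.table(trc_res, file.path(cfg$out_dir, "trc_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    folds <- list(); maxima <- list()
    for (cmp in unique(trc_res$compound)) {
      folds[[cmp]] <- tryCatch(as.numeric(fold_change(trc_res, cmp)),
                               error = function(e) NA_real_)
      maxima[[cmp]] <- tryCatch(find_local_maxima(trc_res, cmp)[1],
                                error = function(e) NA_real_)
    }
    summary$trc_fold_change <- folds
    summary$trc_primary_maximum_depth <- maxima
    logf("trc: ", nrow(trc_res), " profile rows")
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("done")
  invisible(summary)
}

#' Majority genotype category per taxonomy string
#'
#' Links genotype calls to community taxa: for each distinct genome
#' taxonomy, the most frequent category among its genomes (ties broken by
#' category order, PROTOTROPH first).
#'
#' @param calls Calls from [classify_b1_genotypes()].
#' @param meta Genome metadata with `taxonomy`.
#' @return Named character vector: taxonomy string -> category.
#' @export
genotype_map_from_calls <- function(calls, meta) {
  tax <- meta$taxonomy[match(calls$genome_id, meta$genome_id)]
  vapply(split(calls$category, tax), function(cats) {
    tab <- table(factor(cats, levels = B1_CATEGORIES))
    names(tab)[which.max(tab)]
  }, character(1))
}

# per-sample prototroph share where community taxa are linked to genotype
# categories via their taxonomy strings
prototroph_share_by_taxonomy <- function(rel, taxonomy, genotype_map) {
  cats <- genotype_map[taxonomy]
  proto <- !is.na(cats) & cats == "PROTOTROPH"
  colSums(rel[proto, , drop = FALSE])
}
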