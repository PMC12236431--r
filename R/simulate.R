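# synthetic-data generators: genomes from genotype archetypes, MAG
# degradation, depth-stratified communities, and TRC depth profiles with a
# planted OMZ peak -- every pipeline input with recorded ground truth

#' Genotype archetype library
#'
#' Named microbial guilds with their B1 pathway gene sets and
#' chemoautotrophy markers: ammonia-oxidizing archaea (AOA), nitrite
#' oxidizers (Nitrospina), sulfur-oxidizing Thioglobaceae, the
#' HMP-requiring SAR11 and SAR202 lineages, dual-auxotrophic
#' Rhodobacterales, and salvage-only Flavobacteriales. Each archetype's
#' `expected_category` is what [classify_b1_genotype()] returns for its
#' full gene set at completeness 1.
#'
#' @return Data frame with columns `name`, `domain`, `taxonomy` (GTDB-style
#'   semicolon ranks), `genes` and `chemo` (comma-joined symbol lists), and
#'   `expected_category`.
#' @export
b1_archetypes <- function() {
  data.frame(
    name = c("AOA_prototroph", "Nitrospina_prototroph",
             "Thioglobaceae_prototroph", "SAR11_HMP_aux", "SAR202_HMP_aux",
             "Rhodobacterales_dual_aux", "Flavobacteria_salvage"),
    domain = c("archaea", rep("bacteria", 6)),
    taxonomy = c(
      "Archaea;Thermoproteota;Nitrososphaeria;Nitrososphaerales;Nitrosopumilaceae",
      "Bacteria;Nitrospinota;Nitrospinia;Nitrospinales;Nitrospinaceae",
      "Bacteria;Pseudomonadota;Gammaproteobacteria;Thiomicrospirales;Thioglobaceae",
      "Bacteria;Pseudomonadota;Alphaproteobacteria;Pelagibacterales;Pelagibacteraceae",
      "Bacteria;Chloroflexota;Dehalococcoidia;UBA3495;UBA3495",
      "Bacteria;Pseudomonadota;Alphaproteobacteria;Rhodobacterales;Rhodobacteraceae",
      "Bacteria;Bacteroidota;Bacteroidia;Flavobacteriales;Flavobacteriaceae"),
    genes = c("thiC,thi4,thiDN,thiL",
              "thiC,thiG,thiE,thiL,tenA,thiD",
              "thiC,thiG,thiE,thiL",
              "thiG,thiE,thiL,cytX",
              "thiG,thiE,tenA,thiD",
              "thiE,thiL,thiB,thiP,thiQ",
              "thiL,omr1"),
    chemo = c("amoA", "nxr", "aprA,aprB,dsrA,rbcL", "", "", "", ""),
    expected_category = c("PROTOTROPH", "PROTOTROPH", "PROTOTROPH",
                          "AUX_HMP", "AUX_HMP", "AUX_DUAL", "SALVAGE_ONLY"),
    stringsAsFactors = FALSE)
}

split_symbols <- function(x) {
  if (!nzchar(x)) character() else strsplit(x, ",", fixed = TRUE)[[1]]
}

#' Generate a synthetic genome cohort with hit tables and truth
#'
#' Emits one hit row per encoded gene per genome, with full-sequence
#' e-values log-uniform in `[1e-40, 1e-16]` (inside the strict tier) and,
#' at rate `decoy_rate` per genome, decoy hits with e-values log-uniform in
#' `[1e-9, 1e-3]` that every filtering tier must remove. Genome metadata is
#' emitted at completeness 1 and contamination 0; degrade the cohort with
#' [degrade_to_mag()] to emulate MAG incompleteness.
#'
#' @param archetype_mix Named integer vector: genomes to simulate per
#'   archetype name (see [b1_archetypes()]).
#' @param seed Integer seed; identical (arguments, seed) give identical
#'   output.
#' @param decoy_rate Expected decoy hits per genome (default 0.1).
#' @param catalog Gene-family catalog (default shipped catalog).
#' @return List with `hits` (parse_hit_table layout), `meta` (genome
#'   metadata), and `truth` (genome_id, archetype, true_category,
#'   completeness, contamination).
#' @export
generate_genome_set <- function(archetype_mix, seed = 1, decoy_rate = 0.1,
                                catalog = b1_gene_catalog()) {
  arch <- b1_archetypes()
  unknown <- setdiff(names(archetype_mix), arch$name)
  if (length(unknown) > 0) {
    stop("unknown archetype(s): ", paste(unknown, collapse = ", "))
  }
  if (any(archetype_mix < 1)) stop("archetype counts must be >= 1")
  sym2fam <- stats::setNames(catalog$family_id, catalog$gene_symbol)

  run_seeded(seed, {
    hits_list <- list(); meta_list <- list(); truth_list <- list()
    for (a in names(archetype_mix)) {
      row <- arch[arch$name == a, ]
      genes <- c(split_symbols(row$genes), split_symbols(row$chemo))
      fams <- unname(sym2fam[genes])
      for (g in seq_len(archetype_mix[[a]])) {
        gid <- sprintf("%s.g%04d", a, g)
        n_genes <- length(fams)
        ev <- 10^stats::runif(n_genes, -40, -16)
        bit <- stats::runif(n_genes, 60, 400)
        n_decoy <- stats::rpois(1, decoy_rate)
        fam_all <- c(fams, sample(catalog$family_id, n_decoy,
                                  replace = TRUE))
        ev <- c(ev, 10^stats::runif(n_decoy, -9, -3))
        bit <- c(bit, stats::runif(n_decoy, 10, 25))
        m <- length(fam_all)
        hits_list[[gid]] <- data.frame(
          protein_id = sprintf("%s_%05d", gid, seq_len(m)),
          genome_id = gid, family_id = fam_all, evalue = ev,
          bit_score = round(bit, 1),
          ali_from = rep(1L, m),
          ali_to = as.integer(round(stats::runif(m, 150, 600))),
          stringsAsFactors = FALSE)
        meta_list[[gid]] <- data.frame(
          genome_id = gid, domain = row$domain, taxonomy = row$taxonomy,
          completeness = 1, contamination = 0, stringsAsFactors = FALSE)
        truth_list[[gid]] <- data.frame(
          genome_id = gid, archetype = a,
          true_category = row$expected_category,
          completeness = 1, contamination = 0, stringsAsFactors = FALSE)
      }
    }
    list(hits = do.call(rbind, c(hits_list, make.row.names = FALSE)),
         meta = do.call(rbind, c(meta_list, make.row.names = FALSE)),
         truth = do.call(rbind, c(truth_list, make.row.names = FALSE)))
  })
}

#' Degrade a synthetic genome set to MAG-like incompleteness
#'
#' Every true-gene hit is retained independently with probability equal to
#' `completeness` (uniform, independent gene dropout -- the simplest model
#' consistent with a scalar completeness estimate). Contamination adds
#' hits copied from randomly chosen donor genomes at a rate calibrated so
#' the added-gene fraction approximates the contamination estimate.
#' Metadata and truth completeness/contamination fields are updated to the
#' applied values.
#'
#' @param genome_set List from [generate_genome_set()].
#' @param completeness Retention probability in (0, 1].
#' @param contamination Added-gene fraction in \[0, 1).
#' @param seed Integer seed.
#' @return A genome set list with degraded `hits` and updated `meta` and
#'   `truth`.
#' @export
degrade_to_mag <- function(genome_set, completeness, contamination = 0,
                           seed = 1) {
  if (completeness <= 0 || completeness > 1) {
    stop("completeness must lie in (0, 1]")
  }
  if (contamination < 0 || contamination >= 1) {
    stop("contamination must lie in [0, 1)")
  }
  hits <- genome_set$hits
  run_seeded(seed, {
    keep <- stats::runif(nrow(hits)) <= completeness
    out <- hits[keep, , drop = FALSE]
    if (contamination > 0) {
      genomes <- unique(hits$genome_id)
      extra <- list()
      for (gid in genomes) {
        own <- hits[hits$genome_id == gid, , drop = FALSE]
        pool <- hits[hits$genome_id != gid, , drop = FALSE]
        n_add <- stats::rbinom(1, nrow(own),
                               contamination / (1 - contamination))
        if (n_add > 0 && nrow(pool) > 0) {
          add <- pool[sample(nrow(pool), min(n_add, nrow(pool))), ,
                      drop = FALSE]
          add$genome_id <- gid
          add$protein_id <- sprintf("%s_c%05d", gid, seq_len(nrow(add)))
          extra[[gid]] <- add
        }
      }
      out <- do.call(rbind, c(list(out), extra, make.row.names = FALSE))
    }
    genome_set$hits <- out
    genome_set$meta$completeness <- completeness
    genome_set$meta$contamination <- contamination
    genome_set$truth$completeness <- completeness
    genome_set$truth$contamination <- contamination
    genome_set
  })
}

#' Write hits in HMMER3 per-domain tabular (domtblout) format
#'
#' @param hits Hits data frame ([parse_hit_table()] layout).
#' @param path Output path.
#' @export
write_domtbl <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"),
    con)
  if (nrow(hits) > 0) {
    lines <- sprintf(
      "%-20s -          %5d %-20s -          %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f -",
      hits$protein_id, hits$ali_to + 50L, hits$family_id, 400L,
      hits$evalue, hits$bit_score, 0.1, 1L, 1L, hits$evalue, hits$evalue,
      hits$bit_score, 0.1, 1L, 350L, hits$ali_from, hits$ali_to,
      hits$ali_from, hits$ali_to, 0.95)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Default depth-by-oxygen sampling design
#'
#' Eleven depths from the near surface (2 m) to 2500 m with a dissolved
#' oxygen profile whose minimum (8 umol/kg) sits at 700 m; oxygen is at or
#' below 30 umol/kg from 500 to 1250 m, emulating a mesopelagic oxygen
#' minimum zone over an offshore eastern North Pacific station.
#'
#' @return Data frame with `depth_m` and `dissolved_oxygen` (umol/kg).
#' @export
default_depth_design <- function() {
  data.frame(
    depth_m = c(2, 60, 100, 200, 300, 500, 700, 1000, 1250, 2000, 2500),
    dissolved_oxygen = c(250, 230, 180, 120, 60, 28, 8, 25, 30, 80, 120))
}

# planted relative-abundance composition per depth over archetype taxa
default_composition <- function(depth_design) {
  layer <- assign_depth_layer(depth_design$depth_m)
  omz <- depth_design$dissolved_oxygen <= 30
  taxa <- c(b1_archetypes()$name, "Other_heterotrophs")
  comp <- vapply(seq_len(nrow(depth_design)), function(i) {
    if (omz[i] && layer[i] == "mesopelagic") {
      # OMZ: AOA at 0.24, prototroph guilds summing to 0.31
      c(0.24, 0.03, 0.04, 0.12, 0.08, 0.02, 0.03, 0.44)
    } else if (layer[i] == "epipelagic") {
      c(0.05, 0.01, 0.01, 0.28, 0.03, 0.05, 0.11, 0.46)
    } else if (layer[i] == "mesopelagic") {
      c(0.20, 0.02, 0.02, 0.15, 0.07, 0.03, 0.04, 0.47)
    } else {
      c(0.15, 0.02, 0.02, 0.10, 0.10, 0.03, 0.05, 0.53)
    }
  }, numeric(length(taxa)))
  rownames(comp) <- taxa
  colnames(comp) <- paste0("d", depth_design$depth_m)
  comp
}

# nominal ORF lengths (bp) for simulated thiamine genes
SIM_GENE_LENGTHS <- c(thiC = 1900, thiG = 770, thi4 = 980, thiE = 640,
                      thiDN = 1600, thiL = 980, tenA = 700, thiD = 810,
                      cytX = 1300, omr1 = 1900, thiB = 990, thiP = 1600,
                      thiQ = 700)

#' Simulate a depth-stratified community with ORF and transcript counts
#'
#' Generates, per depth of the design: (i) multinomial ASV counts from a
#' planted composition over the archetype taxa (ammonia-oxidizing archaea
#' enriched to 24% and the prototroph guilds to a combined 31% of amplicons
#' in OMZ mesopelagic samples); (ii) negative-binomial metagenomic ORF
#' counts for thiamine genes with planted archaea:bacteria RPKM ratios
#' (thi4 3x, thiC 4x); and (iii) negative-binomial transcript counts with
#' planted class-level shares of thiamine-related transcripts
#' (Gammaproteobacteria 40%, Nitrososphaeria 22%, Alphaproteobacteria 27%,
#' Dehalococcoidia 6%, Bacteroidia 5%).
#'
#' @param depth_design Data frame with `depth_m` and `dissolved_oxygen`
#'   (default [default_depth_design()]).
#' @param composition Optional taxa-by-depth matrix of planted proportions
#'   (columns must sum to 1); default as described above.
#' @param n_reads Reads per sample (>= 1000; default 1e5).
#' @param dispersion Negative-binomial dispersion (variance = mu +
#'   dispersion * mu^2); 0 gives Poisson counts.
#' @param n_orfs_per_gene ORF copies simulated per (domain or class, gene)
#'   cell (default 25); overdispersed noise averages out across ORFs.
#' @param capture Fraction of `n_reads` expected on thiamine-gene ORFs
#'   (default 0.05).
#' @param seed Integer seed.
#' @return List with `asv` (counts, taxonomy, sample metadata), `orf`
#'   (counts + orf_meta for metagenomic gene profiles), `transcripts`
#'   (counts + orf_meta), and `truth` (planted composition, prototroph
#'   shares, domain ratios, transcript shares).
#' @export
simulate_community_profile <- function(depth_design = default_depth_design(),
                                       composition = NULL, n_reads = 1e5,
                                       dispersion = 0.2,
                                       n_orfs_per_gene = 25,
                                       capture = 0.05, seed = 1) {
  if (n_reads < 1e3) stop("n_reads must be at least 1000 per sample")
  if (is.null(composition)) composition <- default_composition(depth_design)
  if (any(abs(colSums(composition) - 1) > 1e-8)) {
    stop("composition columns must sum to 1")
  }
  arch <- b1_archetypes()
  samples <- paste0("d", depth_design$depth_m)
  layer <- assign_depth_layer(depth_design$depth_m)
  omz <- depth_design$dissolved_oxygen <= 30

  rcount <- function(mu) {
    if (dispersion == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }

  # planted metagenomic RPKM expectations per (domain, gene): archaeal thi4
  # 3x and thiC 4x their bacterial counterparts
  gene_design <- data.frame(
    domain = c("archaea", "bacteria", "archaea", "bacteria",
               "archaea", "bacteria", "bacteria"),
    gene_symbol = c("thi4", "thi4", "thiC", "thiC", "thiE", "thiE", "thiG"),
    mu_rpkm = c(30, 10, 40, 10, 5, 20, 20),
    stringsAsFactors = FALSE)

  # planted transcript shares by taxon class
  class_shares <- c(Gammaproteobacteria = 0.40, Nitrososphaeria = 0.22,
                    Alphaproteobacteria = 0.27, Dehalococcoidia = 0.06,
                    Bacteroidia = 0.05)
  class_arch <- c(Gammaproteobacteria = "Thioglobaceae_prototroph",
                  Nitrososphaeria = "AOA_prototroph",
                  Alphaproteobacteria = "SAR11_HMP_aux",
                  Dehalococcoidia = "SAR202_HMP_aux",
                  Bacteroidia = "Flavobacteria_salvage")

  run_seeded(seed, {
    asv_counts <- vapply(seq_along(samples), function(i) {
      as.numeric(stats::rmultinom(1, n_reads, composition[, i]))
    }, numeric(nrow(composition)))
    dimnames(asv_counts) <- list(rownames(composition), samples)
    tax <- c(stats::setNames(arch$taxonomy, arch$name),
             Other_heterotrophs = "Bacteria;mixed;mixed;mixed;mixed")

    # metagenomic ORF counts: n_orfs_per_gene ORFs per (domain, gene),
    # expected counts proportional to planted RPKM x length, scaled so
    # thiamine ORFs capture `capture` of the library
    gd <- gene_design[rep(seq_len(nrow(gene_design)),
                          each = n_orfs_per_gene), ]
    orf_meta <- data.frame(
      orf_id = sprintf("orf_%s_%s_%03d", gd$domain, gd$gene_symbol,
                       sequence(rep(n_orfs_per_gene,
                                    nrow(gene_design)))),
      length_bp = unname(SIM_GENE_LENGTHS[gd$gene_symbol]),
      genome_id = paste0("asm_", gd$domain),
      gene_symbol = gd$gene_symbol,
      domain = gd$domain,
      taxon_class = ifelse(gd$domain == "archaea",
                           "Nitrososphaeria", "mixed_bacteria"),
      stringsAsFactors = FALSE)
    w <- (gd$mu_rpkm / n_orfs_per_gene) * orf_meta$length_bp / 1000
    mu <- outer(w / sum(w) * capture * n_reads, rep(1, length(samples)))
    orf_counts <- matrix(rcount(mu), nrow = nrow(mu),
                         dimnames = list(orf_meta$orf_id, samples))

    # transcript counts: planted class shares split evenly (in RPKM
    # terms) over each class's thiamine genes and their ORF copies
    tr_meta_list <- list()
    for (cl in names(class_shares)) {
      genes <- split_symbols(arch$genes[arch$name == class_arch[[cl]]])
      genes <- intersect(genes, names(SIM_GENE_LENGTHS))
      genes <- rep(genes, each = n_orfs_per_gene)
      tr_meta_list[[cl]] <- data.frame(
        orf_id = sprintf("tr_%s_%s_%03d", cl, genes,
                         sequence(rep(n_orfs_per_gene,
                                      length(genes) / n_orfs_per_gene))),
        length_bp = unname(SIM_GENE_LENGTHS[genes]),
        genome_id = class_arch[[cl]],
        gene_symbol = genes, taxon_class = cl,
        share = class_shares[[cl]] / length(genes),
        stringsAsFactors = FALSE)
    }
    tr_meta <- do.call(rbind, c(tr_meta_list, make.row.names = FALSE))
    wt <- tr_meta$share * tr_meta$length_bp / 1000
    tr_mu <- outer(wt / sum(wt) * capture * n_reads,
                   rep(1, length(samples)))
    tr_counts <- matrix(rcount(tr_mu), nrow = nrow(tr_mu),
                        dimnames = list(tr_meta$orf_id, samples))
    tr_meta$share <- NULL

    proto_taxa <- arch$name[arch$expected_category == "PROTOTROPH"]
    truth <- list(
      composition = composition,
      prototroph_share = colSums(composition[proto_taxa, , drop = FALSE]),
      domain_ratio = c(thi4 = 3, thiC = 4),
      transcript_shares = class_shares,
      n_reads = n_reads, dispersion = dispersion, seed = seed)

    list(asv = list(counts = asv_counts,
                    taxonomy = tax[rownames(asv_counts)],
                    samples = data.frame(sample_id = samples,
                                         depth_m = depth_design$depth_m,
                                         dissolved_oxygen =
                                           depth_design$dissolved_oxygen,
                                         layer = layer, omz = omz,
                                         stringsAsFactors = FALSE)),
         orf = list(counts = orf_counts, orf_meta = orf_meta),
         transcripts = list(counts = tr_counts, orf_meta = tr_meta),
         truth = truth)
  })
}

#' Simulate a replicated TRC depth profile with a planted OMZ peak
#'
#' Builds a baseline concentration profile over the depth design and plants
#' a multiplicative enhancement in the OMZ mesopelagic window such that the
#' default [fold_change()] rule (OMZ-mesopelagic mean over upper-100 m
#' mean) recovers exactly `peak$fold` in the noiseless case, with the
#' single largest value (a strict local maximum) at `peak$depth`.
#' Replicates are log-normal with coefficient of variation `replicate_cv`
#' (multiplicative error, typical of LC-MS quantification; a testbed
#' assumption).
#'
#' @param depth_design Data frame with `depth_m` and `dissolved_oxygen`;
#'   `peak$depth` must be an OMZ-core mesopelagic depth of the design.
#' @param peak List with `depth` (m), `fold` (> 0), `compound`.
#' @param baseline Baseline concentration in pM for the reference layer
#'   (default 30).
#' @param replicate_cv Coefficient of variation of technical replicates
#'   (default 0.1; 0 disables noise).
#' @param n_replicates Technical replicates per depth (default 3).
#' @param seed Integer seed.
#' @param station,campaign Labels for the output tables.
#' @return List with `trc` (replicate-level table), `ctd` (context table),
#'   and `truth` (planted peak parameters and noiseless means).
#' @export
simulate_trc_dataset <- function(depth_design = default_depth_design(),
                                 peak = list(depth = 700, fold = 3.5,
                                             compound = "B1"),
                                 baseline = 30, replicate_cv = 0.1,
                                 n_replicates = 3, seed = 1,
                                 station = "sim-67-70",
                                 campaign = "autumn2018") {
  if (peak$fold <= 0) stop("peak fold must be positive")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  depth <- depth_design$depth_m
  layer <- assign_depth_layer(depth)
  omz <- depth_design$dissolved_oxygen <= 30
  target <- omz & layer == "mesopelagic"
  if (!peak$depth %in% depth[target]) {
    stop("peak depth must be an OMZ mesopelagic depth of the design")
  }
  ref <- depth <= 100
  if (!any(ref)) stop("design has no reference depths (<= 100 m)")

  # baseline shape: flat reference layer, mild sub-surface plateau,
  # decline into the bathypelagic; no secondary strict maxima
  mu <- ifelse(ref, baseline,
               ifelse(layer %in% c("epipelagic", "mesopelagic"),
                      baseline * 1.1, baseline * 0.7))
  # plant the OMZ enhancement: scale target depths so their mean equals
  # fold * reference mean while the peak depth stays the strict maximum
  k <- sum(target)
  ref_mean <- mean(mu[ref])
  need <- peak$fold * ref_mean * k
  others <- target & depth != peak$depth
  if (any(others)) {
    mu[others] <- mu[others] * 0.9  # keep neighbors below the peak
  }
  mu[depth == peak$depth] <- need - sum(mu[others])
  if (mu[depth == peak$depth] <= max(mu[others], 0)) {
    stop("fold too small to plant a strict local maximum at peak depth")
  }

  sdlog <- sqrt(log(1 + replicate_cv^2))
  run_seeded(seed, {
    rows <- list()
    for (i in seq_along(depth)) {
      if (replicate_cv > 0) {
        conc <- stats::rlnorm(n_replicates,
                              meanlog = log(mu[i]) - sdlog^2 / 2,
                              sdlog = sdlog)
      } else {
        conc <- rep(mu[i], n_replicates)
      }
      rows[[i]] <- data.frame(
        station = station, campaign = campaign, depth_m = depth[i],
        compound = peak$compound,
        replicate_id = seq_len(n_replicates),
        concentration = conc, stringsAsFactors = FALSE)
    }
    trc <- do.call(rbind, c(rows, make.row.names = FALSE))
    ctd <- data.frame(station = station, campaign = campaign,
                      depth_m = depth,
                      dissolved_oxygen = depth_design$dissolved_oxygen,
                      stringsAsFactors = FALSE)
    list(trc = trc, ctd = ctd,
         truth = list(peak = peak, mu = stats::setNames(mu, depth),
                      replicate_cv = replicate_cv, seed = seed))
  })
}

#' Path to the synthetic station 67-70 worked-example tables
#'
#' Replicate-level TRC measurements and CTD context for a synthetic
#' offshore-station profile. The tables are a constructed stand-in (not
#' measured data): replicate means at anchor depths reproduce headline
#' values reported for eastern North Pacific station 67-70 profiles -- a
#' dissolved B1 local maximum of 232.52 pM in the OMZ core at 700 m, a
#' 3.5-fold B1 increase from the upper 100 m to the OMZ mesopelagic, and
#' 700 m companion concentrations of AmMP (25.36 pM), HMP (3.19 pM) and
#' cHET (29.59 pM).
#'
#' @param which `"trc"` or `"ctd"`.
#' @return File path to the shipped TSV.
#' @export
synthetic_station_profile <- function(which = c("trc", "ctd")) {
  which <- match.arg(which)
  fname <- switch(which, trc = "synthetic_station6770_trc.tsv",
                  ctd = "synthetic_station6770_ctd.tsv")
  system.file("extdata", fname, package = "b1profiler", mustWork = TRUE)
}
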