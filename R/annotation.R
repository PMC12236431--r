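# annotation ingest: homology-search hit tables -> filtered hits ->
# per-genome gene presence/copy matrix

#' Parse a homology-search hit table
#'
#' Reads per-protein hits either from HMMER3 per-domain tabular output
#' (`domtblout`, whitespace-separated with `#` comment lines) or from a
#' 6-column TSV (`protein_id`, `genome_id`, `family_id`, `evalue`,
#' `bit_score`, `coords` as `start-end`). Hit tables usually carry protein
#' identifiers only; when no genome column is present the genome identifier
#' is taken as the protein-identifier prefix up to the last occurrence of
#' `genome_delim`.
#'
#' @param path Path to the hit table.
#' @param format `"domtbl"`, `"tsv"`, or `"auto"` (guessed from content:
#'   lines starting with `#` and >20 whitespace-separated fields mean
#'   domtblout).
#' @param genome_delim Delimiter separating the genome prefix from the
#'   protein suffix in `protein_id` (default `"_"`).
#' @return A data frame of hits with columns `protein_id`, `genome_id`,
#'   `family_id`, `evalue`, `bit_score`, `ali_from`, `ali_to`.
#' @export
parse_hit_table <- function(path, format = c("auto", "domtbl", "tsv"),
                            genome_delim = "_") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("hit table not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  data_lines <- lines[keep]
  line_no <- seq_along(lines)[keep]
  if (length(data_lines) == 0) return(empty_hits())

  if (format == "auto") {
    nfield <- length(strsplit(trimws(data_lines[1]), "\\s+")[[1]])
    format <- if (nfield >= 20) "domtbl" else "tsv"
  }
  if (format == "domtbl") {
    parse_domtbl_lines(data_lines, line_no, genome_delim)
  } else {
    parse_tsv_lines(data_lines, line_no, genome_delim)
  }
}

empty_hits <- function() {
  data.frame(protein_id = character(), genome_id = character(),
             family_id = character(), evalue = numeric(),
             bit_score = numeric(), ali_from = integer(),
             ali_to = integer(), stringsAsFactors = FALSE)
}

# HMMER3 per-domain table (hmmsearch orientation): target = protein,
# query = profile. Fixed columns 1-22, free-text description after.
parse_domtbl_lines <- function(data_lines, line_no, genome_delim) {
  fields <- strsplit(trimws(data_lines), "\\s+")
  nf <- lengths(fields)
  bad <- nf < 22
  if (any(bad)) {
    stop("malformed domtblout row (expected >= 22 columns) at line ",
         paste(line_no[bad], collapse = ", "))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  evalue <- suppressWarnings(as.numeric(col(7)))
  score <- suppressWarnings(as.numeric(col(8)))
  ali_from <- suppressWarnings(as.integer(col(18)))
  ali_to <- suppressWarnings(as.integer(col(19)))
  check_numeric_fields(evalue, score, line_no)
  family_id <- col(4)
  acc <- col(5)
  family_id[family_id == "-"] <- acc[family_id == "-"]
  protein_id <- col(1)
  data.frame(protein_id = protein_id,
             genome_id = genome_prefix(protein_id, genome_delim),
             family_id = family_id, evalue = evalue, bit_score = score,
             ali_from = ali_from, ali_to = ali_to, stringsAsFactors = FALSE)
}

parse_tsv_lines <- function(data_lines, line_no, genome_delim) {
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  # tolerate a header row
  if (nf[1] >= 5 && identical(fields[[1]][1], "protein_id")) {
    fields <- fields[-1]; line_no <- line_no[-1]; nf <- nf[-1]
    if (length(fields) == 0) return(empty_hits())
  }
  bad <- nf < 5
  if (any(bad)) {
    stop("malformed TSV hit row (expected >= 5 columns) at line ",
         paste(line_no[bad], collapse = ", "))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  has_genome <- all(nf >= 6)
  if (has_genome) {
    protein_id <- col(1); genome_id <- col(2); family_id <- col(3)
    evalue <- suppressWarnings(as.numeric(col(4)))
    score <- suppressWarnings(as.numeric(col(5)))
    coords <- col(6)
  } else {
    protein_id <- col(1)
    genome_id <- genome_prefix(protein_id, genome_delim)
    family_id <- col(2)
    evalue <- suppressWarnings(as.numeric(col(3)))
    score <- suppressWarnings(as.numeric(col(4)))
    coords <- col(5)
  }
  check_numeric_fields(evalue, score, line_no)
  cc <- strsplit(coords, "-", fixed = TRUE)
  ali_from <- suppressWarnings(as.integer(vapply(cc, `[`, character(1), 1)))
  ali_to <- suppressWarnings(as.integer(vapply(cc, `[`, character(1), 2)))
  data.frame(protein_id = protein_id, genome_id = genome_id,
             family_id = family_id, evalue = evalue, bit_score = score,
             ali_from = ali_from, ali_to = ali_to, stringsAsFactors = FALSE)
}

check_numeric_fields <- function(evalue, score, line_no) {
  bad <- is.na(evalue) | is.na(score) | evalue < 0 | !is.finite(score)
  if (any(bad)) {
    stop("non-numeric or invalid e-value/bit score at line ",
         paste(line_no[bad], collapse = ", "))
  }
}

genome_prefix <- function(protein_id, delim = "_") {
  sub(paste0("(.*)", delim, "[^", delim, "]*$"), "\\1", protein_id)
}

#' Filter hits with tiered e-value cutoffs and best-hit resolution
#'
#' Hits to families flagged `strict_tier` in the catalog (B1, nitrification
#' and carbon-fixation families) survive only at e-value <= `strict_threshold`;
#' all other catalog families survive at e-value <= `general_threshold`.
#' Both cutoffs are inclusive. Hits to families absent from the catalog are
#' dropped. Among surviving hits, only the best hit per protein is retained:
#' highest bit score, ties broken by lower e-value, then lexicographically
#' smallest family_id.
#'
#' @param hits Data frame of hits from [parse_hit_table()].
#' @param catalog Gene-family catalog from [b1_gene_catalog()].
#' @param general_threshold General-tier e-value cutoff (default 1e-10).
#' @param strict_threshold Strict-tier e-value cutoff (default 1e-15); must
#'   not exceed `general_threshold`.
#' @return The surviving subset of `hits` (at most one row per protein).
#' @export
filter_hits <- function(hits, catalog, general_threshold = 1e-10,
                        strict_threshold = 1e-15) {
  if (!is.numeric(general_threshold) || !is.numeric(strict_threshold) ||
      general_threshold <= 0 || strict_threshold <= 0) {
    stop("e-value thresholds must be positive")
  }
  if (strict_threshold > general_threshold) {
    stop("strict_threshold must not exceed general_threshold")
  }
  idx <- match(hits$family_id, catalog$family_id)
  known <- !is.na(idx)
  hits <- hits[known, , drop = FALSE]
  idx <- idx[known]
  if (nrow(hits) == 0) return(hits)
  cutoff <- ifelse(catalog$strict_tier[idx], strict_threshold,
                   general_threshold)
  hits <- hits[hits$evalue <= cutoff, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  # best hit per protein: max bit score, then min e-value, then family_id
  ord <- order(hits$protein_id, -hits$bit_score, hits$evalue, hits$family_id)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$protein_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Build a genome-by-gene presence/copy matrix
#'
#' Each cell counts the distinct proteins of a genome whose surviving best
#' hit maps to a gene symbol; multi-copy genes therefore appear as counts
#' greater than one. Genomes without any hit form all-zero rows.
#'
#' @param hits Filtered hits ([filter_hits()]).
#' @param catalog Gene-family catalog.
#' @param genomes Character vector of genome identifiers defining the rows.
#' @return Integer matrix (genomes x gene symbols, full catalog vocabulary
#'   in the columns present in the catalog).
#' @export
build_presence_matrix <- function(hits, catalog, genomes) {
  if (length(genomes) == 0) stop("genomes must be non-empty")
  if (anyDuplicated(genomes)) stop("duplicated genome ids")
  symbols <- sort(unique(catalog$gene_symbol))
  mat <- matrix(0L, nrow = length(genomes), ncol = length(symbols),
                dimnames = list(genomes, symbols))
  if (nrow(hits) == 0) return(mat)
  unknown_genome <- setdiff(unique(hits$genome_id), genomes)
  if (length(unknown_genome) > 0) {
    stop("hits reference genome(s) not in the genome set: ",
         paste(unknown_genome, collapse = ", "))
  }
  sym <- catalog$gene_symbol[match(hits$family_id, catalog$family_id)]
  if (anyNA(sym)) {
    stop("hits reference families absent from the catalog; ",
         "run filter_hits() first")
  }
  # distinct proteins per (genome, symbol)
  key <- paste(hits$genome_id, sym, hits$protein_id, sep = "\r")
  uniq <- !duplicated(key)
  tab <- table(factor(hits$genome_id[uniq], levels = genomes),
               factor(sym[uniq], levels = symbols))
  mat[] <- as.integer(tab)
  mat
}

#' Write / read a presence matrix as TSV
#'
#' @param mat Presence matrix from [build_presence_matrix()].
#' @param path Output path.
#' @export
write_presence_matrix <- function(mat, path) {
  df <- data.frame(genome_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- df$genome_id
  mat
}
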