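#' @keywords internal
"_PACKAGE"

# Controlled vocabulary of gene symbols the pipeline understands. Thiamine
# (B1) biosynthesis, salvage and transport genes plus the chemoautotrophy
# marker genes used to co-annotate genotypes.
B1_SYNTHESIS_SYMBOLS <- c("thiC", "thiD", "thiDN", "thiE", "thiG", "thi4",
                          "thiL", "thiN")
B1_SALVAGE_SYMBOLS <- c("thiK", "thiM", "tenA")
B1_TRANSPORTER_SYMBOLS <- c("thiT", "thiB", "thiP", "thiQ", "thiX", "thiY",
                            "thiZ", "cytX", "ykoC", "ykoD", "ykoE", "ykoF",
                            "omr1")
CHEMOAUTOTROPHY_SYMBOLS <- c("amoA", "nxr", "aprA", "aprB", "dsrA", "rbcL")

GENE_VOCABULARY <- c(B1_SYNTHESIS_SYMBOLS, B1_SALVAGE_SYMBOLS,
                     B1_TRANSPORTER_SYMBOLS, CHEMOAUTOTROPHY_SYMBOLS)

# Gene symbols that count towards salvage capability when the de novo
# condensation step is missing (thiL doubles as a synthesis gene).
SALVAGE_CAPABLE_SYMBOLS <- c("thiL", "thiM", "tenA", "thiD",
                             B1_TRANSPORTER_SYMBOLS)

#' Read a gene-family catalog
#'
#' The catalog maps homology-model identifiers (HMM or KO accessions) to
#' canonical gene symbols, functional roles and filtering tiers. Families
#' flagged `strict_tier` are subject to the stricter e-value cutoff used for
#' B1, nitrification and carbon-fixation annotations (default 1e-15); all
#' other families use the general cutoff (default 1e-10).
#'
#' @param path Path to a tab-separated catalog with header columns
#'   `family_id`, `gene_symbol`, `role`, `domain_scope`, `strict_tier`.
#'   `NULL` (default) loads the catalog shipped with the package.
#' @return A data frame with one row per family, validated against the
#'   controlled gene-symbol vocabulary.
#' @examples
#' cat <- b1_gene_catalog()
#' subset(cat, gene_symbol == "thiC")
#' @export
b1_gene_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gene_family_catalog.tsv",
                        package = "b1profiler", mustWork = TRUE)
  }
  cat <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("family_id", "gene_symbol", "role", "domain_scope",
                "strict_tier")
  missing <- setdiff(required, names(cat))
  if (length(missing) > 0) {
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "))
  }
  cat$strict_tier <- toupper(cat$strict_tier) %in% c("TRUE", "T", "1", "YES")
  validate_catalog(cat)
  cat
}

validate_catalog <- function(cat) {
  if (anyDuplicated(cat$family_id)) {
    dup <- unique(cat$family_id[duplicated(cat$family_id)])
    stop("family_id mapped more than once: ", paste(dup, collapse = ", "))
  }
  bad <- setdiff(cat$gene_symbol, GENE_VOCABULARY)
  if (length(bad) > 0) {
    stop("gene symbol(s) outside the controlled vocabulary: ",
         paste(bad, collapse = ", "))
  }
  bad_role <- setdiff(cat$role,
                      c("synthesis", "salvage", "transport", "chemoautotrophy"))
  if (length(bad_role) > 0) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  }
  bad_scope <- setdiff(cat$domain_scope, c("bacteria", "archaea", "both"))
  if (length(bad_scope) > 0) {
    stop("unknown domain_scope value(s): ", paste(bad_scope, collapse = ", "))
  }
  invisible(cat)
}
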