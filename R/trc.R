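# dissolved thiamine-related compound (TRC) depth profiles: replicate
# statistics, oxygen-layer flags, fold changes, local maxima

TRC_COMPOUNDS <- c("B1", "HMP", "HET", "cHET", "AmMP")

#' Read a long-format TRC concentration table
#'
#' Expected columns: `station`, `campaign`, `depth_m`, `compound`,
#' `replicate_id`, `concentration`, and optionally `units` (`pM`, the
#' default, or `fM`; femtomolar values are converted to pM on ingest).
#'
#' @param path Path to the TSV.
#' @return Data frame of replicate-level measurements, concentrations in pM.
#' @export
read_trc_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("station", "campaign", "depth_m", "compound",
                "replicate_id", "concentration")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("TRC table missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(x$compound), TRC_COMPOUNDS)
  if (length(bad) > 0) {
    stop("unknown compound(s): ", paste(bad, collapse = ", "))
  }
  if (any(x$concentration < 0)) stop("concentrations must be non-negative")
  if ("units" %in% names(x)) {
    fm <- x$units == "fM"
    x$concentration[fm] <- x$concentration[fm] / 1000
    x$units <- NULL
  }
  x
}

#' Read a CTD context table
#'
#' @param path TSV with columns `station`, `campaign`, `depth_m`,
#'   `dissolved_oxygen` (umol/kg) and optionally `nitrite`, `nitrate`,
#'   `temperature`.
#' @return Data frame of per-depth hydrographic context.
#' @export
read_ctd_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("station", "campaign", "depth_m", "dissolved_oxygen")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("CTD table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(x$dissolved_oxygen < 0)) stop("dissolved oxygen must be >= 0")
  x
}

#' Replicate statistics per station, campaign, compound and depth
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator; 0 when
#' n = 1) of technical replicates.
#'
#' @param measurements Replicate-level TRC data frame
#'   ([read_trc_table()] layout).
#' @return Profile data frame (`station`, `campaign`, `compound`,
#'   `depth_m`, `mean_pM`, `sd_pM`, `n`), sorted by depth within profile.
#' @export
replicate_stats <- function(measurements) {
  if (nrow(measurements) == 0) stop("no measurements supplied")
  key <- interaction(measurements$station, measurements$campaign,
                     measurements$compound, measurements$depth_m,
                     drop = TRUE, sep = "\r")
  agg <- function(f, default = NA_real_) {
    as.numeric(tapply(measurements$concentration, key, f))
  }
  parts <- strsplit(levels(key), "\r", fixed = TRUE)
  out <- data.frame(
    station = vapply(parts, `[[`, character(1), 1),
    campaign = vapply(parts, `[[`, character(1), 2),
    compound = vapply(parts, `[[`, character(1), 3),
    depth_m = as.numeric(vapply(parts, `[[`, character(1), 4)),
    mean_pM = agg(mean),
    sd_pM = agg(function(v) if (length(v) > 1) stats::sd(v) else 0),
    n = as.integer(tapply(measurements$concentration, key, length)),
    stringsAsFactors = FALSE)
  out <- out[order(out$station, out$campaign, out$compound, out$depth_m), ]
  rownames(out) <- NULL
  out
}

#' Flag OMZ layers and pelagic zones on a TRC profile
#'
#' Joins each profile row to its CTD context (same station and campaign,
#' nearest depth within `depth_tol`) and flags the oxygen minimum zone
#' (dissolved oxygen <= `omz_threshold`, default 30 umol/kg) and its core
#' (<= `core_threshold`, default 10 umol/kg); both cutoffs inclusive. The
#' pelagic layer label comes from [assign_depth_layer()].
#'
#' @param profile Profile rows from [replicate_stats()].
#' @param ctd CTD context data frame ([read_ctd_table()] layout).
#' @param depth_tol Maximum depth mismatch in meters for the join
#'   (default 5).
#' @param omz_threshold,core_threshold Dissolved-oxygen cutoffs in umol/kg.
#' @return `profile` with added `dissolved_oxygen`, `layer`, `omz`,
#'   `omz_core` columns.
#' @export
assign_oxygen_layers <- function(profile, ctd, depth_tol = 5,
                                 omz_threshold = 30, core_threshold = 10) {
  do <- rep(NA_real_, nrow(profile))
  for (i in seq_len(nrow(profile))) {
    cand <- ctd[ctd$station == profile$station[i] &
                  ctd$campaign == profile$campaign[i], , drop = FALSE]
    if (nrow(cand) > 0) {
      gap <- abs(cand$depth_m - profile$depth_m[i])
      if (min(gap) <= depth_tol) {
        do[i] <- cand$dissolved_oxygen[which.min(gap)]
      }
    }
  }
  if (anyNA(do)) {
    miss <- unique(profile$depth_m[is.na(do)])
    stop("no CTD context within ", depth_tol, " m for depth(s): ",
         paste(miss, collapse = ", "))
  }
  profile$dissolved_oxygen <- do
  profile$layer <- assign_depth_layer(profile$depth_m)
  profile$omz <- do <= omz_threshold
  profile$omz_core <- do <= core_threshold
  profile
}

#' Fold change from a reference depth window to a target selection
#'
#' Default: mean concentration over OMZ-flagged mesopelagic depths divided
#' by the mean over the 0-100 m reference window. With `rule = "max"` the
#' target summary is the maximum instead of the mean.
#'
#' @param profile Layer-flagged profile ([assign_oxygen_layers()]).
#' @param compound Compound to evaluate.
#' @param reference Depth window `c(min, max)` in meters (default
#'   `c(0, 100)`).
#' @param rule Target summary rule, `"mean"` (default) or `"max"`.
#' @param target_filter Logical vector over profile rows selecting the
#'   target depths; default `profile$omz & profile$layer == "mesopelagic"`.
#' @return Fold change (target summary / reference mean) with attribute
#'   `rule`.
#' @export
fold_change <- function(profile, compound, reference = c(0, 100),
                        rule = c("mean", "max"), target_filter = NULL) {
  rule <- match.arg(rule)
  rows <- profile[profile$compound == compound, , drop = FALSE]
  ref <- rows$mean_pM[rows$depth_m >= reference[1] &
                        rows$depth_m <= reference[2]]
  if (length(ref) == 0) stop("reference window contains no depths")
  if (is.null(target_filter)) {
    if (!all(c("omz", "layer") %in% names(rows))) {
      stop("profile lacks OMZ flags; run assign_oxygen_layers() first")
    }
    tgt_rows <- rows[rows$omz & rows$layer == "mesopelagic", , drop = FALSE]
  } else {
    tgt_rows <- profile[target_filter & profile$compound == compound, ,
                        drop = FALSE]
  }
  if (nrow(tgt_rows) == 0) stop("target selection contains no depths")
  ref_mean <- mean(ref)
  if (ref_mean == 0) stop("reference mean is zero; fold change undefined")
  fc <- switch(rule, mean = mean(tgt_rows$mean_pM),
               max = max(tgt_rows$mean_pM)) / ref_mean
  attr(fc, "rule") <- rule
  fc
}

#' Local maxima of a compound's depth profile
#'
#' A sampled depth is a local maximum when its mean strictly exceeds the
#' means at both adjacent sampled depths; endpoints qualify against their
#' single neighbor. Results are sorted by mean concentration, largest
#' first.
#'
#' @param profile Profile rows ([replicate_stats()]).
#' @param compound Compound to evaluate.
#' @return Numeric vector of depths (m).
#' @export
find_local_maxima <- function(profile, compound) {
  rows <- profile[profile$compound == compound, , drop = FALSE]
  rows <- rows[order(rows$depth_m), , drop = FALSE]
  n <- nrow(rows)
  if (n < 3) stop("need at least three sampled depths")
  m <- rows$mean_pM
  is_max <- logical(n)
  is_max[1] <- m[1] > m[2]
  is_max[n] <- m[n] > m[n - 1]
  if (n > 2) {
    mid <- 2:(n - 1)
    is_max[mid] <- m[mid] > m[mid - 1] & m[mid] > m[mid + 1]
  }
  depths <- rows$depth_m[is_max]
  depths[order(m[is_max], decreasing = TRUE)]
}
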