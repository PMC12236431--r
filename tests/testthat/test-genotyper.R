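test_that("absence confidence is (1 - completeness)^k", {
  expect_equal(absence_confidence(1.0, 1), 0)
  expect_equal(absence_confidence(0.5, 1), 0.5)
  expect_equal(absence_confidence(0.9, 2), 0.01)
  expect_equal(absence_confidence(0.7, 0), 1)
  expect_error(absence_confidence(1.2, 1), "completeness")
  expect_error(absence_confidence(0.9, -1), "k_absent")
})

test_that("genotype rules reproduce the canonical pathway patterns", {
  call <- function(row, completeness = 0.98, domain = "bacteria") {
    classify_b1_genotype(row, bact_meta(completeness, domain = domain))
  }
  expect_equal(call(presence_row(thiC = 1, thiG = 1, thiE = 1))$category,
               "PROTOTROPH")
  expect_equal(call(presence_row(thiC = 1, thi4 = 1, thiDN = 1),
                    domain = "archaea")$category, "PROTOTROPH")
  # thiE present, thiC+thiG missing at high completeness: dual auxotroph
  r <- classify_b1_genotype(presence_row(thiE = 1), bact_meta(0.99))
  expect_equal(r$category, "AUX_DUAL")
  expect_equal(r$p_chance, 0.01^2)
  # same gene row at low completeness: downgraded
  r2 <- classify_b1_genotype(presence_row(thiG = 1, thiE = 1),
                             bact_meta(0.60))
  expect_equal(r2$category, "INDETERMINATE")
  expect_equal(r2$p_chance, 0.4)
  # HMP auxotroph at high completeness
  expect_equal(call(presence_row(thiG = 1, thiE = 1),
                    completeness = 0.99)$category, "AUX_HMP")
  # salvage-only and no-pathway
  expect_equal(call(presence_row(thiL = 1, omr1 = 1),
                    completeness = 0.999)$category, "SALVAGE_ONLY")
  expect_equal(call(presence_row(amoA = 1),
                    completeness = 0.999)$category, "NO_PATHWAY")
  # thiDN does not satisfy condensation for bacteria by default
  expect_equal(call(presence_row(thiC = 1, thiG = 1, thiDN = 1),
                    completeness = 0.999)$category, "NO_PATHWAY")
  expect_equal(classify_b1_genotype(
    presence_row(thiC = 1, thiG = 1, thiDN = 1), bact_meta(0.999),
    thiDN_archaea_only = FALSE)$category, "PROTOTROPH")
  expect_error(call(presence_row(bogus = 1)), "unknown gene")
})

test_that("prototroph calls carry no absence claim", {
  r <- classify_b1_genotype(presence_row(thiC = 1, thiG = 1, thiE = 1),
                            bact_meta(0.55))
  expect_equal(r$p_chance, 0)
  expect_equal(r$absent_required, "")
})

test_that("every gene combination maps to exactly one category", {
  symbols <- c("thiC", "thiG", "thi4", "thiE", "thiDN", "thiL", "tenA")
  combos <- expand.grid(rep(list(0:1), length(symbols)))
  names(combos) <- symbols
  for (domain in c("bacteria", "archaea")) {
    cats <- apply(combos, 1, function(v) {
      classify_b1_genotype(presence_row(v),
                           bact_meta(0.999, domain = domain))$category
    })
    expect_equal(length(cats), 2^7)
    expect_true(all(cats %in% c("PROTOTROPH", "AUX_HMP", "AUX_HET",
                                "AUX_DUAL", "SALVAGE_ONLY", "NO_PATHWAY",
                                "INDETERMINATE")))
    # independent truth: recompute from the stated boolean rule
    expected <- apply(combos, 1, function(v) {
      pyr <- v[["thiC"]] > 0
      thz <- v[["thiG"]] > 0 || v[["thi4"]] > 0
      cnd <- v[["thiE"]] > 0 ||
        (domain == "archaea" && v[["thiDN"]] > 0)
      k <- (!pyr) + (!thz) + (!cnd)
      base <- if (pyr && thz && cnd) "PROTOTROPH"
        else if (!pyr && thz && cnd) "AUX_HMP"
        else if (pyr && !thz && cnd) "AUX_HET"
        else if (!pyr && !thz && cnd) "AUX_DUAL"
        else if (v[["thiL"]] > 0 || v[["tenA"]] > 0) "SALVAGE_ONLY"
        else "NO_PATHWAY"
      if (base != "PROTOTROPH" && 0.001^k >= 0.05) "INDETERMINATE" else base
    })
    expect_equal(unname(cats), unname(expected))
  }
})

test_that("chemoautotrophy flags follow the marker genes", {
  expect_setequal(
    annotate_chemoautotrophy(presence_row(amoA = 1, thiC = 1, thi4 = 1,
                                          thiDN = 1)),
    "ammonia_oxidation")
  expect_equal(length(annotate_chemoautotrophy(presence_row())), 0)
  expect_setequal(
    annotate_chemoautotrophy(presence_row(aprA = 1, dsrA = 1, rbcL = 2)),
    c("sulfur_oxidation", "cbb_fixation"))
  expect_setequal(
    annotate_chemoautotrophy(presence_row(nxr = 2, aprB = 1)),
    c("nitrite_oxidation", "sulfur_oxidation"))
})

test_that("quality tiers follow the completeness/contamination gates", {
  tier <- function(c, k) classify_b1_genotype(
    presence_row(thiC = 1, thiG = 1, thiE = 1),
    bact_meta(c, contamination = k))$quality_tier
  expect_equal(tier(0.9, 0.01), "high")
  expect_equal(tier(0.9, 0.08), "medium")
  expect_equal(tier(0.9, 0.12), "below_threshold")
  expect_equal(tier(0.4, 0.01), "below_threshold")
})

test_that("decreasing completeness never converts INDETERMINATE to a definite negative", {
  row <- presence_row(thiG = 1, thiE = 1)  # missing thiC
  cats <- sapply(seq(0.99, 0.3, by = -0.01), function(cc) {
    classify_b1_genotype(row, bact_meta(cc))$category
  })
  seen_indet <- FALSE
  for (cat in cats) {
    if (cat == "INDETERMINATE") seen_indet <- TRUE
    if (seen_indet) expect_equal(cat, "INDETERMINATE")
  }
})

test_that("definite negative calls among degraded prototrophs stay calibrated", {
  n <- 600
  alpha <- 0.05
  gs <- generate_genome_set(c(Thioglobaceae_prototroph = n), seed = 21,
                            decoy_rate = 0)
  for (cc in c(0.95, 0.60)) {
    d <- degrade_to_mag(gs, completeness = cc, seed = 22)
    calls <- genotype_cohort(d, alpha = alpha)
    definite_negative <- !calls$category %in% c("PROTOTROPH",
                                                "INDETERMINATE")
    bound <- alpha + 3 * sqrt(alpha * (1 - alpha) / n)
    expect_lt(mean(definite_negative), bound)
  }
})

test_that("genotype summaries report per-domain fractions that sum to one", {
  gs <- small_cohort(seed = 9, n_each = 4)
  calls <- genotype_cohort(gs)
  summ <- genotype_summary(calls, gs$meta, rank = 4)
  for (d in unique(summ$domain)) {
    expect_equal(sum(summ$fraction[summ$domain == d]), 1)
  }
  # planted fractions recovered exactly at completeness 1
  bact <- summ[summ$domain == "bacteria" & summ$count > 0, ]
  expect_setequal(bact$category, c("AUX_HMP", "SALVAGE_ONLY"))
  expect_equal(bact$fraction, c(0.5, 0.5))
  # empty input
  expect_equal(nrow(genotype_summary(calls[0, ], gs$meta)), 0)
  expect_error(genotype_summary(calls, gs$meta, rank = 99), "shallower")
})

test_that("percent-style completeness columns are auto-rescaled", {
  f <- withr::local_tempfile(lines = c(
    "genome_id\tdomain\ttaxonomy\tcompleteness\tcontamination",
    "g1\tbacteria\tBacteria;P;C;O;F\t85\t4",
    "g2\tarchaea\tArchaea;P;C;O;F\t60\t1"))
  meta <- read_genome_meta(f)
  expect_equal(meta$completeness, c(0.85, 0.60))
  expect_equal(meta$contamination, c(0.04, 0.01))
})
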