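test_that("percent-to-molar conversion and round trip", {
  pct100 <- stats::setNames(rep(100, 9), thrombosim:::FACTOR_NAMES)
  comp <- percent_to_molar(pct100)
  expect_equal(comp$fII_uM, 1.4)
  expect_equal(comp$PC_nM, 65)
  comp2 <- percent_to_molar(stats::setNames(c(100, 100, 100, 150, 100, 100,
                                              100, 100, 72),
                                            thrombosim:::FACTOR_NAMES))
  expect_equal(comp2$fVIII_nM, 1.05)
  expect_equal(comp2$PC_nM, 46.8)    # ~ carrier-group mean
  # molar -> percent -> molar round trip
  means <- physiologic_means()
  set.seed(9)
  pct <- stats::setNames(runif(9, 40, 250), thrombosim:::FACTOR_NAMES)
  back <- percent_to_molar(pct)
  conc <- c(back$fII_uM, back$fV_nM, back$fVII_nM, back$fVIII_nM, back$fIX_nM,
            back$fX_nM, back$AT_uM, back$TFPI_nM, back$PC_nM)
  expect_equal(conc / means[thrombosim:::FACTOR_NAMES] * 100,
               pct, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(percent_to_molar(pct100[-1]), "missing factor")
  expect_error(percent_to_molar(replace(pct100, 3, -5)), "nonpositive")
})

test_that("inclusion filters: counts, identity, multi-flag semantics", {
  roster <- generate_cohort(raw_roster = TRUE, seed = 77)
  expect_identical(nrow(roster), 514L)
  kept <- apply_inclusion_filters(roster)
  fr <- attr(kept, "filter_report")
  expect_identical(fr$n_after, 364L)
  expect_identical(fr$n_removed, 150L)
  expect_identical(unname(fr$category_tallies),
                   unname(thrombosim:::default_exclusion_counts()))
  expect_false(any(as.matrix(kept[, thrombosim:::EXCLUSION_FLAGS])))
  # no flags set -> identity
  again <- apply_inclusion_filters(kept)
  expect_identical(nrow(again), nrow(kept))
  # a doubly flagged row is removed once, tallied twice
  two <- kept[1:3, ]
  two$excl_anticoagulant[2] <- TRUE
  two$excl_unconfirmed_event[2] <- TRUE
  f2 <- apply_inclusion_filters(two)
  expect_identical(nrow(f2), 2L)
  expect_identical(sum(attr(f2, "filter_report")$category_tallies), 2L)
  expect_error(apply_inclusion_filters(two[, -ncol(two)]),
               "missing exclusion-flag")
})

test_that("cohort CSV dialects are detected and converted", {
  d <- withr::local_tempdir()
  molar <- data.frame(subject_id = "a", fII_uM = 1.4, fV_nM = 20, fVII_nM = 10,
                      fVIII_nM = 0.7, fIX_nM = 90, fX_nM = 160, AT_uM = 3.6,
                      TFPI_nM = 2.5, PC_nM = 65)
  fm <- file.path(d, "m.csv"); write.csv(molar, fm, row.names = FALSE)
  expect_equal(read_cohort(fm)$PC_nM, 65)
  pct <- data.frame(subject_id = "a")
  for (f in thrombosim:::FACTOR_NAMES) pct[[paste0(f, "_pct")]] <- 100
  fp <- file.path(d, "p.csv"); write.csv(pct, fp, row.names = FALSE)
  cp <- read_cohort(fp)
  expect_equal(cp$fII_uM, 1.4)
  expect_equal(cp$PC_nM, 65)
  mixed <- cbind(molar, fII_pct = 100)
  fx <- file.path(d, "x.csv"); write.csv(mixed, fx, row.names = FALSE)
  expect_error(read_cohort(fx), "mixed unit dialects")
})

test_that("run_cohort produces both arms with control comparison", {
  m <- default_model()
  base <- generate_cohort(seed = 5)[1:2, ]
  # two subjects identical except PC at the carrier/non-carrier group means
  base$subject_id <- c("pc47", "pc110")
  for (f in names(physiologic_means())) {
    col <- paste0(f, "_", thrombosim:::FACTOR_UNITS[[f]])
    base[[col]] <- physiologic_means()[[f]]
  }
  base$PC_nM <- c(47, 110)
  mx <- run_cohort(base, m)
  expect_identical(nrow(mx), 4L)
  expect_setequal(mx$pathway, c("with_pc", "without_pc"))
  ctrl <- attr(mx, "control")
  expect_s3_class(ctrl$with_pc, "thrombin_metrics")
  w <- mx[mx$pathway == "with_pc", ]
  expect_gt(w$MaxL_nM[w$subject_id == "pc47"],
            w$MaxL_nM[w$subject_id == "pc110"])
  expect_gt(w$AUC_uM_s[w$subject_id == "pc47"],
            w$AUC_uM_s[w$subject_id == "pc110"])
  # removing the PC feedback can only increase peak and exposure
  for (id in base$subject_id) {
    wo <- mx[mx$pathway == "without_pc" & mx$subject_id == id, ]
    wi <- mx[mx$pathway == "with_pc" & mx$subject_id == id, ]
    expect_gte(wo$MaxL_nM, wi$MaxL_nM)
    expect_gte(wo$AUC_uM_s, wi$AUC_uM_s)
  }
  # thrombin traces kept on the common grid
  tr <- attr(mx, "thrombin")$with_pc
  expect_identical(dim(tr), c(2L, 1201L))
})

test_that("group summaries report n, mean, sd per stratum", {
  cohort <- generate_cohort(seed = 31)
  # cheap deterministic pseudo-metrics (no ODE runs needed for summary logic)
  mk <- function(ids) data.frame(
    subject_id = rep(ids, each = 2),
    pathway = rep(c("with_pc", "without_pc"), length(ids)),
    MaxL_nM = rep(seq_along(ids) * 10, each = 2),
    CT_s = 300, MaxR_nM_per_s = 1, AUC_uM_s = 30, TMaxL_s = 700,
    TMaxR_s = 600, stringsAsFactors = FALSE)
  mx <- mk(cohort$subject_id)
  s <- summarize_groups(mx, cohort, "pc_mutation")
  expect_identical(s$n[s$group == "yes"][1], 81L)
  expect_identical(s$n[s$group == "no"][1], 283L)
  s2 <- summarize_groups(mx, cohort, "pc_mutation", by_sex = TRUE)
  expect_identical(sum(unique(s2[s2$stratum != "all" & s2$group == "yes",
                                 "n"])), 81L)
  # hand-built moments
  small <- cohort[1:3, ]; small$pc_mutation <- "yes"
  mx3 <- mk(small$subject_id)
  mx3$MaxL_nM <- rep(c(10, 20, 30), each = 2)
  s3 <- summarize_groups(mx3, small, "pc_mutation")
  expect_equal(s3$mean[s3$metric == "MaxL_nM"], 20)
  expect_equal(s3$sd[s3$metric == "MaxL_nM"], 10)
  # empty group
  none <- cohort[0, ]
  expect_identical(nrow(summarize_groups(mx[0, ], none, "pc_mutation")), 0L)
})

test_that("envelope curves are pointwise moments", {
  t1 <- sin(seq(0, 3, length.out = 50)) + 2
  tr <- rbind(t1, t1)
  env <- envelope_curves(tr, c("g", "g"), time = 0:49)
  expect_true(all(env$sd_nM == 0))
  expect_equal(env$mean_nM, unname(t1))
  tr2 <- rbind(t1, -t1 + 6)
  env2 <- envelope_curves(tr2, c("g", "g"), time = 0:49)
  expect_equal(env2$mean_nM, rep(3, 50))
  set.seed(8)
  tr3 <- matrix(runif(100 * 20), 100, 20)
  env3 <- envelope_curves(tr3, rep("g", 100), time = 0:19)
  expect_true(all(env3$mean_nM <= apply(tr3, 2, max) + 1e-12))
  expect_true(all(env3$mean_nM >= apply(tr3, 2, min) - 1e-12))
  expect_error(envelope_curves(tr3, rep("g", 100), time = 0:10),
               "grid mismatch")
})
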