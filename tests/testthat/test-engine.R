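test_that("initial state maps the composition onto the species vector", {
  m <- default_model()
  y0 <- initial_state(m, mean_physiologic_composition())
  expect_equal(y0[["II"]], 1400)
  expect_equal(y0[["AT"]], 3600)
  expect_equal(y0[["TF"]], 0.005)
  expect_equal(y0[["Tm"]], 1)
  expect_equal(y0[["VIIa"]], 0.1)
  expect_equal(y0[["VII"]], 9.9)
  expect_equal(y0[["PC"]], 65)
  active <- setdiff(names(y0), c("TF", "VII", "VIIa", "X", "IX", "II", "V",
                                 "VIII", "AT", "TFPI", "PC", "Tm"))
  expect_true(all(y0[active] == 0))
  # no trigger: TF entry zero, complexes zero
  y0z <- initial_state(m, mean_physiologic_composition(),
                       sim_config(tf_pM = 0))
  expect_identical(y0z[["TF"]], 0)
  # base submodel carries no PC-pathway species
  yb <- initial_state(select_submodel(m, FALSE),
                      mean_physiologic_composition())
  expect_false(any(c("Tm", "PC", "APC") %in% names(yb)))
})

test_that("mass-action RHS equals its definition on toys and matches C++", {
  m <- toy_decay_model(k = 0.01)
  d <- mass_action_rhs(m, c(IIa = 10, AT = 10, `IIa=AT` = 0))
  expect_equal(d[["IIa=AT"]], 1)
  expect_equal(d[["IIa"]], -1)
  expect_equal(d[["AT"]], -1)
  expect_true(all(mass_action_rhs(m, c(IIa = 0, AT = 0, `IIa=AT` = 0)) == 0))
  expect_error(mass_action_rhs(m, c(IIa = NaN, AT = 0, `IIa=AT` = 0)),
               "NaN/Inf")

  full <- default_model()
  net <- thrombosim:::compile_network(full)
  set.seed(11)
  for (i in 1:20) {
    y <- stats::setNames(runif(nrow(full$species), 0, 100),
                         full$species$symbol)
    a <- mass_action_rhs(full, y)
    b <- brute_force_rhs(full, y)
    expect_lt(max(abs(a - b) / pmax(abs(a), abs(b), 1e-300)), 1e-12)
    cc <- as.numeric(thrombosim:::.ros_rhs(net$S, net$r1, net$r2, net$k, y))
    expect_lt(max(abs(a - cc) / pmax(abs(a), 1e-300)), 1e-12)
  }
})

test_that("the analytic Jacobian matches a finite-difference check", {
  full <- default_model()
  net <- thrombosim:::compile_network(full)
  set.seed(3)
  y <- runif(nrow(full$species), 0, 50)
  J <- thrombosim:::.ros_jac(net$S, net$r1, net$r2, net$k, y)
  h <- 1e-6
  for (j in sample(seq_along(y), 8)) {
    yp <- y; yp[j] <- yp[j] + h
    ym <- y; ym[j] <- ym[j] - h
    fd <- (thrombosim:::.ros_rhs(net$S, net$r1, net$r2, net$k, yp) -
             thrombosim:::.ros_rhs(net$S, net$r1, net$r2, net$k, ym)) / (2 * h)
    expect_equal(as.numeric(J[, j]), as.numeric(fd), tolerance = 1e-6)
  }
})

test_that("integrator reproduces the second-order decay closed form", {
  k <- 0.01; C0 <- 100
  m <- toy_decay_model(k = k)
  tc <- simulate_state(m, c(IIa = C0, AT = C0, `IIa=AT` = 0),
                       sim_config(duration_s = 300))
  expected <- C0 / (1 + k * C0 * tc$time)
  expect_lt(max(abs(tc$conc[, "IIa"] - expected) / expected), 1e-6)
})

test_that("simulation contract: grid, determinism, zero-trigger null", {
  m <- default_model()
  cfg <- sim_config(duration_s = 300)
  tc <- simulate_subject(m, mean_physiologic_composition(), cfg)
  expect_identical(length(tc$time), 301L)
  expect_identical(tc$time, seq(0, 300, by = 1))
  expect_true(all(tc$conc >= 0))
  expect_lt(tc$diagnostics$max_drift, 1e-3)
  # thrombin trace is the weighted sum of its constituents
  expect_equal(tc$thrombin,
               as.numeric(tc$conc[, "IIa"] + 1.2 * tc$conc[, "mIIa"]))
  # determinism
  tc2 <- simulate_subject(m, mean_physiologic_composition(), cfg)
  expect_identical(tc$conc, tc2$conc)
  # no tissue factor, no thrombin
  tc0 <- simulate_subject(m, mean_physiologic_composition(),
                          sim_config(tf_pM = 0, duration_s = 300))
  expect_lt(max(tc0$thrombin), 1e-9)
})

test_that("total thrombin trace weighting", {
  conc <- cbind(IIa = c(10, 0), mIIa = c(5, 0))
  expect_equal(total_thrombin_trace(conc), c(16, 0))
  expect_equal(total_thrombin_trace(conc, w_mIIa = 0), c(10, 0))
  expect_warning(
    out <- total_thrombin_trace(cbind(IIa = 1), include_tm_bound = TRUE),
    "absent from the submodel")
  expect_equal(out, 1)
})

test_that("directional composition effects are simulated correctly", {
  m <- default_model()
  cfg <- sim_config()
  base <- compute_metrics(simulate_subject(m, mean_physiologic_composition(),
                                           cfg))
  up_fII <- compute_metrics(simulate_subject(
    m, suppressWarnings(modified_control(fII_uM = 1.8)), cfg))
  expect_gt(up_fII$AUC_uM_s, base$AUC_uM_s)
  up_AT <- compute_metrics(simulate_subject(
    m, suppressWarnings(modified_control(AT_uM = 4.5)), cfg))
  up_TFPI <- compute_metrics(simulate_subject(
    m, suppressWarnings(modified_control(TFPI_nM = 3.0)), cfg))
  ct <- function(x) if (is.na(x$CT_s)) Inf else x$CT_s  # never clotting = late
  expect_gt(ct(up_AT), base$CT_s)
  expect_gt(ct(up_TFPI), base$CT_s)
})

test_that("exhaustion limit: thrombin plateau approaches prothrombin", {
  m <- default_model()
  comp <- suppressWarnings(modified_control(AT_uM = 0, TFPI_nM = 0,
                                            PC_nM = 0))
  tc <- suppressWarnings(simulate_subject(
    m, comp, sim_config(tm_nM = 0, duration_s = 3600)))
  plateau <- utils::tail(total_thrombin_trace(tc, w_IIa = 1, w_mIIa = 1), 1)
  expect_lt(abs(plateau - 1400) / 1400, 0.05)
})

test_that("config files round-trip the simulation configuration", {
  d <- withr::local_tempdir()
  f <- file.path(d, "cfg.txt")
  writeLines(c("# run setup", "tf_pM = 10", "tm_nM = 0.5",
               "duration_s = 600", "include_pc = FALSE",
               "ct_method = grid"), f)
  cfg <- read_sim_config(f)
  expect_equal(cfg$tf_pM, 10)
  expect_equal(cfg$tm_nM, 0.5)
  expect_identical(cfg$duration_s, 600)
  expect_false(cfg$include_pc)
  expect_identical(cfg$ct_method, "grid")
  expect_identical(cfg$report_interval_s, 1)   # untouched default
  writeLines("nonsense = 1", f)
  expect_error(read_sim_config(f), "unknown config key")
})
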