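# Kinetics engine: initial conditions from a plasma composition, stiff
# integration of the mass-action system, and the total-active-thrombin trace.

#' Construct a plasma composition
#'
#' Holds one individual's nine measured factor levels (fII and AT in uM, the
#' rest in nM) plus covariates and group labels.  Values outside the
#' clinically accepted normal range warn; values outside the observed
#' kindred range warn more strongly, but are simulated either way.
#'
#' @param subject_id string.
#' @param fII_uM,fV_nM,fVII_nM,fVIII_nM,fIX_nM,fX_nM,AT_uM,TFPI_nM,PC_nM
#'   factor concentrations; must be finite and non-negative.
#' @param sex `"F"` or `"M"`; `age` in years.
#' @param pc_mutation,pt_g20210a `"yes"`/`"no"`; `thrombosis_history`
#'   `"definite"`/`"none"`.
#' @return a `plasma_composition` (named list).
#' @examples
#' ctrl <- mean_physiologic_composition()
#' ctrl$PC_nM
#' @export
plasma_composition <- function(subject_id = "subject",
                               fII_uM, fV_nM, fVII_nM, fVIII_nM, fIX_nM,
                               fX_nM, AT_uM, TFPI_nM, PC_nM,
                               sex = NA_character_, age = NA_real_,
                               pc_mutation = NA_character_,
                               pt_g20210a = NA_character_,
                               thrombosis_history = NA_character_) {
  vals <- c(fII = fII_uM, fV = fV_nM, fVII = fVII_nM, fVIII = fVIII_nM,
            fIX = fIX_nM, fX = fX_nM, AT = AT_uM, TFPI = TFPI_nM, PC = PC_nM)
  if (any(!is.finite(vals)))
    stop("composition for ", subject_id, ": all nine factors must be finite")
  if (any(vals < 0))
    stop("composition for ", subject_id, ": negative concentration for ",
         paste(names(vals)[vals < 0], collapse = ", "))
  ref <- factor_reference()
  out_obs <- vals < ref$lo | vals > ref$hi
  out_clin <- vals < ref$clin_lo | vals > ref$clin_hi
  if (any(out_obs))
    warning("composition for ", subject_id, ": ",
            paste(names(vals)[out_obs], collapse = ", "),
            " outside the observed kindred range; simulating anyway",
            call. = FALSE)
  else if (any(out_clin))
    warning("composition for ", subject_id, ": ",
            paste(names(vals)[out_clin], collapse = ", "),
            " outside the clinically accepted normal range", call. = FALSE)
  structure(list(subject_id = subject_id,
                 fII_uM = fII_uM, fV_nM = fV_nM, fVII_nM = fVII_nM,
                 fVIII_nM = fVIII_nM, fIX_nM = fIX_nM, fX_nM = fX_nM,
                 AT_uM = AT_uM, TFPI_nM = TFPI_nM, PC_nM = PC_nM,
                 sex = sex, age = age, pc_mutation = pc_mutation,
                 pt_g20210a = pt_g20210a,
                 thrombosis_history = thrombosis_history),
            class = "plasma_composition")
}

#' Mean physiologic control composition
#'
#' All nine factors at their physiologic mean (fII 1.4 uM, fV 20 nM, fVII
#' 10 nM, fVIII 0.7 nM, fIX 90 nM, fX 160 nM, AT 3.6 uM, TFPI 2.5 nM,
#' PC 65 nM).
#'
#' @return a `plasma_composition`.
#' @export
mean_physiologic_composition <- function() {
  m <- physiologic_means()
  suppressWarnings(plasma_composition(
    "physiologic_control", m[["fII"]], m[["fV"]], m[["fVII"]], m[["fVIII"]],
    m[["fIX"]], m[["fX"]], m[["AT"]], m[["TFPI"]], m[["PC"]]))
}

#' Simulation configuration
#'
#' @param tf_pM tissue factor trigger (default 5 pM).
#' @param tm_nM thrombomodulin level (default 1 nM).
#' @param duration_s,report_interval_s reporting window and grid (defaults
#'   1200 s at 1 s; duration must be divisible by the interval).
#' @param include_pc include the protein C pathway module?
#' @param fviia_fraction fraction of measured fVII initialized as fVIIa
#'   (default 0.01; the measured panel has no fVIIa and the cascade needs a
#'   trace of circulating fVIIa to start).
#' @param w_IIa,w_mIIa weights of thrombin and meizothrombin in the
#'   total-active-thrombin trace (defaults 1 and 1.2).
#' @param include_tm_bound count thrombomodulin-bound thrombin species in
#'   the trace (default FALSE).
#' @param rtol,atol solver relative/absolute tolerances (defaults 1e-8 and
#'   1e-12 nM).
#' @param ct_threshold_nM clot-time threshold (default 10 nM).
#' @param ct_method `"interpolate"` (linear interpolation of the first
#'   upward crossing; default) or `"grid"` (first grid point at/above the
#'   threshold).
#' @param max_steps integrator step budget.
#' @return a `sim_config` list.
#' @export
sim_config <- function(tf_pM = 5, tm_nM = 1, duration_s = 1200,
                       report_interval_s = 1, include_pc = TRUE,
                       fviia_fraction = 0.01, w_IIa = 1.0, w_mIIa = 1.2,
                       include_tm_bound = FALSE, rtol = 1e-8, atol = 1e-12,
                       ct_threshold_nM = 10,
                       ct_method = c("interpolate", "grid"),
                       max_steps = 5e6) {
  stopifnot(tf_pM >= 0, tm_nM >= 0, duration_s > 0, report_interval_s > 0,
            rtol > 0, atol > 0, w_IIa >= 0, w_mIIa >= 0,
            fviia_fraction >= 0, fviia_fraction <= 1)
  if (abs(duration_s / report_interval_s -
          round(duration_s / report_interval_s)) > 1e-9)
    stop("duration_s must be divisible by report_interval_s")
  structure(list(tf_pM = tf_pM, tm_nM = tm_nM, duration_s = duration_s,
                 report_interval_s = report_interval_s,
                 include_pc = isTRUE(include_pc),
                 fviia_fraction = fviia_fraction,
                 w_IIa = w_IIa, w_mIIa = w_mIIa,
                 include_tm_bound = isTRUE(include_tm_bound),
                 rtol = rtol, atol = atol,
                 ct_threshold_nM = ct_threshold_nM,
                 ct_method = match.arg(ct_method),
                 max_steps = max_steps),
            class = "sim_config")
}

#' Read a simulation configuration from a flat key-value file
#'
#' Lines of the form `key = value` (or `key: value`), `#` comments allowed;
#' keys are the [sim_config()] argument names.  Unset keys keep their
#' defaults; unknown keys are an error.
#'
#' @param path config file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_0-9]+)\\s*[=:]\\s*(.*)$", lines))
  if (any(lengths(kv) != 3L)) stop("malformed config line: ",
                                   lines[lengths(kv) != 3L][1])
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  known <- names(formals(sim_config))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- lapply(seq_along(keys), function(i) {
    v <- vals[i]
    if (keys[i] %in% c("include_pc", "include_tm_bound"))
      toupper(v) %in% c("TRUE", "T", "YES", "1")
    else if (keys[i] == "ct_method") v
    else as.numeric(v)
  })
  names(args) <- keys
  do.call(sim_config, args)
}

# Map of model species symbol -> composition field and nM conversion.
.zymogen_map <- data.frame(
  symbol = c("II", "V", "VIII", "IX", "X", "AT", "TFPI", "PC"),
  field = c("fII_uM", "fV_nM", "fVIII_nM", "fIX_nM", "fX_nM", "AT_uM",
            "TFPI_nM", "PC_nM"),
  to_nM = c(1000, 1, 1, 1, 1, 1000, 1, 1),
  stringsAsFactors = FALSE)

#' Initial state vector from a plasma composition
#'
#' Zymogens and inhibitors are set to the measured plasma values in nM (fII
#' and AT converted from uM), tissue factor to the trigger, thrombomodulin
#' to its configured level (when the PC module is in the model), and fVIIa
#' to `fviia_fraction` of the measured fVII (fVII reduced accordingly).
#' Every complex, fragment and other active enzyme starts at zero.
#'
#' @param model a `coag_model` (already restricted to the wanted submodel).
#' @param composition a `plasma_composition`.
#' @param config a `sim_config`.
#' @return named numeric state vector (nM), one entry per model species.
#' @export
initial_state <- function(model, composition, config = sim_config()) {
  stopifnot(inherits(model, "coag_model"),
            inherits(composition, "plasma_composition"))
  syms <- model$species$symbol
  y0 <- stats::setNames(numeric(length(syms)), syms)
  zm <- .zymogen_map[.zymogen_map$symbol %in% syms, ]
  for (i in seq_len(nrow(zm))) {
    v <- composition[[zm$field[i]]]
    if (is.null(v) || !is.finite(v))
      stop("composition missing factor ", zm$field[i],
           " required by the model")
    if (v < 0) stop("negative input for ", zm$field[i])
    y0[zm$symbol[i]] <- v * zm$to_nM[i]
  }
  if (!"VII" %in% syms || !"VIIa" %in% syms || !"TF" %in% syms)
    stop("model lacks TF/VII/VIIa species")
  fvii <- composition$fVII_nM
  if (!is.finite(fvii) || fvii < 0) stop("composition missing factor fVII_nM")
  y0["VIIa"] <- config$fviia_fraction * fvii
  y0["VII"] <- (1 - config$fviia_fraction) * fvii
  y0["TF"] <- config$tf_pM / 1000
  if ("Tm" %in% syms) y0["Tm"] <- config$tm_nM
  y0
}

# Compile a model into the flat arrays the C++ stepper consumes (cached on
# the model object's environment would mutate it; recompute -- it is cheap).
compile_network <- function(model) {
  S <- stoichiometry_matrix(model)
  storage.mode(S) <- "double"
  nr <- length(model$reactions)
  r1 <- integer(nr); r2 <- integer(nr); kk <- numeric(nr)
  kv <- stats::setNames(model$rate_constants$value, model$rate_constants$k_id)
  syms <- model$species$symbol
  for (j in seq_len(nr)) {
    r <- model$reactions[[j]]
    idx <- match(names(r$reactants), syms)
    co <- as.integer(r$reactants)
    if (sum(co) == 1L) { r1[j] <- idx[1]; r2[j] <- 0L }
    else if (length(idx) == 1L) { r1[j] <- idx[1]; r2[j] <- idx[1] }
    else { r1[j] <- idx[1]; r2[j] <- idx[2] }
    kk[j] <- kv[[r$rate_constant_id]]
  }
  list(S = S, r1 = r1, r2 = r2, k = kk, symbols = syms)
}

#' Mass-action right-hand side
#'
#' Computes the derivative vector as the stoichiometry-matrix product with
#' the mass-action flux vector, `d y / d t = S v(y)` with
#' `v_r = k_r * prod(reactant concentrations)`.
#'
#' @param model a `coag_model`.
#' @param state named numeric vector (nM) over the model's species.
#' @return named derivative vector (nM/s).
#' @export
mass_action_rhs <- function(model, state) {
  net <- compile_network(model)
  if (length(state) != length(net$symbols))
    stop("state length does not match species count")
  if (any(!is.finite(state))) stop("NaN/Inf in state")
  y <- as.numeric(state[net$symbols])
  y2 <- ifelse(net$r2 > 0, y[pmax(net$r2, 1L)], 1)
  v <- net$k * y[net$r1] * y2
  stats::setNames(as.numeric(net$S %*% v), net$symbols)
}

#' Simulate thrombin generation for one composition
#'
#' Restricts the model to the configured submodel, builds the initial state,
#' and integrates the stiff mass-action system with the package's Rosenbrock
#' stepper (analytic Jacobian generated from the reaction data), reporting
#' every species and the total-active-thrombin trace on the exact
#' `report_interval_s` grid.  Concentrations are clamped to zero at
#' reporting only; the solver propagates the raw state.  Moiety conservation
#' is audited on the reported trajectories and drift beyond 0.1% relative is
#' an error (advising tighter tolerances).
#'
#' @param model a `coag_model`.
#' @param composition a `plasma_composition`.
#' @param config a `sim_config`.
#' @return a `thrombin_timecourse`: `time` (s), `conc` (time x species, nM),
#'   `thrombin` (nM), and `diagnostics` (steps, rejected steps, max relative
#'   conservation drift).
#' @examples
#' \donttest{
#' tc <- simulate_subject(default_model(), mean_physiologic_composition())
#' compute_metrics(tc)
#' }
#' @export
simulate_subject <- function(model, composition, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  sub <- select_submodel(model, config$include_pc)
  y0 <- initial_state(sub, composition, config)
  tc <- simulate_state(sub, y0, config)
  tc$subject_id <- composition$subject_id
  tc
}

#' Integrate a model from an arbitrary initial state
#'
#' Lower-level entry point behind [simulate_subject()]: integrates the
#' mass-action system from a caller-supplied state vector (useful for toy
#' networks and solver verification).  The thrombin trace is attached when
#' the model contains thrombin or meizothrombin species.
#'
#' @param model a `coag_model` (used as-is; no submodel selection).
#' @param y0 named state vector (nM) over exactly the model's species.
#' @param config a `sim_config` (grid, tolerances, thrombin weights).
#' @return a `thrombin_timecourse`.
#' @export
simulate_state <- function(model, y0, config = sim_config()) {
  net <- compile_network(model)
  if (length(y0) != length(net$symbols) ||
      !setequal(names(y0), net$symbols))
    stop("y0 must be named with exactly the model's species")
  y0 <- y0[net$symbols]
  times <- seq(0, config$duration_s, by = config$report_interval_s)
  res <- .ros_integrate(net$S, net$r1, net$r2, net$k, as.numeric(y0), times,
                        config$rtol, config$atol, config$max_steps)
  if (res$status == 1)
    stop("integrator step-size underflow; stiffest flux at species ",
         net$symbols[res$bad_species])
  if (res$status == 2)
    stop("integrator exceeded max_steps = ", config$max_steps)
  conc <- res$conc
  colnames(conc) <- net$symbols
  # conservation audit on the raw reported states
  drift <- conservation_drift(conc, model$moieties)
  if (is.finite(drift) && drift > 1e-3)
    stop(sprintf(paste0("moiety conservation drift %.3g exceeds 0.1%%; ",
                        "tighten rtol/atol"), drift))
  conc[conc < 0] <- 0                      # clamp at reporting only
  tc <- structure(list(
    time = times, conc = conc,
    thrombin = NULL,
    species = net$symbols,
    diagnostics = list(steps = res$steps, rejected = res$rejected,
                       max_drift = drift),
    config = config,
    subject_id = "state"), class = "thrombin_timecourse")
  if (any(c("IIa", "mIIa") %in% net$symbols))
    tc$thrombin <- suppressWarnings(total_thrombin_trace(tc))
  tc
}

conservation_drift <- function(conc, moieties) {
  totals <- conc %*% moieties[colnames(conc), , drop = FALSE]
  t0 <- totals[1, ]
  keep <- t0 > 0
  if (!any(keep)) return(0)
  max(abs(sweep(totals[, keep, drop = FALSE], 2, t0[keep], "/") - 1))
}

#' Total active thrombin trace
#'
#' `w_IIa * [IIa] + w_mIIa * [mIIa]`, optionally adding
#' thrombomodulin-bound thrombin species at the same weights.  Weights for
#' species absent from the simulated submodel are ignored with a warning.
#'
#' @param timecourse a `thrombin_timecourse` (or its `conc` matrix).
#' @param w_IIa,w_mIIa,include_tm_bound weight set; defaults come from the
#'   time course's own config.
#' @return numeric nM trace on the reporting grid.
#' @export
total_thrombin_trace <- function(timecourse, w_IIa = NULL, w_mIIa = NULL,
                                 include_tm_bound = NULL) {
  if (inherits(timecourse, "thrombin_timecourse")) {
    cfg <- timecourse$config
    conc <- timecourse$conc
  } else { cfg <- sim_config(); conc <- timecourse }
  if (is.null(w_IIa)) w_IIa <- cfg$w_IIa
  if (is.null(w_mIIa)) w_mIIa <- cfg$w_mIIa
  if (is.null(include_tm_bound)) include_tm_bound <- cfg$include_tm_bound
  want <- c(IIa = w_IIa, mIIa = w_mIIa)
  if (include_tm_bound)
    want <- c(want, `IIa=Tm` = w_IIa, `IIa=Tm=PC` = w_IIa,
              `mIIa=Tm` = w_mIIa, `mIIa=Tm=PC` = w_mIIa)
  missing <- setdiff(names(want), colnames(conc))
  if (length(missing)) {
    warning("weights for species absent from the submodel ignored: ",
            paste(missing, collapse = ", "), call. = FALSE)
    want <- want[setdiff(names(want), missing)]
  }
  as.numeric(conc[, names(want), drop = FALSE] %*% unname(want))
}

#' Write a time course to TSV
#'
#' First column `time_s`, then one column per species, then
#' `thrombin_total_nM`.
#'
#' @param timecourse a `thrombin_timecourse`.
#' @param path output path.
#' @export
write_timecourse <- function(timecourse, path) {
  df <- data.frame(time_s = timecourse$time, timecourse$conc,
                   thrombin_total_nM = timecourse$thrombin,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.thrombin_timecourse <- function(x, ...) {
  cat(sprintf("thrombin_timecourse '%s': %d species, %d time points (0..%g s)\n",
              x$subject_id, ncol(x$conc), length(x$time), max(x$time)))
  cat(sprintf("  %s; solver: %g steps (%g rejected), max moiety drift %.2g\n",
              if (is.null(x$thrombin)) "no thrombin species"
              else sprintf("peak thrombin %.3g nM", max(x$thrombin)),
              x$diagnostics$steps, x$diagnostics$rejected,
              x$diagnostics$max_drift))
  invisible(x)
}

#' @export
plot.thrombin_timecourse <- function(x, ...) {
  graphics::plot(x$time, x$thrombin, type = "l", xlab = "time (s)",
                 ylab = "total active thrombin (nM)",
                 main = x$subject_id, ...)
  invisible(x)
}
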