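# Reference tables: physiologic means, observed/clinical ranges, and the
# group-specific marginals and group sizes of the kindred study these
# defaults emulate.  Units: fII and AT in uM, the rest in nM.

FACTOR_NAMES <- c("fII", "fV", "fVII", "fVIII", "fIX", "fX", "AT", "TFPI", "PC")
FACTOR_UNITS <- c(fII = "uM", fV = "nM", fVII = "nM", fVIII = "nM",
                  fIX = "nM", fX = "nM", AT = "uM", TFPI = "nM", PC = "nM")

#' Reference table for the nine plasma factors
#'
#' Per factor: kindred mean (SD), observed range, physiologic mean, and the
#' clinically accepted normal range, in assay units (fII and AT in uM,
#' others nM).  These drive composition validation warnings, the
#' percent-to-molar conversion, and the synthetic-cohort generator defaults.
#'
#' @return data frame with one row per factor.
#' @export
factor_reference <- function() {
  data.frame(
    factor = FACTOR_NAMES,
    unit = unname(FACTOR_UNITS),
    mean = c(1.8, 20.1, 10.0, 0.8, 93.3, 167, 3.4, 2.3, 96),
    sd   = c(0.4, 6.7, 2.5, 0.3, 27, 38, 0.6, 0.6, 38),
    lo   = c(0.7, 7.0, 4.0, 0.24, 47.6, 79.8, 1.5, 1.1, 16.0),
    hi   = c(2.9, 60.0, 20.5, 1.8, 225, 274, 5.6, 5.0, 207),
    phys_mean = c(1.4, 20.0, 10.0, 0.7, 90.0, 160, 3.6, 2.5, 65),
    clin_lo = c(0.8, 12, 6, 0.4, 62, 96, 3.2, 1.1, 50),
    clin_hi = c(2.0, 28, 14, 1.6, 135, 224, 6.3, 4.3, 119),
    stringsAsFactors = FALSE)
}

#' Physiologic mean plasma composition
#'
#' Named vector of the nine factor levels at their physiologic means, used
#' as the 100% reference for percent-of-mean inputs and as the control
#' composition.
#'
#' @return named numeric vector (`fII`, `AT` in uM; others in nM).
#' @export
physiologic_means <- function() {
  ref <- factor_reference()
  stats::setNames(ref$phys_mean, ref$factor)
}

# Group-specific factor marginals (mean/sd overrides by stratifier level).
# PC-mutation groups override all nine factors; PT groups override only fII
# (the polymorphism's documented effect); thrombosis groups get no override.
group_overrides <- function() {
  list(
    pc_mutation = list(
      yes = data.frame(
        factor = FACTOR_NAMES,
        mean = c(1.7, 19.4, 9.9, 0.85, 88, 160, 3.5, 2.2, 47),
        sd   = c(0.4, 6.8, 2.5, 0.27, 27, 39, 0.6, 0.6, 29)),
      no = data.frame(
        factor = FACTOR_NAMES,
        mean = c(1.8, 20.6, 10.1, 0.79, 94, 169, 3.3, 2.4, 110),
        sd   = c(0.4, 6.7, 2.4, 0.27, 26, 38, 0.6, 0.6, 28))),
    pt_g20210a = list(
      yes = data.frame(factor = "fII", mean = 2.1, sd = 0.4),
      no  = data.frame(factor = "fII", mean = 1.7, sd = 0.4)))
}

# Default group sizes and per-group sex splits of the emulated kindred.
default_design_sizes <- function() {
  list(
    n_total = 364L,
    pc_mutation = c(yes = 81L, no = 283L),
    pc_mutation_female = c(yes = 54L, no = 159L),
    pt_g20210a = c(yes = 43L, no = 292L),        # 29 subjects untyped
    pt_g20210a_female = c(yes = 21L, no = 174L),
    thrombosis = c(definite = 13L, none = 351L),
    thrombosis_female = c(definite = 8L, none = 205L),
    thrombosis_carriers = 8L)                     # definite cases with PC mutation
}

# Exclusion-category counts of the emulated 514-member roster.
EXCLUSION_FLAGS <- c("excl_anticoagulant", "excl_unknown_anticoagulant",
                     "excl_unconfirmed_event", "excl_superficial_only",
                     "excl_insufficient_sample", "excl_insufficient_composition")
default_exclusion_counts <- function() {
  stats::setNames(c(35L, 5L, 11L, 18L, 6L, 75L), EXCLUSION_FLAGS)
}
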