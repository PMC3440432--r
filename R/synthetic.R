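# Synthetic cohort generation: factor marginals as moment-matched truncated
# normals, group structure with the emulated kindred's printed sizes and sex
# splits, and a multi-generation pedigree for the polygenic statistics.

# ---- truncated normal with matched moments -------------------------------

trunc_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  d <- (dnorm(a) - dnorm(b)) / Z
  m <- mu + sigma * d
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z - d^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Solve for parent (mu, sigma) so the [lo, hi]-truncated normal has the
# requested mean and SD.  Naive truncation would bias strongly cut margins
# (e.g. a mean 1.07 SD above the lower bound) by a quarter SD or more.
solve_trunc_normal <- function(mean, sd, lo, hi) {
  stopifnot(sd > 0, lo < hi)
  if (mean <= lo || mean >= hi)
    stop("infeasible truncation: target mean outside (lo, hi)")
  key <- paste(mean, sd, lo, hi, sep = "|")
  hit <- .thrombosim_env$trunc_cache[[key]]
  if (!is.null(hit)) return(hit)
  obj <- function(p) {
    mm <- trunc_moments(p[1], exp(p[2]), lo, hi)
    (mm[["mean"]] - mean)^2 / sd^2 + (mm[["sd"]] - sd)^2 / sd^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  if (fit$value > 1e-8)
    stop(sprintf(
      "infeasible truncation: cannot match mean %.3g sd %.3g on [%.3g, %.3g]",
      mean, sd, lo, hi))
  out <- c(mu = fit$par[1], sigma = exp(fit$par[2]))
  if (is.null(.thrombosim_env$trunc_cache))
    .thrombosim_env$trunc_cache <- new.env(parent = emptyenv())
  .thrombosim_env$trunc_cache[[key]] <- out
  out
}

# inverse-CDF sampler; u may be supplied (copula path)
rtrunc_normal <- function(n, mean, sd, lo, hi, u = NULL) {
  if (sd == 0) return(rep(mean, n))                 # degenerate limit
  p <- solve_trunc_normal(mean, sd, lo, hi)
  pa <- pnorm((lo - p[["mu"]]) / p[["sigma"]])
  pb <- pnorm((hi - p[["mu"]]) / p[["sigma"]])
  if (is.null(u)) u <- runif(n)
  x <- p[["mu"]] + p[["sigma"]] * qnorm(pa + u * (pb - pa))
  pmin(pmax(x, lo), hi)
}

# ---- factor distribution spec --------------------------------------------

#' Factor distribution specification for the synthetic cohort
#'
#' Per-factor mean, SD and truncation range (defaulting to the emulated
#' kindred's printed marginals and observed ranges), plus per-group
#' mean/SD overrides (PC-mutation groups override all nine factors;
#' prothrombin G20210A groups override fII).
#'
#' @param base data frame with columns `factor`, `mean`, `sd`, `lo`, `hi`;
#'   defaults to [factor_reference()].
#' @param overrides named list (stratifier -> level -> data frame with
#'   `factor`, `mean`, `sd`); defaults to the kindred group marginals.
#' @return a `factor_spec` object.
#' @export
factor_distribution_spec <- function(base = NULL, overrides = NULL) {
  if (is.null(base)) base <- factor_reference()[, c("factor", "mean", "sd",
                                                    "lo", "hi")]
  if (is.null(overrides)) overrides <- group_overrides()
  stopifnot(all(c("factor", "mean", "sd", "lo", "hi") %in% names(base)),
            all(base$sd > 0), all(base$lo < base$mean),
            all(base$mean < base$hi))
  for (ov in overrides) for (lev in ov) {
    bad <- setdiff(lev$factor, base$factor)
    if (length(bad)) stop("override for unknown factor: ",
                          paste(bad, collapse = ", "))
    if (any(lev$sd <= 0)) stop("override sd must be > 0")
  }
  structure(list(base = base, overrides = overrides), class = "factor_spec")
}

effective_margins <- function(spec, pc_mutation = NA, pt_g20210a = NA) {
  m <- spec$base
  apply_ov <- function(m, ov) {
    idx <- match(ov$factor, m$factor)
    m$mean[idx] <- ov$mean; m$sd[idx] <- ov$sd
    m
  }
  if (!is.na(pc_mutation) && pc_mutation %in% names(spec$overrides$pc_mutation))
    m <- apply_ov(m, spec$overrides$pc_mutation[[pc_mutation]])
  if (!is.na(pt_g20210a) && pt_g20210a %in% names(spec$overrides$pt_g20210a))
    m <- apply_ov(m, spec$overrides$pt_g20210a[[pt_g20210a]])
  m
}

#' Sample plasma factor compositions
#'
#' Draws each factor from a truncated normal whose parent parameters are
#' moment-matched so the *truncated* distribution has the group's printed
#' mean/SD; truncation uses the spec's observed ranges.  Factors are
#' independent unless a correlation matrix is supplied, in which case a
#' Gaussian copula couples the margins.
#'
#' @param n number of draws.
#' @param spec a [factor_distribution_spec()].
#' @param pc_mutation,pt_g20210a group labels selecting mean/SD overrides.
#' @param correlation optional 9x9 positive-semidefinite correlation matrix
#'   (factor order as in the spec).
#' @return data frame with columns `fII_uM`, `fV_nM`, ..., `PC_nM`.
#' @export
sample_compositions <- function(n, spec = factor_distribution_spec(),
                                pc_mutation = NA, pt_g20210a = NA,
                                correlation = NULL) {
  m <- effective_margins(spec, pc_mutation, pt_g20210a)
  k <- nrow(m)
  if (!is.null(correlation)) {
    stopifnot(is.matrix(correlation), nrow(correlation) == k)
    ev <- eigen(correlation, symmetric = TRUE)
    if (min(ev$values) < -1e-8)
      stop("correlation matrix is not positive semidefinite")
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k)
    z <- matrix(rnorm(n * k), n, k) %*% t(L)
    U <- pnorm(z)
  } else U <- matrix(runif(n * k), n, k)
  out <- lapply(seq_len(k), function(j)
    rtrunc_normal(n, m$mean[j], m$sd[j], m$lo[j], m$hi[j], u = U[, j]))
  names(out) <- paste0(m$factor, "_", FACTOR_UNITS[m$factor])
  as.data.frame(out)
}

# ---- cohort design and generation ----------------------------------------

#' Cohort design: group sizes and sex splits
#'
#' Defaults emulate the kindred: 364 subjects, 81/283 PC-mutation
#' carriers/non-carriers (54F/27M vs 159F/124M), 43/292 prothrombin-G20210A
#' yes/no (29 untyped), 13/351 definite/no thrombosis history, 8 of the 13
#' definite cases being PC-mutation carriers.
#'
#' @param pc_mutation,pc_mutation_female,pt_g20210a,pt_g20210a_female,
#'   thrombosis,thrombosis_female named 2-vectors of group sizes (overall
#'   and female counts per group).
#' @param thrombosis_carriers definite-history cases that carry the PC
#'   mutation.
#' @return a `cohort_design` list.
#' @export
cohort_design <- function(pc_mutation = NULL, pc_mutation_female = NULL,
                          pt_g20210a = NULL, pt_g20210a_female = NULL,
                          thrombosis = NULL, thrombosis_female = NULL,
                          thrombosis_carriers = NULL) {
  d <- default_design_sizes()
  take <- function(x, dft) if (is.null(x)) dft else x
  des <- list(pc_mutation = take(pc_mutation, d$pc_mutation),
              pc_mutation_female = take(pc_mutation_female, d$pc_mutation_female),
              pt_g20210a = take(pt_g20210a, d$pt_g20210a),
              pt_g20210a_female = take(pt_g20210a_female, d$pt_g20210a_female),
              thrombosis = take(thrombosis, d$thrombosis),
              thrombosis_female = take(thrombosis_female, d$thrombosis_female),
              thrombosis_carriers = take(thrombosis_carriers,
                                         d$thrombosis_carriers))
  if (any(unlist(des) < 0)) stop("group sizes must be nonnegative")
  if (any(des$pc_mutation_female > des$pc_mutation))
    stop("female split exceeds group size")
  n <- sum(des$pc_mutation)
  if (sum(des$pt_g20210a) > n || sum(des$thrombosis) > n)
    stop("inconsistent nested sizes")
  des$n_total <- n
  structure(des, class = "cohort_design")
}

#' Generate a synthetic cohort
#'
#' Builds a cohort with exactly the designed group sizes and sex splits,
#' samples each subject's composition from the group-specific marginals,
#' and (optionally) appends a flagged remainder so the roster carries the
#' emulated study's exclusion-category counts for filter testing.
#'
#' @param design a [cohort_design()].
#' @param spec a [factor_distribution_spec()].
#' @param raw_roster if TRUE, append excluded rows (counts from the emulated
#'   study: 35 anticoagulated, 5 unknown status, 11 unconfirmed events,
#'   18 superficial-only, 6 insufficient sample, 75 insufficient
#'   composition) for a 514-row roster.
#' @param correlation optional factor correlation matrix, see
#'   [sample_compositions()].
#' @param seed integer seed; the cohort is a pure function of
#'   (seed, design, spec).
#' @return a `cohort_table` data frame: subject id, nine factor columns,
#'   sex, age, group labels, and the six logical exclusion-flag columns.
#' @export
generate_cohort <- function(design = cohort_design(),
                            spec = factor_distribution_spec(),
                            raw_roster = FALSE, correlation = NULL,
                            seed = NULL) {
  if (!is.null(seed)) { old <- globalenv()$.Random.seed
    set.seed(seed)
    on.exit(restore_seed(old), add = TRUE) }

  rows <- list()
  for (g in names(design$pc_mutation)) {
    n_g <- design$pc_mutation[[g]]
    n_f <- design$pc_mutation_female[[g]]
    if (n_g == 0L) next
    rows[[g]] <- data.frame(
      pc_mutation = g,
      sex = sample(rep(c("F", "M"), c(n_f, n_g - n_f))),
      stringsAsFactors = FALSE)
  }
  lab <- do.call(rbind, rows)
  n <- nrow(lab)
  lab <- lab[sample.int(n), , drop = FALSE]
  rownames(lab) <- NULL

  # PT genotype assigned within sex strata to hit the printed sex splits;
  # the remainder is left untyped (NA)
  lab$pt_g20210a <- NA_character_
  for (sx in c("F", "M")) {
    idx <- which(lab$sex == sx)
    n_yes <- if (sx == "F") design$pt_g20210a_female[["yes"]]
             else design$pt_g20210a[["yes"]] - design$pt_g20210a_female[["yes"]]
    n_no <- if (sx == "F") design$pt_g20210a_female[["no"]]
            else design$pt_g20210a[["no"]] - design$pt_g20210a_female[["no"]]
    if (n_yes + n_no > length(idx)) stop("PT sex split exceeds stratum size")
    pick <- sample(idx, n_yes + n_no)
    lab$pt_g20210a[pick[seq_len(n_yes)]] <- "yes"
    if (n_no > 0) lab$pt_g20210a[pick[n_yes + seq_len(n_no)]] <- "no"
  }

  # thrombosis history: printed sex split, with the stated carrier share
  lab$thrombosis_history <- "none"
  def_f <- design$thrombosis_female[["definite"]]
  def_m <- design$thrombosis[["definite"]] - def_f
  carr_tot <- design$thrombosis_carriers
  carr_f <- min(def_f, ceiling(carr_tot * def_f / max(1, def_f + def_m)))
  carr_m <- carr_tot - carr_f
  pick_cases <- function(sx, n_def, n_carr) {
    ic <- which(lab$sex == sx & lab$pc_mutation == "yes")
    inc <- which(lab$sex == sx & lab$pc_mutation == "no")
    if (n_carr > length(ic) || (n_def - n_carr) > length(inc))
      stop("thrombosis split incompatible with carrier counts")
    c(if (n_carr > 0) sample(ic, n_carr),
      if (n_def - n_carr > 0) sample(inc, n_def - n_carr))
  }
  cases <- c(pick_cases("F", def_f, carr_f), pick_cases("M", def_m, carr_m))
  lab$thrombosis_history[cases] <- "definite"

  lab$age <- round(runif(n, 18, 85))

  # compositions per PC group, fII re-drawn per PT group where typed
  comp <- as.data.frame(matrix(NA_real_, n, length(FACTOR_NAMES)))
  names(comp) <- paste0(FACTOR_NAMES, "_", FACTOR_UNITS[FACTOR_NAMES])
  for (g in unique(lab$pc_mutation)) {
    idx <- which(lab$pc_mutation == g)
    comp[idx, ] <- sample_compositions(length(idx), spec, pc_mutation = g,
                                       correlation = correlation)
  }
  for (p in c("yes", "no")) {
    idx <- which(!is.na(lab$pt_g20210a) & lab$pt_g20210a == p)
    if (length(idx))
      comp$fII_uM[idx] <- sample_compositions(length(idx), spec,
                                              pt_g20210a = p)$fII_uM
  }

  out <- cbind(data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                          stringsAsFactors = FALSE),
               comp, lab[, c("sex", "age", "pc_mutation", "pt_g20210a",
                             "thrombosis_history")])
  for (fl in EXCLUSION_FLAGS) out[[fl]] <- FALSE

  if (raw_roster) {
    counts <- default_exclusion_counts()
    n_x <- sum(counts)
    xcomp <- sample_compositions(n_x, spec)
    xrows <- cbind(data.frame(subject_id = sprintf("X%04d", seq_len(n_x)),
                              stringsAsFactors = FALSE),
                   xcomp,
                   data.frame(sex = sample(c("F", "M"), n_x, replace = TRUE),
                              age = round(runif(n_x, 18, 85)),
                              pc_mutation = sample(c("yes", "no"), n_x,
                                                   replace = TRUE,
                                                   prob = c(0.33, 0.67)),
                              pt_g20210a = NA_character_,
                              thrombosis_history = "none",
                              stringsAsFactors = FALSE))
    for (fl in EXCLUSION_FLAGS) xrows[[fl]] <- FALSE
    at <- 0L
    for (fl in names(counts)) {
      if (counts[[fl]] > 0)
        xrows[[fl]][at + seq_len(counts[[fl]])] <- TRUE
      at <- at + counts[[fl]]
    }
    out <- rbind(out, xrows)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "provenance") <- list(source = "synthetic", seed = seed,
                                  n_designed = n, raw_roster = raw_roster)
  out
}

restore_seed <- function(old) {
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
}

# ---- pedigree ------------------------------------------------------------

#' Generate a synthetic multi-generation pedigree
#'
#' Founder couples have `mean_offspring` children per generation; children
#' who must reproduce marry newly introduced founders.  Acyclic by
#' construction, parents precede children, reproducible under `seed`.
#'
#' @param founder_pairs number of generation-0 couples.
#' @param generations number of offspring generations (0 = founders only).
#' @param mean_offspring children per couple; with
#'   `offspring_dist = "fixed"` (default) exactly `round(mean_offspring)`,
#'   with `"poisson"` Poisson-distributed.
#' @param seed integer seed.
#' @param offspring_dist see above.
#' @return a `pedigree` data frame (id, father, mother, sex, age,
#'   generation); founders have `NA` parents.
#' @export
generate_pedigree <- function(founder_pairs = 1, generations = 1,
                              mean_offspring = 2, seed = NULL,
                              offspring_dist = c("fixed", "poisson")) {
  stopifnot(founder_pairs >= 1, generations >= 0, mean_offspring >= 0)
  offspring_dist <- match.arg(offspring_dist)
  if (!is.null(seed)) { old <- globalenv()$.Random.seed
    set.seed(seed)
    on.exit(restore_seed(old), add = TRUE) }
  nid <- 0L
  new_id <- function() { nid <<- nid + 1L; sprintf("I%04d", nid) }
  base_age <- 60 + generations * 25
  ped <- data.frame(id = character(0), father = character(0),
                    mother = character(0), sex = character(0),
                    age = numeric(0), generation = integer(0),
                    stringsAsFactors = FALSE)
  add <- function(father, mother, sex, gen) {
    id <- new_id()
    ped[nrow(ped) + 1L, ] <<- list(id, father, mother, sex,
                                   max(18, base_age - 25 * gen +
                                         round(rnorm(1, 0, 4))), gen)
    id
  }
  couples <- lapply(seq_len(founder_pairs), function(i)
    c(add(NA, NA, "M", 0L), add(NA, NA, "F", 0L)))
  for (g in seq_len(generations)) {
    next_couples <- list()
    for (cp in couples) {
      n_off <- if (offspring_dist == "fixed") as.integer(round(mean_offspring))
               else stats::rpois(1, mean_offspring)
      for (j in seq_len(n_off)) {
        sex <- sample(c("M", "F"), 1)
        child <- add(cp[1], cp[2], sex, g)
        if (g < generations) {
          spouse <- add(NA, NA, if (sex == "M") "F" else "M", g)
          next_couples[[length(next_couples) + 1L]] <-
            if (sex == "M") c(child, spouse) else c(spouse, child)
        }
      }
    }
    couples <- next_couples
    if (!length(couples)) break
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Simulate a polygenic trait on a pedigree
#'
#' Generative additive-genetic model: founder genetic values are
#' `N(0, h2 * total_var)`; each child receives the parental midpoint plus
#' segregation noise of variance `h2 * total_var / 2` (reduced for inbred
#' parents), giving genetic covariance `2 * Phi * sigma_g^2`.  The trait is
#' `X beta + g + e` with iid environmental noise of variance
#' `(1 - h2) * total_var`.
#'
#' @param pedigree a `pedigree` data frame.
#' @param h2 narrow-sense heritability in [0, 1].
#' @param total_var total trait variance.
#' @param beta named fixed effects: `intercept`, `age` (per year), `sexM`
#'   (male minus female), `group` (applied to `group_labels == "yes"`).
#' @param group_labels optional per-member labels for the group effect.
#' @param kinship optional precomputed [kinship_matrix()] for the pedigree
#'   (recomputed when omitted).
#' @param seed integer seed.
#' @return numeric trait vector named by member id, with the genetic values
#'   in `attr(, "genetic")`.
#' @export
simulate_polygenic_trait <- function(pedigree, h2, total_var = 1,
                                     beta = c(intercept = 0, age = 0,
                                              sexM = 0, group = 0),
                                     group_labels = NULL, kinship = NULL,
                                     seed = NULL) {
  stopifnot(h2 >= 0, h2 <= 1, total_var >= 0)
  if (!is.null(seed)) { old <- globalenv()$.Random.seed
    set.seed(seed)
    on.exit(restore_seed(old), add = TRUE) }
  sg2 <- h2 * total_var
  se2 <- (1 - h2) * total_var
  n <- nrow(pedigree)
  Phi <- if (is.null(kinship)) kinship_matrix(pedigree) else kinship
  Fcoef <- stats::setNames(2 * diag(Phi) - 1, pedigree$id)
  g <- stats::setNames(numeric(n), pedigree$id)
  ord <- order(pedigree$generation)
  for (i in ord) {
    f <- pedigree$father[i]; m <- pedigree$mother[i]
    if (is.na(f) || is.na(m)) {
      g[i] <- rnorm(1, 0, sqrt(sg2))
    } else {
      seg <- sg2 / 2 * (1 - (Fcoef[[f]] + Fcoef[[m]]) / 2)
      g[i] <- (g[[f]] + g[[m]]) / 2 + rnorm(1, 0, sqrt(max(seg, 0)))
    }
  }
  xb <- beta[["intercept"]] +
    beta[["age"]] * pedigree$age +
    beta[["sexM"]] * (pedigree$sex == "M")
  if (!is.null(group_labels))
    xb <- xb + beta[["group"]] * (group_labels == "yes")
  y <- xb + g + rnorm(n, 0, sqrt(se2))
  names(y) <- pedigree$id
  attr(y, "genetic") <- g
  y
}
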