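# Fixtures are built in code: toy reaction networks written as the same TSV
# transcription format the package parses, hand-built pedigrees, and a
# gene-dropping Monte-Carlo kinship oracle.

write_toy_tables <- function(species, reactions, rates) {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- list(species = file.path(d, "species.tsv"),
                reactions = file.path(d, "reactions.tsv"),
                rates = file.path(d, "rates.tsv"))
  writeLines(c("symbol\tdisplay_name\tmoieties\tsubmodel", species),
             paths$species)
  writeLines(c("reaction_id\tlhs\tarrow\trhs\tk_fwd_id\tk_rev_id\tsubmodel",
               reactions), paths$reactions)
  writeLines(c("k_id\tvalue\tunits\tsource_note", rates), paths$rates)
  paths
}

# A + B <-> A=B, k1 = dissociation (per_second), k2 = association
toy_binding_model <- function(k_off = 1, k_on = 0.01) {
  p <- write_toy_tables(
    species = c("A\tprotein A\tA:1\tbase_extrinsic",
                "B\tprotein B\tB:1\tbase_extrinsic",
                "A=B\tAB complex\tA:1;B:1\tbase_extrinsic"),
    reactions = "R1\tA + B\t<->\tA=B\tk2\tk1\tbase_extrinsic",
    rates = c(sprintf("k1\t%g\tper_second\ttoy off", k_off),
              sprintf("k2\t%g\tper_nanomolar_per_second\ttoy on", k_on)))
  load_model(p$reactions, p$rates, p$species, name = "toy_binding")
}

# irreversible second-order decay IIa + AT -> IIa=AT (closed form available)
toy_decay_model <- function(k = 0.01) {
  p <- write_toy_tables(
    species = c("IIa\tthrombin\tII:1\tbase_extrinsic",
                "AT\tantithrombin\tAT:1\tbase_extrinsic",
                "IIa=AT\tTAT complex\tII:1;AT:1\tbase_extrinsic"),
    reactions = "R1\tIIa + AT\t->\tIIa=AT\tk1\t\tbase_extrinsic",
    rates = sprintf("k1\t%g\tper_nanomolar_per_second\ttoy", k))
  load_model(p$reactions, p$rates, p$species, name = "toy_decay")
}

# founders F1 x M1 -> full sibs C1, C2; K1 is the child of the sibs
inbred_pedigree <- function() {
  data.frame(
    id = c("F1", "M1", "C1", "C2", "K1"),
    father = c(NA, NA, "F1", "F1", "C1"),
    mother = c(NA, NA, "M1", "M1", "C2"),
    sex = c("M", "F", "M", "F", "M"),
    age = c(80, 78, 50, 48, 20),
    generation = c(0L, 0L, 1L, 1L, 2L),
    stringsAsFactors = FALSE)
}

# Monte-Carlo gene dropping: empirical IBD kinship over n_drops replicates
gene_drop_kinship <- function(ped, n_drops = 1e5) {
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  A1 <- matrix(0L, n_drops, n)
  A2 <- matrix(0L, n_drops, n)
  lab <- 0L
  for (i in order(is.na(fa) + is.na(mo), decreasing = TRUE)) {
    if (is.na(fa[i])) {
      A1[, i] <- lab + 1L; A2[, i] <- lab + 2L; lab <- lab + 2L
    }
  }
  # children in an order where parents are done (assume sorted input ok;
  # iterate until filled)
  done <- is.na(fa)
  while (!all(done)) {
    for (i in which(!done)) {
      if (done[fa[i]] && done[mo[i]]) {
        pick1 <- runif(n_drops) < 0.5
        A1[, i] <- ifelse(pick1, A1[, fa[i]], A2[, fa[i]])
        pick2 <- runif(n_drops) < 0.5
        A2[, i] <- ifelse(pick2, A1[, mo[i]], A2[, mo[i]])
        done[i] <- TRUE
      }
    }
  }
  Phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    p <- mean((A1[, i] == A1[, j]) + (A1[, i] == A2[, j]) +
                (A2[, i] == A1[, j]) + (A2[, i] == A2[, j])) / 4
    Phi[i, j] <- Phi[j, i] <- p
  }
  Phi
}

# brute-force mass-action derivative: per-reaction accumulation loop,
# independent of stoichiometry_matrix()
brute_force_rhs <- function(model, state) {
  dy <- stats::setNames(numeric(length(state)), names(state))
  kv <- stats::setNames(model$rate_constants$value, model$rate_constants$k_id)
  for (r in model$reactions) {
    flux <- kv[[r$rate_constant_id]]
    for (s in names(r$reactants)) flux <- flux * state[[s]]^r$reactants[[s]]
    for (s in names(r$reactants)) dy[s] <- dy[s] - r$reactants[[s]] * flux
    for (s in names(r$products)) dy[s] <- dy[s] + r$products[[s]] * flux
  }
  dy
}

random_composition <- function() {
  x <- sample_compositions(1)
  suppressWarnings(plasma_composition(
    "random", x$fII_uM, x$fV_nM, x$fVII_nM, x$fVIII_nM, x$fIX_nM, x$fX_nM,
    x$AT_uM, x$TFPI_nM, x$PC_nM))
}

modified_control <- function(...) {
  comp <- mean_physiologic_composition()
  mods <- list(...)
  for (nm in names(mods)) comp[[nm]] <- mods[[nm]]
  comp
}
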