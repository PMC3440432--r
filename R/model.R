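# Model definition: parse, validate and manipulate the reaction network.
#
# The network is data, not code: three TSV tables (species, reactions, rate
# constants) are the source of truth.  Reversible rows are expanded into two
# irreversible mass-action reactions so the engine has a single code path.

MODEL_SUBMODELS <- c("base_extrinsic", "pc_pathway")
RATE_UNITS <- c("per_second", "per_nanomolar_per_second")

#' Load a coagulation reaction network from its TSV transcription
#'
#' Reads the species, reaction and rate-constant tables, expands every
#' reversible (`<->`) row into an association/dissociation pair sharing a
#' `reversible_pair_id`, and validates the result: referential integrity,
#' unit/molecularity consistency (unimolecular reactions must cite
#' `per_second` constants, bimolecular `per_nanomolar_per_second`), at most
#' two reactant molecules per reaction, and exact conservation of every
#' elementary protein moiety by every reaction.
#'
#' @param reaction_table path to the reaction TSV (columns `reaction_id`,
#'   `lhs`, `arrow` (`->` or `<->`), `rhs`, `k_fwd_id`, `k_rev_id`,
#'   `submodel`).
#' @param rate_table path to the rate TSV (columns `k_id`, `value`, `units`,
#'   `source_note`).
#' @param species_table path to the species TSV (columns `symbol`,
#'   `display_name`, `moieties` as semicolon-separated `moiety:count` pairs,
#'   `submodel`).
#' @param name,version strings stored on the returned model.
#' @return A `coag_model` object: species table, per-species moiety count
#'   matrix, expanded reaction list, and rate-constant table.
#' @examples
#' model <- default_model()
#' model
#' @export
load_model <- function(reaction_table, rate_table, species_table,
                       name = "coagulation", version = "1") {
  sp <- read.delim(species_table, comment.char = "#", stringsAsFactors = FALSE)
  rx <- read.delim(reaction_table, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = "character")
  rt <- read.delim(rate_table, comment.char = "#", stringsAsFactors = FALSE)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(sprintf("%s table missing column(s): %s",
                                   what, paste(miss, collapse = ", ")))
  }
  need(sp, c("symbol", "display_name", "moieties", "submodel"), "species")
  need(rx, c("reaction_id", "lhs", "arrow", "rhs", "k_fwd_id", "k_rev_id",
             "submodel"), "reaction")
  need(rt, c("k_id", "value", "units", "source_note"), "rate")

  if (anyDuplicated(sp$symbol))
    stop("duplicate species symbol: ",
         paste(unique(sp$symbol[duplicated(sp$symbol)]), collapse = ", "))
  if (anyDuplicated(rx$reaction_id))
    stop("duplicate reaction id: ",
         paste(unique(rx$reaction_id[duplicated(rx$reaction_id)]), collapse = ", "))
  if (anyDuplicated(rt$k_id))
    stop("duplicate rate constant id")
  if (!all(sp$submodel %in% MODEL_SUBMODELS))
    stop("unknown submodel tag in species table")
  if (!all(rx$submodel %in% MODEL_SUBMODELS))
    stop("unknown submodel tag in reaction table")
  if (!all(rt$units %in% RATE_UNITS))
    stop("unknown rate units (expected per_second / per_nanomolar_per_second)")
  if (any(!is.finite(rt$value) | rt$value <= 0))
    stop("rate constant values must be finite and > 0: ",
         paste(rt$k_id[!is.finite(rt$value) | rt$value <= 0], collapse = ", "))

  moieties <- parse_moieties(sp$moieties, sp$symbol)
  if (any(rowSums(moieties) == 0))
    stop("species with all-zero moiety map: ",
         paste(sp$symbol[rowSums(moieties) == 0], collapse = ", "))

  # complex symbols: moiety map must equal the sum of the components' maps
  # (checked only when every "="-separated component is itself a species)
  for (i in seq_len(nrow(sp))) {
    parts <- strsplit(sp$symbol[i], "=", fixed = TRUE)[[1]]
    if (length(parts) > 1L && all(parts %in% sp$symbol)) {
      expect <- colSums(moieties[parts, , drop = FALSE])
      if (!all(expect == moieties[i, ]))
        stop("complex ", sp$symbol[i],
             " moiety map does not equal the sum of its components")
    }
  }

  # expand reversible rows
  rows <- vector("list", nrow(rx))
  for (i in seq_len(nrow(rx))) {
    r <- rx[i, ]
    lhs <- parse_side(r$lhs, sp$symbol, r$reaction_id)
    rhs <- parse_side(r$rhs, sp$symbol, r$reaction_id)
    if (identical(r$arrow, "->")) {
      if (nzchar(trimws(r$k_rev_id)))
        stop("irreversible reaction ", r$reaction_id, " has a k_rev_id")
      rows[[i]] <- list(make_rxn(r$reaction_id, lhs, rhs, r$k_fwd_id,
                                 NA_character_, r$submodel))
    } else if (identical(r$arrow, "<->")) {
      if (!nzchar(trimws(r$k_rev_id)))
        stop("reversible reaction ", r$reaction_id, " lacks a k_rev_id")
      rows[[i]] <- list(
        make_rxn(paste0(r$reaction_id, "_f"), lhs, rhs, r$k_fwd_id,
                 r$reaction_id, r$submodel),
        make_rxn(paste0(r$reaction_id, "_r"), rhs, lhs, r$k_rev_id,
                 r$reaction_id, r$submodel))
    } else stop("reaction ", r$reaction_id, ": arrow must be '->' or '<->'")
  }
  reactions <- do.call(c, rows)

  model <- structure(list(
    species = sp[, c("symbol", "display_name", "submodel")],
    moieties = moieties,
    reactions = reactions,
    rate_constants = rt[, c("k_id", "value", "units", "source_note")],
    name = name, version = version), class = "coag_model")
  validate_model(model)
  model
}

parse_moieties <- function(strings, symbols) {
  pairs <- lapply(strings, function(s) {
    toks <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
    kv <- strsplit(toks, ":", fixed = TRUE)
    if (any(lengths(kv) != 2L)) stop("malformed moiety string: ", s)
    stats::setNames(as.integer(vapply(kv, `[`, "", 2L)),
                    trimws(vapply(kv, `[`, "", 1L)))
  })
  moiety_names <- unique(unlist(lapply(pairs, names)))
  m <- matrix(0L, nrow = length(symbols), ncol = length(moiety_names),
              dimnames = list(symbols, moiety_names))
  for (i in seq_along(pairs)) m[i, names(pairs[[i]])] <- pairs[[i]]
  if (any(m < 0L)) stop("negative moiety count")
  m
}

# "A + 2 B" -> named integer vector c(A = 1, B = 2)
parse_side <- function(side, symbols, rid) {
  toks <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  out <- integer(0)
  for (tk in toks) {
    m <- regmatches(tk, regexec("^([0-9]+)\\s+(.*)$", tk))[[1]]
    if (length(m) == 3L) { coef <- as.integer(m[2]); sym <- m[3] }
    else { coef <- 1L; sym <- tk }
    if (!sym %in% symbols)
      stop("reaction ", rid, ": unresolved species symbol '", sym, "'")
    out[sym] <- (if (sym %in% names(out)) out[[sym]] else 0L) + coef
  }
  out
}

make_rxn <- function(id, reactants, products, k_id, pair, submodel) {
  # cancel species appearing identically on both sides? no -- catalysts are
  # legitimate (A + B -> A + C); keep sides verbatim.
  list(id = id, reactants = reactants, products = products,
       rate_constant_id = k_id, reversible_pair_id = pair, submodel = submodel)
}

#' Validate a coagulation model
#'
#' Checks referential integrity, mass-action molecularity (at most two
#' reactant molecules), rate-unit consistency with molecularity, and
#' per-reaction conservation of every moiety.  Called by [load_model()];
#' exported so programmatically built or edited models can be re-checked.
#'
#' @param model a `coag_model`.
#' @return the model, invisibly; errors identify the offending row.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "coag_model"))
  syms <- model$species$symbol
  rates <- model$rate_constants
  for (r in model$reactions) {
    all_sp <- c(names(r$reactants), names(r$products))
    bad <- setdiff(all_sp, syms)
    if (length(bad))
      stop("reaction ", r$id, ": unresolved species symbol '", bad[1], "'")
    n_mol <- sum(r$reactants)
    if (n_mol < 1L || n_mol > 2L)
      stop("reaction ", r$id, ": mass action requires 1 or 2 reactant molecules")
    ki <- match(r$rate_constant_id, rates$k_id)
    if (is.na(ki))
      stop("reaction ", r$id, ": unknown rate constant '", r$rate_constant_id, "'")
    want <- if (n_mol == 1L) "per_second" else "per_nanomolar_per_second"
    if (rates$units[ki] != want)
      stop("reaction ", r$id, ": unit/molecularity mismatch (", n_mol,
           " reactant molecule(s) but ", r$rate_constant_id, " is ",
           rates$units[ki], ")")
    # moiety conservation
    lhs_m <- side_moieties(r$reactants, model$moieties)
    rhs_m <- side_moieties(r$products, model$moieties)
    if (!isTRUE(all.equal(lhs_m, rhs_m, tolerance = 0)))
      stop("reaction ", r$id, ": moiety conservation violated")
  }
  invisible(model)
}

side_moieties <- function(side, moieties) {
  if (!length(side)) return(colSums(moieties) * 0)
  colSums(moieties[names(side), , drop = FALSE] * as.numeric(side))
}

#' Stoichiometry matrix of a model
#'
#' @param model a validated `coag_model`.
#' @return integer matrix (species x reactions) of net stoichiometric
#'   changes; rownames are species symbols, colnames expanded reaction ids.
#' @export
stoichiometry_matrix <- function(model) {
  syms <- model$species$symbol
  S <- matrix(0L, nrow = length(syms), ncol = length(model$reactions),
              dimnames = list(syms, vapply(model$reactions, `[[`, "", "id")))
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    S[names(r$reactants), j] <- S[names(r$reactants), j] - as.integer(r$reactants)
    S[names(r$products), j]  <- S[names(r$products), j] + as.integer(r$products)
  }
  S
}

#' Report conservation of elementary moieties
#'
#' For every moiety, checks that the vector of per-species moiety counts lies
#' in the left null space of the stoichiometry matrix (every reaction's
#' moiety-weighted net change is zero).  Violations are reported, not raised.
#'
#' @param model a `coag_model`.
#' @return a `conservation_report`: data frame of violations (moiety,
#'   reaction id, imbalance) plus the vector of conserved moiety names.
#' @export
check_conservation <- function(model) {
  S <- stoichiometry_matrix(model)
  M <- model$moieties
  imb <- t(M) %*% S                       # moiety x reaction net change
  viol <- which(imb != 0, arr.ind = TRUE)
  violations <- data.frame(
    moiety = rownames(imb)[viol[, 1]],
    reaction_id = colnames(imb)[viol[, 2]],
    imbalance = imb[viol],
    stringsAsFactors = FALSE)
  structure(list(
    violations = violations,
    conserved = setdiff(colnames(M), violations$moiety),
    n_moieties = ncol(M), n_reactions = ncol(S)),
    class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("Conservation check: %d moieties x %d reactions\n",
              x$n_moieties, x$n_reactions))
  if (nrow(x$violations) == 0) cat("All moieties conserved by every reaction.\n")
  else { cat("VIOLATIONS:\n"); print(x$violations) }
  invisible(x)
}

#' Restrict a model to a submodel
#'
#' With `include_pc = FALSE`, removes every `pc_pathway` reaction together
#' with the species that occur only in those reactions, leaving the closed
#' base extrinsic-cascade model; `include_pc = TRUE` is the identity.
#'
#' @param model a `coag_model`.
#' @param include_pc keep the protein C pathway module?
#' @return a validated `coag_model`.
#' @export
select_submodel <- function(model, include_pc = TRUE) {
  if (include_pc) return(model)
  keep_rx <- Filter(function(r) r$submodel == "base_extrinsic", model$reactions)
  used <- unique(unlist(lapply(keep_rx, function(r)
    c(names(r$reactants), names(r$products)))))
  dangling <- used[model$species$submodel[match(used, model$species$symbol)] !=
                     "base_extrinsic"]
  if (length(dangling))
    stop("model tagging error: base reaction references pc_pathway species ",
         paste(dangling, collapse = ", "))
  keep_sp <- model$species$symbol %in% used
  used_k <- unique(vapply(keep_rx, `[[`, "", "rate_constant_id"))
  out <- structure(list(
    species = model$species[keep_sp, , drop = FALSE],
    moieties = model$moieties[keep_sp, , drop = FALSE],
    reactions = keep_rx,
    rate_constants = model$rate_constants[
      model$rate_constants$k_id %in% used_k, , drop = FALSE],
    name = model$name, version = model$version), class = "coag_model")
  rownames(out$species) <- NULL
  rownames(out$rate_constants) <- NULL
  validate_model(out)
  out
}

#' Serialize a model back to its three-table TSV form
#'
#' Inverse of [load_model()]: reversible pairs are re-collapsed into single
#' `<->` rows; row order, species order and constants are preserved, so
#' `load_model()` on the written files reproduces an identical model.
#'
#' @param model a `coag_model`.
#' @param dir output directory; files `species.tsv`, `reactions.tsv`,
#'   `rates.tsv` are written there.
#' @return invisibly, the three file paths.
#' @export
write_model <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  moiety_str <- apply(model$moieties, 1L, function(m) {
    m <- m[m > 0]
    paste(sprintf("%s:%d", names(m), m), collapse = ";")
  })
  sp <- cbind(model$species[, c("symbol", "display_name")],
              moieties = moiety_str,
              submodel = model$species$submodel)
  side_str <- function(v)
    paste(ifelse(v > 1L, paste(v, names(v)), names(v)), collapse = " + ")
  rows <- list(); done <- character(0)
  for (r in model$reactions) {
    if (!is.na(r$reversible_pair_id)) {
      pid <- r$reversible_pair_id
      if (pid %in% done) next
      mate <- Filter(function(q) identical(q$reversible_pair_id, pid) &&
                       q$id != r$id, model$reactions)[[1]]
      fwd <- if (endsWith(r$id, "_f")) r else mate
      rev <- if (endsWith(r$id, "_f")) mate else r
      rows[[length(rows) + 1L]] <- data.frame(
        reaction_id = pid, lhs = side_str(fwd$reactants), arrow = "<->",
        rhs = side_str(fwd$products), k_fwd_id = fwd$rate_constant_id,
        k_rev_id = rev$rate_constant_id, submodel = r$submodel)
      done <- c(done, pid)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        reaction_id = r$id, lhs = side_str(r$reactants), arrow = "->",
        rhs = side_str(r$products), k_fwd_id = r$rate_constant_id,
        k_rev_id = "", submodel = r$submodel)
    }
  }
  paths <- file.path(dir, c("species.tsv", "reactions.tsv", "rates.tsv"))
  write.table(sp, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(do.call(rbind, rows), paths[2], sep = "\t", quote = FALSE,
              row.names = FALSE)
  rt <- model$rate_constants
  # keep full double precision on round-trip
  rt$value <- formatC(rt$value, format = "g", digits = 17)
  write.table(rt, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Load the packaged synthetic model transcription
#'
#' The base extrinsic cascade follows Hockin et al. (2002); the protein C
#' module is a literature-guided synthetic construction (see
#' `inst/extdata/synthetic_model/README.md`).  The parsed model is cached
#' for the session.
#'
#' @return a validated `coag_model` (47 species, 64 irreversible reactions).
#' @export
default_model <- function() {
  if (is.null(.thrombosim_env$model)) {
    d <- system.file("extdata", "synthetic_model", package = "thrombosim")
    .thrombosim_env$model <- load_model(
      file.path(d, "reactions_synthetic.tsv"),
      file.path(d, "rates_synthetic.tsv"),
      file.path(d, "species_synthetic.tsv"),
      name = "extrinsic+PC", version = "1")
  }
  .thrombosim_env$model
}

.thrombosim_env <- new.env(parent = emptyenv())

#' @export
print.coag_model <- function(x, ...) {
  n_rev <- sum(!vapply(x$reactions, function(r) is.na(r$reversible_pair_id),
                       TRUE)) / 2
  cat(sprintf("coag_model '%s' v%s: %d species, %d reactions (%d reversible pairs), %d rate constants\n",
              x$name, x$version, nrow(x$species), length(x$reactions), n_rev,
              nrow(x$rate_constants)))
  tab <- table(x$species$submodel)
  cat("  species by submodel:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
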