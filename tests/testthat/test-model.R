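test_that("packaged transcription loads with zero validation errors", {
  m <- default_model()
  expect_s3_class(m, "coag_model")
  expect_identical(nrow(m$species), 47L)
  expect_identical(length(m$reactions), 64L)
  rep <- check_conservation(m)
  expect_identical(nrow(rep$violations), 0L)
  expect_setequal(rep$conserved, colnames(m$moieties))
  # every reversible expression yields exactly one association/dissociation pair
  pairs <- vapply(m$reactions, `[[`, "", "reversible_pair_id")
  paired <- m$reactions[!is.na(pairs)]
  expect_identical(length(paired) %% 2L, 0L)
  n_assoc <- sum(vapply(paired, function(r) sum(r$reactants) == 2L, TRUE))
  n_dissoc <- sum(vapply(paired, function(r) sum(r$reactants) == 1L, TRUE))
  expect_identical(n_assoc, n_dissoc)
})

test_that("reversible rows expand with the k_off/k_on convention", {
  m <- toy_binding_model(k_off = 1, k_on = 0.01)
  expect_identical(length(m$reactions), 2L)
  fwd <- m$reactions[[1]]  # association drives lhs -> rhs
  rev <- m$reactions[[2]]
  expect_identical(fwd$rate_constant_id, "k2")
  expect_identical(names(fwd$reactants), c("A", "B"))
  expect_identical(names(fwd$products), "A=B")
  expect_identical(rev$rate_constant_id, "k1")
  expect_identical(names(rev$reactants), "A=B")
  expect_identical(fwd$reversible_pair_id, rev$reversible_pair_id)
})

test_that("invalid transcriptions are rejected with the offending row", {
  # A -> A + B creates B from nothing
  expect_error(with(write_toy_tables(
    species = c("A\ta\tA:1\tbase_extrinsic", "B\tb\tB:1\tbase_extrinsic"),
    reactions = "R1\tA\t->\tA + B\tk1\t\tbase_extrinsic",
    rates = "k1\t1\tper_second\tx"),
    load_model(reactions, rates, species)),
    "R1.*moiety conservation")
  # unresolved species symbol
  expect_error(with(write_toy_tables(
    species = "A\ta\tA:1\tbase_extrinsic",
    reactions = "R1\tA + Q\t->\tA\tk1\t\tbase_extrinsic",
    rates = "k1\t1\tper_nanomolar_per_second\tx"),
    load_model(reactions, rates, species)),
    "unresolved species symbol 'Q'")
  # unit/molecularity mismatch: bimolecular reaction citing per_second
  expect_error(with(write_toy_tables(
    species = c("A\ta\tA:1\tbase_extrinsic", "B\tb\tB:1\tbase_extrinsic",
                "A=B\tab\tA:1;B:1\tbase_extrinsic"),
    reactions = "R1\tA + B\t->\tA=B\tk1\t\tbase_extrinsic",
    rates = "k1\t1\tper_second\tx"),
    load_model(reactions, rates, species)),
    "unit/molecularity mismatch")
  # duplicate reaction id
  expect_error(with(write_toy_tables(
    species = c("A\ta\tA:1\tbase_extrinsic", "B\tb\tB:1\tbase_extrinsic",
                "A=B\tab\tA:1;B:1\tbase_extrinsic"),
    reactions = c("R1\tA + B\t->\tA=B\tk1\t\tbase_extrinsic",
                  "R1\tA=B\t->\tA + B\tk2\t\tbase_extrinsic"),
    rates = c("k1\t1\tper_nanomolar_per_second\tx", "k2\t1\tper_second\tx")),
    load_model(reactions, rates, species)),
    "duplicate reaction id")
})

test_that("stoichiometry matrix has the defining structure", {
  m <- default_model()
  S <- stoichiometry_matrix(m)
  expect_identical(dim(S), c(nrow(m$species), length(m$reactions)))
  # TF + VII -> TF=VII association column
  col <- S[, "R01_f"]
  expect_identical(col[["TF"]], -1L)
  expect_identical(col[["VII"]], -1L)
  expect_identical(col[["TF=VII"]], 1L)
  expect_identical(sum(col != 0L), 3L)
  # each dissociation column is the negation of its association partner
  pairs <- vapply(m$reactions, `[[`, "", "reversible_pair_id")
  for (pid in unique(stats::na.omit(pairs)))
    expect_identical(S[, paste0(pid, "_f")], -S[, paste0(pid, "_r")])
  # widest column: intrinsic-tenase decay releasing four product species
  expect_true(all(colSums(abs(S)) <= 5L))
})

test_that("check_conservation reports an injected fault", {
  m <- toy_binding_model()
  m$reactions[[1]]$products <- stats::setNames(integer(0), character(0))
  rep <- check_conservation(m)
  expect_true(all(rep$violations$reaction_id == "R1_f"))
  expect_setequal(rep$violations$moiety, c("A", "B"))
})

test_that("select_submodel removes the PC pathway cleanly", {
  m <- default_model()
  expect_identical(select_submodel(m, TRUE), m)
  b <- select_submodel(m, FALSE)
  expect_false(any(c("Tm", "PC", "APC") %in% b$species$symbol))
  expect_false(any(grepl("Tm|APC|Va5|VIIIai", b$species$symbol)))
  expect_true(all(b$species$submodel == "base_extrinsic"))
  expect_identical(nrow(check_conservation(b)$violations), 0L)
  # idempotence
  expect_identical(select_submodel(b, FALSE), b)
})

test_that("serialize/load round-trips to an identical model", {
  m <- default_model()
  d <- withr::local_tempdir()
  p <- write_model(m, d)
  m2 <- load_model(p[2], p[3], p[1], name = m$name, version = m$version)
  expect_identical(m2$species, m$species)
  expect_identical(m2$moieties, m$moieties)
  expect_identical(vapply(m2$reactions, `[[`, "", "id"),
                   vapply(m$reactions, `[[`, "", "id"))
  expect_identical(lapply(m2$reactions, `[[`, "reactants"),
                   lapply(m$reactions, `[[`, "reactants"))
  expect_equal(m2$rate_constants$value, m$rate_constants$value,
               tolerance = 0)
})
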