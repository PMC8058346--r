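test_that("the JSON dialect reads a constructed toy and round-trips a model", {
  path <- withr::local_tempfile(fileext = ".json")
  tiny_model_json(path)
  m <- read_model(path)
  expect_s3_class(m, "tl_model")
  expect_equal(dim(m$S), c(3L, 2L))
  expect_equal(m$objective, "r2")

  toy <- make_fig1_toy()$model
  path2 <- withr::local_tempfile(fileext = ".json")
  write_model(toy, path2)
  m2 <- read_model(path2)
  expect_equal(as.matrix(m2$S), as.matrix(toy$S))
  expect_equal(m2$reactions, toy$reactions)
  expect_equal(m2$metabolites, toy$metabolites)
  expect_identical(m2$objective, toy$objective)
})

test_that("SBML round trip preserves stoichiometry, bounds and objective", {
  S <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A_c", "B_c"), "r1"))
  m <- tl_model(S, lb = -5, ub = 10, objective = "r1")
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(m, path, format = "sbml")
  m2 <- read_model(path)
  expect_equal(as.matrix(m2$S), as.matrix(m$S))
  expect_equal(m2$reactions$lb, -5)   # reversible bounds preserved
  expect_equal(m2$reactions$ub, 10)
  expect_identical(m2$objective, "r1")
})

test_that("model parsing fails loudly on malformed input and missing objective", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(read_model(bad), "parse failure")

  no_obj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    metabolites = list(list(id = "A_c")),
    reactions = list(list(id = "r1", lower_bound = 0, upper_bound = 1,
                          metabolites = list(A_c = -1)))
  ), no_obj, auto_unbox = TRUE)
  expect_error(read_model(no_obj), "objective")
  expect_silent(read_model(no_obj, objective = "r1"))

  expect_error(read_model(withr::local_tempfile()), "not found")
})

test_that("thermo tables derive unknown sets and report malformed rows", {
  m <- tiny_model()
  path <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("metabolite_id\tdfG0_kJ_per_mol",
               "A_c\t-100", "B_c\t-50", "C_c\t-10"), path)
  th <- read_thermo(path, m)
  expect_length(th$unknown_metabolites, 0)
  expect_length(th$unknown_reactions, 0)

  # B participates in both reactions: omitting it undetermines both
  writeLines(c("metabolite_id\tdfG0_kJ_per_mol",
               "A_c\t-100", "B_c\tNA", "C_c\t-10"), path)
  th2 <- read_thermo(path, m)
  expect_equal(th2$unknown_metabolites, "B_c")
  expect_setequal(th2$unknown_reactions, c("r1", "r2"))

  writeLines(c("metabolite_id\tdfG0_kJ_per_mol",
               "A_c\t-100", "B_c\tbogus"), path)
  expect_error(read_thermo(path, m), "row 3")

  writeLines(c("metabolite_id\tdfG0_kJ_per_mol",
               "A_c\t-100", "A_c\t-90"), path)
  expect_error(read_thermo(path, m), "duplicate")

  writeLines(c("metabolite_id\tdfG0_kJ_per_mol",
               "A_c\t-100", "Zzz_c\t-1"), path)
  expect_warning(read_thermo(path, m), "absent from the model")
})

test_that("a reaction-level dG0 override marks the reaction determined", {
  m <- tiny_model()
  th <- thermo_data(m, c(A_c = -100, C_c = -10),
                    dG0_override = c(r1 = -25))
  expect_equal(th$unknown_metabolites, "B_c")
  expect_equal(th$unknown_reactions, "r2")
  rdg <- reaction_dG0(m, th)
  expect_equal(rdg$dG0[rdg$reaction_id == "r1"], -25)
  expect_true(is.na(rdg$dG0[rdg$reaction_id == "r2"]))
})

test_that("removing a dfG0 entry never shrinks the undetermined reaction set", {
  toy <- make_fig1_toy()
  full <- toy$thermo
  for (met in names(full$dfG0)) {
    reduced <- thermo_data(toy$model, full$dfG0[names(full$dfG0) != met])
    expect_true(all(full$unknown_reactions %in% reduced$unknown_reactions),
                info = paste("dropping", met))
  }
})

test_that("lump reports validate, serialise and round-trip", {
  toy <- make_fig1_toy()
  rs <- extract_reduced_system(toy$model, toy$thermo)
  groups <- partition_groups(rs)
  run <- combined_procedure(rs, groups)
  rep <- lump_report(run, toy$thermo)

  # the U1 lump has three composition rows
  u1_rows <- rep$composition[rep$composition$lump_id == "L1", ]
  expect_equal(nrow(u1_rows), 3)
  expect_setequal(u1_rows$reaction_id, c("r1", "r2", "r7"))

  dir <- withr::local_tempdir()
  write_lump_report(rep, dir)
  rep2 <- read_lump_report(dir)
  expect_equal(as.data.frame(rep2$composition), as.data.frame(rep$composition))
  expect_equal(as.data.frame(rep2$stoichiometry),
               as.data.frame(rep$stoichiometry))
  expect_equal(as.data.frame(rep2$lumps), as.data.frame(rep$lumps))
  expect_equal(rep2$stats$lps_total, rep$stats$lps_total)
  expect_equal(unlist(rep2$stats$eliminated), unlist(rep$stats$eliminated))

  # an empty report writes headers and zero stats
  gem <- make_synthetic_gem(missing_frac = 0, seed = 3)
  rs0 <- extract_reduced_system(split_reversible(gem$model),
                                thermo_data(split_reversible(gem$model),
                                            gem$thermo$dfG0))
  run0 <- combined_procedure(rs0)
  rep0 <- lump_report(run0, gem$thermo)
  expect_equal(rep0$stats$n_lumps, 0)
  expect_equal(rep0$stats$lps_total, 0L)
  dir0 <- withr::local_tempdir()
  write_lump_report(rep0, dir0)
  rep0b <- read_lump_report(dir0)
  expect_equal(nrow(rep0b$composition), 0)
  expect_equal(rep0b$stats$n_eliminated, 0)

  # tampering with the invariants is caught on write
  bad <- rep
  bad$composition$alpha[1] <- -1
  expect_error(write_lump_report(bad, withr::local_tempdir()), "negative")
})
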