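test_that("splitting reversible reactions is the identity when none exist", {
  m <- tiny_model()
  s <- split_reversible(m)
  expect_equal(as.matrix(s$S), as.matrix(m$S))
  expect_equal(nrow(s$split_map), 0)
})

test_that("one reversible reaction yields a forward/reverse pair with negated column", {
  S <- matrix(0, 3, 5, dimnames = list(
    c("A_c", "B_c", "C_c"), paste0("r", 1:5)))
  S[c("A_c", "B_c"), "r1"] <- c(-1, 1)
  S[c("B_c", "C_c"), "r2"] <- c(-1, 1)
  S["A_c", "r3"] <- 1; S["C_c", "r4"] <- -1; S["B_c", "r5"] <- -1
  m <- tl_model(S, lb = c(-4, 0, 0, 0, 0), ub = 10, objective = "r4")
  s <- split_reversible(m)
  expect_equal(nrow(s$reactions), 6)
  expect_setequal(setdiff(s$reactions$id, m$reactions$id),
                  c("r1_fwd", "r1_rev"))
  expect_equal(as.numeric(s$S[, "r1_rev"]), -as.numeric(s$S[, "r1_fwd"]))
  expect_equal(s$reactions$ub[s$reactions$id == "r1_rev"], 4)
  expect_true(all(s$reactions$lb >= 0))
  expect_equal(s$split_map$original, "r1")
})

test_that("splitting preserves the FBA optimum", {
  gem <- make_synthetic_gem(rev_frac = 0.5, seed = 11)
  expect_gt(sum(gem$model$reactions$lb < 0), 0)  # fixture has reversibles
  f0 <- fba(gem$model)$objective
  f1 <- fba(split_reversible(gem$model))$objective
  expect_equal(f1, f0, tolerance = 1e-9)
})

test_that("reaction roles follow the exchange/biomass/transport conventions", {
  S <- matrix(0, 3, 3, dimnames = list(
    c("A_c", "A_e", "B_c"), c("EX_A", "TR_A", "GROW")))
  S["A_e", "EX_A"] <- -1
  S[c("A_c", "A_e"), "TR_A"] <- c(-1, 1)
  S[c("A_c", "B_c"), "GROW"] <- c(-1, 1)
  m <- tl_model(S, lb = 0, ub = 10, objective = "GROW")
  roles <- classify_reactions(m)
  expect_equal(roles$role[roles$reaction_id == "EX_A"], "exchange")
  expect_equal(roles$role[roles$reaction_id == "TR_A"], "transport")
  expect_equal(roles$role[roles$reaction_id == "GROW"], "biomass")
})

test_that("the reduced system keeps undetermined internal reactions only", {
  toy <- make_fig1_toy()
  rs <- extract_reduced_system(toy$model, toy$thermo)
  expect_setequal(colnames(rs$R), paste0("r", 1:7))
  expect_setequal(rs$unknown_rows, c("A_c", "B_c", "E_c", "G_c", "H_c"))

  # a fully annotated model yields an empty system
  all_known <- thermo_data(toy$model,
                           stats::setNames(rep(-100, 12),
                                           toy$model$metabolites$id))
  rs0 <- extract_reduced_system(toy$model, all_known)
  expect_equal(dim(rs0$R), c(0L, 0L))
  expect_length(rs0$unknown_rows, 0)
})

test_that("the transport flag removes undetermined transport reactions from R", {
  S <- matrix(0, 3, 4, dimnames = list(
    c("T_c", "T_e", "B_c"), c("TR", "R1", "EX_T", "GROW")))
  S[c("T_c", "T_e"), "TR"] <- c(-1, 1)
  S[c("T_c", "B_c"), "R1"] <- c(-1, 1)
  S["T_e", "EX_T"] <- -1
  S["B_c", "GROW"] <- -1
  m <- tl_model(S, lb = 0, ub = 10, objective = "GROW")
  th <- thermo_data(m, c(B_c = -10))   # T unknown in both compartments
  with_tr <- extract_reduced_system(m, th, include_transport = TRUE)
  without_tr <- extract_reduced_system(m, th, include_transport = FALSE)
  expect_true("TR" %in% colnames(with_tr$R))
  expect_false("TR" %in% colnames(without_tr$R))
  expect_true("R1" %in% colnames(without_tr$R))
})

test_that("group partition matches the transitive-closure oracle and is order-invariant", {
  toy <- make_fig1_toy()
  rs <- extract_reduced_system(toy$model, toy$thermo)
  groups <- partition_groups(rs)
  expect_equal(nrow(groups), 2)
  expect_equal(groups$members[[1]], c("A_c", "B_c"))
  expect_equal(groups$members[[2]], c("E_c", "G_c", "H_c"))

  for (seed in c(2, 5, 9)) {
    sys <- rand_lump_system(seed)
    rs_r <- as_reduced(sys$R, sys$unknown)
    got <- lapply(partition_groups(rs_r)$members, sort)
    want <- oracle_partition(sys$R, sys$unknown)
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))

    # permuting rows and columns relabels but does not change the partition
    perm_R <- sys$R[sample(nrow(sys$R)), sample(ncol(sys$R)), drop = FALSE]
    rs_p <- as_reduced(perm_R, intersect(rownames(perm_R), sys$unknown))
    got_p <- lapply(partition_groups(rs_p)$members, sort)
    expect_setequal(lapply(got_p, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
  }
})

test_that("groups are separable: no column touches unknown rows of two groups", {
  for (seed in c(3, 7)) {
    gem <- make_synthetic_gem(missing_frac = 0.4, n_noise = 10, seed = seed)
    split <- split_reversible(gem$model)
    th <- thermo_data(split, gem$thermo$dfG0)
    rs <- extract_reduced_system(split, th)
    groups <- partition_groups(rs)
    if (nrow(groups) < 2) next
    for (i in seq_len(nrow(groups) - 1)) {
      for (j in seq(i + 1, nrow(groups))) {
        Ri <- rs$R[groups$members[[i]], , drop = FALSE]
        Rj <- rs$R[groups$members[[j]], , drop = FALSE]
        expect_false(any(colSums(Ri != 0) > 0 & colSums(Rj != 0) > 0))
      }
    }
    # a single unknown metabolite in a single reaction forms its own group
    expect_true(all(groups$size >= 1))
    expect_lte(nrow(groups), length(rs$unknown_rows))
  }
})

test_that("a lone unknown metabolite forms a singleton group", {
  R <- matrix(c(1, -1), 2, 1, dimnames = list(c("u1", "k1"), "c1"))
  groups <- partition_groups(as_reduced(R, "u1"))
  expect_equal(nrow(groups), 1)
  expect_equal(groups$members[[1]], "u1")
  expect_equal(groups$size, 1L)
})
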