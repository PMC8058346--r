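printed_u2 <- function() toy_u2_matrix()

test_that("the printed 3x4 system reproduces the worked feasibility verdicts", {
  R <- printed_u2()

  # whole group: the row-sum identity forces alpha3 = 0 against alpha3 >= 1
  expect_equal(as.numeric(rep(1, 3) %*% R), c(-2, 0, 0, 0))
  s_all <- solve_lump_lp(R, U = rownames(R))
  expect_equal(s_all$status, "infeasible")

  # G alone: r4 + r5 + r6 cancels everything
  s_g <- solve_lump_lp(R, U = "G_c")
  expect_equal(s_g$status, "optimal")
  expect_equal(s_g$objective, 0, tolerance = 1e-9)
  expect_equal(unname(s_g$alpha / s_g$alpha[["r4"]]), c(0, 1, 1, 1),
               tolerance = 1e-9)

  # E alone: |y_G| + |y_H| >= 2 since y_E+y_G+y_H = -2 alpha3, alpha3 >= 1
  s_e <- solve_lump_lp(R, U = "E_c")
  expect_equal(s_e$status, "optimal")
  expect_equal(s_e$objective, 2, tolerance = 1e-9)
})

test_that("LP feasibility and optima match the exhaustive integer oracle", {
  # frozen systems first: the printed matrix under its three seeds
  R <- printed_u2()
  for (U in list(rownames(R), "G_c", "E_c", "H_c")) {
    want <- oracle_lump(R, U)
    got <- solve_lump_lp(R, U = U, alpha_max = 3, integer = TRUE)
    expect_equal(got$status == "optimal", want$feasible, info = paste(U, collapse = "+"))
    if (want$feasible) {
      expect_equal(got$objective, want$objective, tolerance = 1e-6,
                   info = paste(U, collapse = "+"))
    }
  }

  # random battery: <=5 columns, alpha_max 3
  for (seed in 1:8) {
    sys <- rand_lump_system(seed)
    U <- sys$unknown
    want <- oracle_lump(sys$R, U)
    got_int <- solve_lump_lp(sys$R, U = U, alpha_max = 3, integer = TRUE)
    expect_equal(got_int$status == "optimal", want$feasible,
                 info = paste("seed", seed))
    if (want$feasible) {
      expect_equal(got_int$objective, want$objective, tolerance = 1e-6,
                   info = paste("seed", seed))
      # the continuous relaxation can only do at least as well
      got_lp <- solve_lump_lp(sys$R, U = U, alpha_max = 3)
      expect_equal(got_lp$status, "optimal")
      expect_lte(got_lp$objective, want$objective + 1e-6)
    }
  }
})

test_that("enlarging U never lowers the bar: objective grows, feasibility shrinks", {
  R <- printed_u2()
  chains <- list(c("E_c", "G_c", "H_c"), c("G_c", "E_c"), c("H_c", "G_c"))
  for (chain in chains) {
    prev_obj <- -Inf; prev_feasible <- TRUE
    for (k in seq_along(chain)) {
      U <- chain[seq_len(k)]
      sol <- solve_lump_lp(R, U = U, seeds = chain[1])
      if (sol$status == "optimal") {
        expect_true(prev_feasible)  # feasibility is monotone downward
        expect_gte(sol$objective, prev_obj - 1e-9)
        prev_obj <- sol$objective
      } else {
        prev_feasible <- FALSE
      }
    }
  }
})

test_that("sequential lumping over U2 follows the narrated 8-LP trace", {
  toy <- make_fig1_toy()
  rs <- extract_reduced_system(toy$model, toy$thermo)
  u2 <- c("E_c", "G_c", "H_c")

  run <- sequential_lump(rs, u2)
  expect_equal(run$counts$lps_total, 8L)
  expect_equal(run$eliminated, "G_c")
  expect_length(run$lumps, 1)
  expect_setequal(run$lumps[[1]]$alpha$reaction_id, c("r4", "r5", "r6"))
  lps_by_seed <- table(run$log$seed)
  expect_equal(as.integer(lps_by_seed[c("E_c", "G_c", "H_c")]), c(3L, 2L, 3L))

  run_g <- sequential_lump(rs, "G_c")
  expect_equal(run_g$counts$lps_total, 2L)

  run_u1 <- sequential_lump(rs, c("A_c", "B_c"))
  expect_equal(run_u1$counts$lps_total, 4L)
  expect_setequal(run_u1$eliminated, c("A_c", "B_c"))
})

test_that("group LPs succeed on U1, fail on U2, and fail for forced singletons", {
  toy <- make_fig1_toy()
  rs <- extract_reduced_system(toy$model, toy$thermo)
  g1 <- group_lump(rs, c("A_c", "B_c"))
  expect_false(is.null(g1))
  expect_setequal(names(g1$alpha)[g1$alpha > 1e-9], c("r1", "r2", "r7"))
  expect_null(group_lump(rs, c("E_c", "G_c", "H_c")))

  # a metabolite occurring in exactly one column cannot be zeroed with
  # alpha >= 1 forced on that column
  R <- matrix(c(1, -1), 2, 1, dimnames = list(c("u1", "k1"), "c1"))
  expect_null(group_lump(as_reduced(R, "u1"), "u1"))
})

test_that("the combined procedure matches its parts and group order is immaterial", {
  toy <- make_fig1_toy()
  rs <- extract_reduced_system(toy$model, toy$thermo)
  groups <- partition_groups(rs)

  run <- combined_procedure(rs, groups)
  expect_equal(run$counts$lps_group, 2L)
  expect_equal(run$counts$lps_sequential, 8L)
  expect_equal(run$counts$groups_group_success, 1L)
  expect_setequal(run$eliminated, c("A_c", "B_c", "G_c"))

  rev_groups <- groups[rev(seq_len(nrow(groups))), ]
  run_rev <- combined_procedure(rs, rev_groups)
  expect_setequal(run_rev$eliminated, run$eliminated)

  # naive = sequential over everything; same eliminated set, more LPs
  nv <- naive_iterative(rs)
  expect_setequal(nv$eliminated, run$eliminated)
  expect_equal(nv$counts$lps_total, 12L)
  expect_gte(nv$counts$lps_total, length(rs$unknown_rows))
})

test_that("combined and sequential eliminate the same metabolites on random models", {
  for (seed in c(1, 4)) {
    gem <- make_synthetic_gem(missing_frac = 0.3, n_noise = 10, seed = seed)
    split <- split_reversible(gem$model)
    th <- thermo_data(split, gem$thermo$dfG0)
    rs <- extract_reduced_system(split, th)
    run_c <- combined_procedure(rs)
    run_s <- naive_iterative(rs)
    expect_setequal(run_c$eliminated, run_s$eliminated)
    expect_gte(length(run_c$eliminated), 0)
  }
})

test_that("accepted lumps are recorded in primitive reactions and zero out every unknown", {
  toy <- make_fig1_toy()
  rs <- extract_reduced_system(toy$model, toy$thermo)
  runs <- list(combined_procedure(rs))
  gem <- make_synthetic_gem(missing_frac = 0.3, n_noise = 10, rev_frac = 0.4,
                            seed = 5)
  split <- split_reversible(gem$model)
  th <- thermo_data(split, gem$thermo$dfG0)
  rs2 <- extract_reduced_system(split, th)
  runs$gem <- combined_procedure(rs2)
  rss <- list(rs, rs2)
  for (k in seq_along(runs)) {
    rsk <- rss[[k]]
    for (l in runs[[k]]$lumps) {
      # composition refers to original reduced-system columns only
      expect_true(all(l$alpha$reaction_id %in% colnames(rsk$R)))
      expect_true(all(l$alpha$alpha > 0))
      # recomputing y from the primitive combination on the ORIGINAL R
      alpha_full <- stats::setNames(rep(0, ncol(rsk$R)), colnames(rsk$R))
      alpha_full[l$alpha$reaction_id] <- l$alpha$alpha
      y <- as.numeric(rsk$R %*% alpha_full)
      names(y) <- rownames(rsk$R)
      expect_equal(unname(abs(y[rsk$unknown_rows]) < 1e-6),
                   rep(TRUE, length(rsk$unknown_rows)))
      y_rec <- stats::setNames(l$y$coefficient, l$y$metabolite_id)
      expect_equal(y[names(y_rec)], y_rec, tolerance = 1e-9)
      # never both directions of one split reversible reaction
      if (nrow(rsk$split_pairs)) {
        both <- rsk$split_pairs$forward %in% l$alpha$reaction_id &
          rsk$split_pairs$reverse %in% l$alpha$reaction_id
        expect_false(any(both))
      }
    }
  }
})

test_that("an all-known model produces zero LPs and zero lumps", {
  gem <- make_synthetic_gem(missing_frac = 0, seed = 2)
  split <- split_reversible(gem$model)
  th <- thermo_data(split, gem$thermo$dfG0)
  rs <- extract_reduced_system(split, th)
  run <- combined_procedure(rs)
  expect_equal(run$counts$lps_total, 0L)
  expect_length(run$lumps, 0)
  expect_equal(naive_iterative(rs)$counts$lps_total, 0L)
})
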