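#' Toy network with two groups of unknown metabolites
#'
#' A 12-metabolite, 12-reaction model built so that the lumping procedures
#' exercise every branch at desk scale. Metabolites `A_c, B_c` (group U1)
#' and `E_c, G_c, H_c` (group U2) lack a formation energy; all other
#' metabolites are annotated. The submatrix of rows (E, G, H) over columns
#' (r3, r4, r5, r6) is exactly
#' \preformatted{
#'   E: -1  1 -1  0
#'   G:  0 -1  0  1
#'   H: -1  0  1 -1
#' }
#' The known-metabolite coefficients were chosen (by a bounded search over
#' small integers, frozen here as constants) so that the LP trace is forced:
#' U1 is eliminated by one group LP over \{r1, r2, r7\} (or 4 sequential
#' LPs); the U2 group LP is infeasible (summing the three unknown rows gives
#' `y_E + y_G + y_H = -2 alpha_3` while `alpha_3 >= 1` is forced); the
#' sequential pass over U2 takes 3 + 2 + 3 = 8 LPs and eliminates exactly
#' `G_c` via `r4 + r5 + r6`. [verify_fig1_toy()] re-derives all of this
#' against the LP solver.
#'
#' @return A list with elements `model` (a [tl_model()], all reactions
#'   irreversible) and `thermo` (a [thermo_data()]).
#' @export
make_fig1_toy <- function() {
  mets <- c("A_c", "B_c", "E_c", "G_c", "H_c",
            "X_c", "W_c", "Y_c", "N1_c", "P4_c", "P5_c", "P6_c")
  rxns <- c("r1", "r2", "r3", "r4", "r5", "r6", "r7",
            "EX_X", "EX_W", "EX_N1", "EX_P4", "EX_P5", "EX_P6", "biomass")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S[c("X_c", "A_c"), "r1"] <- c(-2, 1)                    # 2X -> A
  S[c("A_c", "B_c"), "r2"] <- c(-1, 1)                    # A -> B
  S[c("E_c", "H_c", "N1_c"), "r3"] <- c(-1, -1, 1)        # E + H -> N1
  S[c("G_c", "N1_c", "P4_c", "E_c"), "r4"] <- c(-1, -1, -1, 1)  # G+N1+P4 -> E
  S[c("E_c", "P5_c", "H_c"), "r5"] <- c(-1, -2, 1)        # E + 2 P5 -> H
  S[c("H_c", "P6_c", "G_c"), "r6"] <- c(-1, -1, 1)        # H + P6 -> G
  S[c("B_c", "W_c", "Y_c"), "r7"] <- c(-1, -1, 1)         # B + W -> Y
  S["X_c", "EX_X"] <- 1
  S["W_c", "EX_W"] <- 1
  S["N1_c", "EX_N1"] <- -1
  S["P4_c", "EX_P4"] <- 1
  S["P5_c", "EX_P5"] <- 1
  S["P6_c", "EX_P6"] <- 1
  S["Y_c", "biomass"] <- -1
  model <- tl_model(S, lb = 0, ub = 10, objective = "biomass")
  dfG0 <- c(X_c = -200, W_c = -150, Y_c = -800,
            N1_c = 100, P4_c = 50, P5_c = 150, P6_c = 80)
  list(model = model, thermo = thermo_data(model, dfG0))
}

#' The printed 3x4 unknown-metabolite system of the toy network
#'
#' Rows E, G, H over columns r3, r4, r5, r6 — the subsystem on which the
#' group LP is provably infeasible while the combination `r4 + r5 + r6`
#' eliminates G.
#'
#' @return A 3x4 numeric matrix with dimnames.
#' @export
toy_u2_matrix <- function() {
  matrix(c(-1, 1, -1, 0,
           0, -1, 0, 1,
           -1, 0, 1, -1),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("E_c", "G_c", "H_c"), c("r3", "r4", "r5", "r6")))
}

#' Verify the toy network against the LP solver
#'
#' Re-checks, at run time, every property the toy fixture is engineered to
#' have: the printed U2 submatrix; success of the U1 group LP with support
#' \{r1, r2, r7\}; infeasibility of the U2 group LP; the per-seed sequential
#' traces over U2 (E: 3 LPs with G then H drawn in; G: 2 LPs ending in
#' `r4 + r5 + r6`; H: 3 LPs, no lump); and the 2-LPs-per-seed sequential
#' trace over U1. Stops with the first violated property.
#'
#' @param toy Result of [make_fig1_toy()].
#' @param integer Verify with integer-valued lump coefficients instead of
#'   the continuous LP (the trace is engineered to be identical).
#' @return TRUE, invisibly.
#' @export
verify_fig1_toy <- function(toy, integer = FALSE) {
  model <- toy$model; thermo <- toy$thermo
  rs <- extract_reduced_system(model, thermo)
  fail <- function(...) stop("toy verification failed: ", ..., call. = FALSE)

  # (i) printed U2 submatrix
  sub <- rs$R[c("E_c", "G_c", "H_c"), c("r3", "r4", "r5", "r6")]
  if (!isTRUE(all.equal(unname(sub), unname(toy_u2_matrix())))) {
    fail("U2 submatrix differs from the printed system")
  }

  groups <- partition_groups(rs)
  if (nrow(groups) != 2) fail("expected 2 groups")
  u1 <- groups$members[[1]]; u2 <- groups$members[[2]]
  if (!setequal(u1, c("A_c", "B_c"))) fail("U1 members")
  if (!setequal(u2, c("E_c", "G_c", "H_c"))) fail("U2 members")

  # (ii) group LP eliminates U1 through r1, r2, r7
  g1 <- group_lump(rs, u1, integer = integer)
  if (is.null(g1)) fail("U1 group LP should succeed")
  if (!setequal(names(g1$alpha)[g1$alpha > 1e-9], c("r1", "r2", "r7"))) {
    fail("U1 group lump support is not {r1, r2, r7}")
  }

  # (iii) group LP on U2 infeasible
  if (!is.null(group_lump(rs, u2, integer = integer))) fail("U2 group LP should be infeasible")

  # (iv) seed E: G drawn in, then H, then infeasible — 3 LPs, no lump
  s1 <- solve_lump_lp(rs$R, U = "E_c", seeds = "E_c",
                      unknown_rows = rs$unknown_rows, integer = integer)
  if (!identical(s1$involved_unknowns, "G_c")) {
    fail("seed E LP1 should involve exactly G")
  }
  R2 <- cbind(rs$R, aug1 = s1$y)
  s2 <- solve_lump_lp(R2, U = c("E_c", "G_c"), seeds = "E_c",
                      unknown_rows = rs$unknown_rows, integer = integer)
  if (!identical(s2$involved_unknowns, "H_c")) {
    fail("seed E LP2 should involve exactly H")
  }
  run_e <- sequential_lump(rs, "E_c", integer = integer)
  if (run_e$counts$lps_total != 3 || length(run_e$lumps) != 0) {
    fail("seed E should take 3 LPs and accept no lump")
  }

  # (v) seed G: one extraneous unknown, then the r4+r5+r6 lump — 2 LPs
  sg <- solve_lump_lp(rs$R, U = "G_c", seeds = "G_c",
                      unknown_rows = rs$unknown_rows, integer = integer)
  if (length(sg$involved_unknowns) != 1) {
    fail("seed G LP1 should involve exactly one other unknown")
  }
  run_g <- sequential_lump(rs, "G_c", integer = integer)
  if (run_g$counts$lps_total != 2 || length(run_g$lumps) != 1) {
    fail("seed G should take 2 LPs and accept one lump")
  }
  supp <- run_g$lumps[[1]]$alpha
  if (!setequal(supp$reaction_id, c("r4", "r5", "r6"))) {
    fail("seed G lump support is not {r4, r5, r6}")
  }

  # (vi) seed H: 3 LPs, no lump
  run_h <- sequential_lump(rs, "H_c", integer = integer)
  if (run_h$counts$lps_total != 3 || length(run_h$lumps) != 0) {
    fail("seed H should take 3 LPs and accept no lump")
  }

  # (vii) sequential-only over U1: 2 LPs per seed
  run_u1 <- sequential_lump(rs, u1, integer = integer)
  per_seed <- table(run_u1$log$seed)
  if (run_u1$counts$lps_total != 4 || any(per_seed != 2)) {
    fail("sequential over U1 should take 2 LPs per seed (4 total)")
  }
  if (!setequal(run_u1$eliminated, u1)) fail("sequential over U1 eliminates both")

  invisible(TRUE)
}

#' Generate a random genome-scale-like model with missing formation energies
#'
#' A chained pathway backbone (uptake, `m1 -> m2 -> ... -> m_k`, biomass
#' drain) guarantees a nonzero FBA optimum; additional random sparse "noise"
#' reactions create the intertwined unknown-metabolite structure the lumping
#' procedures operate on. Formation energies are drawn from Normal(-300, 200)
#' kJ/mol and assigned in decreasing order along the chain, so the backbone
#' is thermodynamically realisable at moderate concentration ratios. A
#' stated fraction of metabolites then loses its dfG0 entry. Generation is a
#' pure function of the seed.
#'
#' @param n_mets Number of metabolites (>= 2).
#' @param n_noise Number of random non-backbone reactions.
#' @param density Fraction of metabolites participating in each noise
#'   reaction (at least 2 metabolites).
#' @param rev_frac Fraction of noise reactions that are reversible.
#' @param missing_frac Fraction of metabolites lacking dfG0.
#' @param seed Integer RNG seed.
#' @return A list with `model`, `thermo`, and `params`.
#' @export
make_synthetic_gem <- function(n_mets = 12, n_noise = 8, density = 0.2,
                               rev_frac = 0.25, missing_frac = 0.25,
                               seed = 1) {
  stopifnot(n_mets >= 2, n_noise >= 0,
            missing_frac >= 0, missing_frac <= 1,
            rev_frac >= 0, rev_frac <= 1)
  withr::with_seed(seed, {
    for (attempt in 1:10) {
      mets <- sprintf("m%02d_c", seq_len(n_mets))
      backbone_ids <- c("EX_in",
                        sprintf("bb%02d", seq_len(n_mets - 1)),
                        "biomass")
      noise_ids <- if (n_noise > 0) sprintf("nx%02d", seq_len(n_noise))
                   else character(0)
      rxns <- c(backbone_ids, noise_ids)
      S <- matrix(0, n_mets, length(rxns), dimnames = list(mets, rxns))
      S[1, "EX_in"] <- 1
      for (i in seq_len(n_mets - 1)) {
        S[i, i + 1L] <- -1
        S[i + 1L, i + 1L] <- 1
      }
      S[n_mets, "biomass"] <- -1
      lb <- rep(0, length(rxns)); ub <- rep(10, length(rxns))
      k_part <- max(2L, round(density * n_mets))
      for (j in seq_along(noise_ids)) {
        who <- sample.int(n_mets, k_part)
        coef <- sample(c(-2, -1, 1, 2), k_part, replace = TRUE)
        # force at least one substrate and one product
        coef[1] <- -abs(coef[1]); coef[2] <- abs(coef[2])
        S[who, noise_ids[j]] <- coef
        if (stats::runif(1) < rev_frac) lb[match(noise_ids[j], rxns)] <- -10
      }
      model <- tl_model(S, lb, ub, objective = "biomass")
      backbone_dfG0 <- sort(stats::rnorm(n_mets, -300, 200), decreasing = TRUE)
      dfG0 <- stats::setNames(backbone_dfG0, mets)
      n_missing <- round(missing_frac * n_mets)
      if (n_missing > 0) {
        dfG0 <- dfG0[-sample.int(n_mets, n_missing)]
      }
      opt <- tryCatch(fba(model)$objective, error = function(e) 0)
      if (opt > 1e-6) {
        return(list(model = model,
                    thermo = thermo_data(model, dfG0),
                    params = list(n_mets = n_mets, n_noise = n_noise,
                                  density = density, rev_frac = rev_frac,
                                  missing_frac = missing_frac, seed = seed)))
      }
    }
  })
  stop("could not generate a model with a nonzero FBA optimum in 10 attempts")
}
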