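# Exhaustive integer-grid oracle for the lumping program: enumerates all
# alpha in {0..alpha_max}^n (with alpha >= 1 forced on columns touching a
# seed metabolite), keeps combinations whose net stoichiometry vanishes on
# U, and minimises sum(|y|). Independent of the LP encoding it checks.
oracle_lump <- function(R, U, seeds = U, alpha_max = 3, tol = 1e-9) {
  n <- ncol(R)
  seed_cols <- apply(R[seeds, , drop = FALSE] != 0, 2, any)
  grids <- lapply(seq_len(n), function(j) {
    if (seed_cols[j]) seq.int(1, alpha_max) else seq.int(0, alpha_max)
  })
  combos <- as.matrix(expand.grid(grids))
  best <- Inf
  feasible <- FALSE
  for (r in seq_len(nrow(combos))) {
    y <- as.numeric(R %*% combos[r, ])
    if (all(abs(y[match(U, rownames(R))]) <= tol)) {
      feasible <- TRUE
      best <- min(best, sum(abs(y)))
    }
  }
  list(feasible = feasible, objective = if (feasible) best else NA_real_)
}

# Brute-force partition oracle: repeated pairwise merging of unknown
# metabolites that share a reaction (transitive closure).
oracle_partition <- function(R, unknown_rows) {
  groups <- as.list(unknown_rows)
  share <- function(a, b) {
    Ra <- R[a, , drop = FALSE]; Rb <- R[b, , drop = FALSE]
    any(colSums(Ra != 0) > 0 & colSums(Rb != 0) > 0)
  }
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        if (share(groups[[i]], groups[[j]])) {
          groups[[i]] <- c(groups[[i]], groups[[j]])
          groups[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  lapply(groups, sort)
}

# Random small lumping system for property batteries: a few unknown rows,
# a few known filler rows, small integer coefficients.
rand_lump_system <- function(seed, max_cols = 5) {
  withr::with_seed(seed, {
    n <- sample(2:max_cols, 1)
    n_unknown <- sample(1:3, 1)
    n_known <- sample(1:3, 1)
    m <- n_unknown + n_known
    repeat {
      R <- matrix(sample(-2:2, m * n, replace = TRUE,
                         prob = c(.15, .2, .3, .2, .15)), m, n)
      if (all(colSums(R != 0) > 0) && all(rowSums(R != 0) > 0)) break
    }
    rownames(R) <- c(sprintf("u%d", seq_len(n_unknown)),
                     sprintf("k%d", seq_len(n_known)))
    colnames(R) <- sprintf("c%d", seq_len(n))
    list(R = R, unknown = sprintf("u%d", seq_len(n_unknown)))
  })
}
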