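#' Solve one lumping linear program
#'
#' Finds a nonnegative combination `alpha` of the reduced-system columns whose
#' net stoichiometry `y = R alpha` is zero on every metabolite in `U`, while
#' minimising the total absolute stoichiometry `sum(|y|)` of the candidate
#' lumped reaction (via the standard `y = y+ - y-` variable split). Columns
#' containing a *seed* metabolite are forced into the combination
#' (`alpha >= 1`); all other columns have `alpha >= 0`.
#'
#' Infeasibility is a regular outcome (the group cannot be eliminated), not
#' an error; numerical solver failures raise an error.
#'
#' @param R Numeric matrix (metabolites x reactions) with dimnames.
#' @param U Character vector of metabolite row names whose net coefficient is
#'   constrained to zero.
#' @param seeds Character vector of metabolite row names whose containing
#'   columns receive `alpha_min = 1`. Typically `U` itself (group mode) or
#'   the single starting metabolite (sequential mode).
#' @param unknown_rows Metabolite row names lacking dfG0; used to report
#'   which unknown metabolites outside `U` the solution still involves.
#' @param alpha_max Upper bound on every coefficient (default 1000).
#' @param tol Absolute tolerance for treating a coefficient as zero.
#' @param integer Solve with integer-valued `alpha` instead of continuous.
#' @param time_limit Seconds per solve, or NULL.
#' @return An object of class `tl_lump_solution` with fields `status`
#'   (`"optimal"` or `"infeasible"`), `alpha` (named vector over columns),
#'   `y` (named net stoichiometry), `objective`, `involved_unknowns`.
#' @export
solve_lump_lp <- function(R, U, seeds = U, unknown_rows = U,
                          alpha_max = 1000, tol = 1e-9, integer = FALSE,
                          time_limit = NULL) {
  stopifnot(is.matrix(R) || inherits(R, "Matrix"))
  m <- nrow(R); n <- ncol(R)
  stopifnot(all(U %in% rownames(R)), all(seeds %in% rownames(R)))
  seed_cols <- if (length(seeds))
    apply(R[seeds, , drop = FALSE] != 0, 2, any) else rep(FALSE, n)
  alpha_min <- as.numeric(seed_cols)
  if (any(alpha_min > alpha_max)) stop("alpha_max below forced alpha_min")
  # variables: alpha (n), y+ (m), y- (m)
  A_eq <- cbind(as.matrix(R), -diag(m), diag(m))
  lb <- c(alpha_min, rep(0, 2 * m))
  ub <- c(rep(alpha_max, n), rep(Inf, 2 * m))
  u_idx <- match(U, rownames(R))
  ub[n + u_idx] <- 0        # y+_u = 0
  ub[n + m + u_idx] <- 0    # y-_u = 0
  res <- tl_solve(tl_lp(
    c = c(rep(0, n), rep(1, 2 * m)),
    A_eq = A_eq, b_eq = rep(0, m), lb = lb, ub = ub,
    integrality = if (integer) c(rep(1L, n), rep(0L, 2 * m)) else NULL,
    time_limit = time_limit
  ))
  if (res$status == "infeasible") {
    return(structure(list(status = "infeasible", alpha = NULL, y = NULL,
                          objective = NA_real_, involved_unknowns = NULL,
                          U = U, seeds = seeds),
                     class = "tl_lump_solution"))
  }
  if (res$status != "optimal") {
    stop("lumping LP solver failure (status: ", res$status, ")")
  }
  alpha <- stats::setNames(res$x[seq_len(n)], colnames(R))
  alpha[abs(alpha) < tol] <- 0
  y <- stats::setNames(as.numeric(as.matrix(R) %*% alpha), rownames(R))
  y[abs(y) < tol] <- 0
  involved <- setdiff(unknown_rows, U)
  involved <- involved[abs(y[involved]) > tol]
  structure(
    list(status = "optimal", alpha = alpha, y = y,
         objective = res$objective, involved_unknowns = involved,
         U = U, seeds = seeds),
    class = "tl_lump_solution"
  )
}

#' @export
print.tl_lump_solution <- function(x, ...) {
  if (x$status != "optimal") {
    cat("<tl_lump_solution> infeasible\n")
    return(invisible(x))
  }
  cat(sprintf("<tl_lump_solution> objective %.4g, support {%s}\n",
              x$objective,
              paste(names(x$alpha)[x$alpha > 0], collapse = ", ")))
  invisible(x)
}

# Cancel null combinations where both split directions of one reversible
# reaction appear in the support: subtracting min(alpha_fwd, alpha_rev) from
# both leaves y unchanged (the columns are negatives of each other) and the
# objective cannot see the difference.
.cancel_split_pairs <- function(alpha, split_pairs, tol = 1e-9) {
  if (is.null(split_pairs) || nrow(split_pairs) == 0) return(alpha)
  for (i in seq_len(nrow(split_pairs))) {
    f <- split_pairs$forward[i]; r <- split_pairs$reverse[i]
    if (f %in% names(alpha) && r %in% names(alpha)) {
      d <- min(alpha[[f]], alpha[[r]])
      if (d > tol) {
        alpha[[f]] <- alpha[[f]] - d
        alpha[[r]] <- alpha[[r]] - d
      }
    }
  }
  alpha
}

.lump_record <- function(rs, primitive_alpha, U, seed, group_id, mode, n_lps,
                         tol = 1e-9) {
  alpha <- .cancel_split_pairs(primitive_alpha, rs$split_pairs, tol)
  y <- stats::setNames(as.numeric(rs$R %*% alpha), rownames(rs$R))
  y[abs(y) < tol] <- 0
  support <- alpha[alpha > tol]
  list(
    seed = seed, group_id = group_id, mode = mode, n_lps = n_lps,
    targets = U,
    alpha = tibble::tibble(reaction_id = names(support),
                           alpha = as.numeric(support)),
    y = tibble::tibble(metabolite_id = names(y)[y != 0],
                       coefficient = as.numeric(y[y != 0]))
  )
}

.empty_counts <- function() {
  list(lps_total = 0L, lps_group = 0L, lps_sequential = 0L,
       groups_total = 0L, groups_group_success = 0L,
       groups_group_infeasible = 0L)
}

.empty_log <- function() {
  tibble::tibble(phase = character(0), group_id = integer(0),
                 seed = character(0), U_size = integer(0),
                 status = character(0), objective = numeric(0),
                 duration = numeric(0))
}

#' Attempt to eliminate a whole group with one LP
#'
#' Solves the lumping LP with `U = seeds = ` the group members. The solution
#' is accepted only when it is feasible *and* involves no unknown metabolite
#' outside the group target set, so that the lumped reaction's dG0 is
#' computable.
#'
#' @param rs A [extract_reduced_system()] result.
#' @param members Character vector: the group's unknown metabolites.
#' @param ... Passed on to [solve_lump_lp()].
#' @return A `tl_lump_solution` on success, `NULL` otherwise.
#' @export
group_lump <- function(rs, members, ...) {
  sol <- solve_lump_lp(rs$R, U = members, seeds = members,
                       unknown_rows = rs$unknown_rows, ...)
  if (sol$status == "optimal" && length(sol$involved_unknowns) == 0) sol
  else NULL
}

#' Sequential per-seed lumping over a set of unknown metabolites
#'
#' For each seed metabolite `u` (in model index order, never skipping seeds
#' eliminated by earlier iterations): start with the target set `U' = {u}`
#' and the working matrix `R' = rs$R`; repeatedly solve the lumping LP with
#' seeds fixed to `{u}`. An infeasible LP abandons the seed. A solution free
#' of extraneous unknown metabolites is accepted as a lump for `u`. Otherwise
#' one newly involved unknown metabolite (smallest model index) joins `U'`,
#' the solution vector `y` is appended to `R'` as a new column (with
#' `alpha_min = 0`), and the loop continues. Augmentation columns are
#' expanded back to primitive reactions when a lump is recorded, and are
#' discarded when moving to the next seed.
#'
#' @param rs A [extract_reduced_system()] result.
#' @param members Seed metabolites, a subset of `rs$unknown_rows`.
#' @param group_id Integer label recorded with accepted lumps.
#' @param max_iter Iteration cap per seed (default 50).
#' @param alpha_max,tol,integer,time_limit Passed to [solve_lump_lp()].
#' @return A `tl_lump_run` with accepted lumps, eliminated seeds, LP counts
#'   and a per-LP log.
#' @export
sequential_lump <- function(rs, members = rs$unknown_rows, group_id = NA_integer_,
                            max_iter = 50, alpha_max = 1000, tol = 1e-9,
                            integer = FALSE, time_limit = NULL) {
  stopifnot(inherits(rs, "tl_reduced"), all(members %in% rs$unknown_rows))
  members <- members[order(rs$met_index[members])]
  lumps <- list(); eliminated <- character(0)
  counts <- .empty_counts(); log <- list()
  for (seed in members) {
    Rw <- rs$R
    # expansion of working columns into primitive reaction columns
    E <- diag(ncol(rs$R))
    rownames(E) <- colnames(rs$R)
    U_prime <- seed
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) {
        stop("sequential lumping exceeded ", max_iter,
             " iterations for seed '", seed, "'")
      }
      t0 <- proc.time()[["elapsed"]]
      sol <- solve_lump_lp(Rw, U = U_prime, seeds = seed,
                           unknown_rows = rs$unknown_rows,
                           alpha_max = alpha_max, tol = tol,
                           integer = integer, time_limit = time_limit)
      counts$lps_sequential <- counts$lps_sequential + 1L
      log[[length(log) + 1]] <- tibble::tibble(
        phase = "sequential", group_id = group_id, seed = seed,
        U_size = length(U_prime), status = sol$status,
        objective = sol$objective,
        duration = proc.time()[["elapsed"]] - t0)
      if (sol$status == "infeasible") break
      if (length(sol$involved_unknowns) == 0) {
        primitive <- as.numeric(E %*% sol$alpha)
        names(primitive) <- colnames(rs$R)
        lumps[[length(lumps) + 1]] <- .lump_record(
          rs, primitive, U_prime, seed, group_id, "sequential", iter, tol)
        eliminated <- c(eliminated, seed)
        break
      }
      w <- sol$involved_unknowns[
        which.min(rs$met_index[sol$involved_unknowns])]
      U_prime <- c(U_prime, w)
      Rw <- cbind(Rw, sol$y)
      colnames(Rw)[ncol(Rw)] <- paste0(".aug", iter)
      prim_col <- as.numeric(E %*% sol$alpha)
      E <- cbind(E, prim_col)
      colnames(E) <- colnames(Rw)
    }
  }
  counts$lps_total <- counts$lps_sequential
  structure(
    list(lumps = lumps, eliminated = eliminated, counts = counts,
         log = dplyr::bind_rows(c(list(.empty_log()), log))),
    class = "tl_lump_run"
  )
}

#' Combined lumping procedure: group step with sequential fallback
#'
#' For each independent group of unknown metabolites, first attempt to
#' eliminate the whole group with a single LP ([group_lump()]); if that LP is
#' infeasible or its solution involves extraneous unknowns, fall back to the
#' exhaustive per-seed [sequential_lump()] within the group. Eliminates the
#' same metabolites as a purely sequential run while typically solving far
#' fewer LPs.
#'
#' @param rs A [extract_reduced_system()] result.
#' @param groups Result of [partition_groups()] on `rs` (computed if omitted).
#' @param alpha_max,tol,integer,time_limit,max_iter As in [sequential_lump()].
#' @return A `tl_lump_run`.
#' @export
combined_procedure <- function(rs, groups = partition_groups(rs),
                               alpha_max = 1000, tol = 1e-9, integer = FALSE,
                               time_limit = NULL, max_iter = 50) {
  stopifnot(inherits(rs, "tl_reduced"))
  lumps <- list(); eliminated <- character(0)
  counts <- .empty_counts(); log <- list(.empty_log())
  counts$groups_total <- nrow(groups)
  for (i in seq_len(nrow(groups))) {
    members <- groups$members[[i]]
    t0 <- proc.time()[["elapsed"]]
    sol <- solve_lump_lp(rs$R, U = members, seeds = members,
                         unknown_rows = rs$unknown_rows,
                         alpha_max = alpha_max, tol = tol, integer = integer,
                         time_limit = time_limit)
    counts$lps_group <- counts$lps_group + 1L
    accepted <- sol$status == "optimal" &&
      length(sol$involved_unknowns) == 0
    log[[length(log) + 1]] <- tibble::tibble(
      phase = "group", group_id = groups$group_id[i], seed = NA_character_,
      U_size = length(members), status = sol$status,
      objective = sol$objective,
      duration = proc.time()[["elapsed"]] - t0)
    if (accepted) {
      counts$groups_group_success <- counts$groups_group_success + 1L
      lumps[[length(lumps) + 1]] <- .lump_record(
        rs, sol$alpha, members, paste(members, collapse = "+"),
        groups$group_id[i], "group", 1L, tol)
      eliminated <- c(eliminated, members)
    } else {
      if (sol$status == "infeasible") {
        counts$groups_group_infeasible <- counts$groups_group_infeasible + 1L
      }
      seq_run <- sequential_lump(rs, members, group_id = groups$group_id[i],
                                 max_iter = max_iter, alpha_max = alpha_max,
                                 tol = tol, integer = integer,
                                 time_limit = time_limit)
      lumps <- c(lumps, seq_run$lumps)
      eliminated <- c(eliminated, seq_run$eliminated)
      counts$lps_sequential <- counts$lps_sequential + seq_run$counts$lps_sequential
      log[[length(log) + 1]] <- seq_run$log
    }
  }
  counts$lps_total <- counts$lps_group + counts$lps_sequential
  structure(
    list(lumps = lumps, eliminated = eliminated, counts = counts,
         log = dplyr::bind_rows(log)),
    class = "tl_lump_run"
  )
}

#' Naive iterative lumping
#'
#' Applies the sequential implementation to every unknown metabolite as its
#' own seed, ignoring the group structure entirely. Provided as the baseline
#' against which the combined procedure's LP counts are compared; it solves
#' at least one LP per unknown metabolite.
#'
#' @inheritParams combined_procedure
#' @return A `tl_lump_run`.
#' @export
naive_iterative <- function(rs, alpha_max = 1000, tol = 1e-9, integer = FALSE,
                            time_limit = NULL, max_iter = 50) {
  sequential_lump(rs, rs$unknown_rows, group_id = NA_integer_,
                  max_iter = max_iter, alpha_max = alpha_max, tol = tol,
                  integer = integer, time_limit = time_limit)
}

#' @export
print.tl_lump_run <- function(x, ...) {
  cat(sprintf(
    "<tl_lump_run> %d lump(s); eliminated {%s}; %d LPs (%d group + %d sequential)\n",
    length(x$lumps), paste(x$eliminated, collapse = ", "),
    x$counts$lps_total, x$counts$lps_group, x$counts$lps_sequential))
  invisible(x)
}
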