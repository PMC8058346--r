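#' TMFA configuration
#'
#' Collects the physical constants and numerical settings of the
#' thermodynamic MILP.
#'
#' @param temperature Temperature in Kelvin (default 298.15).
#' @param gas_constant Gas constant in kJ/(mol K) (default 8.314e-3).
#' @param big_m Big-M coupling constant in kJ/mol (default 1000); must
#'   dominate |dG0| plus the RT log-concentration span.
#' @param conc_lb,conc_ub Default metabolite concentration bounds in mol/L
#'   (defaults 1e-6 and 2e-2, i.e. 1 uM to 20 mM).
#' @param conc_overrides Named list of `c(lo, hi)` pairs (mol/L) overriding
#'   the default bounds for individual metabolites. Never applied silently:
#'   the caller supplies them.
#' @param biomass_fraction Fraction of the FBA optimum the biomass flux must
#'   reach during variability analysis (default 0.9).
#' @param epsilon Strictness margin in kJ/mol implementing "dG strictly
#'   negative" for active reactions (default 1e-6).
#' @param time_limit Per-solve MILP time limit in seconds (default 120).
#' @return An object of class `tl_tmfa_config`.
#' @export
tmfa_config <- function(temperature = 298.15, gas_constant = 8.314e-3,
                        big_m = 1000, conc_lb = 1e-6, conc_ub = 2e-2,
                        conc_overrides = NULL, biomass_fraction = 0.9,
                        epsilon = 1e-6, time_limit = 120) {
  stopifnot(temperature > 0, gas_constant > 0, big_m > 0,
            conc_lb > 0, conc_lb < conc_ub,
            biomass_fraction > 0, biomass_fraction <= 1)
  if (!is.null(conc_overrides)) {
    ok <- vapply(conc_overrides, function(b) {
      length(b) == 2 && b[1] > 0 && b[1] < b[2]
    }, logical(1))
    if (!all(ok)) stop("each concentration override must be c(lo, hi) with 0 < lo < hi")
  }
  structure(
    list(temperature = temperature, gas_constant = gas_constant,
         big_m = big_m, conc_lb = conc_lb, conc_ub = conc_ub,
         conc_overrides = conc_overrides %||% list(),
         biomass_fraction = biomass_fraction, epsilon = epsilon,
         time_limit = time_limit),
    class = "tl_tmfa_config"
  )
}

#' Example concentration relaxations for the E. coli iJR904 analysis
#'
#' The documented per-metabolite relaxations needed to reach 90% of the FBA
#' biomass optimum in iJR904: glycerophosphoglycerol and
#' sn-glycero-3-phosphoethanolamine get enormous upper bounds, cytosolic
#' water an extended lower bound, and NADH (lumped model only) an upper
#' bound of 41.2 mM. Shipped as data for explicit opt-in, never applied
#' automatically.
#'
#' @return A named list of `c(lo, hi)` concentration bounds (mol/L).
#' @export
ijr904_relaxations <- function() {
  list(
    g3pg_c = c(1e-6, 1.4e55),
    g3pe_c = c(1e-6, 6003),
    h2o_c = c(14.92e-12, 2e-2),
    nadh_c = c(1e-6, 41.2e-3)
  )
}

#' Standard Gibbs free energy of a lumped reaction
#'
#' `dG0 = sum_i y_i dfG0_i` over the lump's net stoichiometry. Defined only
#' when every metabolite with nonzero net coefficient carries a formation
#' energy — which the lumping procedures guarantee for accepted lumps.
#'
#' @param lump A lump record from a `tl_lump_run` (a list with a `y` tibble
#'   of `metabolite_id`, `coefficient`), or a named numeric vector of net
#'   stoichiometry.
#' @param thermo A [thermo_data()] object.
#' @return dG0 in kJ/mol.
#' @export
lump_dG0 <- function(lump, thermo) {
  y <- if (is.list(lump) && !is.null(lump$y)) {
    stats::setNames(lump$y$coefficient, lump$y$metabolite_id)
  } else {
    lump
  }
  y <- y[y != 0]
  if (length(y) == 0) return(0)
  missing <- setdiff(names(y), names(thermo$dfG0))
  if (length(missing)) {
    stop("lump involves metabolites without dfG0: ",
         paste(missing, collapse = ", "))
  }
  sum(y * thermo$dfG0[names(y)])
}

# roles and z/dG variable sets for a split model
.tmfa_structure <- function(model, lumps, thermo) {
  roles <- classify_reactions(model)
  rdg <- reaction_dG0(model, thermo)
  thermo_rxns <- model$reactions$id[
    rdg$determined & roles$role %in% c("internal", "transport")]
  lump_members <- unique(unlist(lapply(lumps, function(l) l$alpha$reaction_id)))
  bad <- setdiff(lump_members, model$reactions$id)
  if (length(bad)) {
    stop("lump references reactions absent from the model: ",
         paste(bad, collapse = ", "))
  }
  z_rxns <- union(thermo_rxns, lump_members)
  z_rxns <- model$reactions$id[model$reactions$id %in% z_rxns]
  list(roles = roles, rdg = rdg, thermo_rxns = thermo_rxns, z_rxns = z_rxns)
}

#' Build the TMFA mixed-integer program
#'
#' Encodes flux balance plus thermodynamic feasibility: steady state
#' `S v = 0` over model reactions only (lumped reactions carry no flux);
#' for every thermodynamically determined internal reaction `j`, flux is
#' allowed only when the binary `z_j` is on (`v_j <= z_j v_max`) and then
#' `dG_j <= -epsilon`, with
#' `dG_j = dG0_j + RT sum_i s_ij ln x_i`; for every lumped reaction `k`,
#' `dG_k <= (1 - y_k) M` and
#' `sum_j alpha_kj z_j <= sum_j alpha_kj - (1 - y_k)`, so an infeasible
#' lump switches off at least one member reaction. Exchange and biomass
#' reactions carry flux but no thermodynamic constraint, as do undetermined
#' model reactions (unless they are lump members, which gives them a `z`
#' binary and the flux coupling only).
#'
#' @param model A reversible-split [tl_model()].
#' @param lumps List of lump records (from a `tl_lump_run`'s `$lumps`).
#' @param thermo A [thermo_data()] for `model`.
#' @param cfg A [tmfa_config()].
#' @param transport_adjustment Optional hook `function(lump, model, cfg)`
#'   returning a dG0 correction (kJ/mol) for lumps whose net stoichiometry
#'   crosses compartments (e.g. membrane potential and proton-motive terms).
#'   With the default `NULL`, cross-compartment lumps trigger a warning and
#'   no correction is applied.
#' @return An object of class `tl_tmfa` holding the MILP blocks and index
#'   maps; solve it with [tmfa_optimum()] or [dG_variability()].
#' @export
build_tmfa <- function(model, lumps = list(), thermo, cfg = tmfa_config(),
                       transport_adjustment = NULL) {
  validate_model(model)
  st <- .tmfa_structure(model, lumps, thermo)
  m <- nrow(model$S); n <- ncol(model$S)
  RT <- cfg$gas_constant * cfg$temperature
  M <- cfg$big_m

  nd <- length(st$thermo_rxns)
  nl <- length(lumps)
  nz <- length(st$z_rxns)
  # variable blocks: v | lnx | dG_model | dG_lump | z | y
  iv <- seq_len(n)
  ix <- n + seq_len(m)
  idg <- n + m + seq_len(nd)
  idgl <- n + m + nd + seq_len(nl)
  iz <- n + m + nd + nl + seq_len(nz)
  iy <- n + m + nd + nl + nz + seq_len(nl)
  nvar <- n + m + nd + nl + nz + nl

  dG0 <- stats::setNames(st$rdg$dG0, st$rdg$reaction_id)
  lump_dG0s <- vapply(lumps, lump_dG0, numeric(1), thermo = thermo)
  comp <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
  for (t in seq_len(nl)) {
    comps <- unique(comp[lumps[[t]]$y$metabolite_id])
    if (length(comps) > 1) {
      if (is.null(transport_adjustment)) {
        warning("lump ", t, " crosses compartments (",
                paste(comps, collapse = ", "),
                "); no membrane-transport dG0 adjustment applied")
      } else {
        lump_dG0s[t] <- lump_dG0s[t] +
          transport_adjustment(lumps[[t]], model, cfg)
      }
    }
  }

  tri <- list(i = integer(0), j = integer(0), x = numeric(0))
  add <- function(tri, i, j, x) {
    tri$i <- c(tri$i, i); tri$j <- c(tri$j, j); tri$x <- c(tri$x, x); tri
  }

  ## equalities: Sv = 0; dG definitions
  eq <- tri; b_eq <- numeric(0); row <- 0L
  Ssum <- methods::as(methods::as(model$S, "generalMatrix"), "TsparseMatrix")
  eq <- add(eq, Ssum@i + 1L, iv[Ssum@j + 1L], Ssum@x)
  row <- m; b_eq <- rep(0, m)
  for (t in seq_len(nd)) {
    rid <- st$thermo_rxns[t]
    k <- match(rid, model$reactions$id)
    col <- model$S[, k]
    nzr <- which(col != 0)
    row <- row + 1L
    eq <- add(eq, rep(row, 1 + length(nzr)),
              c(idg[t], ix[nzr]),
              c(1, -RT * as.numeric(col[nzr])))
    b_eq <- c(b_eq, dG0[[rid]])
  }
  for (t in seq_len(nl)) {
    yk <- lumps[[t]]$y
    idxm <- match(yk$metabolite_id, model$metabolites$id)
    if (anyNA(idxm)) stop("lump stoichiometry references unknown metabolite")
    row <- row + 1L
    eq <- add(eq, rep(row, 1 + nrow(yk)),
              c(idgl[t], ix[idxm]),
              c(1, -RT * yk$coefficient))
    b_eq <- c(b_eq, lump_dG0s[t])
  }
  n_eq <- row

  ## inequalities
  ub_tri <- tri; b_ub <- numeric(0); urow <- 0L
  for (t in seq_len(nz)) {
    rid <- st$z_rxns[t]
    k <- match(rid, model$reactions$id)
    vmax <- model$reactions$ub[k]
    urow <- urow + 1L
    ub_tri <- add(ub_tri, c(urow, urow), c(iv[k], iz[t]), c(1, -vmax))
    b_ub <- c(b_ub, 0)
  }
  for (t in seq_len(nd)) {
    zpos <- match(st$thermo_rxns[t], st$z_rxns)
    urow <- urow + 1L
    ub_tri <- add(ub_tri, c(urow, urow), c(idg[t], iz[zpos]), c(1, M))
    b_ub <- c(b_ub, M - cfg$epsilon)
  }
  for (t in seq_len(nl)) {
    urow <- urow + 1L
    ub_tri <- add(ub_tri, c(urow, urow), c(idgl[t], iy[t]), c(1, M))
    b_ub <- c(b_ub, M)
    al <- lumps[[t]]$alpha
    zpos <- match(al$reaction_id, st$z_rxns)
    urow <- urow + 1L
    ub_tri <- add(ub_tri, rep(urow, nrow(al) + 1),
                  c(iz[zpos], iy[t]), c(al$alpha, -1))
    b_ub <- c(b_ub, sum(al$alpha) - 1)
  }
  n_ub <- urow

  ## bounds
  lo <- log(rep(cfg$conc_lb, m)); hi <- log(rep(cfg$conc_ub, m))
  ov <- cfg$conc_overrides
  if (length(ov)) {
    idxo <- match(names(ov), model$metabolites$id)
    keep <- !is.na(idxo)
    lo[idxo[keep]] <- log(vapply(ov[keep], `[`, numeric(1), 1))
    hi[idxo[keep]] <- log(vapply(ov[keep], `[`, numeric(1), 2))
  }
  lb <- c(model$reactions$lb, lo, rep(-Inf, nd + nl), rep(0, nz + nl))
  ubv <- c(model$reactions$ub, hi, rep(Inf, nd + nl), rep(1, nz + nl))
  integrality <- c(rep(0L, n + m + nd + nl), rep(1L, nz + nl))

  A_eq <- Matrix::sparseMatrix(i = eq$i, j = eq$j, x = eq$x,
                               dims = c(n_eq, nvar))
  A_ub <- if (n_ub > 0)
    Matrix::sparseMatrix(i = ub_tri$i, j = ub_tri$j, x = ub_tri$x,
                         dims = c(n_ub, nvar))
  else NULL

  lump_ids <- vapply(seq_len(nl), function(t) {
    lumps[[t]]$lump_id %||% paste0("lump_", t)
  }, character(1))
  structure(
    list(model = model, cfg = cfg, lumps = lumps,
         A_eq = A_eq, b_eq = b_eq, A_ub = A_ub, b_ub = b_ub,
         lb = lb, ub = ubv, integrality = integrality, nvar = nvar,
         idx = list(v = iv, lnx = ix, dG = idg, dG_lump = idgl,
                    z = iz, y = iy),
         dG_ids = c(st$thermo_rxns, lump_ids),
         thermo_rxns = st$thermo_rxns, z_rxns = st$z_rxns),
    class = "tl_tmfa"
  )
}

#' @export
print.tl_tmfa <- function(x, ...) {
  cat(sprintf(
    "<tl_tmfa> %d flux vars, %d log-concentrations, %d dG vars (%d lumped), %d binaries\n",
    length(x$idx$v), length(x$idx$lnx),
    length(x$idx$dG) + length(x$idx$dG_lump), length(x$idx$dG_lump),
    length(x$idx$z) + length(x$idx$y)))
  invisible(x)
}

.tmfa_lp <- function(p, c_vec, sense, extra_ub = NULL, extra_b = NULL) {
  A_ub <- p$A_ub; b_ub <- p$b_ub
  if (!is.null(extra_ub)) {
    A_ub <- if (is.null(A_ub)) extra_ub else rbind(A_ub, extra_ub)
    b_ub <- c(b_ub, extra_b)
  }
  tl_lp(c = c_vec, A_eq = p$A_eq, b_eq = p$b_eq, A_ub = A_ub, b_ub = b_ub,
        lb = p$lb, ub = p$ub, sense = sense, integrality = p$integrality,
        time_limit = p$cfg$time_limit)
}

#' Solve the TMFA problem for the optimal objective flux
#'
#' Maximises flux through the model's objective (biomass) reaction subject to
#' all thermodynamic constraints. Always at most the FBA optimum, since the
#' TMFA constraint set is a superset of the FBA constraints.
#'
#' @param p A [build_tmfa()] problem.
#' @return A list with `objective`, `status`, and the raw solution vector
#'   `x`.
#' @export
tmfa_optimum <- function(p) {
  stopifnot(inherits(p, "tl_tmfa"))
  cv <- rep(0, p$nvar)
  cv[p$idx$v[match(p$model$objective, p$model$reactions$id)]] <- 1
  res <- tl_solve(.tmfa_lp(p, cv, "max"))
  if (!res$status %in% c("optimal", "limit")) {
    stop("TMFA optimisation failed (status: ", res$status, ")")
  }
  list(objective = res$objective, status = res$status, x = res$x)
}

#' Gibbs free energy variability analysis
#'
#' For every reaction carrying a dG variable (thermodynamically determined
#' model reactions and lumped reactions), computes the minimum and maximum
#' dG subject to the full TMFA MILP with the biomass flux held at a fraction
#' of the FBA optimum. A reaction is classified irreversible when its
#' maximum dG is strictly negative, reversible otherwise.
#'
#' @param p A [build_tmfa()] problem.
#' @param biomass_fraction Overrides the fraction in `p$cfg` if given.
#' @return A tibble of class `tl_dG_ranges` with columns `reaction_id`,
#'   `dG_min`, `dG_max`, `classification`, and attributes `fba_objective`
#'   and `biomass_fraction`.
#' @export
dG_variability <- function(p, biomass_fraction = NULL) {
  stopifnot(inherits(p, "tl_tmfa"))
  frac <- biomass_fraction %||% p$cfg$biomass_fraction
  fba_opt <- fba(p$model)$objective
  obj_idx <- p$idx$v[match(p$model$objective, p$model$reactions$id)]
  extra <- Matrix::sparseMatrix(i = 1L, j = obj_idx, x = -1,
                                dims = c(1L, p$nvar))
  extra_b <- -frac * fba_opt

  dg_idx <- c(p$idx$dG, p$idx$dG_lump)
  if (length(dg_idx) == 0) {
    out <- tibble::tibble(reaction_id = character(0), dG_min = numeric(0),
                          dG_max = numeric(0), classification = character(0))
    return(structure(out, class = c("tl_dG_ranges", class(out)),
                     fba_objective = fba_opt, biomass_fraction = frac))
  }
  probs <- list()
  for (t in seq_along(dg_idx)) {
    cv <- rep(0, p$nvar); cv[dg_idx[t]] <- 1
    probs[[2 * t - 1]] <- .tmfa_lp(p, cv, "min", extra, extra_b)
    probs[[2 * t]] <- .tmfa_lp(p, cv, "max", extra, extra_b)
  }
  res <- tl_solve(probs)
  status <- vapply(res, `[[`, character(1), "status")
  if (any(status == "infeasible")) {
    stop("TMFA infeasible at ", frac,
         " of the FBA optimum; relax concentration bounds for the binding ",
         "metabolites via tmfa_config(conc_overrides = ...) ",
         "(see ijr904_relaxations() for a documented example)")
  }
  if (any(status == "limit")) {
    warning(sum(status == "limit"), " variability solve(s) hit the time limit")
  }
  vals <- vapply(res, function(r) r$objective %||% NA_real_, numeric(1))
  dg_min <- vals[seq(1, length(vals), by = 2)]
  dg_max <- vals[seq(2, length(vals), by = 2)]
  out <- tibble::tibble(
    reaction_id = p$dG_ids,
    dG_min = dg_min, dG_max = dg_max,
    classification = ifelse(dg_max < 0, "irreversible", "reversible")
  )
  structure(out, class = c("tl_dG_ranges", class(out)),
            fba_objective = fba_opt, biomass_fraction = frac)
}

#' Tally reversibility classifications
#'
#' Counts reactions whose dG range is strictly negative (irreversible)
#' versus the rest (reversible); a range with `dG_max = 0` counts as
#' reversible.
#'
#' @param ranges A [dG_variability()] result, or any tibble with a `dG_max`
#'   column (the classification is recomputed from the strict-negativity
#'   rule when absent).
#' @return A named list with elements `irreversible` and `reversible`.
#' @export
classify_reversibility <- function(ranges) {
  cls <- if ("classification" %in% names(ranges)) ranges$classification
         else ifelse(ranges$dG_max < 0, "irreversible", "reversible")
  list(
    irreversible = sum(cls == "irreversible"),
    reversible = sum(cls == "reversible")
  )
}
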