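# Small models built in code for I/O and TMFA tests.

# 3 metabolites, 2 reactions, linear chain with the drain as objective.
tiny_model <- function() {
  S <- matrix(c(1, 0,
                -1, 1,
                0, -1), nrow = 3, byrow = TRUE,
              dimnames = list(c("A_c", "B_c", "C_c"), c("r1", "r2")))
  tl_model(S, lb = c(0, 0), ub = c(10, 10), objective = "r2")
}

tiny_model_json <- function(path) {
  write_model(tiny_model(), path)
  path
}

# Branch model for the closed-form variability test: biomass runs through
# R2 (A -> C) while R1 (A -> B) is an optional branch whose flux may be
# zero, leaving its dG unconstrained by the big-M coupling.
branch_model <- function() {
  mets <- c("A_c", "B_c", "C_c")
  rxns <- c("EX_A", "R1", "EX_B", "R2", "EX_C")
  S <- matrix(0, 3, 5, dimnames = list(mets, rxns))
  S["A_c", "EX_A"] <- 1
  S[c("A_c", "B_c"), "R1"] <- c(-1, 1)
  S["B_c", "EX_B"] <- -1
  S[c("A_c", "C_c"), "R2"] <- c(-1, 1)
  S["C_c", "EX_C"] <- -1
  model <- tl_model(S, lb = 0, ub = 10, objective = "EX_C")
  thermo <- thermo_data(model, c(A_c = -100, B_c = -110, C_c = -200))
  list(model = model, thermo = thermo)
}

# Thermodynamically impossible forced chain: dG0 of the only path is large
# and positive, so no concentration assignment can activate it.
uphill_model <- function() {
  mets <- c("A_c", "B_c")
  rxns <- c("EX_A", "R1", "EX_B")
  S <- matrix(0, 2, 3, dimnames = list(mets, rxns))
  S["A_c", "EX_A"] <- 1
  S[c("A_c", "B_c"), "R1"] <- c(-1, 1)
  S["B_c", "EX_B"] <- -1
  model <- tl_model(S, lb = 0, ub = 10, objective = "EX_B")
  thermo <- thermo_data(model, c(A_c = -100, B_c = 400))
  list(model = model, thermo = thermo)
}

# Reduced system directly from a bare matrix, for solver-level tests.
as_reduced <- function(R, unknown_rows) {
  structure(
    list(R = R, unknown_rows = unknown_rows,
         met_index = stats::setNames(seq_len(nrow(R)), rownames(R)),
         split_pairs = tibble::tibble(original = character(0),
                                      forward = character(0),
                                      reverse = character(0))),
    class = "tl_reduced")
}
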