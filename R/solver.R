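#' @importFrom Matrix sparseMatrix
NULL

.tl_inf <- 1e30

#' Locate the python interpreter used for LP/MILP solves
#'
#' The optimisation backend is HiGHS, reached through scipy. The interpreter
#' can be overridden with `options(thermolump.python = "/path/to/python")`.
#'
#' @return Path to the python executable.
#' @keywords internal
tl_python <- function() {
  py <- getOption("thermolump.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("No python interpreter found; the LP/MILP backend requires python with scipy.",
         call. = FALSE)
  }
  unname(py)
}

# Convert a matrix-like object to the triplet form the bridge expects.
.tl_triplets <- function(A) {
  if (is.null(A) || nrow(A) == 0) return(NULL)
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"), "TsparseMatrix")
  list(
    i = as.integer(A@i + 1L), j = as.integer(A@j + 1L), x = as.numeric(A@x),
    nrow = nrow(A), ncol = ncol(A)
  )
}

#' Define a linear or mixed-integer linear program
#'
#' A thin container consumed by [tl_solve()]. Minimise (or maximise)
#' `c'x` subject to `A_eq x = b_eq`, `A_ub x <= b_ub` and `lb <= x <= ub`,
#' with optional integrality restrictions.
#'
#' @param c Objective coefficient vector.
#' @param A_eq,b_eq Equality constraints (matrix and right-hand side), or NULL.
#' @param A_ub,b_ub Inequality (`<=`) constraints, or NULL.
#' @param lb,ub Variable bounds; `-Inf`/`Inf` allowed.
#' @param sense `"min"` or `"max"`.
#' @param integrality Integer 0/1 vector flagging integer variables, or NULL.
#' @param time_limit Per-solve wall-clock limit in seconds, or NULL.
#' @return An object of class `tl_lp`.
#' @export
tl_lp <- function(c, A_eq = NULL, b_eq = NULL, A_ub = NULL, b_ub = NULL,
                  lb = rep(0, length(c)), ub = rep(Inf, length(c)),
                  sense = "min", integrality = NULL, time_limit = NULL) {
  stopifnot(length(lb) == length(c), length(ub) == length(c))
  structure(
    list(c = as.numeric(c), A_eq = A_eq, b_eq = b_eq, A_ub = A_ub, b_ub = b_ub,
         lb = as.numeric(lb), ub = as.numeric(ub), sense = sense,
         integrality = integrality, time_limit = time_limit),
    class = "tl_lp"
  )
}

.tl_lp_payload <- function(p) {
  lb <- pmax(pmin(p$lb, .tl_inf), -.tl_inf)
  ub <- pmax(pmin(p$ub, .tl_inf), -.tl_inf)
  list(
    sense = p$sense,
    c = p$c,
    A_eq = .tl_triplets(p$A_eq),
    b_eq = if (is.null(p$b_eq)) NULL else as.numeric(p$b_eq),
    A_ub = .tl_triplets(p$A_ub),
    b_ub = if (is.null(p$b_ub)) NULL else as.numeric(p$b_ub),
    lb = lb, ub = ub,
    integrality = if (is.null(p$integrality)) NULL else as.integer(p$integrality),
    time_limit = p$time_limit
  )
}

#' Solve a batch of linear / mixed-integer programs
#'
#' Problems are independent and solved in one backend invocation to amortise
#' interpreter start-up. Infeasibility is an ordinary outcome (status
#' `"infeasible"`), not an error; genuine solver failures carry status
#' `"error"`.
#'
#' @param problems A single [tl_lp()] or a list of them.
#' @return For a single problem, a list with elements `status`, `x`,
#'   `objective`; for a list input, a list of such lists.
#' @export
tl_solve <- function(problems) {
  single <- inherits(problems, "tl_lp")
  if (single) problems <- list(problems)
  stopifnot(all(vapply(problems, inherits, logical(1), "tl_lp")))
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  payload <- list(problems = lapply(problems, .tl_lp_payload))
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  script <- system.file("python", "milp_solve.py", package = "thermolump")
  if (!nzchar(script)) stop("milp_solve.py not found in package installation")
  status <- system2(tl_python(), c(script, infile, outfile),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(outfile)) {
    stop("LP backend failed: ", paste(status, collapse = "\n"))
  }
  res <- jsonlite::read_json(outfile, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  res <- lapply(res, function(r) {
    r$x <- if (is.null(r$x)) NULL else as.numeric(unlist(r$x))
    r
  })
  if (single) res[[1]] else res
}
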