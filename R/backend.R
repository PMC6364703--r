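# Bridge to the HiGHS LP/MILP solver (scipy) via a batched subprocess call.

the <- new.env(parent = emptyenv())

#' Locate the Python interpreter used for the solver backend
#'
#' The LP/MILP sub-problems are solved by HiGHS through `scipy.optimize.milp`,
#' invoked as a short-lived subprocess. The interpreter is taken from the
#' `dielfba.python` option, the `DIELFBA_PYTHON` environment variable, or the
#' first of `python3`/`python` found on the `PATH`.
#'
#' @return Path to the Python executable.
#' @keywords internal
find_python <- function() {
  opt <- getOption("dielfba.python", "")
  if (nzchar(opt)) return(opt)
  env <- Sys.getenv("DIELFBA_PYTHON", "")
  if (nzchar(env)) return(env)
  for (cand in c("python3", "python")) {
    hit <- Sys.which(cand)
    if (nzchar(hit)) return(unname(hit))
  }
  stop("No python interpreter found for the solver backend; set options(dielfba.python = ...)",
       call. = FALSE)
}

backend_script <- function() {
  path <- system.file("python", "highs_backend.py", package = "dielfba")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ is not yet flattened
    path <- file.path("inst", "python", "highs_backend.py")
  }
  if (!file.exists(path)) stop("solver backend script not found", call. = FALSE)
  path
}

new_objective <- function(coef, sense = c("max", "min"), want_x = FALSE) {
  sense <- match.arg(sense)
  nz <- which(coef != 0)
  list(sense = sense, j = as.list(nz - 1L), x = as.list(unname(coef[nz])),
       want_x = want_x)
}

#' Solve a batch of LP/MILP problems
#'
#' Low-level entry into the solver backend. Each problem is a list with
#' elements `n`, `lb`, `ub`, triplet matrix `A` (`i`, `j`, `x`, 0-based),
#' `row_lb`, `row_ub`, optional `integrality`, and a list of `objectives`
#' built by `new_objective()`. All objectives of one problem share its
#' feasible region, so flux variability analysis travels as one problem with
#' many objectives.
#'
#' @param problems List of problem lists.
#' @return A list (one element per problem) of lists (one per objective) with
#'   entries `status`, `objective`, and optionally `x`.
#' @keywords internal
backend_solve <- function(problems) {
  stopifnot(length(problems) > 0)
  payload <- list(problems = lapply(problems, function(p) {
    p$n <- unbox_int(p$n)
    p$lb <- num_array(p$lb)
    p$ub <- num_array(p$ub)
    p$row_lb <- num_array(p$row_lb)
    p$row_ub <- num_array(p$row_ub)
    if (!is.null(p$integrality)) p$integrality <- as.list(as.integer(p$integrality))
    p
  }))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA, null = "null")
  status <- system2(find_python(), c(backend_script(), fin, fout),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop("solver backend failed:\n", paste(status, collapse = "\n"), call. = FALSE)
  }
  res <- jsonlite::read_json(fout, simplifyVector = FALSE)
  lapply(res$results, function(pr) {
    lapply(pr, function(r) {
      r$objective <- if (is.null(r$objective)) NA_real_ else as.numeric(r$objective)
      if (!is.null(r$x)) r$x <- as.numeric(unlist(r$x))
      r
    })
  })
}

unbox_int <- function(x) jsonlite::unbox(as.integer(x))

# JSON has no +/-Inf; the backend treats |value| >= 1e30 as unbounded.
num_array <- function(x) {
  if (is.null(x)) return(list())
  as.list(unname(pmin(pmax(as.numeric(x), -1e30), 1e30)))
}

# Dense triplet helper: convert a dense matrix to the backend's triplet form,
# dropping structural zeros.
dense_to_triplets <- function(mat) {
  nz <- which(mat != 0, arr.ind = TRUE)
  list(i = as.list(unname(nz[, 1]) - 1L), j = as.list(unname(nz[, 2]) - 1L),
       x = as.list(unname(mat[nz])))
}
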