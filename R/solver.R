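# LP/MILP backend. Problems are solved by HiGHS via scipy in a helper
# Python process (inst/python/milp_server.py). A persistent worker is kept
# alive over two FIFOs so that repeated small batches do not pay the
# interpreter start-up cost; if the worker cannot be started or dies, each
# batch transparently falls back to a one-shot subprocess.

.initgem_solver <- new.env(parent = emptyenv())

solver_python <- function() {
  p <- getOption("initgem.python", "")
  if (nzchar(p)) return(p)
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("no python interpreter found on PATH; ",
                       "set options(initgem.python = ...)")
  unname(p)
}

solver_script <- function() {
  s <- system.file("python", "milp_server.py", package = "initgem")
  if (!nzchar(s)) stop("bundled solver helper not found")
  s
}

#' Construct a MILP task for the solver backend
#'
#' Low-level constructor used by the optimisation code; exposed for tests.
#' Constraints are `rlb <= A x <= rub`, variables `lb <= x <= ub`,
#' `vtype[k] == 1` marks integer variables. Use `Inf`/`-Inf` freely; they
#' are encoded for transport.
#'
#' @param c objective coefficients.
#' @param A sparse constraint matrix (anything coercible by
#'   `Matrix::sparseMatrix`) or `NULL` for box-only problems.
#' @param rlb,rub constraint bounds.
#' @param lb,ub variable bounds.
#' @param vtype integer flags (0 continuous, 1 integer).
#' @param sense `"max"` or `"min"`.
#' @param mip_gap relative MIP gap tolerance.
#' @param id opaque task id returned with the result.
#' @return a list ready for [milp_batch()].
#' @export
milp_task <- function(c, A = NULL, rlb = numeric(0), rub = numeric(0),
                      lb = rep(0, length(c)), ub = rep(Inf, length(c)),
                      vtype = rep(0L, length(c)), sense = "max",
                      mip_gap = 1e-6, id = NULL) {
  n <- length(c)
  enc <- function(v) {
    v <- as.numeric(v)
    v[v == Inf] <- 1e30
    v[v == -Inf] <- -1e30
    v
  }
  if (is.null(A)) {
    m <- 0L
    trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  } else {
    A <- methods::as(methods::as(A, "generalMatrix"), "TsparseMatrix")
    m <- nrow(A)
    trip <- list(i = A@i + 1L, j = A@j + 1L, x = A@x)
  }
  list(id = id, sense = sense, n = n, m = m,
       c = enc(c), A = trip, rlb = enc(rlb), rub = enc(rub),
       lb = enc(lb), ub = enc(ub), vtype = as.integer(vtype),
       mip_gap = mip_gap)
}

encode_batch <- function(tasks) {
  # scalars are unboxed; the helper re-expands length-1 vector fields
  as.character(jsonlite::toJSON(list(tasks = tasks), auto_unbox = TRUE,
                                digits = NA, null = "null"))
}

decode_batch <- function(txt, n_expected) {
  res <- jsonlite::fromJSON(txt, simplifyVector = FALSE,
                            simplifyDataFrame = FALSE)$results
  if (length(res) != n_expected) {
    stop("solver returned ", length(res), " results for ", n_expected,
         " tasks")
  }
  lapply(res, function(r) {
    list(id = r$id, status = r$status,
         objective = if (is.null(r$objective)) NA_real_
                     else as.numeric(r$objective),
         x = if (is.null(r$x)) NULL else as.numeric(unlist(r$x)),
         message = r$message)
  })
}

worker_alive <- function() {
  w <- .initgem_solver$worker
  !is.null(w) && isTRUE(w$alive)
}

worker_start <- function() {
  if (isTRUE(.initgem_solver$disabled)) return(invisible(FALSE))
  worker_stop()
  req <- tempfile("initgem-req-")
  resp <- tempfile("initgem-resp-")
  log <- tempfile("initgem-worker-", fileext = ".log")
  system2(solver_python(), c(solver_script(), "--serve", req, resp),
          wait = FALSE, stdout = log, stderr = log)
  # the helper creates both FIFOs, then blocks reading the request FIFO;
  # allow a generous wait for cold interpreter start-up
  for (k in 1:600) {
    if (file.exists(req) && file.exists(resp)) break
    Sys.sleep(0.05)
  }
  if (!file.exists(req) || !file.exists(resp)) {
    .initgem_solver$disabled <- TRUE
    return(invisible(FALSE))
  }
  w <- new.env(parent = emptyenv())
  w$req_path <- req; w$resp_path <- resp; w$log <- log
  w$con_req <- NULL; w$con_resp <- NULL; w$alive <- TRUE
  .initgem_solver$worker <- w
  ok <- tryCatch({
    ans <- worker_request(encode_batch(list(list(type = "ping"))))
    length(ans) == 1 && grepl("\"ok\"", ans)
  }, error = function(e) FALSE)
  if (!ok) {
    worker_stop()
    .initgem_solver$disabled <- TRUE
    return(invisible(FALSE))
  }
  invisible(TRUE)
}

worker_request <- function(payload) {
  w <- .initgem_solver$worker
  if (is.null(w$con_req)) {
    w$con_req <- fifo(w$req_path, open = "w", blocking = TRUE)
  }
  writeLines(payload, w$con_req)
  flush(w$con_req)
  if (is.null(w$con_resp)) {
    w$con_resp <- fifo(w$resp_path, open = "r", blocking = TRUE)
  }
  ans <- readLines(w$con_resp, n = 1)
  if (length(ans) == 0) {
    w$alive <- FALSE
    stop("solver worker terminated unexpectedly")
  }
  ans
}

worker_stop <- function() {
  w <- .initgem_solver$worker
  if (is.null(w)) return(invisible())
  for (con in list(w$con_req, w$con_resp)) {
    if (!is.null(con)) try(close(con), silent = TRUE)
  }
  for (p in c(w$req_path, w$resp_path)) {
    if (!is.null(p) && file.exists(p)) try(unlink(p), silent = TRUE)
  }
  w$alive <- FALSE
  .initgem_solver$worker <- NULL
  invisible()
}

solve_oneshot <- function(payload) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(payload, fin)
  status <- system2(solver_python(), c(solver_script(), fin, fout),
                    stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L) || !file.exists(fout)) {
    stop("solver subprocess failed (exit ", status, ")")
  }
  paste(readLines(fout, warn = FALSE), collapse = "")
}

#' Solve a batch of LP/MILP tasks
#'
#' @param tasks list of tasks from [milp_task()].
#' @return list of results, one per task: `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`, `"error"`), `objective`, and the
#'   variable vector `x` (in the task's `sense`).
#' @export
milp_batch <- function(tasks) {
  if (!length(tasks)) return(list())
  payload <- encode_batch(tasks)
  if (!worker_alive() && !isTRUE(.initgem_solver$disabled)) worker_start()
  if (worker_alive()) {
    ans <- tryCatch(worker_request(payload), error = function(e) NULL)
    if (!is.null(ans)) return(decode_batch(ans, length(tasks)))
    worker_stop()
  }
  decode_batch(solve_oneshot(payload), length(tasks))
}

.onUnload <- function(libpath) {
  try(worker_stop(), silent = TRUE)
}
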