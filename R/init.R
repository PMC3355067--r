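# The extraction MILP. Over a template network with per-reaction evidence
# weights w, choose binary inclusions y maximising
#   sum_i w_i y_i + delta * sum_j x_j
# subject to a relaxed steady state S v = b, b >= 0 on internal
# metabolites, flux coupling eps * y_i <= |v_i| <= M * y_i (direction
# binaries give reversible reactions a nonzero *net* flux), production
# indicators eps_b * x_j <= b_j <= M * x_j, and x_j = 1 forced for
# metabolites with presence evidence. A produced metabolite must be
# *synthesised*: the non-exchange part of its net production must also
# reach eps_b, so neither rewards nor presence forcing can be satisfied
# by mere import. Exchange reactions are always permitted and carry no
# weight.

#' Configuration for the extraction MILP
#'
#' @param epsilon_flux minimum flux through an included reaction.
#' @param epsilon_production minimum net accumulation for a metabolite to
#'   count as produced.
#' @param big_M flux/accumulation bound.
#' @param delta objective reward per produced metabolite; small relative
#'   to the evidence weights so production never overrides evidence.
#' @param solver_gap_tolerance relative MIP gap passed to the solver.
#' @param seed integer seed recorded for provenance.
#' @return a list with class `init_config`.
#' @export
init_config <- function(epsilon_flux = 1, epsilon_production = 1,
                        big_M = 1000, delta = 0.1,
                        solver_gap_tolerance = 1e-6, seed = 1L) {
  stopifnot(epsilon_flux > 0, epsilon_flux < big_M,
            epsilon_production > 0, epsilon_production < big_M,
            delta > 0, solver_gap_tolerance >= 0)
  structure(list(epsilon_flux = epsilon_flux,
                 epsilon_production = epsilon_production,
                 big_M = big_M, delta = delta,
                 solver_gap_tolerance = solver_gap_tolerance,
                 seed = as.integer(seed)),
            class = "init_config")
}

#' Build the extraction MILP for a template and weight vector
#'
#' @param template a `metabolic_model`.
#' @param weights a `weight_vector` from [reaction_weights()] or a named
#'   numeric covering every non-exchange reaction.
#' @param present_metabolites internal metabolite ids whose production is
#'   forced (metabolome evidence).
#' @param config an [init_config()].
#' @return an object of class `init_problem` holding the compiled task
#'   and index maps.
#' @export
build_init_problem <- function(template, weights,
                               present_metabolites = character(),
                               config = init_config()) {
  if (inherits(weights, "weight_vector")) weights <- weights_as_vector(weights)
  rx <- template$reactions
  ne <- which(!rx$is_exchange)
  missing_w <- setdiff(rx$id[ne], names(weights))
  if (length(missing_w)) {
    stop("weights missing for reaction(s): ",
         paste(missing_w, collapse = ", "))
  }
  ints <- internal_metabolites(template)
  bad <- setdiff(present_metabolites, ints)
  if (length(bad)) {
    stop("present metabolite(s) not internal to the template: ",
         paste(bad, collapse = ", "))
  }
  S <- stoichiometric_matrix(template, internal_only = TRUE)
  n <- nrow(rx); nm <- length(ints)
  rev_ne <- ne[rx$reversible[ne]]
  M <- config$big_M; eps <- config$epsilon_flux
  eps_b <- config$epsilon_production; delta <- config$delta
  # variable layout: v (n) | y (per ne) | d (per rev_ne) | b (nm) | x (nm)
  iv <- seq_len(n)
  iy <- stats::setNames(n + seq_along(ne), rx$id[ne])
  id_ <- stats::setNames(n + length(ne) + seq_along(rev_ne), rx$id[rev_ne])
  ib <- stats::setNames(n + length(ne) + length(rev_ne) + seq_len(nm), ints)
  ix <- stats::setNames(max(ib) + seq_len(nm), ints)
  nv <- max(ix)
  lb <- rep(0, nv); ub <- rep(Inf, nv); vtype <- rep(0L, nv)
  lb[iv] <- ifelse(rx$reversible | (rx$is_exchange & rx$reversible), -M, 0)
  lb[iv][!rx$reversible] <- 0
  ub[iv] <- M
  lb[c(iy, id_)] <- 0; ub[c(iy, id_)] <- 1; vtype[c(iy, id_)] <- 1L
  lb[ib] <- 0; ub[ib] <- M
  lb[ix] <- 0; ub[ix] <- 1; vtype[ix] <- 1L
  lb[ix[present_metabolites]] <- 1
  ti <- integer(0); tj <- integer(0); tx <- numeric(0); rlb <- numeric(0)
  rub <- numeric(0)
  row <- 0L
  add_row <- function(js, xs, lo, hi) {
    row <<- row + 1L
    ti <<- c(ti, rep.int(row, length(js))); tj <<- c(tj, js)
    tx <<- c(tx, xs); rlb <<- c(rlb, lo); rub <<- c(rub, hi)
  }
  St <- methods::as(methods::as(S, "generalMatrix"), "TsparseMatrix")
  # S v - b = 0
  for (j in seq_len(nm)) {
    sel <- which(St@i + 1L == j)
    add_row(c(iv[St@j[sel] + 1L], ib[j]), c(St@x[sel], -1), 0, 0)
  }
  for (i in ne) {
    yi <- iy[[rx$id[i]]]
    if (!rx$reversible[i]) {
      add_row(c(iv[i], yi), c(1, -M), -Inf, 0)      # v <= M y
      add_row(c(iv[i], yi), c(1, -eps), 0, Inf)     # v >= eps y
    } else {
      di <- id_[[rx$id[i]]]
      add_row(c(iv[i], yi), c(1, -M), -Inf, 0)      # v <= M y
      add_row(c(iv[i], yi), c(1, M), 0, Inf)        # v >= -M y
      add_row(c(iv[i], yi, di), c(1, -eps, -M), -M, Inf)
      add_row(c(iv[i], yi, di), c(1, eps + M, -M), -Inf, M)
    }
  }
  for (j in seq_len(nm)) {
    add_row(c(ib[j], ix[j]), c(1, -M), -Inf, 0)     # b <= M x
    add_row(c(ib[j], ix[j]), c(1, -eps_b), 0, Inf)  # b >= eps_b x
    # x = 1 additionally requires internal synthesis: the non-exchange
    # part of the net production must reach eps_b (imports don't count)
    sel <- which(St@i + 1L == j & !rx$is_exchange[St@j + 1L])
    Mrow <- M * (1 + sum(abs(St@x[sel])))
    add_row(c(iv[St@j[sel] + 1L], ix[j]),
            c(St@x[sel], -(eps_b + Mrow)), -Mrow, Inf)
  }
  cc <- rep(0, nv)
  cc[iy] <- unname(weights[rx$id[ne]])
  cc[ix] <- delta
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(row, nv))
  task <- milp_task(c = cc, A = A, rlb = rlb, rub = rub, lb = lb, ub = ub,
                    vtype = vtype, sense = "max",
                    mip_gap = config$solver_gap_tolerance)
  structure(list(template = template, weights = weights,
                 present_metabolites = present_metabolites,
                 config = config, task = task,
                 idx = list(v = iv, y = iy, d = id_, b = ib, x = ix)),
            class = "init_problem")
}

decode_init_solution <- function(problem, res) {
  rx <- problem$template$reactions
  if (res$status != "optimal" || is.null(res$x)) {
    return(structure(list(status = res$status, objective = NA_real_,
                          y = NULL, v = NULL, b = NULL, x = NULL),
                     class = "init_solution"))
  }
  xx <- res$x
  idx <- problem$idx
  sol <- structure(list(
    status = "optimal",
    objective = res$objective,
    y = stats::setNames(as.integer(round(xx[idx$y])), names(idx$y)),
    v = stats::setNames(xx[idx$v], rx$id),
    b = stats::setNames(xx[idx$b], names(idx$b)),
    x = stats::setNames(as.integer(round(xx[idx$x])), names(idx$x))),
    class = "init_solution")
  sol
}

#' Assert the feasibility certificate of a solution
#'
#' Recomputes `S v`, compares to `b`, and checks every coupling
#' constraint: `y_i = 1 => |v_i| >= eps`, `y_i = 0 => v_i = 0`,
#' `b >= 0`, `x_j = 1` (hence `b_j >= eps_b`) for every forced
#' metabolite, and the objective identity. Errors on violation; these
#' checks run on every solve.
#'
#' @param problem an `init_problem`.
#' @param solution an `init_solution` with status `"optimal"`.
#' @param tol numeric tolerance.
#' @return `TRUE`, invisibly.
#' @export
check_init_solution <- function(problem, solution, tol = 1e-6) {
  stopifnot(inherits(solution, "init_solution"),
            solution$status == "optimal")
  cfg <- problem$config
  S <- stoichiometric_matrix(problem$template, internal_only = TRUE)
  sv <- as.numeric(S %*% solution$v[colnames(S)])
  if (max(abs(sv - solution$b[rownames(S)])) > tol) {
    stop("certificate failure: S v != b")
  }
  if (any(solution$b < -tol)) stop("certificate failure: b < 0")
  for (rid in names(solution$y)) {
    vi <- solution$v[rid]
    if (solution$y[rid] == 1L) {
      if (abs(vi) < cfg$epsilon_flux - tol) {
        stop("certificate failure: included reaction '", rid,
             "' carries |v| < epsilon")
      }
    } else if (abs(vi) > tol) {
      stop("certificate failure: excluded reaction '", rid,
           "' carries flux")
    }
  }
  is_exch <- problem$template$reactions$is_exchange
  S_ne <- S[, !is_exch, drop = FALSE]
  synth <- as.numeric(S_ne %*% solution$v[colnames(S_ne)])
  names(synth) <- rownames(S)
  for (mid in names(solution$x)) {
    if (solution$x[mid] == 1L) {
      if (solution$b[mid] < cfg$epsilon_production - tol) {
        stop("certificate failure: x = 1 but b < epsilon_b for '", mid, "'")
      }
      if (synth[mid] < cfg$epsilon_production - tol) {
        stop("certificate failure: x = 1 without internal synthesis of '",
             mid, "'")
      }
    } else if (solution$b[mid] > tol) {
      stop("certificate failure: x = 0 but b > 0 for '", mid, "'")
    }
  }
  if (any(solution$x[problem$present_metabolites] != 1L)) {
    stop("certificate failure: forced metabolite not produced")
  }
  w <- problem$weights
  obj <- sum(w[names(solution$y)] * solution$y) +
    cfg$delta * sum(solution$x)
  if (abs(obj - solution$objective) > 1e-5 * max(1, abs(obj))) {
    stop("certificate failure: objective mismatch")
  }
  invisible(TRUE)
}

#' Solve the extraction MILP
#'
#' Returns a proven-optimal solution (within the configured gap) or a
#' solution object with status `"infeasible"`; never throws on
#' infeasibility. Every optimal solution is passed through
#' [check_init_solution()] before being returned.
#'
#' @param problem an `init_problem`.
#' @return an `init_solution`: `status`, `objective`, binary inclusion
#'   `y`, fluxes `v`, accumulations `b`, production indicators `x`,
#'   `wall_time` seconds.
#' @export
solve_init <- function(problem) {
  t0 <- proc.time()[["elapsed"]]
  res <- milp_batch(list(problem$task))[[1]]
  if (res$status == "error") {
    stop("solver error: ", res$message)
  }
  sol <- decode_init_solution(problem, res)
  sol$wall_time <- proc.time()[["elapsed"]] - t0
  if (sol$status == "optimal") check_init_solution(problem, sol)
  sol
}

#' Solve many extraction MILPs in one solver call
#'
#' @param problems list of `init_problem`s.
#' @return list of `init_solution`s.
#' @export
solve_init_batch <- function(problems) {
  res <- milp_batch(lapply(problems, `[[`, "task"))
  out <- vector("list", length(problems))
  for (k in seq_along(problems)) {
    if (res[[k]]$status == "error") stop("solver error: ", res[[k]]$message)
    sol <- decode_init_solution(problems[[k]], res[[k]])
    if (sol$status == "optimal") check_init_solution(problems[[k]], sol)
    out[[k]] <- sol
  }
  out
}

#' @export
print.init_solution <- function(x, ...) {
  cat("init_solution:", x$status)
  if (x$status == "optimal") {
    cat(sprintf(", objective %.4f, %d/%d reactions included",
                x$objective, sum(x$y), length(x$y)))
  }
  cat("\n")
  invisible(x)
}

#' Extract the tissue-specific network from a solution
#'
#' Keeps exactly the reactions with `y = 1` plus the exchange reactions
#' actually used (`|v|` above tolerance). When per-gene scores are
#' supplied, each kept reaction's GPR is pruned to its
#' positive-evidence genes (possibly becoming empty).
#'
#' @param template a `metabolic_model`.
#' @param solution an optimal `init_solution`.
#' @param gene_scores optional named numeric of per-gene evidence scores.
#' @param flux_tol exchange-usage threshold.
#' @return a validated `metabolic_model`.
#' @export
extract_network <- function(template, solution, gene_scores = NULL,
                            flux_tol = 1e-6) {
  stopifnot(solution$status == "optimal")
  keep <- names(solution$y)[solution$y == 1L]
  exch <- template$reactions$id[template$reactions$is_exchange]
  used_exch <- exch[abs(solution$v[exch]) > flux_tol]
  sub <- model_subset(template, c(keep, used_exch))
  if (!is.null(gene_scores)) {
    for (rid in sub$reactions$id) {
      pruned <- prune_gpr(sub$gprs[[rid]], gene_scores)
      sub$gprs[[rid]] <- pruned
      sub$reactions$gpr[sub$reactions$id == rid] <- deparse_gpr(pruned)
    }
    sub$genes <- sort(unique(unlist(lapply(sub$gprs, gpr_genes))))
    validate_model(sub)
  }
  sub
}

# independent encoding of the fixed-subset subproblem used by the oracle:
# inclusion is frozen into variable bounds, only direction and production
# binaries remain; objective is the production reward alone
oracle_subset_task <- function(template, S, ne, include, present, config,
                               id = NULL) {
  rx <- template$reactions
  n <- nrow(rx); nm <- nrow(S)
  M <- config$big_M; eps <- config$epsilon_flux
  eps_b <- config$epsilon_production
  inc_rev <- ne[include & rx$reversible[ne]]
  iv <- seq_len(n)
  id_ <- if (length(inc_rev)) n + seq_along(inc_rev) else integer(0)
  ib <- n + length(inc_rev) + seq_len(nm)
  ix <- n + length(inc_rev) + nm + seq_len(nm)
  nv <- n + length(inc_rev) + 2 * nm
  lb <- rep(0, nv); ub <- rep(0, nv); vtype <- rep(0L, nv)
  # exchanges free, non-exchange per inclusion
  for (i in seq_len(n)) {
    if (rx$is_exchange[i]) {
      lb[i] <- if (rx$reversible[i]) -M else 0
      ub[i] <- M
    } else {
      pos <- match(i, ne)
      if (!include[pos]) { lb[i] <- 0; ub[i] <- 0 }
      else if (!rx$reversible[i]) { lb[i] <- eps; ub[i] <- M }
      else { lb[i] <- -M; ub[i] <- M }
    }
  }
  if (length(id_)) { lb[id_] <- 0; ub[id_] <- 1; vtype[id_] <- 1L }
  lb[ib] <- 0; ub[ib] <- M
  lb[ix] <- 0; ub[ix] <- 1; vtype[ix] <- 1L
  pm <- match(present, rownames(S))
  lb[ix[pm]] <- 1
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  rlb <- numeric(0); rub <- numeric(0); row <- 0L
  add_row <- function(js, xs, lo, hi) {
    row <<- row + 1L
    ti <<- c(ti, rep.int(row, length(js))); tj <<- c(tj, js)
    tx <<- c(tx, xs); rlb <<- c(rlb, lo); rub <<- c(rub, hi)
  }
  St <- methods::as(methods::as(S, "generalMatrix"), "TsparseMatrix")
  for (j in seq_len(nm)) {
    sel <- which(St@i + 1L == j)
    add_row(c(St@j[sel] + 1L, ib[j]), c(St@x[sel], -1), 0, 0)
  }
  for (q in seq_along(inc_rev)) {
    i <- inc_rev[q]
    add_row(c(i, id_[q]), c(1, -M), eps - M, Inf)  # d=1 => v >= eps
    add_row(c(i, id_[q]), c(1, -M), -Inf, -eps)    # d=0 => v <= -eps
  }
  for (j in seq_len(nm)) {
    add_row(c(ib[j], ix[j]), c(1, -M), -Inf, 0)
    add_row(c(ib[j], ix[j]), c(1, -eps_b), 0, Inf)
    sel <- which(St@i + 1L == j & !rx$is_exchange[St@j + 1L])
    Mrow <- M * (1 + sum(abs(St@x[sel])))
    add_row(c(St@j[sel] + 1L, ix[j]),
            c(St@x[sel], -(eps_b + Mrow)), -Mrow, Inf)
  }
  cc <- rep(0, nv); cc[ix] <- config$delta
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(row, nv))
  milp_task(c = cc, A = A, rlb = rlb, rub = rub, lb = lb, ub = ub,
            vtype = vtype, sense = "max",
            mip_gap = config$solver_gap_tolerance, id = id)
}

#' Brute-force optimum by subset enumeration
#'
#' Enumerates every inclusion subset of the non-exchange reactions
#' (bounded by `cap`), checks each with an independently encoded
#' fixed-subset subproblem, and returns the best attainable objective.
#' Subsets are visited in decreasing weight-sum order so that provably
#' dominated subsets (weight sum plus maximal production reward below
#' the incumbent) are pruned without solving.
#'
#' @param template a `metabolic_model`.
#' @param weights named numeric or `weight_vector`.
#' @param present_metabolites forced metabolite ids.
#' @param config an [init_config()].
#' @param cap refuse instances with more non-exchange reactions.
#' @return list `status` (`"optimal"`/`"infeasible"`), `objective`,
#'   `subset` (included reaction ids), `n_solved`.
#' @export
brute_force_oracle <- function(template, weights,
                               present_metabolites = character(),
                               config = init_config(), cap = 12) {
  if (inherits(weights, "weight_vector")) weights <- weights_as_vector(weights)
  rx <- template$reactions
  ne <- which(!rx$is_exchange)
  k <- length(ne)
  if (k > cap) {
    stop("brute_force_oracle: ", k, " non-exchange reactions exceeds cap ",
         cap)
  }
  S <- stoichiometric_matrix(template, internal_only = TRUE)
  w_ne <- unname(weights[rx$id[ne]])
  nsub <- bitwShiftL(1L, k)
  masks <- 0:(nsub - 1)
  wsum <- vapply(masks, function(m) {
    sum(w_ne[bitwAnd(bitwShiftR(m, 0:(max(k - 1, 0))), 1L) == 1L])
  }, numeric(1))
  if (k == 0) wsum <- 0
  ord <- order(wsum, decreasing = TRUE)
  max_reward <- config$delta * nrow(S)
  best <- -Inf; best_mask <- NA_integer_; n_solved <- 0L
  feasible_any <- FALSE
  pos <- 1L
  while (pos <= length(ord)) {
    wave <- ord[pos:min(pos + 63L, length(ord))]
    pos <- pos + length(wave)
    wave <- wave[wsum[wave] + max_reward > best + 1e-9]
    if (!length(wave)) break
    tasks <- lapply(wave, function(oidx) {
      m <- masks[oidx]
      include <- bitwAnd(bitwShiftR(m, 0:(max(k - 1, 0))), 1L) == 1L
      if (k == 0) include <- logical(0)
      oracle_subset_task(template, S, ne, include, present_metabolites,
                         config, id = oidx)
    })
    res <- milp_batch(tasks)
    n_solved <- n_solved + length(tasks)
    for (r in res) {
      if (r$status != "optimal") next
      feasible_any <- TRUE
      oidx <- as.integer(r$id)
      obj <- wsum[oidx] + r$objective
      if (obj > best + 1e-12) {
        best <- obj
        best_mask <- masks[oidx]
      }
    }
  }
  if (!feasible_any) {
    return(list(status = "infeasible", objective = NA_real_,
                subset = NULL, n_solved = n_solved))
  }
  include <- bitwAnd(bitwShiftR(best_mask, 0:(max(k - 1, 0))), 1L) == 1L
  if (k == 0) include <- logical(0)
  list(status = "optimal", objective = best,
       subset = rx$id[ne][include], n_solved = n_solved)
}

#' Jaccard similarity of two sets
#'
#' @param a,b character vectors.
#' @return `|a n b| / |a u b|`; 1 when both are empty.
#' @export
jaccard_index <- function(a, b) {
  u <- union(a, b)
  if (!length(u)) return(1)
  length(intersect(a, b)) / length(u)
}

#' Sensitivity of the extracted network to the staining weights
#'
#' Re-solves the extraction with every staining-category weight scaled by
#' `1 - perturbation` or `1 + perturbation` (full factorial grid by
#' default, or `n_draws` random sign combinations) and reports the
#' Jaccard similarity of each perturbed reaction set to the unperturbed
#' one. Only weights whose provenance is a staining call are rescaled;
#' expression-derived and default weights are left alone.
#'
#' @param template a `metabolic_model`.
#' @param weight_vector a `weight_vector` (provenance is required).
#' @param present_metabolites forced metabolite ids.
#' @param config an [init_config()].
#' @param perturbation relative perturbation (default 0.20).
#' @param n_draws `NULL` for the full 16-combination grid, or a number
#'   of random draws.
#' @param seed RNG seed for sampled draws.
#' @param weight_conf the [weight_config()] whose staining weights are
#'   perturbed.
#' @return data.frame with class `sensitivity_report`: one row per draw,
#'   the four scale factors, and `jaccard`; mean similarity in
#'   `attr(, "mean_jaccard")`.
#' @export
weight_sensitivity <- function(template, weight_vector,
                               present_metabolites = character(),
                               config = init_config(),
                               perturbation = 0.20, n_draws = NULL,
                               seed = 1L,
                               weight_conf = weight_config()) {
  stopifnot(inherits(weight_vector, "weight_vector"))
  base_problem <- build_init_problem(template, weight_vector,
                                     present_metabolites, config)
  if (is.null(n_draws)) {
    grid <- as.matrix(expand.grid(rep(list(c(1 - perturbation,
                                             1 + perturbation)), 4)))
  } else {
    stopifnot(n_draws >= 1)
    set.seed(seed)
    grid <- matrix(sample(c(1 - perturbation, 1 + perturbation),
                          4 * n_draws, replace = TRUE),
                   ncol = 4)
  }
  colnames(grid) <- HPA_LEVELS
  problems <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    w <- weight_vector
    hpa_rows <- which(w$source_type == "hpa")
    for (r in hpa_rows) {
      lvl <- w$source_level[r]
      w$weight[r] <- weight_conf$hpa_weights[[lvl]] * grid[g, lvl]
    }
    problems[[g]] <- build_init_problem(template, w, present_metabolites,
                                        config)
  }
  sols <- solve_init_batch(c(list(base_problem), problems))
  base_sol <- sols[[1]]
  stopifnot(base_sol$status == "optimal")
  base_set <- names(base_sol$y)[base_sol$y == 1L]
  jac <- vapply(seq_len(nrow(grid)), function(g) {
    s <- sols[[g + 1]]
    if (s$status != "optimal") return(NA_real_)
    jaccard_index(base_set, names(s$y)[s$y == 1L])
  }, numeric(1))
  out <- data.frame(grid, jaccard = jac)
  class(out) <- c("sensitivity_report", "data.frame")
  attr(out, "mean_jaccard") <- mean(jac, na.rm = TRUE)
  out
}

#' Write a solution report as JSON
#'
#' @param problem an `init_problem`.
#' @param solution an `init_solution`.
#' @param path output file; `NULL` returns the JSON string.
#' @return JSON string or `path` invisibly.
#' @export
solution_report_json <- function(problem, solution, path = NULL) {
  obj <- list(
    status = solution$status,
    objective = solution$objective,
    wall_time = solution$wall_time,
    reactions = if (is.null(solution$y)) NULL else data.frame(
      reaction = names(solution$y),
      y = as.integer(solution$y),
      w = unname(problem$weights[names(solution$y)]),
      v = unname(solution$v[names(solution$y)])),
    metabolites = if (is.null(solution$b)) NULL else data.frame(
      metabolite = names(solution$b),
      b = unname(solution$b),
      x = as.integer(solution$x)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}
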