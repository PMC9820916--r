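## Genetic-programming symbolic regression ------------------------------------

#' Configuration of a symbolic-regression experiment
#'
#' Desk-scale defaults: population 500 and 200 generations (one generation
#' = one population's worth of steady-state offspring), i.e. 100,000
#' model evaluations per run, with an absolute-error fitness, an 80/20
#' train/validation split and 10 independent runs.
#'
#' @param target Target column name (`"CSAmin"` or `"Vol"`, or any other).
#' @param operators Allowed building blocks, a subset of
#'   `c("add","sub","mul","div","exp","log","pow","sqrt")`.
#' @param pop_size Population size.
#' @param generations Generation budget.
#' @param eval_budget Model-evaluation budget (the run stops at whichever
#'   of the two budgets is hit first).
#' @param train_frac Fraction of rows used for training (in (0,1)).
#' @param runs Number of independent experiments `k`.
#' @param seed Root seed; per-run seeds are derived from it.
#' @param tournament Tournament size for selection.
#' @param p_crossover,p_mutation Crossover / mutation probabilities.
#' @param const_range Range for random constants, or `NULL` (default) to
#'   derive it from the training target's scale
#'   (`2 * (|mean(y)| + 3 * SD(y))`), so models can reach the target's
#'   magnitude without abusing transcendental building blocks as scale
#'   anchors. Power exponents are always generated in \[-3, 3\] and
#'   capped at magnitude 10.
#' @param archive_size Maximum number of models kept on a Pareto front.
#' @param max_size Maximum tree size (nodes); larger offspring are discarded.
#' @param polish Polish the constants of archived models by Nelder-Mead
#'   minimization of the training MAE before reporting a run's front.
#' @return An object of class `sr_config`.
#' @export
sr_config <- function(target, operators = c("add", "sub", "mul", "div",
                                            "exp", "log", "pow", "sqrt"),
                      pop_size = 500, generations = 200, eval_budget = 1e6,
                      train_frac = 0.8, runs = 10, seed = 1, tournament = 3,
                      p_crossover = 0.9, p_mutation = 0.3,
                      const_range = NULL, archive_size = 50,
                      max_size = 30, polish = TRUE) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0,1)")
  if (pop_size < 2 || generations < 1 || eval_budget < 1)
    stop("budgets must be positive")
  bad <- setdiff(operators, c(SR_BINARY, SR_UNARY))
  if (length(bad)) stop("unknown operator(s): ", paste(bad, collapse = ", "))
  structure(list(target = target, operators = operators, pop_size = pop_size,
                 generations = generations, eval_budget = eval_budget,
                 train_frac = train_frac, runs = runs, seed = seed,
                 tournament = tournament, p_crossover = p_crossover,
                 p_mutation = p_mutation, const_range = const_range,
                 archive_size = archive_size, max_size = max_size,
                 polish = polish),
            class = "sr_config")
}

## mutation operators ---------------------------------------------------------

const_indices <- function(tree) {
  idx <- integer(0); k <- 0L
  rec <- function(node) {
    k <<- k + 1L
    if (node$type == "const") idx <<- c(idx, k)
    if (node$type == "op") for (a in node$args) rec(a)
  }
  rec(tree)
  idx
}

jitter_constants <- function(tree, const_range) {
  idx <- const_indices(tree)
  if (!length(idx)) return(tree)
  i <- if (length(idx) == 1L) idx else sample(idx, 1)
  node <- get_subtree(tree, i)
  scale <- max(abs(node$value), 1) * 10^stats::runif(1, -4, 0)
  node$value <- node$value + stats::rnorm(1, 0, scale)
  node$value <- min(max(node$value, const_range[1] * 10), const_range[2] * 10)
  set_subtree(tree, i, node)
}

point_mutate <- function(tree, vars, operators, const_range) {
  n <- tree_size(tree)
  i <- if (n == 1L) 1L else sample.int(n, 1)
  node <- get_subtree(tree, i)
  if (node$type == "op") {
    same <- setdiff(operators[vapply(operators, op_arity, 1L) ==
                                op_arity(node$op)], node$op)
    if (length(same)) node$op <- if (length(same) == 1L) same else sample(same, 1)
  } else if (node$type == "var") {
    other <- setdiff(vars, node$name)
    if (length(other))
      node$name <- if (length(other) == 1L) other else sample(other, 1)
  } else {
    node$value <- stats::runif(1, const_range[1], const_range[2])
  }
  set_subtree(tree, i, node)
}

subtree_mutate <- function(tree, vars, operators, const_range) {
  n <- tree_size(tree)
  i <- if (n == 1L) 1L else sample.int(n, 1)
  set_subtree(tree, i, random_tree(vars, operators, const_range,
                                   max_depth = 2))
}

crossover <- function(t1, t2) {
  n1 <- tree_size(t1); n2 <- tree_size(t2)
  i <- if (n1 == 1L) 1L else sample.int(n1, 1)
  j <- if (n2 == 1L) 1L else sample.int(n2, 1)
  set_subtree(t1, i, get_subtree(t2, j))
}

## size-tracking variants used in the hot loop: return list(tree, size)
crossover_sz <- function(t1, n1, t2, n2) {
  i <- if (n1 == 1L) 1L else sample.int(n1, 1)
  j <- if (n2 == 1L) 1L else sample.int(n2, 1)
  ins <- get_subtree(t2, j)
  rp <- replace_subtree(t1, i, ins)
  list(tree = rp$tree,
       size = n1 - tree_size(rp$removed) + tree_size(ins))
}

subtree_mutate_sz <- function(tree, n, vars, operators, const_range) {
  i <- if (n == 1L) 1L else sample.int(n, 1)
  new <- random_tree(vars, operators, const_range, max_depth = 2)
  rp <- replace_subtree(tree, i, new)
  list(tree = rp$tree,
       size = n - tree_size(rp$removed) + tree_size(new))
}

## Pareto archive: best training MAE per complexity level ---------------------

archive_insert <- function(archive, complexity, mae, tree, a = 0, b = 1) {
  key <- as.character(complexity)
  cur <- archive[[key]]
  if (is.null(cur) || mae < cur$mae)
    archive[[key]] <- list(mae = mae, tree = tree, complexity = complexity,
                           a = a, b = b)
  archive
}

## strict front: increasing complexity, strictly decreasing MAE
archive_front <- function(archive, archive_size) {
  entries <- archive[order(as.integer(names(archive)))]
  front <- list(); best <- Inf
  for (e in entries) {
    if (is.finite(e$mae) && e$mae < best) {
      front[[length(front) + 1L]] <- e
      best <- e$mae
    }
  }
  if (length(front) > archive_size)
    front <- front[seq_len(archive_size)]
  front
}

## fast fitness closures: evaluation environment built once per run.
## The scaled variant implements linear scaling: fitness is the MAE of the
## affine-calibrated prediction a + b * f(x), with (a, b) the least-squares
## optimum on the data; structures are thereby compared by their best
## achievable fit, and (a, b) become explicit constants of the reported
## model. Returns c(mae, a, b).
make_fast_evaluator <- function(data, predictors, target, scale = FALSE) {
  env <- list2env(as.list(data[predictors]))
  parent.env(env) <- asNamespace("airwaymorph")
  y <- data[[target]]
  n <- length(y)
  my <- mean(y)
  if (!scale) {
    return(function(tree) {
      v <- tryCatch(eval(tree_lang(tree), env), error = function(e) NaN)
      if (length(v) == 1L) v <- rep(v, n)
      if (!all(is.finite(v))) return(Inf)
      mean(abs(v - y))
    })
  }
  function(tree) {
    v <- tryCatch(eval(tree_lang(tree), env), error = function(e) NaN)
    if (length(v) == 1L) v <- rep(v, n)
    if (!all(is.finite(v))) return(c(Inf, 0, 0))
    mv <- mean(v)
    den <- sum(v * v) - n * mv * mv
    if (!is.finite(den)) return(c(Inf, 0, 0))  # squared overflow
    if (den < 1e-12 * max(1, mv * mv)) {       # constant prediction
      return(c(mean(abs(my - y)), my, 0))
    }
    b <- (sum(v * y) - n * mv * my) / den
    a <- my - b * mv
    m <- mean(abs(a + b * v - y))
    if (!is.finite(m)) return(c(Inf, 0, 0))
    c(m, a, b)
  }
}

## fold the affine calibration into the expression tree
scale_tree <- function(tree, a, b) {
  if (b == 0) return(sr_const(a))
  if (tree$type == "const") return(sr_const(a + b * tree$value))
  out <- tree
  if (b != 1) out <- sr_op("mul", sr_const(b), out)
  if (a != 0) out <- sr_op("add", sr_const(a), out)
  out
}

polish_model <- function(tree, fast_eval) {
  idx <- const_indices(tree)
  if (!length(idx) || length(idx) > 8L) return(tree)
  get_consts <- vapply(idx, function(i) get_subtree(tree, i)$value, numeric(1))
  assign_consts <- function(v) {
    t2 <- tree
    for (j in seq_along(idx)) {
      node <- get_subtree(t2, idx[j]); node$value <- v[j]
      t2 <- set_subtree(t2, idx[j], node)
    }
    t2
  }
  obj <- function(v) {
    m <- fast_eval(assign_consts(v))
    if (!is.finite(m)) 1e12 else m
  }
  fit <- tryCatch(
    if (length(idx) == 1L) {
      span <- max(abs(get_consts), 1)
      o <- stats::optimize(function(v) obj(v),
                           interval = get_consts + c(-2, 2) * span,
                           tol = 1e-12)
      list(par = o$minimum, value = o$objective)
    } else {
      stats::optim(get_consts, obj, method = "Nelder-Mead",
                   control = list(maxit = 300, reltol = 1e-12))
    },
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) return(tree)
  if (fit$value <= obj(get_consts)) assign_consts(fit$par) else tree
}

## single GP run --------------------------------------------------------------

#' Evolve symbolic-regression models for one run
#'
#' Steady-state genetic programming: tournament selection, subtree
#' crossover, point and subtree mutation, constant jitter and elitism,
#' with the absolute error on the training rows as fitness. Fitness uses
#' linear scaling: each candidate structure f is scored by the MAE of its
#' least-squares affine calibration a + b * f(x), and the calibration
#' constants are folded into the reported expression, so structures
#' compete on their best achievable fit rather than on the luck of their
#' raw constants. A Pareto
#' archive over (complexity, training MAE) is maintained throughout; the
#' run stops at the generation or evaluation budget, whichever comes
#' first. The best model of a run is the front model with the lowest
#' validation MAE, ties resolved toward lower complexity. Deterministic
#' under a fixed seed.
#'
#' @param table Data frame (>= 10 rows) holding predictors and the target.
#' @param config An [sr_config()].
#' @param seed Seed for this run (defaults to `config$seed`).
#' @param predictors Optional character vector of predictor columns
#'   (default: all numeric columns except the target).
#' @return Object of class `sr_run`: `front` (list of
#'   `expression_model`), `best`, `split` (train row indices), `seed`,
#'   `n_evals`.
#' @export
evolve <- function(table, config, seed = config$seed, predictors = NULL) {
  stopifnot(inherits(config, "sr_config"))
  target <- config$target
  if (!target %in% names(table)) stop("unknown target column: ", target)
  if (nrow(table) < 10) stop("need at least 10 rows")
  if (stats::sd(table[[target]]) == 0)
    stop("degenerate target: zero variance")
  if (is.null(predictors)) {
    predictors <- setdiff(
      names(table)[vapply(table, is.numeric, logical(1))], target)
    predictors <- predictors[vapply(table[predictors],
                                    function(x) !anyNA(x), logical(1))]
  }
  predictors <- setdiff(predictors, target)
  if (!length(predictors)) stop("no usable predictor columns")
  used <- c(predictors, target)
  if (anyNA(table[used])) stop("missing values in used columns")

  set.seed(seed)
  n <- nrow(table)
  tr_idx <- sort(sample.int(n, round(config$train_frac * n)))
  train <- table[tr_idx, used, drop = FALSE]
  val <- table[-tr_idx, used, drop = FALSE]

  ops <- config$operators
  cr <- config$const_range
  if (is.null(cr)) {
    r <- 2 * (abs(mean(train[[target]])) + 3 * stats::sd(train[[target]]))
    cr <- c(-r, r)
  }
  fast_tr <- make_fast_evaluator(train, predictors, target, scale = TRUE)
  fast_plain <- make_fast_evaluator(train, predictors, target)
  fast_val <- make_fast_evaluator(val, predictors, target)
  evals <- 0L
  fitness_of <- function(tree) {
    evals <<- evals + 1L
    fast_tr(tree)
  }

  ## archive keys are the complexity of the *reported* (affine-completed)
  ## expression, so the front reflects what the user receives
  reported_cplx <- function(sz, a, b) {
    if (b == 0) 1L else sz + (b != 1) * 2L + (a != 0) * 2L
  }

  pop <- vector("list", config$pop_size)
  fit <- numeric(config$pop_size)
  psz <- integer(config$pop_size)
  archive <- list()
  ## baseline: the mean predictor always sits on the front at complexity 1
  ybar <- mean(train[[target]])
  archive <- archive_insert(archive, 1L, mean(abs(train[[target]] - ybar)),
                            sr_const(ybar), ybar, 0)
  for (i in seq_len(config$pop_size)) {
    depth <- sample(2:4, 1)
    tree <- random_tree(predictors, ops, cr, depth)
    pop[[i]] <- tree
    fv <- fitness_of(tree)
    fit[i] <- fv[1]
    psz[i] <- tree_size(tree)
    archive <- archive_insert(archive, reported_cplx(psz[i], fv[2], fv[3]),
                              fv[1], tree, fv[2], fv[3])
  }

  max_offspring <- config$generations * config$pop_size
  produced <- 0L
  npop <- config$pop_size; tsz <- config$tournament
  ## lexicographic parsimony: fitness first, node count on ties (keeps the
  ## population from bloating once low-error models are common)
  better <- function(i, j) fit[i] < fit[j] ||
    (fit[i] == fit[j] && psz[i] < psz[j])
  elite <- 1L
  for (i in 2:npop) if (better(i, elite)) elite <- i
  while (produced < max_offspring && evals < config$eval_budget) {
    produced <- produced + 1L
    cand <- sample.int(npop, tsz)
    p1 <- cand[1L]
    for (j in cand[-1L]) if (better(j, p1)) p1 <- j
    child <- pop[[p1]]; sz <- psz[p1]
    if (stats::runif(1) < config$p_crossover) {
      cand <- sample.int(npop, tsz)
      p2 <- cand[1L]
      for (j in cand[-1L]) if (better(j, p2)) p2 <- j
      cx <- crossover_sz(child, sz, pop[[p2]], psz[p2])
      child <- cx$tree; sz <- cx$size
    }
    if (stats::runif(1) < config$p_mutation) {
      which_mut <- sample.int(3L, 1L)
      if (which_mut == 1L) {
        child <- point_mutate(child, predictors, ops, cr)
      } else if (which_mut == 2L) {
        sm <- subtree_mutate_sz(child, sz, predictors, ops, cr)
        child <- sm$tree; sz <- sm$size
      } else {
        child <- jitter_constants(child, cr)
      }
    }
    if (sz > config$max_size) next
    fv <- fitness_of(child)
    f <- fv[1]
    archive <- archive_insert(archive, reported_cplx(sz, fv[2], fv[3]),
                              f, child, fv[2], fv[3])
    ## reverse tournament for replacement; elitism: protect the best
    cand <- sample.int(npop, tsz)
    worst <- cand[1L]
    for (j in cand[-1L]) if (better(worst, j)) worst <- j
    if (worst != elite &&
        (f < fit[worst] || (f == fit[worst] && sz <= psz[worst]))) {
      pop[[worst]] <- child
      fit[worst] <- f
      psz[worst] <- sz
      if (better(worst, elite)) elite <- worst
    }
  }

  ## materialize the affine calibration into each archived tree, then
  ## rebuild the strict front on the reported complexities
  entries <- lapply(archive, function(e) {
    mt <- scale_tree(e$tree, e$a, e$b)
    list(mae = e$mae, tree = mt, complexity = tree_size(mt))
  })
  bycplx <- list()
  for (e in entries) {
    key <- as.character(e$complexity)
    if (is.null(bycplx[[key]]) || e$mae < bycplx[[key]]$mae)
      bycplx[[key]] <- e
  }
  front <- archive_front(bycplx, config$archive_size)

  if (config$polish) {
    for (i in seq_along(front)) {
      t2 <- polish_model(front[[i]]$tree, fast_plain)
      m2 <- fast_plain(t2)
      if (m2 < front[[i]]$mae) {
        front[[i]]$tree <- t2
        front[[i]]$mae <- m2
      }
    }
    ## re-impose strict improvement after polishing
    keep <- list(); best <- Inf
    for (e in front) if (e$mae < best) { keep[[length(keep) + 1L]] <- e; best <- e$mae }
    front <- keep
  }

  models <- lapply(front, function(e)
    sr_model(e$tree, mae_train = e$mae, mae_val = fast_val(e$tree)))
  vals <- vapply(models, `[[`, numeric(1), "mae_val")
  cplx <- vapply(models, `[[`, numeric(1), "complexity")
  ord <- order(vals, cplx)
  best_model <- if (length(models)) models[[ord[1]]] else NULL

  structure(list(front = models, best = best_model, split = tr_idx,
                 seed = seed, n_evals = evals, target = target,
                 predictors = predictors),
            class = "sr_run")
}

#' @export
print.sr_run <- function(x, ...) {
  cat(sprintf("<sr_run> target %s: %d front models, %d evaluations\n",
              x$target, length(x$front), x$n_evals))
  if (!is.null(x$best)) { cat("best: "); print(x$best) }
  invisible(x)
}

## experiments ----------------------------------------------------------------

#' Run k independent symbolic-regression experiments
#'
#' Each run draws its own seed (derived from the root seed) and its own
#' random train/validation split, then evolves models independently.
#' Results are pooled into a normalized fitness-weighted variable
#' importance table (over all Pareto-front models of all runs) and a
#' signed sensitivity table (over the best model of each run).
#'
#' @param table Data frame of predictors and target.
#' @param config An [sr_config()].
#' @param predictors Optional predictor subset (see [evolve()]).
#' @return Object of class `sr_experiment`: `runs` (list of `sr_run`),
#'   `importance` (data frame), `sensitivity` (data frame), `config`.
#' @export
run_experiments <- function(table, config, predictors = NULL) {
  stopifnot(inherits(config, "sr_config"))
  set.seed(config$seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, config$runs)
  runs <- lapply(run_seeds, function(s)
    evolve(table, config, seed = s, predictors = predictors))
  pooled <- unlist(lapply(runs, `[[`, "front"), recursive = FALSE)
  imp <- variable_importance(pooled)
  best_models <- Filter(Negate(is.null), lapply(runs, `[[`, "best"))
  sens <- aggregate_sensitivity(best_models, table, config$target)
  structure(list(runs = runs, importance = imp, sensitivity = sens,
                 config = config),
            class = "sr_experiment")
}

#' @export
print.sr_experiment <- function(x, ...) {
  cat(sprintf("<sr_experiment> target %s, %d runs\n",
              x$config$target, length(x$runs)))
  cat("top importance:\n")
  print(utils::head(x$importance, 5), row.names = FALSE)
  invisible(x)
}

#' Normalized fitness-weighted variable importance
#'
#' Each model m gets weight `w_m = 1 / (eps + validation MAE_m)`; the raw
#' importance of a variable is the weighted proportion of models that
#' contain it, `sum(w_m * contains) / sum(w_m)`, then importances are
#' normalized to sum to 1 across variables and ranked descending.
#'
#' @param models List of `expression_model` (e.g. pooled Pareto fronts).
#' @param eps Weight regularizer (default 1e-12).
#' @return Data frame: `variable`, `importance` (sums to 1), `n_models`.
#' @export
variable_importance <- function(models, eps = 1e-12) {
  models <- Filter(function(m) is.finite(m$mae_val), models)
  if (!length(models)) stop("no feasible model to weight")
  w <- vapply(models, function(m) 1 / (eps + m$mae_val), numeric(1))
  vars <- sort(unique(unlist(lapply(models, `[[`, "variables"))))
  if (!length(vars))
    return(data.frame(variable = character(0), importance = numeric(0),
                      n_models = integer(0)))
  raw <- vapply(vars, function(v) {
    has <- vapply(models, function(m) v %in% m$variables, logical(1))
    sum(w[has]) / sum(w)
  }, numeric(1))
  nm <- vapply(vars, function(v)
    sum(vapply(models, function(m) v %in% m$variables, logical(1))), numeric(1))
  imp <- raw / sum(raw)
  out <- data.frame(variable = vars, importance = unname(imp),
                    n_models = as.integer(nm))
  out[order(-out$importance), , drop = FALSE]
}

#' Signed sensitivity (magnitude of effects) of a model
#'
#' For each variable in the model, the standardized mean partial
#' derivative over the table rows: central finite differences with step
#' `1e-4 * SD(x_j)`, scaled by `SD(x_j) / SD(f)`. A positive magnitude
#' means the target increases when the variable increases. Variables
#' whose derivative is undefined on more than 10% of rows are flagged.
#'
#' @param model An `expression_model`.
#' @param table Data frame on which to differentiate.
#' @param target Target column (used only for error messages; the model's
#'   own outputs define the scale).
#' @return Data frame: `variable`, `magnitude`, `flagged`.
#' @export
sensitivity <- function(model, table, target = NULL) {
  stopifnot(inherits(model, "expression_model"))
  f0 <- eval_tree(model$tree, table)
  if (!all(is.finite(f0)))
    stop("model is infeasible on the supplied table")
  sd_f <- stats::sd(f0)
  rows <- lapply(model$variables, function(v) {
    sx <- stats::sd(table[[v]])
    if (sx == 0)
      return(data.frame(variable = v, magnitude = 0, flagged = FALSE))
    h <- 1e-4 * sx
    up <- table; up[[v]] <- up[[v]] + h
    dn <- table; dn[[v]] <- dn[[v]] - h
    d <- (eval_tree(model$tree, up) - eval_tree(model$tree, dn)) / (2 * h)
    bad <- !is.finite(d)
    flag <- mean(bad) > 0.10
    mag <- if (all(bad) || sd_f == 0) NA_real_
           else mean(d[!bad]) * sx / sd_f
    data.frame(variable = v, magnitude = mag, flagged = flag)
  })
  do.call(rbind, rows)
}

#' Mean magnitude of effects across best models
#'
#' Averages each variable's signed sensitivity over the best models that
#' contain it and reports the containment count, the per-experiment
#' summary used to read off the direction of each anatomical effect.
#'
#' @param models List of `expression_model` (one best model per run).
#' @param table Data frame on which sensitivities are evaluated.
#' @param target Target column name (for reference).
#' @return Data frame: `variable`, `mean_magnitude`, `n_models`, `flagged`
#'   (TRUE if flagged in any contributing model).
#' @export
aggregate_sensitivity <- function(models, table, target = NULL) {
  per <- lapply(models, function(m)
    tryCatch(sensitivity(m, table, target), error = function(e) NULL))
  per <- Filter(Negate(is.null), per)
  if (!length(per))
    return(data.frame(variable = character(0), mean_magnitude = numeric(0),
                      n_models = integer(0), flagged = logical(0)))
  all <- do.call(rbind, per)
  agg <- lapply(split(all, all$variable), function(d)
    data.frame(variable = d$variable[1],
               mean_magnitude = mean(d$magnitude, na.rm = TRUE),
               n_models = nrow(d), flagged = any(d$flagged)))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(-abs(out$mean_magnitude)), , drop = FALSE]
}
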