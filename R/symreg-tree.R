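## Expression trees for symbolic regression -----------------------------------
##
## A tree node is a list: list(type = "op", op, args), list(type = "var",
## name), or list(type = "const", value). Allowed operators are the classic
## building blocks: addition, subtraction, multiplication, division,
## exponential, natural logarithm, power and square root. Evaluation is
## strict: any non-finite prediction on any row (division by zero, log of a
## non-positive value, square root of a negative, invalid power) marks the
## model infeasible rather than being "protected" away.

SR_BINARY <- c("add", "sub", "mul", "div", "pow")
SR_UNARY <- c("exp", "log", "sqrt")

op_arity <- function(op) if (op %in% SR_BINARY) 2L else 1L

# warning-free numeric kernels (NaN instead of a condition)
.amlog <- function(x) {
  y <- rep(NaN, length(x)); ok <- is.finite(x) & x > 0
  y[ok] <- log(x[ok]); y
}
.amsqrt <- function(x) {
  y <- rep(NaN, length(x)); ok <- is.finite(x) & x >= 0
  y[ok] <- sqrt(x[ok]); y
}

sr_var <- function(name) list(type = "var", name = name)
sr_const <- function(value) list(type = "const", value = value)
sr_op <- function(op, ...) list(type = "op", op = op, args = list(...))

#' Render an expression tree as an infix string
#'
#' @param tree An expression-tree node (see [sr_model()]).
#' @return Character scalar.
#' @export
tree_infix <- function(tree) {
  switch(tree$type,
    var = tree$name,
    const = format(tree$value, digits = 6),
    op = {
      a <- lapply(tree$args, tree_infix)
      switch(tree$op,
        add = sprintf("(%s + %s)", a[[1]], a[[2]]),
        sub = sprintf("(%s - %s)", a[[1]], a[[2]]),
        mul = sprintf("(%s * %s)", a[[1]], a[[2]]),
        div = sprintf("(%s / %s)", a[[1]], a[[2]]),
        pow = sprintf("(%s ^ %s)", a[[1]], a[[2]]),
        sprintf("%s(%s)", tree$op, a[[1]]))
    })
}

## tree -> R language object, for fast vectorized evaluation
tree_lang <- function(tree) {
  switch(tree$type,
    var = as.name(tree$name),
    const = tree$value,
    op = {
      a <- lapply(tree$args, tree_lang)
      switch(tree$op,
        add = call("+", a[[1]], a[[2]]),
        sub = call("-", a[[1]], a[[2]]),
        mul = call("*", a[[1]], a[[2]]),
        div = call("/", a[[1]], a[[2]]),
        pow = call("^", a[[1]], a[[2]]),
        exp = call("exp", a[[1]]),
        log = call(".amlog", a[[1]]),
        sqrt = call(".amsqrt", a[[1]]))
    })
}

#' Number of nodes of an expression tree
#'
#' Model complexity is the plain node count with unit operator weights.
#'
#' @param tree An expression-tree node.
#' @return Integer.
#' @export
tree_size <- function(tree) {
  if (tree$type != "op") return(1L)
  s <- 1L
  for (a in tree$args) s <- s + tree_size(a)
  s
}

#' Variables used by an expression tree
#'
#' @param tree An expression-tree node.
#' @return Character vector of distinct variable names.
#' @export
tree_variables <- function(tree) {
  switch(tree$type,
    var = tree$name,
    const = character(0),
    op = unique(unlist(lapply(tree$args, tree_variables))))
}

## preorder subtree access (index 1 = root)
get_subtree <- function(tree, i) {
  k <- 0L; found <- NULL
  rec <- function(node) {
    k <<- k + 1L
    if (k == i) { found <<- node; return(invisible()) }
    if (node$type == "op")
      for (a in node$args) {
        if (k >= i) break
        rec(a)
      }
  }
  rec(tree)
  found
}

set_subtree <- function(tree, i, sub) {
  k <- 0L
  rec <- function(node) {
    k <<- k + 1L
    if (k == i) return(sub)
    if (node$type == "op" && k < i)
      for (j in seq_along(node$args)) {
        node$args[[j]] <- rec(node$args[[j]])
        if (k >= i) break
      }
    node
  }
  rec(tree)
}

## single-pass replacement that also reports the removed subtree
replace_subtree <- function(tree, i, sub) {
  k <- 0L; removed <- NULL
  rec <- function(node) {
    k <<- k + 1L
    if (k == i) { removed <<- node; return(sub) }
    if (node$type == "op" && k < i)
      for (j in seq_along(node$args)) {
        node$args[[j]] <- rec(node$args[[j]])
        if (k >= i) break
      }
    node
  }
  out <- rec(tree)
  list(tree = out, removed = removed)
}

## random tree by the grow method
random_tree <- function(vars, operators, const_range, max_depth,
                        p_terminal = 0.3, p_const = 0.2) {
  if (max_depth <= 0 || stats::runif(1) < p_terminal) {
    if (stats::runif(1) < p_const)
      return(sr_const(stats::runif(1, const_range[1], const_range[2])))
    return(sr_var(sample(vars, 1)))
  }
  op <- sample(operators, 1)
  if (op == "pow") {
    # keep exponents bounded: a constant in [-10, 10]
    return(sr_op("pow",
                 random_tree(vars, operators, const_range, max_depth - 1,
                             p_terminal, p_const),
                 sr_const(stats::runif(1, -3, 3))))
  }
  args <- replicate(op_arity(op),
                    random_tree(vars, operators, const_range, max_depth - 1,
                                p_terminal, p_const),
                    simplify = FALSE)
  do.call(sr_op, c(list(op), args))
}

#' Construct a symbolic-regression model object
#'
#' @param tree Expression-tree node.
#' @param mae_train,mae_val Training / validation mean absolute error
#'   (`Inf` when infeasible).
#' @return Object of class `expression_model` with fields `tree`,
#'   `complexity`, `mae_train`, `mae_val`, `infix`, `variables`.
#' @export
sr_model <- function(tree, mae_train = NA_real_, mae_val = NA_real_) {
  structure(list(tree = tree, complexity = tree_size(tree),
                 mae_train = mae_train, mae_val = mae_val,
                 infix = tree_infix(tree), variables = tree_variables(tree)),
            class = "expression_model")
}

#' @export
print.expression_model <- function(x, ...) {
  cat(sprintf("<expression_model> %s\n  complexity %d, MAE train %.4g / val %.4g\n",
              x$infix, x$complexity, x$mae_train, x$mae_val))
  invisible(x)
}

#' Predict from an expression model
#'
#' @param object An `expression_model` (or bare tree node).
#' @param newdata Data frame with the model's variables as columns.
#' @param ... Unused.
#' @return Numeric vector of predictions (may contain non-finite values).
#' @export
predict.expression_model <- function(object, newdata, ...) {
  eval_tree(object$tree, newdata)
}

eval_tree <- function(tree, data) {
  vars <- tree_variables(tree)
  missing <- setdiff(vars, names(data))
  if (length(missing))
    stop("unknown variable(s) in model: ", paste(missing, collapse = ", "))
  env <- list2env(as.list(data[vars]), parent = asNamespace("airwaymorph"))
  v <- eval(tree_lang(tree), env)
  n <- length(data[[1]])
  if (length(v) == 1L) v <- rep(v, n)
  v
}

#' Mean absolute error of a model on a table
#'
#' Any non-finite prediction marks the model infeasible (`Inf`).
#'
#' @param model An `expression_model` or bare tree.
#' @param table Data frame of predictors.
#' @param target Name of the target column in `table`.
#' @return Scalar MAE (mm^2/mm^3 units of the target), or `Inf`.
#' @export
evaluate_model <- function(model, table, target) {
  tree <- if (inherits(model, "expression_model")) model$tree else model
  if (!target %in% names(table)) stop("unknown target column: ", target)
  pred <- eval_tree(tree, table)
  if (!all(is.finite(pred))) return(Inf)
  mean(abs(pred - table[[target]]))
}

#' Serialize a model to JSON (tree, infix, complexity, errors)
#'
#' @param model An `expression_model`.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(tree = model$tree, infix = model$infix,
         complexity = model$complexity,
         mae_train = model$mae_train, mae_val = model$mae_val),
    path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
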