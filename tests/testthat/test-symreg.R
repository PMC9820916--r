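# naive reference interpreter, independent of the package's language-object
# evaluation path
naive_eval <- function(node, row) {
  if (node$type == "var") return(row[[node$name]])
  if (node$type == "const") return(node$value)
  a <- naive_eval(node$args[[1]], row)
  b <- if (length(node$args) > 1) naive_eval(node$args[[2]], row) else NULL
  switch(node$op,
         add = a + b, sub = a - b, mul = a * b, div = a / b, pow = a^b,
         exp = exp(a),
         log = if (is.na(a) || a <= 0) NaN else log(a),
         sqrt = if (is.na(a) || a < 0) NaN else sqrt(a))
}

tiny_cfg <- function(target, ...) {
  sr_config(target = target, pop_size = 60, generations = 20,
            eval_budget = 5000, runs = 2, seed = 7, ...)
}

test_that("model evaluation matches examples and flags infeasibility", {
  tab <- data.frame(x1 = c(3, 1, -2), y = c(5, 3, 0))
  m_add <- airwaymorph:::sr_op("add", airwaymorph:::sr_var("x1"),
                               airwaymorph:::sr_const(2))
  expect_equal(evaluate_model(m_add, tab, "y"), 0)
  m_log <- airwaymorph:::sr_op("log", airwaymorph:::sr_var("x1"))
  expect_equal(evaluate_model(m_log, tab, "y"), Inf)   # x1 <= 0 row
  m_bad <- airwaymorph:::sr_var("nope")
  expect_error(evaluate_model(m_bad, tab, "y"), "unknown variable")
})

test_that("tree evaluation agrees with a naive recursive interpreter", {
  set.seed(42)
  vars <- c("x1", "x2", "x3")
  tab <- data.frame(x1 = runif(15, 0.5, 3), x2 = runif(15, 0.5, 3),
                    x3 = runif(15, 0.5, 3))
  ops <- c("add", "sub", "mul", "div", "exp", "log", "pow", "sqrt")
  for (i in 1:30) {
    tr <- airwaymorph:::random_tree(vars, ops, c(-3, 3), sample(2:4, 1))
    got <- airwaymorph:::eval_tree(tr, tab)
    want <- vapply(seq_len(15),
                   function(r) naive_eval(tr, as.list(tab[r, ])), numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("tree utilities are mutually consistent", {
  set.seed(9)
  ops <- c("add", "sub", "mul", "div", "exp", "log", "pow", "sqrt")
  for (i in 1:20) {
    tr <- airwaymorph:::random_tree(c("a", "b"), ops, c(-5, 5), 3)
    n <- tree_size(tr)
    expect_identical(airwaymorph:::get_subtree(tr, 1), tr)
    k <- sample(n, 1)
    sub <- airwaymorph:::get_subtree(tr, k)
    back <- airwaymorph:::set_subtree(tr, k, sub)
    expect_identical(back, tr)
    expect_true(all(tree_variables(tr) %in% c("a", "b")))
    expect_type(tree_infix(tr), "character")
  }
})

test_that("power exponents stay bounded during generation", {
  set.seed(4)
  ops <- c("add", "pow")
  check <- function(node) {
    if (node$type != "op") return(TRUE)
    if (node$op == "pow") {
      ex <- node$args[[2]]
      if (ex$type == "const" && abs(ex$value) > 10) return(FALSE)
    }
    all(vapply(node$args, check, logical(1)))
  }
  for (i in 1:50)
    expect_true(check(airwaymorph:::random_tree(c("x"), ops, c(-500, 500), 4)))
})

test_that("near-constant targets collapse to the constant model", {
  set.seed(60)
  # an exactly constant target is rejected as degenerate
  flat <- data.frame(x1 = rnorm(20), y = rep(4.25, 20))
  expect_error(evolve(flat, tiny_cfg("y")), "zero variance")

  tab <- data.frame(x1 = rnorm(20), x2 = rnorm(20),
                    y = 4.25 + rnorm(20, 0, 1e-9))
  r <- evolve(tab, tiny_cfg("y"), seed = 3)
  c1 <- Filter(function(m) m$complexity == 1, r$front)
  expect_equal(length(c1), 1)
  expect_lt(c1[[1]]$mae_train, 1e-8)
  expect_equal(c1[[1]]$tree$value, 4.25, tolerance = 1e-6)
  expect_identical(c1[[1]]$tree$type, "const")
})

test_that("evolution is deterministic under a fixed seed", {
  set.seed(1)
  tab <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
  tab$y <- tab$x1 - tab$x2 + rnorm(30, 0, 0.1)
  r1 <- evolve(tab, tiny_cfg("y"), seed = 77)
  r2 <- evolve(tab, tiny_cfg("y"), seed = 77)
  expect_identical(lapply(r1$front, `[[`, "infix"),
                   lapply(r2$front, `[[`, "infix"))
  expect_identical(r1$best$mae_val, r2$best$mae_val)
  expect_identical(r1$split, r2$split)
})

test_that("the Pareto front is strictly improving and non-dominated", {
  set.seed(2)
  tab <- as.data.frame(matrix(rnorm(150), 30, 5))
  names(tab) <- paste0("x", 1:5)
  tab$y <- tab$x1 * 2 + tab$x2^2 + rnorm(30, 0, 0.2)
  r <- evolve(tab, tiny_cfg("y"), seed = 12)
  cplx <- vapply(r$front, `[[`, numeric(1), "complexity")
  mae <- vapply(r$front, `[[`, numeric(1), "mae_train")
  expect_true(all(diff(cplx) > 0))
  expect_true(all(diff(mae) < 0))
})

test_that("evolve validates its preconditions", {
  tab <- data.frame(x1 = rnorm(30), y = rep(1, 30))
  expect_error(evolve(tab, tiny_cfg("y")), "zero variance")
  expect_error(evolve(data.frame(x1 = 1:5, y = 1:5), tiny_cfg("y")),
               "at least 10")
  expect_error(evolve(data.frame(x1 = rnorm(30), y = rnorm(30)),
                      tiny_cfg("nope")), "unknown target")
  expect_error(sr_config("y", train_frac = 1), "train_frac")
})

test_that("variable importance implements inverse-MAE presence weighting", {
  mk <- function(vars, mae) {
    tr <- if (length(vars) == 1) airwaymorph:::sr_var(vars) else
      airwaymorph:::sr_op("add", airwaymorph:::sr_var(vars[1]),
                          airwaymorph:::sr_var(vars[2]))
    m <- sr_model(tr, mae_train = mae, mae_val = mae)
    m
  }
  one <- variable_importance(list(mk("x1", 2)))
  expect_equal(one$importance, 1)

  two <- variable_importance(list(mk("x1", 3), mk("x2", 3)))
  expect_equal(two$importance, c(0.5, 0.5))

  # weights 1/(eps+MAE): (1, 1, 1/9) -> raw x1 = 2, x2 = 1/9, ratio 18
  three <- variable_importance(list(mk("x1", 1), mk("x1", 1), mk("x2", 9)))
  i1 <- three$importance[three$variable == "x1"]
  i2 <- three$importance[three$variable == "x2"]
  expect_equal(i1 / i2, 18, tolerance = 1e-9)
  expect_equal(sum(three$importance), 1)

  # duplicating the model set leaves importance unchanged
  ms <- list(mk("x1", 1), mk("x2", 4))
  expect_equal(variable_importance(c(ms, ms))$importance,
               variable_importance(ms)$importance)
  expect_error(variable_importance(list(mk("x1", Inf))), "no feasible")
})

test_that("sensitivity reports standardized signed mean derivatives", {
  set.seed(20)
  tab <- data.frame(x = rnorm(50, 10, 2), z = rnorm(50, 5, 1))
  m2x <- sr_model(airwaymorph:::sr_op("mul", airwaymorph:::sr_const(2),
                                      airwaymorph:::sr_var("x")))
  s <- sensitivity(m2x, tab)
  expect_equal(s$magnitude, 1, tolerance = 1e-6)
  m3x <- sr_model(airwaymorph:::sr_op("mul", airwaymorph:::sr_const(-3),
                                      airwaymorph:::sr_var("x")))
  expect_equal(sensitivity(m3x, tab)$magnitude, -1, tolerance = 1e-6)

  # f = x * z against a brute-force numeric differentiation oracle
  mprod <- sr_model(airwaymorph:::sr_op("mul", airwaymorph:::sr_var("x"),
                                        airwaymorph:::sr_var("z")))
  s2 <- sensitivity(mprod, tab)
  f0 <- tab$x * tab$z
  for (v in c("x", "z")) {
    h <- 1e-6 * sd(tab[[v]])
    up <- tab; up[[v]] <- up[[v]] + h
    dn <- tab; dn[[v]] <- dn[[v]] - h
    want <- mean((up$x * up$z - dn$x * dn$z) / (2 * h)) * sd(tab[[v]]) / sd(f0)
    expect_equal(s2$magnitude[s2$variable == v], want, tolerance = 1e-6)
  }
})

test_that("run_experiments with k = 1 reduces to a single evolve", {
  set.seed(30)
  tab <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
  tab$y <- 3 * tab$x1 + rnorm(40, 0, 0.1)
  cfg <- tiny_cfg("y"); cfg$runs <- 1L
  ex <- run_experiments(tab, cfg)
  set.seed(cfg$seed)
  s <- sample.int(.Machine$integer.max - 1L, 1)
  solo <- evolve(tab, cfg, seed = s)
  expect_identical(lapply(ex$runs[[1]]$front, `[[`, "infix"),
                   lapply(solo$front, `[[`, "infix"))
})

test_that("larger budgets do not worsen the achievable fit", {
  set.seed(50)
  tab <- data.frame(x1 = rnorm(40), x2 = rnorm(40), x3 = rnorm(40))
  tab$y <- tab$x1 * tab$x2 + rnorm(40, 0, 0.05)
  small <- sr_config("y", pop_size = 40, generations = 8,
                     eval_budget = 320, runs = 1, seed = 1)
  big <- sr_config("y", pop_size = 40, generations = 32,
                   eval_budget = 1280, runs = 1, seed = 1)
  med_small <- median(vapply(1:5, function(i)
    evolve(tab, small, seed = i)$best$mae_val, numeric(1)))
  med_big <- median(vapply(1:5, function(i)
    evolve(tab, big, seed = i)$best$mae_val, numeric(1)))
  expect_lte(med_big, med_small)
})

test_that("model JSON serialization carries tree, errors and complexity", {
  tr <- airwaymorph:::sr_op("add", airwaymorph:::sr_var("x1"),
                            airwaymorph:::sr_const(2.5))
  m <- sr_model(tr, mae_train = 0.1, mae_val = 0.2)
  f <- tempfile(fileext = ".json")
  write_model_json(m, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(obj$complexity, 3)
  expect_equal(obj$mae_val, 0.2)
  expect_match(obj$infix, "x1")
})
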