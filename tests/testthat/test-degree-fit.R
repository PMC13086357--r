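test_that("degree distributions match hand-computed probabilities", {
  net <- supply_network(mk_nodes(c("A", "B", "C")),
                        mk_links(c("A", "B"), c("B", "C")))
  din <- degree_distribution(net, "in")
  expect_equal(din$support, c(0, 1))
  expect_equal(din$probabilities, c(1 / 3, 2 / 3))

  star <- supply_network(
    mk_nodes(c(paste0("R", 1:5), "S")),
    mk_links(paste0("R", 1:5), rep("S", 5))
  )
  din <- degree_distribution(star, "in")
  expect_equal(din$support, c(0, 5))
  expect_equal(din$probabilities, c(5 / 6, 1 / 6))

  # a self-loop adds one to both directions
  loop <- supply_network(mk_nodes("A"), mk_links("A", "A"))
  expect_equal(degree_distribution(loop, "in")$support, 1)
  expect_equal(degree_distribution(loop, "out")$support, 1)

  expect_error(degree_distribution(supply_network(data.frame(), data.frame())),
               "empty")
})

test_that("probabilities always sum to one", {
  for (seed in 1:5) {
    net <- random_digraph(12, p = 0.25, seed = seed, loops = TRUE)
    for (dir in c("in", "out")) {
      dist <- degree_distribution(net, dir)
      expect_equal(sum(dist$probabilities), 1, tolerance = 1e-12)
      expect_equal(sum(dist$counts), dist$n_nodes)
      expect_true(all(diff(dist$support) > 0))
    }
  }
})

# distribution object with prescribed (k, p) pairs for exact-recovery tests
dist_from_pk <- function(k, p, n = 1000) {
  structure(
    list(direction = "in", support = k, probabilities = p,
         counts = p * n, n_nodes = n, degrees = NULL),
    class = "degree_distribution"
  )
}

test_that("fitting exact model data recovers the parameters", {
  k <- c(1, 2, 4, 8)
  fit <- fit_model(dist_from_pk(k, 0.6 * k^(-1)), "power_law")
  expect_equal(fit$params[["a"]], 0.6, tolerance = 1e-6)
  expect_equal(fit$params[["b"]], 1.0, tolerance = 1e-6)
  expect_lt(fit$chi2, 1e-10)

  k <- 0:5
  fit <- fit_model(dist_from_pk(k, 0.5 * exp(-0.5 * k)), "exponential")
  expect_equal(fit$params[["a"]], 0.5, tolerance = 1e-6)
  expect_equal(fit$params[["b"]], 0.5, tolerance = 1e-6)
  expect_lt(fit$chi2, 1e-10)

  k <- 1:8
  p <- 1 / (k * 0.7 * sqrt(2 * pi)) * exp(-(log(k) - 0.9)^2 / (2 * 0.7^2))
  fit <- fit_model(dist_from_pk(k, p), "log_normal")
  expect_equal(fit$params[["mu"]], 0.9, tolerance = 1e-6)
  expect_equal(fit$params[["sigma"]], 0.7, tolerance = 1e-6)
  expect_lt(fit$chi2, 1e-10)
})

test_that("power-law and log-normal fits exclude the zero bin", {
  dist <- dist_from_pk(c(0, 1, 2, 4), c(0.4, 0.3, 0.2, 0.1))
  fit <- fit_model(dist, "power_law")
  expect_equal(fit$fit_support, c(1, 2, 4))
  expect_error(chi_square_gof(dist, fit, include_zero_bin = TRUE),
               "undefined at k = 0")
  # the exponential uses the full support
  fit_e <- fit_model(dist, "exponential")
  expect_equal(fit_e$fit_support, c(0, 1, 2, 4))
})

test_that("too few support points is an error", {
  expect_error(fit_model(dist_from_pk(c(0, 1), c(0.5, 0.5)), "power_law"),
               "fewer support points")
})

test_that("chi-squared statistic matches the hand formula", {
  expect_equal(chisq_statistic(c(10, 10), c(5, 15)), 25 / 5 + 25 / 15)
  expect_error(chisq_statistic(c(1, 2), c(0, 3)), "exclude")

  set.seed(99)
  for (i in 1:20) {
    o <- runif(6, 1, 50)
    e <- runif(6, 1, 50)
    expect_equal(chisq_statistic(o, e), sum((o - e)^2 / e), tolerance = 1e-12)
  }
})

test_that("a perfect fit gives chi2 = 0 and p = 1", {
  k <- c(1, 2, 3, 4, 5)
  fit <- fit_model(dist_from_pk(k, 0.6 * k^(-1.5)), "power_law")
  gof <- chi_square_gof(fit$distribution, fit)
  expect_equal(gof$chi2, 0, tolerance = 1e-10)
  expect_equal(gof$p_value, 1, tolerance = 1e-8)
  # dof convention: bins - 1
  expect_equal(gof$dof, 4)
  # textbook correction available behind the flag
  expect_equal(chi_square_gof(fit$distribution, fit,
                              dof_correction = TRUE)$dof, 2)
})

test_that("chi-squared on counts reproduces the renormalised-count oracle", {
  net <- random_digraph(40, p = 0.1, seed = 3)
  dist <- degree_distribution(net, "in")
  fit <- fit_model(dist, "exponential")
  gof <- chi_square_gof(dist, fit)
  pred <- fit$params[["a"]] * exp(-fit$params[["b"]] * dist$support)
  obs <- dist$counts
  expd <- pred / sum(pred) * sum(obs)
  expect_equal(gof$chi2, sum((obs - expd)^2 / expd), tolerance = 1e-12)
  expect_equal(gof$p_value,
               pchisq(gof$chi2, length(dist$support) - 1, lower.tail = FALSE))
})

test_that("model selection minimises chi2 with a deterministic tie-break", {
  dist <- dist_from_pk(c(1, 2, 3, 4, 6), c(0.4, 0.25, 0.15, 0.12, 0.08))
  fits <- lapply(c("power_law", "exponential", "log_normal"),
                 function(m) fit_model(dist, m))
  best <- select_best_model(fits)
  expect_equal(best$chi2, min(vapply(fits, function(f) f$chi2, numeric(1))))
  expect_identical(select_best_model(fits[2]), fits[[2]])

  # exact tie resolved lexically by model name, and recorded
  f1 <- fits[[1]]; f2 <- fits[[2]]
  f1$chi2 <- 1; f2$chi2 <- 1
  pick <- select_best_model(list(f1, f2))
  expect_equal(pick$model, "exponential")
  expect_match(attr(pick, "tie_break"), "tie on chi2")

  # fits on different distributions cannot be compared
  other <- fit_model(dist_from_pk(c(1, 2, 4), c(0.6, 0.3, 0.1)), "power_law")
  expect_error(select_best_model(list(fits[[1]], other)), "different")
})
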