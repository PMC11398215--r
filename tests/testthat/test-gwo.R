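test_that("the exploration coefficient decays linearly from 2 to 0", {
  expect_equal(gwo_coefficient_a(0, 20), 2)
  expect_equal(gwo_coefficient_a(19, 20), 0)
  expect_equal(gwo_coefficient_a(10, 21), 1)
  expect_equal(gwo_coefficient_a(0, 1), 2)
  expect_error(gwo_coefficient_a(5, 5), "iteration")
})

test_that("position updates respect the leader geometry", {
  space <- gwo_search_space(1, 10, 1, 1, 10, 1)
  # all leaders and the wolf coincide, a = 0: the update is a fixed point
  leaders <- matrix(c(4, 4, 4, 5, 5, 5), 3, 2)
  withr::with_seed(1, {
    expect_equal(gwo_update_position(c(4, 5), leaders, a = 0, space), c(4, 5))
  })

  # leader centroid (6 + 8 + 3)/3 = 5.7 with a = 0 snaps to the unit grid
  space_k <- gwo_search_space(1, 10, 1, 0, 0, 1)
  lead <- matrix(c(6, 8, 3, 0, 0, 0), 3, 2)
  withr::with_seed(2, {
    cand <- gwo_update_position(c(2, 0), lead, a = 0, space_k)
  })
  expect_equal(cand[1], round(5.7))

  # any draw stays inside the bounds and on the grid
  space2 <- gwo_search_space(2, 6, 1, 10, 5000, 10)
  withr::with_seed(3, {
    for (i in 1:50) {
      p <- gwo_update_position(c(2, 10), matrix(c(6, 6, 6, 5000, 5000, 5000), 3, 2),
                               a = 2, space2)
      expect_true(p[1] >= 2 && p[1] <= 6 && p[1] == round(p[1]))
      expect_true(p[2] >= 10 && p[2] <= 5000 && (p[2] - 10) %% 10 == 0)
    }
  })
})

test_that("a constant objective yields that constant with no improvement", {
  g <- gwo_minimize(function(k, pf) 3.25, gwo_search_space(), n_wolves = 6,
                    n_iter = 5, seed = 4)
  expect_equal(g$best_fitness, 3.25)
  expect_equal(g$converged_iteration, 0)
  expect_true(all(g$trace$fitness == 3.25))
})

test_that("GWO matches the exhaustive minimum of a separable bowl", {
  space <- gwo_search_space(2, 6, 1, 10, 5000, 10)
  bowl <- function(k, pf) (k - 4)^2 + ((pf - 2500) / 10)^2
  # exhaustive grid oracle
  grid <- expand.grid(k = 2:6, pf = seq(10, 5000, 10))
  exact <- grid[which.min(bowl(grid$k, grid$pf)), ]
  expect_equal(c(exact$k, exact$pf), c(4, 2500))

  # the always-move (canonical) variant keeps enough late-stage dispersion in
  # the K dimension to localize both coordinates reliably
  hits <- vapply(1:50, function(s) {
    g <- gwo_minimize(bowl, space, seed = s, greedy = FALSE)
    g$best_k >= 3 && g$best_k <= 5 && g$best_pf >= 2400 && g$best_pf <= 2600
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # the greedy default still localizes the dominant PF coordinate
  hits_g <- vapply(1:25, function(s) {
    g <- gwo_minimize(bowl, space, seed = s)
    g$best_pf >= 2400 && g$best_pf <= 2600
  }, logical(1))
  expect_gte(mean(hits_g), 0.95)
})

test_that("small unimodal grids are solved to the exhaustive optimum", {
  space <- gwo_search_space(1, 5, 1, 0, 190, 10)  # 5 x 20 grid
  obj <- function(k, pf) abs(k - 3) + abs(pf - 120) / 50
  grid <- expand.grid(k = 1:5, pf = seq(0, 190, 10))
  best_exact <- min(obj(grid$k, grid$pf))
  hits <- vapply(1:40, function(s) {
    g <- gwo_minimize(obj, space, seed = 100 + s)
    isTRUE(all.equal(g$best_fitness, best_exact))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("best-so-far fitness is monotone non-increasing under greedy updates", {
  g <- gwo_minimize(function(k, pf) (k - 3)^2 + pf / 1000,
                    gwo_search_space(), seed = 7)
  best_by_iter <- vapply(split(g$trace$fitness, g$trace$iteration), min,
                         numeric(1))
  expect_true(all(diff(cummin(best_by_iter)) <= 0))
  leader <- g$trace[g$trace$rank == "alpha", ]
  expect_true(all(diff(leader$fitness) <= 0))
})

test_that("identical seeds give bit-identical traces", {
  f <- function(k, pf) sin(k) + cos(pf / 500)
  g1 <- gwo_minimize(f, gwo_search_space(), n_wolves = 8, n_iter = 6, seed = 9)
  g2 <- gwo_minimize(f, gwo_search_space(), n_wolves = 8, n_iter = 6, seed = 9)
  expect_identical(g1$trace, g2$trace)
  expect_identical(glance(g1), glance(g2))
})

test_that("failed objective evaluations are skipped, not fatal", {
  f <- function(k, pf) if (pf > 2500) stop("boom") else k + pf / 5000
  g <- gwo_minimize(f, gwo_search_space(), n_wolves = 6, n_iter = 5, seed = 11)
  expect_lte(g$best_pf, 2500)
  expect_true(is.finite(g$best_fitness))
  expect_gt(g$n_failed, 0)
})

test_that("visited positions always lie on the grid inside bounds", {
  g <- gwo_minimize(function(k, pf) k + pf, gwo_search_space(), n_wolves = 6,
                    n_iter = 6, seed = 13)
  expect_true(all(g$trace$k >= 2 & g$trace$k <= 6 & g$trace$k == round(g$trace$k)))
  expect_true(all(g$trace$pf >= 10 & g$trace$pf <= 5000 &
                    (g$trace$pf - 10) %% 10 == 0))
})

test_that("the convergence report ends at 100% of the converged values", {
  g <- gwo_minimize(function(k, pf) 1 + (k - 3)^2 + abs(pf - 100) / 100,
                    gwo_search_space(), n_wolves = 8, n_iter = 8, seed = 15)
  conv <- gwo_convergence(g)
  expect_equal(nrow(conv), g$n_iter + 1)
  last <- conv[nrow(conv), ]
  expect_equal(c(last$k_pct, last$pf_pct, last$fitness_pct), c(100, 100, 100))
  expect_s3_class(autoplot(g), "ggplot")
})
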