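# Scenario generation, worst-case objectives, the spot-weight optimizer and
# prescription normalization.

library(Matrix)

test_that("default robustness settings yield exactly 21 unique scenarios", {
  sc <- generate_scenarios()
  expect_length(sc, 21)
  key <- vapply(sc, function(s) paste(c(s$shift_mm, s$range_error),
                                      collapse = "/"), character(1))
  expect_equal(anyDuplicated(key), 0L)
  # nominal scenario first
  expect_equal(sc[[1]]$shift_mm, c(0, 0, 0))
  expect_equal(sc[[1]]$range_error, 0)
  # every shift is axis-aligned: at most one nonzero component of +/- 2 mm
  for (s in sc) {
    expect_lte(sum(s$shift_mm != 0), 1)
    expect_true(all(abs(s$shift_mm) %in% c(0, 2)))
    expect_true(s$range_error %in% c(-0.035, 0, 0.035))
  }
})

test_that("degenerate robustness settings deduplicate to the nominal scenario", {
  sc <- generate_scenarios(0, 0)
  expect_length(sc, 1)
  expect_equal(sc[[1]]$shift_mm, c(0, 0, 0))
})

# tiny two-voxel, two-spot fixture with hand-computable penalties
tiny_terms <- function(bound_min = 10, bound_max = 10, w_min = 1,
                       w_max = 1) {
  list(list(idx = 1:2, type = "min_dose", bound = bound_min,
            weight = w_min, scope = "worst"),
       list(idx = 1:2, type = "max_dose", bound = bound_max,
            weight = w_max, scope = "worst"))
}

test_that("worst-case objective picks the argmax scenario (hand oracle)", {
  # scenario doses chosen so the composite penalties are exactly 4 and 9:
  # bound 10, scenario 1 dose (8, 10) -> mean((2,0)^2) = 2... use 1 voxel
  A1 <- Matrix(matrix(c(8), 1, 1), sparse = TRUE)   # dose 8  -> (10-8)^2 = 4
  A2 <- Matrix(matrix(c(7), 1, 1), sparse = TRUE)   # dose 7  -> (10-7)^2 = 9
  terms <- list(list(idx = 1, type = "min_dose", bound = 10, weight = 1,
                     scope = "worst"))
  ob <- worst_case_objective(1, list(A1, A2), terms)
  expect_equal(ob$value, 9)
  expect_equal(ob$argmax, 2)
  # gradient comes from scenario 2: d/dw (10 - 7w)^2 at w=1 = -2*3*7 = -42
  expect_equal(ob$grad, -42)
  expect_equal(ob$scenario_values, c(4, 9))
})

test_that("worst case reduces to the plain composite for one scenario", {
  A <- Matrix(matrix(c(3, 0, 0, 5), 2, 2), sparse = TRUE)
  terms <- tiny_terms(bound_min = 4, bound_max = 6)
  ob <- worst_case_objective(c(1, 1), list(A), terms)
  # doses (3, 5): min penalty mean((1,0)^2)=0.5, max penalty 0
  expect_equal(ob$value, 0.5)
  # uniform dose exactly at the bounds gives a zero objective
  Au <- Matrix(diag(c(10, 10)), sparse = TRUE)
  expect_equal(worst_case_objective(c(1, 1), list(Au), tiny_terms())$value,
               0)
})

test_that("per-term worst case takes each term's own worst scenario", {
  # scenario 1: cold (7), scenario 2: hot (13); bounds 10/10
  A1 <- Matrix(matrix(7, 1, 1), sparse = TRUE)
  A2 <- Matrix(matrix(13, 1, 1), sparse = TRUE)
  terms <- list(list(idx = 1, type = "min_dose", bound = 10, weight = 1,
                     scope = "worst"),
                list(idx = 1, type = "max_dose", bound = 10, weight = 1,
                     scope = "worst"))
  comp <- worst_case_objective(1, list(A1, A2), terms, mode = "composite")
  pert <- worst_case_objective(1, list(A1, A2), terms, mode = "per_term")
  expect_equal(comp$value, 9)       # both scenarios score 9; max is 9
  expect_equal(pert$value, 18)      # 9 (cold, scen 1) + 9 (hot, scen 2)
  # nominal-scope terms only see the first scenario
  terms_nom <- list(list(idx = 1, type = "max_dose", bound = 10, weight = 1,
                         scope = "nominal"))
  expect_equal(worst_case_objective(1, list(A1, A2), terms_nom,
                                    mode = "per_term")$value, 0)
})

test_that("single-spot optimum matches the closed form within 0.1%", {
  a <- 0.37  # influence of the spot on the single voxel
  p <- 74
  A <- Matrix(matrix(a, 1, 1), sparse = TRUE)
  terms <- list(list(idx = 1, type = "min_dose", bound = p, weight = 1,
                     scope = "worst"),
                list(idx = 1, type = "max_dose", bound = p, weight = 1,
                     scope = "worst"))
  res <- optimize_weights(1, list(A), terms, max_iter = 200)
  expect_lt(abs(res$weights - p / a) / (p / a), 1e-3)
  expect_true(res$converged)
})

test_that("objective history is non-increasing and a fixed point terminates", {
  set.seed(3)
  A <- Matrix(matrix(runif(40 * 12, 0, 0.4), 40, 12), sparse = TRUE)
  A2 <- A * 0.97
  terms <- list(list(idx = 1:40, type = "min_dose", bound = 10, weight = 1,
                     scope = "worst"),
                list(idx = 1:40, type = "max_dose", bound = 11, weight = 1,
                     scope = "worst"))
  res <- optimize_weights(rep(1, 12), list(A, A2), terms, max_iter = 150)
  expect_true(all(diff(res$objective) <= 0))
  expect_lt(res$objective[length(res$objective)], res$objective[1])
  # restarting from the converged weights changes nothing
  res2 <- optimize_weights(res$weights, list(A, A2), terms, max_iter = 150)
  expect_equal(res2$weights, res$weights)
  expect_true(res2$converged)
  # weights stay in the non-negative orthant
  expect_true(all(res$weights >= 0))
})

test_that("optimizer matches a reference minimizer on a convex single-scenario problem", {
  set.seed(8)
  A <- Matrix(matrix(runif(30 * 8, 0, 0.5), 30, 8), sparse = TRUE)
  terms <- list(list(idx = 1:30, type = "min_dose", bound = 10, weight = 1,
                     scope = "worst"),
                list(idx = 1:30, type = "max_dose", bound = 10.5,
                     weight = 1, scope = "worst"))
  res <- optimize_weights(rep(1, 8), list(A), terms, max_iter = 400,
                          tol = 1e-9)
  # independent general-purpose reference: bound-constrained minimization of
  # the same objective value with finite-difference gradients
  ref <- stats::optim(rep(1, 8),
                      fn = function(w) worst_case_objective(w, list(A),
                                                            terms)$value,
                      method = "L-BFGS-B", lower = 0,
                      control = list(maxit = 2000, factr = 1e4))
  f_opt <- res$objective[length(res$objective)]
  expect_lt(abs(f_opt - ref$value) / max(ref$value, 1e-9), 0.005)
})

test_that("degenerate optimizer inputs are rejected", {
  A0 <- Matrix(matrix(0, 3, 2), sparse = TRUE)
  terms <- list(list(idx = 1:3, type = "min_dose", bound = 1, weight = 1,
                     scope = "worst"))
  expect_error(optimize_weights(c(1, 1), list(A0), terms), "no spot")
  expect_error(optimize_weights(numeric(0), list(A0), terms), "no spots")
})

test_that("EUD objective term gradient agrees with finite differences", {
  set.seed(5)
  A <- Matrix(matrix(runif(20 * 6, 0.2, 0.6), 20, 6), sparse = TRUE)
  terms <- list(list(idx = 1:20, type = "eud_max", bound = 2, weight = 1,
                     a = 12, scope = "worst"))
  w <- runif(6, 0.5, 1.5)
  ob <- worst_case_objective(w, list(A), terms)
  num <- vapply(seq_along(w), function(j) {
    h <- 1e-6
    wp <- w; wp[j] <- wp[j] + h
    wm <- w; wm[j] <- wm[j] - h
    (worst_case_objective(wp, list(A), terms)$value -
       worst_case_objective(wm, list(A), terms)$value) / (2 * h)
  }, numeric(1))
  expect_equal(ob$grad, num, tolerance = 1e-4)
})

test_that("normalization scales the CTV median to the prescription", {
  grid <- water_grid(half_xy = 10, half_z = 8)
  mask <- sphere_mask(grid, c(0, 0, 0), 6)
  ctv <- rt_structure("CTV", "target", mask)
  vals <- array(0, grid$dims)
  vals[mask] <- 37
  dose <- structure(list(values = vals, grid = grid), class = "dose_grid")
  expect_equal(normalize_to_median(dose, ctv, 74), 2)
  vals[mask] <- 74
  dose$values <- vals
  expect_equal(normalize_to_median(dose, ctv, 74), 1)
  # interpolated median on a hand-sorted 5-voxel example
  idx <- which(mask)[1:5]
  vals[mask] <- 0
  vals[idx] <- c(5, 1, 4, 2, 3)          # median = 3 by hand
  dose$values <- vals
  small <- array(FALSE, grid$dims)
  small[idx] <- TRUE
  expect_equal(normalize_to_median(dose, rt_structure("S", "target", small),
                                   74), 74 / 3)
  vals[idx] <- 0
  dose$values <- vals
  expect_error(normalize_to_median(dose, rt_structure("S", "target", small),
                                   74), "zero median")
})
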