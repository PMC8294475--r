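# Surrogate objective backends (deterministic residual functions over the
# mathematical coordinates) exercise the optimizer without the oracle.

quad_backend <- function(ref, target_k, weight = 1) {
  force(target_k)
  function(params, seed = 0) {
    k <- kvec_of(params)
    list(residuals = weight * (k - target_k))
  }
}

test_that("damped Gauss-Newton recovers a convex quadratic minimum", {
  ref <- paramset("HCON")
  target <- c(0.8, -0.5, 0.3, 0.2, -0.1, 0.4, 0.6, -0.3)
  cfg <- opt_config(w_reg = 0, obj_tol = 1e-9, step_tol = 1e-9)
  fit <- optimize_params(ref, quad_backend(ref, target), cfg)
  expect_equal(unname(kvec_of(fit$params)), target, tolerance = cfg$step_tol * 100)
  expect_lt(fit$objective$total, 1e-10)
  # with w_reg > 0 the analytic optimum shifts to target/(1 + w/weight^2)
  cfg2 <- opt_config(w_reg = 0.1, obj_tol = 1e-9, step_tol = 1e-9)
  fit2 <- optimize_params(ref, quad_backend(ref, target, weight = 2), cfg2)
  expect_equal(unname(kvec_of(fit2$params)), target * 4 / 4.1, tolerance = 1e-5)
})

test_that("starting at the optimum terminates immediately", {
  ref <- paramset("HCON")
  fit <- optimize_params(ref, quad_backend(ref, rep(0, 8)),
                         opt_config(w_reg = 0))
  expect_lte(max(fit$trace$iter), 1L)
  expect_true(fit$termination %in% c("objective-tol", "step-tol"))
})

test_that("accepted-step objectives are non-increasing and tolerances bind", {
  ref <- paramset("H2CON")
  target <- rep(1.5, 10)
  fit <- optimize_params(ref, quad_backend(ref, target), opt_config())
  expect_true(all(diff(fit$trace$L) <= 0))
  expect_true(fit$termination %in% c("step-tol", "objective-tol", "max-iter"))

  # gradient descent path obeys the same contracts
  fitg <- optimize_params(ref, quad_backend(ref, target),
                          opt_config(method = "gradient-descent",
                                     obj_tol = 1e-6, step_tol = 1e-6,
                                     w_reg = 0, max_iter = 500))
  expect_true(all(diff(fitg$trace$L) <= 0))
  expect_equal(unname(kvec_of(fitg$params)), target, tolerance = 0.01)
})

test_that("a two-basin surrogate yields distinct endpoints by start", {
  ref <- paramset("HCON")
  dw <- function(params, seed = 0) {
    k <- kvec_of(params)
    list(residuals = c((k[1] - 0.5) * (k[1] - 3), 0.1 * (k[1] - 3),
                       0.05 * k[-1]))
  }
  cfg <- opt_config(w_reg = 0, obj_tol = 1e-8, step_tol = 1e-8, max_iter = 200)
  hi <- optimize_params(from_math(c(2.6, rep(0, 7)), ref), dw, cfg)
  lo <- optimize_params(from_math(c(0.7, rep(0, 7)), ref), dw, cfg)
  k_hi <- kvec_of(hi$params)[1]; k_lo <- kvec_of(lo$params)[1]
  expect_gt(abs(k_hi - k_lo), 1)
  expect_gt(abs(hi$objective$total - lo$objective$total), 0.01)
})

test_that("multi_start retains replicates and selects the best", {
  ref <- paramset("HCON")
  fn <- quad_backend(ref, rep(0.6, 8))
  cfg <- opt_config(w_reg = 0, obj_tol = 1e-8, step_tol = 1e-8)
  # deterministic backend, identical starts: identical replicates
  ms0 <- multi_start(ref, fn, cfg, seeds = 1:3, jitter = 0)
  finals <- vapply(ms0$replicates, function(r) r$objective$total, numeric(1))
  expect_equal(ms0$objective_range, 0)
  expect_equal(finals[1], finals[2])
  # with jitter, best equals the min over replicates
  ms <- multi_start(ref, fn, cfg, seeds = 1:3, jitter = 0.5)
  finals <- vapply(ms$replicates, function(r) r$objective$total, numeric(1))
  expect_equal(ms$best$objective$total, min(finals))
  expect_equal(ms$objective_range, max(finals) - min(finals))
})

test_that("embedding a coarse optimum into a refining model is exact", {
  coarse <- paramset("HCON")
  coarse$types$eps <- c(0.02, 0.09, 0.25, 0.19)
  coarse$types$rmin_half <- c(1.3, 2.0, 1.1, 1.5)
  fine <- embed_params(coarse, "H2CON")
  ce <- stats::setNames(coarse$types$eps, coarse$types$type_id)
  expect_equal(fine$types$eps[fine$types$type_id == "H.apolar"], ce[["H"]])
  expect_equal(fine$types$eps[fine$types$type_id == "H.polar"], ce[["H"]])
  # embedded values become the restart's restraint center
  expect_equal(sum(to_math(fine)^2), 0)
  expect_error(embed_params(paramset("H2CON"), "HCO3N"),
               class = "ljtyping_contract_error")
})

test_that("consistency_check flags under-optimized fine models", {
  rel <- refinement_relation("HCO3N", "H2CO3N")
  mk <- function(model, L) {
    list(params = paramset(model),
         objective = total_objective(L, NULL))
  }
  bad <- consistency_check(mk("H2CO3N", 84), mk("HCO3N", 39), rel)
  expect_equal(bad$verdict, "under-optimized")
  expect_s3_class(bad$restart, "lj_paramset")
  expect_equal(bad$restart$model_name, "H2CO3N")

  ok <- consistency_check(mk("H2CO3N", 30), mk("HCO3N", 39), rel)
  expect_equal(ok$verdict, "pass")
  expect_error(consistency_check(mk("H2CO3N", 1), mk("HCO3N", 2),
                                 list(refines = FALSE)),
               class = "ljtyping_contract_error")
})

test_that("superspace law holds on deterministic surrogates", {
  study <- get_study(50, 2, noise = FALSE)
  cfg <- opt_config(w_reg = 0.1)
  for (pair in list(c("HCON", "H2CON"), c("HCON", "HCO3N"),
                    c("H2CON", "H2CO3N"))) {
    cf <- optimize_params(paramset(pair[1]),
                          study_objective(study, pair[1]), cfg)
    fine_start <- embed_params(cf$params, pair[2])
    ff <- optimize_params(fine_start, study_objective(study, pair[2]), cfg)
    expect_lte(ff$objective$total, cf$objective$total + cfg$obj_tol)
  }
})

test_that("greedy search stops at the base when nothing improves", {
  # trivial backend: nothing to fit, constant held-out objective
  flat_factory <- function(model) function(params, seed = 0)
    list(residuals = numeric(0))
  flat_test <- function(model, params) 10
  res <- greedy_split_search("HCON", c("H2CON", "HCO3N"),
                             flat_factory, flat_test,
                             opt_config(w_reg = 0), margin = 0)
  expect_equal(res$final_model, "HCON")
  expect_length(res$accepted, 0L)
})

test_that("jointly-useful splits defeat greedy but not exhaustive search", {
  # constructed oracle: the H and O splits help only together
  flat_factory <- function(model) function(params, seed = 0)
    list(residuals = numeric(0))
  scores <- c(HCON = 10, H2CON = 10, HCO3N = 10, H2CO3N = 2)
  score_test <- function(model, params) unname(scores[[model$name]])
  res <- greedy_split_search("HCON", c("H2CON", "HCO3N", "H2CO3N"),
                             flat_factory, score_test,
                             opt_config(w_reg = 0), margin = 0)
  expect_equal(res$final_model, "HCON")
  # exhaustive enumeration of split pairs finds the joint winner
  pair_scores <- vapply(names(scores), function(mn)
    score_test(typing_model(mn), NULL), numeric(1))
  expect_equal(names(which.min(pair_scores)), "H2CO3N")
})
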