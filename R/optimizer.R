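# Local optimization of LJ parameters in mathematical (k) space.
#
# The default method is damped Gauss-Newton (Levenberg-style) on the scaled
# residual vector, with finite-difference Jacobians; plain gradient descent
# is available as a fidelity option. Termination follows the protocol the
# models were originally fit with: stop when the Euclidean norm of the
# k-step falls below 0.01 or the unitless objective changes by less than
# 1.0 between accepted iterations.
#
# Objective backend contract: a function `fn(params, seed = 0)` returning a
# list with at least `residuals` (numeric vector of scaled data residuals;
# the optimizer appends the sqrt(w_reg) * k restraint residuals itself) and
# optionally `terms` (per-compound L_m) and `predictions`. The backend must
# be deterministic for a fixed seed.

#' Optimizer configuration
#'
#' @param step_tol Termination threshold on the Euclidean norm of the
#'   accepted k-step (default 0.01, mathematical units).
#' @param obj_tol Termination threshold on the unitless objective change
#'   between accepted iterations (default 1.0).
#' @param max_iter Maximum accepted iterations (default 100).
#' @param fd_step Central finite-difference step in k (default 1e-3).
#' @param w_reg Regularization weight (default 0.1).
#' @param method `"gauss-newton"` (damped, default) or
#'   `"gradient-descent"`.
#' @return List of class `lj_opt_config`.
#' @export
opt_config <- function(step_tol = 0.01, obj_tol = 1.0, max_iter = 100L,
                       fd_step = 1e-3, w_reg = DEFAULT_W_REG,
                       method = c("gauss-newton", "gradient-descent")) {
  if (step_tol <= 0 || obj_tol <= 0 || fd_step <= 0)
    stop_config("tolerances must be positive")
  structure(list(step_tol = step_tol, obj_tol = obj_tol,
                 max_iter = as.integer(max_iter), fd_step = fd_step,
                 w_reg = w_reg, method = match.arg(method)),
            class = "lj_opt_config")
}

.residual_vector <- function(fn, params, k, w_reg, seed) {
  out <- fn(params, seed = seed)
  if (is.null(out$residuals))
    stop_contract("objective backend must return a 'residuals' vector")
  r <- c(out$residuals, sqrt(w_reg) * k)
  # non-finite trial points are reported as infinitely bad and rejected by
  # the line search; an abort happens only if the *accepted* state is bad
  list(r = r, out = out, finite = all(is.finite(r)))
}

#' Optimize LJ parameters against an objective backend
#'
#' Minimizes `L(k) = sum(residuals^2) + w_reg |k|^2` in mathematical space,
#' starting from `start` (whose reference values define k = 0 and hence the
#' restraint center).
#'
#' @param start An `lj_paramset` starting point.
#' @param objective_fn Backend function (see module notes): called as
#'   `objective_fn(params, seed)`.
#' @param cfg An [opt_config()].
#' @param seed Seed forwarded to the backend (stochastic backends only).
#' @return An object of class `lj_opt_result`: `params` (final
#'   `lj_paramset`), `objective` (final `lj_objective`), `trace` (data
#'   frame `iter`, `L`, `step_norm`), `k`, `termination`
#'   (`"step-tol"`, `"objective-tol"` or `"max-iter"`), `n_eval`, `seed`.
#' @export
optimize_params <- function(start, objective_fn, cfg = opt_config(), seed = 0) {
  stopifnot(inherits(start, "lj_paramset"))
  k <- to_math(start)
  n <- length(k)
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  eval_r <- function(kv) {
    key <- paste(sprintf("%.12g", kv), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    rr <- .residual_vector(objective_fn, from_math(kv, start), kv,
                           cfg$w_reg, seed)
    n_eval <<- n_eval + 1L
    cache[[key]] <- rr
    rr
  }
  cur <- eval_r(k)
  if (!cur$finite)
    ljt_stop(sprintf("non-finite objective at the starting point k = (%s)",
                     paste(signif(k, 4), collapse = ", ")),
             "ljtyping_objective_error")
  L <- sum(cur$r^2)
  trace <- list(data.frame(iter = 0L, L = L, step_norm = NA_real_))
  lambda <- 1e-3
  termination <- "max-iter"
  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    if (cfg$method == "gauss-newton") {
      J <- .fd_jacobian(eval_r, k, length(cur$r), cfg$fd_step)
      g <- crossprod(J, cur$r)           # 0.5 * gradient
      JtJ <- crossprod(J)
      # Marquardt scaling: damp relative to the curvature of each direction,
      # which crawls ill-conditioned valleys far better than lambda * I
      dscale <- diag(pmax(diag(JtJ), 1e-10), n)
      moved <- FALSE
      for (inner in 1:25) {
        delta <- tryCatch(
          as.numeric(solve(JtJ + lambda * dscale, -g)),
          error = function(e) rep(0, n))
        if (!any(delta != 0)) { lambda <- lambda * 10; next }
        cand <- eval_r(k + delta)
        Lc <- sum(cand$r^2)
        if (is.finite(Lc) && Lc < L) {
          step_norm <- sqrt(sum(delta^2))
          dL <- L - Lc
          k <- k + delta; cur <- cand; L <- Lc
          lambda <- max(lambda / 10, 1e-12)
          moved <- TRUE
          trace[[length(trace) + 1L]] <-
            data.frame(iter = iter, L = L, step_norm = step_norm)
          if (step_norm < cfg$step_tol) termination <- "step-tol"
          else if (dL < cfg$obj_tol) termination <- "objective-tol"
          break
        }
        lambda <- lambda * 10
      }
      if (!moved) { termination <- "objective-tol"; break }
      if (termination != "max-iter") break
    } else {
      grad <- .fd_gradient(function(kv) sum(eval_r(kv)$r^2), k, cfg$fd_step)
      alpha <- 1
      moved <- FALSE
      for (inner in 1:40) {
        delta <- -alpha * grad
        cand <- eval_r(k + delta)
        Lc <- sum(cand$r^2)
        if (is.finite(Lc) && Lc < L) {
          step_norm <- sqrt(sum(delta^2)); dL <- L - Lc
          k <- k + delta; cur <- cand; L <- Lc
          moved <- TRUE
          trace[[length(trace) + 1L]] <-
            data.frame(iter = iter, L = L, step_norm = step_norm)
          if (step_norm < cfg$step_tol) termination <- "step-tol"
          else if (dL < cfg$obj_tol) termination <- "objective-tol"
          break
        }
        alpha <- alpha / 2
      }
      if (!moved) { termination <- "objective-tol"; break }
      if (termination != "max-iter") break
    }
  }
  final_params <- from_math(k, start)
  # project onto the physical domain: the well depth is non-negative by
  # definition, and backends treat negative trial values as zero, so the
  # projection leaves the objective unchanged
  final_params$types$eps <- pmax(final_params$types$eps, 0)
  terms <- if (!is.null(cur$out$terms)) cur$out$terms else
    sum(cur$out$residuals^2)
  structure(list(params = final_params,
                 objective = total_objective(terms, k, cfg$w_reg),
                 trace = do.call(rbind, trace), k = k,
                 termination = termination, n_eval = n_eval, seed = seed,
                 cfg = cfg),
            class = "lj_opt_result")
}

.fd_jacobian <- function(eval_r, k, m, h) {
  n <- length(k)
  J <- matrix(0, m, n)
  for (j in seq_len(n)) {
    kp <- k; kp[j] <- kp[j] + h
    km <- k; km[j] <- km[j] - h
    J[, j] <- (eval_r(kp)$r - eval_r(km)$r) / (2 * h)
  }
  J
}

.fd_gradient <- function(f, k, h) {
  vapply(seq_along(k), function(j) {
    kp <- k; kp[j] <- kp[j] + h
    km <- k; km[j] <- km[j] - h
    (f(kp) - f(km)) / (2 * h)
  }, numeric(1))
}

#' @export
print.lj_opt_result <- function(x, ...) {
  cat(sprintf("<lj_opt_result> L = %.4g after %d accepted steps (%s), %d evaluations\n",
              x$objective$total, max(x$trace$iter), x$termination, x$n_eval))
  invisible(x)
}

#' Triplicate multi-start optimization
#'
#' Runs `optimize_params` once per replicate seed (three by default,
#' matching the original protocol), optionally jittering the start in
#' k-space, and flags the replicate with the lowest final training
#' objective as the selected one. All replicates are retained and the
#' replicate range of the final objective is reported.
#'
#' @param start Starting `lj_paramset`.
#' @param objective_fn Objective backend.
#' @param cfg An [opt_config()].
#' @param seeds Integer vector of replicate seeds (default `1:3`).
#' @param jitter Standard deviation of the Gaussian start jitter in k-space
#'   (default 0: identical starts, so a deterministic backend yields
#'   identical replicates).
#' @return List of class `lj_multistart`: `replicates` (list of
#'   `lj_opt_result`), `best` (the selected result), `best_index`,
#'   `objective_range` (max - min of final totals).
#' @export
multi_start <- function(start, objective_fn, cfg = opt_config(),
                        seeds = 1:3, jitter = 0) {
  if (!length(seeds)) stop_config("need at least one replicate seed")
  reps <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    s0 <- start
    if (jitter > 0) {
      old <- .save_rng(); set.seed(as.integer(seeds[i]))
      k <- to_math(start) + stats::rnorm(length(to_math(start)), 0, jitter)
      .restore_rng(old)
      s0 <- from_math(k, start)
    }
    reps[[i]] <- optimize_params(s0, objective_fn, cfg, seed = seeds[i])
  }
  finals <- vapply(reps, function(r) r$objective$total, numeric(1))
  best <- which.min(finals)
  structure(list(replicates = reps, best = reps[[best]], best_index = best,
                 objective_range = max(finals) - min(finals), seeds = seeds),
            class = "lj_multistart")
}

#' Embed a coarse model's parameters into a refining model
#'
#' Every fine type inherits the parameter values of the coarse type it maps
#' to under the refinement relation. The returned set's reference values are
#' the embedded values themselves, so a subsequent optimization restrains to
#' this restart point (matching the reoptimization-from-alternative-start
#' protocol).
#'
#' @param coarse_params `lj_paramset` of the coarse model.
#' @param fine_model The refining `lj_typing_model` (or name).
#' @param mapping Optional fine-type -> coarse-type map (from
#'   [refinement_relation()]); computed if omitted.
#' @return `lj_paramset` for `fine_model`.
#' @export
embed_params <- function(coarse_params, fine_model, mapping = NULL) {
  if (is.character(fine_model)) fine_model <- typing_model(fine_model)
  if (is.null(mapping)) {
    rel <- refinement_relation(coarse_params$model_name, fine_model)
    if (!rel$refines)
      stop_contract(sprintf("%s does not refine %s", fine_model$name,
                            coarse_params$model_name))
    mapping <- rel$mapping
  }
  ce <- stats::setNames(coarse_params$types$eps, coarse_params$types$type_id)
  cr <- stats::setNames(coarse_params$types$rmin_half,
                        coarse_params$types$type_id)
  tids <- fine_model$types
  if (!all(tids %in% names(mapping)))
    stop_contract("refinement mapping does not cover all fine types")
  paramset(fine_model,
           eps = stats::setNames(ce[mapping[tids]], tids),
           rmin_half = stats::setNames(cr[mapping[tids]], tids))
}

#' Superspace consistency check
#'
#' A model with more finely divided types, fully optimized, can never have
#' a worse training objective than a model it refines, because the fine
#' parameter space is a superspace of the coarse one. A violation
#' diagnoses local-minimum trapping: the verdict is "under-optimized" and
#' the coarse optimum embedded into the fine model is returned as a restart
#' point.
#'
#' @param fine,coarse `lj_opt_result` objects for the two models.
#' @param relation Result of [refinement_relation()] for (coarse, fine);
#'   must hold.
#' @return List with `verdict` (`"under-optimized"` or `"pass"`),
#'   `fine_objective`, `coarse_objective`, and `restart` (embedded
#'   `lj_paramset`, only when under-optimized).
#' @export
consistency_check <- function(fine, coarse, relation) {
  if (is.null(relation$refines) || !relation$refines)
    stop_contract("consistency_check requires a valid refinement relation")
  fo <- fine$objective$total
  co <- coarse$objective$total
  if (fo > co) {
    list(verdict = "under-optimized", fine_objective = fo,
         coarse_objective = co,
         restart = embed_params(coarse$params, fine$params$model_name,
                                relation$mapping))
  } else {
    list(verdict = "pass", fine_objective = fo, coarse_objective = co,
         restart = NULL)
  }
}

#' Greedy type-splitting search
#'
#' Starting from a base typing model, repeatedly fits every candidate
#' refinement (warm-started by embedding the current optimum), evaluates a
#' held-out test objective, and locks in the split with the largest test
#' improvement; stops when no candidate improves by more than `margin`.
#' Greedy by construction: splits that help only jointly are never found.
#'
#' @param base Base `lj_typing_model` (or name).
#' @param candidates Character vector of candidate model names; each round
#'   keeps only those refining the current model.
#' @param objective_factory `function(model)` returning a training
#'   objective backend for that model.
#' @param test_objective `function(model, params)` returning the scalar
#'   held-out objective.
#' @param cfg An [opt_config()].
#' @param margin Minimum test-objective improvement to accept a split
#'   (default 0: any improvement); raise it to guard against noise in the
#'   held-out objective.
#' @param single_split Restrict each round to candidates that split exactly
#'   one element of the current model (default TRUE, the classical greedy
#'   neighborhood); names outside the element-count grammar are exempt.
#' @param start_params Optional starting `lj_paramset` for the base model.
#' @return List of class `lj_greedy_result`: `final_model` (name),
#'   `final_params`, `accepted` (character vector of accepted model names
#'   in order), `history` (data frame of candidate evaluations per round).
#' @export
greedy_split_search <- function(base, candidates, objective_factory,
                                test_objective, cfg = opt_config(),
                                margin = 0, single_split = TRUE,
                                start_params = NULL) {
  if (is.character(base)) base <- typing_model(base)
  cur_model <- base
  cur_start <- if (is.null(start_params)) paramset(base) else start_params
  fit <- optimize_params(cur_start, objective_factory(cur_model), cfg)
  cur_params <- fit$params
  cur_test <- test_objective(cur_model, cur_params)
  accepted <- character(0)
  history <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    best_gain <- margin; best <- NULL
    for (cand in setdiff(candidates, c(cur_model$name, accepted))) {
      cm <- typing_model(cand)
      if (single_split && !.is_single_split(cur_model$name, cand)) next
      rel <- refinement_relation(cur_model, cm)
      if (!rel$refines) next
      start_c <- embed_params(cur_params, cm, rel$mapping)
      fit_c <- optimize_params(start_c, objective_factory(cm), cfg)
      test_c <- test_objective(cm, fit_c$params)
      gain <- cur_test - test_c
      history[[length(history) + 1L]] <-
        data.frame(round = round, candidate = cand, test_objective = test_c,
                   gain = gain, stringsAsFactors = FALSE)
      if (gain > best_gain) {
        best_gain <- gain
        best <- list(model = cm, params = fit_c$params, test = test_c)
      }
    }
    if (is.null(best)) break
    cur_model <- best$model
    cur_params <- best$params
    cur_test <- best$test
    accepted <- c(accepted, cur_model$name)
  }
  structure(list(final_model = cur_model$name, final_params = cur_params,
                 final_test_objective = cur_test, accepted = accepted,
                 history = if (length(history)) do.call(rbind, history)
                           else NULL),
            class = "lj_greedy_result")
}

# Parse an element-count model name into per-element split levels; NULL for
# names outside the grammar (e.g. SmirFF).
.model_levels <- function(name) {
  toks <- regmatches(name, gregexpr("[HCON][0-9]*", name))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != name) return(NULL)
  lv <- stats::setNames(rep(1L, 4L), c("H", "C", "O", "N"))
  for (tok in toks)
    lv[[substr(tok, 1L, 1L)]] <-
      if (nchar(tok) > 1L) as.integer(substr(tok, 2L, nchar(tok))) else 1L
  lv
}

.is_single_split <- function(coarse_name, fine_name) {
  lc <- .model_levels(coarse_name); lf <- .model_levels(fine_name)
  if (is.null(lc) || is.null(lf)) return(TRUE)   # grammar-exempt
  sum(lf != lc) == 1L && all(lf >= lc)
}

# -- study-backed objective builders -------------------------------------

#' Training objective backend for a synthetic study
#'
#' Builds a deterministic residual backend over the study's oracle: for
#' each training compound, the scaled density and HOV residuals against the
#' study's (noisy) reference table.
#'
#' @param study An `lj_study`.
#' @param model Typing model to fit (or name).
#' @param ids Training compound ids (default: all).
#' @param denominators Property denominators.
#' @return A backend `function(params, seed = 0)` suitable for
#'   [optimize_params()].
#' @export
study_objective <- function(study, model, ids = NULL,
                            denominators = DEFAULT_DENOMINATORS) {
  if (is.character(model)) model <- typing_model(model)
  if (is.null(ids)) ids <- study$library$compounds$compound_id
  design <- oracle_design(study$library, model)
  keep <- match(ids, design$compound_id)
  if (anyNA(keep)) stop_input("unknown compound ids in training set")
  refs <- study$references[match(ids, study$references$compound_id), ]
  dd <- denominators[["density"]]; dh <- denominators[["hov"]]
  sub <- list(model = design$model,
              counts = design$counts[keep, , drop = FALSE],
              molar_mass = design$molar_mass[keep],
              polar_h = design$polar_h[keep],
              acceptors = design$acceptors[keep],
              compound_id = design$compound_id[keep])
  constants <- study$constants
  function(params, seed = 0) {
    pred <- oracle_predict_design(sub, params, constants)
    res_d <- (pred$density - refs$density) / dd
    res_h <- (pred$hov - refs$hov) / dh
    terms <- res_d^2 + res_h^2
    list(residuals = c(res_d, res_h), terms = terms, predictions = pred)
  }
}

#' Held-out (test) data objective for a synthetic study
#'
#' Sum of scaled squared density and HOV errors over the test compounds; no
#' restraint term (the restraint belongs to training).
#'
#' @inheritParams study_objective
#' @return `function(model, params)` returning the scalar test objective.
#' @export
study_test_objective <- function(study, ids,
                                 denominators = DEFAULT_DENOMINATORS) {
  force(ids)
  function(model, params) {
    fn <- study_objective(study, model, ids, denominators)
    sum(fn(params)$residuals^2)
  }
}
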