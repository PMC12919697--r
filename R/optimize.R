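# Worst-case robust spot-weight optimization: sparse per-scenario dose
# influence, a composite one-sided quadratic + EUD objective, projected
# gradient descent with monotone line search, and CTV-median prescription
# normalization.

#' Setup/range uncertainty scenario
#'
#' @param shift_mm axis-aligned setup shift (mm 3-vector, at most one
#'   nonzero component in the default scenario set).
#' @param range_error fractional range (RSP) scaling error.
#' @return An object of class `scenario`.
#' @export
scenario <- function(shift_mm = c(0, 0, 0), range_error = 0) {
  structure(list(shift_mm = as.numeric(shift_mm),
                 range_error = range_error), class = "scenario")
}

#' Generate the worst-case scenario set
#'
#' Cartesian product of the seven axis-aligned setup shifts (zero and +/-
#' `setup_mm` along each of left-right, anterior-posterior and
#' cranial-caudal) with the three range errors (0 and +/- `range_frac`):
#' 21 distinct scenarios with the defaults, the nominal scenario first.
#' Degenerate settings deduplicate (0/0 yields the nominal scenario only).
#'
#' @param setup_mm setup uncertainty magnitude (mm), default 2.0.
#' @param range_frac fractional range uncertainty, default 0.035.
#' @return list of [scenario()] objects.
#' @export
generate_scenarios <- function(setup_mm = 2.0, range_frac = 0.035) {
  stopifnot(setup_mm >= 0, range_frac >= 0)
  shifts <- unique(rbind(c(0, 0, 0),
                         setup_mm * diag(3), -setup_mm * diag(3)))
  rerr <- unique(c(0, range_frac, -range_frac))
  out <- list()
  for (e in rerr) for (i in seq_len(nrow(shifts)))
    out[[length(out) + 1]] <- scenario(shifts[i, ], e)
  # nominal first (it already is: e = 0, zero shift is row 1)
  out
}

#' Default plan objectives
#'
#' Composite penalty with both nominal and robust (worst-case) parts:
#' one-sided quadratic CTV minimum/maximum dose terms at the prescription
#' level evaluated on the nominal scenario, worst-case CTV terms at the
#' clinical planning-goal levels (95\% coverage / 107\% homogeneity by
#' default) evaluated over all scenarios, and per-OAR maximum-dose and
#' EUD-based worst-case terms. Nominal terms enforce the planning goals the
#' plan is reported against; robust terms keep scenario coverage and
#' hot spots within the same goals under setup/range errors. The weights
#' and bounds are planning defaults tuned on the package's synthetic
#' phantom and are reported in the plan summary; the EUD exponent defaults
#' to a = 12 (serial-organ behavior).
#'
#' @param prescription_gy total prescription, Gy(RBE), default 74.
#' @param fractions number of fractions (bookkeeping only), default 37.
#' @param ctv_max_gy nominal upper CTV bound for the homogeneity term.
#' @param ctv_min_weight,ctv_max_weight nominal CTV term weights.
#' @param robust_min_frac,robust_max_frac worst-case CTV bounds as a
#'   fraction of the prescription (defaults 0.95 and 1.07, the planning
#'   goals).
#' @param robust_min_weight,robust_max_weight worst-case CTV term weights.
#' @param oar_max_gy,oar_max_weight OAR maximum-dose bound and weight
#'   (worst case).
#' @param oar_eud_gy,oar_eud_weight,oar_eud_a OAR EUD bound, weight and
#'   exponent (worst case).
#' @return list of class `plan_objectives`.
#' @export
default_objectives <- function(prescription_gy = 74, fractions = 37,
                               ctv_max_gy = 75, ctv_min_weight = 1.5,
                               ctv_max_weight = 2.5,
                               robust_min_frac = 0.95,
                               robust_max_frac = 1.07,
                               robust_min_weight = 1,
                               robust_max_weight = 0.5,
                               oar_max_gy = 30, oar_max_weight = 0.02,
                               oar_eud_gy = 24, oar_eud_weight = 0.02,
                               oar_eud_a = 12) {
  stopifnot(prescription_gy > 0,
            all(c(ctv_min_weight, ctv_max_weight, robust_min_weight,
                  robust_max_weight, oar_max_weight,
                  oar_eud_weight) >= 0))
  structure(list(prescription_gy = prescription_gy, fractions = fractions,
                 ctv_max_gy = ctv_max_gy, ctv_min_weight = ctv_min_weight,
                 ctv_max_weight = ctv_max_weight,
                 robust_min_frac = robust_min_frac,
                 robust_max_frac = robust_max_frac,
                 robust_min_weight = robust_min_weight,
                 robust_max_weight = robust_max_weight,
                 oar_max_gy = oar_max_gy,
                 oar_max_weight = oar_max_weight, oar_eud_gy = oar_eud_gy,
                 oar_eud_weight = oar_eud_weight, oar_eud_a = oar_eud_a),
            class = "plan_objectives")
}

# Materialize objective terms against the optimization voxel set.
# struct_idx: named list mapping structure name -> indices into the
# optimization voxel vector; roles: named role per structure.
# Each term carries a `scope`: "worst" terms are evaluated worst-case over
# the scenario set; "nominal" terms only on the nominal scenario.
build_objective_terms <- function(objectives, struct_idx, roles) {
  p <- objectives$prescription_gy
  terms <- list()
  for (nm in names(struct_idx)) {
    idx <- struct_idx[[nm]]
    if (roles[[nm]] == "target") {
      terms <- c(terms, list(
        list(idx = idx, type = "min_dose", bound = p,
             weight = objectives$ctv_min_weight, scope = "nominal"),
        list(idx = idx, type = "max_dose", bound = objectives$ctv_max_gy,
             weight = objectives$ctv_max_weight, scope = "nominal"),
        list(idx = idx, type = "min_dose",
             bound = objectives$robust_min_frac * p,
             weight = objectives$robust_min_weight, scope = "worst"),
        list(idx = idx, type = "max_dose",
             bound = objectives$robust_max_frac * p,
             weight = objectives$robust_max_weight, scope = "worst")))
    } else if (roles[[nm]] == "oar") {
      terms <- c(terms, list(
        list(idx = idx, type = "max_dose", bound = objectives$oar_max_gy,
             weight = objectives$oar_max_weight, scope = "worst"),
        list(idx = idx, type = "eud_max", bound = objectives$oar_eud_gy,
             weight = objectives$oar_eud_weight, a = objectives$oar_eud_a,
             scope = "worst")))
    }
  }
  terms
}

# One objective term on one dose vector; value and d(value)/d(dose[idx]).
term_penalty <- function(d, tm, grad = TRUE) {
  dv <- d[tm$idx]
  n <- length(dv)
  if (tm$type == "min_dose") {
    r <- pmax(tm$bound - dv, 0)
    list(value = tm$weight * sum(r^2) / n,
         grad = if (grad) -2 * tm$weight * r / n)
  } else if (tm$type == "max_dose") {
    r <- pmax(dv - tm$bound, 0)
    list(value = tm$weight * sum(r^2) / n,
         grad = if (grad) 2 * tm$weight * r / n)
  } else if (tm$type == "eud_max") {
    a <- tm$a
    m <- mean(pmax(dv, 0)^a)
    r <- max(m^(1 / a) - tm$bound, 0)
    g <- if (grad) {
      if (r > 0) 2 * tm$weight * r * (pmax(dv, 0)^(a - 1) / n) *
        m^(1 / a - 1)
      else numeric(n)
    }
    list(value = tm$weight * r^2, grad = g)
  } else stop("unknown objective term type")
}

# Composite penalty of one dose vector; returns value and d(value)/d(dose).
composite_penalty <- function(d, terms, grad = TRUE) {
  val <- 0
  g <- if (grad) numeric(length(d)) else NULL
  for (tm in terms) {
    if (tm$weight == 0 || !length(tm$idx)) next
    tp <- term_penalty(d, tm, grad)
    val <- val + tp$value
    if (grad) g[tm$idx] <- g[tm$idx] + tp$grad
  }
  list(value = val, grad = g)
}

#' Worst-case objective over scenarios
#'
#' Two flavors of the worst case, both deterministic for fixed inputs:
#'
#' * `mode = "composite"`: the maximum over scenarios of the composite
#'   penalty (the sum of all terms) evaluated on that scenario's dose, with
#'   the (sub)gradient taken from the argmax scenario.
#' * `mode = "per_term"`: each objective term takes the maximum over
#'   scenarios independently (the TPS-style objective-wise worst case), so
#'   the coverage term tracks its coldest scenario while the homogeneity
#'   and OAR terms track their own hottest ones; the gradient sums each
#'   term's argmax-scenario contribution, and terms carrying
#'   `scope = "nominal"` are evaluated on the nominal (first) scenario
#'   only. This is the planning default in [make_plan()] because the
#'   composite maximum leaves hot spots in non-argmax scenarios
#'   unpenalized.
#'
#' With a single scenario both modes reduce to the plain composite penalty.
#'
#' @param w spot weight vector (>= 0).
#' @param A_list list of per-scenario sparse dose-influence operators
#'   (optimization voxels x spots).
#' @param terms objective terms from [build_objective_terms()].
#' @param mode `"composite"` or `"per_term"`.
#' @return list with `value`, `grad` (with respect to w), `argmax`
#'   (scenario attaining the composite worst case) and `scenario_values`.
#' @export
worst_case_objective <- function(w, A_list, terms,
                                 mode = c("composite", "per_term")) {
  mode <- match.arg(mode)
  stopifnot(length(A_list) >= 1)
  doses <- vector("list", length(A_list))
  tvals <- matrix(0, length(A_list), length(terms))
  for (s in seq_along(A_list)) {
    d <- as.numeric(A_list[[s]] %*% w)
    if (any(!is.finite(d))) stop("non-finite dose in scenario ", s)
    doses[[s]] <- d
    tvals[s, ] <- vapply(terms, function(tm)
      term_penalty(d, tm, grad = FALSE)$value, numeric(1))
  }
  vals <- rowSums(tvals)
  s_star <- which.max(vals)
  if (mode == "composite") {
    cp <- composite_penalty(doses[[s_star]], terms, grad = TRUE)
    grad <- as.numeric(Matrix::crossprod(A_list[[s_star]], cp$grad))
    value <- vals[s_star]
  } else {
    value <- 0
    acc <- vector("list", length(A_list))
    for (t in seq_along(terms)) {
      allowed <- if (identical(terms[[t]]$scope, "nominal")) 1L
                 else seq_along(A_list)
      st <- allowed[which.max(tvals[allowed, t])]
      value <- value + tvals[st, t]
      tp <- term_penalty(doses[[st]], terms[[t]], grad = TRUE)
      if (is.null(acc[[st]])) acc[[st]] <- numeric(length(doses[[st]]))
      acc[[st]][terms[[t]]$idx] <- acc[[st]][terms[[t]]$idx] + tp$grad
    }
    grad <- numeric(length(w))
    for (s in seq_along(A_list)) {
      if (is.null(acc[[s]])) next
      grad <- grad + as.numeric(Matrix::crossprod(A_list[[s]], acc[[s]]))
    }
  }
  list(value = value, grad = grad, argmax = s_star,
       scenario_values = vals, term_values = tvals, mode = mode)
}

# Smoothed worst case: log-sum-exp softening of the max over scenarios with
# relative temperature tau_frac (exact max as tau_frac -> 0). For
# mode = "per_term" each term is softened independently. Returns the
# smoothed value and its gradient plus the exact worst-case value.
smoothed_objective <- function(w, A_list, terms, mode, tau_frac) {
  ns <- length(A_list)
  doses <- lapply(A_list, function(A) as.numeric(A %*% w))
  tvals <- vapply(doses, function(d) vapply(terms, function(tm)
    term_penalty(d, tm, grad = FALSE)$value, numeric(1)),
    numeric(length(terms)))
  tvals <- matrix(tvals, nrow = length(terms))  # terms x scenarios
  svals <- colSums(tvals)
  exact <- if (mode == "composite") max(svals)
           else sum(vapply(seq_along(terms), function(t) {
             allowed <- if (identical(terms[[t]]$scope, "nominal")) 1L
                        else seq_len(ns)
             max(tvals[t, allowed])
           }, numeric(1)))
  lse <- function(v, tau) {
    m <- max(v)
    if (tau <= 0 || ns == 1) return(list(f = m, w = as.numeric(v == m)))
    e <- exp((v - m) / tau)
    list(f = m + tau * log(mean(e)), w = e / sum(e))
  }
  acc <- vector("list", ns)  # per-scenario dose-space gradient accumulators
  if (mode == "composite") {
    sm <- lse(svals, tau_frac * max(abs(svals)))
    f <- sm$f
    for (s in which(sm$w > 1e-4)) {
      cp <- composite_penalty(doses[[s]], terms, grad = TRUE)
      acc[[s]] <- sm$w[s] * cp$grad
    }
  } else {
    f <- 0
    for (t in seq_along(terms)) {
      allowed <- if (identical(terms[[t]]$scope, "nominal")) 1L
                 else seq_len(ns)
      sm <- lse(tvals[t, allowed],
                tau_frac * max(abs(tvals[t, allowed])))
      f <- f + sm$f
      for (q in which(sm$w > 1e-4)) {
        s <- allowed[q]
        tp <- term_penalty(doses[[s]], terms[[t]], grad = TRUE)
        if (is.null(acc[[s]])) acc[[s]] <- numeric(length(doses[[s]]))
        acc[[s]][terms[[t]]$idx] <- acc[[s]][terms[[t]]$idx] +
          sm$w[q] * tp$grad
      }
    }
  }
  grad <- numeric(length(w))
  for (s in seq_len(ns)) {
    if (is.null(acc[[s]])) next
    grad <- grad + as.numeric(Matrix::crossprod(A_list[[s]], acc[[s]]))
  }
  list(value = f, grad = grad, exact = exact)
}

#' Optimize spot weights (robust, bound-constrained)
#'
#' Minimizes the worst-case objective over the non-negative orthant with
#' bound-constrained quasi-Newton (L-BFGS-B) on a log-sum-exp smoothed
#' worst case, annealed toward the exact maximum over a fixed temperature
#' continuation schedule (the smoothed objective is differentiable, which
#' the kinked exact maximum is not). A stage's result is accepted only when
#' the exact worst-case objective decreases, so the reported objective
#' history is non-increasing across accepted iterates; starting at an
#' optimum terminates immediately with unchanged weights. Stops on the
#' iteration cap, on relative improvement below `tol`, or at a fixed point.
#' Fully deterministic (no randomness is involved; optional stochastic
#' restarts would be the only consumer of a seed and are off by default).
#'
#' @param w0 initial non-negative weights.
#' @param A_list per-scenario influence operators.
#' @param terms objective terms.
#' @param max_iter total quasi-Newton iteration budget (split across the
#'   continuation stages).
#' @param tol relative-improvement stopping tolerance on the exact
#'   worst case.
#' @param mode worst-case flavor passed to [worst_case_objective()].
#' @param verbose print per-stage objective values.
#' @return list with `weights`, `objective` (exact worst-case history across
#'   accepted stages), `iterations`, `converged`.
#' @export
optimize_weights <- function(w0, A_list, terms, max_iter = 100,
                             tol = 1e-5, mode = c("composite", "per_term"),
                             verbose = FALSE) {
  mode <- match.arg(mode)
  if (!length(w0)) stop("no spots to optimize")
  if (all(vapply(A_list, function(A) length(A@x) == 0 || max(abs(A@x)) == 0,
                 logical(1))))
    stop("all-zero dose influence: no spot reaches the target")
  w <- pmax(as.numeric(w0), 0)
  exact0 <- worst_case_objective(w, A_list, terms, mode)$value
  hist <- exact0
  taus <- if (length(A_list) == 1) 0 else c(0.1, 0.02, 0.005)
  per_stage <- max(10L, ceiling(max_iter / length(taus)))
  total_it <- 0L
  converged <- FALSE
  for (tau in taus) {
    if (hist[length(hist)] <= 0) { converged <- TRUE; break }
    cache <- new.env(parent = emptyenv())
    eval_pt <- function(x) {
      if (!is.null(cache$x) && identical(x, cache$x)) return(cache$res)
      cache$x <- x
      cache$res <- smoothed_objective(pmax(x, 0), A_list, terms, mode, tau)
      cache$res
    }
    r <- stats::optim(w,
                      fn = function(x) eval_pt(x)$value,
                      gr = function(x) eval_pt(x)$grad,
                      method = "L-BFGS-B", lower = 0,
                      control = list(maxit = per_stage, factr = 1e6))
    total_it <- total_it + r$counts[1]
    exact_new <- worst_case_objective(pmax(r$par, 0), A_list, terms,
                                      mode)$value
    if (verbose)
      message(sprintf("stage tau=%.3f exact %.6g -> %.6g", tau,
                      hist[length(hist)], exact_new))
    if (exact_new < hist[length(hist)]) {
      rel <- (hist[length(hist)] - exact_new) /
        max(hist[length(hist)], 1e-12)
      w <- pmax(r$par, 0)
      hist <- c(hist, exact_new)
      if (rel < tol) { converged <- TRUE; break }
    } else {
      converged <- TRUE  # no exact improvement: fixed point reached
      break
    }
  }
  if (length(hist) > 1 && !converged) converged <- TRUE
  list(weights = w, objective = hist, iterations = as.integer(total_it),
       converged = converged)
}

#' Normalize a plan so the CTV median equals the prescription
#'
#' Returns the scale factor s such that the median (interpolated 50th
#' percentile) of s x dose over the CTV voxels equals the prescription;
#' the factor is applied uniformly to all beam weights.
#'
#' @param dose a `dose_grid` (or numeric array).
#' @param ctv an `rt_structure` (non-empty mask).
#' @param prescription_gy prescription dose.
#' @return scale factor s.
#' @export
normalize_to_median <- function(dose, ctv, prescription_gy = 74) {
  vals <- if (inherits(dose, "dose_grid")) dose$values else dose
  dv <- vals[ctv$mask]
  if (!length(dv)) stop("empty CTV mask")
  med <- as.numeric(stats::quantile(dv, 0.5, type = 7))
  if (med <= 0) stop("zero median CTV dose; cannot normalize")
  prescription_gy / med
}
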