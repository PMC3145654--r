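#' Convert raw ellipticity to mean residue ellipticity
#'
#' `[theta] = millidegrees * MW / (pathlength_mm * conc_mg_ml * n_residues)`
#' in deg cm^2/dmol.  The defaults are the calmodulin CD conditions:
#' MW 16706 Da, 1 mm path, 0.4 mg/ml, 148 residues.  Exactly invertible via
#' [mre_to_mdeg()].
#'
#' @param mdeg signal in millidegrees.
#' @param molecular_weight protein molecular weight (Da).
#' @param pathlength_mm cuvette path length (mm).
#' @param conc_mg_ml protein concentration (mg/ml).
#' @param n_residues number of residues.
#' @return mean residue ellipticity, deg cm^2/dmol.
#' @export
mdeg_to_mre <- function(mdeg, molecular_weight = 16706, pathlength_mm = 1,
                        conc_mg_ml = 0.4, n_residues = 148) {
  denom <- pathlength_mm * conc_mg_ml * n_residues
  if (denom <= 0) stop("pathlength, concentration and residue count must be > 0")
  mdeg * molecular_weight / denom
}

#' @rdname mdeg_to_mre
#' @param mre mean residue ellipticity.
#' @export
mre_to_mdeg <- function(mre, molecular_weight = 16706, pathlength_mm = 1,
                        conc_mg_ml = 0.4, n_residues = 148) {
  denom <- pathlength_mm * conc_mg_ml * n_residues
  if (denom <= 0) stop("pathlength, concentration and residue count must be > 0")
  mre * denom / molecular_weight
}

#' Modified Gibbs-Helmholtz unfolding free energy
#'
#' \eqn{\Delta G(T) = \Delta H_m (1 - T/T_m) +
#' \Delta C_p [(T - T_m) - T \ln(T/T_m)]}, in kcal/mol; zero at the
#' transition midpoint and positive below it (unfolding unfavorable).
#'
#' @param T temperature, Kelvin.
#' @param Tm transition midpoint, Kelvin.
#' @param dHm van't Hoff enthalpy at Tm, kcal/mol.
#' @param dCp heat-capacity change, kcal/(K mol) (default 0).
#' @return Delta G in kcal/mol.
#' @export
gibbs_helmholtz <- function(T, Tm, dHm, dCp = 0) {
  stopifnot(all(T > 0), Tm > 0)
  dHm * (1 - T / Tm) + dCp * ((T - Tm) - T * log(T / Tm))
}

# equilibrium constant for one unfolding transition
.unfold_K <- function(T, Tm, dHm, dCp = 0) {
  exp(-gibbs_helmholtz(T, Tm, dHm, dCp) / (.const$R_kcal * T))
}

#' Two-state unfolding signal
#'
#' \eqn{y(T) = f_N (I_N + S_N T) + f_U (I_U + S_U T)} with
#' \eqn{f_U = K/(1+K)}, \eqn{K = e^{-\Delta G/RT}}.  Baselines are linear
#' in temperature (Kelvin).
#'
#' @param T temperature, Kelvin.
#' @param Tm,dHm,dCp transition parameters (see [gibbs_helmholtz()]).
#' @param b_n,b_u length-2 numeric `(intercept, slope)` of the native and
#'   unfolded baselines.
#' @return the optical signal.
#' @export
two_state_signal <- function(T, Tm, dHm, dCp = 0, b_n, b_u) {
  K <- .unfold_K(T, Tm, dHm, dCp)
  f_u <- K / (1 + K)
  (1 - f_u) * (b_n[1] + b_n[2] * T) + f_u * (b_u[1] + b_u[2] * T)
}

#' Three-state unfolding signal
#'
#' Sequential scheme N <-> I <-> U with populations
#' \eqn{f_N = 1/(1 + K_1 + K_1 K_2)}, \eqn{f_I = K_1 f_N},
#' \eqn{f_U = K_1 K_2 f_N} and signal
#' \eqn{y = \sum_i f_i (I_i + S_i T)}.
#'
#' @param T temperature, Kelvin.
#' @param Tm1,dHm1,dCp1 first transition (N to I).
#' @param Tm2,dHm2,dCp2 second transition (I to U).
#' @param b_n,b_i,b_u `(intercept, slope)` baselines of the three states.
#' @return the optical signal.
#' @export
three_state_signal <- function(T, Tm1, dHm1, dCp1 = 0, Tm2, dHm2, dCp2 = 0,
                               b_n, b_i, b_u) {
  K1 <- .unfold_K(T, Tm1, dHm1, dCp1)
  K2 <- .unfold_K(T, Tm2, dHm2, dCp2)
  f_n <- 1 / (1 + K1 + K1 * K2)
  f_i <- K1 * f_n
  f_u <- K1 * K2 * f_n
  f_n * (b_n[1] + b_n[2] * T) + f_i * (b_i[1] + b_i[2] * T) +
    f_u * (b_u[1] + b_u[2] * T)
}

#' State populations of the unfolding models
#'
#' @inheritParams three_state_signal
#' @return data.frame with `T` and the state fractions (they sum to 1).
#' @export
unfold_populations <- function(T, Tm1, dHm1, dCp1 = 0, Tm2 = NULL,
                               dHm2 = NULL, dCp2 = 0) {
  K1 <- .unfold_K(T, Tm1, dHm1, dCp1)
  if (is.null(Tm2)) {
    f_u <- K1 / (1 + K1)
    return(data.frame(T = T, f_n = 1 - f_u, f_u = f_u))
  }
  K2 <- .unfold_K(T, Tm2, dHm2, dCp2)
  f_n <- 1 / (1 + K1 + K1 * K2)
  data.frame(T = T, f_n = f_n, f_i = K1 * f_n, f_u = K1 * K2 * f_n)
}

#' Construct a melting curve
#'
#' @param temperature strictly increasing temperatures.
#' @param signal optical signal (mean residue ellipticity at 222 nm).
#' @param unit `"C"` or `"K"`.
#' @param metadata free-form list (salt, crowder level, concentration, ...).
#' @return a `melting_curve` data.frame.
#' @export
melting_curve <- function(temperature, signal, unit = c("C", "K"),
                          metadata = list()) {
  unit <- match.arg(unit)
  if (any(diff(temperature) <= 0)) {
    stop("temperatures must be strictly increasing")
  }
  out <- data.frame(temperature = temperature, signal = signal)
  attr(out, "unit") <- unit
  attr(out, "metadata") <- metadata
  class(out) <- c("melting_curve", "data.frame")
  out
}

.curve_kelvin <- function(curve) {
  TT <- curve$temperature
  if (identical(attr(curve, "unit"), "C")) TT <- TT + 273.15
  TT
}

#' Generate a synthetic melting curve
#'
#' Model signal plus Gaussian noise; deterministic per seed.  The generating
#' parameters are kept in the `truth` attribute for recovery studies.
#'
#' @param params named list of model parameters (the arguments of
#'   [two_state_signal()] or [three_state_signal()], with temperatures in
#'   Kelvin).
#' @param temperatures sampling grid, degrees Celsius.
#' @param noise_sd Gaussian noise standard deviation, same units as the
#'   signal.
#' @param seed RNG seed.
#' @param model `"two_state"` or `"three_state"`.
#' @return a [melting_curve()] with attributes `truth` and `model`.
#' @export
generate_melting_curve <- function(params, temperatures = seq(5, 95, by = 1),
                                   noise_sd = 0, seed = 1,
                                   model = c("three_state", "two_state")) {
  model <- match.arg(model)
  TK <- temperatures + 273.15
  y <- if (model == "two_state") {
    do.call(two_state_signal, c(list(T = TK), params))
  } else {
    do.call(three_state_signal, c(list(T = TK), params))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(y), sd = noise_sd)
  }
  out <- melting_curve(temperatures, y, unit = "C",
                       metadata = list(synthetic = TRUE))
  attr(out, "truth") <- params
  attr(out, "model") <- model
  out
}

#' Read / write melting curves as 2-column delimited text
#'
#' `#` header lines carry the unit and metadata.
#'
#' @param file path.
#' @export
read_melting_curve <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  unit <- if (any(grepl("unit=K", hdr))) "K" else "C"
  dat <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE)
  melting_curve(dat[[1]], dat[[2]], unit = unit)
}

#' @rdname read_melting_curve
#' @param curve a `melting_curve`.
#' @export
write_melting_curve <- function(curve, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# melting curve, unit=%s", attr(curve, "unit")), con)
  utils::write.table(as.data.frame(curve), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

# ---------------------------------------------------------------------------
# fitting

.model_pars <- function(model) {
  if (model == "two_state") {
    c("Tm", "dHm", "dCp", "I_N", "S_N", "I_U", "S_U")
  } else {
    c("Tm1", "dHm1", "dCp1", "Tm2", "dHm2", "dCp2",
      "I_N", "S_N", "I_I", "S_I", "I_U", "S_U")
  }
}

.model_eval <- function(model, p, TK) {
  if (model == "two_state") {
    two_state_signal(TK, p["Tm"], p["dHm"], p["dCp"],
                     c(p["I_N"], p["S_N"]), c(p["I_U"], p["S_U"]))
  } else {
    three_state_signal(TK, p["Tm1"], p["dHm1"], p["dCp1"],
                       p["Tm2"], p["dHm2"], p["dCp2"],
                       c(p["I_N"], p["S_N"]), c(p["I_I"], p["S_I"]),
                       c(p["I_U"], p["S_U"]))
  }
}

# initial Tm guesses from extrema of the smoothed numerical derivative
.tm_guesses <- function(TK, y, k) {
  dy <- diff(y) / diff(TK)
  Tm <- (TK[-1] + TK[-length(TK)]) / 2
  if (length(dy) > 7) {
    dy <- stats::filter(dy, rep(1 / 5, 5), sides = 2)
    keep <- !is.na(dy)
    dy <- dy[keep]; Tm <- Tm[keep]
  }
  ord <- order(-abs(dy))
  picks <- numeric(0)
  for (i in ord) {
    if (all(abs(Tm[i] - picks) > 8)) picks <- c(picks, Tm[i])
    if (length(picks) == k) break
  }
  if (length(picks) < k) {
    picks <- c(picks, stats::quantile(TK, seq(0.3, 0.7,
                                              length.out = k - length(picks))))
  }
  sort(picks[seq_len(k)])
}

#' Fit a thermal-unfolding model to a melting curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) with multi-start
#' initialisation: midpoint temperatures are seeded from the extrema of the
#' numerical derivative of the curve and perturbed, baselines from straight
#' lines through the curve ends.  Any parameter can be fixed (the apo
#' three-state fits fix `dCp = 0`; the holo two-state fit lets all
#' parameters vary).
#'
#' @param curve a [melting_curve()].
#' @param model `"two_state"` or `"three_state"`.
#' @param fix named numeric vector of fixed parameters.  The shorthand
#'   `c(dCp = 0)` fixes both heat-capacity terms of the three-state model.
#' @param n_starts number of random restarts around the derivative-based
#'   initial guesses.
#' @param pin_intermediate_slope if `TRUE`, the intermediate baseline slope
#'   `S_I` is fixed at 0 to stabilise difficult fits.
#' @return An `unfold_fit`: estimates and asymptotic standard errors (NA
#'   for fixed parameters), fitted values, residuals, convergence and
#'   conditioning diagnostics.  Midpoint temperatures are reported in
#'   Kelvin.
#' @export
fit_unfolding <- function(curve, model = c("three_state", "two_state"),
                          fix = NULL, n_starts = 5,
                          pin_intermediate_slope = FALSE) {
  model <- match.arg(model)
  TK <- .curve_kelvin(curve)
  y <- curve$signal
  if (model == "three_state" && length(y) < 15) {
    stop("three-state fits need at least 15 points spanning both transitions")
  }
  pars <- .model_pars(model)

  fixed <- numeric(0)
  if (!is.null(fix)) {
    fix <- unlist(fix)
    if ("dCp" %in% names(fix) && model == "three_state") {
      fixed <- c(fixed, dCp1 = unname(fix["dCp"]), dCp2 = unname(fix["dCp"]))
      fix <- fix[names(fix) != "dCp"]
    }
    fixed <- c(fixed, fix)
  }
  if (pin_intermediate_slope && model == "three_state") {
    fixed <- c(fixed, S_I = 0)
  }
  bad <- setdiff(names(fixed), pars)
  if (length(bad)) stop("unknown fixed parameter: ", paste(bad, collapse = ", "))
  free <- setdiff(pars, names(fixed))

  # baseline seeds from the curve ends
  n <- length(y)
  lo <- seq_len(max(3, round(0.15 * n)))
  hi <- seq(n - max(3, round(0.15 * n)) + 1, n)
  bl_n <- stats::coef(stats::lm(y[lo] ~ TK[lo]))
  bl_u <- stats::coef(stats::lm(y[hi] ~ TK[hi]))
  k_trans <- if (model == "two_state") 1 else 2
  tms <- .tm_guesses(TK, y, k_trans)

  base_start <- if (model == "two_state") {
    c(Tm = tms[1], dHm = 40, dCp = 0,
      I_N = unname(bl_n[1]), S_N = unname(bl_n[2]),
      I_U = unname(bl_u[1]), S_U = unname(bl_u[2]))
  } else {
    c(Tm1 = tms[1], dHm1 = 30, dCp1 = 0, Tm2 = tms[2], dHm2 = 45, dCp2 = 0,
      I_N = unname(bl_n[1]), S_N = unname(bl_n[2]),
      I_I = unname((bl_n[1] + bl_u[1]) / 2), S_I = unname((bl_n[2] + bl_u[2]) / 2),
      I_U = unname(bl_u[1]), S_U = unname(bl_u[2]))
  }

  resid_fn <- function(theta) {
    p <- c(theta, fixed)[pars]
    names(p) <- pars
    r <- y - .model_eval(model, p, TK)
    r[!is.finite(r)] <- 1e6
    r
  }

  # when the heat-capacity terms are free, stage the optimisation: a first
  # pass with dCp pinned at 0 locates the transitions, the full fit then
  # releases it -- this keeps edge-of-range transitions from collapsing
  staged <- character(0)
  if (model == "two_state" && !("dCp" %in% names(fixed))) staged <- "dCp"
  if (model == "three_state") {
    staged <- setdiff(c("dCp1", "dCp2"), names(fixed))
  }

  best <- NULL
  set.seed(1)
  for (s in seq_len(n_starts)) {
    start <- base_start
    if (s > 1) {
      jit <- stats::rnorm(k_trans, 0, 3)
      if (model == "two_state") start["Tm"] <- start["Tm"] + jit[1]
      else {
        start["Tm1"] <- start["Tm1"] + jit[1]
        start["Tm2"] <- start["Tm2"] + jit[2]
        start["dHm1"] <- start["dHm1"] * stats::runif(1, 0.6, 1.6)
        start["dHm2"] <- start["dHm2"] * stats::runif(1, 0.6, 1.6)
      }
    }
    theta0 <- start[free]
    lower <- stats::setNames(rep(-Inf, length(free)), free)
    upper <- stats::setNames(rep(Inf, length(free)), free)
    tm_pars <- intersect(free, c("Tm", "Tm1", "Tm2"))
    lower[tm_pars] <- min(TK) - 30
    upper[tm_pars] <- max(TK) + 30
    dh_pars <- intersect(free, c("dHm", "dHm1", "dHm2"))
    lower[dh_pars] <- 0.5
    upper[dh_pars] <- 300
    run_lm <- function(par, fn) {
      tryCatch(
        minpack.lm::nls.lm(par = par, fn = fn,
                           lower = lower[names(par)], upper = upper[names(par)],
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
        error = function(e) NULL)
    }
    if (length(staged)) {
      pin <- stats::setNames(rep(0, length(staged)), staged)
      sub_free <- setdiff(free, staged)
      pre <- run_lm(start[sub_free], function(th) {
        p <- c(th, pin, fixed)[pars]
        names(p) <- pars
        r <- y - .model_eval(model, p, TK)
        r[!is.finite(r)] <- 1e6
        r
      })
      if (!is.null(pre)) theta0 <- c(pre$par, pin)[free]
    }
    ft <- run_lm(theta0, resid_fn)
    if (is.null(ft)) next
    if (is.null(best) || ft$deviance < best$deviance) best <- ft
  }
  if (is.null(best)) {
    stop("unfolding fit failed to converge from any start")
  }

  theta <- best$par
  p_full <- c(theta, fixed)[pars]
  names(p_full) <- pars
  # enforce Tm1 < Tm2 labelling of the three-state transitions
  if (model == "three_state" && p_full["Tm1"] > p_full["Tm2"]) {
    swap <- c(Tm1 = "Tm2", dHm1 = "dHm2", dCp1 = "dCp2", Tm2 = "Tm1",
              dHm2 = "dHm1", dCp2 = "dCp1", I_I = "I_I", S_I = "S_I")
    p_new <- p_full
    for (nm in names(swap)) p_new[nm] <- p_full[swap[nm]]
    p_full <- p_new
  }

  dof <- length(y) - length(free)
  sigma2 <- best$deviance / max(1, dof)
  H <- best$hessian
  se <- rep(NA_real_, length(free))
  ill <- FALSE
  cv <- tryCatch(solve(H) * sigma2, error = function(e) NULL)
  # conditioning judged on the parameter-scaled (correlation-like) Hessian,
  # so the disparate natural scales of Tm vs baselines do not trip the flag
  d <- sqrt(pmax(diag(H), 0))
  Hs <- if (all(d > 0)) H / outer(d, d) else H
  if (is.null(cv) || any(d == 0) || rcond(Hs) < 1e-10) {
    ill <- TRUE
    if (!is.null(cv)) se <- sqrt(pmax(0, diag(cv)))
  } else {
    se <- sqrt(pmax(0, diag(cv)))
  }
  names(se) <- free
  se_full <- stats::setNames(rep(NA_real_, length(pars)), pars)
  se_full[free] <- se
  rel <- abs(se_full[free] / p_full[free])
  if (!ill && any(is.finite(rel) & rel > 10)) ill <- TRUE
  if (ill) {
    warning("unfolding fit is ill-conditioned; parameters are not all ",
            "identifiable from this curve")
  }

  fitted <- .model_eval(model, p_full, TK)
  structure(list(
    model = model, estimate = p_full, se = se_full, fixed = names(fixed),
    fitted = fitted, residuals = y - fitted, curve = curve,
    deviance = best$deviance, ill_conditioned = ill,
    niter = best$niter, covariance = cv, free = free
  ), class = "unfold_fit")
}

#' @export
print.unfold_fit <- function(x, ...) {
  cat("<unfold_fit> ", x$model, " model; residual sd ",
      signif(sqrt(x$deviance / length(x$residuals)), 3),
      if (x$ill_conditioned) " [ill-conditioned]", "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy an unfolding fit
#'
#' One row per model parameter (broom convention).  Midpoint temperatures
#' are in Kelvin, enthalpies in kcal/mol, heat capacities in kcal/(K mol).
#'
#' @param x an `unfold_fit`.
#' @param ... unused.
#' @return data.frame with `term`, `estimate`, `std.error`, `fixed`.
#' @method tidy unfold_fit
#' @export
tidy.unfold_fit <- function(x, ...) {
  data.frame(
    term = names(x$estimate),
    estimate = unname(x$estimate),
    std.error = unname(x$se),
    fixed = names(x$estimate) %in% x$fixed,
    stringsAsFactors = FALSE
  )
}

#' One-line fit summary
#'
#' @param x an `unfold_fit`.
#' @param ... unused.
#' @return data.frame with model tag, residual sd, deviance, iterations and
#'   the conditioning flag.
#' @method glance unfold_fit
#' @export
glance.unfold_fit <- function(x, ...) {
  data.frame(
    model = x$model,
    sigma = sqrt(x$deviance / max(1, length(x$residuals) - length(x$free))),
    deviance = x$deviance,
    niter = x$niter,
    ill_conditioned = x$ill_conditioned
  )
}

#' Model predictions on a temperature grid
#'
#' @param object an `unfold_fit`.
#' @param newdata optional data.frame with a `temperature` column (in the
#'   curve's unit); defaults to the fitted curve.
#' @param ... unused.
#' @return numeric vector of predicted signals.
#' @export
predict.unfold_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  TT <- newdata$temperature
  if (identical(attr(object$curve, "unit"), "C")) TT <- TT + 273.15
  .model_eval(object$model, object$estimate, TT)
}
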