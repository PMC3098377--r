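# ZF-CxxC / CpG-DNA binding: equilibrium fraction bound, 1:1 Langmuir SPR
# response, and K_D estimation by global kinetic fit or steady-state fit.
# A single-site model is used throughout: measured affinities for one- and
# six-CpG probes match closely, so the domain engages one CpG at a time.

#' Equilibrium fraction of probe bound
#'
#' Hyperbolic 1:1 binding: `conc / (conc + kd)`. With `methylated = TRUE` the
#' probe cannot be engaged (CpG methylation abrogates ZF-CxxC binding) and 0
#' is returned at every concentration.
#'
#' @param conc Protein concentration(s), M (>= 0).
#' @param kd Dissociation constant, M (> 0).
#' @param methylated Logical; methylated (or CpG-mutated) probe.
#' @return Fraction bound in \[0, 1\], vectorised over `conc`.
#' @examples
#' fraction_bound(0.64e-6, 0.64e-6) # 0.5 at conc = KD
#' @export
fraction_bound <- function(conc, kd, methylated = FALSE) {
  if (kd <= 0) abort("`kd` must be > 0.")
  if (any(conc < 0)) abort("`conc` must be >= 0.")
  if (methylated) return(rep(0, length(conc)))
  conc / (conc + kd)
}

#' 1:1 Langmuir SPR response
#'
#' @param t Time(s) since phase start, s (>= 0).
#' @param conc Analyte concentration, M.
#' @param params A [kinetic_params()].
#' @param phase "association" or "dissociation".
#' @param r0 Response at the start of dissociation (required for that phase).
#' @return Response units, vectorised over `t`.
#' @export
langmuir_response <- function(t, conc, params,
                              phase = c("association", "dissociation"),
                              r0 = NULL) {
  stopifnot(inherits(params, "kinetic_params"), all(t >= 0))
  phase <- match.arg(phase)
  if (phase == "association") {
    req <- params$rmax * conc / (conc + params$kd)
    req * (1 - exp(-(params$kon * conc + params$koff) * t))
  } else {
    if (is.null(r0)) abort("`r0` is required for the dissociation phase.")
    r0 * exp(-params$koff * t)
  }
}

#' Global kinetic fit of SPR sensorgrams
#'
#' Fits shared `(kon, koff, Rmax)` to all curves (both phases) by nonlinear
#' least squares on log-scale parameters, with multistart over log-spaced
#' initial guesses to avoid local minima. Reports `K_D = koff/kon` in uM.
#'
#' @param sensorgrams Tibble as produced by [simulate_sensorgrams()]:
#'   `time`, `concentration`, `phase`, `response`. Dissociation times are
#'   measured from t = 0 of the whole series; the association duration is
#'   inferred per concentration from the phase labels.
#' @param n_starts Multistart grid size per parameter.
#' @return A `kinetic_fit` list: `params` ([kinetic_params()]), `kd_uM`,
#'   `rss`, `rms`, `se_rel` (per-parameter relative standard errors), `data`,
#'   `fitted`. Methods: [tidy()], [glance()], [autoplot()].
#' @export
fit_kinetics <- function(sensorgrams, n_starts = 5) {
  sg <- as_tibble(sensorgrams)
  stopifnot(all(c("time", "concentration", "phase", "response") %in% names(sg)))
  concs <- sort(unique(sg$concentration))
  if (length(concs) < 2) abort("need >= 2 concentrations for a global fit.")
  if (!all(c("association", "dissociation") %in% sg$phase)) {
    abort("both association and dissociation phases are required.")
  }
  rng <- diff(range(sg$response))
  if (rng < 1e-9 || rng < 0.01 * max(abs(sg$response), 1e-12)) {
    abort("sensorgrams are flat (no binding signal); refusing to fit.")
  }
  t_assoc <- sg %>%
    filter(.data$phase == "association") %>%
    group_by(.data$concentration) %>%
    summarise(t_end = max(.data$time), .groups = "drop")
  sg <- left_join(sg, t_assoc, by = "concentration")

  model_resp <- function(kon, koff, rmax) {
    kd <- koff / kon
    req <- rmax * sg$concentration / (sg$concentration + kd)
    r_end <- req * (1 - exp(-(kon * sg$concentration + koff) * sg$t_end))
    ifelse(sg$phase == "association",
           req * (1 - exp(-(kon * sg$concentration + koff) * sg$time)),
           r_end * exp(-koff * (sg$time - sg$t_end)))
  }
  obj <- function(theta) {
    r <- model_resp(10^theta[1], 10^theta[2], 10^theta[3])
    sum((sg$response - r)^2)
  }
  rmax0 <- max(sg$response)
  starts <- expand.grid(
    kon = seq(3, 7, length.out = n_starts),
    koff = seq(-3, 1, length.out = n_starts)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(c(starts$kon[i], starts$koff[i], log10(rmax0)), obj,
            method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    abort("kinetic fit failed to converge from any start.")
  }
  # polish + curvature at the optimum
  best <- optim(best$par, obj, method = "BFGS", hessian = TRUE,
                control = list(maxit = 1000, reltol = 1e-14))
  theta <- best$par
  params <- kinetic_params(10^theta[1], 10^theta[2], 10^theta[3])
  n <- nrow(sg)
  sigma2 <- best$value / max(n - 3, 1)
  se_rel <- rep(NA_real_, 3)
  cov <- tryCatch(2 * sigma2 * solve(best$hessian), error = function(e) NULL)
  if (!is.null(cov)) {
    # delta method: SE of log10(p) -> relative SE of p
    se_rel <- sqrt(pmax(diag(cov), 0)) * log(10)
  }
  structure(list(
    params = params, kd_uM = params$kd * 1e6,
    rss = best$value, rms = sqrt(best$value / n),
    se_rel = stats::setNames(se_rel, c("kon", "koff", "rmax")),
    n = n, data = sg,
    fitted = model_resp(params$kon, params$koff, params$rmax)
  ), class = "kinetic_fit")
}

#' Steady-state (equilibrium) fit of a binding isotherm
#'
#' Least-squares fit of `Req = Rmax c / (c + K_D)` to equilibrium responses.
#'
#' @param iso Tibble with `concentration` (M, > 0) and `req` (equilibrium
#'   response).
#' @return A `steady_state_fit` list: `kd_uM`, `rmax`, `bracketing_warning`
#'   (TRUE when the concentration series does not bracket the half-maximal
#'   response, so `kd` is an extrapolation), `data`, `fitted`.
#' @export
fit_steady_state <- function(iso) {
  iso <- as_tibble(iso)
  stopifnot(all(c("concentration", "req") %in% names(iso)))
  if (nrow(iso) < 4) abort("need >= 4 concentrations.")
  if (any(iso$concentration <= 0)) abort("concentrations must be > 0.")
  rng <- diff(range(iso$req))
  if (rng < 1e-12 * max(abs(iso$req), 1)) {
    return(structure(list(
      kd_uM = NA_real_, rmax = mean(iso$req), bracketing_warning = TRUE,
      data = iso, fitted = rep(mean(iso$req), nrow(iso))
    ), class = "steady_state_fit"))
  }
  # self-starting initial values: Rmax ~ max response, KD ~ conc at half-max
  rmax0 <- max(iso$req) * 1.05
  kd0 <- iso$concentration[which.min(abs(iso$req - rmax0 / 2))]
  fit <- nls(req ~ rmax * concentration / (concentration + kd), data = iso,
             start = list(rmax = rmax0, kd = kd0),
             algorithm = "port", lower = c(rmax = 0, kd = 0),
             control = stats::nls.control(maxiter = 500, warnOnly = TRUE))
  est <- coef(fit)
  half <- est[["rmax"]] / 2
  bracket <- min(iso$req) <= half && max(iso$req) >= half
  structure(list(
    kd_uM = est[["kd"]] * 1e6, rmax = est[["rmax"]],
    bracketing_warning = !bracket, data = iso,
    fitted = predict(fit), nls = fit
  ), class = "steady_state_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> kon = %.3g /(M s), koff = %.3g /s, Rmax = %.3g RU\n  K_D = %.3g uM, RMS residual = %.3g (n = %d)\n",
    x$params$kon, x$params$koff, x$params$rmax, x$kd_uM, x$rms, x$n
  ))
  invisible(x)
}

#' @export
print.steady_state_fit <- function(x, ...) {
  cat(sprintf("<steady_state_fit> K_D = %.3g uM, Rmax = %.3g RU%s\n",
              x$kd_uM, x$rmax,
              if (isTRUE(x$bracketing_warning)) " [half-max not bracketed]" else ""))
  invisible(x)
}

#' @rdname fit_kinetics
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble(
    term = c("kon", "koff", "rmax", "kd_uM"),
    estimate = c(x$params$kon, x$params$koff, x$params$rmax, x$kd_uM),
    std.error.rel = c(x$se_rel, NA_real_)
  )
}

#' @rdname fit_kinetics
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(kd_uM = x$kd_uM, rss = x$rss, rms = x$rms, n = x$n)
}

#' @rdname fit_steady_state
#' @param x A `steady_state_fit`.
#' @param ... Unused.
#' @export
tidy.steady_state_fit <- function(x, ...) {
  tibble(term = c("kd_uM", "rmax"), estimate = c(x$kd_uM, x$rmax))
}

#' @rdname fit_steady_state
#' @export
glance.steady_state_fit <- function(x, ...) {
  tibble(kd_uM = x$kd_uM, rmax = x$rmax,
         bracketing_warning = x$bracketing_warning, n = nrow(x$data))
}
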