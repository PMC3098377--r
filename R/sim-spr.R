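# Surface-plasmon-resonance sensorgram simulation (1:1 Langmuir model).

#' 1:1 binding kinetic parameters
#'
#' @param kon Association rate constant, 1/(M*s).
#' @param koff Dissociation rate constant, 1/s.
#' @param rmax Maximal response (saturation), response units.
#' @return A `kinetic_params` list with derived `kd` (= koff/kon, in M).
#' @examples
#' kinetic_params(kon = 1e5, koff = 0.064)$kd # 6.4e-7 M = 0.64 uM
#' @export
kinetic_params <- function(kon, koff, rmax = 100) {
  if (any(c(kon, koff, rmax) <= 0)) abort("kon, koff and rmax must all be > 0.")
  structure(list(kon = kon, koff = koff, rmax = rmax, kd = koff / kon),
            class = "kinetic_params")
}

#' Simulate SPR sensorgrams
#'
#' Association phase: `R(t) = Req (1 - exp(-(kon c + koff) t))` with
#' `Req = Rmax c / (c + KD)`; dissociation: exponential decay from the
#' end-of-association level at rate `koff`. Additive Gaussian noise.
#'
#' @param params A [kinetic_params()].
#' @param concentrations Analyte concentrations in M (one curve each).
#' @param t_assoc,t_dissoc Phase durations in s.
#' @param noise_sd Gaussian noise SD in response units (>= 0).
#' @param seed Integer seed.
#' @param dt Sampling interval in s.
#' @return A tibble: `time` (s, continuous across phases), `concentration`
#'   (M), `phase` ("association"/"dissociation"), `response`.
#' @export
simulate_sensorgrams <- function(params, concentrations,
                                 t_assoc = 120, t_dissoc = 120,
                                 noise_sd = 0, seed = 1, dt = 1) {
  stopifnot(inherits(params, "kinetic_params"))
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (any(concentrations <= 0)) abort("concentrations must be > 0.")
  with_seed(seed, {
    purrr::map_dfr(concentrations, function(conc) {
      ta <- seq(0, t_assoc, by = dt)
      ra <- langmuir_response(ta, conc, params, phase = "association")
      r0 <- ra[length(ra)]
      td <- seq(dt, t_dissoc, by = dt)
      rd <- langmuir_response(td, conc, params, phase = "dissociation", r0 = r0)
      out <- tibble(
        time = c(ta, t_assoc + td), concentration = conc,
        phase = rep(c("association", "dissociation"), c(length(ta), length(td))),
        response = c(ra, rd)
      )
      if (noise_sd > 0) out$response <- out$response + rnorm(nrow(out), 0, noise_sd)
      out
    })
  })
}
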