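# I-V curves, reversal potentials, and chloride Nernst predictions.
#
# The reversal potential of GABA_A-mediated currents is dominated by the
# chloride equilibrium potential, so the chloride content of the internal
# solution (set by the experimenter) and the ACSF predicts the somatic
# E_GABA; comparing per-window I-V fits separates synaptic components of
# proximal (early-onset, clamped chloride) and distal (delayed, closer to
# physiological chloride) origin.

#' Fit an I-V curve and its reversal potential
#'
#' Ordinary least-squares line through (holding potential, peak current);
#' the reversal potential is the zero-current crossing `-intercept/slope`
#' and the slope is the synaptic conductance in nS.
#'
#' @param holdings Holding potentials in mV (>= 3 distinct values).
#' @param peak_currents Peak synaptic currents in pA (signed).
#' @return An object of class `"iv_fit"`: list with `holdings`,
#'   `peak_currents`, `slope_ns`, `e_rev_mv`, `r_squared`,
#'   `extrapolated` (e_rev outside the holdings range by more than 20 mV),
#'   `defined` (`FALSE` when the slope is indistinguishable from zero).
#' @examples
#' fit_iv(c(-70, -50, -30, -10), c(-40, -20, 0, 20))  # e_rev -30, 1 nS
#' @export
fit_iv <- function(holdings, peak_currents) {
  if (length(holdings) != length(peak_currents))
    stop("'holdings' and 'peak_currents' must match", call. = FALSE)
  if (length(unique(holdings)) < 3)
    stop("need at least 3 distinct holding potentials", call. = FALSE)
  fit <- stats::lm(peak_currents ~ holdings)
  slope <- stats::coef(fit)[[2L]]
  intercept <- stats::coef(fit)[[1L]]
  smry <- suppressWarnings(summary(fit))   # exact lines warn harmlessly
  r2 <- if (stats::var(peak_currents) > 0) smry$r.squared else NA_real_
  se_slope <- tryCatch(smry$coefficients[2L, 2L],
                       error = function(e) NA_real_)
  defined <- is.finite(slope) && slope != 0 &&
    (!is.finite(se_slope) || abs(slope) > 2 * se_slope)
  e_rev <- if (defined) -intercept / slope else NA_real_
  extrapolated <- defined &&
    (e_rev < min(holdings) - 20 || e_rev > max(holdings) + 20)
  structure(list(holdings = holdings, peak_currents = peak_currents,
                 slope_ns = slope, e_rev_mv = e_rev, r_squared = r2,
                 extrapolated = extrapolated, defined = defined),
            class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  if (!x$defined)
    cat("<iv_fit: slope ~ 0, reversal potential undefined>\n")
  else
    cat(sprintf("<iv_fit: slope %.3f nS, E_rev %.1f mV, R2 %.3f%s>\n",
                x$slope_ns, x$e_rev_mv, x$r_squared,
                if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}

#' @export
coef.iv_fit <- function(object, ...) {
  c(slope_ns = object$slope_ns, e_rev_mv = object$e_rev_mv)
}

# chloride contributed per mM of salt
.cl_stoichiometry <- c(
  nacl = 1, kcl = 1, choline_cl = 1, cacl2 = 2, mgcl2 = 2,
  k_gluconate = 0, na_gluconate = 0, glucose = 0, hepes = 0, egta = 0,
  nah2po4 = 0, nahco3 = 0, na_ascorbate = 0, na_pyruvate = 0,
  kynurenic_acid = 0, atp_tris = 0, phosphocreatine = 0
)

#' Solution composition
#'
#' Salt concentrations in mM, with names matched (case-insensitively,
#' `-`/`.` treated as `_`) against a chloride stoichiometry table: NaCl,
#' KCl and choline-Cl contribute 1 Cl- per mM, CaCl2 and MgCl2 contribute
#' 2; gluconate, phosphate, bicarbonate and the common organic components
#' contribute none. Unknown salts are an error (their chloride content
#' cannot be guessed).
#'
#' @param ... Named concentrations in mM, e.g. `nacl = 125, kcl = 2.5`.
#' @param temperature_c Temperature in Celsius (recordings here are at room
#'   temperature, 23 C).
#' @return An object of class `"solution"` with a `total_chloride_mm`
#'   field.
#' @examples
#' acsf <- solution(nacl = 125, kcl = 2.5, nah2po4 = 2, nahco3 = 25,
#'                  cacl2 = 2, mgcl2 = 1.3, glucose = 10)
#' acsf$total_chloride_mm  # 134.1
#' @export
solution <- function(..., temperature_c = 23) {
  conc <- c(...)
  if (!length(conc) || is.null(names(conc)) || any(names(conc) == ""))
    stop("all concentrations must be named", call. = FALSE)
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  key <- tolower(gsub("[-. ]", "_", names(conc)))
  unknown <- setdiff(key, names(.cl_stoichiometry))
  if (length(unknown))
    stop("unknown salt(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  total_cl <- sum(conc * .cl_stoichiometry[key])
  structure(list(concentrations_mm = stats::setNames(as.numeric(conc), key),
                 temperature_c = temperature_c,
                 total_chloride_mm = total_cl),
            class = "solution")
}

#' Chloride Nernst potential
#'
#' `E_Cl = -(RT/F) * ln([Cl]_out / [Cl]_in)` for the monovalent chloride
#' anion at the stated temperature (taken from the internal solution).
#'
#' @param internal,external [solution()] objects (pipette and bath).
#' @return Equilibrium potential in mV.
#' @examples
#' internal <- solution(k_gluconate = 110, nacl = 5, kcl = 30, mgcl2 = 4)
#' acsf <- solution(nacl = 125, kcl = 2.5, cacl2 = 2, mgcl2 = 1.3)
#' nernst_cl(internal, acsf)   # ~ -29 mV
#' @export
nernst_cl <- function(internal, external) {
  stopifnot(inherits(internal, "solution"), inherits(external, "solution"))
  cl_in <- internal$total_chloride_mm
  cl_out <- external$total_chloride_mm
  if (cl_in <= 0 || cl_out <= 0)
    stop("both solutions must contain chloride", call. = FALSE)
  R <- 8.31446; F_ <- 96485.33
  T_k <- internal$temperature_c + 273.15
  -(R * T_k / F_) * log(cl_out / cl_in) * 1000
}

#' Separate proximal and distal synaptic components by reversal potential
#'
#' Peak (signed extremum) currents are measured on the per-holding average
#' sweeps in an early window (fast, proximal component) and a late window
#' (delayed, distal component); each window yields its own I-V fit and
#' reversal potential. Each component's amplitude and kinetics are then
#' measured at the holding potential nearest to the *other* component's
#' fitted reversal, where the alternate component is silent.
#'
#' @param iv An `"iv_family"` (see [simulate_iv_family()]) or a list with
#'   `holdings` and `sweepsets`, plus the stimulus time `stim_onset_ms`.
#' @param early_window Early window (ms after the stimulus), default
#'   `c(0, 10)`.
#' @param late_window Late window, default `c(20, 100)`; must not overlap
#'   the early window.
#' @return An object of class `"component_pair"`: list with `proximal` and
#'   `distal`, each holding `fit` (an `"iv_fit"`), `measured_at_mv`,
#'   `amplitude_pa`, `peak_latency_ms`; plus the windows used.
#' @export
separate_components <- function(iv, early_window = c(0, 10),
                                late_window = c(20, 100)) {
  if (early_window[2L] > late_window[1L])
    stop("early and late windows must not overlap", call. = FALSE)
  holdings <- iv$holdings
  if (length(holdings) < 3)
    stop("need >= 3 holding potentials", call. = FALSE)
  stim <- iv$stim_onset_ms
  avg <- lapply(iv$sweepsets, average_sweeps)

  window_peak <- function(tr, win) {
    tt <- trace_times(tr) - stim
    sel <- tt >= win[1L] & tt < win[2L]
    seg <- tr$samples[sel]
    i <- which.max(abs(seg))
    c(peak = seg[i], lat = tt[sel][i])
  }
  early <- vapply(avg, window_peak, numeric(2), win = early_window)
  late <- vapply(avg, window_peak, numeric(2), win = late_window)
  fit_e <- fit_iv(holdings, early["peak", ])
  fit_l <- fit_iv(holdings, late["peak", ])

  measure_at <- function(fit_other, win) {
    if (!fit_other$defined) return(list(at = NA_real_, amp = NA_real_,
                                        lat = NA_real_))
    at <- holdings[which.min(abs(holdings - fit_other$e_rev_mv))]
    pk <- window_peak(avg[[which(holdings == at)[1L]]], win)
    list(at = at, amp = pk[["peak"]], lat = pk[["lat"]])
  }
  m_prox <- measure_at(fit_l, early_window)   # distal silent at its e_rev
  m_dist <- measure_at(fit_e, late_window)

  structure(list(
    proximal = list(fit = fit_e, measured_at_mv = m_prox$at,
                    amplitude_pa = m_prox$amp,
                    peak_latency_ms = m_prox$lat),
    distal = list(fit = fit_l, measured_at_mv = m_dist$at,
                  amplitude_pa = m_dist$amp,
                  peak_latency_ms = m_dist$lat),
    early_window = early_window, late_window = late_window),
    class = "component_pair")
}

#' @export
print.component_pair <- function(x, ...) {
  cat(sprintf("<component_pair: proximal E_rev %.1f mV, distal E_rev %.1f mV>\n",
              x$proximal$fit$e_rev_mv, x$distal$fit$e_rev_mv))
  invisible(x)
}
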