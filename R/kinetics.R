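## Carrier-kinetics model of intracellular glucose and lactate.
##
## State: glc_in (mM), lac_in (mM). Glucose enters through a facilitative
## transporter (GLUT, symmetric carrier), is consumed by hexokinase
## (Michaelis-Menten), and a fixed fraction of the consumed glucose
## reappears as lactate (0..2 lactate per glucose; the remainder is oxidized).
## Lactate exchanges across the membrane through monocarboxylate
## transporters (MCT). Extracellular oxamate trans-accelerates MCT efflux
## (carrier occupancy on the trans side) and competes on the trans site;
## AR-C155858 removes the MCT1/2 component, leaving the mct4_frac fraction;
## cytochalasin B blocks the GLUT term.

#' Kinetic parameters for the glucose/lactate carrier model
#'
#' @param j_hk_vmax Maximal hexokinase flux, mM/s.
#' @param k_hk_km Hexokinase Km, mM.
#' @param glut_vmax Maximal glucose-transport flux, mM/s.
#' @param glut_km GLUT Km, mM (used on both membrane faces).
#' @param lac_prod_frac Lactate molecules produced per glucose consumed,
#'   in \[0, 2\]. Encodes the glycolytic vs oxidative fate of pyruvate.
#' @param mct_vmax Maximal MCT flux, mM/s.
#' @param mct_km MCT Km, mM.
#' @param trans_accel_gain Dimensionless gain (>= 0) by which saturating
#'   trans-substrate (oxamate) amplifies MCT turnover. Large by default so
#'   that oxamate depletes intracellular lactate essentially to the
#'   aglycemic floor, the behaviour seen experimentally.
#' @param oxamate_k Half-saturation of the oxamate effects, mM.
#' @param mct4_frac Fraction of MCT transport insensitive to AR-C155858
#'   (the MCT4 component), in \[0, 1\].
#' @param lac_out_baseline Bath lactate, mM (0 in standard ACSF).
#' @param glc_out_baseline Bath glucose, mM (6 mM standard).
#' @return A `kinetic_params` list.
#' @export
#' @examples
#' p <- kinetic_params()
#' steady_state(p)
kinetic_params <- function(j_hk_vmax = 0.01, k_hk_km = 0.05,
                           glut_vmax = 0.05, glut_km = 3,
                           lac_prod_frac = 1.2,
                           mct_vmax = 0.08, mct_km = 3,
                           trans_accel_gain = 50, oxamate_k = 2,
                           mct4_frac = 0,
                           lac_out_baseline = 0, glc_out_baseline = 6) {
  p <- list(j_hk_vmax = j_hk_vmax, k_hk_km = k_hk_km,
            glut_vmax = glut_vmax, glut_km = glut_km,
            lac_prod_frac = lac_prod_frac,
            mct_vmax = mct_vmax, mct_km = mct_km,
            trans_accel_gain = trans_accel_gain, oxamate_k = oxamate_k,
            mct4_frac = mct4_frac,
            lac_out_baseline = lac_out_baseline,
            glc_out_baseline = glc_out_baseline)
  for (nm in c("j_hk_vmax", "glut_vmax", "mct_vmax"))
    check_number(p[[nm]], nm, min = 0)
  for (nm in c("k_hk_km", "glut_km", "mct_km", "oxamate_k"))
    check_number(p[[nm]], nm, min = 0, strict_min = TRUE)
  check_number(lac_prod_frac, "lac_prod_frac", min = 0, max = 2)
  check_number(mct4_frac, "mct4_frac", min = 0, max = 1)
  check_number(trans_accel_gain, "trans_accel_gain", min = 0)
  check_number(lac_out_baseline, "lac_out_baseline", min = 0)
  check_number(glc_out_baseline, "glc_out_baseline", min = 0)
  structure(p, class = "kinetic_params")
}

## Instantaneous fluxes given state and bath. Returns list(j_hk, j_glut, j_mct).
kinetic_fluxes <- function(glc_in, lac_in, p, bath) {
  j_hk <- p$j_hk_vmax * glc_in / (p$k_hk_km + glc_in)
  cytb_block <- if (isTRUE(bath$cytb)) 1 else 0
  j_glut <- p$glut_vmax *
    (bath$glc_out / (p$glut_km + bath$glc_out) -
       glc_in / (p$glut_km + glc_in)) * (1 - cytb_block)
  mct_vmax_eff <- p$mct_vmax *
    (1 + p$trans_accel_gain * bath$ox / (p$oxamate_k + bath$ox))
  if (isTRUE(bath$arc)) mct_vmax_eff <- mct_vmax_eff * p$mct4_frac
  j_mct <- mct_vmax_eff *
    (lac_in / (p$mct_km + lac_in) -
       bath$lac_out / (p$mct_km * (1 + bath$ox / p$oxamate_k) + bath$lac_out))
  list(j_hk = j_hk, j_glut = j_glut, j_mct = j_mct)
}

#' Basal steady state of the kinetic model
#'
#' Solves for the intracellular glucose and lactate concentrations at which
#' transport balances consumption/production under baseline bath conditions.
#' Used as the default initial condition of [simulate_concentrations()].
#'
#' @param params A [kinetic_params()] object.
#' @return Named numeric vector `c(glc_in=, lac_in=)` in mM.
#' @export
steady_state <- function(params) {
  p <- params
  bath <- bath_state(list(), p$glc_out_baseline, p$lac_out_baseline)
  if (p$glut_vmax == 0 && p$j_hk_vmax == 0) {
    glc <- 0
  } else if (p$glut_vmax == 0) {
    glc <- 0
  } else {
    f <- function(g) {
      fl <- kinetic_fluxes(g, 0, p, bath)
      fl$j_glut - fl$j_hk
    }
    upper <- max(bath$glc_out, 1e-6)
    glc <- if (f(1e-12) <= 0) 0 else uniroot(f, c(1e-12, upper), tol = 1e-12)$root
  }
  prod <- p$lac_prod_frac * p$j_hk_vmax * glc / (p$k_hk_km + glc)
  net_mct <- function(l) kinetic_fluxes(glc, l, p, bath)$j_mct
  if (prod <= net_mct(0) + 1e-15) {
    lac <- max(0, p$lac_out_baseline)  # no net production: equilibrate
  } else if (prod >= p$mct_vmax) {
    stopf("production flux exceeds maximal MCT efflux: no finite basal lactate")
  } else {
    g <- function(l) prod - net_mct(l)
    up <- p$mct_km
    while (g(up) > 0 && up < 1e6) up <- up * 2
    lac <- uniroot(g, c(0, up), tol = 1e-12)$root
  }
  c(glc_in = glc, lac_in = lac)
}

#' Simulate intracellular lactate/glucose under an imaging protocol
#'
#' Integrates the two-state carrier model segment by segment across the
#' protocol's bath switches (switches are instantaneous step changes).
#' Integration uses `deSolve::lsoda` with absolute tolerance 1e-9 mM and the
#' output is returned on the uniform grid `seq(0, duration, by = dt)`.
#'
#' @param params A [kinetic_params()] object.
#' @param protocol A [protocol()] object.
#' @param dt Output time step, s.
#' @param init Initial condition `c(glc_in, lac_in)` in mM; defaults to
#'   [steady_state()] so traces begin on their baseline plateau.
#' @return A `concentration_series` data.frame with columns `t`, `lac_in`,
#'   `glc_in` and the protocol attached as an attribute.
#' @export
#' @examples
#' ser <- simulate_concentrations(kinetic_params(), protocol_preset("mct_block"))
#' head(ser)
simulate_concentrations <- function(params, protocol, dt = 1, init = NULL) {
  if (!inherits(params, "kinetic_params")) stopf("'params' must be kinetic_params")
  if (!inherits(protocol, "protocol")) stopf("'protocol' must be a protocol")
  check_number(dt, "dt", min = 0, strict_min = TRUE)
  if (dt > protocol$duration) stopf("dt exceeds the protocol duration")
  if (is.null(init)) init <- steady_state(params)
  if (length(init) != 2L || any(!is.finite(init)) || any(init < 0))
    stopf("'init' must be two nonnegative concentrations c(glc_in, lac_in)")
  y <- c(glc_in = unname(init[1]), lac_in = unname(init[2]))

  t_out <- seq(0, protocol$duration, by = dt)
  onsets <- vapply(protocol$events, `[[`, numeric(1), "onset")
  bounds <- unique(c(onsets, protocol$duration))
  glc <- lac <- numeric(length(t_out))
  filled <- logical(length(t_out))

  rhs <- function(t, y, parms) {
    g <- max(y[1], 0); l <- max(y[2], 0)
    fl <- kinetic_fluxes(g, l, parms$p, parms$bath)
    dg <- fl$j_glut - fl$j_hk
    dl <- parms$p$lac_prod_frac * fl$j_hk - fl$j_mct
    # clamp: no flux out of an empty pool
    if (y[1] <= 0) dg <- max(dg, 0)
    if (y[2] <= 0) dl <- max(dl, 0)
    list(c(dg, dl))
  }

  for (i in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1L]
    bath <- bath_state(protocol$events[onsets <= t0],
                       params$glc_out_baseline, params$lac_out_baseline)
    sel <- t_out >= t0 - 1e-9 & t_out <= t1 + 1e-9 & !filled
    seg_t <- unique(c(t0, t_out[sel], t1))
    sol <- deSolve::lsoda(y, seg_t, rhs, parms = list(p = params, bath = bath),
                          rtol = 1e-8, atol = 1e-9)
    if (any(sel)) {
      idx <- match(round(t_out[sel], 9), round(sol[, 1], 9))
      glc[sel] <- sol[idx, 2]
      lac[sel] <- sol[idx, 3]
      filled[sel] <- TRUE
    }
    y <- c(glc_in = sol[nrow(sol), 2], lac_in = sol[nrow(sol), 3])
  }

  out <- data.frame(t = t_out, lac_in = pmax(lac, 0), glc_in = pmax(glc, 0))
  structure(out, class = c("concentration_series", "data.frame"),
            protocol = protocol, params = params, dt = dt)
}
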