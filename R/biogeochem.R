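# Biological source/sink terms: SOC hydrolysis, DOC uptake and microbial
# growth, death, maintenance respiration, the temperature-moisture rate
# scalar F(T, M), and the three CO2 components.  All flux operations are
# written so that the carbon they move is conserved identically: every
# flux is computed once and applied to both its source and its sink pool.
#
# Functional forms.  Hydrolysis is first-order in the SOC stock and gated
# by a microbial colonization factor g = B / (B + k_i * S_OC): without
# microbes nothing is hydrolyzed, and at the default parameter values the
# spin-up fixed point of the biomass:SOC ratio lands at 1.5-3%, matching
# the conventional 3%-of-SOC biomass initialization.  Both hydrolysis
# and DOC uptake are scaled by a per-layer microbial activity state
# a(t) in [0, f_act] with feast-famine dynamics: a relaxes (timescale
# tau_act) toward f_act * min(U*/D, 1), where U* is the potential DOC
# uptake flux at ceiling activity (an activity-independent measure of
# substrate availability, which keeps the fixed point stable) and
# D = (k_B + k_m) B / Y_DOC the carbon flux needed to sustain the
# standing biomass.  At balanced supply (U = D, the spin-up
# fixed point) the target is f_act and the model reduces exactly to a
# constant activity multiplier.  After a substrate pulse the biomass
# booms; when the pulse is exhausted, demand stays inflated while supply
# collapses, so activity -- and with it SOC hydrolysis -- dips BELOW its
# baseline until the excess biomass has turned over.  This
# substrate-switching (preferential substrate use) famine is the
# classical mechanism of negative priming; necromass recycling to DOC
# (Y_B -> 1) floors the famine and tips the balance positive.
# DOC uptake follows
# Michaelis-Menten kinetics in the aqueous concentration c with
# half-saturation c_half and maximal specific rate
# k_DOC * F * a * k_i * g: the factor k_i * g (bounded above by k_i, the
# "microbial inhabitation constant") is the fraction of the DOC pool
# inside microbially inhabited microsites, which reconciles the very
# large k_DOC (6590 day^-1, a well-colonized microsite rate) with DOC
# lifetimes of hours at the column scale; the saturation means large
# pulses exceed local uptake capacity and survive to be transported to
# depth, while trickle inputs are consumed where they land.  Maintenance respiration is deliberately
# NOT scaled by F(T, M) (maintenance persists at temperatures where growth
# has ceased); death is unscaled by default with a config switch.

#' Biogeochemical rate parameters
#'
#' Arguments are accepted in their conventional published units (mixed
#' day^-1 / h^-1) and converted once to per-hour at construction; the
#' before/after values are kept in `attr(x, "conversions")`.
#'
#' @param k_OC SOC hydrolysis rate coefficient (day^-1).
#' @param Y_OC Fraction of hydrolyzed SOC routed to DOC (unitless).
#' @param k_DOC DOC decomposition rate (day^-1).
#' @param Y_DOC Fraction of consumed DOC routed to microbial biomass.
#' @param k_B Microbial death rate (h^-1).
#' @param k_m Maintenance respiration rate (day^-1).
#' @param k_i Microbial inhabitation constant (unitless).
#' @param Y_B Fraction of microbial necromass routed to DOC.
#' @param f_act Microbial activity multiplier in `[0, 1]`.  No functional
#'   definition is published; the neutral default is 1 (fully active).
#' @param scale_death_by_F Logical; whether F(T, M) also scales death
#'   (default FALSE).
#' @param c_half Michaelis-Menten half-saturation of DOC uptake
#'   (g C mL^-1 of pore water; ~50 mg C L^-1, a typical organic-soil
#'   pore-water DOC concentration).  `Inf` gives first-order uptake.
#' @param tau_act Relaxation timescale (h) of the microbial activity
#'   state toward its supply-sufficiency target; 0 pins activity at
#'   `f_act` (no feast-famine dynamics).
#' @param b_min_frac Dormant-biomass floor as a fraction of SOC.  Layers
#'   whose dissolved substrate is advectively stripped would otherwise be
#'   driven to absorbing extinction, which real soil communities
#'   (dormancy, attachment, dispersal) do not exhibit; the floor is
#'   recruited from SOC itself, so carbon closure is unaffected.
#' @return An object of class `rate_params` with all rates in h^-1.
#' @export
rate_params <- function(k_OC = 0.019, Y_OC = 0.02, k_DOC = 6590,
                        Y_DOC = 0.62, k_B = 0.0002, k_m = 0.01,
                        k_i = 0.00264, Y_B = 0.5, f_act = 1,
                        scale_death_by_F = FALSE, c_half = 5e-5,
                        tau_act = 48, b_min_frac = 1e-3) {
  fracs <- c(Y_OC = Y_OC, Y_DOC = Y_DOC, Y_B = Y_B, f_act = f_act)
  if (any(fracs < 0 | fracs > 1))
    stop("Y_OC, Y_DOC, Y_B, and f_act must lie in [0, 1]")
  if (any(c(k_OC, k_DOC, k_B, k_m, k_i) < 0))
    stop("rate coefficients must be nonnegative")
  out <- structure(list(
    k_OC = per_day_to_per_hour(k_OC),
    Y_OC = Y_OC,
    k_DOC = per_day_to_per_hour(k_DOC),
    Y_DOC = Y_DOC,
    k_B = k_B,
    k_m = per_day_to_per_hour(k_m),
    k_i = k_i, Y_B = Y_B, f_act = f_act,
    scale_death_by_F = scale_death_by_F, c_half = c_half,
    tau_act = tau_act, b_min_frac = b_min_frac
  ), class = "rate_params")
  attr(out, "conversions") <- data.frame(
    parameter = c("k_OC", "k_DOC", "k_m"),
    input_per_day = c(k_OC, k_DOC, k_m),
    stored_per_hour = c(out$k_OC, out$k_DOC, out$k_m)
  )
  out
}

#' Temperature-moisture scalar parameters
#'
#' @param q10 Multiplicative rate increase per 10 degC.
#' @param t_ref Reference temperature (degC) at which the temperature
#'   factor is 1.  The rate coefficients scaled by F were measured in
#'   laboratory incubations near room temperature, so the default
#'   reference is 20 degC; field soils run well below it.
#' @param m_min,m_max Moisture (cm^3 cm^-3) at which activity vanishes
#'   (too dry / anoxically wet).
#' @return An object of class `tm_params`.
#' @export
tm_params <- function(q10 = 2, t_ref = 20, m_min = 0.01, m_max = 1) {
  if (m_min >= m_max) stop("m_min must be < m_max")
  if (q10 <= 0) stop("q10 must be positive")
  structure(list(q10 = q10, t_ref = t_ref, m_min = m_min, m_max = m_max),
            class = "tm_params")
}

#' Temperature-moisture rate scalar F(T, M)
#'
#' `F = q10^((T - t_ref)/10) * fM(M)` where `fM` is a quadratic moisture
#' response, zero at `m_min` and `m_max`, peaking at 1 at their midpoint:
#' `fM = 4 (M - m_min)(m_max - M) / (m_max - m_min)^2`, clamped at 0.
#' Deterministic and nonnegative for all finite inputs.
#'
#' @param T Soil temperature (degC); vectorized.
#' @param M Volumetric moisture; vectorized.
#' @param tm A [tm_params()] object.
#' @return Unitless scalar(s) >= 0.
#' @export
tm_scalar <- function(T, M, tm = tm_params()) {
  if (any(!is.finite(T)) || any(!is.finite(M)))
    stop("non-finite temperature or moisture")
  ft <- tm$q10^((T - tm$t_ref) / 10)
  fm <- 4 * (M - tm$m_min) * (tm$m_max - M) / (tm$m_max - tm$m_min)^2
  ft * pmax(fm, 0)
}

# Colonization factor g = B/(B + k_i S); 0 when both pools are empty.
colonization <- function(B, S_OC, k_i) {
  den <- B + k_i * S_OC
  ifelse(den > 0, B / den, 0)
}

# Supply-sufficiency target of the activity state: f_act * min(U*/D, 1)
# with U* the potential (ceiling-activity) uptake flux and D the biomass
# sustenance demand.  Empty biomass (D = 0) targets full activity if any
# substrate flows.
activity_target <- function(B, uptake_flux, rp) {
  if (rp$Y_DOC <= 0) return(rep(rp$f_act, length(B)))
  demand <- (rp$k_B + rp$k_m) * B / rp$Y_DOC
  suff <- ifelse(demand > 0, pmin(uptake_flux / demand, 1),
                 as.numeric(uptake_flux > 0))
  rp$f_act * suff
}

#' Hydrolysis fluxes
#'
#' Hydrolyzed mass `H = k_OC * F * S_OC * g * a * dt` (capped at the
#' available stock), with colonization `g = B/(B + k_i S_OC)` and
#' microbial activity `a` (the dynamic state in coupled runs; `f_act`
#' here by default); `Y_OC * H` becomes DOC and `(1 - Y_OC) * H` is
#' respired.
#'
#' @param S_OC SOC stock (g C cm^-2); vectorized over layers.
#' @param B Microbial biomass (g C cm^-2).
#' @param F Temperature-moisture scalar from [tm_scalar()].
#' @param rp A [rate_params()] object.
#' @param dt Step (h).
#' @param activity Microbial activity multiplier; defaults to `f_act`.
#' @return List `doc_gain`, `co2`, `soc_loss` (all g C cm^-2; the first
#'   two sum exactly to the third).
#' @export
hydrolysis_fluxes <- function(S_OC, B, F, rp, dt, activity = rp$f_act) {
  g <- colonization(B, S_OC, rp$k_i)
  H <- pmin(rp$k_OC * F * S_OC * g * activity * dt, S_OC)
  list(doc_gain = rp$Y_OC * H, co2 = (1 - rp$Y_OC) * H, soc_loss = H)
}

#' DOC uptake fluxes
#'
#' Consumed DOC `U = m * (1 - exp(-u_eff dt))` where the effective rate
#' `u_eff = u * c_half / (c_half + c)` saturates in the aqueous
#' concentration `c` (Michaelis-Menten, rate frozen within the step) and
#' `u = k_DOC * F * a * k_i * g` is the maximal specific rate; the
#' exponential form can never overdraw the pool.  `Y_DOC * U` becomes
#' biomass and `(1 - Y_DOC) * U` is growth CO2.
#'
#' @param m_DOC Aqueous DOC mass (g C cm^-2, i.e. `theta * S_DOC * dx`).
#' @param B Microbial biomass (g C cm^-2).
#' @param S_OC SOC stock (g C cm^-2), needed for the colonization factor.
#' @param conc Aqueous concentration (g C mL^-1) for the saturation term;
#'   defaults to 0 (no saturation).
#' @inheritParams hydrolysis_fluxes
#' @return List `biomass_gain`, `co2`, `doc_loss`.
#' @export
uptake_fluxes <- function(m_DOC, B, S_OC, F, rp, dt,
                          activity = rp$f_act, conc = 0) {
  g <- colonization(B, S_OC, rp$k_i)
  u <- rp$k_DOC * F * activity * rp$k_i * g
  sat <- if (is.finite(rp$c_half)) rp$c_half / (rp$c_half + conc) else 1
  U <- m_DOC * (1 - exp(-u * sat * dt))
  list(biomass_gain = rp$Y_DOC * U, co2 = (1 - rp$Y_DOC) * U, doc_loss = U)
}

#' Microbial death fluxes
#'
#' Necromass `D = k_B * B * dt` (capped at `B`), split `Y_B` to DOC and
#' `1 - Y_B` to SOC.
#'
#' @inheritParams hydrolysis_fluxes
#' @return List `doc_gain`, `soc_gain`, `biomass_loss`.
#' @export
death_fluxes <- function(B, rp, dt) {
  D <- pmin(rp$k_B * B * dt, B)
  list(doc_gain = rp$Y_B * D, soc_gain = (1 - rp$Y_B) * D, biomass_loss = D)
}

#' Maintenance respiration
#'
#' `co2 = k_m * B * dt`, independent of temperature and moisture.
#'
#' @inheritParams hydrolysis_fluxes
#' @return CO2 mass (g C cm^-2).
#' @export
maintenance_flux <- function(B, rp, dt) {
  pmin(rp$k_m * B * dt, B)
}

#' One mass-closed biological reaction step (all layers)
#'
#' Applies hydrolysis, death, maintenance, external SOC input, and DOC
#' uptake/growth in `n_sub` internal sub-steps.  Death and maintenance are
#' drawn together from biomass by an exact exponential so their sum can
#' never exceed the stock; uptake uses the exact first-order decay of the
#' aqueous DOC mass after the step's DOC sources are added.  The per-layer
#' carbon balance closes identically:
#' `dSOC + dB + dDOC = I_SOC - (co2_h + co2_g + co2_m)`.
#'
#' @param state A `pool_state` (see [initialize_state()]).
#' @param T,M Temperature (degC) and moisture per layer.
#' @param i_soc_rate External SOC input per layer (g C cm^-2 h^-1).
#' @param rp A [rate_params()] object.
#' @param dt Step (h).
#' @param theta Moisture used for the aqueous-mass conversion (defaults
#'   to `M`).
#' @param dx Layer thickness (cm).
#' @param tm A [tm_params()] object.
#' @param n_sub Internal sub-steps.
#' @return List with updated `state` and per-layer flux vectors
#'   `co2_hydrolysis`, `co2_growth`, `co2_maintenance`, `i_soc_applied`
#'   (g C cm^-2 over `dt`).
#' @export
reaction_step <- function(state, T, M, i_soc_rate, rp, dt, theta = M,
                          dx = 1, tm = tm_params(), n_sub = 1) {
  F <- tm_scalar(T, M, tm)
  soc <- state$soc; B <- state$mbc
  act <- state$act
  if (is.null(act)) act <- rep(rp$f_act, length(soc))
  m_doc <- theta * state$doc * dx
  h <- dt / n_sub
  co2_h <- co2_g <- co2_m <- numeric(length(soc))
  i_applied <- numeric(length(soc))
  Fd <- if (rp$scale_death_by_F) F else 1
  sat_of <- function(m) {
    if (!is.finite(rp$c_half)) return(1)
    rp$c_half / (rp$c_half + m / (theta * dx))
  }
  for (s in seq_len(n_sub)) {
    g <- colonization(B, soc, rp$k_i)
    u <- rp$k_DOC * F * act * rp$k_i * g
    H <- pmin(rp$k_OC * F * soc * g * act * h, soc)
    # Death + maintenance drawn jointly (exact exponential), split by rate.
    lr <- rp$k_B * Fd + rp$k_m
    loss <- B * (1 - exp(-lr * h))
    D <- ifelse(lr > 0, loss * rp$k_B * Fd / lr, 0)
    Mm <- loss - D
    # DOC sources enter, then uptake decays the pool exactly.
    src <- rp$Y_OC * H + rp$Y_B * D
    m_doc <- m_doc + src
    sat <- sat_of(m_doc)
    U <- m_doc * (1 - exp(-u * sat * h))
    m_doc <- m_doc - U
    soc <- soc - H + (1 - rp$Y_B) * D + i_soc_rate * h
    B <- B - loss + rp$Y_DOC * U
    # Activity state relaxes toward its supply-sufficiency target; the
    # potential uptake flux at ceiling activity measures availability.
    if (rp$tau_act > 0) {
      u_pot <- rp$k_DOC * F * rp$f_act * rp$k_i * g * sat_of(m_doc)
      tgt <- activity_target(B, u_pot * m_doc, rp)
      act <- tgt + (act - tgt) * exp(-h / rp$tau_act)
    }
    co2_h <- co2_h + (1 - rp$Y_OC) * H
    co2_g <- co2_g + (1 - rp$Y_DOC) * U
    co2_m <- co2_m + Mm
    i_applied <- i_applied + i_soc_rate * h
    # Dormant-biomass floor, recruited from SOC (internal transfer; the
    # per-layer carbon balance is untouched).
    if (rp$b_min_frac > 0) {
      recruit <- pmin(pmax(rp$b_min_frac * soc - B, 0), pmax(soc, 0))
      B <- B + recruit
      soc <- soc - recruit
    }
  }
  if (any(soc < -1e-12) || any(B < -1e-12) || any(m_doc < -1e-12))
    stop("reaction step drove a pool negative; diagnostics: min(soc)=",
         min(soc), " min(B)=", min(B), " min(doc)=", min(m_doc))
  state$soc <- pmax(soc, 0)
  state$mbc <- pmax(B, 0)
  state$act <- act
  state$doc <- pmax(m_doc, 0) / (theta * dx)
  list(state = state, co2_hydrolysis = co2_h, co2_growth = co2_g,
       co2_maintenance = co2_m, i_soc_applied = i_applied)
}
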