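# Shared fixtures: small columns built in code, an independent
# advection-dispersion oracle, and memoized spun-up states for the
# expensive whole-model checks.

# A uniform single-horizon column for transport verification.
uniform_column <- function(n = 100, dx = 0.5, K_sat = 10, theta_r = 0.05,
                           theta_s = 0.9, vg_n = 1.8, rho_b = 0.1,
                           soc = 0.01) {
  soil_column(list(horizon_spec(
    "uniform", thickness = n * dx,
    vg = vg_params(K_sat, theta_r, theta_s, vg_n),
    rho_b = rho_b, soc_density = soc)), dx = dx)
}

# Closed-form solution for 1-D advection-dispersion with a constant
# concentration c0 at the inlet of an initially clean semi-infinite
# domain (constant v, D).  The exponential term is evaluated in log
# space to survive large v*x/D.
ade_closed_form <- function(x, t, v, D, c0 = 1) {
  erfc_log <- function(z) log(2) + stats::pnorm(-z * sqrt(2), log.p = TRUE)
  a <- (x - v * t) / (2 * sqrt(D * t))
  b <- (x + v * t) / (2 * sqrt(D * t))
  term1 <- exp(erfc_log(a))
  term2 <- exp(v * x / D + erfc_log(b))
  0.5 * c0 * (term1 + term2)
}

# Drive the bare transport operator (no biology) for `hours` with
# constant face flux q and dispersion D over a uniform column.
run_tracer <- function(column, doc0, theta, q, D, tp, hours, dt = 0.5,
                       bc = list(top = list(type = "concentration", c0 = 1)),
                       theta_t = 0.5, advection = "central") {
  n <- column$n_layers
  doc <- doc0
  qf <- rep(q, n + 1)
  Df <- rep(D, n + 1)
  thv <- rep(theta, n)
  export <- 0
  for (s in seq_len(round(hours / dt))) {
    st <- transport_step(doc, column, thv, qf, Df, tp, dt, bc = bc,
                         theta_t = theta_t, advection = advection)
    doc <- st$doc
    export <- export + st$export
  }
  list(doc = doc, export = export)
}

# Memoized expensive setups shared by the acceptance tests.
.fixture_cache <- new.env(parent = emptyenv())

spun_site <- function(site = "WD") {
  key <- paste0("spun_", site)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  arch <- site_archetype(site)
  col <- generate_column(arch)
  opts <- run_options(bottom_bc = if (site == "MWDp") "impermeable"
                      else "free_drainage")
  state <- spinup(initialize_state(col), col, arch, options = opts,
                  max_seasons = 600)
  out <- list(archetype = arch, column = col, options = opts,
              state = state)
  .fixture_cache[[key]] <- out
  out
}
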