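# Configuration loading, validation, and run manifests.  The canonical
# run configuration is a YAML file; omitted rate/transport entries fall
# back to the published defaults, validation collects every violation
# before failing, and unknown keys are rejected.

default_config <- function() {
  list(
    site = "WD",
    seed = 1L,
    column = list(dx = 1, soc_total = NULL, thicknesses = NULL),
    rates = list(k_OC = 0.019, Y_OC = 0.02, k_DOC = 6590, Y_DOC = 0.62,
                 k_B = 0.0002, k_m = 0.01, k_i = 0.00264, Y_B = 0.5,
                 f_act = 1),
    transport = list(D_w = 0.018, dispersivity = 0.5, f = 0.317,
                     K_d = 0.136, alpha = 0.274),
    tm = list(q10 = 2, t_ref = 20, m_min = 0.01, m_max = 1),
    experiment = list(doc_fraction = 0.3, period_h = 60, y_b = 0.5,
                      dT = 0, no_transport = FALSE),
    numerics = list(n_sub_react = 2, n_sub_transport = 1, theta_t = 1,
                    spinup_tol = 1e-4, spinup_dt = 6,
                    max_spinup_seasons = 400)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, fills omitted entries with the
#' published defaults, and validates the result.  All schema violations
#' are reported together, not first-error-only; unknown keys are
#' rejected.
#'
#' @param path Path to a YAML file, or a list to validate directly.
#' @return A validated configuration list of class `run_config`.
#' @export
load_config <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) path
  else stop("path must be a file path or a list")
  if (is.null(user)) user <- list()

  def <- default_config()
  errs <- character()
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    errs <- c(errs, paste0("unknown top-level keys: ",
                           paste(unknown, collapse = ", ")))
  for (sec in intersect(names(user), names(def))) {
    if (is.list(def[[sec]]) && is.list(user[[sec]])) {
      bad <- setdiff(names(user[[sec]]), names(def[[sec]]))
      if (length(bad))
        errs <- c(errs, paste0("unknown keys in '", sec, "': ",
                               paste(bad, collapse = ", ")))
    }
  }
  # merge that keeps the default when the user value is NULL (so "~"
  # entries round-trip instead of deleting keys, unlike modifyList)
  merge_keep <- function(d, u) {
    for (nm in names(u)) {
      if (is.list(d[[nm]]) && is.list(u[[nm]]))
        d[[nm]] <- merge_keep(d[[nm]], u[[nm]])
      else if (!is.null(u[[nm]])) d[[nm]] <- u[[nm]]
    }
    d
  }
  cfg <- merge_keep(def, user[intersect(names(user), names(def))])

  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(cfg$site %in% c("WD", "MWDp"), "site must be 'WD' or 'MWDp'")
  fr <- cfg$rates
  for (nm in c("Y_OC", "Y_DOC", "Y_B", "f_act"))
    chk(fr[[nm]] >= 0 && fr[[nm]] <= 1,
        paste0("rates$", nm, " must lie in [0, 1]"))
  for (nm in c("k_OC", "k_DOC", "k_B", "k_m", "k_i"))
    chk(fr[[nm]] >= 0, paste0("rates$", nm, " must be nonnegative"))
  tpv <- cfg$transport
  chk(tpv$f >= 0 && tpv$f <= 1, "transport$f must lie in [0, 1]")
  for (nm in c("D_w", "dispersivity", "K_d", "alpha"))
    chk(tpv[[nm]] >= 0, paste0("transport$", nm, " must be nonnegative"))
  chk(cfg$tm$m_min < cfg$tm$m_max, "tm$m_min must be < tm$m_max")
  ex <- cfg$experiment
  chk(ex$doc_fraction > 0, "experiment$doc_fraction must be positive")
  chk(ex$period_h > 0, "experiment$period_h must be positive")
  chk(ex$y_b >= 0 && ex$y_b <= 1, "experiment$y_b must lie in [0, 1]")
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed),
      "seed must be an integer")

  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  structure(cfg, class = c("run_config", "list"))
}

#' Build model objects from a validated configuration
#'
#' @param cfg A `run_config` from [load_config()].
#' @return List with `archetype`, `column`, `rp`, `tp`, `tm`, `options`,
#'   `scenario`, and `seed`.
#' @export
config_objects <- function(cfg) {
  arch <- site_archetype(cfg$site)
  thick <- cfg$column$thicknesses
  if (!is.null(thick)) thick <- unlist(thick)
  column <- generate_column(arch, thicknesses = thick,
                            soc_total = cfg$column$soc_total,
                            dx = cfg$column$dx)
  rp <- do.call(rate_params, cfg$rates)
  tp <- do.call(transport_params, cfg$transport)
  tm <- do.call(tm_params, cfg$tm)
  options <- run_options(
    no_transport = isTRUE(cfg$experiment$no_transport),
    bottom_bc = if (arch$moisture_regime == "saturated_at_depth")
      "impermeable" else "free_drainage",
    n_sub_react = cfg$numerics$n_sub_react,
    n_sub_transport = cfg$numerics$n_sub_transport,
    theta_t = cfg$numerics$theta_t)
  list(archetype = arch, column = column, rp = rp, tp = tp, tm = tm,
       options = options,
       scenario = list(fraction = cfg$experiment$doc_fraction,
                       period_h = cfg$experiment$period_h,
                       y_b = cfg$experiment$y_b),
       dT = cfg$experiment$dT,
       seed = as.integer(cfg$seed), config = cfg)
}

#' Normalize and dump a configuration
#'
#' `dump_config(load_config(x))` equals `dump_config(load_config(
#' dump_config(load_config(x))))` -- the normalized round trip.
#'
#' @param cfg A `run_config`.
#' @param path Optional output path; when `NULL` the YAML text is
#'   returned.
#' @return The YAML text (invisibly when written to a file).
#' @export
dump_config <- function(cfg, path = NULL) {
  txt <- yaml::as.yaml(unclass(cfg))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# Small content hash (polynomial rolling hash mod 2^31 - 1 over the
# deparsed config; stays within exact double-precision integers).
config_fingerprint <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a run manifest
#'
#' Records the effective configuration, its fingerprint, the seed, and
#' the package version -- enough to reproduce a run bit-exactly.
#'
#' @param cfg A `run_config`.
#' @param path Output JSON path.
#' @param extra Optional named list merged into the manifest.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(cfg, path, extra = list()) {
  man <- c(list(
    fingerprint = config_fingerprint(cfg),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("docprime")),
    config = unclass(cfg)), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(man)
}
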