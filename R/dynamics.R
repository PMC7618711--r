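## NTP pool dynamics after glucose withdrawal: residual production balanced
## against a hierarchy of Michaelis-Menten ATP sinks. The post-shift
## equilibrium ("set point") emerges where residual production equals the
## summed residual sink flux. Supports wild-type and hxk2-delta scenarios.

#' One ATP-consuming process in the pool-dynamics model
#'
#' @param name sink label.
#' @param vmax maximal flux, mM/s (> 0).
#' @param km half-saturation ATP concentration, mM (> 0).
#' @param active whether the sink starts active.
#' @param shutoff_atp optional ATP level (mM) below which the sink is
#'   deactivated (a latched, regulated shutoff; once off it stays off).
#' @return object of class `sink_spec`.
#' @export
sink_spec <- function(name, vmax, km, active = TRUE, shutoff_atp = NA_real_) {
  stop_if_not_number(vmax, "vmax", positive = TRUE)
  stop_if_not_number(km, "km", positive = TRUE)
  if (!is.na(shutoff_atp)) stop_if_not_number(shutoff_atp, "shutoff_atp", nonneg = TRUE)
  structure(list(name = name, vmax = vmax, km = km, active = isTRUE(active),
                 shutoff_atp = shutoff_atp),
            class = "sink_spec")
}

#' ATP production specification
#'
#' @param pre_shift_flux production flux before withdrawal, mM/s; calibrate
#'   with [steady_state_production()] so the pre-shift state is a fixed point.
#' @param residual_fraction fraction of pre-shift production remaining after
#'   withdrawal, in `[0, 1]` (the residual source is unidentified
#'   biologically and treated as a free parameter).
#' @return object of class `production_spec`.
#' @export
production_spec <- function(pre_shift_flux, residual_fraction) {
  stop_if_not_number(pre_shift_flux, "pre_shift_flux", nonneg = TRUE)
  stop_if_not_number(residual_fraction, "residual_fraction", nonneg = TRUE)
  if (residual_fraction > 1)
    stop("residual_fraction must lie in [0, 1]", call. = FALSE)
  structure(list(pre_shift_flux = pre_shift_flux,
                 residual_fraction = residual_fraction),
            class = "production_spec")
}

## Summed Michaelis-Menten flux of the sinks marked active in `on`
## (logical vector; defaults to the sink objects' own flags), ignoring shutoff
## thresholds -- those are handled by the caller.
sink_flux_total <- function(sinks, atp, on = NULL) {
  if (is.null(on)) on <- vapply(sinks, function(s) s$active, logical(1))
  f <- 0
  for (i in seq_along(sinks))
    if (on[i]) f <- f + sinks[[i]]$vmax * atp / (sinks[[i]]$km + atp)
  f
}

## Shutoff-aware total flux: a sink with a threshold contributes nothing
## below it (used for set-point analysis; the simulator latches instead).
sink_flux_piecewise <- function(sinks, atp) {
  f <- 0
  for (s in sinks) {
    if (!s$active) next
    if (!is.na(s$shutoff_atp) && atp < s$shutoff_atp) next
    f <- f + s$vmax * atp / (s$km + atp)
  }
  f
}

#' Production flux balancing the sinks at a given state
#'
#' Returns the summed sink flux at the state's ATP concentration; using this
#' as `pre_shift_flux` makes the state a fixed point of the dynamics.
#'
#' @param sinks list of [sink_spec()] (all treated as active).
#' @param state a [nucleotide_state()].
#' @return flux in mM/s.
#' @export
steady_state_production <- function(sinks, state) {
  if (!length(sinks)) stop("empty sink list", call. = FALSE)
  sink_flux_total(sinks, state$ATP, on = rep(TRUE, length(sinks)))
}

#' Simulate NTP pool dynamics after glucose withdrawal
#'
#' Integrates `d[ATP]/dt = production * residual_fraction - sum(sink fluxes)`
#' with deSolve's stiff-safe lsoda integrator. With `conservation = TRUE`,
#' consumed ATP is transferred to ADP, production converts ADP back to ATP
#' (saturably, so ADP cannot go negative), and an adenylate-kinase-like step
#' `2 ADP <-> ATP + AMP` exchanges within the adenylate pool, whose total is
#' conserved. Sinks with a `shutoff_atp` threshold are deactivated by root
#' detection when ATP first crosses below the threshold (latched off, which
#' avoids chattering at the crossing). GTP/CTP/UTP are slaved pools derived
#' from the ATP trajectory (see `slave` argument).
#'
#' @param initial a [nucleotide_state()] (mM).
#' @param sinks list of [sink_spec()].
#' @param production a [production_spec()].
#' @param t_end end time, seconds.
#' @param dt output grid spacing, seconds.
#' @param conservation couple ATP consumption to ADP/AMP bookkeeping.
#' @param atol,rtol solver tolerances.
#' @param ak_rate,ak_keq adenylate-kinase rate constant (1/(mM s)) and
#'   equilibrium constant.
#' @param slave named vector of slaving factors for GTP/CTP/UTP: pool X
#'   follows `X0 * (1 - slave_X * (1 - ATP/ATP0))`. The GTP default maps
#'   0.46 mM to 0.089 mM when ATP falls 2 -> 0.3 mM.
#' @return object of class `ntp_sim`: list with `trajectory` (data.frame of
#'   time and concentrations), `sink_flux` (per-sink flux trajectories),
#'   `shutoff_times`, and the inputs.
#' @export
simulate_ntp <- function(initial, sinks, production, t_end, dt = 0.5,
                         conservation = TRUE, atol = 1e-9, rtol = 1e-6,
                         ak_rate = 0.5, ak_keq = 1,
                         slave = c(GTP = 0.94885, CTP = 0.9, UTP = 0.9)) {
  stopifnot(inherits(initial, "nucleotide_state"),
            inherits(production, "production_spec"))
  stop_if_not_number(t_end, "t_end", positive = TRUE)
  if (!length(sinks)) stop("empty sink list", call. = FALSE)

  r <- production$pre_shift_flux * production$residual_fraction
  on <- vapply(sinks, function(s) s$active, logical(1))
  thr <- vapply(sinks, function(s) s$shutoff_atp, numeric(1))

  deriv <- function(t, y, parms) {
    A <- max(y[["ATP"]], 0); D <- max(y[["ADP"]], 0); M <- max(y[["AMP"]], 0)
    cons <- sink_flux_total(sinks, A, on = parms$on)
    prod_flux <- if (conservation) r * D / (D + 1e-3) else r
    ak <- if (conservation) ak_rate * (D^2 - A * M / ak_keq) else 0
    dA <- prod_flux - cons + ak
    dD <- if (conservation) cons - prod_flux - 2 * ak else 0
    dM <- if (conservation) ak else 0
    if (A <= 0 && dA < 0) dA <- 0
    if (D <= 0 && dD < 0) dD <- 0
    if (M <= 0 && dM < 0) dM <- 0
    list(c(ATP = dA, ADP = dD, AMP = dM))
  }

  y <- c(ATP = initial$ATP, ADP = initial$ADP, AMP = initial$AMP)
  times_all <- seq(0, t_end, by = dt)
  if (times_all[length(times_all)] < t_end) times_all <- c(times_all, t_end)
  out <- NULL
  t0 <- 0
  shutoff_times <- stats::setNames(rep(NA_real_, length(sinks)),
                                   vapply(sinks, `[[`, "", "name"))
  repeat {
    watch <- which(on & !is.na(thr) & thr < y[["ATP"]])
    rootfun <- if (length(watch))
      function(t, y, parms) y[["ATP"]] - thr[watch] else NULL
    seg_times <- unique(c(t0, times_all[times_all > t0]))
    sol <- deSolve::lsoda(y, seg_times, deriv, parms = list(on = on),
                          atol = atol, rtol = rtol, rootfunc = rootfun)
    if (attr(sol, "istate")[1] < 0)
      stop("integration error at t = ", utils::tail(sol[, "time"], 1),
           "; last state ATP = ", utils::tail(sol[, "ATP"], 1), call. = FALSE)
    out <- rbind(out, sol[sol[, "time"] %in% times_all | sol[, "time"] == t0, ,
                          drop = FALSE])
    t_last <- sol[nrow(sol), "time"]
    hit_root <- !is.null(rootfun) && !is.null(attr(sol, "iroot")) &&
      t_last < t_end
    if (!hit_root && t_last >= t_end) break
    if (hit_root) {
      iroot <- attr(sol, "iroot")
      off_idx <- watch[iroot]
      on[off_idx] <- FALSE
      shutoff_times[off_idx] <- t_last
      y <- sol[nrow(sol), c("ATP", "ADP", "AMP")]
      t0 <- t_last
    } else break
  }
  out <- out[!duplicated(out[, "time"]), , drop = FALSE]
  traj <- as.data.frame(out)
  traj[c("ATP", "ADP", "AMP")] <- lapply(traj[c("ATP", "ADP", "AMP")],
                                         function(v) pmax(v, 0))

  ## slaved NTP pools follow the relative ATP trajectory
  a_rel <- if (initial$ATP > 0) traj$ATP / initial$ATP else rep(0, nrow(traj))
  for (sp in names(slave)) {
    x0 <- initial[[sp]]
    traj[[sp]] <- pmax(x0 * (1 - slave[[sp]] * (1 - a_rel)), 0)
  }

  ## per-sink flux trajectories (0 after a sink's shutoff time)
  flux <- sapply(seq_along(sinks), function(i) {
    s <- sinks[[i]]
    f <- s$vmax * traj$ATP / (s$km + traj$ATP)
    if (!s$active) f[] <- 0
    if (!is.na(shutoff_times[i])) f[traj$time > shutoff_times[i]] <- 0
    f
  })
  colnames(flux) <- vapply(sinks, `[[`, "", "name")

  structure(list(trajectory = traj, sink_flux = as.data.frame(flux),
                 shutoff_times = shutoff_times, sinks = sinks,
                 production = production, conservation = conservation,
                 initial = initial),
            class = "ntp_sim")
}

#' @export
print.ntp_sim <- function(x, ...) {
  tr <- x$trajectory
  cat("NTP pool simulation:", nrow(tr), "time points over",
      max(tr$time), "s\n")
  cat(sprintf("  ATP: %.3f -> %.3f mM\n", tr$ATP[1], tr$ATP[nrow(tr)]))
  off <- x$shutoff_times[!is.na(x$shutoff_times)]
  if (length(off))
    cat("  sink shutoffs:",
        paste(sprintf("%s@%.1fs", names(off), off), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.ntp_sim <- function(x, species = c("ATP", "ADP", "AMP", "GTP"), ...) {
  tr <- x$trajectory
  species <- intersect(species, names(tr))
  graphics::matplot(tr$time, tr[species], type = "l", lty = 1,
                    xlab = "time (s)", ylab = "concentration (mM)", ...)
  graphics::legend("topright", legend = species, lty = 1,
                   col = seq_along(species), bty = "n")
  invisible(x)
}

#' Post-shift ATP set point
#'
#' Solves `residual production = total sink flux([ATP]*)` by bracketed
#' root-finding on the shutoff-aware flux curve. When the residual
#' production falls inside the discontinuity of a shutoff threshold, the
#' threshold itself is the (boundary) set point: the sink holds the
#' concentration at its shutoff level.
#'
#' @inheritParams simulate_ntp
#' @param upper initial upper bracket for the search, mM (expanded
#'   automatically while the balance is still negative there).
#' @param tol root tolerance, mM.
#' @return the equilibrium ATP concentration in mM.
#' @export
find_set_point <- function(sinks, production, upper = 10, tol = 1e-9) {
  if (!length(sinks)) stop("empty sink list", call. = FALSE)
  r <- production$pre_shift_flux * production$residual_fraction
  if (r == 0) return(0)
  vtot <- sum(vapply(sinks, function(s) if (s$active) s$vmax else 0, numeric(1)))
  if (r >= vtot)
    stop("no equilibrium: residual production >= total sink capacity",
         call. = FALSE)
  g <- function(a) sink_flux_piecewise(sinks, a) - r
  tries <- 0
  while (g(upper) < 0 && tries < 60) { upper <- upper * 2; tries <- tries + 1 }
  ## breakpoints where the flux curve jumps
  brk <- sort(unique(c(0, stats::na.omit(
    vapply(sinks, function(s) s$shutoff_atp, numeric(1))), upper)))
  brk <- brk[brk >= 0 & brk <= upper]
  if (brk[length(brk)] < upper) brk <- c(brk, upper)
  eps <- 1e-12
  for (i in seq_len(length(brk) - 1)) {
    lo <- brk[i] + eps; hi <- brk[i + 1] - eps
    if (hi <= lo) next
    if (g(lo) <= 0 && g(hi) >= 0)
      return(stats::uniroot(g, c(lo, hi), tol = tol)$root)
    ## jump interval: flux below the breakpoint < r <= flux above it
    b <- brk[i + 1]
    if (b < upper && g(b - eps) < 0 && g(b + eps) >= 0) return(b)
  }
  if (g(upper) < 0)
    stop("no equilibrium found below upper bracket", call. = FALSE)
  stats::uniroot(g, c(eps, upper), tol = tol)$root
}

#' Default scenario configuration
#'
#' Anchor concentrations and sink layout used to calibrate the wild-type and
#' hxk2-delta scenarios. The sink set comprises a Pma1-like plasma-membrane
#' ATPase carrying 30% of the pre-shift ATP budget, a moderate-affinity bulk
#' sink (translation and other Km ~0.5 mM ATPases) and a high-affinity
#' maintenance sink. Calibration (see [ntp_scenario()]) solves the sink
#' shares so that (i) the wild-type set point sits at `wt_set_point`,
#' (ii) removing the Pma1-like sink moves the set point to
#' `hxk2_set_point`, and (iii) the initial net depletion equals
#' `depletion_mM_s` (3e6 molecules/s through the cell model).
#'
#' @return list of configuration values.
#' @export
scenario_config <- function() {
  list(
    initial = list(ATP = 2.0, ADP = 0.18, AMP = 0.05,
                   GTP = 0.46, CTP = 0.3, UTP = 0.6),
    atp0 = 2.0,
    wt_set_point = 0.3,
    hxk2_set_point = 1.0,
    approach_time_s = 30,
    approach_ratio = 1.1,
    pma1_share = 0.30,
    sinks = list(pma1 = list(km = 0.1), bulk = list(km = 0.5),
                 maintenance = list(km = 0.05))
  )
}

## Normalised per-share flux of a unit sink with f(atp0) = share
unit_flux <- function(km, atp0, a) (km + atp0) / atp0 * a / (km + a)

#' Calibrated wild-type / hxk2-delta NTP scenarios
#'
#' Builds the sink set and production spec for a scenario. Both scenarios
#' share one calibration (see [scenario_config()]); the hxk2-delta scenario
#' is identical to wild type except that the Pma1-like sink carries a
#' shutoff threshold at the mutant set point, so it is inactivated at a
#' higher ATP level and the pool plateaus near 1 mM instead of 0.3 mM.
#'
#' @param name `"wild_type"` or `"hxk2_delta"`.
#' @param config configuration list, by default [scenario_config()].
#' @param overrides named list merged over `config`.
#' @return list with elements `sinks`, `production`, `initial` (a
#'   [nucleotide_state()]) and `config`.
#' @export
ntp_scenario <- function(name = c("wild_type", "hxk2_delta"),
                         config = scenario_config(), overrides = list()) {
  name <- match.arg(name)
  config[names(overrides)] <- overrides
  a0 <- config$atp0
  a_wt <- config$wt_set_point
  a_mut <- config$hxk2_set_point
  km_p <- config$sinks$pma1$km
  km_b <- config$sinks$bulk$km
  km_m <- config$sinks$maintenance$km
  s_p <- config$pma1_share

  ## Solve the bulk/maintenance share split so that the full sink set at the
  ## WT set point consumes exactly what the non-Pma1 sinks consume at the
  ## mutant set point (both must equal the shared residual production).
  split <- function(s_b) {
    s_m <- 1 - s_p - s_b
    f_all_wt <- s_p * unit_flux(km_p, a0, a_wt) +
      s_b * unit_flux(km_b, a0, a_wt) + s_m * unit_flux(km_m, a0, a_wt)
    f_rest_mut <- s_b * unit_flux(km_b, a0, a_mut) +
      s_m * unit_flux(km_m, a0, a_mut)
    f_all_wt - f_rest_mut
  }
  s_b <- stats::uniroot(split, c(1e-6, 1 - s_p - 1e-6), tol = 1e-12)$root
  s_m <- 1 - s_p - s_b

  ## overall rate scale fitted against the kinetic anchor: ATP reaches
  ## within `approach_ratio` of the wild-type set point by `approach_time_s`
  ## (the printed time course falls from 2 mM to ~0.3 mM within 30 s)
  shares <- c(pma1 = s_p, bulk = s_b, maintenance = s_m)
  kms <- c(pma1 = km_p, bulk = km_b, maintenance = km_m)
  f_norm <- function(a) sum(shares * unit_flux(kms, a0, a))   # f(a0) = 1
  residual_fraction <- f_norm(a_wt)
  initial <- do.call(nucleotide_state, config$initial)
  atp_at_anchor <- function(p0) {
    sks <- lapply(names(shares), function(nm) sink_spec(
      nm, vmax = shares[[nm]] * p0 * (kms[[nm]] + a0) / a0, km = kms[[nm]]))
    sim <- simulate_ntp(initial, sks,
                        production_spec(p0, residual_fraction),
                        t_end = config$approach_time_s,
                        dt = config$approach_time_s / 4)
    utils::tail(sim$trajectory$ATP, 1)
  }
  target <- config$approach_ratio * a_wt
  p0 <- stats::uniroot(function(p) atp_at_anchor(p) - target,
                       c(0.02, 5), tol = 1e-4)$root

  mk <- function(nm) sink_spec(
    nm,
    vmax = shares[[nm]] * p0 * (kms[[nm]] + a0) / a0,
    km = kms[[nm]],
    shutoff_atp = if (nm == "pma1" && name == "hxk2_delta") a_mut else NA_real_)
  sinks <- lapply(names(shares), mk)
  names(sinks) <- names(shares)

  list(sinks = sinks,
       production = production_spec(pre_shift_flux = p0,
                                    residual_fraction = residual_fraction),
       initial = initial, config = config, name = name)
}
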