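## Ribosome run-off simulation: occupancy-gated initiation, GTP-gated
## elongation on an exclusion process (TASEP with extended particles), and
## synthetic polysome-profile rendering/alignment.

#' mRNA pool specification
#'
#' @param id transcript identifiers.
#' @param cds_length CDS lengths in codons (> footprint).
#' @param initiation_rate pre-stress initiation rates, events/s.
#' @param copies copy numbers (>= 1).
#' @return data.frame with one row per mRNA species.
#' @export
mrna_pool <- function(id, cds_length, initiation_rate, copies = 1L) {
  stop_if_not_number(cds_length, "cds_length", positive = TRUE)
  stop_if_not_number(initiation_rate, "initiation_rate", nonneg = TRUE)
  stop_if_not_number(copies, "copies", positive = TRUE)
  data.frame(id = as.character(id), cds_length = as.numeric(cds_length),
             initiation_rate = as.numeric(initiation_rate),
             copies = as.integer(copies))
}

## Occupancy gates from a nucleotide state: initiation is gated by the
## competitive eIF4A occupancy (single rate multiplier; eIF4B/Ded1 are
## co-limiting, not separately rate-setting), elongation by eEF1A GTP
## occupancy.
state_gates <- function(state, factors = default_factors()) {
  init_f <- factors$eIF4A
  elong_f <- factors$eEF1A
  c(init = if (!is.na(init_f$K_adp)) occupancy_competitive(init_f, state)
    else occupancy(init_f, state),
    elong = occupancy(elong_f, state))
}

## Resolve a timeline argument into a step function t -> c(init, elong).
## `timeline` is a single nucleotide_state (constant) or a data.frame with
## columns time_s, ATP, ADP, GTP (piecewise constant between rows).
timeline_gates <- function(timeline, t_end, factors = default_factors(),
                           gate = NULL) {
  if (!is.null(gate)) return(gate)
  if (inherits(timeline, "nucleotide_state")) {
    g <- state_gates(timeline, factors)
    return(function(t) g)
  }
  stopifnot(is.data.frame(timeline), all(c("time_s", "ATP", "GTP") %in% names(timeline)))
  if (min(timeline$time_s) > 0 || max(timeline$time_s) < t_end)
    stop("timeline does not cover [0, t_end]", call. = FALSE)
  if (!"ADP" %in% names(timeline)) timeline$ADP <- 0
  gm <- t(apply(timeline, 1, function(row)
    state_gates(nucleotide_state(ATP = row[["ATP"]], ADP = row[["ADP"]],
                                 GTP = row[["GTP"]]), factors)))
  ts <- timeline$time_s
  function(t) {
    i <- findInterval(t, ts, rightmost.closed = TRUE)
    c(init = gm[max(i, 1), "init"], elong = gm[max(i, 1), "elong"])
  }
}

## Steady-state initial loading: ribosomes spaced v/alpha codons apart
## (low-density TASEP), at least one footprint.
steady_positions <- function(L, alpha, v, footprint) {
  if (alpha <= 0 || v <= 0) return(numeric(0))
  spacing <- max(footprint, v / alpha)
  if (spacing > L) return(numeric(0))
  pos <- seq(L - 1, 0, by = -spacing)
  sort(pos)
}

#' Simulate ribosome run-off on an mRNA pool
#'
#' Initiation attempts occur at `initiation_rate * init-gate(t)` per copy and
#' are blocked while the first footprint is occupied. Each ribosome advances
#' at `elongation_rate * elong-gate(t)` codons/s, deterministically or as
#' exponential-waiting-time single-codon steps (stochastic mode), with the
#' exclusion constraint that adjacent ribosomes stay at least one footprint
#' apart. Ribosomes passing the last codon terminate instantly and are
#' removed. The gates come from factor occupancies at the nucleotide state
#' timeline: competitive eIF4A occupancy for initiation, eEF1A GTP occupancy
#' for elongation.
#'
#' @param mrnas a [mrna_pool()] data.frame.
#' @param timeline a [nucleotide_state()] held constant, or a data.frame
#'   `time_s ATP ADP GTP` treated as piecewise constant, covering
#'   `[0, t_end]`.
#' @param t_end simulated seconds.
#' @param mode `"deterministic"` (continuous positions, mean-field) or
#'   `"stochastic"` (seeded exclusion-process sampling).
#' @param seed RNG seed for stochastic mode.
#' @param factors factor set supplying the gating occupancies.
#' @param footprint ribosome footprint in codons (default 10).
#' @param elongation_rate unstressed elongation speed, codons/s.
#' @param dt deterministic integration step / gate refresh interval, s.
#' @param snapshot_times times at which to record ribosome snapshots
#'   (default: 25 evenly spaced including 0 and t_end).
#' @param initial `"steady"` for steady-state pre-loading at the unstressed
#'   rates, `"empty"`, or a list of numeric position vectors (one per copy).
#' @param gate optional override: function(t) returning
#'   `c(init =, elong =)` fractions, replacing occupancy computation.
#' @return object of class `runoff_sim`: snapshots (list, per time, of
#'   per-copy position vectors), copy metadata, termination log and
#'   bookkeeping counters.
#' @export
simulate_runoff <- function(mrnas, timeline, t_end,
                            mode = c("deterministic", "stochastic"),
                            seed = NULL, factors = default_factors(),
                            footprint = 10, elongation_rate = 2.6, dt = 0.1,
                            snapshot_times = NULL, initial = "steady",
                            gate = NULL) {
  mode <- match.arg(mode)
  stop_if_not_number(t_end, "t_end", positive = TRUE)
  gates <- timeline_gates(timeline, t_end, factors, gate)
  if (is.null(snapshot_times))
    snapshot_times <- unique(c(seq(0, t_end, length.out = 25), t_end))
  snapshot_times <- sort(unique(pmin(snapshot_times, t_end)))

  ## expand species to copies
  copy_species <- rep(seq_len(nrow(mrnas)), mrnas$copies)
  L <- mrnas$cds_length[copy_species]
  alpha0 <- mrnas$initiation_rate[copy_species]
  n_copies <- length(copy_species)

  g0 <- gates(0)
  pos <- if (is.list(initial)) {
    stopifnot(length(initial) == n_copies)
    lapply(initial, sort)
  } else if (identical(initial, "empty")) {
    rep(list(numeric(0)), n_copies)
  } else {
    lapply(seq_len(n_copies), function(i)
      steady_positions(L[i], alpha0[i] * g0[["init"]],
                       elongation_rate * g0[["elong"]], footprint))
  }
  for (i in seq_len(n_copies))
    if (length(pos[[i]]) > 1 && any(diff(pos[[i]]) < footprint))
      stop("initial snapshot violates the exclusion constraint", call. = FALSE)

  initiated <- sum(lengths(pos))
  terminated <- 0L
  term_log <- list()

  snap_at <- function(snaps, t) { snaps[[length(snaps) + 1]] <- list(time = t, pos = lapply(pos, identity)); snaps }
  snaps <- list()
  si <- 1
  if (snapshot_times[1] == 0) { snaps <- snap_at(snaps, 0); si <- 2 }

  run_det <- function() {
    t <- 0
    acc <- rep(0, n_copies)  # initiation accumulators
    while (t < t_end - 1e-12) {
      t_next <- min(t + dt, t_end,
                    if (si <= length(snapshot_times)) snapshot_times[si] else Inf)
      h <- t_next - t
      g <- gates(t)
      v <- elongation_rate * g[["elong"]]
      for (i in seq_len(n_copies)) {
        p <- pos[[i]]
        if (length(p)) {
          ## uniform advance preserves gaps; leader limited by nothing
          p <- p + v * h
          done <- p >= L[i]
          if (any(done)) {
            tt <- t + (L[i] - (p[done] - v * h)) / max(v, 1e-300)
            term_log[[length(term_log) + 1]] <<- data.frame(time = tt, copy = i)
            terminated <<- terminated + sum(done)
            p <- p[!done]
          }
          pos[[i]] <<- p
        }
        ## deterministic initiation: fire when the accumulated expected
        ## number of events reaches 1 and the first footprint is free
        acc[i] <- acc[i] + alpha0[i] * g[["init"]] * h
        while (acc[i] >= 1 &&
               (!length(pos[[i]]) || min(pos[[i]]) >= footprint)) {
          pos[[i]] <<- c(0, pos[[i]])
          initiated <<- initiated + 1L
          acc[i] <- acc[i] - 1
        }
      }
      t <- t_next
      while (si <= length(snapshot_times) &&
             snapshot_times[si] <= t + 1e-12) {
        snaps <<- snap_at(snaps, snapshot_times[si])
        si <- si + 1
      }
    }
  }

  run_stoch <- function() {
    for (i in seq_len(n_copies)) {
      t <- 0
      p <- pos[[i]]
      s_local <- si
      repeat {
        g <- gates(t)
        hop <- elongation_rate * g[["elong"]]
        a_init <- alpha0[i] * g[["init"]] *
          as.numeric(!length(p) || min(p) >= footprint)
        ## which ribosomes may hop (gap ahead > footprint, leader always)
        nr <- length(p)
        can <- if (nr) c(diff(p) >= footprint + 1, TRUE) else logical(0)
        rates <- c(a_init, rep(hop, nr) * can)
        tot <- sum(rates)
        t_ev <- if (tot > 0) t + stats::rexp(1, tot) else Inf
        while (s_local <= length(snapshot_times) &&
               snapshot_times[s_local] <= min(t_ev, t_end)) {
          snaps[[s_local]]$pos[[i]] <<- p
          s_local <- s_local + 1
        }
        if (t_ev > t_end || !is.finite(t_ev)) break
        t <- t_ev
        k <- sample.int(length(rates), 1, prob = rates)
        if (k == 1) {
          p <- c(0, p); initiated <<- initiated + 1L
        } else {
          j <- k - 1
          p[j] <- p[j] + 1
          if (p[j] >= L[i]) {
            term_log[[length(term_log) + 1]] <<- data.frame(time = t, copy = i)
            terminated <<- terminated + 1L
            p <- p[-j]
          }
        }
      }
      pos[[i]] <<- p
    }
  }

  if (mode == "deterministic") {
    run_det()
  } else {
    ## pre-create snapshot skeletons (filled per copy)
    for (k in seq(si, length.out = max(0, length(snapshot_times) - si + 1)))
      snaps[[k]] <- list(time = snapshot_times[k],
                         pos = rep(list(numeric(0)), n_copies))
    with_seed(seed, run_stoch())
  }

  term <- if (length(term_log)) do.call(rbind, term_log) else
    data.frame(time = numeric(0), copy = integer(0))
  structure(list(snapshots = snaps, mrnas = mrnas, copy_species = copy_species,
                 cds_length = L, footprint = footprint, mode = mode,
                 initiated = initiated, terminated = terminated,
                 terminations = term, t_end = t_end),
            class = "runoff_sim")
}

#' @export
print.runoff_sim <- function(x, ...) {
  last <- x$snapshots[[length(x$snapshots)]]
  cat("ribosome run-off simulation (", x$mode, "): ",
      length(x$copy_species), " mRNA copies, t_end = ", x$t_end, " s\n",
      sep = "")
  cat("  initiated:", x$initiated, " terminated:", x$terminated,
      " on-mRNA:", sum(lengths(last$pos)), "\n")
  invisible(x)
}

#' Polysome class histogram of a ribosome snapshot
#'
#' Counts mRNA copies by ribosome load: free (0 ribosomes), 80S monosome
#' (1), then n-somes up to a `>= max_class` tail.
#'
#' @param x a `runoff_sim` or a snapshot (list with `pos`).
#' @param time snapshot time to use (default: last); matched exactly.
#' @param max_class polysome classes above this load are pooled.
#' @return object of class `polysome_profile`: named integer vector of
#'   class counts with attributes.
#' @export
polysome_histogram <- function(x, time = NULL, max_class = 8) {
  stopifnot(max_class >= 3)
  pos <- if (inherits(x, "runoff_sim")) {
    times <- vapply(x$snapshots, `[[`, numeric(1), "time")
    idx <- if (is.null(time)) length(times) else match(time, times)
    if (is.na(idx)) stop("no snapshot at time ", time, call. = FALSE)
    x$snapshots[[idx]]$pos
  } else x$pos
  loads <- lengths(pos)
  cls <- pmin(loads, max_class)
  counts <- tabulate(cls + 1L, nbins = max_class + 1L)
  names(counts) <- c("free", "80S", paste0(2:(max_class - 1), "-some"),
                     paste0(">=", max_class, "-some"))
  structure(counts, total_copies = length(loads), max_class = max_class,
            class = "polysome_profile")
}

#' @export
print.polysome_profile <- function(x, ...) {
  cat("polysome profile (", attr(x, "total_copies"), " copies):\n", sep = "")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Render a pseudo-absorbance trace from a polysome profile
#'
#' Sum of Gaussian peaks, one per ribosome-containing class, centred at the
#' class's gradient position with height proportional to class count times
#' ribosomes per class (free mRNA carries no ribosome mass and no peak).
#'
#' @param profile a [polysome_histogram()] result.
#' @param peak_width Gaussian sd in gradient units (> 0).
#' @param gradient_positions positions of the classes (free, 80S, 2-some,
#'   ...) along the gradient; default `0:(n-1)`.
#' @param resolution points per gradient unit.
#' @return data.frame `position absorbance`.
#' @export
render_trace <- function(profile, peak_width = 0.15,
                         gradient_positions = NULL, resolution = 50) {
  stop_if_not_number(peak_width, "peak_width", positive = TRUE)
  n <- length(profile)
  if (is.null(gradient_positions)) gradient_positions <- seq_len(n) - 1
  stopifnot(length(gradient_positions) == n)
  load_per_class <- 0:(n - 1)  # ribosomes per class (tail class at its floor)
  xs <- seq(min(gradient_positions) - 1, max(gradient_positions) + 1,
            by = 1 / resolution)
  y <- rep(0, length(xs))
  for (k in seq_len(n)) {
    h <- as.numeric(profile[k]) * load_per_class[k]
    if (h > 0) y <- y + h * exp(-(xs - gradient_positions[k])^2 / (2 * peak_width^2))
  }
  data.frame(position = xs, absorbance = y)
}

## first local maximum above frac*max(y), in gradient order
find_monosome_peak <- function(trace, frac = 0.05) {
  y <- trace$absorbance
  if (all(y <= 0)) return(NA_real_)
  thr <- frac * max(y)
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n], FALSE)
  idx <- which(is_max & y > thr)
  if (!length(idx)) return(NA_real_)
  trace$position[idx[1]]
}

#' Zero baselines and align monosome peaks across traces
#'
#' Subtracts each trace's starting absorbance, then shifts each trace's
#' gradient coordinate so that the monosome peak (the first substantial
#' local maximum) coincides with the first trace's.
#'
#' @param traces list of data.frames `position absorbance`.
#' @param peak_frac detection threshold as a fraction of trace maximum.
#' @return list of aligned traces (same shape), with attribute `shifts`.
#' @export
align_profiles <- function(traces, peak_frac = 0.05) {
  stopifnot(is.list(traces), length(traces) >= 1)
  peaks <- vapply(seq_along(traces), function(i) {
    p <- find_monosome_peak(traces[[i]], peak_frac)
    if (is.na(p))
      stop("no detectable monosome peak in trace ", i, call. = FALSE)
    p
  }, numeric(1))
  ref <- peaks[1]
  shifts <- ref - peaks
  out <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(position = tr$position + shifts[i],
               absorbance = tr$absorbance - tr$absorbance[1])
  })
  attr(out, "shifts") <- shifts
  out
}
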