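## Translation energy-budget arithmetic: ribosome numbers x elongation rate
## x NTP cost per amino acid, related to the observed ATP depletion rate.

#' Translation energy budget
#'
#' Defaults are the standard fast-growth figures for budding yeast:
#' 1.5e5 ribosomes per cell of which 1e5 are translationally engaged,
#' mean elongation 2.6 aa/s, and a minimum of three NTPs per amino acid
#' incorporated (two GTP at the ribosome plus ATP in aminoacylation).
#' `ntp_overhead` adds unquantified initiation/termination/synthesis costs
#' on top of the minimum of 3.
#'
#' @param n_ribosomes total ribosomes per cell.
#' @param n_engaged translationally engaged ribosomes (<= n_ribosomes).
#' @param elongation_rate amino acids per second per ribosome.
#' @param ntp_per_aa NTPs consumed per amino acid (>= 3).
#' @param ntp_overhead additional NTPs per aa beyond `ntp_per_aa`.
#' @return object of class `translation_budget`.
#' @export
translation_budget <- function(n_ribosomes = 1.5e5, n_engaged = 1e5,
                               elongation_rate = 2.6, ntp_per_aa = 3,
                               ntp_overhead = 0) {
  stop_if_not_number(n_ribosomes, "n_ribosomes", nonneg = TRUE)
  stop_if_not_number(n_engaged, "n_engaged", nonneg = TRUE)
  stop_if_not_number(elongation_rate, "elongation_rate", positive = TRUE)
  stop_if_not_number(ntp_per_aa, "ntp_per_aa")
  stop_if_not_number(ntp_overhead, "ntp_overhead", nonneg = TRUE)
  if (n_engaged > n_ribosomes)
    stop("n_engaged must not exceed n_ribosomes", call. = FALSE)
  if (ntp_per_aa < 3)
    stop("ntp_per_aa below the minimum of 3", call. = FALSE)
  structure(list(n_ribosomes = n_ribosomes, n_engaged = n_engaged,
                 elongation_rate = elongation_rate,
                 ntp_per_aa = ntp_per_aa, ntp_overhead = ntp_overhead),
            class = "translation_budget")
}

#' Total amino acid incorporation rate (aa/s)
#'
#' @param budget a [translation_budget()].
#' @return `n_engaged * elongation_rate`; 2.6e5 aa/s at defaults.
#' @export
incorporation_rate <- function(budget = translation_budget()) {
  stopifnot(inherits(budget, "translation_budget"))
  budget$n_engaged * budget$elongation_rate
}

#' Elongation NTP cost (NTP/s)
#'
#' @param budget a [translation_budget()].
#' @param sig_figs optional reporting significant figures (1 gives the
#'   headline 8e5 NTP/s at defaults; raw value 7.8e5).
#' @return incorporation rate times NTPs per aa (+ overhead).
#' @export
elongation_ntp_cost <- function(budget = translation_budget(), sig_figs = NULL) {
  out <- incorporation_rate(budget) * (budget$ntp_per_aa + budget$ntp_overhead)
  if (!is.null(sig_figs)) out <- report_signif(out, sig_figs)
  out
}

#' Fraction of total NTP depletion attributable to a cost (percent)
#'
#' @param cost NTP/s consumed by the process.
#' @param total_depletion observed depletion, molecules/s (> 0).
#' @param report if TRUE, round to the nearest 5 percentage points (the
#'   reporting convention mapping 26.7% to ~25%).
#' @return percent `100 * cost / total_depletion`.
#' @export
depletion_fraction <- function(cost, total_depletion, report = FALSE) {
  stop_if_not_number(cost, "cost", nonneg = TRUE)
  stop_if_not_number(total_depletion, "total_depletion", positive = TRUE)
  out <- 100 * cost / total_depletion
  if (report) out <- round(out / 5) * 5
  out
}
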