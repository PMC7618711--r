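## Differential-affinity occupancy model: fractional nucleotide saturation
## of translation factors, competitive ADP inhibition, and active/released
## classification. Binding constants are treated as generic half-saturation
## constants (the literature mixes Km and Kd language for these factors).

#' Translation factor kinetics
#'
#' @param name factor name.
#' @param role `"initiation"` or `"elongation"`.
#' @param nucleotide cognate nucleotide, `"ATP"` or `"GTP"`.
#' @param K_nt half-saturation constant for the cognate nucleotide, in uM.
#' @param K_adp half-saturation constant for ADP (competitive inhibitor), in
#'   uM, or `NA` when no ADP constant is known for the factor.
#' @return an object of class `factor_kinetics`.
#' @export
factor_kinetics <- function(name, role = c("initiation", "elongation"),
                            nucleotide = c("ATP", "GTP"), K_nt, K_adp = NA_real_) {
  role <- match.arg(role)
  nucleotide <- match.arg(nucleotide)
  stop_if_not_number(K_nt, "K_nt", positive = TRUE)
  if (!is.na(K_adp)) stop_if_not_number(K_adp, "K_adp", positive = TRUE)
  structure(list(name = name, role = role, nucleotide = nucleotide,
                 K_nt = K_nt, K_adp = K_adp),
            class = "factor_kinetics")
}

#' Default factor table
#'
#' The four published constants used throughout: eIF4A (ATP, 540 uM; ADP,
#' 27 uM), Ded1 (ATP, 300 uM) and eEF1A (GTP, 0.14 uM). Users may extend the
#' list with further [factor_kinetics()] entries.
#'
#' @return named list of `factor_kinetics`.
#' @export
default_factors <- function() {
  list(
    eIF4A = factor_kinetics("eIF4A", "initiation", "ATP", K_nt = 540, K_adp = 27),
    Ded1  = factor_kinetics("Ded1",  "initiation", "ATP", K_nt = 300),
    eEF1A = factor_kinetics("eEF1A", "elongation", "GTP", K_nt = 0.14)
  )
}

#' Instantaneous intracellular nucleotide state (mM)
#'
#' @param ATP,ADP,AMP,GTP,CTP,UTP concentrations in mM (>= 0).
#' @return an object of class `nucleotide_state`.
#' @export
nucleotide_state <- function(ATP = 0, ADP = 0, AMP = 0, GTP = 0, CTP = 0, UTP = 0) {
  vals <- c(ATP = ATP, ADP = ADP, AMP = AMP, GTP = GTP, CTP = CTP, UTP = UTP)
  stop_if_not_number(vals, "concentrations", nonneg = TRUE)
  structure(as.list(vals), class = "nucleotide_state")
}

cognate_mM <- function(factor, state) {
  nt <- state[[factor$nucleotide]]
  if (is.null(nt)) stop("state lacks ", factor$nucleotide, call. = FALSE)
  nt
}

#' Fractional nucleotide occupancy of a factor
#'
#' Simple saturation form `[NT]/(K + [NT])` with the mM concentration
#' reconciled against the uM constant.
#'
#' @param factor a [factor_kinetics()].
#' @param state a [nucleotide_state()] (mM).
#' @return fraction in `[0, 1]`.
#' @examples
#' occupancy(default_factors()$eIF4A, nucleotide_state(ATP = 2.0))  # ~0.787
#' @export
occupancy <- function(factor, state) {
  nt_uM <- cognate_mM(factor, state) * 1e3
  stop_if_not_number(nt_uM, "concentration", nonneg = TRUE)
  nt_uM / (factor$K_nt + nt_uM)
}

#' Occupancy under competitive ADP inhibition
#'
#' Classical competitive-inhibition saturation
#' `(\[ATP\]/K_nt) / (1 + \[ATP\]/K_nt + \[ADP\]/K_adp)`; reduces to
#' [occupancy()] at ADP = 0. Only defined for factors with a known ADP
#' constant.
#'
#' @inheritParams occupancy
#' @return fraction in `[0, 1]`.
#' @export
occupancy_competitive <- function(factor, state) {
  if (is.na(factor$K_adp))
    stop("factor ", factor$name, " has no ADP constant; competitive occupancy unsupported",
         call. = FALSE)
  atp_uM <- state$ATP * 1e3
  adp_uM <- state$ADP * 1e3
  stop_if_not_number(c(atp_uM, adp_uM), "concentrations", nonneg = TRUE)
  a <- atp_uM / factor$K_nt
  a / (1 + a + adp_uM / factor$K_adp)
}

#' Classify factors as active or released at a nucleotide state
#'
#' `km_threshold` marks a factor released unless its cognate nucleotide
#' concentration strictly exceeds its half-saturation constant
#' (equivalently, active iff plain occupancy > 0.5; at the exact boundary
#' the factor counts as released). `occupancy_half` marks it released iff
#' the competitive occupancy (where an ADP constant exists, else plain
#' occupancy) is below 0.5.
#'
#' @param factors list of [factor_kinetics()].
#' @param state a [nucleotide_state()].
#' @param rule `"km_threshold"` or `"occupancy_half"`.
#' @return data.frame `name role nucleotide occupancy status`.
#' @export
classify_factors <- function(factors, state,
                             rule = c("km_threshold", "occupancy_half")) {
  rule <- match.arg(rule)
  if (!length(factors)) stop("empty factor list", call. = FALSE)
  rows <- lapply(factors, function(f) {
    occ_plain <- occupancy(f, state)
    occ <- if (rule == "occupancy_half" && !is.na(f$K_adp))
      occupancy_competitive(f, state) else occ_plain
    released <- if (rule == "km_threshold")
      cognate_mM(f, state) * 1e3 <= f$K_nt else occ < 0.5
    data.frame(name = f$name, role = f$role, nucleotide = f$nucleotide,
               occupancy = occ,
               status = if (released) "released" else "active")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ratio of binding affinities between factor groups
#'
#' Affinity ratio of `a` over `b` computed on half-saturation constants:
#' K(a)/K(b), optionally with `a` and/or `b` given as a set whose constants
#' are aggregated by geometric mean. The initiation ATPases (540, 300 uM)
#' against eEF1A (0.14 uM) give ~2.9e3, reported as ~3,000-fold.
#'
#' @param a,b a [factor_kinetics()] or list of them.
#' @param aggregation `"single"` (first element) or `"geometric_mean_set"`.
#' @param report if TRUE, round to the nearest 1,000.
#' @return fold ratio.
#' @export
affinity_ratio <- function(a, b, aggregation = c("geometric_mean_set", "single"),
                           report = FALSE) {
  aggregation <- match.arg(aggregation)
  kset <- function(x) {
    if (inherits(x, "factor_kinetics")) x <- list(x)
    vapply(x, function(f) f$K_nt, numeric(1))
  }
  agg <- function(k) if (aggregation == "single") k[[1]] else exp(mean(log(k)))
  out <- agg(kset(a)) / agg(kset(b))
  if (report) out <- round(out / 1000) * 1000
  out
}
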