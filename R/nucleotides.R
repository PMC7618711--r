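## Nucleotide quantification: unit conversion from HPLC output
## (pmol per 1e8 cells) to intracellular concentrations and per-cell
## molecule counts, plus depletion statistics.

NT_SPECIES <- c("ATP", "ADP", "AMP", "GTP", "CTP", "UTP")

#' Haploid yeast cell model for concentration estimation
#'
#' The soluble volume of a cell is estimated by subtracting dry mass from
#' wet mass and converting the soluble mass to volume at the given density.
#' Defaults are the standard haploid budding-yeast figures: wet mass
#' 60e-12 g, dry mass 15e-12 g, density 1 g/mL, giving a soluble volume of
#' 4.5e-14 L/cell.
#'
#' @param wet_mass wet mass per cell, grams.
#' @param dry_mass dry mass per cell, grams.
#' @param density density of the soluble fraction, g/mL.
#' @return an object of class `cell_model`.
#' @examples
#' soluble_volume(cell_model())  # 4.5e-14 L
#' @export
cell_model <- function(wet_mass = 60e-12, dry_mass = 15e-12, density = 1) {
  stop_if_not_number(wet_mass, "wet_mass", positive = TRUE)
  stop_if_not_number(dry_mass, "dry_mass", positive = TRUE)
  stop_if_not_number(density, "density", positive = TRUE)
  if (wet_mass <= dry_mass)
    stop("invalid cell model: wet_mass must exceed dry_mass", call. = FALSE)
  structure(list(wet_mass = wet_mass, dry_mass = dry_mass, density = density,
                 avogadro = AVOGADRO),
            class = "cell_model")
}

#' Soluble volume of a cell
#'
#' @param cell a [cell_model()].
#' @return soluble volume in liters per cell: `(wet - dry)/density`
#'   (g / (g/mL) = mL, converted to L).
#' @export
soluble_volume <- function(cell = cell_model()) {
  stopifnot(inherits(cell, "cell_model"))
  mass <- cell$wet_mass - cell$dry_mass       # g of soluble fraction
  if (mass <= 0) stop("invalid cell model: non-positive soluble mass", call. = FALSE)
  mass / cell$density * 1e-3                  # mL -> L
}

#' Convert pmol per 1e8 cells to intracellular concentration (mM)
#'
#' `amount` pmol per 1e8 cells corresponds to `amount * 1e-12 / 1e8` mol per
#' cell; dividing by the soluble volume gives mol/L, reported in mM.
#'
#' @param amount pmol per 1e8 cells (vectorised, must be >= 0).
#' @param volume soluble volume in L per cell.
#' @return concentration in mM.
#' @export
pmol_to_mM <- function(amount, volume = soluble_volume()) {
  stop_if_not_number(amount, "amount", nonneg = TRUE)
  stop_if_not_number(volume, "volume", positive = TRUE)
  mol_per_cell <- amount * 1e-12 / 1e8
  mol_per_cell / volume * 1e3
}

#' Inverse of [pmol_to_mM()]
#' @param conc_mM concentration in mM.
#' @inheritParams pmol_to_mM
#' @return pmol per 1e8 cells.
#' @export
mM_to_pmol <- function(conc_mM, volume = soluble_volume()) {
  stop_if_not_number(conc_mM, "conc_mM", nonneg = TRUE)
  stop_if_not_number(volume, "volume", positive = TRUE)
  conc_mM * 1e-3 * volume * 1e8 / 1e-12
}

#' Molecules per cell from mol per cell
#'
#' @param mol mol per cell (>= 0).
#' @param sig_figs if non-NULL, round the result to this many significant
#'   figures for reporting (headline convention: 1).
#' @return molecule count.
#' @examples
#' molecules_per_cell(1.7e-16, sig_figs = 1)  # ~1e8
#' @export
molecules_per_cell <- function(mol, sig_figs = NULL) {
  stop_if_not_number(mol, "mol", nonneg = TRUE)
  out <- mol * AVOGADRO
  if (!is.null(sig_figs)) out <- report_signif(out, sig_figs)
  out
}

#' Depletion rate in molecules per second
#'
#' @param pool_before,pool_after pool sizes in molecules.
#' @param dt elapsed time, seconds (> 0).
#' @param sig_figs optional reporting significant figures.
#' @return `(pool_before - pool_after)/dt`; negative for accumulation.
#' @export
depletion_rate <- function(pool_before, pool_after, dt, sig_figs = NULL) {
  stop_if_not_number(pool_before, "pool_before")
  stop_if_not_number(pool_after, "pool_after")
  stop_if_not_number(dt, "dt", positive = TRUE)
  out <- (pool_before - pool_after) / dt
  if (!is.null(sig_figs)) out <- report_signif(out, sig_figs)
  out
}

#' Fold change of a concentration drop
#'
#' @param before,after concentrations in mM. `after` values of 0 are flagged
#'   as below detection (`NA` with a `"censored"` attribute) rather than
#'   returned as infinite folds.
#' @param report if TRUE, round to the nearest integer fold.
#' @return `before/after`.
#' @export
fold_change <- function(before, after, report = FALSE) {
  stop_if_not_number(before, "before", nonneg = TRUE)
  stop_if_not_number(after, "after", nonneg = TRUE)
  out <- ifelse(after == 0, NA_real_, before / after)
  if (report) out <- round(out)
  if (any(after == 0)) attr(out, "censored") <- which(after == 0)
  out
}

#' Pointwise ADP:ATP ratio time course
#'
#' @param adp,atp numeric vectors of matched concentrations (mM), or two
#'   rows of a concentration series on identical time grids.
#' @param time_s optional shared time grid (checked for equality when both
#'   series carry one).
#' @return numeric vector `adp/atp`.
#' @export
adp_atp_ratio <- function(adp, atp, time_s = NULL) {
  stop_if_not_number(adp, "adp", nonneg = TRUE)
  stop_if_not_number(atp, "atp", positive = TRUE)
  if (length(adp) != length(atp))
    stop("alignment error: ADP and ATP series differ in length", call. = FALSE)
  adp / atp
}

#' Validate a nucleotide measurement table
#'
#' Expected columns: `species`, `condition`, `time_s`, `replicate`,
#' `pmol_per_1e8_cells` (the HPLC output convention).
#'
#' @param x data.frame.
#' @return `x`, invisibly, after validation.
#' @export
validate_measurements <- function(x) {
  need <- c("species", "condition", "time_s", "replicate", "pmol_per_1e8_cells")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!all(x$species %in% NT_SPECIES))
    stop("unknown species: ",
         paste(unique(setdiff(x$species, NT_SPECIES)), collapse = ", "),
         call. = FALSE)
  stop_if_not_number(x$time_s, "time_s", nonneg = TRUE)
  stop_if_not_number(x$pmol_per_1e8_cells, "pmol_per_1e8_cells", nonneg = TRUE)
  key <- paste(x$species, x$condition, x$time_s, x$replicate)
  if (anyDuplicated(key))
    stop("duplicated (species, condition, time_s, replicate) rows", call. = FALSE)
  invisible(x)
}

#' Aggregate measurements into a concentration time course
#'
#' Converts each measurement to mM via the cell model and aggregates
#' replicates at each (species, condition, time) by the mean (the figure
#' convention for triplicate time courses), with the sd and n retained.
#'
#' @param x measurement table (see [validate_measurements()]).
#' @param cell a [cell_model()].
#' @return data.frame `species condition time_s mean_mM sd_mM n`, ordered by
#'   species, condition and strictly increasing time.
#' @export
concentration_series <- function(x, cell = cell_model()) {
  validate_measurements(x)
  vol <- soluble_volume(cell)
  x$mM <- pmol_to_mM(x$pmol_per_1e8_cells, vol)
  agg <- aggregate(mM ~ species + condition + time_s, data = x,
                   FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  out <- data.frame(species = agg$species, condition = agg$condition,
                    time_s = agg$time_s,
                    mean_mM = agg$mM[, "mean"], sd_mM = agg$mM[, "sd"],
                    n = as.integer(agg$mM[, "n"]))
  out <- out[order(out$species, out$condition, out$time_s), ]
  rownames(out) <- NULL
  out
}

#' Read / write nucleotide tables
#'
#' Plain TSV with the measurement or series header.
#' @param path file path.
#' @return `read_ntp_table`: a validated data.frame.
#' @export
read_ntp_table <- function(path) {
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_measurements(x)
  x
}

#' @param x table to write.
#' @rdname read_ntp_table
#' @export
write_ntp_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
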