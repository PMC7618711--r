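## Nascent-proteome (AHA labelling) analysis stage: presence filtering,
## median-centring normalisation, left-censored MinProb imputation,
## differential-enrichment flags, and z-scored k-means clustering with
## cross-modal summaries.

#' Intensity matrix container
#'
#' @param intensities numeric matrix of log2 intensities, proteins x
#'   samples; NA marks missing values.
#' @param fraction per-sample `"input"` or `"eluate"`.
#' @param label per-sample `"AHA"` or `"control"`.
#' @param condition per-sample condition (e.g. glucose / no_glucose).
#' @param replicate per-sample replicate id.
#' @return object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(intensities, fraction, label, condition, replicate) {
  intensities <- as.matrix(intensities)
  if (any(!is.finite(intensities) & !is.na(intensities)))
    stop("intensities must be finite where present", call. = FALSE)
  n <- ncol(intensities)
  stopifnot(length(fraction) == n, length(label) == n,
            length(condition) == n, length(replicate) == n)
  structure(list(intensities = intensities,
                 fraction = as.character(fraction),
                 label = as.character(label),
                 condition = as.character(condition),
                 replicate = as.character(replicate),
                 imputed = matrix(FALSE, nrow(intensities), n,
                                  dimnames = dimnames(intensities))),
            class = "intensity_matrix")
}

#' Presence filter for reliably quantified proteins
#'
#' Retains proteins with no missing value across all labelled eluate
#' samples of at least one condition (the nascent-proteome reliability
#' rule).
#'
#' @param m an [intensity_matrix()].
#' @return filtered `intensity_matrix`.
#' @export
filter_quantified <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  sel <- m$fraction == "eluate" & m$label == "AHA"
  if (!any(sel))
    stop("no labelled eluate samples present", call. = FALSE)
  conds <- unique(m$condition[sel])
  keep <- rep(FALSE, nrow(m$intensities))
  for (cond in conds) {
    cols <- which(sel & m$condition == cond)
    keep <- keep | rowSums(is.na(m$intensities[, cols, drop = FALSE])) == 0
  }
  subset_proteins(m, keep)
}

subset_proteins <- function(m, keep) {
  m$intensities <- m$intensities[keep, , drop = FALSE]
  m$imputed <- m$imputed[keep, , drop = FALSE]
  m
}

#' Median-centring normalisation
#'
#' Subtracts each sample's median observed log2 intensity and adds back the
#' first sample's median (the reference), so all sample medians coincide
#' and within-sample rank order is preserved; a constant offset applied to
#' any non-reference sample is removed exactly. This is the package's
#' declared stand-in for variance-stabilising normalisation: the
#' affine-noise variance model is not re-derived, so results are not
#' claimed identical to a VSN fit.
#'
#' @param m an [intensity_matrix()].
#' @param reference index of the sample whose median becomes the common
#'   location (default 1).
#' @return normalised `intensity_matrix`.
#' @export
normalize_median <- function(m, reference = 1L) {
  stopifnot(inherits(m, "intensity_matrix"))
  meds <- apply(m$intensities, 2, stats::median, na.rm = TRUE)
  m$intensities <- sweep(m$intensities, 2, meds - meds[reference], "-")
  m
}

#' Left-censored MinProb imputation
#'
#' Missing values are assumed missing-not-at-random (censored at the
#' detection limit): each missing cell is drawn from a Gaussian centred at
#' its sample's `q` quantile of observed intensities, with sd equal to
#' `scale` times the median per-protein sd of observed values. Imputed
#' cells are flagged; output is reproducible given the seed.
#'
#' @param m an [intensity_matrix()].
#' @param q quantile of the observed distribution used as centre
#'   (default 0.01).
#' @param scale sd multiplier (default 1).
#' @param seed RNG seed.
#' @return imputed `intensity_matrix` with updated `imputed` flags.
#' @export
minprob_impute <- function(m, q = 0.01, scale = 1, seed = NULL) {
  stopifnot(inherits(m, "intensity_matrix"))
  x <- m$intensities
  prot_sd <- apply(x, 1, stats::sd, na.rm = TRUE)
  spread <- scale * stats::median(prot_sd, na.rm = TRUE)
  if (!is.finite(spread) || spread <= 0) spread <- 0.3
  with_seed(seed, {
    for (j in seq_len(ncol(x))) {
      obs <- x[, j][!is.na(x[, j])]
      if (!length(obs))
        stop("sample ", j, " has no observed values", call. = FALSE)
      miss <- which(is.na(x[, j]))
      if (length(miss)) {
        centre <- stats::quantile(obs, q, names = FALSE)
        x[miss, j] <- stats::rnorm(length(miss), centre, spread)
        m$imputed[miss, j] <- TRUE
      }
    }
  })
  m$intensities <- x
  m
}

#' Differential-enrichment flags (Welch t + BH stand-in)
#'
#' Per-protein log2 fold change and Welch t-test between the two sides of a
#' contrast, Benjamini-Hochberg adjusted; a protein is flagged when
#' `|FC| > fc_threshold` and `FDR <= fdr`. This is a deliberate stand-in
#' for moderated / local-FDR statistics: shrinkage is package-version
#' dependent and is not reproduced. Proteins with degenerate variance in
#' both groups are marked untestable rather than silently passed.
#'
#' @param m an [intensity_matrix()] (log2 scale, imputation done).
#' @param contrast list with `cols1` and `cols2`: column indices (or a
#'   logical/selector) for the two sides; log2FC is side 2 minus side 1.
#' @param fc_threshold linear fold-change gate (default 1.5).
#' @param fdr FDR gate, inclusive (default 0.05).
#' @return data.frame `id log2FC PValue FDR flagged untestable`.
#' @export
differential <- function(m, contrast, fc_threshold = 1.5, fdr = 0.05) {
  stopifnot(inherits(m, "intensity_matrix"))
  x1 <- m$intensities[, contrast$cols1, drop = FALSE]
  x2 <- m$intensities[, contrast$cols2, drop = FALSE]
  if (ncol(x1) < 2 || ncol(x2) < 2)
    stop("need >= 2 replicates on each side of the contrast", call. = FALSE)
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- apply(x1, 1, stats::var, na.rm = TRUE)
  v2 <- apply(x2, 1, stats::var, na.rm = TRUE)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  untestable <- !is.finite(tstat) | !is.finite(df) | n1 < 2 | n2 < 2
  pval <- rep(NA_real_, length(tstat))
  ok <- !untestable
  pval[ok] <- 2 * stats::pt(-abs(tstat[ok]), df[ok])
  padj <- rep(NA_real_, length(pval))
  padj[ok] <- stats::p.adjust(pval[ok], "BH")
  lfc <- m2 - m1
  flagged <- ok & abs(lfc) > log2(fc_threshold) & padj <= fdr
  flagged[is.na(flagged)] <- FALSE
  ids <- rownames(m$intensities)
  if (is.null(ids)) ids <- paste0("row", seq_along(lfc))
  data.frame(id = ids, log2FC = lfc, PValue = pval,
             FDR = padj, flagged = flagged, untestable = untestable,
             row.names = NULL)
}

## k-means++ style seeding: first centre uniform, then proportional to
## squared distance to the nearest chosen centre.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) idx <- sample.int(n, 1)
    else idx <- sample.int(n, 1, prob = d2)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' Row z-scoring followed by seeded k-means clustering
#'
#' Each protein's profile over the sample-class medians is z-scored (mean
#' 0, sd 1 across the row) and k-means clustered with `n_init` restarts of
#' k-means++ seeding; the restart with the lowest total within-cluster sum
#' of squares wins. Deterministic given the seed.
#'
#' @param medians numeric matrix, proteins x sample classes (e.g. median
#'   intensities of input/eluate by condition).
#' @param k number of clusters (default 4).
#' @param seed RNG seed.
#' @param n_init number of seeded restarts (default 50).
#' @return object of class `cluster_result`: list with `cluster` (named
#'   integer vector), `centers` (k x classes, on z-scores), `tot_withinss`,
#'   and the z-scored matrix.
#' @export
zscore_kmeans <- function(medians, k = 4, seed = NULL, n_init = 50) {
  medians <- as.matrix(medians)
  if (k > nrow(medians))
    stop("k exceeds number of proteins", call. = FALSE)
  mu <- rowMeans(medians)
  sd_ <- apply(medians, 1, stats::sd)
  sd_[sd_ == 0] <- 1   # flat profiles z-score to all-zero rows
  z <- (medians - mu) / sd_
  best <- NULL
  with_seed(seed, {
    for (i in seq_len(n_init)) {
      cen <- kmeanspp_centers(z, k)
      fit <- suppressWarnings(stats::kmeans(z, centers = cen, iter.max = 100))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  structure(list(cluster = stats::setNames(best$cluster, rownames(medians)),
                 centers = best$centers, tot_withinss = best$tot.withinss,
                 z = z, k = k),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("k-means clustering (k =", x$k, ") of", length(x$cluster), "proteins\n")
  print(table(x$cluster))
  invisible(x)
}

#' Per-cluster cross-modal fold-change summary
#'
#' Joins per-feature fold changes from RNA-seq, binding and protein
#' intensity by shared id and summarises them per cluster (mean of each
#' modality; missing cross-modal entries tolerated), plus the overlap of
#' each cluster with a provided top-induced set.
#'
#' @param clusters a [zscore_kmeans()] result.
#' @param rnaseq_fc,binding_fc,protein_fc named numeric vectors of log2
#'   fold changes keyed by feature id (any may be missing entries).
#' @param induced_set character vector of top-induced feature ids.
#' @return list with `summary` (per-cluster data.frame) and `joined`
#'   (per-protein table).
#' @export
crossmodal_summary <- function(clusters, rnaseq_fc = NULL, binding_fc = NULL,
                               protein_fc = NULL, induced_set = character(0)) {
  stopifnot(inherits(clusters, "cluster_result"))
  ids <- names(clusters$cluster)
  joined <- data.frame(id = ids, cluster = as.integer(clusters$cluster),
                       rnaseq_log2FC = if (is.null(rnaseq_fc)) NA_real_ else
                         unname(rnaseq_fc[ids]),
                       binding_log2FC = if (is.null(binding_fc)) NA_real_ else
                         unname(binding_fc[ids]),
                       protein_log2FC = if (is.null(protein_fc)) NA_real_ else
                         unname(protein_fc[ids]),
                       induced = ids %in% induced_set,
                       row.names = NULL)
  per <- lapply(split(joined, joined$cluster), function(d) data.frame(
    cluster = d$cluster[1], n = nrow(d),
    mean_rnaseq_log2FC = mean(d$rnaseq_log2FC, na.rm = TRUE),
    mean_binding_log2FC = mean(d$binding_log2FC, na.rm = TRUE),
    mean_protein_log2FC = mean(d$protein_log2FC, na.rm = TRUE),
    n_induced = sum(d$induced),
    pct_of_induced_set = if (length(induced_set))
      100 * sum(d$induced) / length(induced_set) else 0))
  list(summary = do.call(rbind, per), joined = joined)
}
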