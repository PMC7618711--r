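## Independent oracles used across tests.

## Literal reapplication of the written binding-pipeline rules on a toy
## table, kept deliberately brute-force and separate from the package code.
brute_force_binding <- function(rpm_mat, condition_of_col, reference,
                                threshold = 0.5, min_reps = 2,
                                pseudocount = 0.5) {
  conds <- unique(condition_of_col)
  med <- matrix(NA_real_, nrow(rpm_mat), length(conds),
                dimnames = list(rownames(rpm_mat), conds))
  detected <- med
  for (cond in conds) {
    cols <- which(condition_of_col == cond)
    for (i in seq_len(nrow(rpm_mat))) {
      vals <- rpm_mat[i, cols]
      n_ok <- sum(vals >= threshold)
      detected[i, cond] <- as.numeric(n_ok >= min_reps)
      med[i, cond] <- stats::median(vals)
    }
  }
  keep <- detected[, reference] == 1
  med <- med[keep, , drop = FALSE]
  detected <- detected[keep, , drop = FALSE]
  imputed <- detected * 0
  for (cond in setdiff(conds, reference)) {
    for (i in seq_len(nrow(med))) {
      if (detected[i, cond] == 0) {
        med[i, cond] <- pseudocount
        imputed[i, cond] <- 1
      } else if (detected[i, cond] == 0) med[i, cond] <- NA
    }
  }
  for (cond in conds) med[detected[, cond] == 0 & imputed[, cond] == 0, cond] <- NA
  list(rpm = med, imputed = imputed == 1)
}

## Exhaustive CTMC for the small exclusion-process case: enumerate all
## ribosome configurations on an L-codon CDS with the footprint constraint,
## build the generator matrix for (initiation, hop, termination) moves, and
## exponentiate to get the load-class distribution at time t.
ctmc_load_distribution <- function(L, footprint, alpha, hop, t_end) {
  states <- list(numeric(0))
  grow <- function(cfg) {
    last <- if (length(cfg)) cfg[length(cfg)] + footprint else 0
    if (last > L - 1) return(list())
    lapply(last:(L - 1), function(p) c(cfg, p))
  }
  frontier <- list(numeric(0))
  while (length(frontier)) {
    nxt <- list()
    for (cfg in frontier) nxt <- c(nxt, grow(cfg))
    states <- c(states, nxt)
    frontier <- nxt
  }
  key <- vapply(states, paste, "", collapse = ",")
  idx <- function(cfg) match(paste(cfg, collapse = ","), key)
  n <- length(states)
  Q <- matrix(0, n, n)
  for (s in seq_len(n)) {
    cfg <- states[[s]]
    ## initiation at codon 0 when the first footprint is free
    if (!length(cfg) || cfg[1] >= footprint) {
      to <- idx(c(0, cfg))
      Q[s, to] <- Q[s, to] + alpha
    }
    ## hops (ribosomes sorted ascending; last is the leader)
    for (j in seq_along(cfg)) {
      newpos <- cfg[j] + 1
      if (j < length(cfg) && cfg[j + 1] - newpos < footprint) next
      ncfg <- if (newpos >= L) cfg[-j] else { tmp <- cfg; tmp[j] <- newpos; tmp }
      to <- idx(ncfg)
      Q[s, to] <- Q[s, to] + hop
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  p0 <- numeric(n); p0[idx(numeric(0))] <- 1
  pt <- as.numeric(p0 %*% as.matrix(Matrix::expm(Q * t_end)))
  loads <- lengths(states)
  tapply(pt, loads, sum)
}

## small toy count table builder
toy_count_table <- function(counts, condition, lib = NULL, assay = "CRAC") {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  count_table(counts, library_size = lib, assay = assay,
              condition = condition,
              replicate = stats::ave(condition, condition, FUN = seq_along))
}
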