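## minimal intensity matrix: 2 conditions x (input, eluate) x (AHA, control)
toy_intensity <- function(x, reps = 3) {
  classes <- expand.grid(replicate = seq_len(reps),
                         condition = c("glucose", "no_glucose"),
                         fraction = c("input", "eluate"),
                         label = c("AHA", "control"),
                         stringsAsFactors = FALSE)
  intensity_matrix(x, fraction = classes$fraction, label = classes$label,
                   condition = classes$condition, replicate = classes$replicate)
}

test_that("presence filter requires complete labelled eluates in one condition", {
  x <- matrix(20, 3, 24, dimnames = list(paste0("p", 1:3), NULL))
  m0 <- toy_intensity(x)
  elu_glu <- which(m0$fraction == "eluate" & m0$label == "AHA" &
                     m0$condition == "glucose")
  elu_ng <- which(m0$fraction == "eluate" & m0$label == "AHA" &
                    m0$condition == "no_glucose")
  ## p1 complete everywhere; p2 complete only in no-glucose eluates;
  ## p3 missing one eluate sample in each condition
  x[2, elu_glu[1]] <- NA
  x[2, which(m0$fraction == "input")[1]] <- NA
  x[3, elu_glu[1]] <- NA
  x[3, elu_ng[1]] <- NA
  m <- toy_intensity(x)
  kept <- rownames(filter_quantified(m)$intensities)
  expect_equal(kept, c("p1", "p2"))
  ## fully observed matrix unchanged
  full <- toy_intensity(matrix(20, 3, 24, dimnames = list(paste0("p", 1:3), NULL)))
  expect_equal(filter_quantified(full)$intensities, full$intensities)
  ## monotone: adding an observation never removes a protein
  x2 <- x; x2[3, elu_ng[1]] <- 20
  kept2 <- rownames(filter_quantified(toy_intensity(x2))$intensities)
  expect_true(all(kept %in% kept2))
})

test_that("median centring equalises sample medians and undoes shifts", {
  set.seed(1)
  x <- matrix(rnorm(50 * 24, 25, 2), 50, 24,
              dimnames = list(paste0("p", 1:50), NULL))
  m <- toy_intensity(x)
  norm <- normalize_median(m)
  meds <- apply(norm$intensities, 2, median)
  expect_equal(unname(meds), rep(meds[1], 24))
  ## already median-equal matrix unchanged
  norm2 <- normalize_median(norm)
  expect_equal(norm2$intensities, norm$intensities)
  ## adding a constant to one sample is exactly undone
  shifted <- m
  shifted$intensities[, 3] <- shifted$intensities[, 3] + 1.7
  expect_equal(normalize_median(shifted)$intensities[, 3],
               norm$intensities[, 3])
  ## rank order preserved within samples
  expect_equal(order(norm$intensities[, 5]), order(x[, 5]))
})

test_that("MinProb imputation is seeded, left-censored and leaves data alone", {
  set.seed(2)
  ## realistic structure: proteins differ in baseline (sd 2 between rows),
  ## replicate noise within a protein is small (sd 0.3)
  base <- rnorm(200, 25, 2)
  x <- matrix(base + rnorm(200 * 8, 0, 0.3), 200, 8,
              dimnames = list(paste0("p", 1:200), NULL))
  x[sample(length(x), 150)] <- NA
  m <- intensity_matrix(x, fraction = rep("eluate", 8), label = rep("AHA", 8),
                        condition = rep(c("glucose", "no_glucose"), each = 4),
                        replicate = rep(1:4, 2))
  i1 <- minprob_impute(m, seed = 42)
  i2 <- minprob_impute(m, seed = 42)
  expect_identical(i1$intensities, i2$intensities)
  expect_false(any(is.na(i1$intensities)))
  obs <- !is.na(x)
  expect_equal(i1$intensities[obs], x[obs])
  expect_equal(i1$imputed, is.na(x))
  ## no missing values: unchanged regardless of seed
  full <- intensity_matrix(matrix(20, 4, 8), rep("eluate", 8), rep("AHA", 8),
                           rep("g", 8), 1:8)
  expect_equal(minprob_impute(full, seed = 1)$intensities, full$intensities)
  ## imputed values sit below each sample's median essentially always
  for (j in 1:8) {
    imp <- i1$intensities[i1$imputed[, j], j]
    if (length(imp))
      expect_gt(mean(imp < median(x[, j], na.rm = TRUE)), 0.99)
  }
})

test_that("imputation draws centre on the low quantile of observed values", {
  set.seed(3)
  x <- matrix(rnorm(5000, 25, 2), 5000, 2)
  x[1:4000, 2] <- NA   # many draws from one sample's censoring model
  m <- intensity_matrix(x, rep("eluate", 2), rep("AHA", 2), rep("g", 2), 1:2)
  imp <- minprob_impute(m, q = 0.01, scale = 1, seed = 9)
  draws <- imp$intensities[imp$imputed[, 2], 2]
  centre <- quantile(x[!is.na(x[, 2]), 2], 0.01, names = FALSE)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - centre), 3 * se)
})

test_that("differential flags need both the FC gate and the FDR gate", {
  set.seed(4)
  n <- 100
  x1 <- matrix(rnorm(n * 3, 24, 0.2), n, 3)
  x2 <- matrix(rnorm(n * 3, 24, 0.2), n, 3)
  spike <- 1:30
  x2[spike, ] <- x2[spike, ] + 2           # log2FC = 2 at n = 3/3, sd 0.2
  near <- 31:50
  ## exact 1.4-fold shift of the same draws: tiny p, FC below the 1.5 gate
  x2[near, ] <- x1[near, ] + log2(1.4)
  x <- cbind(x1, x2)
  rownames(x) <- paste0("p", 1:n)
  m <- intensity_matrix(x, rep("eluate", 6), rep("AHA", 6),
                        rep(c("glucose", "no_glucose"), each = 3),
                        rep(1:3, 2))
  de <- differential(m, list(cols1 = 1:3, cols2 = 4:6))
  expect_gt(mean(de$flagged[spike]), 0.95)
  expect_false(any(de$flagged[near]))      # tiny p but FC below gate
  ## per-protein p-values agree with the reference Welch implementation
  p_oracle <- vapply(seq_len(n), function(i)
    stats::t.test(x[i, 4:6], x[i, 1:3])$p.value, numeric(1))
  expect_equal(de$PValue, p_oracle, tolerance = 1e-10)
  ## identical groups -> nothing flagged
  m0 <- intensity_matrix(cbind(x1, x1), rep("eluate", 6), rep("AHA", 6),
                         rep(c("a", "b"), each = 3), rep(1:3, 2))
  expect_equal(sum(differential(m0, list(cols1 = 1:3, cols2 = 4:6))$flagged), 0)
  ## degenerate variance is marked untestable
  xc <- x; xc[1, ] <- 24
  mc <- intensity_matrix(xc, rep("eluate", 6), rep("AHA", 6),
                         rep(c("a", "b"), each = 3), rep(1:3, 2))
  dc <- differential(mc, list(cols1 = 1:3, cols2 = 4:6))
  expect_true(dc$untestable[1])
  expect_false(dc$flagged[1])
  expect_error(differential(m, list(cols1 = 1, cols2 = 2:6)), ">= 2")
})

test_that("z-scored k-means recovers separated blobs and honours invariances", {
  skip_if_not_installed("mclust")
  set.seed(5)
  n <- 120
  truth <- rep(1:2, each = n / 2)
  base <- matrix(rnorm(n * 4, 0, 0.3), n, 4)
  base[truth == 1, ] <- base[truth == 1, ] + matrix(rep(c(2, 2, -2, -2), each = n / 2), n / 2, 4)
  base[truth == 2, ] <- base[truth == 2, ] + matrix(rep(c(-2, 2, 2, -2), each = n / 2), n / 2, 4)
  rownames(base) <- paste0("p", 1:n)
  cl <- zscore_kmeans(base, k = 2, seed = 6, n_init = 20)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, truth), 1)
  ## z-scored rows have mean 0, sd 1
  expect_equal(unname(rowMeans(cl$z)), rep(0, n), tolerance = 1e-12)
  expect_equal(unname(apply(cl$z, 1, sd)), rep(1, n), tolerance = 1e-12)
  ## duplicating every row leaves centroids unchanged (up to label order)
  dup <- rbind(base, base)
  rownames(dup) <- paste0("q", seq_len(2 * n))
  cl2 <- zscore_kmeans(dup, k = 2, seed = 6, n_init = 20)
  match_order <- function(a, b) {
    d <- as.matrix(dist(rbind(a, b)))[seq_len(nrow(a)), nrow(a) + seq_len(nrow(b))]
    apply(d, 1, which.min)
  }
  expect_equal(unname(cl$centers), unname(cl2$centers[match_order(cl$centers, cl2$centers), ]),
               tolerance = 1e-8)
  ## determinism under seed
  expect_identical(zscore_kmeans(base, k = 2, seed = 6, n_init = 5)$cluster,
                   zscore_kmeans(base, k = 2, seed = 6, n_init = 5)$cluster)
  expect_error(zscore_kmeans(base[1:3, ], k = 4), "exceeds")
})

test_that("cross-modal summaries join by id and count induced overlap", {
  cl <- structure(list(cluster = stats::setNames(c(1L, 1L, 2L, 3L, 3L, 3L),
                                                 paste0("p", 1:6)),
                       centers = matrix(0, 3, 2), tot_withinss = 0,
                       z = matrix(0, 6, 2), k = 3),
                  class = "cluster_result")
  rn <- stats::setNames(c(1, 2, 3, -1, -2, 0), paste0("p", 1:6))
  bd <- stats::setNames(c(0.5, 0.5, 1, 1, -1, -1), paste0("p", 1:6))
  pr <- stats::setNames(c(2, 0, 1, 0, -1, 1), paste0("p", 1:6))
  out <- crossmodal_summary(cl, rn, bd, pr, induced_set = c("p1", "p3", "p9", "p10"))
  expect_equal(out$summary$n, c(2L, 1L, 3L))
  expect_equal(out$summary$mean_rnaseq_log2FC, c(1.5, 3, -1))
  expect_equal(out$summary$n_induced, c(1L, 1L, 0L))
  expect_equal(out$summary$pct_of_induced_set, c(25, 25, 0))
  ## empty induced set -> all overlaps zero
  out0 <- crossmodal_summary(cl, rn, bd, pr, induced_set = character(0))
  expect_true(all(out0$summary$n_induced == 0))
  ## hand-joined check
  expect_equal(out$joined$binding_log2FC, unname(bd))
})
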