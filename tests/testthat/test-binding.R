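test_that("RPM and RPKM normalisation follow the unit definitions", {
  counts <- matrix(c(1, 0, 10, 100), 4, 1,
                   dimnames = list(paste0("g", 1:4), "s1"))
  r <- rpm(counts, library_size = 2e6)
  expect_equal(unname(r[1, 1]), 0.5)   # ~1 count at the 2e6 library scale
  expect_equal(unname(r[2, 1]), 0)
  r2 <- rpm(counts[, 1, drop = FALSE], library_size = 1e6)
  expect_equal(unname(r2[3, 1]), 10)
  ann <- data.frame(id = paste0("g", 1:4), biotype = "protein_coding; exon",
                    length_nt = c(1000, 1000, 500, 1000))
  rk <- rpkm(counts, ann, library_size = 1e6)
  expect_equal(unname(rk[4, 1]), 100)
  expect_equal(unname(rk[3, 1]), unname(r2[3, 1]) / 0.5)  # length 500 doubles
  expect_equal(unname(rk[2, 1]), 0)
  ## linearity and identity rpkm = rpm/(len/1000)
  expect_equal(rpm(2 * counts, library_size = 1e6),
               2 * rpm(counts, library_size = 1e6))
  expect_equal(rk, rpm(counts, 1e6) / (ann$length_nt / 1000))
  expect_error(rpm(counts, library_size = 0), "library")
  expect_error(rpkm(counts, ann[1:2, ], library_size = 1e6), "length")
})

test_that("CPM filter applies both thresholds with the smallest-group rule", {
  lib <- 1e6
  counts <- rbind(g1 = c(16, 16, 16, 16), g2 = c(0, 0, 0, 0),
                  g3 = c(25, 25, 25, 25), g4 = c(30, 30, 4, 4))
  ct <- toy_count_table(counts, condition = c("a", "a", "b", "b"),
                        lib = rep(lib, 4))
  keep <- cpm_filter(ct)
  expect_false("g1" %in% keep)  # mean 16 fails overall > 20
  expect_false("g2" %in% keep)
  expect_true("g3" %in% keep)
  ## g4: per-sample >15 in 2 samples (= smallest group), mean 17 < 20
  expect_false("g4" %in% keep)
  keep2 <- cpm_filter(ct, per_sample = 15, overall = 15)
  expect_true("g4" %in% keep2)
})

test_that("replicate-median detection follows the written rule", {
  ## counts chosen so the RPM rows are {0.6,0.7,0}, {0.4,0.4,0.4},
  ## {0.6,0.3,0.3} at a 2e7 library
  cc <- count_table(rbind(g1 = c(12, 14, 0), g2 = c(8, 8, 8),
                          g3 = c(12, 6, 6)),
                    library_size = rep(2e7, 3),
                    condition = rep("glucose", 3), replicate = 1:3)
  bt <- median_binding(cc)
  expect_true(bt$detected["g1", "glucose"])
  expect_equal(bt$rpm["g1", "glucose"], 0.6)
  expect_false(bt$detected["g2", "glucose"])   # all 0.4 < 0.5
  expect_false(bt$detected["g3", "glucose"])   # only one rep >= 0.5
  expect_true(is.na(bt$rpm["g2", "glucose"]))
  ## all-replicates variant
  bt_all <- median_binding(cc, require_all_replicates = TRUE)
  expect_false(bt_all$detected["g1", "glucose"])
  expect_error(median_binding(count_table(cbind(a = 1:2), library_size = 2e6,
                                          condition = "x", replicate = 1)),
               "fewer than")
})

test_that("pseudocount imputation keeps reference-detected features only", {
  cc <- count_table(
    rbind(g1 = c(10, 10, 10, 0, 0, 0),    # detected glu, lost at 30 s
          g2 = c(10, 12, 10, 8, 8, 8),    # detected both
          g3 = c(0, 0, 1, 9, 9, 9)),      # undetected in glucose -> dropped
    library_size = rep(2e6, 6),
    condition = rep(c("glucose", "s30"), each = 3), replicate = rep(1:3, 2))
  bt <- impute_pseudocount(median_binding(cc), "glucose")
  expect_equal(sort(rownames(bt$rpm)), c("g1", "g2"))
  expect_equal(bt$rpm["g1", "s30"], 0.5)
  expect_true(bt$imputed["g1", "s30"])
  expect_false(bt$imputed["g2", "s30"])
  expect_equal(bt$rpm["g2", "s30"], 4)
  expect_error(impute_pseudocount(median_binding(cc), "nope"), "reference")
})

test_that("high-confidence filter enforces biotype and inclusive RPKM threshold", {
  cc <- count_table(rbind(g1 = c(10, 10), g2 = c(10, 10), g3 = c(10, 10)),
                    library_size = rep(2e6, 2),
                    condition = c("glucose", "glucose"), replicate = 1:2)
  bt <- impute_pseudocount(median_binding(cc), "glucose")
  ann <- data.frame(id = c("g1", "g2", "g3"),
                    biotype = c("protein_coding; exon", "ncRNA",
                                "protein_coding; exon"),
                    length_nt = c(1000, 1000, 1000))
  rk <- matrix(c(10, 50, 9.9), 3, 1, dimnames = list(c("g1", "g2", "g3"), "glucose"))
  hc <- high_confidence_filter(bt, ann, rk, "glucose")
  expect_equal(rownames(hc$rpm), "g1")   # g2 wrong biotype, g3 below 10
  hc2 <- high_confidence_filter(bt, ann, rk, "glucose", rpkm_min = 9.9)
  expect_equal(sort(rownames(hc2$rpm)), c("g1", "g3"))
})

test_that("expression normalisation maps the 30-s condition onto glucose RNA-seq", {
  cc <- count_table(rbind(g1 = c(20, 20, 2, 2)),
                    library_size = rep(2e6, 4),
                    condition = rep(c("glucose", "s30"), each = 2),
                    replicate = rep(1:2, 2))
  bt <- impute_pseudocount(median_binding(cc), "glucose")
  rk <- matrix(c(50, 10), 1, 2,
               dimnames = list("g1", c("glucose", "s30_rnaseq")))
  norm <- expression_normalize(bt, rk, c(glucose = "glucose", s30 = "glucose"))
  expect_equal(unname(norm$normalized["g1", "s30"]), 1 / 50)
  ## the 30-s column uses glucose RPKM even though a 30-s RNA-seq exists
  norm2 <- expression_normalize(bt, rk, c(glucose = "glucose",
                                          s30 = "s30_rnaseq"))
  expect_equal(unname(norm2$normalized["g1", "s30"]), 1 / 10)
  expect_error(expression_normalize(bt, rk, c(glucose = "glucose")),
               "cover")
  rk0 <- matrix(c(0, 0), 1, 2, dimnames = dimnames(rk))
  norm0 <- expression_normalize(bt, rk0, c(glucose = "glucose", s30 = "glucose"))
  expect_true(all(norm0$undefined))
})

test_that("top-N DE sets rank by fold change with lexicographic ties", {
  de <- data.frame(id = c("a", "b", "c", "d", "e"),
                   log2FC = c(3, 2, -1, -4, 1),
                   FDR = c(0.01, 0.001, 0.04, 0.02, 0.2))
  s <- topN_sets(de, n = 2, fdr = 0.05)
  expect_equal(s$induced, c("a", "b"))
  expect_equal(s$repressed, c("d", "c"))
  ## all non-significant -> empty
  de2 <- de; de2$FDR <- 0.5
  expect_equal(length(suppressWarnings(topN_sets(de2, n = 2))$induced), 0)
  ## ties break by id
  de3 <- data.frame(id = c("z", "y"), log2FC = c(2, 2), FDR = 0.01)
  expect_equal(suppressWarnings(topN_sets(de3, n = 1))$induced, "y")
})

test_that("set summaries count imputed members and partition consistently", {
  mat <- rbind(matrix(rep(c(10, 10, 10, 0, 0, 0), 4), 4, 6, byrow = TRUE),
               matrix(rep(c(10, 10, 10, 6, 6, 6), 6), 6, 6, byrow = TRUE))
  rownames(mat) <- paste0("g", 1:10)
  cc <- count_table(mat,
    library_size = rep(2e6, 6),
    condition = rep(c("glucose", "s30"), each = 3), replicate = rep(1:3, 2))
  bt <- impute_pseudocount(median_binding(cc), "glucose")
  s <- set_summary(bt, list(ten = paste0("g", 1:10)))
  expect_equal(s$fraction_undetected, 0.4)
  ## all-imputed set
  s2 <- set_summary(bt, list(lost = paste0("g", 1:4)))
  expect_equal(s2$fraction_undetected, 1)
  ## weighted partition identity for the mean percent
  sa <- set_summary(bt, list(p1 = paste0("g", 1:4), p2 = paste0("g", 5:10),
                             all = paste0("g", 1:10)))
  w <- c(4, 6) / 10
  expect_equal(sa$mean_pct_of_reference[sa$set == "all"],
               sum(w * sa$mean_pct_of_reference[sa$set %in% c("p1", "p2")]))
  expect_error(set_summary(bt, list(bad = "nope")), "absent")
})

test_that("the filter chain matches brute-force rule reapplication and is idempotent", {
  set.seed(99)
  counts <- matrix(rpois(20 * 6, lambda = rep(c(0.4, 2, 8), length.out = 20)),
                   20, 6, dimnames = list(sprintf("g%02d", 1:20), NULL))
  cond <- rep(c("glucose", "s30"), each = 3)
  ct <- count_table(counts, library_size = rep(2e6, 6),
                    condition = cond, replicate = rep(1:3, 2))
  bt <- impute_pseudocount(median_binding(ct), "glucose")
  oracle <- brute_force_binding(rpm(ct), cond, "glucose")
  expect_equal(rownames(bt$rpm), rownames(oracle$rpm))
  expect_equal(unname(bt$rpm), unname(oracle$rpm))
  expect_equal(unname(bt$imputed), unname(oracle$imputed))
  ## idempotence: re-imputing changes nothing
  bt2 <- impute_pseudocount(bt, "glucose")
  expect_equal(bt2$rpm, bt$rpm)
  expect_equal(bt2$imputed, bt$imputed)
})

test_that("coverage tracks merge equal adjacent values in bedGraph convention", {
  tr <- coverage_track(rep(1, 10), library_size = 1e6)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$start, 0)
  expect_equal(tr$end, 10)
  expect_equal(tr$value, 1)
  tr2 <- coverage_track(c(rep(2, 5), rep(3, 5)), library_size = 1e6)
  expect_equal(tr2$start, c(0, 5))
  expect_equal(tr2$end, c(5, 10))
  tr3 <- coverage_track(c(0, 0, 4, 0), library_size = 1e6)
  expect_equal(nrow(tr3), 1)
  expect_equal(tr3$start, 2)
  expect_equal(nrow(coverage_track(integer(0), 1e6)), 0)
  expect_error(coverage_track(rep(1, 5), 1e6, seq_length = 3), "bounds")
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr2, path)
  lines <- readLines(path)
  expect_match(lines[1], "^track type=bedGraph")
  expect_equal(length(lines), 3)
})

test_that("western quantification normalises to Pab1 as percent of pre-shift", {
  expect_equal(western_normalize(5, 2, 5, 2), 100)
  expect_equal(western_normalize(2.5, 2, 5, 2), 50)
  expect_equal(western_normalize(0, 2, 5, 2), 0)
  expect_equal(western_normalize(5, 4, 5, 2), 50)  # Pab1 doubling halves the call
  expect_error(western_normalize(1, 0, 1, 1), "> 0")
})

test_that("the stand-in exact NB test agrees with an established exact test", {
  skip_if_not_installed("edgeR")
  set.seed(7)
  n <- 60
  mu <- rexp(n, 1 / 200)
  disp <- 0.05
  fc <- rep(1, n); fc[1:10] <- 4
  counts <- cbind(
    sapply(1:3, function(i) rnbinom(n, size = 1 / disp, mu = mu)),
    sapply(1:3, function(i) rnbinom(n, size = 1 / disp, mu = mu * fc)))
  rownames(counts) <- paste0("g", 1:n)
  ct <- count_table(counts, library_size = rep(sum(mu) * 3, 6),
                    condition = rep(c("a", "b"), each = 3),
                    replicate = rep(1:3, 2))
  mine <- nb_exact_test(ct, dispersion = disp)
  dge <- edgeR::DGEList(counts = counts,
                        group = rep(c("a", "b"), each = 3),
                        lib.size = rep(sum(mu) * 3, 6))
  et <- edgeR::exactTest(dge, dispersion = disp)
  ## directions agree and significance calls are concordant
  expect_gt(suppressWarnings(
    cor(mine$log2FC, et$table$logFC, method = "spearman")), 0.95)
  hits_mine <- mine$id[mine$FDR < 0.05]
  hits_edger <- rownames(et$table)[p.adjust(et$table$PValue, "BH") < 0.05]
  expect_gt(length(intersect(hits_mine, hits_edger)) /
              max(1, length(union(hits_mine, hits_edger))), 0.7)
  expect_true(all(paste0("g", 1:10) %in% hits_mine))
})

test_that("binding-loss estimation is exact on noise-free tables", {
  ## construct a table whose stress RPM is exactly lambda * reference
  lam <- 0.2
  ref <- c(10, 40, 5, 100)
  cc <- count_table(rbind(g1 = c(rep(ref[1], 3), rep(ref[1] * lam, 3)),
                          g2 = c(rep(ref[2], 3), rep(ref[2] * lam, 3)),
                          g3 = c(rep(ref[3], 3), rep(ref[3] * lam, 3)),
                          g4 = c(rep(ref[4], 3), rep(ref[4] * lam, 3))),
                    library_size = rep(2e6, 6),
                    condition = rep(c("glucose", "s30"), each = 3),
                    replicate = rep(1:3, 2))
  bt <- impute_pseudocount(median_binding(cc), "glucose")
  for (m in c("weighted", "per_feature")) {
    est <- estimate_binding_loss(bt, "s30", method = m, n_boot = 50, seed = 1)
    expect_equal(est$estimate, lam, tolerance = 1e-12)
  }
})
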