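## Seeded synthetic-data generators. Each generator is a pure function of
## (config, seed) and emulates the statistical structure of the
## corresponding experimental dataset: noisy NTP time courses,
## negative-binomial CRAC/RNA-seq counts with condition-dependent binding
## loss, and cluster-structured log2 protein intensities with left-censored
## missingness. The generated truth is attached so every pipeline output
## can be scored without re-generation.

#' Generator configuration
#'
#' Defaults encode the study conditions the generators emulate: library
#' size 2e6 (so the 0.5 RPM detection threshold corresponds to ~1 count),
#' NB dispersion 0.05 (typical bulk RNA-seq), expression lognormal with
#' sdlog 1.5 (three to four decades of mRNA abundance, placing roughly a
#' fifth of transcripts below detection at the 30-s binding-loss factor),
#' global binding loss lambda = 0.05 at 30 s persisting to 16 min, a
#' re-binding boost of 1.5 on the induced set at 16 min, transcriptional
#' effect |log2FC| = 2 (4-fold) on 100 induced and 100 repressed
#' transcripts, and triplicate samples throughout.
#'
#' @param ... named overrides of any default.
#' @return list of configuration values.
#' @export
synth_config <- function(...) {
  cfg <- list(
    n_genes = 5000,
    frac_noncoding = 0.05,
    library_size = 2e6,
    dispersion = 0.05,
    expr_sdlog = 1.5,
    binding_sdlog = 0.5,
    length_meanlog = log(1350), length_sdlog = 0.45,
    n_induced = 100, n_repressed = 100,
    effect_log2fc = 2,
    lambda = c(glucose = 1, no_glucose_30s = 0.05, no_glucose_16min = 0.05),
    rebind_boost = 1.5,
    n_replicates = 3,
    crac_mrna_fraction = 0.9,
    ntp_noise_sdlog = 0.1,
    n_proteins = 1000,
    proteome_base_mean = 25, proteome_base_sd = 2,
    proteome_amplitude = 2, proteome_noise_sd = 0.5,
    proteome_enrichment = 5,
    censor_threshold = 21.5, censor_slope = 0.8,
    pool_n = 200, pool_len_meanlog = log(450), pool_len_sdlog = 0.45,
    pool_init_rate = 0.1, pool_init_sdlog = 0.3
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

provenance <- function(generator, seed, config) {
  list(generator = generator, seed = seed,
       config_digest = paste(names(config), vapply(config, function(v)
         paste(format(v, digits = 10), collapse = ","), ""), sep = "=",
         collapse = ";"))
}

#' Write / read a TSV with a provenance header
#'
#' Provenance (generator name, seed, config digest) is stored in leading
#' `#key<TAB>value` comment lines and round-trips through the reader.
#'
#' @param x data.frame to write (with optional `provenance` attribute).
#' @param path file path.
#' @return the path (writer) or the data.frame with restored provenance
#'   attribute (reader).
#' @export
write_synth_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  prov <- attr(x, "provenance")
  if (!is.null(prov))
    for (k in names(prov))
      writeLines(sprintf("#%s\t%s", k, prov[[k]]), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_synth_tsv
#' @export
read_synth_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  prov <- NULL
  if (length(hdr)) {
    kv <- strsplit(sub("^#", "", lines[hdr]), "\t")
    prov <- stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
  }
  x <- utils::read.delim(text = paste(lines[setdiff(seq_along(lines), hdr)],
                                      collapse = "\n"),
                         stringsAsFactors = FALSE)
  attr(x, "provenance") <- prov
  x
}

#' Synthetic NTP time course in HPLC output units
#'
#' Simulates the requested scenario, samples the trajectory at `times`,
#' converts mM back to pmol per 1e8 cells through the cell model, and
#' applies multiplicative lognormal replicate noise. The noise-free mM
#' truth is attached as attribute `truth`.
#'
#' @param config a [synth_config()].
#' @param scenario `"wild_type"` or `"hxk2_delta"`.
#' @param times sampling times in seconds.
#' @param seed RNG seed.
#' @param cell cell model for the unit conversion.
#' @return measurement data.frame
#'   `species condition time_s replicate pmol_per_1e8_cells` with
#'   attributes `truth` (data.frame of mM by time) and `provenance`.
#' @export
gen_ntp_timecourse <- function(config = synth_config(),
                               scenario = c("wild_type", "hxk2_delta"),
                               times = c(0, 10, 20, 30, 40, 50, 60, 960),
                               seed = 1, cell = cell_model()) {
  scenario <- match.arg(scenario)
  sc <- ntp_scenario(scenario)
  sim <- simulate_ntp(sc$initial, sc$sinks, sc$production,
                      t_end = max(times), dt = min(diff(sort(unique(c(0, times))))))
  tr <- sim$trajectory
  idx <- vapply(times, function(t) which.min(abs(tr$time - t)), integer(1))
  truth <- tr[idx, c("time", NT_SPECIES)]
  vol <- soluble_volume(cell)
  rows <- with_seed(seed, {
    out <- list()
    for (sp in NT_SPECIES) for (k in seq_along(times)) {
      mm <- truth[[sp]][k]
      noise <- if (config$ntp_noise_sdlog > 0)
        stats::rlnorm(config$n_replicates, 0, config$ntp_noise_sdlog)
      else rep(1, config$n_replicates)
      out[[length(out) + 1]] <- data.frame(
        species = sp, condition = scenario, time_s = times[k],
        replicate = paste0("rep", seq_len(config$n_replicates)),
        pmol_per_1e8_cells = mM_to_pmol(mm, vol) * noise)
    }
    do.call(rbind, out)
  })
  attr(rows, "truth") <- truth
  attr(rows, "provenance") <- provenance("gen_ntp_timecourse", seed, config)
  rows
}

#' Synthetic CRAC + RNA-seq experiment
#'
#' Gene expression is lognormal; RNA-seq counts are negative binomial with
#' mean proportional to condition expression (induced/repressed effects
#' applied at 16 min); CRAC counts are negative binomial with mean
#' proportional to expression times a gene-specific binding propensity,
#' globally scaled by the condition's binding-loss factor lambda, except
#' that at 16 min the induced (newly synthesised) set carries the
#' re-binding boost instead. Library size is the total mapped reads and is
#' the RPM denominator; lost binding reads are not resequenced, so column
#' sums shrink with lambda.
#'
#' @param config a [synth_config()].
#' @param seed RNG seed.
#' @return list with `crac` and `rnaseq` ([count_table()]), `annotation`
#'   (id/biotype/length_nt), and `truth` (induced/repressed ids, lambda,
#'   dispersion, per-gene expression and binding propensity).
#' @export
gen_crac_experiment <- function(config = synth_config(), seed = 1) {
  with_seed(seed, {
    n <- config$n_genes
    n_nc <- round(config$frac_noncoding * n)
    ids <- sprintf("gene%04d", seq_len(n + n_nc))
    biotype <- c(rep("protein_coding; exon", n), rep("ncRNA", n_nc))
    len <- round(stats::rlnorm(n + n_nc, config$length_meanlog,
                               config$length_sdlog))
    expr <- stats::rlnorm(n + n_nc, 0, config$expr_sdlog)
    bind <- stats::rlnorm(n + n_nc, 0, config$binding_sdlog)

    coding <- seq_len(n)
    induced <- sample(coding, config$n_induced)
    repressed <- sample(setdiff(coding, induced), config$n_repressed)
    eff <- rep(1, n + n_nc)
    eff[induced] <- 2^config$effect_log2fc
    eff[repressed] <- 2^(-config$effect_log2fc)
    expr16 <- expr * eff

    lib <- config$library_size
    reps <- config$n_replicates
    size <- 1 / config$dispersion

    nb_cols <- function(mu, label, cond) {
      m <- vapply(seq_len(reps), function(r)
        stats::rnbinom(length(mu), size = size, mu = mu), numeric(length(mu)))
      colnames(m) <- paste0(cond, "_rep", seq_len(reps))
      m
    }

    ## RNA-seq: relative expression resequenced to full depth
    mu_rna_glu <- expr / sum(expr) * lib
    mu_rna_16 <- expr16 / sum(expr16) * lib
    rna_counts <- cbind(nb_cols(mu_rna_glu, "r", "glucose"),
                        nb_cols(mu_rna_16, "r", "no_glucose_16min"))
    rownames(rna_counts) <- ids
    rnaseq <- count_table(rna_counts, library_size = rep(lib, 2 * reps),
                          assay = "RNAseq",
                          condition = rep(c("glucose", "no_glucose_16min"),
                                          each = reps),
                          replicate = rep(seq_len(reps), 2))

    ## CRAC: glucose composition scaled so mRNA reads are a fixed fraction
    ## of the library; stress conditions keep the same scale, so global
    ## binding loss shows up as a global RPM drop
    w_glu <- expr * bind
    s <- config$crac_mrna_fraction * lib / sum(w_glu)
    lam <- config$lambda
    w30 <- w_glu * lam[["no_glucose_30s"]]
    w16 <- expr16 * bind * lam[["no_glucose_16min"]]
    w16[induced] <- expr16[induced] * bind[induced] * config$rebind_boost
    crac_counts <- cbind(nb_cols(s * w_glu, "c", "glucose"),
                         nb_cols(s * w30, "c", "no_glucose_30s"),
                         nb_cols(s * w16, "c", "no_glucose_16min"))
    rownames(crac_counts) <- ids
    crac <- count_table(crac_counts, library_size = rep(lib, 3 * reps),
                        assay = "CRAC",
                        condition = rep(c("glucose", "no_glucose_30s",
                                          "no_glucose_16min"), each = reps),
                        replicate = rep(seq_len(reps), 3))

    annotation <- data.frame(id = ids, biotype = biotype, length_nt = len)
    truth <- list(induced = ids[induced], repressed = ids[repressed],
                  lambda = lam, rebind_boost = config$rebind_boost,
                  dispersion = config$dispersion,
                  expression = stats::setNames(expr, ids),
                  expression_16min = stats::setNames(expr16, ids),
                  binding_propensity = stats::setNames(bind, ids))
    out <- list(crac = crac, rnaseq = rnaseq, annotation = annotation,
                truth = truth)
    attr(out, "provenance") <- provenance("gen_crac_experiment", seed, config)
    out
  })
}

## archetype shapes over (input_glu, input_noglu, eluate_glu, eluate_noglu):
## 1 stable, 2 preferential label on glucose, 3 preferential label after
## withdrawal, 4 input-dominant (low nascent enrichment)
proteome_archetypes <- function() {
  rbind(c(1, 1, -1, -1),
        c(0.5, -0.5, 1, -1),
        c(-0.5, 0.5, -1, 1),
        c(-1, -1, 1, 1))
}

#' Synthetic nascent-proteome intensity matrix
#'
#' Cluster-structured log2 intensities over labelled input and eluate
#' samples in two conditions (plus unlabeled controls), with left-censored
#' missing-not-at-random values: the probability that a cell is missing
#' rises steeply as its intensity falls below the censoring threshold.
#' AHA eluates carry the planted enrichment over control eluates.
#'
#' @param config a [synth_config()].
#' @param seed RNG seed.
#' @return an [intensity_matrix()] with attributes `truth` (cluster
#'   assignment, archetypes, censor threshold) and `provenance`.
#' @export
gen_proteome <- function(config = synth_config(), seed = 1) {
  with_seed(seed, {
    n <- config$n_proteins
    reps <- config$n_replicates
    arch <- proteome_archetypes() * config$proteome_amplitude
    cl <- sample(rep_len(seq_len(4), n))
    base <- stats::rnorm(n, config$proteome_base_mean, config$proteome_base_sd)

    classes <- expand.grid(replicate = seq_len(reps),
                           condition = c("glucose", "no_glucose"),
                           fraction = c("input", "eluate"),
                           label = c("AHA", "control"),
                           stringsAsFactors = FALSE)
    class_idx <- function(fraction, condition)
      (match(fraction, c("input", "eluate")) - 1) * 2 +
      match(condition, c("glucose", "no_glucose"))
    x <- matrix(NA_real_, n, nrow(classes))
    for (j in seq_len(nrow(classes))) {
      mu <- base + arch[cl, class_idx(classes$fraction[j], classes$condition[j])]
      if (classes$fraction[j] == "eluate")
        mu <- mu - if (classes$label[j] == "control")
          config$proteome_enrichment else 0
      x[, j] <- mu + stats::rnorm(n, 0, config$proteome_noise_sd)
    }
    rownames(x) <- sprintf("prot%04d", seq_len(n))
    colnames(x) <- with(classes, paste(fraction, label, condition,
                                       paste0("rep", replicate), sep = "_"))
    ## left-censored MNAR missingness
    pmiss <- stats::plogis((config$censor_threshold - x) / config$censor_slope)
    miss <- matrix(stats::runif(length(x)) < pmiss, n)
    x[miss] <- NA_real_

    m <- intensity_matrix(x, fraction = classes$fraction,
                          label = classes$label,
                          condition = classes$condition,
                          replicate = classes$replicate)
    attr(m, "truth") <- list(cluster = stats::setNames(cl, rownames(x)),
                             archetypes = arch,
                             censor_threshold = config$censor_threshold,
                             enrichment = config$proteome_enrichment)
    attr(m, "provenance") <- provenance("gen_proteome", seed, config)
    m
  })
}

#' Synthetic mRNA pool for the run-off simulator
#'
#' CDS lengths lognormal around ~450 codons; initiation rates lognormal
#' around the configured baseline.
#'
#' @param config a [synth_config()].
#' @param seed RNG seed.
#' @param n pool size (default `config$pool_n`).
#' @return a [mrna_pool()] data.frame with a `provenance` attribute.
#' @export
gen_mrna_pool <- function(config = synth_config(), seed = 1,
                          n = config$pool_n) {
  with_seed(seed, {
    out <- mrna_pool(
      id = sprintf("mrna%04d", seq_len(n)),
      cds_length = pmax(20, round(stats::rlnorm(n, config$pool_len_meanlog,
                                                config$pool_len_sdlog))),
      initiation_rate = stats::rlnorm(n, log(config$pool_init_rate),
                                      config$pool_init_sdlog),
      copies = 1L)
    attr(out, "provenance") <- provenance("gen_mrna_pool", seed, config)
    out
  })
}
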