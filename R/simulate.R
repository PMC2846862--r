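# Seeded synthetic-data generation: diploid genomes as random unions of
# haplotypes from a pool, gene-dropped pedigrees, noisy pyrogram read-outs,
# and expression / qPCR tables.  All randomness flows through a single seed;
# the RNG state of the caller is restored afterwards.

# Evaluate code under a temporary seed, restoring .Random.seed on exit.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  force(code)
}

# Gaussian noise truncated (by resampling, then clamping) to keep
# fractions in [0, 1].
.truncnorm <- function(mean, sd, max_iter = 20L) {
  if (sd == 0) return(mean)
  out <- stats::rnorm(length(mean), mean, sd)
  for (k in seq_len(max_iter)) {
    bad <- out < 0 | out > 1
    if (!any(bad)) break
    out[bad] <- stats::rnorm(sum(bad), mean[bad], sd)
  }
  pmin(pmax(out, 0), 1)
}

#' Haplotype pool
#'
#' A set of per-chromosome haplotypes (duplicon counts `(b, n, c)`) with
#' population frequencies.  Diploid genomes are formed as two independent
#' draws from the pool (random union of gametes).
#'
#' @param haplotypes matrix or data frame with columns `b`, `n`, `c`
#'   (one row per haplotype).
#' @param freq numeric vector of frequencies, `>= 0`, summing to 1
#'   (tolerance 1e-9).
#' @return Object of class `haplotype_pool`.
#' @examples
#' haplotype_pool(rbind(c(0, 1, 1), c(1, 1, 1)), c(0.3, 0.7))
#' @export
haplotype_pool <- function(haplotypes, freq) {
  h <- as.matrix(haplotypes)
  colnames(h) <- c("b", "n", "c")
  storage.mode(h) <- "integer"
  if (nrow(h) == 0L) stop("empty haplotype pool", call. = FALSE)
  stopifnot(length(freq) == nrow(h), all(freq >= 0))
  if (abs(sum(freq) - 1) > 1e-9)
    stop("haplotype frequencies must sum to 1", call. = FALSE)
  if (any(h < 0)) stop("negative duplicon counts", call. = FALSE)
  structure(list(haplotypes = h, freq = as.numeric(freq)),
            class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat("Haplotype pool (", nrow(x$haplotypes), " haplotypes)\n", sep = "")
  for (i in seq_len(nrow(x$haplotypes)))
    cat(sprintf("  (%d,%d,%d)  %.3f\n", x$haplotypes[i, 1],
                x$haplotypes[i, 2], x$haplotypes[i, 3], x$freq[i]))
  invisible(x)
}

#' Built-in population haplotype-pool presets
#'
#' Minimal-support haplotype pools for the three study populations
#' (African-American, Caucasian, Mexican), chosen so that the implied
#' diploid ratio-class distribution and per-paralog mean copy numbers match
#' the published population summaries as closely as a random union of
#' gametes permits.  The published Mexican class table shows a heterozygote
#' excess (3:2 at 50% exceeding the combined even classes) that no pool can
#' reproduce exactly under independent haplotype draws; the preset is the
#' least-squares fit.  See the package vignette for the derivation.
#'
#' @param population `"AA"`, `"Caucasian"` or `"Mexican"` (aliases
#'   `"African-American"`, `"Cau"`, `"Mex"`).
#' @return A [haplotype_pool()].
#' @examples
#' population_preset("Mexican")
#' @export
population_preset <- function(population) {
  key <- switch(tolower(population),
                "aa" = , "african-american" = "AA",
                "cau" = , "caucasian" = "Cau",
                "mex" = , "mexican" = "Mex",
                stop("unknown population preset: ", population, call. = FALSE))
  switch(key,
    AA = haplotype_pool(rbind(c(0, 1, 1), c(1, 1, 1), c(0, 1, 2)),
                        c(0.15, 0.70, 0.15)),
    Cau = haplotype_pool(rbind(c(0, 1, 1), c(1, 1, 0), c(1, 1, 1),
                               c(0, 1, 2), c(1, 1, 2)),
                         c(0.07, 0.14, 0.70, 0.03, 0.06)),
    Mex = haplotype_pool(rbind(c(0, 1, 0), c(1, 1, 0), c(0, 1, 1),
                               c(1, 1, 1), c(2, 1, 0)),
                         c(0.012, 0.400, 0.248, 0.280, 0.060)))
}

#' Diploid ratio-class distribution implied by a haplotype pool
#'
#' Exact distribution of the diploid pseudogene-total : NCF1 ratio class
#' under two independent draws from the pool.
#'
#' @param pool a [haplotype_pool()].
#' @return Named numeric vector of class probabilities (names "p:q").
#' @export
pool_class_distribution <- function(pool) {
  stopifnot(inherits(pool, "haplotype_pool"))
  h <- pool$haplotypes
  probs <- list()
  for (i in seq_len(nrow(h))) for (j in seq_len(nrow(h))) {
    trio <- h[i, ] + h[j, ]
    key <- paste0(trio[1] + trio[3], ":", trio[2])
    probs[[key]] <- (probs[[key]] %||% 0) + pool$freq[i] * pool$freq[j]
  }
  out <- unlist(probs)
  out[order(as.numeric(sub(":.*", "", names(out))))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Measurement-noise model for simulated pyrograms
#'
#' Gaussian noise of SD `sigma_f` added to allele fractions (truncated to
#' `[0, 1]`), plus a lognormal-scale coefficient of variation for raw peak
#' heights.  The default `sigma_f = 0.015` back-calculates, via the delta
#' method (`SD_ratio = SD_fraction / (1 - f)^2`, i.e. x9 at the 4:2 class),
#' to a ratio-scale spread of ~0.135 at the 4:2 class, matching the
#' published replicate spread of that class.
#'
#' @param sigma_f fraction-scale Gaussian SD.
#' @param peak_cv coefficient of variation of simulated total peak signal.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sigma_f = 0.015, peak_cv = 0.05) {
  stopifnot(sigma_f >= 0, peak_cv >= 0)
  structure(list(sigma_f = sigma_f, peak_cv = peak_cv), class = "noise_model")
}

#' Simulate a population of diploid genomes with pyrogram read-outs
#'
#' Each individual is the union of two independent haplotype draws from the
#' pool; its PSV allele fractions are the forward-model expectations plus
#' truncated Gaussian noise, and peak-height pairs consistent with the noisy
#' fractions are emitted for the peak-table pathway.
#'
#' @param pool a [haplotype_pool()] (or preset name accepted by
#'   [population_preset()]).
#' @param n number of individuals, `>= 1`.
#' @param noise a [noise_model()].
#' @param seed optional integer seed (caller RNG state is preserved).
#' @param prefix sample-id prefix.
#' @return List with `samples` (data frame: `sample_id`, `f_gt`, `f_a`, and
#'   per-assay peak heights) , `peaks` (long-format peak table as read by
#'   [fractions_from_peaks()]), `truth` (data frame of true trios and the
#'   two drawn haplotypes) and `pool`.
#' @examples
#' sim <- simulate_population(population_preset("AA"), 5, seed = 7)
#' sim$truth
#' @export
simulate_population <- function(pool, n, noise = noise_model(), seed = NULL,
                                prefix = "S") {
  if (is.character(pool)) pool <- population_preset(pool)
  stopifnot(inherits(pool, "haplotype_pool"), n >= 1)
  with_seed(seed, {
    i1 <- sample.int(nrow(pool$haplotypes), n, replace = TRUE,
                     prob = pool$freq)
    i2 <- sample.int(nrow(pool$haplotypes), n, replace = TRUE,
                     prob = pool$freq)
    h1 <- pool$haplotypes[i1, , drop = FALSE]
    h2 <- pool$haplotypes[i2, , drop = FALSE]
    b <- h1[, "b"] + h2[, "b"]
    nn <- h1[, "n"] + h2[, "n"]
    cc <- h1[, "c"] + h2[, "c"]
    ids <- sprintf("%s%04d", prefix, seq_len(n))
    ef <- expected_fractions(b, nn, cc, sample = ids)
    f_gt <- .truncnorm(ef$f_gt, noise$sigma_f)
    f_a <- .truncnorm(ef$f_a, noise$sigma_f)
    # peak pairs consistent with the noisy fractions (signal ~ lognormal)
    amp2 <- 100 * exp(stats::rnorm(n, 0, noise$peak_cv))
    amp9 <- 100 * exp(stats::rnorm(n, 0, noise$peak_cv))
    samples <- data.frame(
      sample_id = ids, f_gt = f_gt, f_a = f_a,
      h_gt = amp2 * f_gt, h_gtgt = amp2 * (1 - f_gt),
      h_a = amp9 * f_a, h_g = amp9 * (1 - f_a))
    peaks <- rbind(
      data.frame(sample_id = ids, assay = "exon2",
                 h_allele1 = samples$h_gt, h_allele2 = samples$h_gtgt),
      data.frame(sample_id = ids, assay = "exon9",
                 h_allele1 = samples$h_a, h_allele2 = samples$h_g))
    truth <- data.frame(sample_id = ids, b = b, n = nn, c = cc,
                        hap1 = apply(h1, 1, paste, collapse = "/"),
                        hap2 = apply(h2, 1, paste, collapse = "/"))
    list(samples = samples, peaks = peaks, truth = truth, pool = pool)
  })
}

#' A three-generation pedigree structure
#'
#' Convenience ten-member structure in the style of the large reference
#' families used for transmission studies: two founder couples, one child of
#' each married into the middle generation, and four grandchildren.
#'
#' @return Data frame with columns `family`, `id`, `father`, `mother`,
#'   `sex`, `phenotype`.
#' @export
three_generation_pedigree <- function() {
  data.frame(
    family = "FAM1",
    id = c("gf1", "gm1", "gf2", "gm2", "dad", "mom",
           "kid1", "kid2", "kid3", "kid4"),
    father = c("0", "0", "0", "0", "gf1", "gf2",
               "dad", "dad", "dad", "dad"),
    mother = c("0", "0", "0", "0", "gm1", "gm2",
               "mom", "mom", "mom", "mom"),
    sex = c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2),
    phenotype = 0,
    stringsAsFactors = FALSE)
}

#' Gene-drop a pedigree from a haplotype pool
#'
#' Founders receive two independent haplotype draws from the pool; every
#' non-founder inherits one uniformly chosen haplotype from each parent.
#' True haplotypes are retained so downstream deductions can be checked
#' against the simulation truth.
#'
#' @param pool a [haplotype_pool()] or preset name.
#' @param structure pedigree data frame (`id`, `father`, `mother`; see
#'   [three_generation_pedigree()]).
#' @param noise a [noise_model()] for the emitted fraction table.
#' @param seed optional integer seed.
#' @return List with `ped` (the structure), `trios` (true diploid trios per
#'   id), `haplotypes` (named list of true 2x3 haplotype pairs), and
#'   `samples` (noisy fraction table keyed by id).
#' @export
simulate_pedigree <- function(pool, structure = three_generation_pedigree(),
                              noise = noise_model(), seed = NULL) {
  if (is.character(pool)) pool <- population_preset(pool)
  stopifnot(inherits(pool, "haplotype_pool"))
  ped <- .validate_ped(structure) # topological order, structural checks
  with_seed(seed, {
    haps <- list() # per id: list(pat, mat) haplotype vectors
    for (i in seq_len(nrow(ped))) {
      id <- ped$id[i]
      if (ped$father[i] == "0") {
        idx <- sample.int(nrow(pool$haplotypes), 2, replace = TRUE,
                          prob = pool$freq)
        haps[[id]] <- list(pool$haplotypes[idx[1], ],
                           pool$haplotypes[idx[2], ])
      } else {
        from_f <- haps[[ped$father[i]]][[sample.int(2, 1)]]
        from_m <- haps[[ped$mother[i]]][[sample.int(2, 1)]]
        haps[[id]] <- list(from_f, from_m)
      }
    }
    trios <- do.call(rbind, lapply(ped$id, function(id)
      data.frame(id = id,
                 b = haps[[id]][[1]]["b"] + haps[[id]][[2]]["b"],
                 n = haps[[id]][[1]]["n"] + haps[[id]][[2]]["n"],
                 c = haps[[id]][[1]]["c"] + haps[[id]][[2]]["c"])))
    rownames(trios) <- NULL
    ef <- expected_fractions(trios$b, trios$n, trios$c, sample = trios$id)
    samples <- data.frame(sample_id = trios$id,
                          f_gt = .truncnorm(ef$f_gt, noise$sigma_f),
                          f_a = .truncnorm(ef$f_a, noise$sigma_f))
    pairs <- setNames(lapply(ped$id, function(id)
      .make_pair(haps[[id]][[1]], haps[[id]][[2]])), ped$id)
    list(ped = structure, trios = trios, haplotypes = pairs,
         samples = samples)
  })
}

#' Expression and qPCR generative model
#'
#' Per-paralog per-copy transcription rates; the fractions `rho_B`, `rho_C`
#' of each pseudogene's transcripts that retain the GT exon (NCF1 retains
#' GTGT with probability 1 — the remaining pseudogene transcripts use
#' alternative exons and are invisible to the exon-2 assay); Gaussian noise
#' for cDNA fractions and Ct values; and the true standard curves of the
#' target (GT/GTGT pool) and reference assays.  The default
#' `rho_B = rho_C = 0.25` with equal rates reproduces the observed
#' pseudogene:NCF1 cDNA ratio of 0.5 for a 2:2:2 genome.
#'
#' @param rate named per-copy transcription rates (NCF1B, NCF1, NCF1C).
#' @param rho_B,rho_C GT-exon retention fractions of the pseudogenes.
#' @param sigma_f cDNA fraction noise SD.
#' @param curve_slope,curve_intercept true standard-curve parameters shared
#'   by target and reference assays (slope -3.3219 = perfect doubling).
#' @param ct_sd Gaussian SD of simulated Ct values.
#' @param n_replicates qPCR replicates per condition.
#' @param reference_quantity true reference-gene quantity (constant across
#'   conditions).
#' @return Object of class `expression_model`.
#' @export
expression_model <- function(rate = c(NCF1B = 1, NCF1 = 1, NCF1C = 1),
                             rho_B = 0.25, rho_C = 0.25,
                             sigma_f = 0.015,
                             curve_slope = -3.3219, curve_intercept = 30,
                             ct_sd = 0.1, n_replicates = 5,
                             reference_quantity = 1) {
  stopifnot(all(rate >= 0), rho_B >= 0, rho_B <= 1, rho_C >= 0, rho_C <= 1,
            sigma_f >= 0, curve_slope < 0, ct_sd >= 0, n_replicates >= 1,
            reference_quantity > 0)
  structure(list(rate = rate, rho = c(B = rho_B, N = 1, C = rho_C),
                 sigma_f = sigma_f, curve_slope = curve_slope,
                 curve_intercept = curve_intercept, ct_sd = ct_sd,
                 n_replicates = as.integer(n_replicates),
                 reference_quantity = reference_quantity),
            class = "expression_model")
}

# True GT-pool shares and total GT output for one trio under one condition.
.true_expression <- function(trio, model, mult) {
  w <- c(trio[1] * model$rate["NCF1B"] * model$rho["B"] * mult[1],
         trio[2] * model$rate["NCF1"] * mult[2],
         trio[3] * model$rate["NCF1C"] * model$rho["C"] * mult[3])
  if (sum(w) == 0) stop("all-zero expression", call. = FALSE)
  list(shares = w / sum(w), total = sum(w))
}

#' Simulate cDNA fraction and qPCR Ct tables for a set of genomes
#'
#' GT-pool transcript shares are `p_i` proportional to
#' `copies_i x rate_i x rho_i x multiplier_i(condition)`; the cDNA assay
#' fractions are `f_gtgt = p_N` and `f_g = p_C` plus truncated Gaussian
#' noise.  The target qPCR measures the total GT/GTGT-pool output through
#' the inverse standard curve plus Ct noise; the reference gene has constant
#' true quantity.
#'
#' @param trios data frame (`sample_id`, `b`, `n`, `c`) of genomic copy
#'   numbers.
#' @param model an [expression_model()].
#' @param conditions data frame with columns `condition`, `mult_B`,
#'   `mult_N`, `mult_C` (per-paralog output multipliers).  Default: a single
#'   `baseline` condition with unit multipliers.
#' @param seed optional integer seed.
#' @return List with `cdna` (per sample x condition: `f_gtgt`, `f_g`),
#'   `qpcr` (per sample x condition x replicate x gene: `ct`), `curves`
#'   (true [fit_standard_curve()]-compatible parameters refit from noiseless
#'   points), `standards` (a noiseless standards table), and `truth`
#'   (true shares and totals).
#' @export
simulate_expression <- function(trios, model = expression_model(),
                                conditions = NULL, seed = NULL) {
  if (is.null(conditions))
    conditions <- data.frame(condition = "baseline",
                             mult_B = 1, mult_N = 1, mult_C = 1)
  stopifnot(inherits(model, "expression_model"),
            all(c("condition", "mult_B", "mult_N", "mult_C") %in%
                  names(conditions)),
            all(c("b", "n", "c") %in% names(trios)))
  ids <- if ("sample_id" %in% names(trios)) as.character(trios$sample_id)
         else sprintf("S%03d", seq_len(nrow(trios)))
  with_seed(seed, {
    cdna <- list(); qpcr <- list(); truth <- list()
    for (i in seq_len(nrow(trios))) for (k in seq_len(nrow(conditions))) {
      trio <- as.numeric(trios[i, c("b", "n", "c")])
      mult <- as.numeric(conditions[k, c("mult_B", "mult_N", "mult_C")])
      te <- .true_expression(trio, model, mult)
      cdna[[length(cdna) + 1L]] <- data.frame(
        sample_id = ids[i], condition = conditions$condition[k],
        f_gtgt = .truncnorm(te$shares[2], model$sigma_f),
        f_g = .truncnorm(te$shares[3], model$sigma_f))
      for (r in seq_len(model$n_replicates)) {
        ct_t <- model$curve_intercept +
          model$curve_slope * log10(te$total) +
          stats::rnorm(1, 0, model$ct_sd)
        ct_r <- model$curve_intercept +
          model$curve_slope * log10(model$reference_quantity) +
          stats::rnorm(1, 0, model$ct_sd)
        qpcr[[length(qpcr) + 1L]] <- data.frame(
          sample_id = rep(ids[i], 2),
          condition = rep(conditions$condition[k], 2),
          gene = c("GT_pool", "reference"),
          ct = c(ct_t, ct_r), replicate = rep(r, 2))
      }
      truth[[length(truth) + 1L]] <- data.frame(
        sample_id = ids[i], condition = conditions$condition[k],
        p_B = te$shares[1], p_N = te$shares[2], p_C = te$shares[3],
        total_gt_output = te$total)
    }
    q10 <- 10^seq(0, 3) # noiseless serial-dilution standards
    standards <- rbind(
      data.frame(gene = "GT_pool", quantity = q10,
                 ct = model$curve_intercept + model$curve_slope * log10(q10)),
      data.frame(gene = "reference", quantity = q10,
                 ct = model$curve_intercept + model$curve_slope * log10(q10)))
    curves <- list(
      GT_pool = fit_standard_curve(q10, standards$ct[standards$gene ==
                                                       "GT_pool"]),
      reference = fit_standard_curve(q10, standards$ct[standards$gene ==
                                                         "reference"]))
    list(cdna = do.call(rbind, cdna), qpcr = do.call(rbind, qpcr),
         curves = curves, standards = standards,
         truth = do.call(rbind, truth))
  })
}
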