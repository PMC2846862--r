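# Dissection of cDNA pyrosequencing read-outs into per-paralog transcript
# contributions, and standard-curve RT-qPCR relative quantification.
#
# The exon-2 cDNA assay sees only transcripts retaining the (mutant GT or
# wild-type GTGT) exon 2; within that pool the GTGT fraction is NCF1's share
# and, at exon 9, the G fraction is NCF1C's share.  NCF1B's share is obtained
# by subtraction and therefore inherits both assays' errors.

#' Dissect cDNA allele fractions into per-paralog transcript shares
#'
#' Shares of the GT/GTGT-containing transcript pool: `p_N = f_gtgt` (GTGT
#' fraction of the exon-2 cDNA assay), `p_C = f_g` (G fraction of the exon-9
#' cDNA assay), `p_B = 1 - f_gtgt - f_g`.  A slightly negative `p_B` within
#' `tol` is clipped to zero and the shares renormalised; a more negative
#' value signals inconsistent assays and is an error.
#'
#' @param f_gtgt,f_g numeric vectors in `[0, 1]` (recycled): GTGT fraction
#'   (exon 2) and G fraction (exon 9) measured in cDNA.
#' @param tol inconsistency tolerance for the subtracted share
#'   (default 0.02, typical pyrosequencing noise).
#' @return Data frame with columns `p_B`, `p_N`, `p_C`; rows sum to 1.
#' @examples
#' dissect_contributions(0.527, 0.144) # 32.9% NCF1B, 52.7% NCF1, 14.4% NCF1C
#' @export
dissect_contributions <- function(f_gtgt, f_g, tol = 0.02) {
  stopifnot(is.numeric(f_gtgt), is.numeric(f_g), tol >= 0)
  len <- max(length(f_gtgt), length(f_g))
  f_gtgt <- rep_len(f_gtgt, len); f_g <- rep_len(f_g, len)
  if (any(f_gtgt < 0 | f_gtgt > 1 | f_g < 0 | f_g > 1, na.rm = TRUE))
    stop("cDNA fractions must lie in [0, 1]", call. = FALSE)
  p_b <- 1 - f_gtgt - f_g
  bad <- which(p_b < -tol)
  if (length(bad))
    stop(sprintf(paste0("inconsistent cDNA assays at row(s) %s: ",
                        "f_gtgt + f_g exceeds 1 by more than tol = %g ",
                        "(f_gtgt = %s, f_g = %s)"),
                 paste(bad, collapse = ", "), tol,
                 paste(signif(f_gtgt[bad], 4), collapse = ", "),
                 paste(signif(f_g[bad], 4), collapse = ", ")),
         call. = FALSE)
  clip <- !is.na(p_b) & p_b < 0
  p_b[clip] <- 0
  tot <- p_b + f_gtgt + f_g
  data.frame(p_B = p_b / tot, p_N = f_gtgt / tot, p_C = f_g / tot)
}

.contrib_vec <- function(contributions) {
  if (is.data.frame(contributions)) {
    stopifnot(nrow(contributions) == 1L)
    contributions <- unlist(contributions[1, c("p_B", "p_N", "p_C")])
  }
  stopifnot(length(contributions) == 3L, all(contributions >= 0),
            abs(sum(contributions) - 1) < 1e-6)
  names(contributions) <- c("p_B", "p_N", "p_C")
  contributions
}

#' Pseudogene:NCF1 ratio of a cDNA transcript pool
#'
#' `(p_B + p_C) / p_N`: the GT:GTGT ratio measured in cDNA, comparable to
#' the genomic ratio of [expected_gt_ratio()].  An individual with genomic
#' ratio 2 (four pseudogene copies vs two NCF1) but cDNA ratio 0.5 has
#' pseudogenes contributing only half the transcripts of one NCF1 copy.
#'
#' @param contributions a single-row data frame from
#'   [dissect_contributions()] or a numeric vector `(p_B, p_N, p_C)`.
#' @return The ratio, `>= 0`.
#' @export
cdna_gt_ratio <- function(contributions) {
  p <- .contrib_vec(contributions)
  if (p["p_N"] == 0)
    stop("cDNA GT:GTGT ratio undefined: no NCF1 (GTGT) transcripts",
         call. = FALSE)
  unname((p["p_B"] + p["p_C"]) / p["p_N"])
}

#' Per-copy transcriptional activity relative to NCF1
#'
#' Divides each paralog's share of the GT-containing transcript pool by its
#' share of gene copies, normalised so NCF1 is exactly 1:
#' `a_i = (p_i / (g_i / T)) / (p_N / (n / T))`.  Also reports the combined
#' pseudogene activity (both pseudogenes treated as one gene class).
#'
#' @param contributions as in [cdna_gt_ratio()].
#' @param trio integer vector `c(b, n, c)` of genomic copy numbers.
#' @return List with `activity` (named vector NCF1B, NCF1, NCF1C; NCF1 = 1)
#'   and `pseudogene_combined`.
#' @examples
#' # 4 pseudogene copies contributing 1/3 of transcripts vs 2 NCF1 copies
#' # contributing 2/3: combined per-copy activity 0.25
#' per_copy_activity(c(1/6, 2/3, 1/6), c(2, 2, 2))$pseudogene_combined
#' @export
per_copy_activity <- function(contributions, trio) {
  p <- .contrib_vec(contributions)
  stopifnot(length(trio) == 3L, all(trio >= 0))
  g <- as.numeric(trio)
  if (g[2] == 0 || p["p_N"] == 0)
    stop("activity normalisation requires NCF1 copies and NCF1 transcripts",
         call. = FALSE)
  if (any(p > 0 & g == 0))
    stop("impossible configuration: transcript share > 0 with zero copies",
         call. = FALSE)
  tot <- sum(g)
  dens <- ifelse(g > 0, p / (g / tot), 0)
  act <- dens / (p["p_N"] / (g[2] / tot))
  names(act) <- c("NCF1B", "NCF1", "NCF1C")
  comb <- if (g[1] + g[3] > 0)
    ((p["p_B"] + p["p_C"]) / ((g[1] + g[3]) / tot)) /
      (p["p_N"] / (g[2] / tot)) else 0
  list(activity = act, pseudogene_combined = unname(comb))
}

#' Fit a qPCR standard curve (Ct versus log10 quantity)
#'
#' Least-squares line of Ct on log10(quantity) over serially diluted
#' standards.  The amplification efficiency is `E = 10^(-1/slope) - 1`
#' (E = 1, i.e. perfect doubling, at slope -3.3219).
#'
#' @param quantity positive numeric vector of standard quantities.
#' @param ct numeric vector of observed Ct values.
#' @return Object of class `standard_curve`: `slope`, `intercept` (Ct at
#'   quantity 1), `efficiency`, `r_squared`, `n`, and `positive_slope`
#'   (warning flag, `TRUE` for an invalid rising curve).
#' @examples
#' fit_standard_curve(c(1, 10, 100), c(30, 26.68, 23.36))
#' @export
fit_standard_curve <- function(quantity, ct) {
  stopifnot(is.numeric(quantity), is.numeric(ct),
            length(quantity) == length(ct))
  if (any(quantity <= 0)) stop("standard quantities must be > 0", call. = FALSE)
  if (length(unique(quantity)) < 2)
    stop("need at least 2 distinct standard quantities", call. = FALSE)
  fit <- stats::lm(ct ~ log10(quantity))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::resid(fit)^2) / ss_tot
  structure(list(slope = slope, intercept = intercept,
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = r2, n = length(ct),
                 positive_slope = slope >= 0),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: Ct = %.4f %+.4f * log10(Q)  (n = %d)\n",
              x$intercept, x$slope, x$n))
  cat(sprintf("  efficiency E = %.3f, r^2 = %.4f%s\n", x$efficiency,
              x$r_squared,
              if (x$positive_slope) "  [WARNING: positive slope]" else ""))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @rdname fit_standard_curve
#' @param object a `standard_curve`.
#' @param quantity quantities at which to predict Ct.
#' @param ... unused.
#' @export
predict.standard_curve <- function(object, quantity, ...) {
  stopifnot(all(quantity > 0))
  object$intercept + object$slope * log10(quantity)
}

#' Interpolate a quantity from a Ct value on a standard curve
#'
#' `Q = 10^((ct - intercept) / slope)`; strictly decreasing in Ct for a
#' valid (negative-slope) curve.
#'
#' @param curve a [fit_standard_curve()] object.
#' @param ct numeric vector of Ct values.
#' @return Numeric vector of quantities (units of the standards).
#' @export
quantify <- function(curve, ct) {
  stopifnot(inherits(curve, "standard_curve"), is.numeric(ct))
  10^((ct - curve$intercept) / curve$slope)
}

#' Reference-normalised fold change between two conditions
#'
#' Standard-curve relative quantification: every well's Ct is interpolated
#' to a quantity on its gene's curve, target quantities are normalised by
#' the matched (same condition and replicate) reference-gene quantities, and
#' the fold change is the mean normalised quantity under the treated
#' condition divided by the mean under `baseline`.  The p-value is a
#' two-sample t test ([two_sample_t()]) on the replicate-level normalised
#' quantities; the confidence interval is a t interval on the log scale.
#'
#' @param qpcr data frame with columns `condition`, `gene`, `ct`,
#'   `replicate`.
#' @param target,reference gene names in `qpcr` (target of interest and
#'   normalisation reference, e.g. GAPDH).
#' @param curves named list of [fit_standard_curve()] objects, one per gene.
#' @param baseline the baseline condition label; the remaining condition is
#'   treated.
#' @param method t-test flavour, see [two_sample_t()].
#' @param conf_level confidence level for the fold-change interval.
#' @return Object of class `fold_change`: `fold`, `p`, `conf_int`,
#'   `baseline`, `treated`, `ratios` (replicate-level normalised
#'   quantities by condition), `method`.
#' @export
normalized_fold_change <- function(qpcr, target, reference, curves, baseline,
                                   method = c("student", "welch"),
                                   conf_level = 0.95) {
  method <- match.arg(method)
  need <- c("condition", "gene", "ct", "replicate")
  miss <- setdiff(need, names(qpcr))
  if (length(miss))
    stop("qpcr table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  conds <- unique(as.character(qpcr$condition))
  if (!baseline %in% conds) stop("baseline condition not present", call. = FALSE)
  if (length(conds) != 2)
    stop("exactly two conditions required", call. = FALSE)
  treated <- setdiff(conds, baseline)
  for (g in c(target, reference))
    if (!g %in% names(curves) || !inherits(curves[[g]], "standard_curve"))
      stop("no standard curve for gene: ", g, call. = FALSE)
  norm_q <- function(cond) {
    tg <- qpcr[qpcr$condition == cond & qpcr$gene == target, ]
    rf <- qpcr[qpcr$condition == cond & qpcr$gene == reference, ]
    reps <- intersect(tg$replicate, rf$replicate)
    if (length(reps) < 2)
      stop("need >= 2 matched replicates per condition", call. = FALSE)
    qt <- quantify(curves[[target]], tg$ct[match(reps, tg$replicate)])
    qr <- quantify(curves[[reference]], rf$ct[match(reps, rf$replicate)])
    if (any(qr == 0)) stop("zero reference quantity", call. = FALSE)
    qt / qr
  }
  r_base <- norm_q(baseline)
  r_trt <- norm_q(treated)
  fold <- mean(r_trt) / mean(r_base)
  tt <- two_sample_t(r_trt, r_base, method = method)
  # t interval on the log-fold scale
  lt <- log(r_trt); lb <- log(r_base)
  se <- sqrt(stats::var(lt) / length(lt) + stats::var(lb) / length(lb))
  dfw <- if (se == 0) length(lt) + length(lb) - 2 else
    (stats::var(lt) / length(lt) + stats::var(lb) / length(lb))^2 /
    ((stats::var(lt) / length(lt))^2 / (length(lt) - 1) +
       (stats::var(lb) / length(lb))^2 / (length(lb) - 1))
  crit <- stats::qt(1 - (1 - conf_level) / 2, dfw)
  ci <- exp(mean(lt) - mean(lb) + c(-1, 1) * crit * se)
  structure(list(fold = fold, p = tt$p, conf_int = ci,
                 conf_level = conf_level,
                 baseline = baseline, treated = treated,
                 ratios = list(baseline = r_base, treated = r_trt),
                 method = method),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("Fold change %s vs %s: %.3f (%.0f%% CI %.3f-%.3f), p = %.3g\n",
              x$treated, x$baseline, x$fold, 100 * x$conf_level,
              x$conf_int[1], x$conf_int[2], x$p))
  invisible(x)
}
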