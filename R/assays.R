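#' Paralog-specific-variant (PSV) assay definitions for the NCF1 locus
#'
#' The three NCF1-locus duplicons (NCF1B, NCF1, NCF1C) are distinguished by
#' two paralog-specific variants: a 2-bp indel in exon 2, where NCF1 carries
#' `GTGT` and both pseudogenes carry the deleted `GT` allele, and an A/G
#' substitution in exon 9, where NCF1B and NCF1 carry `A` and NCF1C carries
#' `G`.  Jointly the two sites separate the three paralogs: exon 2 isolates
#' NCF1, exon 9 isolates NCF1C.
#'
#' Each assay carries a multiplicative calibration factor, the relative peak
#' yield of its second allele versus its first in a pyrogram.  The default
#' 1.0 treats peak heights as directly proportional to template counts; a
#' one-parameter skew absorbs incorporation-yield differences (e.g. between
#' a 2-bp and a 1-bp allele).
#'
#' @param cal_exon2,cal_exon9 positive reals; relative peak yield of allele 2
#'   (`GTGT`, resp. `G`) versus allele 1 (`GT`, resp. `A`).
#' @return An object of class `psv_assays`: a list with components `exon2`
#'   and `exon9`, each holding `site_id`, the allele labels, the
#'   paralog-to-allele map and `calibration_factor`.
#' @examples
#' psv_assays()
#' @export
psv_assays <- function(cal_exon2 = 1, cal_exon9 = 1) {
  stopifnot(is.numeric(cal_exon2), length(cal_exon2) == 1L, cal_exon2 > 0,
            is.numeric(cal_exon9), length(cal_exon9) == 1L, cal_exon9 > 0)
  structure(list(
    exon2 = list(site_id = "exon2_indel",
                 alleles = c(allele1 = "GT", allele2 = "GTGT"),
                 paralog_allele = c(NCF1B = "GT", NCF1 = "GTGT", NCF1C = "GT"),
                 calibration_factor = cal_exon2),
    exon9 = list(site_id = "exon9_snv",
                 alleles = c(allele1 = "A", allele2 = "G"),
                 paralog_allele = c(NCF1B = "A", NCF1 = "A", NCF1C = "G"),
                 calibration_factor = cal_exon9)
  ), class = "psv_assays")
}

#' @export
print.psv_assays <- function(x, ...) {
  cat("PSV assays for the NCF1 locus\n")
  for (a in x) {
    cat(sprintf("  %-11s alleles %s/%s  (NCF1B=%s, NCF1=%s, NCF1C=%s)  cal=%g\n",
                a$site_id, a$alleles[1], a$alleles[2],
                a$paralog_allele["NCF1B"], a$paralog_allele["NCF1"],
                a$paralog_allele["NCF1C"], a$calibration_factor))
  }
  invisible(x)
}

.check_trio <- function(b, n, c, sample = NULL) {
  if (!all(is.finite(b) & is.finite(n) & is.finite(c)))
    stop("copy numbers must be finite", call. = FALSE)
  if (any(b < 0 | n < 0 | c < 0) || any(b != round(b) | n != round(n) | c != round(c)))
    stop("copy numbers must be non-negative integers", call. = FALSE)
}

#' Expected allele fractions for a copy-number trio
#'
#' Forward arithmetic from integer copy numbers (b, n, c) of NCF1B, NCF1 and
#' NCF1C to the two PSV allele fractions a pooled-template pyrosequencing
#' assay reads out: `f_gt = (b + c) / T` (fraction of GT-deletion alleles at
#' exon 2) and `f_a = (b + n) / T` (fraction of A alleles at exon 9), with
#' `T = b + n + c` the total duplicon count.
#'
#' Fractions depend only on copy-number proportions, so any integer multiple
#' of a trio produces the same profile; breaking that scale non-identifiability
#' is the job of the caller's constraints (see [call_constraints()]).
#'
#' @param b,n,c non-negative integer vectors, recycled to common length:
#'   copies of NCF1B, NCF1 and NCF1C.
#' @param sample optional sample labels used in error messages.
#' @return A data frame with columns `f_gt` and `f_a`, both in `[0, 1]`.
#' @examples
#' expected_fractions(1, 2, 3) # f_gt = 2/3, f_a = 1/2
#' @export
expected_fractions <- function(b, n, c, sample = NULL) {
  .check_trio(b, n, c)
  len <- max(length(b), length(n), length(c))
  b <- rep_len(b, len); n <- rep_len(n, len); c <- rep_len(c, len)
  tot <- b + n + c
  if (any(tot == 0)) {
    bad <- which(tot == 0)
    lab <- if (!is.null(sample)) rep_len(sample, len)[bad] else bad
    stop("zero-total copy-number trio for sample(s): ",
         paste(lab, collapse = ", "), call. = FALSE)
  }
  data.frame(f_gt = (b + c) / tot, f_a = (b + n) / tot)
}

#' Expected pseudogene:NCF1 (GT:GTGT) ratio for a trio
#'
#' The diploid GT-deletion to GTGT ratio implied by a copy-number trio,
#' `r = (b + c) / n`.  This is the quantity reported as the ratio class of a
#' genome, e.g. 4:2 for (1, 2, 3).  Equals `f_gt / (1 - f_gt)` of
#' [expected_fractions()].
#'
#' @inheritParams expected_fractions
#' @return Numeric vector of ratios, `>= 0`.
#' @examples
#' expected_gt_ratio(1, 2, 3) # 2
#' @export
expected_gt_ratio <- function(b, n, c) {
  .check_trio(b, n, c)
  len <- max(length(b), length(n), length(c))
  b <- rep_len(b, len); n <- rep_len(n, len); c <- rep_len(c, len)
  if (any(n == 0))
    stop("GT:GTGT ratio undefined for n = 0 (no NCF1 copies, CGD-like genotype)",
         call. = FALSE)
  (b + c) / n
}

#' Convert pyrogram peak heights to an allele fraction
#'
#' Calibrated height normalisation: the fraction of allele 1 is
#' `h1 / (h1 + cal * h2)`, where `cal` is the assay's relative yield of
#' allele 2 versus allele 1 (see [psv_assays()]).  With `cal = 1` this is the
#' plain height share `h1 / (h1 + h2)`.
#'
#' @param h1,h2 non-negative numeric vectors of informative peak heights for
#'   alleles 1 and 2 (recycled).
#' @param calibration positive scalar calibration factor.
#' @return Numeric vector of allele-1 fractions in `[0, 1]`.  A zero-sum
#'   peak pair yields `NA` (a no-call marker), not an error.
#' @examples
#' peaks_to_fractions(4, 2)            # 2/3
#' peaks_to_fractions(4, 2, calibration = 1.1)
#' @export
peaks_to_fractions <- function(h1, h2, calibration = 1) {
  stopifnot(is.numeric(h1), is.numeric(h2),
            length(calibration) == 1L, calibration > 0)
  if (any(h1 < 0, na.rm = TRUE) || any(h2 < 0, na.rm = TRUE))
    stop("peak heights must be non-negative", call. = FALSE)
  len <- max(length(h1), length(h2))
  h1 <- rep_len(h1, len); h2 <- rep_len(h2, len)
  denom <- h1 + calibration * h2
  out <- h1 / denom
  out[!is.na(denom) & denom == 0] <- NA_real_
  out
}

#' Assemble allele-fraction profiles from a peak-height table
#'
#' Converts a long-format peak table (one row per sample x assay, columns
#' `sample_id`, `assay` in `exon2`/`exon9`, `h_allele1`, `h_allele2`) into a
#' wide fraction table ready for [ncf1_call()].  For exon 2 allele 1 is GT,
#' so the converted fraction is `f_gt` directly; for exon 9 allele 1 is A,
#' giving `f_a`.
#'
#' @param peaks data frame with columns `sample_id`, `assay`, `h_allele1`,
#'   `h_allele2`.
#' @param assays a [psv_assays()] object supplying calibration factors.
#' @return Data frame with columns `sample_id`, `f_gt`, `f_a`.  Samples with
#'   a zero-sum peak pair get `NA` in the affected fraction.
#' @export
fractions_from_peaks <- function(peaks, assays = psv_assays()) {
  need <- c("sample_id", "assay", "h_allele1", "h_allele2")
  miss <- setdiff(need, names(peaks))
  if (length(miss))
    stop("peak table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(peaks$assay %in% c("exon2", "exon9")))
    stop("assay must be 'exon2' or 'exon9'", call. = FALSE)
  ids <- unique(peaks$sample_id)
  grab <- function(which_assay, cal) {
    rows <- peaks[peaks$assay == which_assay, , drop = FALSE]
    f <- peaks_to_fractions(rows$h_allele1, rows$h_allele2, cal)
    f[match(ids, rows$sample_id)]
  }
  data.frame(sample_id = ids,
             f_gt = grab("exon2", assays$exon2$calibration_factor),
             f_a  = grab("exon9", assays$exon9$calibration_factor))
}
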