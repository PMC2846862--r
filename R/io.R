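# TSV / PED readers and writers.  All formats are UTF-8 tab-separated text
# with '#' comment lines; validation errors are row-addressed.

.read_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(data.frame())
  utils::read.delim(text = paste(lines, collapse = "\n"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
}

.check_fraction_col <- function(df, col, what) {
  v <- df[[col]]
  bad <- which(!is.na(v) & (v < 0 | v > 1))
  if (length(bad))
    stop(sprintf("%s: %s outside [0, 1] at row(s) %s", what, col,
                 paste(bad, collapse = ", ")), call. = FALSE)
}

#' Read a sample sheet of allele fractions
#'
#' TSV with columns `sample_id`, `f_gt`, `f_a` and optionally `population`.
#' Fractions must lie in `[0, 1]` (`NA` = failed assay); duplicate sample
#' ids are rejected.  An empty file yields an empty data frame.
#'
#' @param path file path.
#' @return Data frame ready for [ncf1_call()].
#' @export
read_sample_sheet <- function(path) {
  df <- .read_tsv(path)
  if (nrow(df) == 0L && ncol(df) == 0L)
    return(data.frame(sample_id = character(), f_gt = numeric(),
                      f_a = numeric()))
  .require_cols(df, c("sample_id", "f_gt", "f_a"), "sample sheet")
  dup <- which(duplicated(df$sample_id))
  if (length(dup))
    stop("sample sheet: duplicate sample_id at row(s) ",
         paste(dup, collapse = ", "), call. = FALSE)
  .check_fraction_col(df, "f_gt", "sample sheet")
  .check_fraction_col(df, "f_a", "sample sheet")
  df
}

#' Read a pyrogram peak-height table
#'
#' Long-format TSV with columns `sample_id`, `assay` (`exon2` or `exon9`),
#' `h_allele1`, `h_allele2`; the header names the alleles by position
#' (exon2: allele1 = GT, allele2 = GTGT; exon9: allele1 = A, allele2 = G).
#' Negative heights are rejected with row numbers.
#'
#' @param path file path.
#' @return Data frame for [fractions_from_peaks()] / [ncf1_call()].
#' @export
read_peak_table <- function(path) {
  df <- .read_tsv(path)
  if (nrow(df) == 0L && ncol(df) == 0L)
    return(data.frame(sample_id = character(), assay = character(),
                      h_allele1 = numeric(), h_allele2 = numeric()))
  .require_cols(df, c("sample_id", "assay", "h_allele1", "h_allele2"),
                "peak table")
  bad <- which(!df$assay %in% c("exon2", "exon9"))
  if (length(bad))
    stop("peak table: unknown assay at row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- which(df$h_allele1 < 0 | df$h_allele2 < 0)
  if (length(bad))
    stop("peak table: negative peak height at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  df
}

#' Read a PED-style pedigree file
#'
#' Whitespace-separated six-column text (family, id, father, mother, sex,
#' phenotype), `0` marking unknown parents, `#` comments.
#'
#' @param path file path.
#' @return Data frame with columns `family`, `id`, `father`, `mother`,
#'   `sex`, `phenotype` (ids as character), structurally validated.
#' @export
read_ped <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(family = character(), id = character(),
                      father = character(), mother = character(),
                      sex = integer(), phenotype = integer()))
  df <- utils::read.table(text = paste(lines, collapse = "\n"),
                          header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("family", "id", "father", "mother",
                                        "sex", "phenotype"))
  for (col in c("family", "id", "father", "mother"))
    df[[col]] <- as.character(df[[col]])
  .validate_ped(df) # structural errors before any analysis
  df
}

#' Read a per-individual copy-number trio table
#'
#' TSV with columns `id`, `b`, `n`, `c` (`NA` counts mark untyped members).
#'
#' @param path file path.
#' @return Data frame for [check_transmission()] / [deduce_haplogenotypes()].
#' @export
read_trios <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("id", "b", "n", "c"), "trio table")
  df$id <- as.character(df$id)
  bad <- which(apply(df[, c("b", "n", "c")], 1,
                     function(r) any(!is.na(r) & (r < 0 | r != round(r)))))
  if (length(bad))
    stop("trio table: invalid copy numbers at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  df
}

#' Read a qPCR Ct table
#'
#' TSV with columns `sample_id`, `condition`, `gene`, `ct`, `replicate`.
#' Ct values must be finite and positive.
#'
#' @param path file path.
#' @return Data frame for [normalized_fold_change()].
#' @export
read_qpcr <- function(path) {
  df <- .read_tsv(path)
  if (nrow(df) == 0L && ncol(df) == 0L)
    return(data.frame(sample_id = character(), condition = character(),
                      gene = character(), ct = numeric(),
                      replicate = integer()))
  .require_cols(df, c("sample_id", "condition", "gene", "ct", "replicate"),
                "qPCR table")
  bad <- which(!is.finite(df$ct) | df$ct <= 0)
  if (length(bad))
    stop("qPCR table: non-finite or non-positive Ct at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  df
}

#' Read a qPCR standards table
#'
#' TSV with columns `gene`, `quantity`, `ct`; one [fit_standard_curve()] is
#' fitted per gene.
#'
#' @param path file path.
#' @return Named list of `standard_curve` objects.
#' @export
read_standards <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("gene", "quantity", "ct"), "standards table")
  bad <- which(df$quantity <= 0)
  if (length(bad))
    stop("standards table: non-positive quantity at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  lapply(split(df, df$gene),
         function(d) fit_standard_curve(d$quantity, d$ct))
}

#' Read a cDNA allele-fraction table
#'
#' TSV with columns `sample_id`, `condition`, `f_gtgt`, `f_g`.
#'
#' @param path file path.
#' @return Data frame for [dissect_contributions()].
#' @export
read_cdna_fractions <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("sample_id", "condition", "f_gtgt", "f_g"),
                "cDNA fraction table")
  .check_fraction_col(df, "f_gtgt", "cDNA fraction table")
  .check_fraction_col(df, "f_g", "cDNA fraction table")
  df
}

#' Write copy-number calls to TSV (and optionally JSON)
#'
#' The TSV holds one row per sample (`sample_id`, `f_gt`, `f_a`, `b`, `n`,
#' `c`, `total`, `class`, `residual`, `no_call`, runner-up columns); reading
#' it back with [read_calls()] round-trips losslessly.
#'
#' @param x an [ncf1_call()] object or its calls data frame.
#' @param path output TSV path.
#' @param json_path optional JSON output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(x, path, json_path = NULL) {
  df <- if (inherits(x, "ncf1_call")) x$calls else x
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  if (!is.null(json_path))
    jsonlite::write_json(df, json_path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) .read_tsv(path)
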