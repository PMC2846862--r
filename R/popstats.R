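# Population-level summaries of copy-number calls and two-sample t tests
# computable either from raw per-individual values or from printed summary
# statistics (mean, SD, n).

#' Summarise copy-number calls by population
#'
#' Per-population sample means and SDs (n-1 denominator) of the NCF1B, NCF1
#' and NCF1C copy numbers, ratio-class frequency tables, and gene-pool shares
#' (the share of each paralog among all gene copies in the population).
#' No-call samples are excluded from the statistics and counted separately.
#'
#' @param calls an [ncf1_call()] object, or its `calls` data frame (columns
#'   `b`, `n`, `c`, `class`, `no_call`, and `population` unless supplied).
#' @param population optional character vector of population labels
#'   overriding a `population` column.
#' @return An object of class `ncf1_popsummary`: a named list of per-
#'   population summaries, each with `population`, `n`, `n_no_call`,
#'   `mean`, `sd`, `class_freq` (proportions summing to 1) and
#'   `gene_pool_share` (shares of B, N, C summing to 1).  An empty
#'   population yields an explicit empty summary (`n = 0`, `NA` statistics).
#' @examples
#' sim <- simulate_population(population_preset("Mexican"), 50, seed = 1)
#' calls <- ncf1_call(sim$samples)
#' summarize_populations(calls, population = rep("Mex", 50))
#' @export
summarize_populations <- function(calls, population = NULL) {
  df <- if (inherits(calls, "ncf1_call")) calls$calls else calls
  if (!is.null(population)) df$population <- rep_len(as.character(population),
                                                     nrow(df))
  if (is.null(df$population))
    stop("no population labels: supply `population` or a population column",
         call. = FALSE)
  out <- lapply(split(df, df$population), function(d) {
    ok <- d[!d$no_call, , drop = FALSE]
    if (nrow(ok) == 0L) {
      return(list(population = d$population[1], n = 0L,
                  n_no_call = sum(d$no_call),
                  mean = c(b = NA_real_, n = NA_real_, c = NA_real_),
                  sd = c(b = NA_real_, n = NA_real_, c = NA_real_),
                  class_freq = table(character()),
                  gene_pool_share = c(NCF1B = NA_real_, NCF1 = NA_real_,
                                      NCF1C = NA_real_)))
    }
    m <- colMeans(ok[, c("b", "n", "c")])
    s <- if (nrow(ok) > 1) apply(ok[, c("b", "n", "c")], 2, stats::sd)
         else c(b = 0, n = 0, c = 0)
    tot <- sum(ok$b) + sum(ok$n) + sum(ok$c)
    list(population = d$population[1],
         n = nrow(ok),
         n_no_call = sum(d$no_call),
         mean = m,
         sd = s,
         class_freq = table(ok$class) / nrow(ok),
         gene_pool_share = c(NCF1B = sum(ok$b), NCF1 = sum(ok$n),
                             NCF1C = sum(ok$c)) / tot)
  })
  structure(out, class = "ncf1_popsummary")
}

#' @export
print.ncf1_popsummary <- function(x, ...) {
  for (s in x) {
    cat(sprintf("%s: n = %d (%d no-call)\n", s$population, s$n, s$n_no_call))
    if (s$n > 0) {
      cat(sprintf("  copies (mean ± SD): B %.2f±%.2f  N %.2f±%.2f  C %.2f±%.2f\n",
                  s$mean["b"], s$sd["b"], s$mean["n"], s$sd["n"],
                  s$mean["c"], s$sd["c"]))
      cat("  gene-pool shares:",
          paste(sprintf("%s %.1f%%", names(s$gene_pool_share),
                        100 * s$gene_pool_share), collapse = "  "), "\n")
      f <- sort(s$class_freq, decreasing = TRUE)
      cat("  ratio classes:",
          paste(sprintf("%s %.1f%%", names(f), 100 * as.numeric(f)),
                collapse = "  "), "\n")
    }
  }
  invisible(x)
}

.group_stats <- function(g) {
  if (is.numeric(g) && is.null(names(g)) && length(g) > 1) {
    c(mean = mean(g), sd = stats::sd(g), n = length(g))
  } else if (all(c("mean", "sd", "n") %in% names(g))) {
    c(mean = unname(g[["mean"]]), sd = unname(g[["sd"]]), n = unname(g[["n"]]))
  } else {
    stop("each group must be a numeric vector (length >= 2) or have ",
         "named elements mean, sd, n", call. = FALSE)
  }
}

#' Two-sample t test from raw values or summary statistics
#'
#' Pooled-variance Student's t (default) or Welch's t, computable from raw
#' per-individual values or from printed summary statistics (mean, SD, n) —
#' the latter is what allows re-testing published group comparisons when the
#' underlying per-individual data are not available.
#'
#' @param group1,group2 either numeric vectors of raw values (length >= 2)
#'   or named vectors/lists with elements `mean`, `sd`, `n`.
#' @param method `"student"` (pooled variance) or `"welch"`.
#' @return An object of class `ttest_result`: list with `t`, `df`, `p`
#'   (two-sided), `estimate` (mean1 - mean2), `method`, `degenerate`
#'   (`TRUE` when both variances are zero).  With zero variance in both
#'   groups, equal means give `t = 0, p = 1`; unequal means give `p = 0`
#'   flagged degenerate.
#' @examples
#' two_sample_t(c(mean = 2.3, sd = 0.6, n = 32),
#'              c(mean = 1.0, sd = 0.4, n = 24)) # t ~ 9.18, df 54
#' @export
two_sample_t <- function(group1, group2, method = c("student", "welch")) {
  method <- match.arg(method)
  g1 <- .group_stats(group1)
  g2 <- .group_stats(group2)
  if (g1["n"] < 2 || g2["n"] < 2)
    stop("each group needs n >= 2", call. = FALSE)
  if (g1["sd"] < 0 || g2["sd"] < 0) stop("negative SD", call. = FALSE)
  diff <- g1["mean"] - g2["mean"]
  degenerate <- g1["sd"] == 0 && g2["sd"] == 0
  if (degenerate) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
    df <- g1["n"] + g2["n"] - 2
    p <- if (diff == 0) 1 else 0
  } else if (method == "student") {
    df <- g1["n"] + g2["n"] - 2
    sp2 <- ((g1["n"] - 1) * g1["sd"]^2 + (g2["n"] - 1) * g2["sd"]^2) / df
    t <- diff / sqrt(sp2 * (1 / g1["n"] + 1 / g2["n"]))
    p <- 2 * stats::pt(-abs(t), df)
  } else {
    v1 <- g1["sd"]^2 / g1["n"]; v2 <- g2["sd"]^2 / g2["n"]
    t <- diff / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (g1["n"] - 1) + v2^2 / (g2["n"] - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(t = unname(t), df = unname(df), p = unname(p),
                 estimate = unname(diff), method = method,
                 degenerate = unname(degenerate)),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("Two-sample t (%s): t = %.4g, df = %.4g, p = %.3g%s\n",
              x$method, x$t, x$df, x$p,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Pairwise between-population comparisons of per-paralog copy numbers
#'
#' All pairwise two-sample t tests, per paralog, across populations.  No
#' multiple-testing correction by default; Bonferroni (p multiplied by the
#' number of tests, capped at 1) is opt-in.
#'
#' @param calls an [ncf1_call()] object or calls data frame with a
#'   `population` column (see [summarize_populations()]).
#' @param method passed to [two_sample_t()].
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @return Data frame with one row per population pair x paralog:
#'   `pop1`, `pop2`, `paralog`, `mean1`, `mean2`, `t`, `df`, `p`.
#' @export
compare_populations <- function(calls, method = c("student", "welch"),
                                correction = c("none", "bonferroni")) {
  method <- match.arg(method)
  correction <- match.arg(correction)
  df <- if (inherits(calls, "ncf1_call")) calls$calls else calls
  if (is.null(df$population)) stop("population column required", call. = FALSE)
  df <- df[!df$no_call, , drop = FALSE]
  pops <- sort(unique(df$population))
  if (length(pops) < 2) stop("need at least two populations", call. = FALSE)
  rows <- list()
  for (i in seq_len(length(pops) - 1)) for (j in (i + 1):length(pops)) {
    for (paralog in c("b", "n", "c")) {
      x <- df[[paralog]][df$population == pops[i]]
      y <- df[[paralog]][df$population == pops[j]]
      tt <- two_sample_t(c(mean = mean(x), sd = stats::sd(x), n = length(x)),
                         c(mean = mean(y), sd = stats::sd(y), n = length(y)),
                         method = method)
      rows[[length(rows) + 1L]] <- data.frame(
        pop1 = pops[i], pop2 = pops[j],
        paralog = c(b = "NCF1B", n = "NCF1", c = "NCF1C")[paralog],
        mean1 = mean(x), mean2 = mean(y),
        t = tt$t, df = tt$df, p = tt$p)
    }
  }
  out <- do.call(rbind, rows)
  if (correction == "bonferroni") out$p <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  out
}
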