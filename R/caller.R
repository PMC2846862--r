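#' Constraints for the integer copy-number grid search
#'
#' The forward model is scale-invariant (any integer multiple of a trio gives
#' identical fractions), so the caller must bound and anchor the candidate
#' grid.  `fixed_two` pins NCF1 at two copies, matching the convention of
#' reporting genomes as pseudogene:NCF1 ratios "p:2"; `free` searches NCF1
#' over `n_range` and breaks residual ties by minimum total copy number,
#' which maps e.g. the fractions of (2,4,6) to the call (1,2,3).
#'
#' @param n_mode `"fixed_two"` (default) or `"free"`.
#' @param n_range integer range for NCF1 copies under `free` mode.
#' @param max_per_pseudogene upper bound for NCF1B and NCF1C copies.
#' @param tolerance maximum acceptable residual (Euclidean distance in
#'   fraction space over the two sites); calls with a larger best residual
#'   are flagged `no_call`.
#' @return An object of class `call_constraints`.
#' @export
call_constraints <- function(n_mode = c("fixed_two", "free"),
                             n_range = 1:4,
                             max_per_pseudogene = 6,
                             tolerance = 0.04) {
  n_mode <- match.arg(n_mode)
  stopifnot(length(max_per_pseudogene) == 1L, max_per_pseudogene >= 0,
            is.numeric(tolerance), length(tolerance) == 1L, tolerance >= 0,
            length(n_range) >= 1L, all(n_range >= 1))
  structure(list(n_mode = n_mode,
                 n_range = sort(unique(as.integer(n_range))),
                 max_per_pseudogene = as.integer(max_per_pseudogene),
                 tolerance = tolerance,
                 tie_break = "min_total"),
            class = "call_constraints")
}

#' @export
print.call_constraints <- function(x, ...) {
  cat("Copy-number call constraints\n")
  cat("  NCF1 copies:", if (x$n_mode == "fixed_two") "fixed at 2"
      else paste0("free in ", min(x$n_range), "..", max(x$n_range)), "\n")
  cat("  NCF1B/NCF1C copies: 0..", x$max_per_pseudogene, "\n", sep = "")
  cat("  residual tolerance:", x$tolerance,
      " tie-break:", x$tie_break, "\n")
  invisible(x)
}

# Candidate grid with expected fractions, ordered by (total, b, n, c) so that
# the first index among residual ties realises the min-total tie-break.
candidate_grid <- function(constraints = call_constraints()) {
  stopifnot(inherits(constraints, "call_constraints"))
  ns <- if (constraints$n_mode == "fixed_two") 2L else constraints$n_range
  g <- expand.grid(b = 0:constraints$max_per_pseudogene,
                   n = ns,
                   c = 0:constraints$max_per_pseudogene,
                   KEEP.OUT.ATTRS = FALSE)
  if (nrow(g) == 0L)
    stop("empty candidate grid: contradictory constraints", call. = FALSE)
  g$total <- g$b + g$n + g$c
  g <- g[order(g$total, g$b, g$n, g$c), , drop = FALSE]
  rownames(g) <- NULL
  ef <- expected_fractions(g$b, g$n, g$c)
  g$f_gt <- ef$f_gt
  g$f_a <- ef$f_a
  g
}

# Vectorised core: nearest candidate per profile, residual ties broken by
# grid order (total, b, n, c).  NA profiles yield NA calls.
.call_core <- function(f_gt, f_a, grid, tie_eps = 1e-9) {
  s <- length(f_gt)
  best <- integer(s); second <- integer(s)
  d_gt <- outer(f_gt, grid$f_gt, "-")
  d_a <- outer(f_a, grid$f_a, "-")
  dist <- sqrt(d_gt^2 + d_a^2) # s x m
  for (i in seq_len(s)) {
    if (is.na(f_gt[i]) || is.na(f_a[i])) { best[i] <- NA; second[i] <- NA; next }
    di <- dist[i, ]
    mn <- min(di)
    best[i] <- which(di <= mn + tie_eps)[1L]
    di2 <- di
    di2[best[i]] <- Inf
    mn2 <- min(di2)
    second[i] <- which(di2 <= mn2 + tie_eps)[1L]
  }
  list(best = best, second = second,
       residual = dist[cbind(seq_len(s), best)],
       runner_up_residual = dist[cbind(seq_len(s), second)])
}

#' Call integer NCF1-locus copy numbers from allele-fraction profiles
#'
#' Fits, per sample, the integer copy-number trio (b, n, c) whose expected
#' PSV fractions are nearest (Euclidean distance in fraction space over the
#' exon-2 and exon-9 sites) to the observed profile, over the candidate grid
#' implied by `constraints`.  Residual ties (within 1e-9) are broken towards
#' the smallest total copy number, then smallest NCF1B.  A call whose best
#' residual exceeds `constraints$tolerance` is flagged `no_call`.
#'
#' @param data data frame of observed profiles with columns `f_gt` and `f_a`
#'   (fractions in `[0, 1]`; `NA` marks a failed assay), optionally
#'   `sample_id` and `population`.  A peak table (columns `sample_id`,
#'   `assay`, `h_allele1`, `h_allele2`) is accepted and converted via
#'   [fractions_from_peaks()].
#' @param constraints a [call_constraints()] object.
#' @param assays a [psv_assays()] object (used only when `data` is a peak
#'   table).
#' @return An object of class `ncf1_call`: a list with `calls` (one row per
#'   sample: trio, `total`, `class` label "p:q", `residual`, `no_call`,
#'   runner-up trio and residual), `constraints`, `grid` and the input
#'   profiles.  Methods: [print.ncf1_call()], [summary.ncf1_call()],
#'   [coef.ncf1_call()], [fitted.ncf1_call()], [residuals.ncf1_call()],
#'   [predict.ncf1_call()], [simulate.ncf1_call()].
#' @examples
#' calls <- ncf1_call(data.frame(f_gt = c(0.60, 2/3), f_a = c(0.40, 0.50)))
#' coef(calls) # trios (0,2,3) and (1,2,3)
#' @export
ncf1_call <- function(data, constraints = call_constraints(),
                      assays = psv_assays()) {
  if (all(c("assay", "h_allele1", "h_allele2") %in% names(data)))
    data <- fractions_from_peaks(data, assays)
  if (!all(c("f_gt", "f_a") %in% names(data)))
    stop("data must contain columns f_gt and f_a (or be a peak table)",
         call. = FALSE)
  f_gt <- as.numeric(data$f_gt)
  f_a <- as.numeric(data$f_a)
  ok <- !is.na(f_gt) & !is.na(f_a)
  if (any(f_gt[ok] < 0 | f_gt[ok] > 1 | f_a[ok] < 0 | f_a[ok] > 1)) {
    bad <- which(ok & (f_gt < 0 | f_gt > 1 | f_a < 0 | f_a > 1))
    stop("fractions outside [0, 1] at row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sample_id <- if ("sample_id" %in% names(data)) as.character(data$sample_id)
               else sprintf("S%03d", seq_along(f_gt))
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id values", call. = FALSE)
  grid <- candidate_grid(constraints)
  res <- .call_core(f_gt, f_a, grid)
  pick <- function(idx, col) ifelse(is.na(idx), NA_integer_, grid[[col]][idx])
  calls <- data.frame(
    sample_id = sample_id,
    f_gt = f_gt, f_a = f_a,
    b = pick(res$best, "b"), n = pick(res$best, "n"), c = pick(res$best, "c"),
    stringsAsFactors = FALSE)
  calls$total <- calls$b + calls$n + calls$c
  calls$class <- ifelse(is.na(calls$b), NA_character_,
                        paste0(calls$b + calls$c, ":", calls$n))
  calls$residual <- res$residual
  calls$no_call <- is.na(calls$b) | calls$residual > constraints$tolerance
  calls$runner_up_b <- pick(res$second, "b")
  calls$runner_up_n <- pick(res$second, "n")
  calls$runner_up_c <- pick(res$second, "c")
  calls$runner_up_residual <- res$runner_up_residual
  if ("population" %in% names(data))
    calls$population <- as.character(data$population)
  structure(list(calls = calls, constraints = constraints, grid = grid),
            class = "ncf1_call")
}

#' @rdname ncf1_call
#' @param x,object an `ncf1_call` object.
#' @param ... unused.
#' @export
print.ncf1_call <- function(x, ...) {
  cat("NCF1-locus copy-number calls:", nrow(x$calls), "sample(s),",
      sum(x$calls$no_call), "no-call(s)\n")
  cat("NCF1 mode:", x$constraints$n_mode, "  tolerance:",
      x$constraints$tolerance, "\n\n")
  show <- utils::head(x$calls[, c("sample_id", "f_gt", "f_a", "b", "n", "c",
                                  "class", "residual", "no_call")], 10L)
  print(show, digits = 4, row.names = FALSE)
  if (nrow(x$calls) > 10L) cat("... and", nrow(x$calls) - 10L, "more\n")
  invisible(x)
}

#' @rdname ncf1_call
#' @export
summary.ncf1_call <- function(object, ...) {
  cl <- object$calls
  called <- cl[!cl$no_call, , drop = FALSE]
  out <- list(
    n = nrow(cl),
    n_called = nrow(called),
    n_no_call = sum(cl$no_call),
    class_table = if (nrow(called)) sort(table(called$class),
                                         decreasing = TRUE) else table(character()),
    mean_copies = if (nrow(called)) colMeans(called[, c("b", "n", "c")]) else
      c(b = NA_real_, n = NA_real_, c = NA_real_),
    sd_copies = if (nrow(called) > 1)
      apply(called[, c("b", "n", "c")], 2, stats::sd) else
      c(b = NA_real_, n = NA_real_, c = NA_real_),
    residual_quartiles = stats::quantile(cl$residual, c(0.25, 0.5, 0.75),
                                         na.rm = TRUE))
  class(out) <- "summary.ncf1_call"
  out
}

#' @export
print.summary.ncf1_call <- function(x, ...) {
  cat("NCF1-locus copy-number call summary\n")
  cat(sprintf("  samples: %d (called %d, no-call %d)\n",
              x$n, x$n_called, x$n_no_call))
  cat("  mean copies (b, n, c):",
      paste(sprintf("%.2f", x$mean_copies), collapse = ", "), "\n")
  cat("  SD copies   (b, n, c):",
      paste(sprintf("%.2f", x$sd_copies), collapse = ", "), "\n")
  cat("  ratio classes:\n")
  print(x$class_table)
  cat("  residual quartiles:",
      paste(sprintf("%.4f", x$residual_quartiles), collapse = " / "), "\n")
  invisible(x)
}

#' @rdname ncf1_call
#' @export
coef.ncf1_call <- function(object, ...) {
  m <- as.matrix(object$calls[, c("b", "n", "c")])
  rownames(m) <- object$calls$sample_id
  m
}

#' @rdname ncf1_call
#' @export
fitted.ncf1_call <- function(object, ...) {
  cl <- object$calls
  out <- matrix(NA_real_, nrow(cl), 2,
                dimnames = list(cl$sample_id, c("f_gt", "f_a")))
  ok <- !is.na(cl$b)
  if (any(ok)) {
    ef <- expected_fractions(cl$b[ok], cl$n[ok], cl$c[ok])
    out[ok, ] <- as.matrix(ef)
  }
  out
}

#' @rdname ncf1_call
#' @export
residuals.ncf1_call <- function(object, ...) {
  obs <- as.matrix(object$calls[, c("f_gt", "f_a")])
  rownames(obs) <- object$calls$sample_id
  obs - fitted(object)
}

#' @rdname ncf1_call
#' @param newdata data frame of new profiles (as in `data`); called with the
#'   same constraints.
#' @export
predict.ncf1_call <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$calls)
  ncf1_call(newdata, constraints = object$constraints)$calls
}

#' @rdname ncf1_call
#' @param nsim number of simulated datasets.
#' @param seed optional integer seed.
#' @param noise a [noise_model()] describing fraction-scale measurement noise.
#' @export
simulate.ncf1_call <- function(object, nsim = 1, seed = NULL,
                               noise = noise_model(), ...) {
  cl <- object$calls[!object$calls$no_call, , drop = FALSE]
  with_seed(seed, {
    lapply(seq_len(nsim), function(k) {
      ef <- expected_fractions(cl$b, cl$n, cl$c)
      data.frame(sample_id = cl$sample_id,
                 f_gt = .truncnorm(ef$f_gt, noise$sigma_f),
                 f_a = .truncnorm(ef$f_a, noise$sigma_f))
    })
  })
}

#' Classify a measured GT:GTGT ratio into the nearest ratio class
#'
#' Assigns each measured pseudogene:NCF1 ratio to the candidate class with
#' the nearest expected ratio `p / q` (p pseudogene copies, q NCF1 copies).
#' Exact midpoint ties go to the class with fewer pseudogene copies.
#'
#' @param measured_r numeric vector of measured ratios, `>= 0`.
#' @param pseudo_copies integer vector of candidate pseudogene totals
#'   (default 0..6).
#' @param ncf1_copies positive integer, NCF1 copies of the candidate classes
#'   (default 2, the "p:2" convention).
#' @return Data frame with one row per measurement: `measured`,
#'   `pseudo_copies`, `ncf1_copies`, `expected_ratio`, `class`.
#' @examples
#' classify_ratio(c(2.41, 1.97, 1.53, 1.0))$class # "5:2" "4:2" "3:2" "2:2"
#' @export
classify_ratio <- function(measured_r, pseudo_copies = 0:6, ncf1_copies = 2) {
  stopifnot(is.numeric(measured_r), all(measured_r >= 0, na.rm = TRUE),
            length(pseudo_copies) >= 1L, all(pseudo_copies >= 0),
            length(ncf1_copies) == 1L, ncf1_copies > 0)
  pseudo_copies <- sort(unique(as.integer(pseudo_copies)))
  expected <- pseudo_copies / ncf1_copies
  idx <- vapply(measured_r, function(r) {
    if (is.na(r)) return(NA_integer_)
    d <- abs(expected - r)
    which.min(d) # ties -> first, i.e. smaller pseudo_copies
  }, integer(1))
  data.frame(measured = measured_r,
             pseudo_copies = pseudo_copies[idx],
             ncf1_copies = ncf1_copies,
             expected_ratio = expected[idx],
             class = paste0(pseudo_copies[idx], ":", ncf1_copies))
}

#' Identifiability report for a candidate grid
#'
#' Lists groups of distinct candidate trios sharing identical expected
#' fraction profiles (scalar multiples of one another), documenting where the
#' grid is non-identifiable and the tie-break matters.  Under the default
#' `fixed_two` grid no two trios collide.
#'
#' @param constraints a [call_constraints()] object.
#' @return A list with `groups` (list of data frames of colliding trios),
#'   `n_candidates` and `n_profiles` (count of distinct fraction profiles).
#' @examples
#' enumerate_collisions(call_constraints("free"))
#' @export
enumerate_collisions <- function(constraints = call_constraints()) {
  g <- candidate_grid(constraints)
  key <- paste(sprintf("%.12f", g$f_gt), sprintf("%.12f", g$f_a))
  sp <- split(g[, c("b", "n", "c", "total")], key)
  groups <- Filter(function(d) nrow(d) > 1, sp)
  groups <- unname(lapply(groups, function(d) {
    rownames(d) <- NULL
    d
  }))
  list(groups = groups, n_candidates = nrow(g), n_profiles = length(sp))
}
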