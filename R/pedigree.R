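# Pedigree analysis of the NCF1-locus CNV: per-chromosome haplotypes are
# duplicon-count vectors (b, n, c) on one chromosome 7; a haplogenotype is an
# unordered pair of haplotypes summing to the individual's diploid trio.
# Transmission requires each non-founder to inherit exactly one haplotype
# from each parent; de novo copy-number changes are reported, not repaired.

.hap_key <- function(h) paste(h, collapse = "/")

.pair_key <- function(p) paste(sort(c(.hap_key(p[1, ]), .hap_key(p[2, ]))),
                               collapse = "|")

.make_pair <- function(h1, h2) {
  m <- rbind(h1, h2)
  if (.hap_key(h2) < .hap_key(h1)) m <- rbind(h2, h1)
  dimnames(m) <- list(NULL, c("b", "n", "c"))
  storage.mode(m) <- "integer"
  m
}

#' Enumerate haplotype pairs summing to a copy-number trio
#'
#' All unordered pairs of per-chromosome haplotypes (duplicon counts
#' `(b, n, c)` on one chromosome, each count bounded by `bound`) whose
#' component-wise sum equals the diploid trio.
#'
#' @param trio integer vector `c(b, n, c)` of diploid copy numbers.
#' @param bound per-arm upper bound on duplicon counts of a single
#'   chromosome (default 3).
#' @return A list of 2x3 integer matrices (rows = the two haplotypes,
#'   columns `b`, `n`, `c`), each pair in canonical row order.  Empty when
#'   the trio cannot be decomposed within the bound.
#' @examples
#' length(enumerate_haplotype_pairs(c(1, 2, 3))) # decompositions of 1:2:3
#' @export
enumerate_haplotype_pairs <- function(trio, bound = 3) {
  stopifnot(length(trio) == 3L, all(trio >= 0), all(trio == round(trio)),
            length(bound) == 1L, bound >= 0)
  trio <- as.integer(trio)
  rng <- function(t) max(0L, t - as.integer(bound)):min(as.integer(bound), t)
  if (any(trio > 2 * bound)) return(list())
  out <- list()
  seen <- character()
  for (b1 in rng(trio[1])) for (n1 in rng(trio[2])) for (c1 in rng(trio[3])) {
    p <- .make_pair(c(b1, n1, c1), trio - c(b1, n1, c1))
    k <- .pair_key(p)
    if (!k %in% seen) {
      seen <- c(seen, k)
      out[[length(out) + 1L]] <- p
    }
  }
  out
}

# All bounded haplotype pairs (candidates for an untyped individual).
.all_pairs <- function(bound) {
  haps <- as.matrix(expand.grid(b = 0:bound, n = 0:bound, c = 0:bound))
  out <- list()
  for (i in seq_len(nrow(haps))) for (j in i:nrow(haps))
    out[[length(out) + 1L]] <- .make_pair(haps[i, ], haps[j, ])
  out
}

.hap_in_pair <- function(h, p) all(h == p[1, ]) || all(h == p[2, ])

# Can child pair pc arise from parent pairs pf, pm (one haplotype each)?
.triple_ok <- function(pf, pm, pc) {
  (.hap_in_pair(pc[1, ], pf) && .hap_in_pair(pc[2, ], pm)) ||
    (.hap_in_pair(pc[2, ], pf) && .hap_in_pair(pc[1, ], pm))
}

.validate_ped <- function(ped) {
  need <- c("id", "father", "mother")
  if (!all(need %in% names(ped)))
    stop("pedigree needs columns id, father, mother", call. = FALSE)
  id <- as.character(ped$id)
  fa <- as.character(ped$father); mo <- as.character(ped$mother)
  fa[is.na(fa)] <- "0"; mo[is.na(mo)] <- "0"
  if (anyDuplicated(id)) stop("duplicate pedigree ids", call. = FALSE)
  if (any((fa == "0") != (mo == "0")))
    stop("individuals must have both parents known or both unknown",
         call. = FALSE)
  for (p in c(fa, mo)[c(fa, mo) != "0"])
    if (!p %in% id) stop("unknown parent id: ", p, call. = FALSE)
  # topological order: founders first; cycle check
  ord <- character(0)
  placed <- setNames(rep(FALSE, length(id)), id)
  repeat {
    ready <- id[!placed[id] &
                  (fa == "0" | placed[fa]) & (mo == "0" | placed[mo])]
    if (!length(ready)) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  if (length(ord) != length(id))
    stop("pedigree contains a cycle", call. = FALSE)
  data.frame(id = id, father = fa, mother = mo,
             stringsAsFactors = FALSE)[match(ord, id), , drop = FALSE]
}

# Candidate haplogenotype sets per individual; trios is data.frame(id,b,n,c),
# missing / NA rows mean untyped.
.candidate_sets <- function(ped, trios, bound) {
  all_p <- NULL
  out <- list()
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    row <- trios[match(id, as.character(trios$id)), , drop = FALSE]
    if (nrow(row) == 0L || any(is.na(row[, c("b", "n", "c")]))) {
      if (is.null(all_p)) all_p <- .all_pairs(bound)
      out[[id]] <- all_p
    } else {
      out[[id]] <- enumerate_haplotype_pairs(
        as.integer(row[1, c("b", "n", "c")]), bound)
    }
  }
  out
}

# Arc-consistency pruning over (father, mother, child) constraints.
.prune <- function(ped, cand) {
  kids <- which(ped$father != "0")
  repeat {
    changed <- FALSE
    for (i in kids) {
      ch <- ped$id[i]; fa <- ped$father[i]; mo <- ped$mother[i]
      keep_c <- vapply(cand[[ch]], function(pc)
        any(vapply(cand[[fa]], function(pf)
          any(vapply(cand[[mo]], function(pm) .triple_ok(pf, pm, pc),
                     logical(1))), logical(1))), logical(1))
      keep_f <- vapply(cand[[fa]], function(pf)
        any(vapply(cand[[ch]], function(pc)
          any(vapply(cand[[mo]], function(pm) .triple_ok(pf, pm, pc),
                     logical(1))), logical(1))), logical(1))
      keep_m <- vapply(cand[[mo]], function(pm)
        any(vapply(cand[[ch]], function(pc)
          any(vapply(cand[[fa]], function(pf) .triple_ok(pf, pm, pc),
                     logical(1))), logical(1))), logical(1))
      for (nm in list(list(ch, keep_c), list(fa, keep_f), list(mo, keep_m))) {
        if (!all(nm[[2]])) {
          cand[[nm[[1]]]] <- cand[[nm[[1]]]][nm[[2]]]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  cand
}

# Depth-first witness search in topological order; returns named list of
# pairs or NULL.
.witness <- function(ped, cand) {
  n <- nrow(ped)
  assign_env <- new.env(parent = emptyenv())
  dfs <- function(k) {
    if (k > n) return(TRUE)
    id <- ped$id[k]; fa <- ped$father[k]; mo <- ped$mother[k]
    for (p in cand[[id]]) {
      if (fa != "0" &&
          !.triple_ok(get(fa, assign_env), get(mo, assign_env), p)) next
      assign(id, p, envir = assign_env)
      if (dfs(k + 1L)) return(TRUE)
    }
    if (exists(id, assign_env)) rm(list = id, envir = assign_env)
    FALSE
  }
  if (!dfs(1L)) return(NULL)
  setNames(lapply(ped$id, get, envir = assign_env), ped$id)
}

#' Check Mendelian transmission of the NCF1-locus CNV across a pedigree
#'
#' Searches for a global assignment of haplogenotypes (one unordered pair of
#' bounded haplotypes per individual, summing to that individual's diploid
#' trio) such that every non-founder inherits exactly one haplotype from each
#' parent.  Untyped individuals (absent from `trios` or with `NA` counts) are
#' unconstrained.  Candidate sets are first narrowed by constraint
#' propagation over parent-parent-child triples, then a backtracking search
#' either produces a witness assignment or declares the pedigree
#' inconsistent, reporting the individuals whose candidate sets were
#' exhausted.
#'
#' @param ped data frame with columns `id`, `father`, `mother` ("0" or `NA`
#'   marks a founder); extra columns (family, sex, phenotype) are ignored.
#' @param trios data frame with columns `id`, `b`, `n`, `c` of diploid calls.
#' @param bound per-arm haplotype bound (default 3).
#' @param max_drop if the pedigree is inconsistent, retry with up to
#'   `max_drop` typed individuals treated as untyped (genotyping-error
#'   tolerance); dropped individuals are reported, never silently repaired.
#' @return An object of class `transmission_report`: list with `consistent`
#'   (logical), `witness` (named list of 2x3 haplotype-pair matrices, or
#'   `NULL`), `conflicted` (ids implicated in the inconsistency), `dropped`
#'   (ids untyped to restore consistency), and `candidates` (per-individual
#'   surviving pair counts after pruning).
#' @examples
#' ped <- data.frame(id = c("f", "m", "k"), father = c("0", "0", "f"),
#'                   mother = c("0", "0", "m"))
#' trios <- data.frame(id = c("f", "m", "k"),
#'                     b = c(1, 0, 1), n = c(2, 2, 2), c = c(3, 2, 3))
#' check_transmission(ped, trios)$consistent
#' @export
check_transmission <- function(ped, trios, bound = 3, max_drop = 0) {
  ped <- .validate_ped(ped)
  run <- function(tri) {
    cand <- .candidate_sets(ped, tri, bound)
    cand <- .prune(ped, cand)
    empty <- names(cand)[vapply(cand, length, integer(1)) == 0L]
    wit <- if (length(empty)) NULL else .witness(ped, cand)
    list(cand = cand, empty = empty, wit = wit)
  }
  r <- run(trios)
  dropped <- character(0)
  if (is.null(r$wit) && max_drop > 0) {
    typed <- intersect(ped$id, as.character(trios$id))
    for (k in seq_len(min(max_drop, length(typed)))) {
      combs <- utils::combn(typed, k, simplify = FALSE)
      for (dr in combs) {
        tri2 <- trios[!as.character(trios$id) %in% dr, , drop = FALSE]
        r2 <- run(tri2)
        if (!is.null(r2$wit)) {
          r <- r2
          dropped <- dr
          break
        }
      }
      if (length(dropped)) break
    }
  }
  conflicted <- if (is.null(r$wit)) {
    if (length(r$empty)) r$empty else intersect(ped$id,
                                                as.character(trios$id))
  } else character(0)
  structure(list(consistent = !is.null(r$wit),
                 witness = r$wit,
                 conflicted = conflicted,
                 dropped = dropped,
                 candidates = vapply(r$cand, length, integer(1))),
            class = "transmission_report")
}

#' @export
print.transmission_report <- function(x, ...) {
  cat("Pedigree transmission:",
      if (x$consistent) "CONSISTENT" else "INCONSISTENT", "\n")
  if (length(x$dropped))
    cat("  individuals dropped to restore consistency:",
        paste(x$dropped, collapse = ", "), "\n")
  if (length(x$conflicted))
    cat("  conflicted individuals:", paste(x$conflicted, collapse = ", "), "\n")
  if (x$consistent) {
    cat("  witness haplogenotypes:\n")
    for (id in names(x$witness)) {
      p <- x$witness[[id]]
      cat(sprintf("    %-8s (%s) + (%s)\n", id,
                  paste(p[1, ], collapse = ","),
                  paste(p[2, ], collapse = ",")))
    }
  }
  invisible(x)
}

#' Deduce per-individual haplogenotype sets surviving pedigree constraints
#'
#' For each individual, the subset of its [enumerate_haplotype_pairs()]
#' candidates that participates in at least one globally consistent
#' assignment of the whole pedigree (the union over all consistent global
#' assignments).  A unique surviving pair is a fully deduced haplogenotype.
#'
#' @inheritParams check_transmission
#' @return A named list (by individual id) of lists of 2x3 haplotype-pair
#'   matrices, with attribute `report` (the [check_transmission()] result).
#'   All sets are empty when the pedigree is inconsistent.
#' @export
deduce_haplogenotypes <- function(ped, trios, bound = 3) {
  ped <- .validate_ped(ped)
  cand <- .candidate_sets(ped, trios, bound)
  cand <- .prune(ped, cand)
  report <- check_transmission(ped, trios, bound)
  out <- setNames(vector("list", nrow(ped)), ped$id)
  if (!report$consistent) {
    out[] <- list(list())
    attr(out, "report") <- report
    return(out)
  }
  for (id in ped$id) {
    keep <- list()
    for (p in cand[[id]]) {
      cand2 <- cand
      cand2[[id]] <- list(p)
      cand2 <- .prune(ped, cand2)
      if (all(vapply(cand2, length, integer(1)) > 0L) &&
          !is.null(.witness(ped, cand2)))
        keep[[length(keep) + 1L]] <- p
    }
    out[[id]] <- keep
  }
  attr(out, "report") <- report
  out
}
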