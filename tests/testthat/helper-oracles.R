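# Independent brute-force oracles used by the pedigree and caller tests.
# These deliberately re-derive results from first principles rather than
# calling the package internals they check.

# All unordered haplotype pairs (each arm count 0..bound) summing to trio.
oracle_pairs <- function(trio, bound = 3) {
  haps <- as.matrix(expand.grid(b = 0:bound, n = 0:bound, c = 0:bound))
  out <- list()
  for (i in seq_len(nrow(haps))) for (j in i:nrow(haps)) {
    if (all(haps[i, ] + haps[j, ] == trio))
      out[[length(out) + 1L]] <- unname(rbind(haps[i, ], haps[j, ]))
  }
  out
}

oracle_pair_key <- function(p) {
  k <- apply(p, 1, paste, collapse = "/")
  paste(sort(k), collapse = "|")
}

oracle_hap_in <- function(h, p) all(h == p[1, ]) || all(h == p[2, ])

oracle_triple_ok <- function(pf, pm, pc) {
  (oracle_hap_in(pc[1, ], pf) && oracle_hap_in(pc[2, ], pm)) ||
    (oracle_hap_in(pc[2, ], pf) && oracle_hap_in(pc[1, ], pm))
}

# Exhaustive enumeration of all globally consistent assignments for a small
# pedigree; returns per-individual union of surviving pairs (as key sets)
# and a consistency flag.
oracle_deduce <- function(ped, trios, bound = 3) {
  ids <- as.character(ped$id)
  fa <- as.character(ped$father)
  mo <- as.character(ped$mother)
  cand <- lapply(ids, function(id) {
    row <- trios[match(id, as.character(trios$id)), , drop = FALSE]
    stopifnot(nrow(row) == 1L)
    oracle_pairs(as.integer(row[1, c("b", "n", "c")]), bound)
  })
  names(cand) <- ids
  sizes <- vapply(cand, length, integer(1))
  if (any(sizes == 0L))
    return(list(consistent = FALSE,
                sets = setNames(rep(list(character(0)), length(ids)), ids)))
  idx <- do.call(expand.grid, lapply(sizes, seq_len))
  keep <- setNames(rep(list(character(0)), length(ids)), ids)
  consistent <- FALSE
  for (r in seq_len(nrow(idx))) {
    asg <- lapply(ids, function(id) cand[[id]][[idx[r, id]]])
    names(asg) <- ids
    ok <- TRUE
    for (k in which(fa != "0")) {
      if (!oracle_triple_ok(asg[[fa[k]]], asg[[mo[k]]], asg[[ids[k]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      consistent <- TRUE
      for (id in ids)
        keep[[id]] <- union(keep[[id]], oracle_pair_key(asg[[id]]))
    }
  }
  list(consistent = consistent, sets = keep)
}

# Deterministic numeric vector with exact mean and sd (for t-test oracles
# from printed summary statistics).
raw_with_stats <- function(mean, sd, n) {
  x <- as.numeric(scale(seq_len(n)))
  x * sd + mean
}
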