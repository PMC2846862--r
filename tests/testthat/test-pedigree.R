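test_that("haplotype-pair enumeration matches brute force", {
  expect_length(enumerate_haplotype_pairs(c(0, 0, 0)), 1L)
  p000 <- enumerate_haplotype_pairs(c(0, 0, 0))[[1]]
  expect_equal(unname(p000), rbind(c(0L, 0L, 0L), c(0L, 0L, 0L)))
  # (0,2,2) decompositions include the balanced (0,1,1)+(0,1,1)
  keys <- vapply(enumerate_haplotype_pairs(c(0, 2, 2)), function(p)
    paste(sort(apply(p, 1, paste, collapse = "/")), collapse = "|"),
    character(1))
  expect_true("0/1/1|0/1/1" %in% keys)
  for (trio in list(c(0, 2, 2), c(0, 2, 3), c(1, 2, 3), c(2, 2, 2),
                    c(6, 2, 6), c(0, 2, 0))) {
    got <- enumerate_haplotype_pairs(trio)
    want <- oracle_pairs(trio)
    expect_length(got, length(want))
    expect_setequal(vapply(got, oracle_pair_key, character(1)),
                    vapply(want, oracle_pair_key, character(1)))
  }
  # trio exceeding twice the bound admits no decomposition
  expect_length(enumerate_haplotype_pairs(c(7, 2, 0), bound = 3), 0L)
})

test_that("transmission check accepts a mixed-lineage family", {
  # paternal lineage constant 4:2 (1,2,3); maternal constant 2:2 (0,2,2)
  ped <- data.frame(
    id = c("gf2", "gm2", "dad", "mom", "k1", "k2"),
    father = c("0", "0", "0", "gf2", "dad", "dad"),
    mother = c("0", "0", "0", "gm2", "mom", "mom"))
  trios <- data.frame(id = c("gf2", "gm2", "dad", "mom", "k1", "k2"),
                      b = c(0, 0, 1, 0, 1, 0),
                      n = c(2, 2, 2, 2, 2, 2),
                      c = c(2, 2, 3, 2, 2, 3))
  rep <- check_transmission(ped, trios)
  expect_true(rep$consistent)
  # witness haplogenotypes re-sum to the input trios ...
  for (id in names(rep$witness))
    expect_equal(unname(colSums(rep$witness[[id]])),
                 as.integer(trios[trios$id == id, c("b", "n", "c")]),
                 ignore_attr = TRUE)
  # ... and satisfy transmission at every parents-child triple
  for (k in which(ped$father != "0"))
    expect_true(oracle_triple_ok(rep$witness[[ped$father[k]]],
                                 rep$witness[[ped$mother[k]]],
                                 rep$witness[[ped$id[k]]]))
})

test_that("impossible children are flagged inconsistent, not repaired", {
  ped <- data.frame(id = c("f", "m", "k"), father = c("0", "0", "f"),
                    mother = c("0", "0", "m"))
  trios <- data.frame(id = c("f", "m", "k"),
                      b = c(0, 0, 5), n = c(2, 2, 2), c = c(2, 2, 5))
  rep <- check_transmission(ped, trios)
  expect_false(rep$consistent)
  expect_true(length(rep$conflicted) > 0)
  # genotyping-error tolerance: dropping the child restores consistency
  rep2 <- check_transmission(ped, trios, max_drop = 1)
  expect_true(rep2$consistent)
  expect_equal(rep2$dropped, "k")
})

test_that("deduction equals the exhaustive oracle on small pedigrees", {
  peds <- list(
    list(ped = data.frame(id = c("f", "m", "k"),
                          father = c("0", "0", "f"),
                          mother = c("0", "0", "m")),
         trios = data.frame(id = c("f", "m", "k"),
                            b = c(1, 0, 0), n = c(2, 2, 2),
                            c = c(3, 2, 3))),
    list(ped = data.frame(id = c("f", "m", "k1", "k2"),
                          father = c("0", "0", "f", "f"),
                          mother = c("0", "0", "m", "m")),
         trios = data.frame(id = c("f", "m", "k1", "k2"),
                            b = c(0, 1, 1, 0), n = rep(2, 4),
                            c = c(2, 3, 2, 3))))
  for (case in peds) {
    got <- deduce_haplogenotypes(case$ped, case$trios)
    want <- oracle_deduce(case$ped, case$trios)
    expect_true(attr(got, "report")$consistent == want$consistent)
    for (id in case$ped$id) {
      got_keys <- vapply(got[[id]], oracle_pair_key, character(1))
      expect_setequal(got_keys, want$sets[[id]])
    }
  }
})

test_that("an untyped founder keeps every bounded pair", {
  ped <- data.frame(id = "solo", father = "0", mother = "0")
  got <- deduce_haplogenotypes(ped, data.frame(id = character(),
                                               b = integer(), n = integer(),
                                               c = integer()), bound = 1)
  # 8 haplotypes in the 0..1 cube -> 8*9/2 unordered pairs
  expect_length(got$solo, 8 * 9 / 2)
})

test_that("gene-dropped pedigrees are always consistent", {
  for (seed in 1:8) {
    pool <- population_preset(c("AA", "Caucasian", "Mexican")[seed %% 3 + 1])
    sim <- simulate_pedigree(pool, seed = seed)
    rep <- check_transmission(sim$ped, sim$trios)
    expect_true(rep$consistent)
    # the simulation truth survives deduction for every individual
    ded <- deduce_haplogenotypes(sim$ped, sim$trios)
    for (id in names(sim$haplotypes))
      expect_true(oracle_pair_key(sim$haplotypes[[id]]) %in%
                    vapply(ded[[id]], oracle_pair_key, character(1)))
  }
})

test_that("trio-randomised pedigrees lose consistency", {
  pool <- population_preset("AA")
  n_ok <- 0L
  n_rep <- 30L
  for (seed in seq_len(n_rep)) {
    sim <- simulate_pedigree(pool, seed = seed)
    shuffled <- local({
      set.seed(1000 + seed)
      i1 <- sample.int(nrow(pool$haplotypes), nrow(sim$trios), TRUE,
                       pool$freq)
      i2 <- sample.int(nrow(pool$haplotypes), nrow(sim$trios), TRUE,
                       pool$freq)
      data.frame(id = sim$trios$id,
                 b = pool$haplotypes[i1, "b"] + pool$haplotypes[i2, "b"],
                 n = pool$haplotypes[i1, "n"] + pool$haplotypes[i2, "n"],
                 c = pool$haplotypes[i1, "c"] + pool$haplotypes[i2, "c"])
    })
    if (check_transmission(sim$ped, shuffled)$consistent) n_ok <- n_ok + 1L
  }
  expect_lt(n_ok / n_rep, 0.8)
})

test_that("malformed pedigrees fail before any search", {
  expect_error(check_transmission(
    data.frame(id = "k", father = "ghost", mother = "m"),
    data.frame(id = "k", b = 1, n = 2, c = 1)), "parent")
  expect_error(check_transmission(
    data.frame(id = c("a", "b"), father = c("b", "a"),
               mother = c("b", "a")), data.frame()), "cycle|parents")
  expect_error(check_transmission(
    data.frame(id = "k", father = "0", mother = "m"),
    data.frame(id = "k", b = 1, n = 2, c = 1)), "both")
})
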