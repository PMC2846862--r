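test_that("haplotype pools validate their frequencies", {
  expect_error(haplotype_pool(rbind(c(0, 1, 1)), 0.9), "sum to 1")
  expect_error(haplotype_pool(matrix(numeric(0), 0, 3), numeric(0)), "empty")
  expect_error(haplotype_pool(rbind(c(-1, 1, 1)), 1), "negative")
  pool <- haplotype_pool(rbind(c(0, 1, 1), c(1, 1, 1)), c(0.25, 0.75))
  expect_s3_class(pool, "haplotype_pool")
  expect_equal(sum(pool_class_distribution(pool)), 1, tolerance = 1e-12)
})

test_that("a degenerate pool gives exact noiseless profiles", {
  pool <- haplotype_pool(rbind(c(1, 1, 1)), 1)
  sim <- simulate_population(pool, 5, noise = noise_model(0, 0), seed = 4)
  expect_true(all(sim$truth$b == 2 & sim$truth$n == 2 & sim$truth$c == 2))
  expect_equal(sim$samples$f_gt, rep(2 / 3, 5))
  expect_equal(sim$samples$f_a, rep(2 / 3, 5))
})

test_that("simulation is reproducible and seeds do not leak", {
  set.seed(123)
  before <- .Random.seed
  a <- simulate_population("AA", 50, seed = 17)
  expect_identical(before, .Random.seed) # caller RNG state untouched
  b <- simulate_population("AA", 50, seed = 17)
  expect_identical(a, b)
  d <- simulate_population("AA", 50, seed = 18)
  expect_false(identical(a$samples, d$samples))
  p1 <- simulate_pedigree("Cau", seed = 5)
  p2 <- simulate_pedigree("Cau", seed = 5)
  expect_identical(p1, p2)
  e1 <- simulate_expression(data.frame(b = 2, n = 2, c = 2), seed = 9)
  e2 <- simulate_expression(data.frame(b = 2, n = 2, c = 2), seed = 9)
  expect_identical(e1, e2)
})

test_that("zero-noise simulation round-trips through the caller", {
  # every fixed-two trio, simulated without noise, is recovered exactly
  g <- expand.grid(b = 0:6, c = 0:6)
  ef <- expected_fractions(g$b, 2, g$c)
  calls <- ncf1_call(data.frame(f_gt = ef$f_gt, f_a = ef$f_a))$calls
  expect_equal(calls[, c("b", "c")], g, ignore_attr = TRUE)
  # and the peak-table pathway carries the same information
  pool <- population_preset("AA")
  sim <- simulate_population(pool, 40, noise = noise_model(0, 0.05),
                             seed = 21)
  from_peaks <- ncf1_call(sim$peaks)$calls
  expect_equal(from_peaks[, c("b", "n", "c")],
               sim$truth[, c("b", "n", "c")], ignore_attr = TRUE)
})

test_that("class frequencies converge to the pool-implied distribution", {
  for (pop in c("AA", "Caucasian", "Mexican")) {
    pool <- population_preset(pop)
    implied <- pool_class_distribution(pool)
    sim <- simulate_population(pool, 10000, seed = 42)
    emp <- table(paste0(sim$truth$b + sim$truth$c, ":", sim$truth$n)) / 10000
    for (cls in names(implied)[implied > 0.01])
      expect_equal(as.numeric(emp[cls]), unname(implied[cls]),
                   tolerance = 0.2)
  }
})

test_that("population presets match the published population profile", {
  # AA and Caucasian 4:2 predominance and per-paralog means
  aa <- pool_class_distribution(population_preset("AA"))
  expect_equal(unname(aa["4:2"]), 0.719, tolerance = 0.02)
  cau <- pool_class_distribution(population_preset("Cau"))
  expect_equal(unname(cau["4:2"]), 0.561, tolerance = 0.02)
  mean_copies <- function(pool) {
    2 * colSums(pool$haplotypes * pool$freq)
  }
  expect_equal(unname(mean_copies(population_preset("AA"))),
               c(1.4, 2.0, 2.3), tolerance = 0.05)
  expect_equal(unname(mean_copies(population_preset("Cau"))),
               c(1.8, 2.0, 1.9), tolerance = 0.05)
  expect_equal(unname(mean_copies(population_preset("Mex"))),
               c(1.6, 2.0, 1.06), tolerance = 0.05)
})

test_that("noisy calling at the default noise level is highly accurate", {
  correct <- 0L
  total <- 0L
  for (pop in c("AA", "Caucasian", "Mexican")) {
    sim <- simulate_population(pop, 500, noise = noise_model(0.015),
                               seed = 1234)
    calls <- ncf1_call(sim$samples)$calls
    correct <- correct + sum(calls$b == sim$truth$b &
                               calls$n == sim$truth$n &
                               calls$c == sim$truth$c)
    total <- total + 500L
  }
  expect_gte(correct / total, 0.95)
})

test_that("gene dropping respects the pedigree structure", {
  sim <- simulate_pedigree("AA", seed = 77)
  # children's haplotypes each occur in the corresponding parent
  ped <- sim$ped
  for (k in which(ped$father != "0")) {
    kid <- sim$haplotypes[[ped$id[k]]]
    pf <- sim$haplotypes[[ped$father[k]]]
    pm <- sim$haplotypes[[ped$mother[k]]]
    expect_true(oracle_triple_ok(pf, pm, kid))
  }
  # homozygous founder couple breeds true
  pool <- haplotype_pool(rbind(c(0, 1, 1)), 1)
  sim2 <- simulate_pedigree(pool, noise = noise_model(0), seed = 3)
  expect_true(all(sim2$trios$b == 0 & sim2$trios$n == 2 & sim2$trios$c == 2))
  expect_error(simulate_pedigree("AA",
                                 structure = data.frame(id = "x",
                                                        father = "y",
                                                        mother = "0")),
               "both|parent")
})

test_that("zero-noise expression tables invert to the true shares", {
  trios <- data.frame(sample_id = c("a", "b"), b = c(2, 1), n = c(2, 2),
                      c = c(2, 3))
  model <- expression_model(sigma_f = 0, ct_sd = 0)
  sim <- simulate_expression(trios, model, seed = 8)
  diss <- dissect_contributions(sim$cdna$f_gtgt, sim$cdna$f_g)
  expect_equal(diss$p_B, sim$truth$p_B, tolerance = 1e-9)
  expect_equal(diss$p_N, sim$truth$p_N, tolerance = 1e-9)
  expect_equal(diss$p_C, sim$truth$p_C, tolerance = 1e-9)
  # equal rates with rho = 0.25 reproduce the 0.5:1 cDNA ratio for 2:2:2
  thp <- sim$truth[sim$truth$sample_id == "a", ]
  expect_equal(cdna_gt_ratio(c(thp$p_B, thp$p_N, thp$p_C)), 0.5)
  # Ct values invert to the true totals through the standard curve
  q_hat <- quantify(sim$curves$GT_pool,
                    sim$qpcr$ct[sim$qpcr$gene == "GT_pool"])
  expect_equal(q_hat,
               sim$truth$total_gt_output[match(
                 sim$qpcr$sample_id[sim$qpcr$gene == "GT_pool"],
                 sim$truth$sample_id)], tolerance = 1e-6)
  expect_error(simulate_expression(data.frame(b = 0, n = 0, c = 0),
                                   expression_model()), "zero-total|zero")
})

test_that("uniform rho = 1 makes cDNA shares mirror copy shares", {
  model <- expression_model(rho_B = 1, rho_C = 1, sigma_f = 0, ct_sd = 0)
  sim <- simulate_expression(data.frame(b = 2, n = 2, c = 2), model, seed = 2)
  expect_equal(unlist(sim$truth[, c("p_B", "p_N", "p_C")]),
               c(p_B = 1, p_N = 1, p_C = 1) / 3, tolerance = 1e-12)
})
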