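# Population simulator and map-quality evaluation.

test_that("marker grid includes both chromosome ends", {
  sim <- simulate_pop("BC", 5, chr_len = c(100, 200), spacing = 1, seed = 1)
  expect_equal(nrow(sim$dataset$geno), 101L + 201L)
  expect_equal(max(sim$truth$pos[sim$truth$group == "chr1"]), 100)
  expect_equal(max(sim$truth$pos[sim$truth$group == "chr2"]), 200)
})

test_that("crossover process matches the Poisson/Haldane model", {
  set.seed(2)
  pos <- c(0, 100)
  n <- 10000
  gam <- replicate(n, seriamap:::sim_gamete(pos, 100))
  # mean crossovers per gamete on 100 cM: recombinant fraction at 100 cM
  rec <- mean(gam[1, ] != gam[2, ])
  expect_lt(abs(rec - haldane_d_to_r(100)), 0.015)
  # adjacent-marker recombinant fraction at 1 cM (BC, n = 10000)
  sim <- simulate_pop("BC", 10000, chr_len = 1, spacing = 1, seed = 3)
  r1 <- mean(sim$dataset$geno[1, ] != sim$dataset$geno[2, ])
  expect_lt(abs(r1 - haldane_d_to_r(1)), 0.001 + 3 * sqrt(0.0099 / 10000) * 3)
  expect_lt(abs(r1 - 0.00990), 0.004)
})

test_that("same seed gives a bitwise-identical population", {
  a <- simulate_pop("CP", 30, chr_len = 50, spacing = 5, error_rate = 0.05,
                    missing_rate = 0.1, seed = 9)
  b <- simulate_pop("CP", 30, chr_len = 50, spacing = 5, error_rate = 0.05,
                    missing_rate = 0.1, seed = 9)
  expect_identical(a$dataset$geno, b$dataset$geno)
  expect_identical(a$error_mask, b$error_mask)
  expect_identical(a$missing_mask, b$missing_mask)
})

test_that("error and missing masks are disjoint and faithful", {
  for (pt in c("F2", "CP")) {
    sim <- simulate_pop(pt, 80, chr_len = 30, spacing = 5, error_rate = 0.1,
                        missing_rate = 0.15, seed = 13)
    expect_false(any(sim$error_mask & sim$missing_mask))
    expect_true(all(sim$dataset$geno[sim$missing_mask] == "-"))
    expect_false(any(sim$dataset$geno[sim$error_mask] == "-"))
    # zero rates: masks all false and no missing codes
    sim0 <- simulate_pop(pt, 40, chr_len = 30, spacing = 5, seed = 13)
    expect_false(any(sim0$error_mask))
    expect_false(any(sim0$missing_mask))
    expect_false(any(sim0$dataset$geno == "-"))
  }
})

test_that("empirical 2-locus class frequencies match the model tables", {
  n <- 50000
  for (pt in c("BC", "F2", "RIL", "IRIL")) {
    sim <- simulate_pop(pt, n, chr_len = 20, spacing = 20,
                        self_gens = if (pt %in% c("RIL", "IRIL")) 6 else Inf,
                        intermate_gens = if (pt == "IRIL") 2 else 0,
                        seed = 17)
    model <- pop_model(sim$dataset)
    r <- haldane_d_to_r(20)
    expected <- expected_joint_freqs(model, r)
    obs <- table(factor(sim$dataset$geno[1, ], levels = rownames(expected)),
                 factor(sim$dataset$geno[2, ], levels = colnames(expected)))
    p_obs <- obs / n
    se <- sqrt(expected * (1 - expected) / n)
    expect_true(all(abs(p_obs - expected) <= 3 * se + 1e-8), label = pt)
  }
})

test_that("gamma error-rate model converges to the uniform model", {
  sim_rate <- function(shape) {
    sim <- simulate_pop("BC", 400, chr_len = 20, spacing = 1,
                        error_rate = 0.1, error_model = "gamma",
                        gamma_shape = shape, seed = 23)
    rowMeans(sim$error_mask)  # realized per-marker rates
  }
  sharp <- sim_rate(1e6)   # effectively uniform
  lsh <- sim_rate(0.5)     # L-shaped
  expect_lt(sd(sharp), sd(lsh))
  expect_lt(abs(mean(sharp) - 0.1), 0.02)
  unif <- rowMeans(simulate_pop("BC", 400, chr_len = 20, spacing = 1,
                                error_rate = 0.1, seed = 23)$error_mask)
  expect_lt(abs(sd(sharp) - sd(unif)), 0.01)
})

test_that("map evaluation handles identity, reversal and truncation", {
  sim <- simulate_pop("BC", 10, chr_len = c(60, 100), spacing = 10, seed = 29)
  truth <- sim$truth
  q <- evaluate_map(truth, truth)
  expect_true(all(q$spearman == 1))
  expect_equal(q$length_ratio, 1)
  expect_equal(q$inclusion_rate, 1)
  # reversed groups are orientation-free
  rev_map <- as.data.frame(truth)
  for (g in unique(rev_map$group)) {
    i <- rev_map$group == g
    rev_map$pos[i] <- max(rev_map$pos[i]) - rev(rev_map$pos[i])
    rev_map$marker[i] <- rev(rev_map$marker[i])
  }
  q2 <- evaluate_map(genetic_map(rev_map), truth)
  expect_true(all(abs(q2$spearman) == 1))
  # dropping a terminal 10 cM of a 100 cM group: covered ratio 1, full 0.9-ish
  cut <- as.data.frame(truth)
  drop <- cut$group == "chr2" & cut$pos > 90
  cut <- cut[!drop, ]
  q3 <- evaluate_map(genetic_map(cut), truth)
  expect_equal(q3$length_ratio_covered, 1, tolerance = 1e-9)
  expect_equal(q3$length_ratio, 150 / 160, tolerance = 1e-9)
  # disjoint maps give the undefined-sentinel report
  other <- data.frame(group = "LG1", marker = c("x1", "x2"), pos = c(0, 5),
                      status = "framework", bin = NA)
  q4 <- evaluate_map(genetic_map(other), truth)
  expect_true(is.na(q4$length_ratio))
  expect_equal(q4$n_groups, 0L)
})
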