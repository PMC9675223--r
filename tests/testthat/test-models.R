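# Mapping functions, 2-locus distributions, RIL chains, 2-point estimation.

test_that("Haldane mapping function and inverse", {
  expect_equal(haldane_r_to_d(0), 0)
  expect_equal(haldane_r_to_d(0.25), -50 * log(0.5), tolerance = 1e-12)
  expect_equal(haldane_d_to_r(100), (1 - exp(-2)) / 2, tolerance = 1e-12)
  r <- seq(0, 0.49, by = 0.01)
  expect_equal(haldane_d_to_r(haldane_r_to_d(r)), r, tolerance = 1e-12)
  expect_warning(out <- haldane_r_to_d(0.5), "infinite")
  expect_identical(out, Inf)
  expect_error(haldane_r_to_d(-0.1))
  # Kosambi pair is mutually inverse too
  expect_equal(kosambi_d_to_r(kosambi_r_to_d(r)), r, tolerance = 1e-12)
})

# exhaustive ordered-gamete enumeration oracle for 2-locus class tables
enum_joint <- function(pop_type, r) {
  t2 <- matrix(c(1 - r, r, r, 1 - r), 2L)
  if (pop_type == "BC") {
    out <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
    for (a in 0:1) for (b in 0:1)
      out[a + 1, b + 1] <- out[a + 1, b + 1] + 0.5 * t2[a + 1, b + 1]
    return(out)
  }
  # F2: enumerate the 4x4 table of ordered maternal x paternal gametes
  out <- matrix(0, 3, 3, dimnames = list(c("A", "H", "B"), c("A", "H", "B")))
  cls <- function(x, y) if (x == 0 && y == 0) 1 else if (x == 1 && y == 1) 3 else 2
  for (am in 0:1) for (bm in 0:1) for (ap in 0:1) for (bp in 0:1) {
    pm <- 0.5 * t2[am + 1, bm + 1]
    pp <- 0.5 * t2[ap + 1, bp + 1]
    out[cls(am, ap), cls(bm, bp)] <- out[cls(am, ap), cls(bm, bp)] + pm * pp
  }
  out
}

test_that("expected 2-locus class tables match enumeration and factorize", {
  for (r in c(0, 0.1, 0.27, 0.5)) {
    bc <- expected_joint_freqs(pop_model("BC"), r)
    expect_equal(sum(bc), 1, tolerance = 1e-12)
    expect_equal(unclass(bc), unclass(enum_joint("BC", r)), tolerance = 1e-12)
    f2 <- expected_joint_freqs(pop_model("F2"), r)
    expect_equal(sum(f2), 1, tolerance = 1e-12)
    expect_equal(unclass(f2), unclass(enum_joint("F2", r)), tolerance = 1e-12)
    # RIL and CP tables are proper distributions at every r
    ril <- expected_joint_freqs(pop_model("RIL", self_gens = 6), r)
    expect_equal(sum(ril), 1, tolerance = 1e-12)
    cp <- expected_joint_freqs(pop_model("CP"), r)
    expect_equal(sum(cp), 1, tolerance = 1e-12)
  }
  # r = 0 leaves only the two parental classes in a BC
  expect_equal(as.vector(expected_joint_freqs(pop_model("BC"), 0)),
               c(0.5, 0, 0, 0.5))
  # r = 0.5 factorizes into single-locus margins
  f2 <- expected_joint_freqs(pop_model("F2"), 0.5)
  expect_equal(unclass(f2), outer(c(.25, .5, .25), c(.25, .5, .25)),
               ignore_attr = TRUE, tolerance = 1e-12)
  # F2 double-heterozygote probability, closed form
  r <- 0.17
  expect_equal(expected_joint_freqs(pop_model("F2"), r)["H", "H"],
               ((1 - r)^2 + r^2) / 2, tolerance = 1e-12)
})

test_that("RIL observed recombinant fraction matches the closed form", {
  expect_equal(ril_observed_R(0), 0)
  expect_equal(ril_observed_R(0.5), 0.5, tolerance = 1e-9)
  r <- c(0.05, 0.2, 0.35)
  expect_equal(ril_observed_R(r), 2 * r / (1 + 2 * r), tolerance = 1e-9)
  # IRIL with 0 intermating generations is a plain RIL, on a grid of r
  expect_equal(ril_observed_R(r, self_gens = 6, intermate_gens = 0),
               ril_observed_R(r, self_gens = 6), tolerance = 1e-12)
  # intermating expands the observed recombination
  expect_true(all(ril_observed_R(r, Inf, 3) > ril_observed_R(r, Inf, 0)))
  # R is monotone in r (needed for the inverse transform)
  Rs <- ril_observed_R(seq(0, 0.5, by = 0.05), 8, 2)
  expect_true(all(diff(Rs) > 0))
})

test_that("BC 2-point estimates match count maximum likelihood", {
  ds <- bc_pair(100, 10)
  est <- estimate_two_point(ds, "m1", "m2")
  expect_equal(est$r_hat, 0.10, tolerance = 1e-6)
  expect_equal(est$n_informative, 100L)
  ds0 <- bc_pair(100, 0)
  est0 <- estimate_two_point(ds0, "m1", "m2")
  expect_equal(est0$r_hat, 0, tolerance = 1e-5)
  expect_equal(est0$lod, 100 * log10(2), tolerance = 1e-6)
})

test_that("CP opposite-parent pseudo-testcross pair is uninformative", {
  g <- rbind(m1 = c("aa", "ab", "aa", "ab"), m2 = c("aa", "ab", "ab", "aa"))
  colnames(g) <- paste0("i", 1:4)
  ds <- seg_data(g, "CP", cp_parents = rbind(c("ab", "aa"), c("aa", "ab")))
  est <- estimate_two_point(ds, "m1", "m2")
  expect_false(est$informative)
  expect_equal(est$lod, 0)
  expect_true(is.na(est$r_hat))
})

test_that("2-point EM equals fine-grid ML across population types", {
  set.seed(11)
  for (rep in 1:25) {
    pt <- c("BC", "F2", "RIL", "CP")[(rep %% 4) + 1]
    ds <- random_ds(pt, m = 2, n = 40, miss = 0.15)
    est <- estimate_two_point(ds, 1, 2)
    if (!est$informative) next
    oracle <- grid_two_point(ds)
    expect_equal(est$r_hat, unname(oracle["r"]), tolerance = 5e-4,
                 label = sprintf("%s rep %d r_hat", pt, rep))
  }
})

test_that("2-point estimation is symmetric in its arguments", {
  set.seed(3)
  for (pt in c("F2", "CP")) {
    ds <- random_ds(pt, m = 2, n = 50)
    a <- estimate_two_point(ds, 1, 2)
    b <- estimate_two_point(ds, 2, 1)
    expect_equal(a$r_hat, b$r_hat, tolerance = 1e-6)
    expect_equal(a$lod, b$lod, tolerance = 1e-6)
  }
})

test_that("2-point matrix is symmetric with sentinel diagonal", {
  sim <- simulate_pop("F2", 60, chr_len = 30, spacing = 10, seed = 5)
  tp <- two_point_matrix(sim$dataset)
  expect_true(all(is.na(diag(tp$lod))))
  expect_equal(tp$lod, t(tp$lod))
  expect_equal(tp$r, t(tp$r))
  # permuting individuals leaves the matrix unchanged
  ds2 <- sim$dataset
  perm <- sample(ncol(ds2$geno))
  ds2$geno <- ds2$geno[, perm]
  tp2 <- two_point_matrix(ds2)
  expect_equal(tp2$lod, tp$lod, tolerance = 1e-9)
})

test_that("a duplicated marker attains the maximum LOD for the sample size", {
  ds <- bc_pair(80, 8)
  g <- rbind(ds$geno, m3 = ds$geno["m1", ])
  ds3 <- seg_data(g, "BC")
  tp <- two_point_matrix(ds3)
  expect_equal(tp$lod["m1", "m3"], 80 * log10(2), tolerance = 1e-6)
})

test_that("LOD decreases with true r on simulated data (in expectation)", {
  set.seed(21)
  mean_lod <- vapply(c(0.05, 0.15, 0.3), function(r) {
    lods <- replicate(30, {
      n <- 120
      m1 <- sample(c("A", "B"), n, replace = TRUE)
      rec <- runif(n) < r
      m2 <- ifelse(rec, ifelse(m1 == "A", "B", "A"), m1)
      g <- rbind(m1 = m1, m2 = m2); colnames(g) <- paste0("i", 1:n)
      estimate_two_point(seg_data(g, "BC"), "m1", "m2")$lod
    })
    mean(lods)
  }, 0)
  expect_true(all(diff(mean_lod) < 0))
})
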