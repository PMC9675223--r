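# Multipoint HMM: likelihood, EM, posteriors, phase inference.

test_that("multipoint likelihood equals exhaustive enumeration", {
  set.seed(4)
  for (pt in c("BC", "DH", "F2", "RIL", "IRIL", "CP")) {
    ds <- random_ds(pt, m = 3, n = 5, miss = 0.2)
    d <- c(8, 15)
    mod <- mp_model(ds, rownames(ds$geno), d = d, eps = 0.02,
                    phases = if (pt == "CP") c(1L, 2L, 1L) else NULL)
    ll <- multipoint_loglik(mod, ds)
    expect_equal(as.numeric(ll), enum_loglik(ds, rownames(ds$geno), d, 0.02,
                                             mod$phases),
                 tolerance = 1e-10, label = pt)
  }
})

test_that("2-marker multipoint reduces to the 2-point likelihood", {
  ds <- bc_pair(60, 9)
  r0 <- haldane_d_to_r(20)
  mod <- mp_model(ds, c("m1", "m2"), d = 20, eps = 0)
  ll_mp <- as.numeric(multipoint_loglik(mod, ds))
  # 2-point likelihood on class counts at the same r
  jf <- expected_joint_freqs(pop_model("BC"), r0)
  n_rec <- sum(ds$geno["m1", ] != ds$geno["m2", ])
  ll_2pt <- n_rec * log10(r0 / 2) + (60 - n_rec) * log10((1 - r0) / 2)
  expect_equal(ll_mp, ll_2pt, tolerance = 1e-10)
  expect_equal(jf["A", "B"] + jf["B", "A"], r0, tolerance = 1e-12)
})

test_that("a fully missing marker leaves the likelihood invariant to its intervals", {
  ds <- random_ds("F2", m = 3, n = 10, miss = 0)
  ds$geno[2L, ] <- "-"
  mk <- rownames(ds$geno)
  l1 <- multipoint_loglik(mp_model(ds, mk, d = c(5, 20), eps = 0), ds)
  l2 <- multipoint_loglik(mp_model(ds, mk, d = c(20, 5), eps = 0), ds)
  l3 <- multipoint_loglik(mp_model(ds, mk, d = c(12.5, 12.5), eps = 0), ds)
  # only the total distance matters once the middle marker is blank
  d1 <- haldane_r_to_d(0.5 * (1 - (1 - 2 * haldane_d_to_r(5)) *
                                (1 - 2 * haldane_d_to_r(20))))
  expect_equal(as.numeric(l1), as.numeric(l2), tolerance = 1e-12)
  expect_equal(as.numeric(l1), as.numeric(l3), tolerance = 1e-12)
  expect_equal(d1, 25, tolerance = 1e-9)  # Haldane distances are additive
})

test_that("EM on complete BC data recovers adjacent-pair count estimates", {
  sim <- simulate_pop("BC", 120, chr_len = 40, spacing = 10, seed = 9)
  ds <- sim$dataset
  mk <- rownames(ds$geno)
  counts <- vapply(seq_len(length(mk) - 1L),
                   function(k) mean(ds$geno[k, ] != ds$geno[k + 1L, ]), 0)
  mod <- mp_model(ds, mk, d = rep(10, length(mk) - 1L), eps = 0)
  fit <- em_fit_intervals(mod, ds)
  expect_equal(fit$r, counts, tolerance = 1e-5)
  # log-likelihood trace is non-decreasing
  expect_true(all(diff(fit$trace) > -1e-9))
})

test_that("EM recovers interval r under heavy missingness (F2)", {
  set.seed(31)
  errs <- replicate(20, {
    sim <- simulate_pop("F2", 200, chr_len = 25, spacing = 2.5,
                        missing_rate = 0.2)
    ds <- sim$dataset
    mk <- rownames(ds$geno)
    mod <- mp_model(ds, mk, d = rep(2.5, length(mk) - 1L), eps = 0)
    fit <- em_fit_intervals(mod, ds)
    mean(fit$r)
  })
  r_true <- haldane_d_to_r(2.5)
  expect_lt(abs(mean(errs) - r_true), 0.015)
})

test_that("posteriors match brute-force conditioning and force imputation", {
  set.seed(12)
  ds <- random_ds("BC", m = 3, n = 6, miss = 0.25)
  mk <- rownames(ds$geno)
  mod <- mp_model(ds, mk, d = c(10, 20), eps = 0)
  post <- impute_posteriors(mod, ds)
  # brute force: P(state at locus 2 | all obs) per individual
  r <- haldane_d_to_r(c(10, 20))
  for (q in seq_len(6)) {
    num <- c(0, 0); den <- 0
    for (s1 in 1:2) for (s2 in 1:2) for (s3 in 1:2) {
      w <- 0.5 * (if (s1 == s2) 1 - r[1] else r[1]) *
           (if (s2 == s3) 1 - r[2] else r[2])
      obs <- ds$geno[, q]
      comp <- all(obs == "-" | (obs == "A" & c(s1, s2, s3) == 1) |
                    (obs == "B" & c(s1, s2, s3) == 2))
      if (comp) { num[s2] <- num[s2] + w; den <- den + w }
    }
    expect_equal(post$gamma[, q, 2L], num / den, tolerance = 1e-10)
  }
  expect_true(all(abs(colSums(post$gamma[, , 2L]) - 1) < 1e-12))
  # missing call flanked at r ~ 0 by identical homozygotes is forced
  g <- rbind(a = c("A", "B"), b = c("-", "B"), c = c("A", "B"))
  colnames(g) <- c("i1", "i2")
  dsf <- seg_data(g, "BC")
  modf <- mp_model(dsf, c("a", "b", "c"), d = c(1e-6, 1e-6), eps = 0)
  pf <- impute_posteriors(modf, dsf)
  expect_equal(pf$gamma[1L, 1L, 2L], 1, tolerance = 1e-4)
  expect_equal(unname(pf$imputed["b", 1L]), "A")
})

test_that("likelihood is invariant under chain reversal", {
  set.seed(14)
  for (pt in c("BC", "F2", "RIL", "CP")) {
    ds <- random_ds(pt, m = 4, n = 12, miss = 0.1)
    mk <- rownames(ds$geno)
    ph <- if (pt == "CP") rep(1L, 4L) else NULL
    d <- c(5, 12, 8)
    l1 <- multipoint_loglik(mp_model(ds, mk, d = d, eps = 0.01, phases = ph), ds)
    l2 <- multipoint_loglik(mp_model(ds, rev(mk), d = rev(d), eps = 0.01,
                                     phases = ph), ds)
    expect_equal(as.numeric(l1), as.numeric(l2), tolerance = 1e-10, label = pt)
  }
})

test_that("a nonzero error rate absorbs singleton calls", {
  # individual 1 carries an isolated flip at the middle of a tight grid
  n <- 20
  g <- matrix("A", 5, n, dimnames = list(paste0("m", 1:5), paste0("i", 1:n)))
  g[, seq(2, n, by = 2)] <- "B"
  g[3, 1] <- "B"  # singleton in individual 1
  ds <- seg_data(g, "BC")
  mk <- rownames(g)
  l_eps <- multipoint_loglik(mp_model(ds, mk, d = rep(1, 4), eps = 0.01), ds)
  l_0 <- multipoint_loglik(mp_model(ds, mk, d = rep(1, 4), eps = 1e-12), ds)
  expect_gt(as.numeric(l_eps), as.numeric(l_0))
})

test_that("CP phase is recovered when extending a map", {
  set.seed(17)
  hits <- replicate(50, {
    sim <- simulate_pop("CP", 200, chr_len = 20, spacing = 10,
                        cp_class_probs = c(0, 0, 0, 1))  # ab x cd markers
    ds <- sim$dataset
    mk <- rownames(ds$geno)
    # chain = first two markers with phases matching the simulated haplotypes
    hap <- sim$parent_haplotypes
    true_cfg <- function(k) {
      sw1 <- hap[k, 1L] > hap[k, 2L]   # alleles sorted means swap iff reversed
      sw2 <- hap[k, 3L] > hap[k, 4L]
      1L + sw1 + 2L * sw2
    }
    mod <- mp_model(ds, mk[1:2], d = 10, eps = 0,
                    phases = c(true_cfg(1L), true_cfg(2L)))
    inf <- infer_phase_on_extension(mod, ds, mk[3L])
    inf$phase == true_cfg(3L)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("phase inference structure: one-parent markers give 2 variants", {
  g <- rbind(m1 = c("ac", "ad", "bc", "bd"), m2 = c("ac", "bd", "ad", "bc"),
             m3 = c("aa", "ab", "aa", "ab"))
  colnames(g) <- paste0("i", 1:4)
  ds <- seg_data(g, "CP",
                 cp_parents = rbind(c("ab", "cd"), c("ab", "cd"), c("ab", "aa")))
  mod <- mp_model(ds, c("m1", "m2"), d = 10, eps = 0, phases = c(1L, 1L))
  inf <- infer_phase_on_extension(mod, ds, "m3")
  expect_equal(length(inf$ll_by_variant), 2L)
  expect_gte(inf$advantage, 0)
  # uninformative marker is rejected upstream
  g2 <- rbind(g, m4 = c("aa", "aa", "aa", "aa"))
  ds2 <- seg_data(g2, "CP", cp_parents = rbind(ds$cp_parents, c("aa", "aa")))
  mod2 <- mp_model(ds2, c("m1", "m2"), d = 10, eps = 0, phases = c(1L, 1L))
  expect_error(infer_phase_on_extension(mod2, ds2, "m4"), "uninformative")
})
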