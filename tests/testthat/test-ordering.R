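# Seeds, scaffold seriation, framework densification, order robustness.

sim_small_f2 <- function(seed = 23, n = 150) {
  simulate_pop("F2", n, chr_len = c(40, 60), spacing = 4, seed = seed)
}

test_that("seed generation honors anchoring, twins and linkage", {
  sim <- sim_small_f2()
  ds <- sim$dataset
  tp <- two_point_matrix(ds)
  set.seed(1)
  # with a physical map: at least one pair per declared chromosome
  phymap <- data.frame(marker = sim$truth$marker,
                       chr = sim$truth$group,
                       pos = sim$truth$pos)
  class(phymap) <- c("physical_map", "data.frame")
  seeds <- generate_seeds(ds, tp, phymap, map_params())
  expect_gte(length(seeds), 2L)
  chr_of <- setNames(phymap$chr, phymap$marker)
  expect_setequal(unique(vapply(seeds, function(s) chr_of[[s$markers[1]]], "")),
                  c("chr1", "chr2"))
  # without anchoring: one seed per linkage component
  seeds2 <- generate_seeds(ds, tp, NULL, map_params())
  expect_equal(length(seeds2), 2L)

  # mutually unlinked markers cannot seed a map
  g <- matrix(sample(c("A", "B"), 20 * 30, replace = TRUE), 20, 30,
              dimnames = list(paste0("m", 1:20), paste0("i", 1:30)))
  dsu <- seg_data(g, "BC")
  tpu <- two_point_matrix(dsu)
  expect_error(generate_seeds(dsu, tpu, NULL, map_params()), "seed")

  # a twin pair is never a seed even at maximal LOD
  base <- sample(c("A", "B"), 60, replace = TRUE)
  g2 <- rbind(t1 = base, t2 = base,
              x1 = sample(c("A", "B"), 60, replace = TRUE))
  colnames(g2) <- paste0("i", 1:60)
  ds2 <- seg_data(g2, "BC")
  tp2 <- two_point_matrix(ds2)
  tw <- find_twins(ds2, 20)
  expect_error(generate_seeds(ds2, tp2, NULL, map_params(), twins = tw), "seed")
})

test_that("scaffold seriation recovers the simulated order", {
  sim <- simulate_pop("BC", 200, chr_len = 60, spacing = 4, seed = 41)
  ds <- sim$dataset
  tp <- two_point_matrix(ds)
  set.seed(2)
  seeds <- generate_seeds(ds, tp, NULL, map_params())
  sc <- build_scaffold(seeds[[1]], ds, tp, map_params())
  expect_gte(length(sc$markers), 5L)
  truth_pos <- sim$truth$pos[match(sc$markers, sim$truth$marker)]
  expect_equal(abs(cor(seq_along(sc$markers), truth_pos, method = "spearman")), 1)

  # a seed pair among only unlinked markers stays a pair
  g <- rbind(ds$geno[c(1, 2), ],
             u1 = sample(c("A", "B"), 200, replace = TRUE),
             u2 = sample(c("A", "B"), 200, replace = TRUE))
  rownames(g) <- c("s1", "s2", "u1", "u2")
  ds2 <- seg_data(g, "BC")
  tp2 <- two_point_matrix(ds2)
  sc2 <- build_scaffold(list(markers = c("s1", "s2"),
                             component = rownames(g)), ds2, tp2, map_params())
  expect_equal(sort(sc2$markers), c("s1", "s2"))
})

test_that("overlapping scaffolds from two seeds on one chromosome merge", {
  sim <- simulate_pop("BC", 200, chr_len = 60, spacing = 3, seed = 47)
  ds <- sim$dataset
  tp <- two_point_matrix(ds)
  mk <- rownames(ds$geno)
  pool <- mk
  s1 <- build_scaffold(list(markers = mk[c(3, 5)], component = pool), ds, tp)
  s2 <- build_scaffold(list(markers = mk[c(15, 17)], component = pool), ds, tp)
  # the two scaffolds tile the same chromosome (strong cross-linkage)
  expect_gte(max(tp$lod[s1$markers, s2$markers], na.rm = TRUE), 6)
  merged <- merge_scaffolds(list(s1, s2), ds, tp, map_params())
  expect_equal(length(merged), 1L)
  truth_pos <- sim$truth$pos[match(merged[[1]]$markers, sim$truth$marker)]
  expect_equal(abs(cor(seq_along(truth_pos), truth_pos, method = "spearman")), 1)
  # chains sharing markers also collapse into one group
  s3 <- s1
  merged2 <- merge_scaffolds(list(s1, s3), ds, tp, map_params())
  expect_equal(length(merged2), 1L)
})

test_that("densification gates on the robustness LOD", {
  sim <- sim_small_f2(seed = 29, n = 200)
  ds <- sim$dataset
  tp <- two_point_matrix(ds)
  set.seed(3)
  seeds <- generate_seeds(ds, tp, NULL, map_params())
  g1 <- seeds[[which(vapply(seeds, function(s)
    startsWith(s$markers[1], "c1"), TRUE))[1]]]
  sc <- build_scaffold(g1, ds, tp, map_params())
  cand <- setdiff(g1$component, sc$markers)
  fw <- build_framework(sc, cand, ds, tp, map_params())
  # every accepted marker's recorded gap clears the threshold
  expect_true(all(fw$accepted$gap >= 3))
  # scaffold subset of framework subset of assigned candidates
  expect_true(all(sc$markers %in% fw$chain$markers))
  expect_true(all(fw$chain$markers %in% c(sc$markers, cand)))

  # a twin of an existing framework marker is rejected (likelihood tie)
  twin_of <- fw$chain$markers[3]
  g <- rbind(ds$geno, twinX = ds$geno[twin_of, ])
  ds2 <- seg_data(g, "F2")
  tp2 <- two_point_matrix(ds2, c(fw$chain$markers, "twinX"))
  fw2 <- build_framework(fw$chain, "twinX", ds2, tp2, map_params())
  expect_true("twinX" %in% fw2$rejected)
})

test_that("framework passes its own robustness verification", {
  sim <- simulate_pop("BC", 150, chr_len = 50, spacing = 5, seed = 31)
  ds <- sim$dataset
  tp <- two_point_matrix(ds)
  set.seed(4)
  seeds <- generate_seeds(ds, tp, NULL, map_params())
  sc <- build_scaffold(seeds[[1]], ds, tp, map_params())
  fw <- build_framework(sc, setdiff(seeds[[1]]$component, sc$markers), ds, tp,
                        map_params())
  v <- verify_order_robustness(fw$chain, ds, 3)
  expect_true(v$pass)
})

test_that("insufficient information to order a tight pair fails verification", {
  # two markers 0.5 cM apart in 100 individuals cannot be ordered at LOD 3
  sim <- simulate_pop("BC", 100, chr_len = 40, spacing = 20, seed = 53)
  ds <- sim$dataset
  set.seed(9)
  tight <- ifelse(runif(100) < 0.005,
                  ifelse(ds$geno[2, ] == "A", "B", "A"), ds$geno[2, ])
  g <- rbind(ds$geno[1:2, ], tight = tight, ds$geno[3, , drop = FALSE])
  rownames(g) <- c("a", "b", "tight", "c")
  ds2 <- seg_data(g, "BC")
  mod <- mp_model(ds2, c("a", "tight", "b", "c"), d = c(10, 0.5, 10), eps = 1e-4)
  v <- verify_order_robustness(mod, ds2, 3)
  expect_false(v$pass)
  expect_lt(v$report$gap[v$report$marker == "tight"], 3)
})

test_that("verification min-gap matches factorial enumeration on 4 markers", {
  sim <- simulate_pop("BC", 120, chr_len = 45, spacing = 15, seed = 61)
  ds <- sim$dataset
  mk <- rownames(ds$geno)
  mod <- em_fit_intervals(mp_model(ds, mk, d = rep(15, 3), eps = 0), ds)
  v <- verify_order_robustness(mod, ds, 3, exact = TRUE)
  # brute force: all 4!/2 orders, each EM-refitted
  orders <- combinat_perms(4L)
  lls <- vapply(orders, function(o) {
    if (identical(o, 1:4) || identical(o, 4:1)) return(NA_real_)
    alt <- mp_model(ds, mk[o], d = rep(10, 3), eps = 0)
    em_fit_intervals(alt, ds)$loglik
  }, 0)
  ll_map <- em_fit_intervals(mod, ds)$loglik
  expect_equal(v$min_gap, ll_map - max(lls, na.rm = TRUE), tolerance = 1e-2)
})
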