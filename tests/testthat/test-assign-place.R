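# Assignment to linkage groups and bin placement.

build_two_group_fixture <- function() {
  sim <- simulate_pop("F2", 200, chr_len = c(40, 60), spacing = 4, seed = 77)
  ds <- sim$dataset
  tp <- two_point_matrix(ds)
  set.seed(6)
  seeds <- generate_seeds(ds, tp, NULL, map_params())
  chains <- lapply(seeds, build_scaffold, ds = ds, tp = tp,
                   params = map_params())
  list(sim = sim, ds = ds, tp = tp, chains = chains)
}

test_that("markers are assigned to their simulated chromosome", {
  fx <- build_two_group_fixture()
  asg <- assign_markers(fx$ds, fx$chains, fx$tp, map_params())
  chain_chr <- vapply(fx$chains, function(ch)
    substr(ch$markers[1], 1, 2), "")
  assigned <- asg[asg$status == "assigned", ]
  expect_gt(nrow(assigned), 10L)
  expect_true(all(substr(assigned$marker, 1, 2) ==
                  chain_chr[assigned$group]))
  # a random-noise marker is unlinked
  set.seed(10)
  g <- rbind(fx$ds$geno,
             noise = sample(c("A", "H", "B"), ncol(fx$ds$geno),
                            replace = TRUE,
                            prob = c(0.25, 0.5, 0.25)))
  ds2 <- seg_data(g, "F2")
  tp2 <- two_point_matrix(ds2)
  asg2 <- assign_markers(ds2, fx$chains, tp2, map_params())
  expect_equal(asg2$status[asg2$marker == "noise"], "unlinked")
})

test_that("near-tied group LODs are flagged ambiguous", {
  # duplicated-segment construction: a chimeric marker matching two unlinked
  # patterns on exactly 150/200 calls each -> its two group LODs tie exactly
  A <- "A"; B <- "B"
  P <- rep(c(A, B), each = 100)
  Q <- rep(rep(c(A, B), each = 50), 2)
  chim <- c(rep(A, 50),                      # Q1: P=A Q=A
            rep(c(A, B), c(25, 25)),         # Q2: P=A Q=B, 25 apiece
            rep(c(A, B), c(25, 25)),         # Q3: P=B Q=A, 25 apiece
            rep(B, 50))                      # Q4: P=B Q=B
  flip <- function(v, i) { v[i] <- ifelse(v[i] == A, B, A); v }
  g <- rbind(P = P, P2 = flip(P, 1:5), Q = Q, Q2 = flip(Q, 1:5), chim = chim)
  colnames(g) <- paste0("i", 1:200)
  ds <- seg_data(g, "BC")
  tp <- two_point_matrix(ds)
  expect_equal(tp$lod["chim", "P"], tp$lod["chim", "Q"], tolerance = 1e-9)
  ch1 <- mp_model(ds, c("P", "P2"), d = 3, eps = 0)
  ch2 <- mp_model(ds, c("Q", "Q2"), d = 3, eps = 0)
  asg <- assign_markers(ds, list(ch1, ch2), tp, map_params(),
                        markers = "chim")
  expect_equal(asg$status, "ambiguous")
  expect_gte(asg$lod, map_params()$lod_assign)
})

test_that("placement freezes the framework and fills bins", {
  fx <- build_two_group_fixture()
  ds <- fx$ds; tp <- fx$tp
  params <- map_params()
  chains <- lapply(fx$chains, function(sc) {
    build_framework(sc, setdiff(rownames(ds$geno), sc$markers), ds, tp,
                    params)$chain
  })
  asg <- assign_markers(ds, chains, tp, params)
  total <- place_markers(chains, asg, ds, params,
                         scaffold_markers = unlist(lapply(fx$chains, `[[`, "markers")))
  # total = framework union placed, no duplicates
  expect_false(anyDuplicated(total$marker) > 0)
  fw_markers <- unlist(lapply(chains, `[[`, "markers"))
  expect_setequal(setdiff(total$marker, fw_markers),
                  asg$marker[asg$status == "assigned"])
  # framework cumulative positions are bitwise identical after placement
  for (g in seq_along(chains)) {
    pos_fw <- c(0, cumsum(chains[[g]]$d))
    in_total <- total$pos[match(chains[[g]]$markers, total$marker)]
    expect_identical(unname(in_total), unname(pos_fw))
  }
  # placed markers sit inside their bin
  placed <- total[total$status == "placed" & grepl("\\.\\.", total$bin), ]
  for (q in seq_len(nrow(placed))) {
    fl <- strsplit(placed$bin[q], "..", fixed = TRUE)[[1]]
    expect_gte(placed$pos[q], total$pos[total$marker == fl[1]])
    expect_lte(placed$pos[q], total$pos[total$marker == fl[2]])
  }
  # total map is colinear with the simulated truth
  q <- evaluate_map(total, fx$sim$truth, ds)
  expect_true(all(abs(q$spearman) == 1))

  # placement of zero leftovers returns the framework unchanged
  asg0 <- asg[0, ]
  fw_only <- place_markers(chains, asg0, ds, params)
  expect_setequal(fw_only$marker, fw_markers)

  # a twin of a framework marker is placed at distance 0 from it
  rep_m <- chains[[1]]$markers[4]
  twins <- list(groups = setNames(list(c(rep_m, "tw1")), rep_m),
                representative = setNames(rep_m, rep_m))
  tot2 <- place_markers(chains, asg0, ds, params, twins = twins)
  expect_equal(tot2$pos[tot2$marker == "tw1"],
               tot2$pos[tot2$marker == rep_m])
  expect_equal(tot2$status[tot2$marker == "tw1"], "placed")
})
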