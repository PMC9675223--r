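# small deterministic fixtures built in code

# BC dataset with a given recombinant pattern between two markers
bc_pair <- function(n = 100, n_rec = 10) {
  half <- n / 2
  m1 <- rep(c("A", "B"), each = half)
  m2 <- m1
  flip <- c(seq_len(n_rec %/% 2), half + seq_len(n_rec - n_rec %/% 2))
  m2[flip] <- ifelse(m1[flip] == "A", "B", "A")
  g <- rbind(m1 = m1, m2 = m2)
  colnames(g) <- paste0("i", seq_len(n))
  seg_data(g, "BC")
}

# random valid dataset for a population type
random_ds <- function(pop_type, m = 4, n = 30, miss = 0.1) {
  if (pop_type == "CP") {
    par <- t(replicate(m, sample(c("ab", "aa", "cd"), 2L,
                                 prob = c(.6, .2, .2), replace = TRUE)))
    bad <- par[, 1L] == "aa" & par[, 2L] == "aa"
    par[bad, 1L] <- "ab"
    g <- matrix("", m, n)
    for (k in seq_len(m)) {
      p1 <- strsplit(par[k, 1], "")[[1]]; p2 <- strsplit(par[k, 2], "")[[1]]
      g[k, ] <- replicate(n, paste(sort(c(sample(p1, 1), sample(p2, 1))),
                                   collapse = ""))
    }
    g[matrix(runif(m * n) < miss, m, n)] <- "-"
    dimnames(g) <- list(paste0("m", seq_len(m)), paste0("i", seq_len(n)))
    seg_data(g, "CP", cp_parents = par)
  } else {
    alpha <- switch(pop_type, BC = , DH = c("A", "B"), c("A", "H", "B"))
    g <- matrix(sample(alpha, m * n, replace = TRUE), m, n,
                dimnames = list(paste0("m", seq_len(m)), paste0("i", seq_len(n))))
    g[matrix(runif(m * n) < miss, m, n)] <- "-"
    seg_data(g, pop_type, self_gens = if (pop_type %in% c("RIL", "IRIL")) 6 else Inf,
             intermate_gens = if (pop_type == "IRIL") 2 else 0)
  }
}

# grid-search ML of the 2-point likelihood for any population type (oracle)
grid_two_point <- function(ds, i = 1L, j = 2L, step = 1e-4) {
  model <- pop_model(ds)
  obs <- seriamap:::encode_obs(ds)[c(i, j), , drop = FALSE]
  ok <- obs[1L, ] > 0L & obs[2L, ] > 0L
  obs <- obs[, ok, drop = FALSE]
  cvi <- seriamap:::compat_variants(ds, i, model)
  cvj <- seriamap:::compat_variants(ds, j, model)
  S <- model$S
  ll_at <- function(r, Ci, Cj) {
    p <- if (model$ril) ril_observed_R(r, model$self_gens, model$intermate_gens) else r
    T2 <- matrix(c(1 - p, p, p, 1 - p), 2L)
    T <- if (S == 2L) T2 else kronecker(matrix(c(1 - r, r, r, 1 - r), 2L),
                                        matrix(c(1 - r, r, r, 1 - r), 2L))
    ll <- 0
    for (q in seq_len(ncol(obs))) {
      w <- sum((Ci[obs[1L, q], ] / S) * (T %*% Cj[obs[2L, q], ]))
      ll <- ll + log(w)
    }
    ll
  }
  best <- c(r = NA, ll = -Inf)
  for (vj in seq_along(cvj)) {
    Ci <- cvi[[1L]]; Cj <- cvj[[vj]]
    # coarse scan, then fine scan at `step` around the coarse optimum
    coarse <- seq(1e-6, 0.5, by = 0.005)
    lls <- vapply(coarse, ll_at, 0, Ci = Ci, Cj = Cj)
    r0 <- coarse[which.max(lls)]
    fine <- seq(max(1e-6, r0 - 0.006), min(0.5, r0 + 0.006), by = step)
    lls <- vapply(fine, ll_at, 0, Ci = Ci, Cj = Cj)
    if (max(lls) > best["ll"])
      best <- c(r = fine[which.max(lls)], ll = max(lls))
  }
  best
}

# all permutations of 1..n
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1L))
    for (pos in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

# exhaustive hidden-sequence enumeration oracle (any population type)
enum_loglik <- function(ds, markers, d, eps = 0, phases = NULL) {
  model <- pop_model(ds)
  S <- model$S
  m <- length(markers)
  tab <- seriamap:::p_table(model)
  p <- seriamap:::p_of_d(tab, d)
  trans <- lapply(p, function(pk) {
    t2 <- matrix(c(1 - pk, pk, pk, 1 - pk), 2L)
    if (S == 2L) t2 else kronecker(t2, t2)  # for 4-state chains p = r
  })
  E <- seriamap:::emission_array(ds, markers, model, eps, phases)
  n <- dim(E)[2L]
  states <- as.matrix(expand.grid(rep(list(seq_len(S)), m)))
  total <- 0
  for (q in seq_len(n)) {
    tot <- 0
    for (z in seq_len(nrow(states))) {
      s <- states[z, ]
      w <- 1 / S * E[s[1L], q, 1L]
      for (k in seq_len(m - 1L))
        w <- w * trans[[k]][s[k], s[k + 1L]] * E[s[k + 1L], q, k + 1L]
      tot <- tot + w
    }
    total <- total + log10(tot)
  }
  total
}
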