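# Mapping-population simulator with known truth, and map-quality evaluation.
# Crossovers are drawn as a Poisson process along each chromosome (count
# ~ Poisson(L/100), positions uniform, no interference), which makes
# Haldane's mapping function exact for the simulated data.

# one gamete from a diploid parent: returns 0/1 homolog indicator per marker
sim_gamete <- function(pos, L) {
  nco <- rpois(1L, L / 100)
  xo <- sort(runif(nco, 0, L))
  (sample.int(2L, 1L) - 1L + findInterval(pos, xo)) %% 2L
}

#' Simulate a biparental mapping population
#'
#' Markers are regularly spaced at positions `0, s, 2s, ..., L` (both
#' chromosome ends included) on chromosomes of the given cM lengths.
#' Meioses are simulated without crossover interference.  Population
#' construction follows the crossing scheme: BC (one F1 gamete onto the
#' recurrent parent), DH (one gamete doubled), F2 (two F1 gametes), RIL
#' (`self_gens` selfing generations by single-seed descent), IRIL
#' (`intermate_gens` random-intermating generations after the F2, then
#' selfing), CP (two heterozygous outbred parents with independently
#' simulated meioses; marker informativeness classes drawn from
#' `cp_class_probs`).  Genotyping errors resample the observed code among
#' the other valid codes at a uniform or Gamma-distributed per-marker rate;
#' missing data are applied independently (the two masks are disjoint).
#'
#' @param pop_type population type.
#' @param n_ind number of individuals.
#' @param chr_len chromosome lengths in cM (default `c(100, 200)`).
#' @param spacing marker spacing in cM (default 1 = 1 marker/cM).
#' @param self_gens,intermate_gens RIL/IRIL generation parameters
#'   (`self_gens = Inf` is simulated as 20 selfing generations).
#' @param error_rate mean genotyping-error rate (0-1).
#' @param error_model `"uniform"` (same rate everywhere) or `"gamma"`
#'   (per-marker rates from a Gamma with mean `error_rate`); large
#'   `gamma_shape` approaches the uniform model, small shapes give the
#'   L-shaped distributions typical of marker-specific failure.
#' @param gamma_shape shape of the Gamma rate distribution.
#' @param missing_rate independent missing-data rate.
#' @param cp_class_probs CP informativeness-class probabilities, in the
#'   order (female-testcross ab x aa, male-testcross aa x ab,
#'   both-informative ab x ab, both-informative ab x cd).
#' @param seed optional RNG seed, recorded in the output.
#' @return object of class `sim_pop`: `truth` ([genetic_map]), `dataset`
#'   ([seg_data]), `error_mask`/`missing_mask` (logical matrices),
#'   `parent_haplotypes` (CP), `seed`.
#' @export
simulate_pop <- function(pop_type, n_ind, chr_len = c(100, 200), spacing = 1,
                         self_gens = Inf, intermate_gens = 0,
                         error_rate = 0, error_model = c("uniform", "gamma"),
                         gamma_shape = 2, missing_rate = 0,
                         cp_class_probs = c(0.25, 0.25, 0.25, 0.25),
                         seed = NULL) {
  pop_type <- match.arg(toupper(pop_type), POP_TYPES)
  error_model <- match.arg(error_model)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(error_rate >= 0, error_rate <= 1, missing_rate >= 0,
            missing_rate <= 1, all(chr_len > 0))
  sim_self <- if (is.finite(self_gens)) self_gens else 20L

  truth_rows <- list()
  geno_all <- list()
  cp_par_all <- list()
  cp_hap_all <- list()
  for (ci in seq_along(chr_len)) {
    L <- chr_len[ci]
    pos <- seq(0, L, by = spacing)
    m <- length(pos)
    mk <- sprintf("c%dm%04d", ci, seq_len(m))
    truth_rows[[ci]] <- data.frame(group = paste0("chr", ci), marker = mk,
                                   pos = pos, status = "framework",
                                   bin = NA_character_)
    if (pop_type == "CP") {
      sim <- sim_cp_chr(pos, L, m, n_ind, cp_class_probs)
      geno <- sim$geno
      cp_par_all[[ci]] <- sim$parents
      cp_hap_all[[ci]] <- sim$haplotypes
    } else {
      geno <- sim_inbred_chr(pop_type, pos, L, m, n_ind, sim_self,
                             intermate_gens)
    }
    rownames(geno) <- mk
    geno_all[[ci]] <- geno
  }
  geno <- do.call(rbind, geno_all)
  colnames(geno) <- sprintf("ind%03d", seq_len(n_ind))
  truth <- genetic_map(do.call(rbind, truth_rows))

  # missing first, then errors on the remaining cells (disjoint masks)
  miss_mask <- matrix(runif(length(geno)) < missing_rate, nrow(geno),
                      dimnames = dimnames(geno))
  rate <- if (error_rate == 0) {
    matrix(0, nrow(geno), ncol(geno))
  } else if (error_model == "uniform") {
    matrix(error_rate, nrow(geno), ncol(geno))
  } else {
    per_marker <- pmin(rgamma(nrow(geno), shape = gamma_shape,
                              rate = gamma_shape / error_rate), 1)
    matrix(per_marker, nrow(geno), ncol(geno))
  }
  err_mask <- matrix(runif(length(geno)) < rate, nrow(geno),
                     dimnames = dimnames(geno)) & !miss_mask

  cp_parents <- if (pop_type == "CP") do.call(rbind, cp_par_all) else NULL
  if (any(err_mask)) {
    for (k in seq_len(nrow(geno))) {
      bad <- which(err_mask[k, ])
      if (!length(bad)) next
      valid <- if (pop_type == "CP") {
        p1 <- strsplit(cp_parents[k, 1L], "")[[1L]]
        p2 <- strsplit(cp_parents[k, 2L], "")[[1L]]
        unique(as.vector(outer(p1, p2, function(a, b)
          mapply(function(x, y) paste(sort(c(x, y)), collapse = ""), a, b))))
      } else switch(pop_type, BC = , DH = c("A", "B"), c("A", "H", "B"))
      for (q in bad) {
        wrong <- setdiff(valid, geno[k, q])
        geno[k, q] <- if (length(wrong)) sample(wrong, 1L) else geno[k, q]
      }
    }
  }
  geno[miss_mask] <- MISSING_CODE

  ds <- seg_data(geno, pop_type,
                 self_gens = if (pop_type %in% c("RIL", "IRIL")) self_gens else Inf,
                 intermate_gens = intermate_gens,
                 cp_parents = cp_parents)
  structure(list(truth = truth, dataset = ds, error_mask = err_mask,
                 missing_mask = miss_mask,
                 parent_haplotypes = if (pop_type == "CP")
                   do.call(rbind, cp_hap_all) else NULL,
                 seed = seed),
            class = "sim_pop")
}

sim_inbred_chr <- function(pop_type, pos, L, m, n_ind, self_gens,
                           intermate_gens) {
  geno <- matrix("", m, n_ind)
  code_from <- function(h1, h2) {
    ifelse(h1 == 0L & h2 == 0L, "A", ifelse(h1 == 1L & h2 == 1L, "B", "H"))
  }
  if (pop_type %in% c("BC", "DH")) {
    for (q in seq_len(n_ind)) {
      g <- sim_gamete(pos, L)
      geno[, q] <- ifelse(g == 0L, "A", "B")
    }
  } else if (pop_type == "F2") {
    for (q in seq_len(n_ind))
      geno[, q] <- code_from(sim_gamete(pos, L), sim_gamete(pos, L))
  } else {
    # RIL / IRIL: individuals are pairs of haplotypes over the F1 alleles
    # F1 = (all 0, all 1); meiosis recombines an individual's pair
    meiosis <- function(ind) {
      g <- sim_gamete(pos, L)
      ifelse(g == 0L, ind[[1L]], ind[[2L]])
    }
    pop <- replicate(n_ind, list(rep(0L, m), rep(1L, m)), simplify = FALSE)
    # F2 from intermating the F1 with itself (two independent meioses)
    pop <- lapply(pop, function(ind) list(meiosis(ind), meiosis(ind)))
    if (pop_type == "IRIL" && intermate_gens > 0) {
      for (t in seq_len(intermate_gens)) {
        pop <- lapply(seq_len(n_ind), function(q) {
          par <- sample.int(n_ind, 2L, replace = FALSE)
          list(meiosis(pop[[par[1L]]]), meiosis(pop[[par[2L]]]))
        })
      }
    }
    n_self <- self_gens - 1L  # F2 construction used one generation
    if (n_self > 0) for (t in seq_len(n_self))
      pop <- lapply(pop, function(ind) list(meiosis(ind), meiosis(ind)))
    for (q in seq_len(n_ind))
      geno[, q] <- code_from(pop[[q]][[1L]], pop[[q]][[2L]])
  }
  geno
}

sim_cp_chr <- function(pos, L, m, n_ind, class_probs) {
  cls <- sample.int(4L, m, replace = TRUE, prob = class_probs)
  # parental genotypes per class; haplotype alleles assigned in random phase
  p1 <- matrix("", m, 2L); p2 <- matrix("", m, 2L)
  for (k in seq_len(m)) {
    al <- switch(cls[k],
      list(c("a", "b"), c("a", "a")),   # female-informative pseudo-testcross
      list(c("a", "a"), c("a", "b")),   # male-informative
      list(c("a", "b"), c("a", "b")),   # both, 3 classes
      list(c("a", "b"), c("c", "d")))   # both, 4 classes
    p1[k, ] <- if (runif(1) < 0.5) al[[1L]] else rev(al[[1L]])
    p2[k, ] <- if (runif(1) < 0.5) al[[2L]] else rev(al[[2L]])
  }
  geno <- matrix("", m, n_ind)
  for (q in seq_len(n_ind)) {
    g1 <- sim_gamete(pos, L) + 1L  # transmitted homolog of parent 1
    g2 <- sim_gamete(pos, L) + 1L
    a1 <- p1[cbind(seq_len(m), g1)]
    a2 <- p2[cbind(seq_len(m), g2)]
    geno[, q] <- mapply(function(x, y) paste(sort(c(x, y)), collapse = ""),
                        a1, a2)
  }
  parents <- cbind(paste0(p1[, 1L], p1[, 2L]), paste0(p2[, 1L], p2[, 2L]))
  list(geno = geno, parents = parents,
       haplotypes = cbind(p1, p2))  # columns: P1 hom1, P1 hom2, P2 hom1, P2 hom2
}

#' Compare a computed map against the reference map
#'
#' Candidate groups are matched to reference chromosomes by shared-marker
#' majority.  Reports per matched group the orientation-free Spearman rank
#' correlation between candidate and reference positions, the summed map
#' length ratio — both against the full reference length (`length_ratio`)
#' and against the reference span actually covered by the candidate's
#' markers (`length_ratio_covered`) — and the inclusion rate (mapped
#' markers / polymorphic markers in the dataset, or / reference markers
#' when no dataset is given).
#'
#' @param candidate a [genetic_map].
#' @param truth the reference [genetic_map].
#' @param ds optional [seg_data] for the inclusion denominator.
#' @param status_in restrict candidate markers to these statuses.
#' @return object of class `map_quality`: `per_group` data frame,
#'   `spearman` (named per group), `length_ratio`, `length_ratio_covered`,
#'   `inclusion_rate`, `n_groups`.
#' @export
evaluate_map <- function(candidate, truth, ds = NULL, status_in = NULL) {
  cand <- as.data.frame(candidate)
  if (!is.null(status_in)) cand <- cand[cand$status %in% status_in, ]
  tru <- as.data.frame(truth)
  shared_all <- intersect(cand$marker, tru$marker)
  if (!length(shared_all)) {
    return(structure(list(per_group = NULL, spearman = NA_real_,
                          length_ratio = NA_real_,
                          length_ratio_covered = NA_real_,
                          inclusion_rate = 0, n_groups = 0L),
                     class = "map_quality"))
  }
  per <- list()
  for (g in unique(cand$group)) {
    cg <- cand[cand$group == g, ]
    shared <- intersect(cg$marker, tru$marker)
    if (!length(shared)) next
    tchr <- names(which.max(table(tru$group[match(shared, tru$marker)])))
    tg <- tru[tru$group == tchr, ]
    sh <- intersect(cg$marker, tg$marker)
    cp_ <- cg$pos[match(sh, cg$marker)]
    tp_ <- tg$pos[match(sh, tg$marker)]
    # markers at identical candidate positions (twins, bin co-location)
    # carry no order claim: score ties in reference order, both orientations
    rho <- if (length(sh) >= 3L) {
      max(abs(cor(order(order(cp_, tp_)), rank(tp_))),
          abs(cor(order(order(-cp_, tp_)), rank(tp_))))
    } else NA_real_
    # snap floating-point residue so exact colinearity reports exactly 1
    if (!is.na(rho) && abs(rho - 1) < 1e-9) rho <- 1
    covered <- diff(range(tg$pos[match(sh, tg$marker)]))
    per[[length(per) + 1L]] <- data.frame(
      group = g, ref_group = tchr, n_shared = length(sh), spearman = rho,
      cand_length = max(cg$pos) - min(cg$pos),
      ref_length = max(tg$pos) - min(tg$pos),
      ref_covered = covered)
  }
  per <- do.call(rbind, per)
  # each reference chromosome counted once even if split across groups
  ref_total <- sum(vapply(split(per$ref_length, per$ref_group), max, 0))
  denom <- if (!is.null(ds)) sum(!monomorphic_markers(ds)) else nrow(tru)
  structure(list(
    per_group = per,
    spearman = setNames(per$spearman, per$group),
    length_ratio = sum(per$cand_length) / ref_total,
    length_ratio_covered = sum(per$cand_length) /
      sum(vapply(split(per$ref_covered, per$ref_group), max, 0)),
    inclusion_rate = nrow(cand) / denom,
    n_groups = nrow(per)), class = "map_quality")
}

#' @export
print.map_quality <- function(x, ...) {
  cat(sprintf(
    "map quality: %d group(s); |Spearman| %s; length ratio %.3f (covered %.3f); inclusion %.3f\n",
    x$n_groups, paste(sprintf("%.3f", x$spearman), collapse = "/"),
    x$length_ratio, x$length_ratio_covered, x$inclusion_rate))
  invisible(x)
}
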