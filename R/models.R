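# Population-type genetic models: mapping functions, 2-locus expected
# genotype distributions, RIL/IRIL generation chains, 2-point estimation.

#' Mapping functions
#'
#' Haldane's mapping function (exact for crossovers drawn as a Poisson
#' process without interference, which is the model used by
#' [simulate_pop()]): `d = -50 ln(1 - 2r)` and its inverse
#' `r = (1 - exp(-d/50))/2`.  Kosambi's function is provided for distance
#' reporting only.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in cM, `>= 0`.
#' @return distances in cM, or recombination fractions.
#' @export
haldane_r_to_d <- function(r) {
  if (any(r < 0, na.rm = TRUE)) stop("r must be >= 0")
  out <- ifelse(r >= 0.5, Inf, -50 * log(1 - 2 * r))
  if (any(r >= 0.5, na.rm = TRUE))
    warning("r >= 0.5 maps to infinite distance")
  out
}

#' @rdname haldane_r_to_d
#' @export
haldane_d_to_r <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("d must be >= 0")
  (1 - exp(-d / 50)) / 2
}

#' @rdname haldane_r_to_d
#' @export
kosambi_r_to_d <- function(r) {
  if (any(r < 0, na.rm = TRUE)) stop("r must be >= 0")
  ifelse(r >= 0.5, Inf, 25 * log((1 + 2 * r) / (1 - 2 * r)))
}

#' @rdname haldane_r_to_d
#' @export
kosambi_d_to_r <- function(d) 0.5 * tanh(d / 50)

# ---------------------------------------------------------------------------
# RIL / IRIL two-locus generation chains.
# Haplotypes over two loci are indexed 1..4 = (0,0),(0,1),(1,0),(1,1)
# (allele 0 from parent A, 1 from parent B); a genotype is an ordered pair
# of haplotypes (16 states).  The selfing operator is one generation of
# meiosis + self-fertilization; intermating updates the gamete-pool linkage
# disequilibrium D by the classic factor (1 - r) per generation.
# ---------------------------------------------------------------------------

HAP <- cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))

# gamete distribution of a genotype (pair of haplotype indices), given r
gamete_dist <- function(h1, h2, r) {
  g <- numeric(4L)
  add <- function(a1, a2, w) {
    idx <- 1L + 2L * a1 + a2
    g[idx] <<- g[idx] + w
  }
  # pick locus-1 homolog at random; locus-2 stays (1-r) or switches (r)
  add(HAP[h1, 1L], HAP[h1, 2L], 0.5 * (1 - r))
  add(HAP[h1, 1L], HAP[h2, 2L], 0.5 * r)
  add(HAP[h2, 1L], HAP[h2, 2L], 0.5 * (1 - r))
  add(HAP[h2, 1L], HAP[h1, 2L], 0.5 * r)
  g
}

selfing_step <- function(P, r) {
  # P: 4x4 genotype distribution (ordered haplotype pairs)
  out <- matrix(0, 4L, 4L)
  for (h1 in 1:4) for (h2 in 1:4) {
    w <- P[h1, h2]
    if (w == 0) next
    g <- gamete_dist(h1, h2, r)
    out <- out + w * (g %o% g)
  }
  out
}

# genotype distribution of a RIL/IRIL line at the observed generation
ril_genotype_dist <- function(r, self_gens = Inf, intermate_gens = 0,
                              max_gens = 200L, tol = 1e-13) {
  if (intermate_gens > 0) {
    # gamete pool after t intermating rounds beyond the F2:
    # D_t = D_0 (1-r)^t with D_0 = (1-2r)/4 for F1 gametes
    D <- (1 - 2 * r) / 4 * (1 - r)^intermate_gens
    q <- c(0.25 + D, 0.25 - D, 0.25 - D, 0.25 + D)
    P <- q %o% q  # random union of gametes
    n_self <- if (is.finite(self_gens)) self_gens - 1L else Inf
  } else {
    P <- matrix(0, 4L, 4L); P[1L, 4L] <- 1  # F1: AB / ab in coupling
    n_self <- self_gens
  }
  g <- 0L
  repeat {
    if (g >= n_self || g >= max_gens) break
    P2 <- selfing_step(P, r)
    if (!is.finite(n_self) && max(abs(P2 - P)) < tol) { P <- P2; break }
    P <- P2
    g <- g + 1L
  }
  P
}

#' Expected fraction of recombinant fixed lines in RIL/IRIL populations
#'
#' The observed 2-point recombination parameter R of the fixed-line states,
#' obtained by iterating the per-generation 2-locus genotype transition
#' (selfing recursion; random intermating shrinks gamete-pool disequilibrium
#' by (1-r) per generation).  For selfing to fixation this equals the
#' closed-form 2r/(1+2r).
#'
#' @param r per-meiosis recombination fraction(s), in `[0, 0.5]`.
#' @param self_gens selfing generations from the F1 (`Inf` = fixation).
#' @param intermate_gens random-intermating generations beyond the F2.
#' @return expected recombinant fraction R among both-locus-homozygous lines.
#' @export
ril_observed_R <- function(r, self_gens = Inf, intermate_gens = 0) {
  vapply(r, function(ri) {
    if (ri <= 0) return(0)
    P <- ril_genotype_dist(ri, self_gens, intermate_gens)
    hom <- diag(P)  # genotypes (h,h): homozygous at both loci
    sum(hom[2:3]) / sum(hom)
  }, 0)
}

# residual per-locus heterozygote frequency of a RIL/IRIL line
ril_resid_het <- function(self_gens = Inf, intermate_gens = 0) {
  if (!is.finite(self_gens)) return(0)
  n_self <- if (intermate_gens > 0) self_gens else self_gens
  0.5^n_self
}

# ---------------------------------------------------------------------------
# Population model: hidden-state chain specification
# ---------------------------------------------------------------------------

#' Population model for multipoint analysis
#'
#' Bundles the hidden-state chain used in 2-point and multipoint
#' likelihoods: BC/DH use 2 gamete states; F2 and CP use 4 states (ordered
#' pair of two meioses); RIL/IRIL use 2 fixed-line states whose transition
#' parameter is the observed recombinant-line fraction R(r), with residual
#' heterozygotes handled in the emission.
#'
#' @param ds a [seg_data] object (or a population type string).
#' @param self_gens,intermate_gens RIL/IRIL generation parameters (taken
#'   from `ds` when it is a dataset).
#' @return object of class `pop_model`.
#' @export
pop_model <- function(ds, self_gens = Inf, intermate_gens = 0) {
  if (inherits(ds, "seg_data")) {
    type <- ds$pop_type
    if (type %in% c("RIL", "IRIL")) {
      self_gens <- ds$self_gens
      intermate_gens <- ds$intermate_gens
    }
  } else type <- match.arg(toupper(ds), POP_TYPES)
  kind <- switch(type, BC = "two", DH = "two", RIL = "two", IRIL = "two",
                 F2 = "kron4", CP = "kron4")
  structure(list(
    type = type, kind = kind, S = if (kind == "two") 2L else 4L,
    ril = type %in% c("RIL", "IRIL"),
    self_gens = self_gens, intermate_gens = intermate_gens,
    resid_het = if (type %in% c("RIL", "IRIL"))
      ril_resid_het(self_gens, intermate_gens) else 0
  ), class = "pop_model")
}

# lookup table between map distance d (cM) and the chain transition
# parameter p: p = r (Haldane) for meiosis chains, p = R(r) for RIL chains
p_table <- function(model) {
  d <- c(seq(0, 10, by = 0.1), seq(10.5, 60, by = 0.5), seq(61, 400, by = 1))
  r <- haldane_d_to_r(d)
  p <- if (model$ril) ril_observed_R(r, model$self_gens, model$intermate_gens) else r
  list(d = d, p = p)
}

p_of_d <- function(tab, d) approx(tab$d, tab$p, xout = pmin(d, max(tab$d)),
                                  rule = 2L)$y
d_of_p <- function(tab, p) approx(tab$p, tab$d, xout = pmin(pmax(p, 0), max(tab$p)),
                                  rule = 2L)$y
r_of_p <- function(model, tab, p) {
  if (model$ril) haldane_d_to_r(d_of_p(tab, p)) else p
}

# ---------------------------------------------------------------------------
# Expected 2-locus genotype-class distributions
# ---------------------------------------------------------------------------

#' Expected 2-locus genotype-class probabilities
#'
#' Probability table over observed genotype-class pairs for two linked loci
#' at recombination fraction `r`.  BC/DH: classes A,B; F2 and RIL/IRIL:
#' classes A,H,B (RIL/IRIL computed exactly from the generation chain); CP:
#' offspring genotype classes of the two markers given their parental
#' genotypes and a coupling phase (defaults to fully informative ab x cd).
#'
#' @param model a [pop_model] (or population type string).
#' @param r recombination fraction in `[0, 0.5]`.
#' @param parents1,parents2 CP only: parental genotypes of the two markers,
#'   length-2 character vectors like `c("ab","cd")`.
#' @return matrix of class probabilities (rows = locus 1, columns = locus 2)
#'   summing to 1; at `r = 0.5` it factorizes into its margins.
#' @export
expected_joint_freqs <- function(model, r,
                                 parents1 = c("ab", "cd"),
                                 parents2 = c("ab", "cd")) {
  if (!inherits(model, "pop_model")) model <- pop_model(model)
  stopifnot(r >= 0, r <= 0.5)
  T2 <- matrix(c(1 - r, r, r, 1 - r), 2L)
  if (model$type %in% c("BC", "DH")) {
    out <- T2 / 2
    dimnames(out) <- list(c("A", "B"), c("A", "B"))
    return(out)
  }
  if (model$type == "F2") {
    T4 <- kronecker(T2, T2)
    # state = (maternal gamete allele, paternal gamete allele), A=0/B=1
    cls <- c(1L, 2L, 2L, 3L)  # AA, AB, BA, BB -> A, H, B
    out <- matrix(0, 3L, 3L, dimnames = list(c("A", "H", "B"), c("A", "H", "B")))
    for (s in 1:4) for (t in 1:4)
      out[cls[s], cls[t]] <- out[cls[s], cls[t]] + 0.25 * T4[s, t]
    return(out)
  }
  if (model$ril) {
    P <- ril_genotype_dist(r, model$self_gens, model$intermate_gens)
    out <- matrix(0, 3L, 3L, dimnames = list(c("A", "H", "B"), c("A", "H", "B")))
    cls1 <- function(a1, a2) if (a1 == a2) (if (a1 == 0L) 1L else 3L) else 2L
    for (h1 in 1:4) for (h2 in 1:4) {
      c1 <- cls1(HAP[h1, 1L], HAP[h2, 1L])
      c2 <- cls1(HAP[h1, 2L], HAP[h2, 2L])
      out[c1, c2] <- out[c1, c2] + P[h1, h2]
    }
    return(out)
  }
  # CP: 4 states = transmitted homolog of each parent, coupling phase
  T4 <- kronecker(T2, T2)
  g1 <- cp_state_genotypes(parents1)
  g2 <- cp_state_genotypes(parents2)
  k1 <- sort(unique(g1)); k2 <- sort(unique(g2))
  out <- matrix(0, length(k1), length(k2), dimnames = list(k1, k2))
  for (s in 1:4) for (t in 1:4)
    out[g1[s], g2[t]] <- out[g1[s], g2[t]] + 0.25 * T4[s, t]
  out
}

# offspring genotype of each CP hidden state (homolog pair), identity phase
cp_state_genotypes <- function(parents, swap1 = FALSE, swap2 = FALSE) {
  p1 <- strsplit(parents[1L], "")[[1L]]
  p2 <- strsplit(parents[2L], "")[[1L]]
  if (swap1) p1 <- rev(p1)
  if (swap2) p2 <- rev(p2)
  # states in kron order: (homolog of P1, homolog of P2) = 11,12,21,22
  out <- character(4L)
  s <- 0L
  for (i in 1:2) for (j in 1:2) {
    s <- s + 1L
    out[s] <- paste(sort(c(p1[i], p2[j])), collapse = "")
  }
  out
}
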