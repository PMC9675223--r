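# Multipoint engine: HMM over ordered loci with EM-fitted inter-marker
# recombination fractions, missing-data imputation via forward-backward
# posteriors, genotyping-error emission model and CP phase tracking.
# Likelihood kernels live in src/hmm.cpp; this file builds the observation
# encodings and emission/compatibility matrices per population type.

# --- observation encoding ---------------------------------------------------

# integer-code a dataset: 0 = missing, else class index into marker_classes
encode_obs <- function(ds, markers = markers_of(ds)) {
  idx <- marker_index(ds, markers)
  if (ds$pop_type == "CP") {
    obs <- matrix(0L, length(idx), ncol(ds$geno),
                  dimnames = list(markers_of(ds)[idx], individuals_of(ds)))
    for (k in seq_along(idx)) {
      cls <- cp_marker_classes(ds, idx[k])
      v <- ds$geno[idx[k], ]
      m <- match(v, cls)
      m[v == MISSING_CODE] <- 0L
      if (anyNA(m)) stop("unclassifiable CP code at marker ", markers[k])
      obs[k, ] <- m
    }
    obs
  } else {
    cls <- marker_classes(ds)
    m <- match(ds$geno[idx, , drop = FALSE], cls)
    m[is.na(m)] <- 0L
    matrix(as.integer(m), length(idx), ncol(ds$geno),
           dimnames = list(markers_of(ds)[idx], individuals_of(ds)))
  }
}

marker_classes <- function(ds) pop_alphabet(ds$pop_type)

# --- compatibility matrices (0/1, no-error model) ---------------------------

# one K x S matrix per phase variant; non-CP markers have a single variant.
# CP variants carry attribute "configs": which of the 4 phase configurations
# (swapP1, swapP2) each structurally distinct variant represents.
compat_variants <- function(ds, marker, model = pop_model(ds)) {
  if (ds$pop_type != "CP") {
    list(inbred_compat(model))
  } else {
    i <- marker_index(ds, marker)
    cls <- cp_marker_classes(ds, i)
    par <- ds$cp_parents[i, ]
    cfgs <- list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))
    mats <- lapply(cfgs, function(cf) {
      sg <- cp_state_genotypes(par, cf[1L], cf[2L])
      outer(cls, sg, `==`) * 1.0
    })
    keep <- !duplicated(lapply(mats, c))
    out <- mats[keep]
    attr(out, "configs") <- which(keep)
    out
  }
}

inbred_compat <- function(model) {
  switch(model$type,
    BC = , DH = diag(2),
    F2 = rbind(A = c(1, 0, 0, 0), H = c(0, 1, 1, 0), B = c(0, 0, 0, 1),
               C = c(0, 1, 1, 1), D = c(1, 1, 1, 0)),
    RIL = , IRIL = rbind(A = c(1, 0), H = c(1, 1), B = c(0, 1)))
}

# --- emission matrices (K x S, error model) ---------------------------------

# P(observed class | hidden state) with miscall rate eps; RIL residual
# heterozygosity enters as a state-conditional true-call distribution.
emission_matrix <- function(ds, marker, model, eps, phase_config = 1L) {
  if (ds$pop_type == "CP") {
    i <- marker_index(ds, marker)
    cls <- cp_marker_classes(ds, i)
    K <- length(cls)
    cfgs <- list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))
    cf <- cfgs[[phase_config]]
    sg <- cp_state_genotypes(ds$cp_parents[i, ], cf[1L], cf[2L])
    C <- outer(cls, sg, `==`) * 1.0
    if (K == 1L) return(matrix(1, 1L, 4L))
    M <- matrix(eps / (K - 1L), K, K); diag(M) <- 1 - eps
    M %*% C
  } else {
    switch(model$type,
      BC = , DH = {
        M <- matrix(c(1 - eps, eps, eps, 1 - eps), 2L)
        M  # states are the two calls
      },
      F2 = {
        M3 <- matrix(eps / 2, 3L, 3L); diag(M3) <- 1 - eps
        calls <- rbind(A = c(1, 0, 0, 0), H = c(0, 1, 1, 0), B = c(0, 0, 0, 1))
        W <- M3 %*% calls  # rows: observed A,H,B
        rbind(W, C = W[2L, ] + W[3L, ], D = W[1L, ] + W[2L, ])
      },
      RIL = , IRIL = {
        h <- model$resid_het
        M3 <- matrix(eps / 2, 3L, 3L); diag(M3) <- 1 - eps
        callgiven <- cbind(c(1 - h, h, 0), c(0, h, 1 - h))  # state AA, BB
        M3 %*% callgiven
      })
  }
}

# full emission array (S x n_ind x n_mark) for an ordered marker set
emission_array <- function(ds, markers, model, eps, phases = NULL,
                           obs = NULL) {
  if (is.null(obs)) obs <- encode_obs(ds, markers)
  S <- model$S
  n <- ncol(obs); m <- nrow(obs)
  E <- array(1, dim = c(S, n, m))
  for (k in seq_len(m)) {
    ph <- if (is.null(phases)) 1L else phases[k]
    W <- emission_matrix(ds, markers[k], model, eps, ph)
    nm <- which(obs[k, ] > 0L)
    if (length(nm)) E[, nm, k] <- t(W[obs[k, nm], , drop = FALSE])
  }
  E
}

# --- multipoint model object ------------------------------------------------

#' Multipoint model over an ordered set of markers
#'
#' @param ds a [seg_data] object.
#' @param markers ordered character vector of markers (>= 2).
#' @param d inter-marker distances in cM (length `length(markers) - 1`);
#'   defaults to distances from adjacent 2-point estimates.
#' @param eps genotyping-error emission rate (0 disables the error model).
#' @param phases CP only: integer vector of phase configurations (1..4,
#'   meaning (no swap, swap parent 1, swap parent 2, swap both)) per marker.
#' @return object of class `mp_model`.
#' @export
mp_model <- function(ds, markers, d = NULL, eps = 0.01, phases = NULL) {
  model <- pop_model(ds)
  stopifnot(length(markers) >= 2L)
  if (is.null(d)) {
    d <- vapply(seq_len(length(markers) - 1L), function(k) {
      est <- estimate_two_point(ds, markers[k], markers[k + 1L])
      r <- if (is.na(est$r_hat)) 0.3 else min(est$r_hat, 0.45)
      haldane_r_to_d(r)
    }, 0)
  }
  stopifnot(length(d) == length(markers) - 1L, all(d >= 0))
  if (model$type == "CP" && is.null(phases)) phases <- rep(1L, length(markers))
  structure(list(ds_pop = model, markers = markers, d = d, eps = eps,
                 phases = phases, tab = p_table(model)),
            class = "mp_model")
}

mp_params <- function(mod) p_of_d(mod$tab, mod$d)

mp_emission <- function(mod, ds) {
  emission_array(ds, mod$markers, mod$ds_pop, mod$eps, mod$phases)
}

#' Multipoint log10-likelihood of an ordered marker set
#'
#' Forward-algorithm likelihood summed over individuals; a missing
#' observation emits 1 in every hidden state (missing data are thereby
#' marginalized), and with `eps > 0` observations incompatible with a state
#' carry the miscall probability.
#'
#' @param mod an [mp_model].
#' @param ds the [seg_data] the model refers to.
#' @return log10-likelihood (scalar, attribute `per_ind` has per-individual
#'   contributions).
#' @export
multipoint_loglik <- function(mod, ds) {
  E <- mp_emission(mod, ds)
  res <- cpp_loglik(E, mp_params(mod), mod$ds_pop$kind)
  out <- res$loglik / log(10)
  attr(out, "per_ind") <- res$per_ind / log(10)
  out
}

#' Fit inter-marker recombination fractions by EM (Baum-Welch)
#'
#' The log-likelihood is non-decreasing across iterations; stops when the
#' log10-likelihood improves by less than `tol` or after `max_iter`
#' iterations (returning the best-so-far fit flagged `converged = FALSE`).
#'
#' @param mod an [mp_model].
#' @param ds the dataset.
#' @param max_iter,tol EM stopping rule.
#' @return the model with fitted `d` (cM distances via the mapping
#'   function), plus `loglik` (log10), `trace`, `r` and `converged`.
#' @export
em_fit_intervals <- function(mod, ds, max_iter = 100L, tol = 1e-6) {
  E <- mp_emission(mod, ds)
  res <- cpp_em(E, mp_params(mod), mod$ds_pop$kind, max_iter, tol,
                1e-7, max(mod$tab$p) - 1e-9)
  mod$d <- d_of_p(mod$tab, res$p)
  mod$r <- r_of_p(mod$ds_pop, mod$tab, res$p)
  mod$loglik <- res$loglik / log(10)
  mod$trace <- res$trace
  mod$converged <- res$converged
  mod
}

#' Forward-backward posterior genotype distributions
#'
#' Per individual and marker, the posterior over hidden states given all
#' observations of that individual (missing data are thereby imputed).
#'
#' @param mod a fitted [mp_model].
#' @param ds the dataset.
#' @return object of class `posterior_genotypes`: `gamma` array
#'   (states x individuals x markers), `imputed` (argmax observed-class
#'   view, markers x individuals), markers and individuals.
#' @export
impute_posteriors <- function(mod, ds) {
  E <- mp_emission(mod, ds)
  fb <- cpp_fb(E, mp_params(mod), mod$ds_pop$kind)
  g <- fb$gamma
  m <- length(mod$markers); n <- dim(g)[2L]
  imput <- matrix(NA_character_, m, n,
                  dimnames = list(mod$markers, individuals_of(ds)))
  for (k in seq_len(m)) {
    ph <- if (is.null(mod$phases)) 1L else mod$phases[k]
    C <- compat_for_config(ds, mod$markers[k], mod$ds_pop, ph)
    cls <- if (ds$pop_type == "CP") cp_marker_classes(ds, mod$markers[k])
           else marker_classes(ds)
    # posterior over observable classes = C %*% gamma, take argmax
    post <- C %*% g[, , k, drop = TRUE]
    if (n == 1L) post <- matrix(post, ncol = 1L)
    imput[k, ] <- cls[apply(post, 2L, which.max)]
  }
  structure(list(gamma = g, imputed = imput, markers = mod$markers,
                 individuals = individuals_of(ds), loglik = fb$loglik / log(10)),
            class = "posterior_genotypes")
}

# 0/1 compatibility matrix of one marker under a given phase configuration
compat_for_config <- function(ds, marker, model, config = 1L) {
  if (ds$pop_type != "CP") return(inbred_compat(model))
  i <- marker_index(ds, marker)
  cls <- cp_marker_classes(ds, i)
  cfgs <- list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))
  cf <- cfgs[[config]]
  sg <- cp_state_genotypes(ds$cp_parents[i, ], cf[1L], cf[2L])
  outer(cls, sg, `==`) * 1.0
}

#' Infer the linkage phase of a CP marker added to a map
#'
#' Evaluates the candidate marker's structurally distinct parental phase
#' configurations (at most 4; 2 when the marker is informative in a single
#' parent) at the marker's maximum-likelihood attachment to the current map,
#' and returns the best configuration together with its log10-likelihood
#' advantage over the runner-up.
#'
#' @param mod a fitted CP [mp_model].
#' @param ds the dataset.
#' @param new_marker marker name (not in the model).
#' @return list with `phase` (configuration index 1..4), `advantage`
#'   (log10 units, >= 0), `slot` (best insertion slot), `d_attach`,
#'   `ll_by_variant`.
#' @export
infer_phase_on_extension <- function(mod, ds, new_marker) {
  stopifnot(mod$ds_pop$type == "CP")
  inf <- cp_informative_parents(ds, new_marker)
  if (!any(inf)) stop("marker ", new_marker, " is uninformative in both parents")
  sc <- insert_scan(mod, ds, new_marker)
  best_by_v <- apply(sc$slot_ll, 2L, max)
  v <- which.max(best_by_v)
  adv <- if (length(best_by_v) > 1L)
    (best_by_v[v] - max(best_by_v[-v])) / log(10) else Inf
  cfgs <- attr(sc$variants, "configs")
  list(phase = cfgs[v], advantage = max(adv, 0),
       slot = which.max(sc$slot_ll[, v]),
       d_attach = sc$slot_dl[which.max(sc$slot_ll[, v]), v],
       ll_by_variant = best_by_v / log(10))
}

# scan insertion of one candidate marker into every slot of the model's map
# slots are 1..(m+1): 1 = before the first marker, m+1 = beyond the last,
# slot k (2..m) = inside interval k-1 (total interval distance preserved).
insert_scan <- function(mod, ds, marker, refine_k = 8L, d_ext_max = 80) {
  E <- mp_emission(mod, ds)
  cv <- compat_variants(ds, marker, mod$ds_pop)
  nv <- length(cv)
  n <- dim(E)[2L]; S <- mod$ds_pop$S
  cand <- array(1, dim = c(S, n, nv))
  obs <- encode_obs(ds, marker)
  cfgs <- attr(cv, "configs")
  for (v in seq_len(nv)) {
    ph <- if (is.null(cfgs)) 1L else cfgs[v]
    W <- emission_matrix(ds, marker, mod$ds_pop, mod$eps, ph)
    nm <- which(obs[1L, ] > 0L)
    if (length(nm)) cand[, nm, v] <- t(W[obs[1L, nm], , drop = FALSE])
  }
  sc <- cpp_insert_scan(E, mod$d, mod$ds_pop$kind, mod$tab$d, mod$tab$p,
                        cand, refine_k, d_ext_max)
  list(slot_ll = sc$slot_ll, slot_dl = sc$slot_dl,
       loglik_chain = sc$loglik_chain, variants = cv)
}
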