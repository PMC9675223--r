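# Genotyping-error detection (posterior-based and singleton rule) and
# redundant-marker ("twin") detection.  Flagged calls are masked to missing,
# never rewritten to the imputed value.

#' Detect putative genotyping errors from multipoint posteriors
#'
#' Under a fitted multipoint model with a nonzero error emission rate, a
#' call is flagged when the posterior probability of its observed class
#' (summed over the hidden states compatible with it) falls below
#' `threshold` — the signature of a call that the surrounding markers
#' contradict, e.g. an isolated double recombinant.
#'
#' @param mod a fitted [mp_model] with `eps > 0`.
#' @param ds the dataset.
#' The threshold must exceed the posterior plateau that the error model
#' itself assigns to a contradicted call (about `eps * r_left * r_right`
#' rescaled; ~2.5e-3 at a 1 cM spacing with `eps = 0.01`), or nothing can
#' ever be flagged.
#'
#' @param threshold posterior compatibility threshold (default 0.01).
#' @return data frame (marker, individual, code, p_obs, method).
#' @export
detect_errors_posterior <- function(mod, ds, threshold = 0.01) {
  stopifnot(mod$eps > 0)
  E <- mp_emission(mod, ds)
  fb <- cpp_fb(E, mp_params(mod), mod$ds_pop$kind)
  obs <- encode_obs(ds, mod$markers)
  out <- list()
  for (k in seq_along(mod$markers)) {
    ph <- if (is.null(mod$phases)) 1L else mod$phases[k]
    C <- compat_for_config(ds, mod$markers[k], mod$ds_pop, ph)
    g <- fb$gamma[, , k, drop = TRUE]
    if (is.null(dim(g))) g <- matrix(g, ncol = 1L)
    nm <- which(obs[k, ] > 0L)
    if (!length(nm)) next
    p_obs <- colSums(t(C[obs[k, nm], , drop = FALSE]) * g[, nm, drop = FALSE])
    bad <- nm[p_obs < threshold]
    if (length(bad))
      out[[length(out) + 1L]] <- data.frame(
        marker = mod$markers[k], individual = individuals_of(ds)[bad],
        code = ds$geno[marker_index(ds, mod$markers[k]), bad],
        p_obs = p_obs[match(bad, nm)], method = "posterior")
  }
  if (!length(out))
    return(data.frame(marker = character(), individual = character(),
                      code = character(), p_obs = numeric(),
                      method = character()))
  do.call(rbind, out)
}

#' Detect singleton calls on an ordered map
#'
#' A singleton is a call that disagrees with both flanking non-missing calls
#' while those flanks agree with each other and lie within `window_cM` — the
#' typical signature of a miscall interpreted as an unlikely double
#' crossover.  Calls adjacent to a missing flank, and terminal-marker
#' discordances, are never flagged by this rule.  The rule compares raw
#' codes and is therefore meaningful for populations sharing one code
#' alphabet across markers (BC/DH/F2/RIL); for CP data, whose offspring
#' classes are marker-specific, the posterior method should be used
#' instead.
#'
#' @param markers ordered marker names of one linkage group.
#' @param pos cumulative cM positions of those markers.
#' @param ds the dataset.
#' @param window_cM flank search window (default 10 cM).
#' @return data frame (marker, individual, code, method).
#' @export
detect_singletons <- function(markers, pos, ds, window_cM = 10) {
  idx <- marker_index(ds, markers)
  G <- ds$geno[idx, , drop = FALSE]
  m <- nrow(G); n <- ncol(G)
  out <- list()
  for (k in seq_len(m)) {
    for (q in seq_len(n)) {
      code <- G[k, q]
      if (code == MISSING_CODE) next
      up <- k - 1L; dn <- k + 1L
      if (up < 1L || dn > m) next
      # immediate flanks only: a missing flank shields the call
      if (G[up, q] == MISSING_CODE || G[dn, q] == MISSING_CODE) next
      if (pos[k] - pos[up] > window_cM || pos[dn] - pos[k] > window_cM) next
      if (G[up, q] == G[dn, q] && G[up, q] != code)
        out[[length(out) + 1L]] <- data.frame(
          marker = markers[k], individual = individuals_of(ds)[q],
          code = code, method = "singleton")
    }
  }
  if (!length(out))
    return(data.frame(marker = character(), individual = character(),
                      code = character(), method = character()))
  do.call(rbind, out)
}

#' Mask flagged calls as missing
#'
#' @param ds a [seg_data] object.
#' @param flags data frame with columns marker, individual (as returned by
#'   the detection functions).
#' @return the dataset with flagged cells set to the missing code.
#' @export
mask_calls <- function(ds, flags) {
  if (nrow(flags) == 0L) return(ds)
  i <- marker_index(ds, flags$marker)
  j <- match(flags$individual, individuals_of(ds))
  ds$geno[cbind(i, j)] <- MISSING_CODE
  ds
}

#' Group redundant ("twin") markers
#'
#' Markers whose non-missing calls are identical on at least `min_overlap`
#' co-typed individuals are grouped (for CP, identical up to a relabelling
#' of the marker's genotype classes, i.e. a consistent allele swap).  One
#' representative per group (fewest missing calls, ties broken by name)
#' enters ordering; the others are re-attached at its position in the total
#' map.
#'
#' @param ds a [seg_data] object.
#' @param min_overlap minimum co-typed individuals (default 20; capped at
#'   the number of individuals).
#' @return list with `groups` (list of marker-name vectors) and
#'   `representative` (named by group's representative marker).
#' @export
find_twins <- function(ds, min_overlap = 20L) {
  min_overlap <- min(min_overlap, ncol(ds$geno))
  obs <- encode_obs(ds)
  m <- nrow(obs)
  nm <- obs > 0L
  cot <- tcrossprod(nm * 1)  # co-typed counts
  if (ds$pop_type != "CP") {
    K <- max(obs)
    eq <- matrix(0, m, m)
    for (c in seq_len(K)) eq <- eq + tcrossprod((obs == c) * 1)
    twin <- eq == cot & cot >= min_overlap
  } else {
    twin <- matrix(FALSE, m, m)
    cand <- which(cot >= min_overlap & upper.tri(cot), arr.ind = TRUE)
    for (q in seq_len(nrow(cand))) {
      i <- cand[q, 1L]; j <- cand[q, 2L]
      ok <- nm[i, ] & nm[j, ]
      tb <- table(obs[i, ok], obs[j, ok])
      # identical up to class relabelling: cross-tab is one-to-one
      if (all(rowSums(tb > 0) <= 1L) && all(colSums(tb > 0) <= 1L))
        twin[i, j] <- twin[j, i] <- TRUE
    }
  }
  diag(twin) <- TRUE
  # union-find grouping
  parent <- seq_len(m)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(m - 1L)) for (j in which(twin[i, ] & seq_len(m) > i))
    parent[find(j)] <- find(i)
  roots <- vapply(seq_len(m), find, 0L)
  mk <- rownames(obs)
  miss <- rowSums(!nm)
  groups <- lapply(split(seq_len(m), roots), function(ix) mk[ix])
  reps <- vapply(split(seq_len(m), roots), function(ix) {
    ix <- ix[order(miss[ix], mk[ix])]
    mk[ix[1L]]
  }, "")
  names(groups) <- reps
  list(groups = groups, representative = reps)
}
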