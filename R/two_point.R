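# 2-point estimation: EM over observed 2-locus class counts, phase-maximized
# for CP markers; LOD against r = 0.5.

#' 2-point recombination fraction and LOD for a marker pair
#'
#' Maximizes the 2-point likelihood marginalized over the hidden states
#' compatible with each observed class (EM on class counts; individuals
#' missing at either locus are excluded).  For RIL/IRIL the likelihood is
#' maximized over the observed recombinant-line fraction R and transformed
#' back to r; for CP the likelihood is maximized jointly over the parental
#' phase configurations and the reported phase is the argmax.
#'
#' @param ds a [seg_data] object.
#' @param marker_i,marker_j distinct marker names or indices.
#' @param max_iter,tol EM stopping rule.
#' @return object of class `two_point_result`: `r_hat` in `[0, 0.5]`
#'   (`NA` when uninformative), `lod` (>= 0), `phase` (CP: configuration
#'   1..4, else `NA`), `phase_ambiguous`, `n_informative` (co-typed
#'   individuals), `informative`.
#' @export
estimate_two_point <- function(ds, marker_i, marker_j,
                               max_iter = 200L, tol = 1e-8) {
  i <- marker_index(ds, marker_i); j <- marker_index(ds, marker_j)
  if (i == j) stop("markers must be distinct")
  model <- pop_model(ds)
  mk <- markers_of(ds)[c(i, j)]
  obs <- encode_obs(ds, mk)
  cv_i <- compat_variants(ds, mk[1L], model)
  cv_j <- compat_variants(ds, mk[2L], model)
  n_cot <- sum(obs[1L, ] > 0L & obs[2L, ] > 0L)

  uninformative <- function() {
    structure(list(r_hat = NA_real_, lod = 0, phase = NA_integer_,
                   phase_ambiguous = FALSE, n_informative = n_cot,
                   informative = FALSE), class = "two_point_result")
  }
  mono <- function(k) length(unique(obs[k, obs[k, ] > 0L])) <= 1L
  if (n_cot == 0L || mono(1L) || mono(2L)) return(uninformative())
  if (model$type == "CP") {
    inf_i <- cp_informative_parents(ds, mk[1L])
    inf_j <- cp_informative_parents(ds, mk[2L])
    if (!any(inf_i & inf_j)) return(uninformative())  # e.g. female x male testcross
  }

  # evaluate each phase variant of marker j separately so ties can be seen
  lls <- lapply(seq_along(cv_j), function(v) {
    res <- cpp_two_point_all(obs, list(cv_i[1L], cv_j[v]), model$kind,
                             max_iter, tol, 0.25, 1L, 2L)
    c(p = res$p[1L, 2L], lod = res$lod[1L, 2L])
  })
  lods <- vapply(lls, `[[`, 0, "lod")
  v <- which.max(lods)
  tab <- p_table(model)
  r_hat <- r_of_p(model, tab, lls[[v]][["p"]])
  cfgs <- attr(cv_j, "configs")
  phase <- if (model$type == "CP") as.integer(cfgs[v]) else NA_integer_
  amb <- length(lods) > 1L && sort(lods, decreasing = TRUE)[2L] > max(lods) - 1e-6
  structure(list(r_hat = min(max(r_hat, 0), 0.5), lod = max(lods),
                 phase = if (amb) NA_integer_ else phase,
                 phase_ambiguous = amb,
                 n_informative = n_cot, informative = TRUE),
            class = "two_point_result")
}

#' @export
print.two_point_result <- function(x, ...) {
  cat(sprintf("two-point: r = %s, LOD = %.3f, n = %d%s\n",
              ifelse(is.na(x$r_hat), "NA", sprintf("%.4f", x$r_hat)),
              x$lod, x$n_informative,
              if (!x$informative) " (uninformative)" else ""))
  invisible(x)
}

#' All-pairs 2-point matrices
#'
#' Symmetric matrices of estimated recombination fractions and LOD scores
#' over all marker pairs (diagonal = `NA` sentinel; uninformative pairs hold
#' LOD 0).  For CP, the phase matrix holds the best phase configuration of
#' the column marker relative to the row marker held at configuration 1.
#'
#' @param ds a [seg_data] object (>= 2 markers).
#' @param markers optional marker subset.
#' @param max_iter,tol EM stopping rule.
#' @return object of class `two_point_matrix`: list with matrices `r`,
#'   `lod`, `phase`, `n` and the marker names.
#' @export
two_point_matrix <- function(ds, markers = markers_of(ds),
                             max_iter = 100L, tol = 1e-9) {
  model <- pop_model(ds)
  obs <- encode_obs(ds, markers)
  compat <- lapply(markers, function(m) {
    cv <- compat_variants(ds, m, model)
    attr(cv, "cfg") <- attr(cv, "configs")
    cv
  })
  res <- cpp_two_point_all(obs, compat, model$kind, max_iter, tol, 0.25,
                           integer(), integer())
  tab <- p_table(model)
  r <- res$p
  r[] <- r_of_p(model, tab, as.vector(res$p))
  diag(r) <- NA_real_
  lod <- res$lod; diag(lod) <- NA_real_
  # map variant index back to phase configuration
  phase <- res$phase
  if (model$type == "CP") {
    for (k in seq_along(markers)) {
      cfg <- attr(compat[[k]], "cfg")
      col <- phase[, k]
      ok <- !is.na(col)
      phase[ok, k] <- cfg[col[ok]]
    }
  }
  dn <- list(markers, markers)
  dimnames(r) <- dimnames(lod) <- dimnames(phase) <- dimnames(res$n) <- dn
  # structurally uninformative CP pairs: opposite-parent pseudo-testcrosses
  if (model$type == "CP") {
    inf <- t(vapply(markers, function(m) cp_informative_parents(ds, m),
                    logical(2L)))
    no_info <- !((inf[, 1L] %o% inf[, 1L]) | (inf[, 2L] %o% inf[, 2L]))
    lod[no_info] <- 0
    r[no_info] <- NA_real_
    diag(lod) <- NA_real_
  }
  structure(list(markers = markers, r = r, lod = lod, phase = phase,
                 n = res$n), class = "two_point_matrix")
}

#' @export
print.two_point_matrix <- function(x, ...) {
  cat(sprintf("two_point_matrix: %d markers, max off-diagonal LOD %.2f\n",
              length(x$markers), max(x$lod, na.rm = TRUE)))
  invisible(x)
}
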