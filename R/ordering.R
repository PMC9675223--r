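# Order-robust core: seed drawing, scaffold construction by seriation,
# framework densification under a LOD robustness gate, and order-robustness
# verification.
#
# Working maps are mp_model chains (ordered markers + cM intervals + CP
# phases); conversion to genetic_map rows happens in the pipeline.

# connected components of the 2-point linkage graph at a LOD threshold
linkage_components <- function(tp, lod) {
  m <- length(tp$markers)
  adj <- !is.na(tp$lod) & tp$lod >= lod
  comp <- integer(m)
  cur <- 0L
  for (s in seq_len(m)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  split(tp$markers, comp)
}

#' Draw seed marker pairs to initiate seriation
#'
#' Seed pairs must be mutually linked at `seed_lod` with `r <= seed_rmax`,
#' have low missing rates, and not be twins of each other.  With a physical
#' (anchor) map, at least one pair is drawn per declared chromosome;
#' without, one pair is drawn per connected component of the 2-point
#' linkage graph at `group_lod` ("disjoint linkage neighborhoods").  Pair
#' choice is a random draw among the highest-LOD qualifying pairs, governed
#' by the session RNG state.
#'
#' @param ds a [seg_data] object.
#' @param tp a [two_point_matrix] over the ordering pool.
#' @param phymap optional `physical_map` to guide seed drawing.
#' @param params a [map_params] configuration.
#' @param twins optional result of [find_twins()] (twin pairs excluded).
#' @return list of seed descriptors: `markers` (pair), `component`
#'   (marker names of the seed's linkage neighborhood).
#' @export
generate_seeds <- function(ds, tp, phymap = NULL, params = map_params(),
                           twins = NULL) {
  comps <- linkage_components(tp, params$group_lod)
  miss_frac <- rowMeans(ds$geno[tp$markers, , drop = FALSE] == MISSING_CODE)
  twin_of <- function(a, b) {
    if (is.null(twins)) return(FALSE)
    any(vapply(twins$groups, function(g) a %in% g && b %in% g, TRUE))
  }
  pairs_in <- function(mk) {
    sub <- tp$lod[mk, mk, drop = FALSE]
    rr <- tp$r[mk, mk, drop = FALSE]
    ok <- which(upper.tri(sub) & !is.na(sub) & sub >= params$seed_lod &
                !is.na(rr) & rr >= params$seed_rmin &
                rr <= params$seed_rmax, arr.ind = TRUE)
    if (!nrow(ok)) return(NULL)
    df <- data.frame(a = mk[ok[, 1L]], b = mk[ok[, 2L]],
                     lod = sub[ok], r = rr[ok])
    df <- df[miss_frac[df$a] <= params$seed_max_missing &
             miss_frac[df$b] <= params$seed_max_missing, ]
    if (!nrow(df)) return(NULL)
    df <- df[!mapply(twin_of, df$a, df$b), ]
    if (!nrow(df)) return(NULL)
    df[order(-df$lod), ]
  }
  units <- if (!is.null(phymap) && nrow(phymap)) {
    anchored <- phymap[phymap$marker %in% tp$markers, ]
    split(anchored$marker, anchored$chr)
  } else comps
  seeds <- list()
  for (u in units) {
    if (length(u) < 2L) next
    df <- pairs_in(u)
    if (is.null(df)) next
    top <- head(df, 25L)
    pick <- top[sample.int(nrow(top), 1L), ]
    comp_of <- comps[[which(vapply(comps, function(cc) pick$a %in% cc, TRUE))]]
    seeds[[length(seeds) + 1L]] <- list(markers = c(pick$a, pick$b),
                                        lod = pick$lod, r = pick$r,
                                        component = comp_of)
  }
  if (!length(seeds))
    stop("no qualifying seed pair found; consider relaxing seed_lod/seed_rmax")
  seeds
}

# start a 2-marker chain from a seed pair, fixing CP phases
init_chain <- function(seed, ds, params) {
  mk <- seed$markers
  est <- estimate_two_point(ds, mk[1L], mk[2L])
  phases <- NULL
  if (ds$pop_type == "CP")
    phases <- c(1L, if (is.na(est$phase)) 1L else est$phase)
  mp_model(ds, mk, d = haldane_r_to_d(min(est$r_hat, 0.45)),
           eps = eff_eps(params), phases = phases)
}

# gap between best slot and best alternative slot from an insertion scan;
# returns list(slot, variant, ll, gap, d_attach)
scan_best <- function(sc) {
  per_slot <- apply(sc$slot_ll, 1L, max)  # best phase variant per slot
  slot <- which.max(per_slot)
  variant <- which.max(sc$slot_ll[slot, ])
  alt <- max(per_slot[-slot])  # best alternative *position*
  list(slot = slot, variant = variant, ll = per_slot[slot],
       gap = (per_slot[slot] - alt) / log(10),
       d_attach = sc$slot_dl[slot, variant])
}

# append candidate to a chain at an exterior slot
chain_extend <- function(mod, marker, side, d_attach, phase_cfg = NULL) {
  if (side == "left") {
    mod$markers <- c(marker, mod$markers)
    mod$d <- c(d_attach, mod$d)
    if (!is.null(mod$phases)) mod$phases <- c(phase_cfg, mod$phases)
  } else {
    mod$markers <- c(mod$markers, marker)
    mod$d <- c(mod$d, d_attach)
    if (!is.null(mod$phases)) mod$phases <- c(mod$phases, phase_cfg)
  }
  mod
}

# insert candidate into interior slot k (between markers k-1 and k of the
# chain, slot numbering as in insert_scan), splitting the interval distance
chain_insert <- function(mod, marker, slot, d_left, phase_cfg = NULL) {
  m <- length(mod$markers)
  if (slot == 1L) return(chain_extend(mod, marker, "left", d_left, phase_cfg))
  if (slot == m + 1L) return(chain_extend(mod, marker, "right", d_left, phase_cfg))
  k <- slot - 1L  # interval index
  d_tot <- mod$d[k]
  d_left <- min(max(d_left, 0), d_tot)
  mod$markers <- append(mod$markers, marker, after = k)
  mod$d <- append(mod$d[-k], c(d_left, d_tot - d_left), after = k - 1L)
  if (!is.null(mod$phases)) mod$phases <- append(mod$phases, phase_cfg, after = k)
  mod
}

#' Build a scaffold map by seriation from a seed pair
#'
#' Bidirectional elongation: at each step the pool marker with the highest
#' 2-point LOD to a terminal marker, with estimated r inside
#' `[scaffold_rmin, scaffold_rmax]`, is appended provided (i) its multipoint
#' ML position is terminal and (ii) the order-robustness gap of the extended
#' map stays at or above `lod_framework`.  CP phases are inferred at each
#' extension.  Interval distances are re-fitted by EM after each acceptance.
#' Stops when no candidate qualifies at either end.
#'
#' @param seed a seed descriptor from [generate_seeds()] (or a list with a
#'   `markers` pair and a `component` pool).
#' @param ds the dataset.
#' @param tp a [two_point_matrix] covering the pool.
#' @param params a [map_params].
#' @param pool candidate markers (defaults to the seed's component).
#' @return an `mp_model` chain (may be just the seed pair).
#' @export
build_scaffold <- function(seed, ds, tp, params = map_params(), pool = NULL) {
  if (is.null(pool)) pool <- seed$component
  mod <- init_chain(seed, ds, params)
  mod <- em_fit_intervals(mod, ds)
  pool <- setdiff(pool, mod$markers)
  open <- c(left = TRUE, right = TRUE)
  while (any(open) && length(pool)) {
    for (side in c("left", "right")[open]) {
      terminal <- if (side == "left") mod$markers[1L] else
        mod$markers[length(mod$markers)]
      r_t <- tp$r[terminal, pool]
      lod_t <- tp$lod[terminal, pool]
      ok <- !is.na(r_t) & r_t >= params$scaffold_rmin &
            r_t <= params$scaffold_rmax
      cands <- pool[ok][order(-lod_t[ok])]
      cands <- head(cands, params$try_k)
      accepted <- FALSE
      for (cand in cands) {
        sc <- insert_scan(mod, ds, cand)
        b <- scan_best(sc)
        want_slot <- if (side == "left") 1L else length(mod$markers) + 1L
        if (b$slot != want_slot || b$gap < params$lod_framework) next
        cfg <- if (ds$pop_type == "CP") attr(sc$variants, "configs")[b$variant]
               else NULL
        mod <- chain_extend(mod, cand, side, b$d_attach, cfg)
        mod <- em_fit_intervals(mod, ds)
        pool <- setdiff(pool, cand)
        accepted <- TRUE
        break
      }
      if (!accepted) open[side] <- FALSE
    }
  }
  mod
}

#' Merge scaffolds that belong to the same linkage group
#'
#' Two chains are recognized as parts of one linkage group when they share
#' markers or when any cross-chain marker pair is linked at `group_lod`.
#' They are merged by union densification: the larger chain is kept and the
#' other's markers are re-inserted one by one through the robustness-gated
#' insertion machinery (which also extends chain ends, so adjacent segments
#' concatenate naturally); markers that do not pass the gate remain
#' available for placement.
#'
#' @param chains list of `mp_model` chains.
#' @param ds,tp,params as in [build_scaffold()].
#' @return list of merged chains.
#' @export
merge_scaffolds <- function(chains, ds, tp, params = map_params()) {
  repeat {
    n <- length(chains)
    if (n < 2L) return(chains)
    merged <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        a <- chains[[i]]; b <- chains[[j]]
        linked <- length(intersect(a$markers, b$markers)) > 0L ||
          max(tp$lod[a$markers, b$markers], na.rm = TRUE) >= params$group_lod
        if (!linked) next
        if (length(b$markers) > length(a$markers)) { tmp <- a; a <- b; b <- tmp }
        extra <- setdiff(b$markers, a$markers)
        fw <- build_framework(a, extra, ds, tp, params)
        chains[[i]] <- fw$chain
        chains[[j]] <- NULL
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) return(chains)
  }
}

#' Densify a scaffold into a framework map
#'
#' Candidates are processed in decreasing informativeness (non-missing call
#' count, then maximum 2-point LOD to the group, then name).  Each candidate
#' is inserted at its multipoint-ML slot and kept only when the
#' log10-likelihood gap to the best alternative slot is at least
#' `lod_framework`; rejected candidates remain available for placement.
#' Passes repeat until no candidate is accepted.  Distances are re-fitted
#' after each acceptance (ML split of the receiving interval, with a full
#' EM refit plus error re-detection every `refit_every` acceptances and at
#' the end).
#'
#' @param scaffold an `mp_model` chain.
#' @param candidates marker names assigned to this group.
#' @param ds,tp,params as in [build_scaffold()].
#' @return list: `chain` (framework `mp_model`), `accepted` data frame
#'   (marker, gap), `rejected` marker names, `flags` (masked error calls),
#'   `ds` (dataset after masking).
#' @export
build_framework <- function(scaffold, candidates, ds, tp,
                            params = map_params()) {
  mod <- scaffold
  candidates <- setdiff(candidates, mod$markers)
  nonmiss <- rowSums(ds$geno[, , drop = FALSE] != MISSING_CODE)
  all_flags <- list()
  accepted <- list()
  since_refit <- 0L
  refit <- function() {
    mod <<- em_fit_intervals(mod, ds)
    if (params$error_correction && mod$eps > 0) {
      fl <- detect_errors_posterior(mod, ds, params$error_threshold)
      if (nrow(fl)) {
        ds <<- mask_calls(ds, fl)
        all_flags[[length(all_flags) + 1L]] <<- fl
        mod <<- em_fit_intervals(mod, ds)
      }
    }
    since_refit <<- 0L
  }
  repeat {
    if (!length(candidates)) break
    max_lod <- suppressWarnings(
      apply(tp$lod[candidates, mod$markers, drop = FALSE], 1L, max, na.rm = TRUE))
    ord <- order(-nonmiss[candidates], -max_lod, candidates)
    pass_accepted <- 0L
    for (cand in candidates[ord]) {
      sc <- insert_scan(mod, ds, cand)
      b <- scan_best(sc)
      if (b$gap < params$lod_framework) next
      cfg <- if (ds$pop_type == "CP") attr(sc$variants, "configs")[b$variant]
             else NULL
      mod <- chain_insert(mod, cand, b$slot, b$d_attach, cfg)
      accepted[[length(accepted) + 1L]] <- data.frame(marker = cand, gap = b$gap)
      candidates <- setdiff(candidates, cand)
      pass_accepted <- pass_accepted + 1L
      since_refit <- since_refit + 1L
      if (since_refit >= params$refit_every) refit()
    }
    if (pass_accepted == 0L) break
  }
  refit()
  list(chain = mod,
       accepted = if (length(accepted)) do.call(rbind, accepted)
                  else data.frame(marker = character(), gap = numeric()),
       rejected = candidates,
       flags = if (length(all_flags)) do.call(rbind, all_flags)
               else data.frame(),
       ds = ds)
}

#' Verify order robustness of a map
#'
#' For each marker, the accepted map's log10-likelihood is compared against
#' the best alternative map obtained by moving that marker to any other
#' interval of its group, or flipping it with a neighbor.  The map passes at
#' `lod_threshold` iff the minimum gap over markers meets the threshold.
#' With `exact = TRUE` every alternative is re-fitted by full EM (use for
#' small groups); the default evaluates alternatives conditional on the
#' current fitted distances, the approximation used during densification.
#'
#' @param mod an `mp_model` chain (one linkage group).
#' @param ds the dataset.
#' @param lod_threshold pass threshold (default 3).
#' @param exact re-fit alternatives by EM (exhaustive; small groups only).
#' @return object of class `order_robustness`: data frame (marker, gap),
#'   `min_gap`, `pass`.
#' @export
verify_order_robustness <- function(mod, ds, lod_threshold = 3,
                                    exact = FALSE) {
  m <- length(mod$markers)
  stopifnot(m >= 3L)
  mod <- em_fit_intervals(mod, ds)
  ll_map <- multipoint_loglik(mod, ds)
  gaps <- numeric(m)
  for (k in seq_len(m)) {
    red <- drop_marker(mod, k)
    if (exact) {
      alts <- c()
      for (slot in seq_len(m)) {  # slots of the reduced chain: 1..m
        if (slot == k) next      # re-inserting at the original slot
        cfg <- if (!is.null(mod$phases)) mod$phases[k] else NULL
        alt <- chain_insert(red, mod$markers[k], slot,
                            d_left = if (slot == 1L || slot == m) 1
                                     else red$d[slot - 1L] / 2, cfg)
        # try all phase configs for CP
        alt_ll <- best_ll_over_phases(alt, ds, k_new = slot)
        alts <- c(alts, alt_ll)
      }
      gaps[k] <- ll_map - max(alts)
    } else {
      sc <- insert_scan(red, ds, mod$markers[k])
      cur_slot <- k  # slot k of the reduced chain = original position
      ll <- sc$slot_ll
      alt <- max(ll[-cur_slot, , drop = FALSE])
      gaps[k] <- (ll[cur_slot, which.max(ll[cur_slot, ])] - alt) / log(10)
    }
  }
  # adjacent flips
  for (k in seq_len(m - 1L)) {
    fl <- flip_pair(mod, k)
    ll_fl <- if (exact) best_ll_over_phases(fl, ds, k_new = NULL)
             else multipoint_loglik(fl, ds)
    gap <- ll_map - ll_fl
    gaps[k] <- min(gaps[k], gap)
    gaps[k + 1L] <- min(gaps[k + 1L], gap)
  }
  out <- data.frame(marker = mod$markers, gap = gaps)
  structure(list(report = out, min_gap = min(gaps),
                 pass = min(gaps) >= lod_threshold,
                 lod_threshold = lod_threshold),
            class = "order_robustness")
}

best_ll_over_phases <- function(mod, ds, k_new) {
  if (is.null(mod$phases) || is.null(k_new)) {
    fit <- em_fit_intervals(mod, ds)
    return(fit$loglik)
  }
  best <- -Inf
  for (cfg in seq_len(4L)) {
    mod$phases[k_new] <- cfg
    fit <- em_fit_intervals(mod, ds)
    best <- max(best, fit$loglik)
  }
  best
}

#' @export
print.order_robustness <- function(x, ...) {
  cat(sprintf("order robustness: min gap %.2f (threshold %.1f) -> %s\n",
              x$min_gap, x$lod_threshold, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

drop_marker <- function(mod, k) {
  m <- length(mod$markers)
  d <- mod$d
  if (k == 1L) d <- d[-1L]
  else if (k == m) d <- d[-(m - 1L)]
  else {
    d[k - 1L] <- d[k - 1L] + d[k]
    d <- d[-k]
  }
  mod$markers <- mod$markers[-k]
  mod$d <- d
  if (!is.null(mod$phases)) mod$phases <- mod$phases[-k]
  mod
}

flip_pair <- function(mod, k) {
  ix <- c(k + 1L, k)
  mod$markers[k:(k + 1L)] <- mod$markers[ix]
  if (!is.null(mod$phases)) mod$phases[k:(k + 1L)] <- mod$phases[ix]
  mod
}
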