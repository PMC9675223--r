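# Fully automatic pipeline: load -> twins -> seeds -> scaffolds ->
# assignment -> framework densification (with error handling) -> placement;
# plus the command-line interface.

stage_seed <- function(seed, stage)
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% 2147483647)

#' Automatic map construction
#'
#' Chains all stages of the bin-mapping strategy: redundant-marker (twin)
#' grouping, all-pairs 2-point analysis, seed drawing, scaffold seriation,
#' marker assignment to linkage groups, robustness-gated framework
#' densification with genotyping-error handling, and placement of all
#' remaining polymorphic markers into framework bins.  Every random choice
#' is governed by `seed`; reruns with identical input and seed produce
#' identical maps.
#'
#' @param ds a [seg_data] object.
#' @param phymap optional `physical_map` guiding seed drawing and the Marey
#'   table.
#' @param params a [map_params] configuration.
#' @param seed integer run seed (fanned out to per-stage child seeds).
#' @param out_dir optional directory: writes `scaffold.map`,
#'   `framework.map`, `total.map`, `robustness.tsv`, `errors.tsv`,
#'   `lod_matrix.tsv`, `marey.tsv` and `run.log`.
#' @param truth optional reference [genetic_map]; adds a quality report.
#' @return list of class `auto_map_result`: `scaffold_map`,
#'   `framework_map`, `total_map` ([genetic_map]s), `chains`, `twins`,
#'   `seeds`, `assignment`, `robustness`, `error_flags`, `two_point`,
#'   `quality` (if truth given), `log`.
#' @export
auto_map <- function(ds, phymap = NULL, params = map_params(), seed = 1L,
                     out_dir = NULL, truth = NULL) {
  t0 <- Sys.time()
  logl <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    logl <<- c(logl, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg))
    message(msg)
  }
  say("auto_map: %s population, %d markers x %d individuals, seed %d",
      ds$pop_type, nrow(ds$geno), ncol(ds$geno), seed)
  say("thresholds: framework LOD %.1f, assign LOD %.1f, error correction %s",
      params$lod_framework, params$lod_assign,
      if (params$error_correction) "on" else "off")

  mono <- monomorphic_markers(ds)
  poly <- names(mono)[!mono]
  say("polymorphic markers: %d (%d monomorphic excluded)",
      length(poly), sum(mono))

  set.seed(stage_seed(seed, 1L))
  twins <- find_twins(subset_markers(ds, poly), params$twin_min_overlap)
  reps <- unname(twins$representative)
  say("twin groups: %d representatives for %d markers",
      length(reps), length(poly))

  say("2-point matrix over %d markers ...", length(reps))
  tp <- two_point_matrix(ds, reps)

  set.seed(stage_seed(seed, 2L))
  seeds <- generate_seeds(ds, tp, phymap, params, twins)
  say("seeds: %d pair(s): %s", length(seeds),
      paste(vapply(seeds, function(s) paste(s$markers, collapse = "+"), ""),
            collapse = ", "))

  set.seed(stage_seed(seed, 3L))
  chains <- list()
  used <- character()
  for (sd in seeds) {
    if (any(sd$markers %in% used)) next
    pool <- setdiff(intersect(sd$component, reps), used)
    ch <- build_scaffold(sd, ds, tp, params, pool = pool)
    used <- c(used, ch$markers)
    chains[[length(chains) + 1L]] <- ch
    say("scaffold %d: %d markers, %.1f cM", length(chains),
        length(ch$markers), sum(ch$d))
  }
  chains <- merge_scaffolds(chains, ds, tp, params)
  scaffold_markers <- unlist(lapply(chains, `[[`, "markers"))
  scaffold_map <- chains_to_map(chains, params)

  assignment <- assign_markers(ds, chains, tp, params)
  say("assignment: %d assigned, %d ambiguous, %d unlinked",
      sum(assignment$status == "assigned"),
      sum(assignment$status == "ambiguous"),
      sum(assignment$status == "unlinked"))

  set.seed(stage_seed(seed, 4L))
  flags <- list()
  ds_work <- ds
  for (g in seq_along(chains)) {
    cand <- assignment$marker[assignment$status == "assigned" &
                              assignment$group == g]
    fw <- build_framework(chains[[g]], cand, ds_work, tp, params)
    chains[[g]] <- fw$chain
    ds_work <- fw$ds
    if (nrow(fw$flags)) flags[[length(flags) + 1L]] <- fw$flags
    say("framework group %d: %d markers, %.1f cM (%d rejected for placement)",
        g, length(fw$chain$markers), sum(fw$chain$d), length(fw$rejected))
  }
  # singleton rule on the framework order (defined on the shared code
  # alphabet of inbred-type populations; for CP the posterior method covers
  # the same double-crossover signature)
  if (params$error_correction && ds$pop_type != "CP") {
    for (g in seq_along(chains)) {
      ch <- chains[[g]]
      fl <- detect_singletons(ch$markers, c(0, cumsum(ch$d)), ds_work,
                              params$singleton_window)
      if (nrow(fl)) {
        ds_work <- mask_calls(ds_work, fl)
        flags[[length(flags) + 1L]] <- fl[, c("marker", "individual", "code",
                                              "method")]
        chains[[g]] <- em_fit_intervals(ch, ds_work)
      }
    }
  }
  # final distance re-estimation on the masked data with the residual
  # error rate (construction eps is for ordering robustness, not distances)
  for (g in seq_along(chains)) {
    chains[[g]]$eps <- if (params$error_correction) params$eps_final else 0
    chains[[g]] <- em_fit_intervals(chains[[g]], ds_work)
  }

  error_flags <- if (length(flags)) {
    do.call(rbind, lapply(flags, function(f)
      f[, c("marker", "individual", "code", "method")]))
  } else data.frame(marker = character(), individual = character(),
                    code = character(), method = character())
  say("error handling: %d calls masked", nrow(error_flags))

  framework_map <- chains_to_map(chains, params, scaffold_markers)

  robustness <- lapply(chains, function(ch)
    if (length(ch$markers) >= 3L)
      verify_order_robustness(ch, ds_work, params$lod_framework) else NULL)

  # refresh assignment against the densified frameworks, then place
  assignment <- assign_markers(ds, chains, tp, params)
  total_map <- place_markers(chains, assignment, ds_work, params,
                             scaffold_markers, twins)
  say("total map: %d markers in %d group(s), %.1f cM",
      nrow(total_map), length(unique(total_map$group)),
      sum(map_lengths(total_map)))

  quality <- if (!is.null(truth)) {
    q <- evaluate_map(total_map, truth, ds)
    qf <- evaluate_map(framework_map, truth, ds)
    say("framework vs truth: |Spearman| %s, length ratio %.3f",
        paste(sprintf("%.3f", qf$spearman), collapse = "/"), qf$length_ratio)
    list(framework = qf, total = q)
  } else NULL

  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out <- structure(list(
    scaffold_map = scaffold_map, framework_map = framework_map,
    total_map = total_map, chains = chains, twins = twins, seeds = seeds,
    assignment = assignment, robustness = robustness,
    error_flags = error_flags, two_point = tp, quality = quality,
    params = params, seed = seed, log = logl), class = "auto_map_result")
  if (!is.null(out_dir)) write_run_outputs(out, ds, phymap, out_dir)
  out
}

chains_to_map <- function(chains, params, scaffold_markers = NULL) {
  rows <- lapply(seq_along(chains), function(g) {
    ch <- chains[[g]]
    status <- if (is.null(scaffold_markers)) "scaffold"
              else ifelse(ch$markers %in% scaffold_markers, "scaffold",
                          "framework")
    data.frame(group = paste0("LG", g), marker = ch$markers,
               pos = c(0, cumsum(ch$d)), status = status,
               bin = NA_character_)
  })
  genetic_map(do.call(rbind, rows), lod_threshold = params$lod_framework)
}

write_run_outputs <- function(res, ds, phymap, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_map(res$scaffold_map, fp("scaffold.map"))
  write_map(res$framework_map, fp("framework.map"))
  write_map(res$total_map, fp("total.map"))
  write_lod_matrix(res$two_point, fp("lod_matrix.tsv"))
  rb <- do.call(rbind, lapply(seq_along(res$robustness), function(g) {
    r <- res$robustness[[g]]
    if (is.null(r)) return(NULL)
    cbind(group = paste0("LG", g), r$report)
  }))
  con <- file(fp("robustness.tsv"), "w")
  writeLines("# order-robustness report: gap = LOD to best alternative position", con)
  if (!is.null(rb))
    suppressWarnings(write.table(rb, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
  close(con)
  write.table(res$error_flags, fp("errors.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(phymap)) write_marey_table(res$total_map, phymap, fp("marey.tsv"))
  writeLines(res$log, fp("run.log"))
  invisible(out_dir)
}

#' @export
print.auto_map_result <- function(x, ...) {
  cat("auto_map result\n  framework: ")
  print(x$framework_map)
  cat("  total: ")
  print(x$total_map)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Command-line interface
# ---------------------------------------------------------------------------

#' Command-line interface
#'
#' Subcommands: `automap` (full pipeline), `simulate` (write a simulated
#' population), `twopoint` (LOD matrix), `evaluate` (map vs reference),
#' `check` (order-robustness verification of a map file).  Run the
#' installed `exec/seriamap` script, or call this function with an argv
#' vector.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code (0 = success), invisibly.
#' @export
seriamap_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: seriamap <command> [options]",
    "commands:",
    "  automap  --data FILE [--pop-type T] [--phymap FILE] [--out-dir DIR]",
    "           [--lod-framework X] [--lod-assign X] [--seed N]",
    "           [--no-error-correction]",
    "  simulate --pop-type T --n-ind N [--chr-len L1,L2] [--spacing S]",
    "           [--error-rate E] [--missing-rate M] [--seed N] --out-dir DIR",
    "  twopoint --data FILE --out FILE",
    "  evaluate --map FILE --truth FILE",
    "  check    --map FILE --data FILE [--lod-framework X]",
    sep = "\n")
  if (length(argv) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- argv[1L]
  opts <- parse_cli_opts(argv[-1L])
  if (is.character(opts)) { message(opts, "\n", usage); return(invisible(1L)) }
  get <- function(k, default = NULL) if (k %in% names(opts)) opts[[k]] else default
  num <- function(k, default = NULL) {
    v <- get(k); if (is.null(v)) default else as.numeric(v)
  }
  read_data <- function(path) {
    if (grepl("\\.gen$", path)) read_gen(path) else read_raw(path)
  }
  res <- tryCatch(switch(cmd,
    automap = {
      path <- get("data"); if (is.null(path)) stop("--data is required")
      ds <- read_data(path)
      if (!is.null(get("pop-type")) && toupper(get("pop-type")) != ds$pop_type)
        stop("--pop-type conflicts with the data file header")
      phymap <- if (!is.null(get("phymap"))) read_physical_map(get("phymap"))
      params <- map_params(
        lod_framework = num("lod-framework", 3.0),
        lod_assign = num("lod-assign", 6),
        error_correction = !isTRUE(get("no-error-correction")))
      auto_map(ds, phymap, params, seed = as.integer(num("seed", 1)),
               out_dir = get("out-dir", "seriamap_run"))
      0L
    },
    simulate = {
      out_dir <- get("out-dir"); if (is.null(out_dir)) stop("--out-dir is required")
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      chr <- as.numeric(strsplit(get("chr-len", "100,200"), ",")[[1L]])
      sim <- simulate_pop(get("pop-type", "F2"), as.integer(num("n-ind", 200)),
                          chr_len = chr, spacing = num("spacing", 1),
                          error_rate = num("error-rate", 0),
                          missing_rate = num("missing-rate", 0),
                          seed = as.integer(num("seed", 1)))
      ext <- if (sim$dataset$pop_type == "CP") "segData.gen" else "segData.raw"
      write_seg_data(sim$dataset, file.path(out_dir, ext))
      write_map(sim$truth, file.path(out_dir, "truth.map"))
      message("wrote ", file.path(out_dir, ext), " and truth.map")
      0L
    },
    twopoint = {
      ds <- read_data(get("data"))
      tp <- two_point_matrix(ds)
      write_lod_matrix(tp, get("out", "lod_matrix.tsv"))
      0L
    },
    evaluate = {
      q <- evaluate_map(read_map(get("map")), read_map(get("truth")))
      print(q)
      0L
    },
    check = {
      map <- read_map(get("map"))
      ds <- read_data(get("data"))
      params <- map_params(lod_framework = num("lod-framework", 3.0))
      ok <- TRUE
      for (g in unique(map$group)) {
        mk <- map$marker[map$group == g & map$status != "placed"]
        mk <- mk[mk %in% markers_of(ds)]
        if (length(mk) < 3L) next
        mod <- mp_model(ds, mk, d = pmax(diff(map$pos[match(mk, map$marker)]),
                                         1e-3), eps = eff_eps(params))
        v <- verify_order_robustness(mod, ds, params$lod_framework)
        cat(g, ": "); print(v)
        ok <- ok && v$pass
      }
      if (ok) 0L else 2L
    },
    { message("unknown command: ", cmd, "\n", usage); 1L }
  ), error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(as.integer(res))
}

# parse --key value / --flag style options; returns named list or an error string
parse_cli_opts <- function(args) {
  flags <- c("no-error-correction")
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) return(sprintf("unexpected argument '%s'", a))
    key <- substring(a, 3L)
    if (key %in% flags) { out[[key]] <- TRUE; i <- i + 1L; next }
    if (i == length(args)) return(sprintf("option --%s needs a value", key))
    if (key %in% names(out)) return(sprintf("conflicting repeated option --%s", key))
    out[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}
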