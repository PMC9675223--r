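# File formats: .raw / .gen segregation data, physical-map tables, map and
# QC outputs.  All tables are tab-separated UTF-8; lines starting with '#'
# are comments.

#' Read inbred-population segregation data (.raw dialect)
#'
#' Format (MapMaker-compatible subset): first non-comment line
#' `data type <poptype>` where poptype is one of `bc`, `dh`, `f2`,
#' `ril` (selfed to fixation), `ril<n>` (n selfing generations) or
#' `iril<t>` (t intermating generations, then selfed to fixation);
#' second line `<n_ind> <n_mark>`; then one record per marker starting
#' `*name` followed by n_ind single-character codes (either separate
#' tokens or one contiguous string, continuation lines allowed).
#'
#' @param path file path.
#' @return a [seg_data] object.
#' @export
read_raw <- function(path) {
  ln <- read_clean_lines(path)
  if (length(ln) < 3L) stop("truncated .raw file: ", path)
  ty <- tolower(trimws(sub("^data\\s+type\\s+", "", ln[1L], ignore.case = TRUE)))
  if (ty == tolower(trimws(ln[1L]))) stop("first line must be 'data type <poptype>'")
  pop <- parse_pop_type(ty)
  hd <- as.integer(strsplit(trimws(ln[2L]), "\\s+")[[1L]])
  if (length(hd) < 2L || anyNA(hd)) stop("second line must be '<n_ind> <n_mark>'")
  n_ind <- hd[1L]; n_mark <- hd[2L]
  body <- ln[-(1:2)]
  inames <- parse_individuals_line(body, n_ind)
  if (!is.null(inames)) body <- body[-1L]
  recs <- parse_marker_records(body, n_ind, split_chars = TRUE)
  if (length(recs) != n_mark)
    stop(sprintf("header declares %d markers but %d found", n_mark, length(recs)))
  geno <- do.call(rbind, lapply(recs, `[[`, "codes"))
  rownames(geno) <- vapply(recs, `[[`, "", "name")
  colnames(geno) <- if (is.null(inames)) paste0("ind", seq_len(n_ind)) else inames
  ds <- seg_data(geno, pop$type, self_gens = pop$self, intermate_gens = pop$intermate)
  attr(ds, "monomorphic") <- monomorphic_markers(ds)
  ds
}

#' Read cross-pollinated (CP) segregation data (.gen dialect)
#'
#' Format: `data type cp`; `<n_ind> <n_mark>`; then per marker
#' `*name <P1genotype>x<P2genotype>` followed by n_ind two-letter offspring
#' codes (`--` for missing), continuation lines allowed.
#'
#' @param path file path.
#' @return a [seg_data] object with `pop_type = "CP"` and derived
#'   segregation classes available via [cp_segregation_class()].
#' @export
read_gen <- function(path) {
  ln <- read_clean_lines(path)
  ty <- tolower(trimws(sub("^data\\s+type\\s+", "", ln[1L], ignore.case = TRUE)))
  if (ty != "cp") stop(".gen file must declare 'data type cp'")
  hd <- as.integer(strsplit(trimws(ln[2L]), "\\s+")[[1L]])
  n_ind <- hd[1L]; n_mark <- hd[2L]
  body <- ln[-(1:2)]
  inames <- parse_individuals_line(body, n_ind)
  if (!is.null(inames)) body <- body[-1L]
  recs <- parse_marker_records(body, n_ind, split_chars = FALSE, n_extra = 1L)
  if (length(recs) != n_mark)
    stop(sprintf("header declares %d markers but %d found", n_mark, length(recs)))
  geno <- do.call(rbind, lapply(recs, `[[`, "codes"))
  rownames(geno) <- vapply(recs, `[[`, "", "name")
  colnames(geno) <- if (is.null(inames)) paste0("ind", seq_len(n_ind)) else inames
  par <- t(vapply(recs, function(r) {
    g <- strsplit(tolower(r$extra), "x")[[1L]]
    if (length(g) != 2L || any(nchar(g) != 2L))
      stop("bad parental genotype spec '", r$extra, "' at marker ", r$name)
    g
  }, c("", "")))
  seg_data(geno, "CP", cp_parents = par)
}

read_clean_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  ln <- ln[!grepl("^\\s*#", ln)]
  ln[nzchar(trimws(ln))]
}

# optional 'individuals <name...>' line carrying individual names
parse_individuals_line <- function(body, n_ind) {
  toks <- strsplit(trimws(body[1L]), "\\s+")[[1L]]
  if (tolower(toks[1L]) != "individuals") return(NULL)
  if (length(toks) != n_ind + 1L)
    stop("individuals line must carry one name per declared individual")
  toks[-1L]
}

parse_pop_type <- function(ty) {
  if (ty %in% c("bc", "backcross")) return(list(type = "BC", self = NA, intermate = 0))
  if (ty == "dh") return(list(type = "DH", self = NA, intermate = 0))
  if (ty %in% c("f2", "f2 intercross")) return(list(type = "F2", self = NA, intermate = 0))
  if (grepl("^ril[0-9]*$", ty)) {
    n <- sub("^ril", "", ty)
    return(list(type = "RIL", self = if (nzchar(n)) as.numeric(n) else Inf, intermate = 0))
  }
  if (grepl("^iril[0-9]+$", ty))
    return(list(type = "IRIL", self = Inf, intermate = as.numeric(sub("^iril", "", ty))))
  stop("unknown population type: ", ty)
}

# shared record parser: '*name [extra] codes...' with continuation lines
parse_marker_records <- function(lines, n_ind, split_chars, n_extra = 0L) {
  recs <- list()
  cur <- NULL
  flush <- function(cur) {
    if (length(cur$codes) != n_ind)
      stop(sprintf("marker '%s': %d codes found but %d individuals declared",
                   cur$name, length(cur$codes), n_ind))
    cur
  }
  for (l in lines) {
    toks <- strsplit(trimws(l), "\\s+")[[1L]]
    if (startsWith(toks[1L], "*")) {
      if (!is.null(cur)) recs[[length(recs) + 1L]] <- flush(cur)
      name <- sub("^\\*", "", toks[1L])
      extra <- if (n_extra > 0L) paste(toks[seq_len(n_extra) + 1L], collapse = "") else NULL
      toks <- toks[-seq_len(1L + n_extra)]
      cur <- list(name = name, extra = extra, codes = character())
    } else if (is.null(cur)) {
      stop("data line before first marker record")
    }
    if (length(toks)) {
      if (split_chars && length(toks) == 1L && nchar(toks) > 1L)
        toks <- strsplit(toks, "")[[1L]]
      cur$codes <- c(cur$codes, toks)
    }
  }
  if (!is.null(cur)) recs[[length(recs) + 1L]] <- flush(cur)
  recs
}

#' Write segregation data in the .raw / .gen dialect
#'
#' Inverse of [read_raw()] / [read_gen()]: the dialect is chosen from the
#' dataset's population type.  A read of the written file reproduces the
#' dataset.
#'
#' @param ds a [seg_data] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_seg_data <- function(ds, path) {
  con <- file(path, "w"); on.exit(close(con))
  if (ds$pop_type == "CP") {
    writeLines(c("data type cp",
                 sprintf("%d %d", ncol(ds$geno), nrow(ds$geno)),
                 paste(c("individuals", colnames(ds$geno)), collapse = " ")),
               con)
    codes <- ds$geno
    codes[codes == MISSING_CODE] <- "--"
    for (k in seq_len(nrow(codes)))
      writeLines(paste0("*", rownames(codes)[k], " ",
                        ds$cp_parents[k, 1L], "x", ds$cp_parents[k, 2L], " ",
                        paste(codes[k, ], collapse = " ")), con)
  } else {
    ty <- switch(ds$pop_type,
      BC = "bc", DH = "dh", F2 = "f2",
      RIL = if (is.finite(ds$self_gens)) paste0("ril", ds$self_gens) else "ril",
      IRIL = paste0("iril", ds$intermate_gens))
    writeLines(c(paste("data type", ty),
                 sprintf("%d %d", ncol(ds$geno), nrow(ds$geno)),
                 paste(c("individuals", colnames(ds$geno)), collapse = " ")),
               con)
    for (k in seq_len(nrow(ds$geno)))
      writeLines(paste0("*", rownames(ds$geno)[k], " ",
                        paste(ds$geno[k, ], collapse = "")), con)
  }
  invisible(path)
}

#' Read a physical / anchor map table
#'
#' Whitespace- or tab-separated table with columns marker, chromosome,
#' position (header line optional).  Positions are carried through
#' untouched; the unit (bp or cM) is not interpreted.
#'
#' @param path file path.
#' @return data frame of class `physical_map` with columns
#'   `marker`, `chr`, `pos`.
#' @export
read_physical_map <- function(path) {
  ln <- read_clean_lines(path)
  if (length(ln) == 0L) {
    out <- data.frame(marker = character(), chr = character(), pos = numeric())
    class(out) <- c("physical_map", "data.frame")
    return(out)
  }
  first <- strsplit(trimws(ln[1L]), "\\s+")[[1L]]
  if (length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L]))))
    ln <- ln[-1L]  # header line
  tab <- do.call(rbind, strsplit(trimws(ln), "\\s+"))
  if (ncol(tab) < 3L) stop("physical map needs columns marker, chromosome, position")
  out <- data.frame(marker = tab[, 1L], chr = tab[, 2L],
                    pos = as.numeric(tab[, 3L]))
  if (anyNA(out$pos)) stop("non-numeric position in physical map")
  if (any(out$pos < 0)) stop("negative position in physical map")
  if (anyDuplicated(out$marker))
    stop("duplicated marker in physical map: ",
         out$marker[duplicated(out$marker)][1L])
  class(out) <- c("physical_map", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# GeneticMap
# ---------------------------------------------------------------------------

#' Genetic map object
#'
#' Ordered linkage groups with cumulative cM positions, a status per marker
#' (`scaffold`, `framework` or `placed`) and, for placed markers, the
#' flanking-framework-marker bin.
#'
#' @param df data frame with columns `group`, `marker`, `pos`, `status`,
#'   `bin` (bin as `"left..right"`, `NA` for framework markers).
#' @param lod_threshold order-robustness LOD threshold the framework was
#'   built at (recorded as an attribute).
#' @return object of class `genetic_map` (a data frame).
#' @export
genetic_map <- function(df, lod_threshold = NA_real_) {
  need <- c("group", "marker", "pos", "status")
  if (!all(need %in% names(df))) stop("map needs columns ", paste(need, collapse = ", "))
  if (is.null(df$bin)) df$bin <- NA_character_
  if (anyDuplicated(df$marker)) stop("marker appears twice in map")
  for (g in unique(df$group)) {
    p <- df$pos[df$group == g]
    if (length(p) && abs(min(p)) > 1e-9) stop("group ", g, " does not start at 0")
    if (is.unsorted(p, strictly = FALSE)) stop("positions not non-decreasing in group ", g)
  }
  df <- df[, c("group", "marker", "pos", "status", "bin")]
  attr(df, "lod_threshold") <- lod_threshold
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' @export
print.genetic_map <- function(x, ...) {
  ng <- length(unique(x$group))
  cat(sprintf("genetic_map: %d markers in %d linkage group(s), %.1f cM total\n",
              nrow(x), ng, sum(tapply(x$pos, x$group, max))))
  st <- table(x$status)
  cat("  status:", paste(names(st), st, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Map lengths per linkage group
#' @param map a [genetic_map].
#' @param status_in restrict to markers with these statuses (default all).
#' @return named numeric vector of group lengths in cM.
#' @export
map_lengths <- function(map, status_in = NULL) {
  df <- as.data.frame(map)
  if (!is.null(status_in)) df <- df[df$status %in% status_in, ]
  vapply(split(df$pos, df$group), function(p) max(p) - min(p), 0)
}

#' Write / read a genetic map file
#'
#' Tab-separated with columns group, marker, position (cM), status, bin.
#' `read_map()` round-trips the object written by `write_map()`.
#'
#' @param map a [genetic_map].
#' @param path file path.
#' @return `path` invisibly (`write_map`); a [genetic_map] (`read_map`).
#' @export
write_map <- function(map, path) {
  if (nrow(map) == 0L) stop("refusing to write an empty map")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# genetic map; lod_threshold=%s",
                     format(attr(map, "lod_threshold"))), con)
  writeLines("group\tmarker\tpos\tstatus\tbin", con)
  df <- as.data.frame(map)
  df$bin[is.na(df$bin)] <- "."
  write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  ln <- readLines(path, warn = FALSE)
  thr <- NA_real_
  hd <- grep("lod_threshold=", ln, value = TRUE)
  if (length(hd)) thr <- suppressWarnings(as.numeric(sub(".*lod_threshold=", "", hd[1L])))
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   colClasses = c("character", "character", "numeric",
                                  "character", "character"))
  df$bin[df$bin == "."] <- NA_character_
  genetic_map(df, lod_threshold = thr)
}

#' Write the pairwise 2-point LOD matrix
#'
#' Square tab-separated matrix with marker-name header row/column; the
#' diagonal is written as the sentinel `NA` (a self-pair has no LOD).
#'
#' @param tp a `two_point_matrix` object (see [two_point_matrix()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lod_matrix <- function(tp, path) {
  lod <- tp$lod
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# pairwise 2-point LOD matrix (diagonal = NA)", con)
  writeLines(paste(c("marker", colnames(lod)), collapse = "\t"), con)
  write.table(cbind(rownames(lod), format(round(lod, 4L), trim = TRUE)),
              con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a Marey-map table
#'
#' Genetic positions versus physical (anchor) positions, for markers present
#' in both the map and the physical map.  Plotting genetic vs physical
#' position per chromosome gives the Marey map; its slope is the local
#' recombination rate.
#'
#' @param map a [genetic_map].
#' @param phymap a `physical_map` from [read_physical_map()].
#' @param path output path.
#' @return the table, invisibly; warns and writes an empty table when no
#'   markers are shared.
#' @export
write_marey_table <- function(map, phymap, path) {
  shared <- intersect(map$marker, phymap$marker)
  if (length(shared) == 0L)
    warning("no markers shared between map and physical map; writing empty Marey table")
  i <- match(shared, map$marker); j <- match(shared, phymap$marker)
  out <- data.frame(marker = shared,
                    phys_chr = phymap$chr[j], phys_pos = phymap$pos[j],
                    gen_group = map$group[i], gen_pos = map$pos[i])
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# Marey map table: genetic vs physical positions", con)
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    write.table(format(out, digits = 10, trim = TRUE), con, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(out)
}

#' Write a graphical-genotypes table
#'
#' Tab-separated matrix of observed-or-imputed genotype calls (markers in
#' map order x individuals), the table behind graphical-genotype displays
#' of data and map quality.
#'
#' @param post a `posterior_genotypes` object from [impute_posteriors()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphical_genotypes <- function(post, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# graphical genotypes: argmax imputed calls in map order", con)
  writeLines(paste(c("marker", post$individuals), collapse = "\t"), con)
  write.table(cbind(post$markers, post$imputed), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
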