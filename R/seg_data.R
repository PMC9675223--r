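# Segregation datasets: construction, validation, genotype-code alphabets.

POP_TYPES <- c("BC", "DH", "F2", "RIL", "IRIL", "CP")
MISSING_CODE <- "-"
MISSING_ALIASES <- c("-", "--", "U", "NA", ".")

#' Segregation dataset for a biparental mapping population
#'
#' Container for a marker-by-individual matrix of observed genotype codes
#' plus population-type metadata.  Codes are canonicalized: missing data is
#' `"-"` (aliases `U`, `NA`, `--` accepted on input).  Valid alphabets are
#' `A,B` for BC/DH; `A,H,B,C,D` for F2 (`C` = "not A" i.e. H-or-B dominant
#' code, `D` = "not B"); `A,H,B` for RIL/IRIL; and for CP populations the
#' offspring codes are two-letter allele pairs drawn from the union of the
#' marker's parental alleles (e.g. `ab`, `ac`).
#'
#' @param geno character matrix (markers x individuals) of genotype codes;
#'   must have unique row and column names.
#' @param pop_type one of `"BC"`, `"DH"`, `"F2"`, `"RIL"`, `"IRIL"`, `"CP"`.
#' @param self_gens number of selfing generations from the F1 for RIL/IRIL
#'   (`Inf` = selfed to fixation; `1` would be an F2).
#' @param intermate_gens number of extra random-intermating generations
#'   between the F2 and the selfing phase (IRIL only).
#' @param cp_parents for CP: character matrix (markers x 2) of parental
#'   genotypes, e.g. `"ab"`, `"aa"`.
#' @return an object of class `seg_data`.
#' @export
seg_data <- function(geno, pop_type, self_gens = Inf, intermate_gens = 0,
                     cp_parents = NULL) {
  pop_type <- match.arg(toupper(pop_type), POP_TYPES)
  if (!is.matrix(geno) || !is.character(geno))
    stop("geno must be a character matrix")
  if (is.null(rownames(geno)) || is.null(colnames(geno)))
    stop("geno must have marker row names and individual column names")
  if (anyDuplicated(rownames(geno))) stop("duplicated marker names")
  if (anyDuplicated(colnames(geno))) stop("duplicated individual names")
  if (nrow(geno) < 2L) stop("need at least 2 markers")
  if (ncol(geno) < 1L) stop("need at least 1 individual")
  geno[geno %in% MISSING_ALIASES] <- MISSING_CODE

  if (pop_type == "CP") {
    if (is.null(cp_parents)) stop("CP dataset needs cp_parents")
    cp_parents <- as.matrix(cp_parents)
    if (nrow(cp_parents) != nrow(geno)) stop("cp_parents must have one row per marker")
    cp_parents <- t(apply(cp_parents, 1L, function(g) {
      vapply(g, sort_code, "")
    }))
    rownames(cp_parents) <- rownames(geno)
    for (k in seq_len(nrow(geno))) {
      alleles <- unique(unlist(strsplit(cp_parents[k, ], "")))
      for (q in seq_len(ncol(geno))) {
        code <- geno[k, q]
        if (code == MISSING_CODE) next
        code <- sort_code(code)
        geno[k, q] <- code
        al <- strsplit(code, "")[[1L]]
        if (nchar(code) != 2L || !all(al %in% alleles))
          stop(sprintf(
            "offspring code '%s' at marker '%s', individual '%s' is not compatible with parental genotypes %sx%s",
            code, rownames(geno)[k], colnames(geno)[q],
            cp_parents[k, 1L], cp_parents[k, 2L]))
        # each allele must be carried by at least one parent able to donate it
        p1 <- strsplit(cp_parents[k, 1L], "")[[1L]]
        p2 <- strsplit(cp_parents[k, 2L], "")[[1L]]
        ok <- (al[1L] %in% p1 && al[2L] %in% p2) || (al[1L] %in% p2 && al[2L] %in% p1)
        if (!ok)
          stop(sprintf(
            "offspring code '%s' at marker '%s', individual '%s' cannot arise from %sx%s (putative non-Mendelian call)",
            code, rownames(geno)[k], colnames(geno)[q],
            cp_parents[k, 1L], cp_parents[k, 2L]))
      }
    }
  } else {
    alphabet <- pop_alphabet(pop_type)
    bad <- matrix(!(geno %in% c(alphabet, MISSING_CODE)), nrow(geno))
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf("unknown code '%s' at marker '%s', individual '%s' for population type %s",
                   geno[w[1L], w[2L]], rownames(geno)[w[1L]], colnames(geno)[w[2L]], pop_type))
    }
  }

  structure(list(
    pop_type = pop_type,
    geno = geno,
    self_gens = if (pop_type %in% c("RIL", "IRIL")) self_gens else NA_real_,
    intermate_gens = if (pop_type == "IRIL") intermate_gens else 0,
    cp_parents = if (pop_type == "CP") cp_parents else NULL
  ), class = "seg_data")
}

sort_code <- function(code) {
  paste(sort(strsplit(code, "")[[1L]]), collapse = "")
}

pop_alphabet <- function(pop_type) {
  switch(pop_type,
    BC = c("A", "B"), DH = c("A", "B"),
    F2 = c("A", "H", "B", "C", "D"),
    RIL = c("A", "H", "B"), IRIL = c("A", "H", "B"),
    CP = NULL)
}

#' @export
print.seg_data <- function(x, ...) {
  cat(sprintf("seg_data: %s population, %d markers x %d individuals (%.1f%% missing)\n",
              x$pop_type, nrow(x$geno), ncol(x$geno),
              100 * mean(x$geno == MISSING_CODE)))
  invisible(x)
}

#' @export
dim.seg_data <- function(x) dim(x$geno)

markers_of <- function(ds) rownames(ds$geno)
individuals_of <- function(ds) colnames(ds$geno)

#' Flag markers that are monomorphic in the sample
#'
#' A marker is monomorphic if at most one distinct non-missing code is
#' observed (for CP, if its parental genotypes admit a single offspring
#' class, or a single class is observed).
#'
#' @param ds a [seg_data] object.
#' @return named logical vector over markers.
#' @export
monomorphic_markers <- function(ds) {
  out <- apply(ds$geno, 1L, function(v) length(unique(v[v != MISSING_CODE])) <= 1L)
  if (ds$pop_type == "CP") {
    k <- vapply(seq_len(nrow(ds$geno)),
                function(i) length(cp_marker_classes(ds, i)), 0L)
    out <- out | (k <= 1L)
  }
  out
}

# offspring genotype classes of one CP marker, given its parental genotypes
cp_marker_classes <- function(ds, marker) {
  i <- marker_index(ds, marker)
  p1 <- strsplit(ds$cp_parents[i, 1L], "")[[1L]]
  p2 <- strsplit(ds$cp_parents[i, 2L], "")[[1L]]
  g <- outer(p1, p2, function(a, b) {
    mapply(function(x, y) paste(sort(c(x, y)), collapse = ""), a, b)
  })
  sort(unique(as.vector(g)))
}

# segregation class of a CP marker: which parents are heterozygous
cp_informative_parents <- function(ds, marker) {
  i <- marker_index(ds, marker)
  p1 <- strsplit(ds$cp_parents[i, 1L], "")[[1L]]
  p2 <- strsplit(ds$cp_parents[i, 2L], "")[[1L]]
  c(p1 = p1[1L] != p1[2L], p2 = p2[1L] != p2[2L])
}

#' Segregation class of CP markers
#'
#' Classifies each marker of a CP dataset as `"female-informative"`
#' (heterozygous in parent 1 only, pseudo-testcross), `"male-informative"`
#' (parent 2 only), `"both-informative"`, or `"uninformative"`.
#'
#' @param ds a CP [seg_data] object.
#' @return named character vector over markers.
#' @export
cp_segregation_class <- function(ds) {
  stopifnot(ds$pop_type == "CP")
  out <- vapply(markers_of(ds), function(m) {
    inf <- cp_informative_parents(ds, m)
    if (inf[1L] && inf[2L]) "both-informative"
    else if (inf[1L]) "female-informative"
    else if (inf[2L]) "male-informative"
    else "uninformative"
  }, "")
  out
}

marker_index <- function(ds, marker) {
  if (is.character(marker)) {
    i <- match(marker, markers_of(ds))
    if (anyNA(i)) stop("unknown marker: ", paste(marker[is.na(i)], collapse = ", "))
    i
  } else as.integer(marker)
}

#' Restrict a dataset to a subset of markers
#' @param ds a [seg_data] object.
#' @param markers character or integer vector of markers to keep.
#' @return a [seg_data] with the selected markers, in the requested order.
#' @export
subset_markers <- function(ds, markers) {
  i <- marker_index(ds, markers)
  seg_data(ds$geno[i, , drop = FALSE], ds$pop_type,
           self_gens = ds$self_gens, intermate_gens = ds$intermate_gens,
           cp_parents = if (!is.null(ds$cp_parents)) ds$cp_parents[i, , drop = FALSE])
}
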