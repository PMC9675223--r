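# Assignment of polymorphic markers to linkage groups and placement of
# non-framework markers into framework bins.

#' Assign markers to linkage groups by best 2-point LOD
#'
#' For each marker, the best LOD is the maximum 2-point LOD to any member of
#' a group.  A marker is `assigned` when its best LOD reaches `lod_assign`
#' and beats the second-best group by `assign_gap`; `ambiguous` when two or
#' more groups lie within `assign_gap`; `unlinked` otherwise.
#'
#' @param ds the dataset.
#' @param chains list of `mp_model` group chains (scaffolds or frameworks).
#' @param tp a [two_point_matrix] covering markers and chain members.
#' @param params a [map_params].
#' @param markers markers to assign (default: all markers of `tp` not in a
#'   chain).
#' @return data frame of class `assignment_result`: marker, group (index
#'   into `chains`), lod, second_group, second_lod, status.
#' @export
assign_markers <- function(ds, chains, tp, params = map_params(),
                           markers = NULL) {
  in_chain <- unlist(lapply(chains, `[[`, "markers"))
  if (is.null(markers)) markers <- setdiff(tp$markers, in_chain)
  if (!length(markers)) {
    out <- data.frame(marker = character(), group = integer(),
                      lod = numeric(), second_group = integer(),
                      second_lod = numeric(), status = character())
    class(out) <- c("assignment_result", "data.frame")
    return(out)
  }
  out <- data.frame(marker = markers, group = NA_integer_, lod = 0,
                    second_group = NA_integer_, second_lod = 0,
                    status = "unlinked", stringsAsFactors = FALSE)
  by_group <- vapply(chains, function(ch) {
    apply(tp$lod[markers, ch$markers, drop = FALSE], 1L,
          function(v) if (all(is.na(v))) 0 else max(v, na.rm = TRUE))
  }, numeric(length(markers)))
  by_group <- matrix(by_group, nrow = length(markers))
  for (q in seq_along(markers)) {
    o <- order(-by_group[q, ])
    out$group[q] <- o[1L]
    out$lod[q] <- by_group[q, o[1L]]
    if (length(o) > 1L) {
      out$second_group[q] <- o[2L]
      out$second_lod[q] <- by_group[q, o[2L]]
    }
    if (out$lod[q] < params$lod_assign) out$status[q] <- "unlinked"
    else if (out$lod[q] - out$second_lod[q] < params$assign_gap)
      out$status[q] <- "ambiguous"
    else out$status[q] <- "assigned"
  }
  class(out) <- c("assignment_result", "data.frame")
  out
}

#' Place markers into framework bins to build the total map
#'
#' Each marker is evaluated by multipoint likelihood at every interval of
#' its group and placed at its ML interval, with an ML within-bin position;
#' the framework skeleton and its cumulative positions are frozen (a marker
#' whose ML attachment lies beyond a terminal framework marker is clamped to
#' the terminal position).  Twins are re-attached at their representative's
#' position with status `placed`.
#'
#' @param chains list of framework `mp_model` chains.
#' @param assignment an `assignment_result`; markers with status `assigned`
#'   are placed.
#' @param ds the dataset.
#' @param params a [map_params].
#' @param scaffold_markers optional character vector: markers to label with
#'   status `scaffold` rather than `framework`.
#' @param twins optional [find_twins()] result for re-attachment.
#' @return a [genetic_map] with statuses scaffold/framework/placed and bin
#'   references for placed markers.
#' @export
place_markers <- function(chains, assignment, ds, params = map_params(),
                          scaffold_markers = character(), twins = NULL) {
  rows <- list()
  for (g in seq_along(chains)) {
    ch <- chains[[g]]
    pos <- c(0, cumsum(ch$d))
    status <- ifelse(ch$markers %in% scaffold_markers, "scaffold", "framework")
    rows[[length(rows) + 1L]] <- data.frame(
      group = paste0("LG", g), marker = ch$markers, pos = pos,
      status = status, bin = NA_character_)
    todo <- assignment$marker[assignment$status == "assigned" &
                              assignment$group == g]
    todo <- setdiff(todo, ch$markers)
    m <- length(ch$markers)
    for (cand in todo) {
      sc <- insert_scan(ch, ds, cand)
      b <- scan_best(sc)
      if (b$slot == 1L) {
        p <- 0; bin <- paste0("<", ch$markers[1L])
      } else if (b$slot == m + 1L) {
        p <- pos[m]; bin <- paste0(">", ch$markers[m])
      } else {
        k <- b$slot - 1L
        p <- pos[k] + min(max(b$d_attach, 0), ch$d[k])
        bin <- paste0(ch$markers[k], "..", ch$markers[k + 1L])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = paste0("LG", g), marker = cand, pos = p,
        status = "placed", bin = bin)
    }
  }
  df <- do.call(rbind, rows)
  # re-attach twins at their representative's position
  if (!is.null(twins)) {
    for (rep_m in names(twins$groups)) {
      others <- setdiff(twins$groups[[rep_m]], rep_m)
      if (!length(others)) next
      at <- df[df$marker == rep_m, ]
      if (nrow(at) != 1L) next
      others <- setdiff(others, df$marker)
      if (!length(others)) next
      df <- rbind(df, data.frame(group = at$group, marker = others,
                                 pos = at$pos, status = "placed",
                                 bin = paste0("=", rep_m)))
    }
  }
  df <- df[order(df$group, df$pos, df$status == "placed", df$marker), ]
  rownames(df) <- NULL
  genetic_map(df, lod_threshold = params$lod_framework)
}
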