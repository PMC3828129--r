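#' Default greek-key spatial signatures
#'
#' Deltas of sheet spatial positions read across a window of four
#' sequence-consecutive strands. The classical greek key places the first
#' strand three sheet positions away from the next three, which walk back one
#' position at a time; the mirrored signature covers the reversed sheet
#' numbering.
#'
#' @return List of integer delta triples.
#' @export
greek_key_signatures <- function() {
  list(c(3L, -1L, -1L), c(-3L, 1L, 1L))
}

#' Detect greek key motifs in a sheet topology
#'
#' Scans every window of four sequence-consecutive strands lying in one
#' sheet. A window is a greek key when its spatial-position deltas (read in
#' sequence order) match a configured signature and every pairing between
#' spatially adjacent window strands is antiparallel.
#'
#' @param topology list with `strands` (sheet_id, strand_id, sequence_order,
#'   spatial_position) and `pairings` (strand_a, strand_b, orientation), as
#'   from [read_topology()] or a synthetic domain.
#' @param signatures list of delta triples; see [greek_key_signatures()].
#' @return data.frame of calls (motif, sheet_id, strand_ids comma-joined);
#'   zero rows when none found.
#' @export
find_greek_keys <- function(topology, signatures = greek_key_signatures()) {
  calls <- list()
  st <- topology$strands
  for (sheet in unique(st$sheet_id)) {
    s <- st[st$sheet_id == sheet, , drop = FALSE]
    s <- s[order(s$sequence_order), , drop = FALSE]
    if (nrow(s) < 4) next
    for (i in seq_len(nrow(s) - 3)) {
      w <- s[i:(i + 3), , drop = FALSE]
      if (!all(diff(w$sequence_order) == 1)) next
      deltas <- diff(w$spatial_position)
      if (!any(vapply(signatures, function(sig)
        all(deltas == sig), TRUE))) next
      if (!.adjacent_pairs_antiparallel(w, topology$pairings)) next
      calls[[length(calls) + 1L]] <-
        data.frame(motif = "greek_key", sheet_id = sheet,
                   strand_ids = paste(w$strand_id, collapse = ","),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(motif = character(0), sheet_id = character(0),
                      strand_ids = character(0)))
  do.call(rbind, calls)
}

# every spatially adjacent pair within the window must be paired antiparallel
.adjacent_pairs_antiparallel <- function(w, pairings) {
  for (i in seq_len(nrow(w))) for (j in seq_len(nrow(w))) {
    if (i >= j) next
    if (abs(w$spatial_position[i] - w$spatial_position[j]) != 1L) next
    hit <- (pairings$strand_a == w$strand_id[i] &
              pairings$strand_b == w$strand_id[j]) |
      (pairings$strand_a == w$strand_id[j] &
         pairings$strand_b == w$strand_id[i])
    if (!any(hit)) return(FALSE)
    if (any(pairings$orientation[hit] != "antiparallel")) return(FALSE)
  }
  TRUE
}

#' Detect jelly roll motifs from greek key calls
#'
#' A jelly roll is a greek key wrapped by two extra strands: one immediately
#' preceding and one immediately following the key in sequence, sitting at
#' the two outer spatial slots of the sheet and paired antiparallel with
#' their spatial neighbours.
#'
#' @param topology as for [find_greek_keys()].
#' @param greek_keys greek key calls for the same domain (computed if
#'   missing).
#' @return data.frame of jelly roll calls (possibly zero rows).
#' @export
find_jelly_rolls <- function(topology, greek_keys = NULL) {
  if (is.null(greek_keys)) greek_keys <- find_greek_keys(topology)
  empty <- data.frame(motif = character(0), sheet_id = character(0),
                      strand_ids = character(0))
  if (!nrow(greek_keys)) return(empty)
  calls <- list()
  st <- topology$strands
  for (r in seq_len(nrow(greek_keys))) {
    sheet <- greek_keys$sheet_id[r]
    key_ids <- strsplit(greek_keys$strand_ids[r], ",")[[1]]
    s <- st[st$sheet_id == sheet, , drop = FALSE]
    key <- s[match(key_ids, s$strand_id), , drop = FALSE]
    before <- s[s$sequence_order == min(key$sequence_order) - 1L, , drop = FALSE]
    after <- s[s$sequence_order == max(key$sequence_order) + 1L, , drop = FALSE]
    if (nrow(before) != 1 || nrow(after) != 1) next
    outer_slots <- c(min(key$spatial_position) - 1L,
                     max(key$spatial_position) + 1L)
    wrap <- rbind(before, after)
    if (!setequal(wrap$spatial_position, outer_slots)) next
    win <- rbind(key, wrap)
    if (!.adjacent_pairs_antiparallel(win, topology$pairings)) next
    calls[[length(calls) + 1L]] <-
      data.frame(motif = "jelly_roll", sheet_id = sheet,
                 strand_ids = paste(win$strand_id[order(win$sequence_order)],
                                    collapse = ","),
                 stringsAsFactors = FALSE)
  }
  if (!length(calls)) return(empty)
  do.call(rbind, calls)
}

#' Classify superfamilies into greek key and jelly roll sets
#'
#' Jelly-roll membership is any-domain: one jelly roll call anywhere puts the
#' superfamily in the jelly roll set. The greek key set holds the remaining
#' superfamilies with at least one greek key call, so the two sets are
#' disjoint by construction.
#'
#' @param calls data.frame with columns `superfamily_id` and `motif`
#'   (`greek_key` / `jelly_roll`), pooled over all representative domains.
#' @return List with character vectors `greek_key_set` and `jelly_roll_set`.
#' @export
classify_superfamily_motifs <- function(calls) {
  jr <- unique(calls$superfamily_id[calls$motif == "jelly_roll"])
  gk <- setdiff(unique(calls$superfamily_id[calls$motif == "greek_key"]), jr)
  list(greek_key_set = sort(gk), jelly_roll_set = sort(jr))
}
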