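#' Synthetic domain structure with plausible C-alpha geometry
#'
#' Builds a toy domain from a secondary-structure plan: ideal alpha-helical
#' spirals (2.3 A radius, 1.5 A rise, 100 degrees per residue), near-extended
#' strands, and seeded random-walk coils, all with 3.8 A virtual C-alpha
#' bonds and clash avoidance (non-consecutive residues at least 3.5 A apart;
#' the whole chain is re-drawn on a clash, up to `max_retries` times).
#' Residue annotations (secondary structure, relative exposure sampled to hit
#' a target buried fraction, optional disulphides between spatially proximal
#' residues mutated to cysteine) and a sheet topology for the strands are
#' generated alongside, standing in for DSSP/JOY/PROMOTIF output on real
#' structures.
#'
#' @param plan data.frame with columns `ss_element`
#'   (`helix`/`strand`/`coil`) and `length` (residues); total length >= 10.
#' @param seed integer seed.
#' @param domain_id,superfamily_id identifiers carried on the record.
#' @param target_buried fraction of residues annotated as buried.
#' @param exposure_threshold burial cutoff used when sampling exposures.
#' @param n_disulphides number of disulphide bridges to plant (best effort:
#'   requires spatially proximal non-local pairs).
#' @param spatial_positions optional integer vector, one sheet slot per
#'   strand in plan order (default: meander, 1..k).
#' @param orientations optional pairing orientations between spatially
#'   adjacent strands (default all `"antiparallel"`).
#' @param max_retries chain re-draws allowed before giving up.
#' @return A `domain_structure` list: `domain_id`, `superfamily_id`,
#'   `sequence`, `ca_coords`, `annotations`, `topology`.
#' @export
synthetic_domain <- function(plan, seed = 1, domain_id = "dom1",
                             superfamily_id = "sf1", target_buried = 0.3,
                             exposure_threshold = 7, n_disulphides = 0,
                             spatial_positions = NULL, orientations = NULL,
                             max_retries = 50) {
  stopifnot(all(plan$ss_element %in% c("helix", "strand", "coil")),
            sum(plan$length) >= 10)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n <- sum(plan$length)
  coords <- NULL
  for (try in seq_len(max_retries)) {
    coords <- .build_chain(plan)
    if (!is.null(coords) && .chain_ok(coords)) break
    coords <- NULL
  }
  if (is.null(coords))
    stop("clash avoidance failed after ", max_retries, " retries")

  aa_pool <- names(omh_scale())
  sequence <- sample(setdiff(aa_pool, "C"), n, replace = TRUE)
  ss <- rep(plan$ss_element, plan$length)
  strand_rows <- which(plan$ss_element == "strand")
  strand_id <- rep(NA_character_, n)
  idx <- cumsum(plan$length) - plan$length
  for (j in seq_along(strand_rows)) {
    r <- strand_rows[j]
    strand_id[(idx[r] + 1):(idx[r] + plan$length[r])] <- sprintf("s%d", j)
  }
  # exposures: buried residues strictly below the threshold
  n_buried <- round(target_buried * n)
  buried <- sample.int(n, n_buried)
  expo <- stats::runif(n, exposure_threshold + 0.5, 100)
  expo[buried] <- stats::runif(n_buried, 0, max(exposure_threshold - 0.5, 0.1))
  # disulphides between spatially proximal, sequence-distant pairs
  partner <- rep(NA_integer_, n)
  if (n_disulphides > 0) {
    d <- as.matrix(stats::dist(coords))
    sep <- abs(outer(seq_len(n), seq_len(n), "-"))
    cand <- which(upper.tri(d) & d < 7 & sep >= 5, arr.ind = TRUE)
    used <- integer(0)
    if (nrow(cand)) for (b in seq_len(n_disulphides)) {
      free <- cand[!(cand[, 1] %in% used) & !(cand[, 2] %in% used), ,
                   drop = FALSE]
      if (!nrow(free)) break
      pick <- free[sample.int(nrow(free), 1), ]
      sequence[pick] <- "C"
      partner[pick[1]] <- pick[2]; partner[pick[2]] <- pick[1]
      used <- c(used, pick)
    }
  }
  annotations <- data.frame(residue_index = seq_len(n), aa = sequence,
                            ss_element = ss, strand_id = strand_id,
                            relative_exposure = expo,
                            disulphide_partner = partner,
                            stringsAsFactors = FALSE)
  topology <- .plan_topology(length(strand_rows), spatial_positions,
                             orientations)
  structure(list(domain_id = domain_id, superfamily_id = superfamily_id,
                 sequence = paste(sequence, collapse = ""),
                 ca_coords = coords, annotations = annotations,
                 topology = topology),
            class = "domain_structure")
}

.plan_topology <- function(k, spatial_positions, orientations) {
  if (k == 0)
    return(list(strands = data.frame(sheet_id = character(0),
                                     strand_id = character(0),
                                     sequence_order = integer(0),
                                     spatial_position = integer(0)),
                pairings = data.frame(sheet_id = character(0),
                                      strand_a = character(0),
                                      strand_b = character(0),
                                      orientation = character(0))))
  if (is.null(spatial_positions)) spatial_positions <- seq_len(k)
  stopifnot(length(spatial_positions) == k,
            !anyDuplicated(spatial_positions))
  ids <- sprintf("s%d", seq_len(k))
  strands <- data.frame(sheet_id = "A", strand_id = ids,
                        sequence_order = seq_len(k),
                        spatial_position = as.integer(spatial_positions),
                        stringsAsFactors = FALSE)
  ord <- order(strands$spatial_position)
  pa <- ids[ord][-k]; pb <- ids[ord][-1]
  if (is.null(orientations)) orientations <- rep("antiparallel", k - 1)
  pairings <- if (k >= 2)
    data.frame(sheet_id = "A", strand_a = pa, strand_b = pb,
               orientation = rep_len(orientations, k - 1),
               stringsAsFactors = FALSE)
  else data.frame(sheet_id = character(0), strand_a = character(0),
                  strand_b = character(0), orientation = character(0))
  list(strands = strands, pairings = pairings)
}

# sequentially place ideal secondary-structure templates with random rigid
# orientations, keeping every virtual bond at ~3.8 A
.build_chain <- function(plan) {
  pts <- matrix(numeric(0), 0, 3)
  for (r in seq_len(nrow(plan))) {
    L <- plan$length[r]
    tmpl <- switch(plan$ss_element[r],
                   helix = .helix_template(L),
                   strand = .strand_template(L),
                   coil = .coil_template(L))
    placed <- NULL
    for (attempt in 1:30) {         # re-orient the segment on a clash
      seg <- tmpl %*% t(.random_rotation())
      if (nrow(pts)) {
        offset <- pts[nrow(pts), ] + 3.8 * .random_unit()
        seg <- sweep(seg, 2, seg[1, ]) + rep(offset, each = L)
      }
      if (!nrow(pts) || .no_cross_clash(pts, seg)) { placed <- seg; break }
    }
    if (is.null(placed)) return(NULL)
    pts <- rbind(pts, placed)
  }
  pts
}

# new segment vs existing chain: everything except the joining virtual bond
# must stay at least 3.5 A apart
.no_cross_clash <- function(pts, seg) {
  for (i in seq_len(nrow(seg))) {
    old <- if (i == 1) pts[-nrow(pts), , drop = FALSE] else pts
    if (!nrow(old)) next
    if (min(rowSums(sweep(old, 2, seg[i, ])^2)) < 3.5^2) return(FALSE)
  }
  TRUE
}

.chain_ok <- function(pts) {
  d <- as.matrix(stats::dist(pts))
  steps <- d[cbind(seq_len(nrow(pts) - 1), 2:nrow(pts))]
  if (any(steps < 2.8 | steps > 4.2)) return(FALSE)
  sep <- abs(outer(seq_len(nrow(pts)), seq_len(nrow(pts)), "-"))
  all(d[sep >= 2] >= 3.5)
}

.helix_template <- function(L) {
  t <- seq_len(L) - 1
  ang <- t * 100 * pi / 180
  cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * t)
}

.strand_template <- function(L) {
  t <- seq_len(L) - 1
  cbind(3.35 * t, 0.9 * (-1)^t, 0)   # step = sqrt(3.35^2 + 1.8^2) ~ 3.8 A
}

.coil_template <- function(L) {
  pts <- matrix(0, L, 3)
  if (L == 1) return(pts)
  for (i in 2:L) {
    for (tries in 1:100) {
      p <- pts[i - 1, ] + 3.8 * .random_unit()
      if (i < 3 || min(sqrt(rowSums(sweep(pts[1:(i - 2), , drop = FALSE],
                                          2, p)^2))) >= 3.6) break
    }
    pts[i, ] <- p
  }
  pts
}

.random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

.random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
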