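#' Optimal matching hydrophobicity (OMH) scale
#'
#' Per-residue hydrophobicity values of Sweet & Eisenberg's optimal matching
#' hydrophobicity scale, keyed by one-letter amino-acid code.
#'
#' @return Named numeric vector of length 20.
#' @export
omh_scale <- function() {
  c(A = -0.40, R = -0.59, N = -0.92, D = -1.31, C = 0.17,
    Q = -0.91, E = -1.22, G = -0.67, H = -0.64, I = 1.25,
    L = 1.22, K = -0.67, M = 1.02, F = 1.92, P = -0.49,
    S = -0.55, T = -0.28, W = 0.50, Y = 1.67, V = 0.91)
}

#' Radius of gyration of a point set
#'
#' Root-mean-square distance of the points (C-alpha atoms) from their
#' centroid; invariant under rigid motion.
#'
#' @param coords numeric matrix, one row per residue, columns x/y/z.
#' @return Radius of gyration in the coordinate units (Angstrom).
#' @export
radius_of_gyration <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("need at least 2 points")
  ctr <- colMeans(coords)
  sqrt(mean(rowSums(sweep(coords, 2, ctr)^2)))
}

#' Residue contact counts
#'
#' Two residues are in contact if their C-alpha atoms lie within
#' `dist_threshold` Angstrom; a contact is non-local if the residues are at
#' least `min_separation` positions apart in sequence. Unordered pairs
#' `i < j` are counted once.
#'
#' @param coords C-alpha coordinate matrix.
#' @param dist_threshold contact distance in Angstrom.
#' @param min_separation minimum `j - i` for a non-local contact.
#' @return Named vector `c(total = , nonlocal = )`.
#' @export
contact_counts <- function(coords, dist_threshold = 8, min_separation = 5) {
  if (dist_threshold <= 0 || min_separation <= 0)
    stop("thresholds must be positive")
  n <- nrow(coords)
  if (n < 2) return(c(total = 0L, nonlocal = 0L))
  d <- as.matrix(stats::dist(coords))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  up <- upper.tri(d)
  in_contact <- up & d <= dist_threshold
  c(total = sum(in_contact),
    nonlocal = sum(in_contact & sep >= min_separation))
}

#' Non-local contacts normalised by radius of gyration
#'
#' @param coords C-alpha coordinate matrix.
#' @inheritParams contact_counts
#' @return Non-local contact count divided by Rg (contacts per Angstrom).
#' @export
nonlocal_contacts_norm <- function(coords, dist_threshold = 8,
                                   min_separation = 5) {
  rg <- radius_of_gyration(coords)
  if (rg == 0) stop("radius of gyration is zero")
  unname(contact_counts(coords, dist_threshold, min_separation)["nonlocal"]) / rg
}

#' Buried-residue fraction normalised by radius of gyration
#'
#' A residue is buried if its relative solvent exposure is below
#' `exposure_threshold` percent. The default divides the buried
#' \emph{proportion} by Rg; `normalize = "count"` divides the raw count
#' instead (the normalisation the published text leaves ambiguous).
#'
#' @param relative_exposure numeric vector of per-residue exposures (0-100).
#' @param coords C-alpha coordinate matrix (for Rg).
#' @param exposure_threshold burial cutoff in percent.
#' @param normalize `"proportion"` or `"count"`.
#' @return Normalised burial descriptor (per Angstrom).
#' @export
buried_fraction_norm <- function(relative_exposure, coords,
                                 exposure_threshold = 7,
                                 normalize = c("proportion", "count")) {
  normalize <- match.arg(normalize)
  if (anyNA(relative_exposure))
    stop("missing exposure for residues: ",
         paste(which(is.na(relative_exposure)), collapse = ", "))
  rg <- radius_of_gyration(coords)
  if (rg == 0) stop("radius of gyration is zero")
  n_buried <- sum(relative_exposure < exposure_threshold)
  if (normalize == "proportion")
    (n_buried / length(relative_exposure)) / rg
  else n_buried / rg
}

#' Mean hydrophobicity of a sequence
#'
#' Sum of per-residue scale values divided by the sequence length.
#'
#' @param sequence amino-acid string (one-letter codes) or character vector.
#' @param scale named residue -> value map; default the OMH scale.
#' @param unknown `"error"` rejects codes missing from the scale (X/B/Z...);
#'   `"mean"` maps them to the scale mean.
#' @return Mean hydrophobicity in scale units.
#' @export
hydrophobicity <- function(sequence, scale = omh_scale(),
                           unknown = c("error", "mean")) {
  unknown <- match.arg(unknown)
  aa <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  if (!length(aa)) stop("empty sequence")
  vals <- scale[aa]
  if (anyNA(vals)) {
    if (unknown == "error")
      stop("residue codes not in scale: ",
           paste(unique(aa[is.na(vals)]), collapse = ", "))
    vals[is.na(vals)] <- mean(scale)
  }
  mean(vals)
}

#' Strand-direction label of a domain
#'
#' Classifies a domain as parallel, antiparallel or mixed from the
#' orientations of its strand pairings; each strand residue inherits the
#' orientation(s) of its strand's pairings (a strand paired both ways counts
#' once per pairing). Domains with strand content below `min_strand_content`
#' are `not_applicable`.
#'
#' @param ss_element per-residue secondary structure (`helix`/`strand`/`coil`).
#' @param strand_id per-residue strand identifier (NA off-strand).
#' @param pairings data.frame (strand_a, strand_b, orientation) with
#'   orientation `"parallel"` or `"antiparallel"`.
#' @param min_strand_content minimum strand-residue fraction.
#' @param majority_threshold fraction of oriented strand residues required to
#'   call a pure direction.
#' @return One of `"parallel"`, `"antiparallel"`, `"mixed"`,
#'   `"not_applicable"`.
#' @export
strand_direction_label <- function(ss_element, strand_id, pairings,
                                   min_strand_content = 0.15,
                                   majority_threshold = 0.7) {
  is_strand <- ss_element == "strand"
  if (mean(is_strand) < min_strand_content) return("not_applicable")
  orient_of <- function(sid) {
    hit <- pairings$strand_a == sid | pairings$strand_b == sid
    pairings$orientation[hit]
  }
  par_w <- anti_w <- 0
  for (i in which(is_strand)) {
    o <- orient_of(strand_id[i])
    par_w <- par_w + sum(o == "parallel")
    anti_w <- anti_w + sum(o == "antiparallel")
  }
  tot <- par_w + anti_w
  if (tot == 0) return("not_applicable")
  if (par_w / tot >= majority_threshold) return("parallel")
  if (anti_w / tot >= majority_threshold) return("antiparallel")
  "mixed"
}

#' Disulphide class of a superfamily
#'
#' `"with"` if more than half the representative domains contain at least one
#' disulphide bond, `"without"` only if none do, `"ambiguous"` otherwise
#' (ambiguous superfamilies are excluded from the with/without contrast).
#'
#' @param has_disulphide logical vector, one entry per representative domain.
#' @return `"with"`, `"without"` or `"ambiguous"`.
#' @export
disulphide_class <- function(has_disulphide) {
  if (!length(has_disulphide)) stop("no domains")
  if (mean(has_disulphide) > 0.5) "with"
  else if (!any(has_disulphide)) "without"
  else "ambiguous"
}

#' Amino-acid propensities by age group
#'
#' Propensity of amino acid `a` in group `G`:
#' \deqn{P(a, G) = \frac{n_{a,G}/N_G}{n_a/N}}
#' with expected value 1 under no enrichment. Significance per cell comes
#' from a 1-df chi-square on the 2x2 amino-acid-by-group table
#' ([chi_square_propensity()]), Bonferroni-corrected over all cells tested.
#'
#' @param sequences_by_group named list: group -> character vector of domain
#'   sequences (one-letter codes).
#' @param background optional vector of sequences defining the overall counts
#'   (defaults to the union of all groups).
#' @param alpha significance level before correction.
#' @return data.frame (aa, group, propensity, n_aa_group, N_group, n_aa, N,
#'   p, significant); amino acids absent overall get `NA` propensity.
#' @export
amino_acid_propensities <- function(sequences_by_group, background = NULL,
                                    alpha = 0.05) {
  count_aa <- function(seqs) {
    aa <- unlist(strsplit(paste(seqs, collapse = ""), ""))
    table(factor(aa, levels = names(omh_scale())))
  }
  if (is.null(background)) background <- unlist(sequences_by_group)
  tot <- count_aa(background)
  N <- sum(tot)
  rows <- list()
  for (grp in names(sequences_by_group)) {
    cnt <- count_aa(sequences_by_group[[grp]])
    Ng <- sum(cnt)
    for (aa in names(tot)) {
      n_aa <- as.integer(tot[aa]); n_ag <- as.integer(cnt[aa])
      prop <- if (n_aa == 0) NA_real_ else (n_ag / Ng) / (n_aa / N)
      p <- if (n_aa == 0) NA_real_ else
        chi_square_propensity(n_ag, Ng, n_aa, N)$p
      rows[[length(rows) + 1L]] <-
        data.frame(aa = aa, group = grp, propensity = prop,
                   n_aa_group = n_ag, N_group = Ng, n_aa = n_aa, N = N,
                   p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  tested <- !is.na(out$p)
  out$significant <- FALSE
  out$significant[tested] <- bonferroni(out$p[tested], m = sum(tested),
                                        alpha = alpha)
  out
}

#' Per-domain descriptor record
#'
#' Computes the full descriptor suite for one representative domain.
#'
#' @param domain a `domain_structure` (see [synthetic_domain()] or
#'   [read_ca_pdb()] plus [read_annotations()]).
#' @param dist_threshold,min_separation contact definition.
#' @param exposure_threshold burial cutoff (percent exposure).
#' @param min_strand_content,majority_threshold strand-direction thresholds.
#' @return One-row data.frame of descriptors.
#' @export
domain_descriptors <- function(domain, dist_threshold = 8, min_separation = 5,
                               exposure_threshold = 7,
                               min_strand_content = 0.15,
                               majority_threshold = 0.7) {
  ann <- domain$annotations
  pair <- if (!is.null(domain$topology)) domain$topology$pairings else
    data.frame(strand_a = character(0), strand_b = character(0),
               orientation = character(0))
  data.frame(
    domain_id = domain$domain_id,
    superfamily_id = domain$superfamily_id,
    length = nrow(ann),
    rg = radius_of_gyration(domain$ca_coords),
    nonlocal_contacts_norm = nonlocal_contacts_norm(
      domain$ca_coords, dist_threshold, min_separation),
    buried_norm = buried_fraction_norm(ann$relative_exposure,
                                       domain$ca_coords, exposure_threshold),
    hydrophobicity = hydrophobicity(domain$sequence),
    strand_label = strand_direction_label(ann$ss_element, ann$strand_id, pair,
                                          min_strand_content,
                                          majority_threshold),
    has_disulphide = any(!is.na(ann$disulphide_partner)),
    stringsAsFactors = FALSE)
}

#' Summarise descriptor records to superfamily level
#'
#' Numeric descriptors are averaged over a superfamily's representative
#' domains; the strand label is the strict majority label (`mixed` on a tie);
#' the disulphide class follows [disulphide_class()].
#'
#' @param records data.frame of [domain_descriptors()] rows.
#' @return One data.frame row per superfamily.
#' @export
summarize_superfamily <- function(records) {
  stopifnot(nrow(records) >= 1)
  out <- lapply(split(records, records$superfamily_id), function(df) {
    tab <- table(df$strand_label[df$strand_label != "not_applicable"])
    lab <- if (!length(tab)) "not_applicable" else {
      mx <- names(tab)[tab == max(tab)]
      if (length(mx) == 1 && max(tab) > sum(tab) / 2) mx else "mixed"
    }
    data.frame(superfamily_id = df$superfamily_id[1],
               n_domains = nrow(df),
               mean_length = mean(df$length),
               mean_rg = mean(df$rg),
               mean_nonlocal_norm = mean(df$nonlocal_contacts_norm),
               mean_buried_norm = mean(df$buried_norm),
               mean_hydrophobicity = mean(df$hydrophobicity),
               strand_label = lab,
               disulphide_class = disulphide_class(df$has_disulphide),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
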