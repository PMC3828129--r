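#' Tie-corrected Mann-Whitney U test
#'
#' Rank-sum comparison of two samples using midranks, with the normal
#' approximation variance adjusted for ties:
#' \deqn{Var(U) = \frac{n_1 n_2}{12}\Big[(N+1) - \sum_j \frac{t_j^3 - t_j}{N(N-1)}\Big]}
#' over tie groups of size \eqn{t_j}. Ages are heavily tied (many units share
#' an internal node), so the correction matters. A continuity correction of
#' 0.5 is applied to the normal deviate. For pooled sizes `N <= 12` an exact
#' permutation p-value over all \eqn{\binom{N}{n_1}} splits is also computed
#' (no continuity correction on that path).
#'
#' @param x,y numeric samples.
#' @param exact compute the exact permutation p-value (forced off for
#'   `N > 12`).
#' @return List with `U` (for `x`), `n1`, `n2`, `z`, `p_two_sided`,
#'   `p_one_sided` (alternative: `x` tends larger), `degenerate`, and, when
#'   computed, `p_exact_one_sided` / `p_exact_two_sided`.
#' @export
mann_whitney_ties <- function(x, y, exact = NULL) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)                      # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  v <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  degenerate <- v <= 0
  if (degenerate) {
    z <- 0; p2 <- 1; p1 <- 1
  } else {
    cc <- 0.5 * sign(U - mu)
    z <- (U - mu - cc) / sqrt(v)
    if (U == mu) z <- 0
    p1 <- stats::pnorm(z, lower.tail = FALSE)
    p2 <- 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
    p2 <- min(p2, 1)
  }
  out <- list(U = U, n1 = n1, n2 = n2, z = z,
              p_two_sided = p2, p_one_sided = p1, degenerate = degenerate)
  if (is.null(exact)) exact <- N <= 12
  if (exact && N <= 12) {
    idx <- utils::combn(N, n1)
    us <- apply(idx, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
    out$p_exact_one_sided <- mean(us >= U)
    out$p_exact_two_sided <- mean(abs(us - mu) >= abs(U - mu))
    # mid-p: half the point mass at the observed statistic; under heavy ties
    # this is the quantity the continuous normal approximation estimates
    out$p_exact_one_sided_mid <- mean(us > U) + 0.5 * mean(us == U)
    out$p_exact_two_sided_mid <- mean(abs(us - mu) > abs(U - mu)) +
      0.5 * mean(abs(us - mu) == abs(U - mu))
  }
  out
}

#' Chi-square test of an amino-acid proportion between a group and the rest
#'
#' Pearson chi-square with one degree of freedom on the 2x2 table (amino acid
#' vs other residues) x (age group vs rest).
#'
#' @param n_aa_group count of the amino acid in the group.
#' @param N_group total residues in the group.
#' @param n_aa count of the amino acid overall.
#' @param N total residues overall.
#' @return List with `chisq`, `p`, `low_expected` (any expected cell < 1).
#' @export
chi_square_propensity <- function(n_aa_group, N_group, n_aa, N) {
  if (n_aa_group > N_group || n_aa_group > n_aa || N_group > N || n_aa > N)
    stop("inconsistent counts")
  tab <- matrix(c(n_aa_group, N_group - n_aa_group,
                  n_aa - n_aa_group, (N - N_group) - (n_aa - n_aa_group)),
                2, 2)
  if (any(tab < 0)) stop("inconsistent counts")
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(chisq = 0, p = 1, low_expected = TRUE))
  chisq <- sum((tab - expd)^2 / expd)
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       low_expected = any(expd < 1))
}

#' Bonferroni significance flags
#'
#' @param p numeric vector of p-values.
#' @param m number of tests corrected for (must be at least `length(p)`).
#' @param alpha family-wise error level.
#' @return Logical vector: `p < alpha / m`.
#' @export
bonferroni <- function(p, m = length(p), alpha = 0.05) {
  if (m < length(p)) stop("m must be at least the number of p-values")
  p < alpha / m
}

#' Hypergeometric term enrichment by group with Bonferroni correction
#'
#' For every (term, group) pair tests over-representation of the term among
#' the group's superfamilies with a one-sided hypergeometric upper tail
#' \eqn{P(X \ge k)}, where the universe holds `N` superfamilies of which `K`
#' carry the term, and the group holds `n` of which `k` carry it.
#'
#' @param annotations data.frame with columns `superfamily_id`, `term_id`.
#' @param groups data.frame with columns `superfamily_id`, `group`.
#' @param universe character vector of superfamily ids; by default all
#'   annotated superfamilies (unannotated ones are excluded — set explicitly
#'   to change this).
#' @param m number of tests for the Bonferroni correction; default the number
#'   of distinct terms tested.
#' @param alpha family-wise error level.
#' @return data.frame (term_id, group, k, n, K, N, p, m, significant); terms
#'   with `K = 0` in the universe are skipped (attribute `skipped_terms`).
#' @export
hypergeometric_enrichment <- function(annotations, groups, universe = NULL,
                                      m = NULL, alpha = 0.05) {
  ann <- unique(annotations[, c("superfamily_id", "term_id")])
  if (is.null(universe)) universe <- unique(ann$superfamily_id)
  if (!all(groups$superfamily_id %in% universe))
    stop("groups contain superfamilies outside the universe")
  ann <- ann[ann$superfamily_id %in% universe, , drop = FALSE]
  N <- length(universe)
  terms <- sort(unique(as.character(ann$term_id)))
  Ks <- table(factor(ann$term_id, levels = terms))
  skipped <- terms[Ks == 0]
  terms <- terms[Ks > 0]
  res <- list()
  for (grp in sort(unique(as.character(groups$group)))) {
    members <- unique(groups$superfamily_id[groups$group == grp])
    n <- length(members)
    in_grp <- ann[ann$superfamily_id %in% members, , drop = FALSE]
    ks <- table(factor(in_grp$term_id, levels = terms))
    K <- as.integer(Ks[terms])
    k <- as.integer(ks)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    res[[grp]] <- data.frame(term_id = terms, group = grp, k = k, n = n,
                             K = K, N = N, p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (is.null(m)) m <- length(terms)   # corrected over terms, as published
  out$m <- m
  out$significant <- out$p < alpha / max(m, 1)
  attr(out, "skipped_terms") <- skipped
  out
}

#' Percentile curves of age distributions
#'
#' Age quantiles at the integer percentiles 0..100 (linear interpolation),
#' the representation used for the published age-distribution plots.
#'
#' @param ages numeric vector of ages.
#' @param labels group label per age.
#' @return data.frame (group, percentile, age).
#' @export
percentile_curves <- function(ages, labels) {
  stopifnot(length(ages) == length(labels))
  out <- lapply(split(ages, labels), function(a)
    data.frame(percentile = 0:100,
               age = unname(stats::quantile(a, probs = 0:100 / 100))))
  out <- do.call(rbind, Map(function(g, df)
    cbind(group = g, df, stringsAsFactors = FALSE), names(out), out))
  rownames(out) <- NULL
  out
}

#' Structure-versus-function age contrast
#'
#' Asks whether the age difference between parallel and antiparallel sheet
#' superfamilies is driven by structure or merely reflects function. Three
#' Mann-Whitney contrasts are reported: (i) by structural label (parallel vs
#' antiparallel superfamilies); (ii) by functional annotation (superfamilies
#' carrying any term enriched in the parallel set vs any term enriched in the
#' antiparallel set, overlaps allowed and counted); (iii) as (ii) but
#' restricted to superfamilies annotated on exactly one side.
#'
#' @param ages named numeric vector, superfamily -> age.
#' @param strand_labels named character vector, superfamily ->
#'   parallel/antiparallel/mixed/not_applicable.
#' @param annotations data.frame (superfamily_id, term_id).
#' @param alpha enrichment significance level (Bonferroni-corrected).
#' @return List with the three `mann_whitney_ties` results, the enriched term
#'   lists, overlap count, empty-side flags and percentile curves per
#'   structural label.
#' @export
structure_vs_function_contrast <- function(ages, strand_labels, annotations,
                                           alpha = 0.05) {
  sf <- names(ages)
  lab <- strand_labels[sf]
  par_sf <- sf[!is.na(lab) & lab == "parallel"]
  anti_sf <- sf[!is.na(lab) & lab == "antiparallel"]
  structural <- if (length(par_sf) && length(anti_sf))
    mann_whitney_ties(ages[par_sf], ages[anti_sf]) else NULL

  grp <- rbind(data.frame(superfamily_id = par_sf, group = "parallel"),
               data.frame(superfamily_id = anti_sf, group = "antiparallel"))
  ann <- annotations[annotations$superfamily_id %in% sf, , drop = FALSE]
  enr <- hypergeometric_enrichment(ann, grp, universe = sf, alpha = alpha)
  par_terms <- enr$term_id[enr$group == "parallel" & enr$significant]
  anti_terms <- enr$term_id[enr$group == "antiparallel" & enr$significant]

  with_terms <- function(terms)
    unique(ann$superfamily_id[ann$term_id %in% terms])
  fun_par <- with_terms(par_terms)
  fun_anti <- with_terms(anti_terms)
  overlap <- intersect(fun_par, fun_anti)
  empty_side <- c(parallel = length(par_terms) == 0,
                  antiparallel = length(anti_terms) == 0)
  functional <- if (length(fun_par) && length(fun_anti))
    mann_whitney_ties(ages[fun_par], ages[fun_anti]) else NULL
  uniq_par <- setdiff(fun_par, fun_anti)
  uniq_anti <- setdiff(fun_anti, fun_par)
  unique_annotation <- if (length(uniq_par) && length(uniq_anti))
    mann_whitney_ties(ages[uniq_par], ages[uniq_anti]) else NULL

  keep <- !is.na(lab) & lab %in% c("parallel", "antiparallel")
  if (!any(keep))
    return(list(structural = NULL, functional = functional,
                unique_annotation = unique_annotation,
                parallel_terms = par_terms,
                antiparallel_terms = anti_terms,
                overlap_count = length(overlap), empty_side = empty_side,
                unique_empty = c(parallel = length(uniq_par) == 0,
                                 antiparallel = length(uniq_anti) == 0),
                curves = NULL))
  list(structural = structural, functional = functional,
       unique_annotation = unique_annotation,
       parallel_terms = par_terms, antiparallel_terms = anti_terms,
       overlap_count = length(overlap), empty_side = empty_side,
       unique_empty = c(parallel = length(uniq_par) == 0,
                        antiparallel = length(uniq_anti) == 0),
       curves = percentile_curves(ages[keep], lab[keep]))
}
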