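#' Genome metadata table
#'
#' Constructs the genome metadata table used throughout the pipeline: one row
#' per completely sequenced genome with its superkingdom and the removal flags
#' applied before tree building (pathogen annotation, provisional
#' \emph{candidatus} status, manual removal after inspecting tree resolution).
#'
#' @param genome_id character vector of unique genome identifiers.
#' @param superkingdom character vector, one of `"Archaea"`, `"Bacteria"`,
#'   `"Eukarya"` per genome.
#' @param multicellular,pathogen,candidatus,manual_remove logical vectors
#'   (recycled if length 1).
#' @return A `data.frame` with one row per genome.
#' @export
genome_table <- function(genome_id, superkingdom,
                         multicellular = FALSE, pathogen = FALSE,
                         candidatus = FALSE, manual_remove = FALSE) {
  genome_id <- as.character(genome_id)
  if (anyDuplicated(genome_id))
    stop("duplicate genome_id: ",
         paste(unique(genome_id[duplicated(genome_id)]), collapse = ", "))
  superkingdom <- match.arg(as.character(superkingdom),
                            c("Archaea", "Bacteria", "Eukarya"),
                            several.ok = TRUE)
  if (length(superkingdom) == 1L)
    superkingdom <- rep(superkingdom, length(genome_id))
  stopifnot(length(superkingdom) == length(genome_id))
  data.frame(genome_id = genome_id,
             superkingdom = superkingdom,
             multicellular = rep_len(as.logical(multicellular), length(genome_id)),
             pathogen = rep_len(as.logical(pathogen), length(genome_id)),
             candidatus = rep_len(as.logical(candidatus), length(genome_id)),
             manual_remove = rep_len(as.logical(manual_remove), length(genome_id)),
             stringsAsFactors = FALSE)
}

#' Filter genomes by removal flags
#'
#' Drops genomes carrying any of the enabled removal flags. A genome flagged
#' in several categories is removed once (set-union semantics); row order of
#' the survivors is preserved.
#'
#' @param genomes data.frame as returned by [genome_table()].
#' @param drop_pathogen,drop_candidatus,drop_manual logical; which flag
#'   categories to apply.
#' @return The surviving rows of `genomes`.
#' @export
filter_genomes <- function(genomes, drop_pathogen = TRUE,
                           drop_candidatus = TRUE, drop_manual = TRUE) {
  stopifnot(is.data.frame(genomes), nrow(genomes) > 0)
  drop <- rep(FALSE, nrow(genomes))
  if (drop_pathogen)   drop <- drop | genomes$pathogen
  if (drop_candidatus) drop <- drop | genomes$candidatus
  if (drop_manual)     drop <- drop | genomes$manual_remove
  out <- genomes[!drop, , drop = FALSE]
  if (nrow(out) == 0L) warning("all genomes removed by filtering")
  rownames(out) <- NULL
  out
}

#' Build a binary occurrence matrix from per-genome assignments
#'
#' Collapses (genome, unit) assignment pairs to a binary presence/absence
#' matrix of structural units (superfamilies or folds) by genomes. Duplicate
#' assignments collapse to a single presence.
#'
#' @param assignments data.frame with columns `genome_id` and `unit_id` (one
#'   row per predicted domain assignment).
#' @param genomes data.frame of genome metadata; every `genome_id` in
#'   `assignments` must appear here. Its genomes define the matrix columns.
#' @param unit_ids optional character vector fixing the row universe (units
#'   never assigned get all-zero rows).
#' @param level `"superfamily"` or `"fold"`.
#' @return An `occurrence_matrix`: integer 0/1 matrix with units as rows and
#'   genomes as columns, with attributes `level` and `genomes` (the metadata).
#' @export
build_matrix <- function(assignments, genomes, unit_ids = NULL,
                         level = c("superfamily", "fold")) {
  level <- match.arg(level)
  stopifnot(all(c("genome_id", "unit_id") %in% names(assignments)))
  gid <- as.character(genomes$genome_id)
  unknown <- setdiff(unique(as.character(assignments$genome_id)), gid)
  if (length(unknown))
    stop("assignment refers to unknown genome_id: ",
         paste(unknown, collapse = ", "))
  if (is.null(unit_ids)) unit_ids <- sort(unique(as.character(assignments$unit_id)))
  m <- matrix(0L, nrow = length(unit_ids), ncol = length(gid),
              dimnames = list(unit_ids, gid))
  if (nrow(assignments))
    m[cbind(as.character(assignments$unit_id),
            as.character(assignments$genome_id))] <- 1L
  occurrence_matrix(m, level = level, genomes = genomes)
}

#' Construct an occurrence matrix object from a 0/1 matrix
#'
#' @param m integer/numeric matrix with unit rownames and genome colnames,
#'   values 0/1.
#' @param level `"superfamily"` or `"fold"`.
#' @param genomes optional genome metadata data.frame covering all columns.
#' @return The matrix with class `occurrence_matrix`.
#' @export
occurrence_matrix <- function(m, level = c("superfamily", "fold"),
                              genomes = NULL) {
  level <- match.arg(level)
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1))) stop("occurrence values must be 0/1")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("unit rownames and genome colnames are required")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("duplicate unit or genome identifiers")
  if (!is.null(genomes)) {
    missing <- setdiff(colnames(m), genomes$genome_id)
    if (length(missing))
      stop("genomes without metadata: ", paste(missing, collapse = ", "))
  }
  storage.mode(m) <- "integer"
  structure(m, level = level, genomes = genomes,
            class = c("occurrence_matrix", "matrix", "array"))
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf("occurrence_matrix: %d %s units x %d genomes (%.1f%% present)\n",
              nrow(x), attr(x, "level"), ncol(x), 100 * mean(x)))
  invisible(x)
}

#' Collapse a superfamily matrix to fold level
#'
#' A fold is present on a genome iff any of its member superfamilies is.
#'
#' @param m superfamily-level `occurrence_matrix`.
#' @param sf_to_fold named character vector mapping superfamily id to fold id;
#'   every unit of `m` must be mapped.
#' @return Fold-level `occurrence_matrix`.
#' @export
collapse_to_fold <- function(m, sf_to_fold) {
  if (attr(m, "level") != "superfamily")
    stop("collapse_to_fold expects a superfamily-level matrix")
  unmapped <- setdiff(rownames(m), names(sf_to_fold))
  if (length(unmapped))
    stop("unmapped superfamilies: ", paste(unmapped, collapse = ", "))
  fold <- sf_to_fold[rownames(m)]
  folded <- rowsum(unclass(m), group = fold)
  folded <- (folded > 0) + 0L
  folded <- folded[sort(rownames(folded)), , drop = FALSE]
  occurrence_matrix(folded, level = "fold", genomes = attr(m, "genomes"))
}

#' Contingency counts between two genomes
#'
#' Counts units present on both genomes (`a`), only on the first (`b`) and
#' only on the second (`c`). Units absent from both are ignored, matching the
#' presence-only presentation of the distance metrics.
#'
#' @param m `occurrence_matrix`.
#' @param gi,gj genome identifiers (columns of `m`).
#' @return Named integer vector `c(a=,b=,c=)`.
#' @export
contingency <- function(m, gi, gj) {
  for (g in c(gi, gj))
    if (!g %in% colnames(m)) stop("unknown genome id: ", g)
  x <- m[, gi]; y <- m[, gj]
  c(a = sum(x == 1L & y == 1L),
    b = sum(x == 1L & y == 0L),
    c = sum(x == 0L & y == 1L))
}

#' Jaccard dissimilarity from contingency counts
#'
#' `(b + c) / (a + b + c)`: the fraction of the union of the two genomes'
#' unit repertoires not shared by both.
#'
#' @param cc named vector with components `a`, `b`, `c` (see [contingency()]).
#' @return Dissimilarity in `[0, 1]`.
#' @export
jaccard_distance <- function(cc) {
  a <- cc[["a"]]; b <- cc[["b"]]; cval <- cc[["c"]]
  if (a + b + cval == 0) stop("no shared universe: all counts zero")
  (b + cval) / (a + b + cval)
}

#' Bray-Curtis dissimilarity from contingency counts
#'
#' Presence/absence Bray-Curtis, `(b + c) / (2a + b + c)`; shared units count
#' twice in the denominator, so it is never larger than the Jaccard
#' dissimilarity on the same counts.
#'
#' @inheritParams jaccard_distance
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis_distance <- function(cc) {
  a <- cc[["a"]]; b <- cc[["b"]]; cval <- cc[["c"]]
  if (2 * a + b + cval == 0) stop("no shared universe: all counts zero")
  (b + cval) / (2 * a + b + cval)
}

#' All-pairs dissimilarity matrix between genomes
#'
#' @param m `occurrence_matrix` with at least 3 genomes.
#' @param metric `"jaccard"` or `"braycurtis"`.
#' @return Symmetric zero-diagonal matrix of dissimilarities with attribute
#'   `metric`.
#' @export
distance_matrix <- function(m, metric = c("jaccard", "braycurtis")) {
  metric <- match.arg(metric)
  if (ncol(m) < 3) stop("need at least 3 genomes")
  x <- unclass(m)
  a <- crossprod(x)                       # shared presences
  tot <- colSums(x)
  b <- outer(tot, rep(1, length(tot))) - a
  cc <- t(b)
  union <- a + b + cc
  if (any(union == 0 & upper.tri(union))) {
    bad <- which(union == 0 & upper.tri(union), arr.ind = TRUE)[1, ]
    stop(sprintf("empty union between genomes '%s' and '%s'",
                 colnames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  d <- if (metric == "jaccard") (b + cc) / union else (b + cc) / (a + union)
  diag(d) <- 0
  dimnames(d) <- list(colnames(m), colnames(m))
  structure(d, metric = metric)
}

#' Read / write occurrence matrices as TSV
#'
#' Matrix files are unit rows by genome columns: first row genome ids, first
#' column unit ids, values 0/1, tab-separated, no quoting.
#'
#' @param path file path.
#' @param level matrix level for [occurrence_matrix()].
#' @return `read_occurrence`: an `occurrence_matrix`.
#' @export
read_occurrence <- function(path, level = c("superfamily", "fold")) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  occurrence_matrix(as.matrix(df), level = match.arg(level))
}

#' @param m `occurrence_matrix` to write.
#' @rdname read_occurrence
#' @export
write_occurrence <- function(m, path) {
  df <- data.frame(unit_id = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
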