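#' Read C-alpha coordinates from a PDB file
#'
#' Parses ATOM records via `bio3d`, keeping CA atoms of the first chain and
#' the first alternate location only.
#'
#' @param path PDB file.
#' @return List with `coords` (n x 3 matrix), `sequence` (one-letter string)
#'   and `resno` (residue numbers).
#' @export
read_ca_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
  if (!nrow(atoms)) stop("no CA ATOM records in ", path)
  atoms <- atoms[atoms$chain == atoms$chain[1], , drop = FALSE]
  atoms <- atoms[is.na(atoms$alt) | atoms$alt == atoms$alt[!is.na(atoms$alt)][1] |
                   !duplicated(atoms$resno), , drop = FALSE]
  atoms <- atoms[!duplicated(atoms$resno), , drop = FALSE]
  list(coords = as.matrix(atoms[, c("x", "y", "z")]),
       sequence = paste(bio3d::aa321(atoms$resid), collapse = ""),
       resno = atoms$resno)
}

#' Write a C-alpha trace as a PDB file
#'
#' Minimal single-chain CA-only PDB writer for synthetic domains.
#'
#' @param domain a `domain_structure`.
#' @param path output file.
#' @export
write_ca_pdb <- function(domain, path) {
  aa3 <- bio3d::aa123(strsplit(domain$sequence, "")[[1]])
  xyz <- domain$ca_coords
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(xyz)), aa3, seq_len(nrow(xyz)),
    xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read / write per-residue annotation tables
#'
#' The annotation TSV is the boundary to DSSP/JOY/PROMOTIF-style tools:
#' columns `residue_index`, `aa`, `ss_element`, `strand_id`,
#' `relative_exposure`, `disulphide_partner` (empty for none).
#'
#' @param path TSV file.
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue_index", "aa", "ss_element", "strand_id",
            "relative_exposure", "disulphide_partner")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("annotation file lacks columns: ",
                            paste(missing, collapse = ", "))
  df$strand_id[df$strand_id %in% c("", "NA")] <- NA
  df$disulphide_partner <- suppressWarnings(as.integer(df$disulphide_partner))
  df
}

#' @param annotations data.frame to write.
#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write sheet-topology tables
#'
#' Strand rows carry `sheet_id`, `strand_id`, `sequence_order`,
#' `spatial_position`; pairing rows carry `strand_a`, `strand_b`,
#' `orientation`. The two tables live in one TSV with a `record` column
#' (`strand` / `pairing`).
#'
#' @param path TSV file.
#' @return List with data.frames `strands` and `pairings`.
#' @export
read_topology <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  strands <- df[df$record == "strand",
                c("sheet_id", "strand_id", "sequence_order",
                  "spatial_position")]
  pairings <- df[df$record == "pairing",
                 c("sheet_id", "strand_a", "strand_b", "orientation")]
  strands$sequence_order <- as.integer(strands$sequence_order)
  strands$spatial_position <- as.integer(strands$spatial_position)
  rownames(strands) <- rownames(pairings) <- NULL
  list(strands = strands, pairings = pairings)
}

#' @param topology list with `strands` and `pairings` to write.
#' @rdname read_topology
#' @export
write_topology <- function(topology, path) {
  s <- topology$strands
  p <- topology$pairings
  a <- data.frame(record = "strand", sheet_id = s$sheet_id,
                  strand_id = s$strand_id, sequence_order = s$sequence_order,
                  spatial_position = s$spatial_position,
                  strand_a = "", strand_b = "", orientation = "")
  b <- if (nrow(p)) data.frame(record = "pairing", sheet_id = p$sheet_id,
                               strand_id = "", sequence_order = "",
                               spatial_position = "",
                               strand_a = p$strand_a, strand_b = p$strand_b,
                               orientation = p$orientation) else NULL
  utils::write.table(rbind(a, b), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write genome metadata tables
#'
#' @param path TSV with the [genome_table()] columns.
#' @return data.frame of genome metadata.
#' @export
read_genomes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("multicellular", "pathogen", "candidatus", "manual_remove"))
    df[[col]] <- as.logical(df[[col]])
  genome_table(df$genome_id, df$superkingdom, df$multicellular,
               df$pathogen, df$candidatus, df$manual_remove)
}

#' @param genomes data.frame to write.
#' @rdname read_genomes
#' @export
write_genomes <- function(genomes, path) {
  utils::write.table(genomes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
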