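#' FNV-1a hash of a configuration object (hex string)
#' @keywords internal
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a table in the pipeline's TSV dialect
#'
#' Tab-delimited UTF-8; one comment line carrying the package version and
#' config hash, then a single '#'-prefixed header line; missing values as
#' `"NA"`.
#'
#' @param df Data frame.
#' @param path Output path (written atomically via a temp file).
#' @param hash Config hash string to embed (optional).
#' @export
write_tsv <- function(df, path, hash = "none") {
  tmp <- tempfile(tmpdir = dirname(path))
  con <- file(tmp, open = "w", encoding = "UTF-8")
  version <- as.character(utils::packageVersion("disordAS"))
  writeLines(paste0("# disordAS ", version, " config=", hash), con)
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a table written by [write_tsv()]
#'
#' @param path Input path.
#' @return Data frame with the original column names.
#' @export
read_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr_idx <- max(which(startsWith(lines, "#")))
  cols <- strsplit(sub("^#", "", lines[hdr_idx]), "\t", fixed = TRUE)[[1L]]
  body <- lines[-seq_len(hdr_idx)]
  if (length(body) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character()), length(cols)),
                                         cols), stringsAsFactors = FALSE)
    return(out)
  }
  utils::read.table(text = body, sep = "\t", quote = "", na.strings = "NA",
                    col.names = cols, stringsAsFactors = FALSE)
}

#' Write alignments and disorder tracks as FASTA
#'
#' One alignment FASTA (gapped rows, ids as in `species_ids`) and one
#' track FASTA (same ids, 'D'/'O' characters, ungapped lengths).
#'
#' @param groups Named list of [aligned_group()] objects.
#' @param aln_path,tracks_path Output FASTA paths.
#' @export
write_alignment_fasta <- function(groups, aln_path, tracks_path) {
  ids <- unlist(lapply(groups, function(g)
    paste0(g$group_id, "/", g$species_ids)))
  seqs <- unlist(lapply(groups, function(g)
    apply(g$aln, 1L, paste, collapse = "")))
  aln <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
  Biostrings::writeXStringSet(aln, aln_path)
  trk <- unlist(lapply(groups, function(g)
    vapply(g$tracks, paste, character(1), collapse = "")))
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(trk, ids)), tracks_path)
  invisible(aln_path)
}

#' Read alignments and disorder tracks from FASTA
#'
#' Inverse of [write_alignment_fasta()]. Sequence ids are
#' `"<group>/<species_id>"`; the reference row carries the `"HUMAN|"`
#' species prefix.
#'
#' @param aln_path,tracks_path FASTA paths.
#' @return Named list of [aligned_group()] objects.
#' @export
read_alignment_groups <- function(aln_path, tracks_path) {
  aln <- Biostrings::readAAStringSet(aln_path)
  trk <- Biostrings::readBStringSet(tracks_path)
  if (!identical(names(aln), names(trk)))
    stop("alignment and track FASTA ids do not match")
  grp_of <- sub("/.*$", "", names(aln))
  sp_of <- sub("^[^/]*/", "", names(aln))
  out <- lapply(split(seq_along(aln), factor(grp_of, unique(grp_of))),
                function(idx) {
    rows <- as.character(aln[idx])
    tracks <- lapply(as.character(trk[idx]),
                     function(s) strsplit(s, "")[[1L]])
    ref <- which(startsWith(sp_of[idx], "HUMAN|"))
    if (length(ref) != 1L)
      stop("group '", grp_of[idx[1L]],
           "' must contain exactly one HUMAN| reference row")
    aligned_group(unname(rows), unname(tracks),
                  group_id = grp_of[idx[1L]],
                  species_ids = sp_of[idx], reference_index = ref)
  })
  out
}

#' Write transcript sequences as FASTA
#' @param transcripts Named character vector of DNA sequences.
#' @param path Output path.
#' @export
write_transcripts_fasta <- function(transcripts, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(transcripts), path)
  invisible(path)
}

#' Read transcript sequences from FASTA
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_transcripts_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a simulated dataset to a directory in the pipeline's formats
#'
#' Emits alignment/track FASTA, exon/feature/mutation/counts TSVs,
#' transcript FASTA, and one ground-truth TSV per entity class.
#'
#' @param sim A `disord_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  h <- config_hash(sim$config)
  p <- function(f) file.path(dir, f)
  write_alignment_fasta(sim$groups, p("alignments.fasta"),
                        p("disorder_tracks.fasta"))
  write_tsv(sim$exons, p("exons.tsv"), h)
  write_tsv(sim$features, p("features.tsv"), h)
  write_tsv(sim$mutations, p("mutations.tsv"), h)
  write_tsv(sim$expression$counts, p("counts.tsv"), h)
  write_tsv(sim$expression$totals, p("totals.tsv"), h)
  write_transcripts_fasta(sim$expression$transcripts, p("transcripts.fasta"))
  write_tsv(data.frame(transcript_id = names(sim$expression$tx2gene),
                       gene_id = unname(sim$expression$tx2gene),
                       stringsAsFactors = FALSE), p("tx2gene.tsv"), h)
  write_tsv(sim$annotations, p("go_annotations.tsv"), h)
  write_tsv(sim$bona_fide, p("bona_fide.tsv"), h)
  write_tsv(data.frame(key = "rest_exome_nt", value = sim$rest_exome_nt),
            p("scalars.tsv"), h)
  write_tsv(sim$truth$residues, p("ground_truth_residues.tsv"), h)
  write_tsv(sim$truth$mutation_sites, p("ground_truth_mutations.tsv"), h)
  write_tsv(sim$truth$genes, p("ground_truth_genes.tsv"), h)
  invisible(dir)
}

#' Read a simulated dataset back from a directory
#'
#' @param dir Directory written by [write_sim_dataset()].
#' @return List with the same data slots as a `disord_sim` (without plan
#'   or config).
#' @export
read_sim_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  scal <- read_tsv(p("scalars.tsv"))
  tx2g <- read_tsv(p("tx2gene.tsv"))
  list(groups = read_alignment_groups(p("alignments.fasta"),
                                      p("disorder_tracks.fasta")),
       exons = read_tsv(p("exons.tsv")),
       features = read_tsv(p("features.tsv")),
       mutations = read_tsv(p("mutations.tsv")),
       rest_exome_nt = scal$value[scal$key == "rest_exome_nt"],
       expression = list(
         transcripts = read_transcripts_fasta(p("transcripts.fasta")),
         tx2gene = stats::setNames(tx2g$gene_id, tx2g$transcript_id),
         counts = read_tsv(p("counts.tsv")),
         totals = read_tsv(p("totals.tsv"))),
       annotations = read_tsv(p("go_annotations.tsv")),
       bona_fide = read_tsv(p("bona_fide.tsv")))
}
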