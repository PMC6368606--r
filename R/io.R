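# Readers and writers for the pipeline's plain-text exchange formats:
# per-metagenome protein FASTA (headers "<metagenome>|<protein_id>"),
# tab-separated geochemistry / KO / category / MAG tables, newick trees,
# and the synthetic generator's ground-truth JSON.

#' Read per-metagenome protein FASTA files
#'
#' Headers follow the convention `<metagenome>|<protein_id>`; a header
#' without a `|` is assigned to the file's basename (without extension).
#'
#' @param files Character vector of FASTA file paths.
#' @return A protein record table (see [protein_records()]).
#' @export
read_protein_fasta <- function(files) {
  recs <- lapply(files, function(f) {
    aa <- Biostrings::readAAStringSet(f)
    hdr <- names(aa)
    has_mg <- grepl("|", hdr, fixed = TRUE)
    mg <- ifelse(has_mg, sub("\\|.*$", "", hdr),
                 sub("\\.[^.]*$", "", basename(f)))
    pid <- ifelse(has_mg, sub("^[^|]*\\|", "", hdr), hdr)
    data.frame(protein_id = pid, metagenome_id = mg,
               seq = as.character(aa))
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  protein_records(out$protein_id, out$metagenome_id, out$seq)
}

#' Write per-metagenome protein FASTA files
#'
#' @param records Protein record table.
#' @param dir Output directory (created if needed); one
#'   `<metagenome>.faa` per metagenome.
#' @return Invisibly, the written file paths.
#' @export
write_protein_fasta <- function(records, dir) {
  validate_protein_records(records)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(split(records, records$metagenome_id), function(df) {
    aa <- Biostrings::AAStringSet(df$seq)
    names(aa) <- paste0(df$metagenome_id, "|", df$protein_id)
    path <- file.path(dir, paste0(df$metagenome_id[1L], ".faa"))
    Biostrings::writeXStringSet(aa, path)
    path
  }, character(1))
  invisible(unname(paths))
}

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a KO abundance table from TSV
#'
#' Expects metagenomes in rows (first column `metagenome_id`) and KO
#' identifiers as the remaining column names.
#'
#' @param path TSV file path.
#' @return Numeric matrix, metagenomes x KOs.
#' @export
read_ko_table <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "numeric"
  m
}

#' Write a KO abundance (or family abundance) matrix to TSV
#'
#' @param table Matrix with metagenome row names.
#' @param path Output path.
#' @export
write_ko_table <- function(table, path) {
  df <- data.frame(metagenome_id = rownames(table), table,
                   check.names = FALSE)
  .write_tsv(df, path)
}

#' Write a full synthetic study to a directory
#'
#' Emits per-spring protein FASTA files (under `proteins/`), the
#' geochemistry, KO, KO-category and MAG tables as TSV, the family truth
#' table as TSV, the tree as newick, the tagged tip list as plain text,
#' and the planted truth record as JSON.
#'
#' @param study A `synthetic_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_protein_fasta(study$proteins, file.path(dir, "proteins"))
  .write_tsv(study$geochem, file.path(dir, "geochem.tsv"))
  write_ko_table(study$ko_table, file.path(dir, "ko_table.tsv"))
  .write_tsv(study$ko_categories, file.path(dir, "ko_categories.tsv"))
  .write_tsv(study$mag_table, file.path(dir, "mag_table.tsv"))
  write_ko_table(study$truth_family_table, file.path(dir, "truth_family_table.tsv"))
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  writeLines(study$tagged_tips, file.path(dir, "tagged_tips.txt"))
  truth <- study$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a geochemistry table from TSV
#'
#' @param path TSV with columns `spring_id`, `sulfate`, `chloride` (plus
#'   optional `pH`, `temperature`).
#' @return A validated geochemistry table with `log_ratio` (see
#'   [geochem_records()]).
#' @export
read_geochem <- function(path) geochem_records(.read_tsv(path))

#' Read a MAG summary table from TSV
#'
#' @param path TSV with columns `bin_id`, `total_length`, `mapped_reads`,
#'   `completeness`, `contamination`.
#' @return A validated MAG table.
#' @export
read_mag_table <- function(path) .check_mag_table(.read_tsv(path))

#' Read a KO category map from TSV
#'
#' @param path TSV with columns `ko`, `category`, `subcategory`.
#' @return The category map data frame.
#' @export
read_ko_categories <- function(path) {
  df <- .read_tsv(path)
  stopifnot(all(c("ko", "category", "subcategory") %in% names(df)))
  df
}
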