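#' Read a FASTA file into a validated named character vector
#'
#' Sequences are uppercased and validated against the requested alphabet:
#' the 20 standard amino acids plus \code{X} for proteins, \code{ACGTN} for
#' DNA. Gap characters (\code{-}) are accepted only when \code{aligned =
#' TRUE}. Record ids (the first whitespace-delimited token of each header)
#' must be unique and non-empty.
#'
#' @param path path to a FASTA file.
#' @param alphabet \code{"protein"} or \code{"dna"}.
#' @param aligned logical; permit gap characters (aligned FASTA input).
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna"), aligned = FALSE) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(!nzchar(ids)))
    stop("empty sequence id at record ", which(!nzchar(ids))[1], " in ", path)
  if (anyDuplicated(ids))
    stop("duplicate sequence id '", ids[duplicated(ids)][1], "' in ", path)
  ok <- .alphabet_chars(alphabet, aligned)
  for (i in seq_along(seqs)) {
    bad <- regexpr(sprintf("[^%s]", ok), seqs[[i]])
    if (bad > 0L)
      stop("illegal residue '", substr(seqs[[i]], bad, bad), "' at position ",
           bad, " in record '", ids[i], "' of ", path)
  }
  seqs
}

.alphabet_chars <- function(alphabet, aligned) {
  base <- if (alphabet == "protein") "ACDEFGHIKLMNPQRSTVWYX" else "ACGTN"
  if (aligned) paste0(base, "-") else base
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses \code{gene} features of a canonical GFF3 file into a gene-model
#' table. Coordinates are kept 1-based inclusive exactly as stored; strand
#' is carried but never used to flip coordinates. Malformed rows are
#' rejected with their line number rather than repaired.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns \code{gene_id}, \code{chromosome},
#'   \code{start}, \code{end}, \code{strand}, \code{protein_id},
#'   \code{cds_id}.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop("malformed GFF3 row (", length(f), " fields) at line ", ln,
           " of ", path)
    if (f[3] != "gene") next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end))
      stop("non-numeric coordinate at line ", ln, " of ", path)
    if (start > end)
      stop("start > end (", start, " > ", end, ") at line ", ln, " of ", path)
    if (!nzchar(f[1]))
      stop("empty chromosome field at line ", ln, " of ", path)
    attrs <- .parse_gff_attributes(f[9])
    if (is.na(attrs["ID"]) || !nzchar(attrs["ID"]))
      stop("gene feature missing ID attribute at line ", ln, " of ", path)
    id <- unname(attrs["ID"])
    out[[length(out) + 1L]] <- data.frame(
      gene_id = id, chromosome = f[1], start = start, end = end,
      strand = if (f[7] %in% c("+", "-")) f[7] else "unknown",
      protein_id = unname(ifelse(is.na(attrs["protein_id"]), id,
                                 attrs["protein_id"])),
      cds_id = unname(ifelse(is.na(attrs["cds_id"]), id, attrs["cds_id"])),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_id = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      strand = character(), protein_id = character(),
                      cds_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

.parse_gff_attributes <- function(s) {
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  kv <- kv[vapply(kv, length, 1L) == 2L]
  vals <- vapply(kv, function(x) utils::URLdecode(trimws(x[2])), "")
  names(vals) <- vapply(kv, function(x) trimws(x[1]), "")
  vals
}

#' Write gene models to a GFF3 file
#'
#' @param genes gene-model data.frame as returned by [read_gff3()].
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @export
write_gff3 <- function(genes, path, source = "drebfam") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attrs <- paste0("ID=", g$gene_id,
                    ";protein_id=", g$protein_id,
                    ";cds_id=", g$cds_id)
    writeLines(paste(g$chromosome, source, "gene", g$start, g$end, ".",
                     if (g$strand %in% c("+", "-")) g$strand else ".",
                     ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Read an HMMER per-domain hit table (domtblout)
#'
#' One row per domain hit; envelope coordinates are taken as the domain
#' extent. Query names (or accessions) containing \code{AP2}/\code{PF00847}
#' map to domain \code{AP2}, \code{B3}/\code{PF02362} to \code{B3}, and
#' anything else to \code{other}.
#'
#' @param path path to a whitespace-delimited HMMER domtblout file.
#' @return data.frame with columns \code{protein_id}, \code{domain_name},
#'   \code{start}, \code{end}, \code{score}, \code{evalue}.
#' @export
read_domtblout <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    f <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(f) < 22L)
      stop("malformed domtblout row (", length(f), " fields, need >= 22) ",
           "at line ", ln, " of ", path)
    start <- suppressWarnings(as.integer(f[20]))
    end <- suppressWarnings(as.integer(f[21]))
    if (is.na(start) || is.na(end) || start < 1L || start > end)
      stop("bad envelope coordinates at line ", ln, " of ", path)
    out[[length(out) + 1L]] <- data.frame(
      protein_id = f[1],
      domain_name = .domain_label(f[4], f[5]),
      start = start, end = end,
      score = suppressWarnings(as.numeric(f[14])),
      evalue = suppressWarnings(as.numeric(f[13])),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(protein_id = character(), domain_name = character(),
                      start = integer(), end = integer(), score = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

.domain_label <- function(query, accession) {
  key <- toupper(paste(query, accession))
  if (grepl("AP2|PF00847", key)) "AP2"
  else if (grepl("\\bB3\\b|PF02362", key)) "B3"
  else "other"
}

#' Write a domain-hit table in domtblout layout
#'
#' Emits the 22 standard columns (unused ones as placeholders) so the file
#' round-trips through [read_domtblout()].
#'
#' @param hits domain-hit data.frame.
#' @param path output path.
#' @export
write_domtblout <- function(hits, path) {
  acc <- ifelse(hits$domain_name == "AP2", "PF00847.21",
                ifelse(hits$domain_name == "B3", "PF02362.23", "-"))
  rows <- sprintf(
    "%s - 500 %s %s 60 1e-20 %.1f 0.1 1 1 1e-20 %g %.1f 0.1 1 60 %d %d %d %d 0.95 -",
    hits$protein_id, hits$domain_name, acc,
    ifelse(is.na(hits$score), 50, hits$score),
    ifelse(is.na(hits$evalue), 1e-20, hits$evalue),
    ifelse(is.na(hits$score), 50, hits$score),
    hits$start, hits$end, hits$start, hits$end)
  writeLines(c("# drebfam domain hits", rows), path)
  invisible(path)
}

#' Serialise a phylogenetic tree as newick
#'
#' @param tree an \pkg{ape} \code{phylo} object with uniquely labelled
#'   leaves; node labels (bootstrap supports) are written when present.
#' @param path optional output path; when \code{NULL} the newick string is
#'   returned.
#' @return the newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (any(!nzchar(tree$tip.label)) || anyNA(tree$tip.label))
    stop("all leaves must carry non-empty labels")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf label '", tree$tip.label[duplicated(tree$tip.label)][1], "'")
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Write an analysis report as JSON or TSV
#'
#' @param results a named list (JSON) or data.frame (TSV).
#' @param path output path.
#' @param format \code{"json"} or \code{"tsv"}.
#' @export
write_report <- function(results, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
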