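# internal helpers shared across modules

# run code with a local RNG state: deterministic per seed, and the caller's
# random stream is left untouched
.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# union-find over n items; returns component id per item (1..k, stable)
.components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs)) for (p in pairs) {
    a <- find(p[1]); b <- find(p[2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

.AA_LETTERS <- c("A","R","N","D","C","E","Q","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# standard genetic code keyed by codon
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

.GENETIC_CODE <- NULL
.genetic_code <- function() {
  if (is.null(.GENETIC_CODE))
    utils::assignInMyNamespace(".GENETIC_CODE", .codon_table())
  .GENETIC_CODE
}

.translate_codon <- function(codon) unname(.genetic_code()[codon])

.is_stop <- function(codon) .translate_codon(codon) == "*"

.SENSE_CODONS <- NULL
.sense_codons <- function() {
  if (is.null(.SENSE_CODONS)) {
    gc <- .genetic_code()
    utils::assignInMyNamespace(".SENSE_CODONS", names(gc)[gc != "*"])
  }
  .SENSE_CODONS
}

.split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length ", n, " is not a multiple of 3")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

.translate_cds <- function(cds) {
  paste(vapply(.split_codons(cds), function(c) {
    aa <- .translate_codon(c)
    if (is.na(aa)) "X" else aa
  }, ""), collapse = "")
}

# chromosome label -> list(number, haplotype letter); "Chr2D" -> 2, "D"
.parse_chromosome <- function(chrom) {
  m <- regmatches(chrom, regexec("^(?:[Cc]hr)?0*([0-9]+)([A-Za-z]?)$", chrom))[[1]]
  if (length(m) < 2L || !nzchar(m[2]))
    return(list(number = NA_integer_, haplotype = NA_character_))
  list(number = as.integer(m[2]),
       haplotype = if (nzchar(m[3])) toupper(m[3]) else NA_character_)
}

# global pairwise protein identity (fraction, 0..1) via Needleman-Wunsch
.protein_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  Biostrings::pid(aln, type = "PID1") / 100
}
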