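# IUPAC nucleotide sets; gaps/missing handled separately.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
MISSING_CHARS <- c("-", "N", "?")

#' Read an aligned FASTA file
#'
#' @param path FASTA file.
#' @param gene gene name attached to the alignment.
#' @return object of class `alignment`: list with `gene`, `seqs` (named
#'   uppercase character vector, one string per specimen) and `length`.
#' @export
read_alignment <- function(path, gene = NA_character_) {
  dna <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(dna), paste, "", collapse = ""))
  alignment(seqs, gene = gene)
}

#' Build an alignment object from named sequences
#'
#' @param seqs named character vector of equal-length IUPAC DNA strings
#'   (gaps `-`, missing `N`/`?` allowed).
#' @param gene gene name.
#' @return `alignment` object.
#' @export
alignment <- function(seqs, gene = NA_character_) {
  seqs <- toupper(seqs)
  if (!length(seqs)) stop("alignment: no sequences", call. = FALSE)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("alignment: sequences must have unique names", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("alignment: sequences differ in length", call. = FALSE)
  alph <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  bad <- setdiff(alph, c(names(IUPAC_SETS), MISSING_CHARS))
  if (length(bad))
    stop("alignment: illegal characters: ", paste(bad, collapse = " "),
         call. = FALSE)
  structure(list(gene = gene, seqs = seqs, length = lens[[1]]),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment:", x$gene, "-", length(x$seqs), "sequences x",
      x$length, "bp\n")
  invisible(x)
}

#' Write an alignment to FASTA
#' @param aln an `alignment`.
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(aln$seqs))
    writeLines(c(paste0(">", nm), aln$seqs[[nm]]), con)
  invisible(path)
}

# Can two sequences be the same haplotype under the compatible rule?
# At every column the IUPAC sets must intersect and at least one side must be
# unambiguous; gaps/missing never match anything.
.compatible_seqs <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  for (i in seq_along(ca)) {
    x <- ca[i]; y <- cb[i]
    if (x == y && !x %in% MISSING_CHARS) next
    if (x %in% MISSING_CHARS || y %in% MISSING_CHARS) return(FALSE)
    sx <- IUPAC_SETS[[x]]; sy <- IUPAC_SETS[[y]]
    if (length(sx) > 1L && length(sy) > 1L) return(FALSE)
    if (!length(intersect(sx, sy))) return(FALSE)
  }
  TRUE
}

#' Collapse identical sequences to unique haplotypes
#'
#' In `strict` mode two sequences merge only when equal character by
#' character. In `compatible` mode they merge when, at every column, their
#' IUPAC sets intersect and at least one side is unambiguous (gaps and
#' missing never match); merging is greedy in input order. The first member
#' is the representative. Haplotype ids are `H1`, `H2`, ... in order of first
#' appearance.
#'
#' @param aln an [alignment()].
#' @param ambiguity_mode `"strict"` (default) or `"compatible"`.
#' @return object of class `haplotype_set`: list with `representatives`
#'   (named character vector haplotype id -> sequence) and `membership`
#'   (named list haplotype id -> specimen ids).
#' @export
collapse_haplotypes <- function(aln, ambiguity_mode = c("strict", "compatible")) {
  ambiguity_mode <- match.arg(ambiguity_mode)
  seqs <- aln$seqs
  if (ambiguity_mode == "strict") {
    key <- match(seqs, unique(seqs))
  } else {
    reps_idx <- integer(0)
    key <- integer(length(seqs))
    for (i in seq_along(seqs)) {
      hit <- 0L
      for (r in seq_along(reps_idx)) {
        if (.compatible_seqs(seqs[[i]], seqs[[reps_idx[r]]])) { hit <- r; break }
      }
      if (hit == 0L) { reps_idx <- c(reps_idx, i); hit <- length(reps_idx) }
      key[i] <- hit
    }
  }
  n_hap <- max(key)
  hap_ids <- paste0("H", seq_len(n_hap))
  membership <- split(names(seqs), key)
  names(membership) <- hap_ids
  first <- vapply(membership, `[`, "", 1L)
  representatives <- setNames(unname(seqs[first]), hap_ids)
  structure(list(representatives = representatives,
                 membership = membership, gene = aln$gene),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", length(x$representatives), "haplotypes over",
      length(unlist(x$membership)), "sequences\n")
  invisible(x)
}

#' Expand a haplotype set back into a full alignment
#'
#' Each member receives its haplotype's representative sequence. Under
#' strict-mode collapsing this reproduces the input sequence multiset.
#'
#' @param hs a `haplotype_set`.
#' @return an [alignment()].
#' @export
expand_haplotypes <- function(hs) {
  ids <- unlist(hs$membership, use.names = FALSE)
  rep_of <- rep(names(hs$membership), lengths(hs$membership))
  alignment(setNames(hs$representatives[rep_of], ids), gene = hs$gene)
}

#' Write haplotype representatives and membership
#' @param hs a `haplotype_set`.
#' @param fasta_path FASTA output for representatives.
#' @param membership_path TSV output (`haplotype`, `specimens`).
#' @export
write_haplotypes <- function(hs, fasta_path, membership_path) {
  write_alignment(alignment(hs$representatives, gene = hs$gene), fasta_path)
  write_tip_map(hs$membership, membership_path)
  invisible(NULL)
}

#' Alignment summary statistics
#'
#' Variable sites are columns with at least two distinct unambiguous
#' nucleotides; parsimony-informative sites additionally require at least
#' two states each present in at least two sequences. Missing data is the
#' fraction of cells in `-`, `N`, `?`. Percentages are on `[0, 100]`.
#'
#' @param aln an [alignment()].
#' @return list with `n_seqs`, `length`, `pct_variable`,
#'   `pct_parsimony_informative`, `pct_missing`.
#' @export
alignment_stats <- function(aln) {
  mat <- do.call(rbind, strsplit(aln$seqs, ""))
  n_missing <- sum(mat %in% MISSING_CHARS)
  unamb <- c("A", "C", "G", "T")
  variable <- 0L; pinf <- 0L
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[col %in% unamb]
    if (!length(col)) next
    counts <- table(col)
    if (length(counts) >= 2L) {
      variable <- variable + 1L
      if (sum(counts >= 2L) >= 2L) pinf <- pinf + 1L
    }
  }
  list(n_seqs = length(aln$seqs),
       length = aln$length,
       pct_variable = 100 * variable / aln$length,
       pct_parsimony_informative = 100 * pinf / aln$length,
       pct_missing = 100 * n_missing / (length(aln$seqs) * aln$length))
}

GENETIC_CODES <- list(
  standard = c("TAA", "TAG", "TGA"),
  invertebrate_mitochondrial = c("TAA", "TAG"))

#' Screen sequences for in-frame stop codons
#'
#' Emits a warning (never filters) listing sequences containing a stop codon
#' in the given reading frame. Codons containing ambiguity or missing
#' characters are skipped.
#'
#' @param aln an [alignment()].
#' @param frame_offset 0, 1 or 2: column where codon position 1 starts.
#' @param code `"invertebrate_mitochondrial"` (default, fits COI) or
#'   `"standard"`.
#' @return invisibly, character vector of offending sequence names.
#' @export
check_stop_codons <- function(aln, frame_offset = 0,
                              code = c("invertebrate_mitochondrial", "standard")) {
  code <- match.arg(code)
  stops <- GENETIC_CODES[[code]]
  hits <- character(0)
  for (nm in names(aln$seqs)) {
    s <- gsub("-", "", aln$seqs[[nm]])
    s <- substring(s, frame_offset + 1)
    n_codon <- nchar(s) %/% 3
    if (n_codon < 1) next
    codons <- substring(s, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
    # ignore the final codon: a terminal stop is biologically expected
    if (any(codons[-n_codon] %in% stops)) hits <- c(hits, nm)
  }
  if (length(hits))
    warning("in-frame stop codon(s) in: ", paste(hits, collapse = ", "),
            call. = FALSE)
  invisible(hits)
}
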