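# Proteome and label IO, candidate pair enumeration, feature table IO.

#' Read an annotated proteome from FASTA
#'
#' Reads one amino-acid FASTA record per annotated protein. Identifiers are
#' the first whitespace-delimited token of each header and must be unique.
#' Non-canonical residues are resolved so every downstream descriptor is
#' defined over the 20-letter alphabet.
#'
#' @param path FASTA file (multi-line sequences allowed).
#' @param policy \code{"default"}: drop trailing \code{*}, map
#'   \code{U->C}, \code{O->K}, \code{B->D}, \code{Z->E}, \code{J->L} and
#'   \code{X} to the most frequent canonical residue of that sequence;
#'   \code{"strict"}: any non-canonical residue is an error.
#' @return an \code{\link[Biostrings]{AAStringSet}} in file order, names =
#'   protein ids, sequences sanitized to \code{ACDEFGHIKLMNPQRSTVWY}.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 descr", "MKV", ">p2", "GGAL"), tf)
#' readProteome(tf)
readProteome <- function(path, policy = c("default", "strict")) {
  policy <- match.arg(policy)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(aas))
  if (any(ids == "")) stop("empty FASTA identifier", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate protein id: ", dup[1], call. = FALSE)
  seqs <- vapply(as.character(aas), sanitizeSequence, character(1),
                 policy = policy, USE.NAMES = FALSE)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write a proteome to FASTA
#'
#' @param proteome named \code{AAStringSet} (or named character vector).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeProteome <- function(proteome, path) {
  seqs <- as.character(proteome)
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' Sanitize one amino-acid sequence
#'
#' @inheritParams readProteome
#' @param seq raw sequence string.
#' @return sequence over the 20 canonical letters.
#' @export
sanitizeSequence <- function(seq, policy = c("default", "strict")) {
  policy <- match.arg(policy)
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) == 0L) stop("empty sequence", call. = FALSE)
  # trailing stop codons are annotation artifacts, not residues
  while (length(chars) && chars[length(chars)] == "*")
    chars <- chars[-length(chars)]
  if (length(chars) == 0L) stop("empty sequence", call. = FALSE)
  noncanon <- !(chars %in% AA_ALPHABET20)
  if (policy == "strict") {
    if (any(noncanon))
      stop("non-canonical residue '", chars[noncanon][1],
           "' under strict policy", call. = FALSE)
    return(paste(chars, collapse = ""))
  }
  if (any(noncanon)) {
    map <- c(U = "C", O = "K", B = "D", Z = "E", J = "L")
    idx <- which(noncanon)
    mapped <- map[chars[idx]]
    chars[idx[!is.na(mapped)]] <- mapped[!is.na(mapped)]
    xs <- which(chars == "X")
    if (length(xs)) {
      canon <- chars[chars %in% AA_ALPHABET20]
      if (!length(canon))
        stop("sequence has no canonical residues to resolve 'X'",
             call. = FALSE)
      tab <- table(canon)
      chars[xs] <- names(tab)[which.max(tab)]
    }
    left <- !(chars %in% AA_ALPHABET20)
    if (any(left))
      stop("unhandled residue '", chars[left][1], "'", call. = FALSE)
  }
  paste(chars, collapse = "")
}

#' Load curated ortholog labels
#'
#' Reads a headerless two-column TSV of curated ortholog id pairs
#' ("gold-groups" style). Every pair of the \code{p1 x p2} cross product not
#' listed is implicitly a negative (non-ortholog).
#'
#' @param path TSV file; may be empty (no positives).
#' @param p1,p2 the two proteomes (named \code{AAStringSet}s).
#' @return a \code{\link{GoldLabels}} object.
#' @export
loadGoldLabels <- function(path, p1, p2) {
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines == 0L) {
    pairs <- data.frame(id1 = character(), id2 = character(),
                        stringsAsFactors = FALSE)
  } else {
    pairs <- read.table(path, sep = "\t", header = FALSE,
                        colClasses = "character",
                        col.names = c("id1", "id2"))
  }
  goldLabels(pairs, names(p1), names(p2))
}

#' @rdname loadGoldLabels
#' @param pairs data.frame with columns id1, id2.
#' @param ids1,ids2 the full id sets of the two proteomes.
#' @export
goldLabels <- function(pairs, ids1, ids2) {
  new("GoldLabels", pairs = pairs[, c("id1", "id2")],
      ids1 = as.character(ids1), ids2 = as.character(ids2))
}

#' Enumerate all candidate protein pairs
#'
#' Deterministic lexicographic enumeration of the full cross product:
#' proteome-1 order is the slow index, proteome-2 order the fast one, so a
#' feature matrix built over these pairs is byte-for-byte reproducible.
#'
#' @param p1,p2 proteomes (named \code{AAStringSet}s or named vectors).
#' @return data.frame with \code{nrow = length(p1) * length(p2)} and
#'   character columns \code{id1}, \code{id2}.
#' @export
#' @examples
#' p1 <- Biostrings::AAStringSet(c(a = "MK", b = "GG"))
#' p2 <- Biostrings::AAStringSet(c(x = "MK"))
#' enumeratePairs(p1, p2)
enumeratePairs <- function(p1, p2) {
  if (length(p1) == 0L || length(p2) == 0L)
    stop("both proteomes must be non-empty", call. = FALSE)
  data.frame(id1 = rep(names(p1), each = length(p2)),
             id2 = rep(names(p2), times = length(p1)),
             stringsAsFactors = FALSE)
}

#' Label candidate pairs against gold labels
#'
#' @param gold a \code{\link{GoldLabels}} object.
#' @param pairs data.frame with columns id1, id2.
#' @return integer vector: 1 for curated orthologs, 0 otherwise.
#' @export
labelPairs <- function(gold, pairs) {
  stopifnot(is(gold, "GoldLabels"))
  pos <- paste(gold@pairs$id1, gold@pairs$id2, sep = "\r")
  as.integer(paste(pairs$id1, pairs$id2, sep = "\r") %in% pos)
}

#' Write / read a pair feature table
#'
#' TSV with header \code{id1 id2 <feature names> [label]}; feature names are
#' written exactly as stored (they contain characters like \code{-}).
#' Writing then reading restores an identical \code{PairFeatures} object up
#' to numeric formatting (15 significant digits are written).
#'
#' @param x a \code{\link{PairFeatures}} object.
#' @param path TSV path.
#' @return \code{writeFeatureTable}: \code{path} invisibly;
#'   \code{readFeatureTable}: a \code{PairFeatures} object.
#' @export
writeFeatureTable <- function(x, path) {
  stopifnot(is(x, "PairFeatures"))
  df <- data.frame(x@pairs[, c("id1", "id2")],
                   format(x@features, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (length(x@label)) df$label <- x@label
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  has_label <- "label" %in% names(df)
  feat_cols <- setdiff(names(df), c("id1", "id2", "label"))
  new("PairFeatures",
      pairs = df[, c("id1", "id2")],
      features = as.matrix(df[, feat_cols, drop = FALSE]),
      label = if (has_label) as.integer(df$label) else integer(0),
      params = list(source = path))
}
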