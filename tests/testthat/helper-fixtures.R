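# shared test fixtures, all generated in code

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomSeq <- function(n) paste(sample(AA20, n, replace = TRUE),
                               collapse = "")

writeFasta <- function(seqs, path = tempfile(fileext = ".fasta"),
                       width = NULL) {
  lines <- character(0)
  for (id in names(seqs)) {
    s <- seqs[[id]]
    body <- if (is.null(width)) s else
      vapply(seq(1, nchar(s), width), function(i)
        substr(s, i, min(i + width - 1, nchar(s))), character(1))
    lines <- c(lines, paste0(">", id), body)
  }
  writeLines(lines, path)
  path
}

# mutate a fixed fraction of positions to a different uniform-random
# residue (independent of the package's BLOSUM-conditional mutator)
mutateFraction <- function(seq, frac) {
  ch <- strsplit(seq, "")[[1]]
  k <- round(frac * length(ch))
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(AA20, ch[p]), 1)
  paste(ch, collapse = "")
}

# three tiny hand-listed proteins per proteome, long enough that every
# descriptor family (maxlag 30, lambda 10) is defined
toyProteomes <- function() {
  p1 <- c(
    a1 = "MKVLAWGKHMDSTECFRYPQNNAIVLGKHMDSTECF",
    a2 = "GGALWKHMDSTECFRYPQNIVAGGALWKHMDSTECFRYPQ",
    a3 = "TTRCEQNPYRFCETSDMHKWAGTTRCEQNPYRFCETSDM")
  p2 <- c(
    b1 = "MKVLAWGKHMDATECFRYPQNNAIVLGKHMDSTECW",
    b2 = "PPLHWKHMDSTECFRYAQNIVAGGALWKHMDSTECFRYGG",
    b3 = "AAAAACDEFGHIKLMNPQRSTVWYAAAAACDEFGHIKLM")
  list(p1 = Biostrings::AAStringSet(p1), p2 = Biostrings::AAStringSet(p2))
}
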