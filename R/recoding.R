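# Invertebrate mitochondrial genetic code (NCBI translation table 5).
# Differences from the standard code: AGA/AGG = Ser, ATA = Met, TGA = Trp.
.mito_code5 <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0
  )))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CCWW",  # TTT..TGG
    "LLLLPPPPHHQQRRRR",  # CTT..CGG
    "IIMMTTTTNNKKSSSS",  # ATT..AGG  (ATA=M, AGA/AGG=S)
    "VVVVAAAADDEEGGGG"   # GTT..GGG
  ), "")[[1]]
  stats::setNames(aa, codons)
})

#' Translate a coding sequence under the invertebrate mitochondrial code
#'
#' Uses NCBI translation table 5 (AGA/AGG = Ser, ATA = Met, TGA = Trp). A
#' trailing partial codon is dropped. Codons containing characters outside
#' `A,C,G,T` (ambiguities such as `N`, used to pad frame errors) translate
#' to `X`; all-gap codons (`---`) translate to `-`. Internal stop codons are
#' rendered `*` and reported via a warning rather than an error, so frame
#' repair can follow.
#'
#' @param cds Character vector of nucleotide strings (reading orientation,
#'   starting at codon position 1).
#' @param warn_internal_stop Warn when a `*` occurs before the final codon?
#' @return Character vector of amino-acid strings.
#' @export
#' @examples
#' translate_mito("ATAAGAAGG")  # "MSS"
#' translate_mito("TGA")        # "W"
translate_mito <- function(cds, warn_internal_stop = TRUE) {
  stopifnot(is.character(cds))
  vapply(cds, function(s) {
    s <- toupper(s)
    n <- nchar(s) - nchar(s) %% 3L
    if (n < 3) return("")
    codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
    aa <- unname(.mito_code5[codons])
    aa[is.na(aa) & codons == "---"] <- "-"
    aa[is.na(aa)] <- "X"
    if (warn_internal_stop && any(aa[-length(aa)] == "*")) {
      warning("internal stop codon(s) at codon ",
              paste(which(aa[-length(aa)] == "*"), collapse = ","),
              call. = FALSE)
    }
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# ---------------------------------------------------------------------------
# alignment containers

.new_alignment <- function(seq, alphabet, partitions = NULL,
                           class = "recoded_alignment") {
  stopifnot(is.character(seq), !is.null(names(seq)))
  if (length(unique(nchar(seq))) != 1) {
    stop("alignment rows must have equal length", call. = FALSE)
  }
  if (is.null(partitions)) {
    partitions <- tibble::tibble(gene = "all", start = 1L,
                                 end = nchar(seq[1]))
  }
  structure(
    list(seq = seq, alphabet = alphabet, partitions = partitions),
    class = c(class, "mito_alignment")
  )
}

#' @export
print.mito_alignment <- function(x, ...) {
  cat("<", class(x)[1], "> ", length(x$seq), " taxa x ", nchar(x$seq[1]),
      " columns, alphabet: ", x$alphabet, "\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname aa_alignment
#' @param x A `mito_alignment`.
#' @param ... Unused.
tidy.mito_alignment <- function(x, ...) {
  tibble::tibble(taxon = names(x$seq), sequence = unname(x$seq),
                 width = nchar(x$seq))
}

#' Construct alignment objects
#'
#' `aa_alignment()` holds an aligned amino-acid matrix (one string per
#' taxon); `codon_alignment()` holds aligned codon triplets (row length
#' divisible by 3, gap codons all-or-nothing). Both carry a partition map
#' (`gene`, `start`, `end` in alignment columns -- amino-acid columns for
#' `aa_alignment`, nucleotide columns for `codon_alignment`).
#'
#' @param seq Named character vector, one aligned row per taxon.
#' @param partitions Optional partition tibble.
#' @return An alignment object.
#' @export
aa_alignment <- function(seq, partitions = NULL) {
  .new_alignment(toupper(seq), "AA", partitions, "aa_alignment")
}

#' @rdname aa_alignment
#' @export
codon_alignment <- function(seq, partitions = NULL) {
  seq <- toupper(seq)
  if (nchar(seq[1]) %% 3L != 0L) {
    stop("codon alignment length must be divisible by 3", call. = FALSE)
  }
  bad <- vapply(seq, function(s) {
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    any(grepl("-", cod) & cod != "---")
  }, logical(1))
  if (any(bad)) {
    stop("gap codons must be all-or-nothing within a triplet (taxon ",
         paste(names(seq)[bad], collapse = ", "), ")", call. = FALSE)
  }
  .new_alignment(seq, "nucleotide", partitions, "codon_alignment")
}

#' Back-translate an amino-acid alignment to a codon alignment
#'
#' Each amino-acid column expands to one codon column taken from the
#' taxon's unaligned coding sequence; amino-acid gaps expand to `---`. The
#' per-taxon CDS must translate (under the invertebrate mitochondrial code)
#' to the ungapped amino-acid row; `X` and `*` positions are tolerated.
#'
#' @param aa_aln An [aa_alignment()] (or named character vector).
#' @param cds Named character vector of unaligned coding sequences, one per
#'   taxon in `aa_aln`.
#' @return A [codon_alignment()] with the partition map scaled to
#'   nucleotide columns.
#' @export
backtranslate_alignment <- function(aa_aln, cds) {
  if (!inherits(aa_aln, "aa_alignment")) aa_aln <- aa_alignment(aa_aln)
  stopifnot(all(names(aa_aln$seq) %in% names(cds)))
  rows <- purrr::imap_chr(aa_aln$seq, function(row, taxon) {
    aa <- strsplit(row, "", fixed = TRUE)[[1]]
    s <- toupper(cds[[taxon]])
    n <- nchar(s) - nchar(s) %% 3L
    codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
    ungapped <- aa[aa != "-"]
    # drop a trailing stop in the CDS not represented in the alignment
    if (length(codons) == length(ungapped) + 1 &&
          .mito_code5[codons[length(codons)]] %in% "*") {
      codons <- codons[-length(codons)]
    }
    if (length(codons) != length(ungapped)) {
      stop("taxon ", taxon, ": CDS has ", length(codons),
           " codons but alignment row has ", length(ungapped),
           " residues", call. = FALSE)
    }
    trans <- translate_mito(paste(codons, collapse = ""),
                            warn_internal_stop = FALSE)
    tr <- strsplit(trans, "", fixed = TRUE)[[1]]
    mism <- which(tr != ungapped & !(tr %in% c("X", "*")) &
                    !(ungapped %in% c("X", "*")))
    if (length(mism)) {
      stop("taxon ", taxon, ": translation mismatch at alignment column ",
           which(cumsum(aa != "-") == mism[1] & aa != "-")[1],
           " (", tr[mism[1]], " vs ", ungapped[mism[1]], ")", call. = FALSE)
    }
    out <- character(length(aa))
    out[aa == "-"] <- "---"
    out[aa != "-"] <- codons
    paste(out, collapse = "")
  })
  parts <- dplyr::mutate(aa_aln$partitions,
                         start = (start - 1L) * 3L + 1L, end = end * 3L)
  codon_alignment(rows, parts)
}

# ---------------------------------------------------------------------------
# recoding

.ry_chars <- function(chars) {
  dplyr::case_match(
    chars,
    c("A", "G") ~ "R",
    c("C", "T") ~ "Y",
    c("-", "R", "Y") ~ chars,
    .default = "?"
  )
}

#' RY-recode selected codon positions
#'
#' Replaces purines (`A`,`G`) with `R` and pyrimidines (`C`,`T`) with `Y`
#' at the selected codon positions; other positions keep their nucleotides.
#' Gaps are unchanged; ambiguity codes become `?`. The two classic settings
#' are `positions = 3` and `positions = c(1, 3)`.
#'
#' @param aln A [codon_alignment()].
#' @param positions Subset of `c(1, 2, 3)`; must be non-empty.
#' @return A recoded alignment (alphabet `"RY"` when all three positions
#'   are recoded, otherwise `"mixed_nt_RY"`).
#' @export
ry_recode <- function(aln, positions = 3) {
  stopifnot(inherits(aln, "codon_alignment"))
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) == 0 || !all(positions %in% 1:3)) {
    stop("positions must be a non-empty subset of 1:3", call. = FALSE)
  }
  width <- nchar(aln$seq[1])
  posidx <- rep_len(1:3, width)
  sel <- posidx %in% positions
  seq <- vapply(aln$seq, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    chars[sel] <- .ry_chars(chars[sel])
    paste(chars, collapse = "")
  }, character(1))
  alphabet <- if (length(positions) == 3) "RY" else "mixed_nt_RY"
  .new_alignment(seq, alphabet, aln$partitions)
}

#' Default Neutral-Transitions-Excluded site predicate
#'
#' Given the codons observed in one alignment column (gap codons removed),
#' decides whether the column's first position should be RY-recoded: all
#' non-ambiguous codons must belong to families whose first-position
#' transition is treated as neutral -- Leucine `TTR`/`CTN` and Arginine
#' `CGN`.
#'
#' @param codons Character vector of 3-letter codons in one column.
#' @return `TRUE`/`FALSE`.
#' @export
nte_default_predicate <- function(codons) {
  codons <- toupper(codons[codons != "---"])
  codons <- codons[!grepl("[^ACGT]", codons)]
  if (length(codons) == 0) return(FALSE)
  leu <- grepl("^TT[AG]$", codons) | grepl("^CT[ACGT]$", codons)
  arg <- grepl("^CG[ACGT]$", codons)
  all(leu | arg)
}

#' Neutral-Transitions-Excluded (NTE) recoding
#'
#' RY-recodes exactly the sites where transitions are expected to be
#' synonymous under the invertebrate mitochondrial code: every 3rd codon
#' position, plus the 1st position of codon columns selected by
#' `predicate` (by default Leucine `TTR`/`CTN` and Arginine `CGN`
#' columns; see [nte_default_predicate()]). Second positions are never
#' recoded. The exact site set is an interpretation and the predicate is
#' swappable.
#'
#' @param aln A [codon_alignment()].
#' @param predicate Function of the column's codons returning `TRUE` when
#'   the column's 1st position should be recoded.
#' @return A recoded alignment with alphabet `"mixed_nt_RY"`.
#' @export
nte_recode <- function(aln, predicate = nte_default_predicate) {
  stopifnot(inherits(aln, "codon_alignment"))
  width <- nchar(aln$seq[1])
  ncod <- width %/% 3L
  mat <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  recode_first <- vapply(seq_len(ncod), function(j) {
    cols <- (j - 1L) * 3L + 1:3
    codons <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
    isTRUE(predicate(codons))
  }, logical(1))
  sel <- rep(FALSE, width)
  sel[seq(3, width, by = 3)] <- TRUE                    # all 3rd positions
  sel[(which(recode_first) - 1L) * 3L + 1L] <- TRUE     # selected 1st positions
  seq <- vapply(aln$seq, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    chars[sel] <- .ry_chars(chars[sel])
    paste(chars, collapse = "")
  }, character(1))
  .new_alignment(seq, "mixed_nt_RY", aln$partitions)
}

# six physiochemical groups
.physio_groups <- list(
  h = c("V", "L", "I", "M"),            # hydrophobic
  a = c("F", "Y", "W"),                 # aromatic
  s = c("S", "T", "A", "P", "G"),       # small / neutral
  d = c("D", "E", "N", "Q"),            # acidic / amides
  b = c("H", "R", "K"),                 # basic
  c = "C"                               # sulfhydryl
)

#' Recode amino acids into six physiochemical groups
#'
#' Collapses the 20 amino acids into six functional groups: hydrophobic
#' (`V,L,I,M` -> `h`), aromatic (`F,Y,W` -> `a`), small/neutral
#' (`S,T,A,P,G` -> `s`), acidic/amides (`D,E,N,Q` -> `d`), basic
#' (`H,R,K` -> `b`) and sulfhydryl (`C` -> `c`). Gaps stay `-`; `X` and
#' `*` become `?`. Any other residue character is an error.
#'
#' @param aa_aln An [aa_alignment()] (or named character vector).
#' @return A recoded alignment with alphabet `"physiochemical"`.
#' @export
physiochemical_recode <- function(aa_aln) {
  if (!inherits(aa_aln, "aa_alignment")) aa_aln <- aa_alignment(aa_aln)
  map <- stats::setNames(
    rep(names(.physio_groups), lengths(.physio_groups)),
    unlist(.physio_groups, use.names = FALSE)
  )
  map <- c(map, "-" = "-", X = "?", "*" = "?", "?" = "?")
  seq <- vapply(aa_aln$seq, function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    out <- unname(map[chars])
    if (anyNA(out)) {
      stop("unknown residue character(s): ",
           paste(unique(chars[is.na(out)]), collapse = ", "), call. = FALSE)
    }
    paste(out, collapse = "")
  }, character(1))
  .new_alignment(seq, "physiochemical", aa_aln$partitions)
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Taxa missing from a gene are filled with gaps (a message notes the
#' fill). The partition map records each gene's column range; taxon order
#' is the order of first appearance across the inputs.
#'
#' @param alignments Named list of alignment objects (names are gene
#'   labels) sharing one alphabet family.
#' @return An alignment of the same class with a multi-gene partition map.
#' @export
concatenate_partitions <- function(alignments) {
  stopifnot(is.list(alignments), !is.null(names(alignments)))
  alphabets <- unique(vapply(alignments, function(a) a$alphabet,
                             character(1)))
  if (length(alphabets) != 1) {
    stop("inconsistent alphabets: ", paste(alphabets, collapse = ", "),
         call. = FALSE)
  }
  taxa <- unique(unlist(lapply(alignments, function(a) names(a$seq))))
  offset <- 0L
  parts <- list()
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  for (g in names(alignments)) {
    a <- alignments[[g]]
    w <- unname(nchar(a$seq[1]))
    missing <- setdiff(taxa, names(a$seq))
    if (length(missing)) {
      message("gene ", g, ": filling ", length(missing),
              " absent taxon/taxa with gaps")
    }
    block <- stats::setNames(rep(strrep("-", w), length(taxa)), taxa)
    block[names(a$seq)] <- a$seq
    rows <- paste0(rows, block)
    parts[[g]] <- tibble::tibble(gene = g, start = offset + 1L,
                                 end = offset + w)
    offset <- offset + w
  }
  names(rows) <- taxa
  .new_alignment(rows, alphabets, dplyr::bind_rows(parts),
                 class = class(alignments[[1]])[1])
}

# ---------------------------------------------------------------------------
# alignment I/O

#' Read / write alignments
#'
#' FASTA I/O goes through Biostrings; the relaxed PHYLIP dialect
#' (`ntaxa nchar` header, whitespace-separated name and row, full rows) is
#' read and written directly so that recoded alphabets (RY, physiochemical
#' symbols) survive the round trip. `write_partition_file()` emits
#' charset-style `GENE = start-end` lines.
#'
#' @param path File path.
#' @param alphabet Alphabet label to attach on read.
#' @return Alignment objects, or (for writers) the path invisibly.
#' @export
read_fasta_alignment <- function(path, alphabet = "AA") {
  seqs <- Biostrings::readBStringSet(path)
  v <- stats::setNames(as.character(seqs), names(seqs))
  if (alphabet == "AA") aa_alignment(v) else
    .new_alignment(toupper(v), alphabet)
}

#' @rdname read_fasta_alignment
#' @param aln An alignment object.
#' @export
write_fasta_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln$seq), path,
                              width = 70)
  invisible(path)
}

#' @rdname read_fasta_alignment
#' @export
write_phylip_alignment <- function(aln, path) {
  names_ <- names(aln$seq)
  pad <- max(nchar(names_)) + 2L
  lines <- c(
    paste(length(aln$seq), nchar(aln$seq[1])),
    paste0(formatC(names_, width = -pad), unname(aln$seq))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_fasta_alignment
#' @export
read_phylip_alignment <- function(path, alphabet = "AA") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- lines[-1]
  if (length(body) != hdr[1]) {
    stop("expected ", hdr[1], " sequence rows, found ", length(body),
         call. = FALSE)
  }
  parts <- stringr::str_match(body, "^(\\S+)\\s+(.*)$")
  v <- stats::setNames(gsub("\\s+", "", parts[, 3]), parts[, 2])
  if (any(nchar(v) != hdr[2])) {
    stop("sequence length disagrees with PHYLIP header", call. = FALSE)
  }
  if (alphabet == "AA") aa_alignment(v) else
    .new_alignment(toupper(v), alphabet)
}

#' @rdname read_fasta_alignment
#' @param partitions Partition tibble (`gene`, `start`, `end`).
#' @export
write_partition_file <- function(partitions, path) {
  writeLines(sprintf("%s = %d-%d", partitions$gene, partitions$start,
                     partitions$end), path)
  invisible(path)
}
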