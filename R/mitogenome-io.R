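#' Construct a mitochondrial genome object
#'
#' A `mito_genome` bundles one circular (or linear) nucleotide sequence with
#' an ordered feature table. Coordinates are 1-based inclusive, GenBank
#' style; a feature with `end < start` spans the origin of the circular
#' molecule (it runs `start..L` then `1..end`). The deposited orientation is
#' taken as the major strand.
#'
#' @param sequence Single nucleotide string (characters outside `A,C,G,T`
#'   are preserved as ambiguity codes, never dropped).
#' @param features Data frame with columns `gene`, `start`, `end`, `strand`
#'   (`"major"`/`"minor"` or `"+"`/`"-"`); optional `category` (derived from
#'   the canonical name when absent).
#' @param taxon,accession Labels.
#' @param circular Is the molecule circular? Default `TRUE`.
#' @return An object of class `mito_genome`.
#' @export
#' @examples
#' g <- mito_genome("ATGAAATAA",
#'   features = data.frame(gene = "CO1", start = 1, end = 9, strand = "major"),
#'   taxon = "toy")
#' tidy(g)
mito_genome <- function(sequence, features, taxon = "unknown",
                        accession = NA_character_, circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) > 0)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  features <- tibble::as_tibble(features)
  stopifnot(all(c("gene", "start", "end", "strand") %in% names(features)))
  features$strand <- .norm_strand(features$strand)
  if (!"category" %in% names(features)) {
    features$category <- .gene_category(features$gene)
  }
  features <- features[, c("gene", "category", "start", "end", "strand")]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (any(features$start < 1 | features$start > n |
            features$end < 1 | features$end > n)) {
    stop("feature coordinates outside 1..", n, call. = FALSE)
  }
  if (!circular && any(features$end < features$start)) {
    stop("origin-wrapping feature on a linear molecule", call. = FALSE)
  }
  canon <- features$gene[.is_canonical(features$gene)]
  if (anyDuplicated(canon)) {
    stop(
      "duplicate canonical gene(s): ",
      paste(unique(canon[duplicated(canon)]), collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      taxon = taxon, accession = accession, sequence = sequence,
      circular = circular, features = features
    ),
    class = "mito_genome"
  )
}

.norm_strand <- function(x) {
  out <- dplyr::case_match(
    as.character(x),
    c("major", "+", "1") ~ "major",
    c("minor", "-", "-1") ~ "minor",
    .default = NA_character_
  )
  if (anyNA(out)) stop("strand must be major/minor or +/-", call. = FALSE)
  out
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(
    "<mito_genome> ", x$taxon,
    if (!is.na(x$accession)) paste0(" [", x$accession, "]"), "\n",
    "  ", nchar(x$sequence), " nt, ",
    if (x$circular) "circular" else "linear", ", ",
    nrow(x$features), " features\n",
    sep = ""
  )
  invisible(x)
}

#' @export
#' @rdname mito_genome
#' @param x A `mito_genome`.
#' @param ... Unused.
tidy.mito_genome <- function(x, ...) {
  dplyr::mutate(
    x$features,
    taxon = x$taxon,
    length = .feature_length(start, end, nchar(x$sequence)),
    .before = 1
  )
}

.feature_length <- function(start, end, n) {
  ifelse(end >= start, end - start + 1L, n - start + 1L + end)
}

#' Extract a gene's sequence in reading orientation
#'
#' Returns the nucleotides of a feature in its own reading orientation:
#' minor-strand features are reverse-complemented, and features spanning
#' the circular origin are stitched across it.
#'
#' @param genome A [mito_genome()].
#' @param gene Canonical gene name of a feature in `genome`, or a one-row
#'   data frame with `start`, `end`, `strand`.
#' @return A single nucleotide string.
#' @export
#' @examples
#' g <- mito_genome("AACG",
#'   features = data.frame(gene = "trnA", start = 1, end = 4, strand = "minor"))
#' extract_gene_sequence(g, "trnA")  # "CGTT"
extract_gene_sequence <- function(genome, gene) {
  stopifnot(inherits(genome, "mito_genome"))
  if (is.character(gene)) {
    feat <- genome$features[genome$features$gene == gene, ]
    if (nrow(feat) == 0) stop("no feature named ", gene, call. = FALSE)
    feat <- feat[1, ]
  } else {
    feat <- tibble::as_tibble(gene)[1, ]
  }
  n <- nchar(genome$sequence)
  s <- feat$start
  e <- feat$end
  if (e >= s) {
    out <- substr(genome$sequence, s, e)
  } else {
    if (!genome$circular) stop("wrapping feature on linear molecule")
    out <- paste0(
      substr(genome$sequence, s, n),
      substr(genome$sequence, 1, e)
    )
  }
  if (.norm_strand(feat$strand) == "minor") out <- revcomp(out)
  out
}

#' Reverse-complement a nucleotide string
#'
#' IUPAC-aware reverse complement (delegates to Biostrings when the string is
#' pure DNA alphabet; unknown characters are complemented by identity).
#'
#' @param x Single nucleotide string.
#' @return The reverse complement string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  ok <- grepl("^[ACGTRYSWKMBDHVN-]*$", toupper(x))
  if (ok) {
    return(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(toupper(x)))
    ))
  }
  comp <- chartr(
    "ACGTRYSWKMBDHVNacgtryswkmbdhvn",
    "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x
  )
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# ---------------------------------------------------------------------------
# GenBank flat-file reader

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Parses LOCUS/ACCESSION/ORGANISM, the feature table (CDS, tRNA, rRNA,
#' D-loop, misc_feature, rep_origin) and the ORIGIN sequence of a local
#' GenBank flat file. Gene names are normalized with
#' [normalize_gene_name()]; `join(...)` locations spanning the origin are
#' collapsed to a single feature with `end < start` (the wrap convention).
#' The sequence is preserved verbatim in the deposited orientation, which is
#' treated as the major strand.
#'
#' @param path Path to a GenBank flat file containing one record.
#' @param reorient_co1_major If `TRUE` and CO1 is annotated on the minor
#'   strand, the whole record is reverse-complemented so that CO1 lies on the
#'   major strand (for non-standard deposits). Default `FALSE`.
#' @return A [mito_genome()].
#' @export
read_genbank <- function(path, reorient_co1_major = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty GenBank file", call. = FALSE)

  accession <- NA_character_
  taxon <- "unknown"
  circular <- TRUE
  m <- grep("^LOCUS", lines, value = TRUE)
  if (length(m)) circular <- grepl("\\bcircular\\b", m[1], ignore.case = TRUE)
  m <- grep("^ACCESSION", lines, value = TRUE)
  if (length(m)) accession <- stringr::str_trim(sub("^ACCESSION\\s+", "", m[1]))
  m <- grep("^\\s*ORGANISM", lines, value = TRUE)
  if (length(m)) taxon <- stringr::str_trim(sub("^\\s*ORGANISM\\s+", "", m[1]))

  org_i <- grep("^ORIGIN", lines)
  if (length(org_i) == 0) stop("GenBank record has no ORIGIN sequence",
                               call. = FALSE)
  seq_lines <- lines[(org_i[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0) stop("GenBank record has no sequence",
                                 call. = FALSE)

  feat_i <- grep("^FEATURES", lines)
  features <- tibble::tibble(
    gene = character(), category = character(),
    start = integer(), end = integer(), strand = character()
  )
  if (length(feat_i)) {
    block <- lines[(feat_i[1] + 1):(org_i[1] - 1)]
    # feature lines start at column 6; qualifier/continuation lines at 22
    starts <- grep("^ {5}\\S", block)
    keep_keys <- c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature",
                   "rep_origin", "repeat_region")
    recs <- purrr::map(seq_along(starts), function(i) {
      from <- starts[i]
      to <- if (i < length(starts)) starts[i + 1] - 1 else length(block)
      chunk <- block[from:to]
      key <- stringr::str_trim(substr(chunk[1], 6, 21))
      if (!key %in% keep_keys) return(NULL)
      # location may continue over lines until the first qualifier
      qual_i <- grep("^\\s+/", chunk)
      loc_end <- if (length(qual_i)) qual_i[1] - 1 else length(chunk)
      loc <- gsub("\\s+", "", paste(
        c(stringr::str_trim(substr(chunk[1], 22, nchar(chunk[1]))),
          stringr::str_trim(chunk[seq_len(loc_end)[-1]])),
        collapse = ""
      ))
      quals <- paste(chunk[seq_along(chunk) >= loc_end + 1], collapse = " ")
      name <- .gb_qualifier(quals, "gene")
      if (is.na(name)) name <- .gb_qualifier(quals, "product")
      if (is.na(name)) name <- .gb_qualifier(quals, "note")
      if (is.na(name)) name <- if (key %in% c("D-loop", "repeat_region"))
        key else "unnamed"
      pos <- .gb_location(loc)
      tibble::tibble(
        raw = name, key = key,
        start = pos$start, end = pos$end, strand = pos$strand
      )
    })
    recs <- dplyr::bind_rows(recs)
    if (nrow(recs)) {
      norm <- normalize_gene_name(recs$raw)
      features <- tibble::tibble(
        gene = norm$gene,
        category = norm$category,
        start = recs$start, end = recs$end, strand = recs$strand
      )
      # D-loop key implies the control region even with an odd label
      features$gene[recs$key == "D-loop"] <- "CONTROL_REGION"
      features$category[recs$key == "D-loop"] <- "control"
    }
  }
  g <- mito_genome(sequence, features, taxon = taxon, accession = accession,
                   circular = circular)
  if (reorient_co1_major && "CO1" %in% g$features$gene &&
        g$features$strand[g$features$gene == "CO1"] == "minor") {
    g <- .flip_genome(g)
  }
  g
}

.gb_qualifier <- function(quals, name) {
  m <- stringr::str_match(quals, paste0('/', name, '="([^"]*)"'))[, 2]
  if (is.na(m)) {
    m <- stringr::str_match(quals, paste0('/', name, '=([^\\s/]+)'))[, 2]
  }
  m
}

# Parse a GenBank location string into (start, end, strand). join() segments
# that run to the end of the molecule and restart at 1 collapse to the wrap
# convention end < start.
.gb_location <- function(loc) {
  strand <- "major"
  if (grepl("^complement\\(", loc)) {
    strand <- "minor"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  loc <- gsub("[<>]", "", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  bounds <- purrr::map(parts, function(p) {
    nums <- as.integer(stringr::str_match(p, "^(\\d+)(?:\\.\\.(\\d+))?$")[, 2:3])
    if (is.na(nums[2])) nums[2] <- nums[1]
    nums
  })
  first <- bounds[[1]]
  last <- bounds[[length(bounds)]]
  list(start = first[1], end = last[2], strand = strand)
}

.flip_genome <- function(g) {
  n <- nchar(g$sequence)
  f <- g$features
  new_start <- ifelse(f$end >= f$start, n - f$end + 1L, n - f$end + 1L)
  new_end <- n - f$start + 1L
  f2 <- f
  f2$start <- new_start
  f2$end <- new_end
  wrap <- f$end < f$start  # wrapped features stay wrapped after flip
  f2$start[wrap] <- n - f$end[wrap] + 1L
  f2$end[wrap] <- n - f$start[wrap] + 1L
  f2$strand <- ifelse(f$strand == "major", "minor", "major")
  mito_genome(revcomp(g$sequence), f2, taxon = g$taxon,
              accession = g$accession, circular = g$circular)
}

# ---------------------------------------------------------------------------
# FASTA + gene-table dialect (what the simulator writes)

#' Read a mitogenome from FASTA + gene table
#'
#' The gene table is a TSV with header `taxon gene start end strand`
#' (1-based inclusive coordinates; strand `major`/`minor` or `+`/`-`). This
#' is the dialect written by [write_gene_table()] and by the synthetic
#' genome simulator.
#'
#' @param fasta Path to a FASTA file holding one sequence.
#' @param table Path to the gene-table TSV.
#' @return A [mito_genome()].
#' @export
read_gene_table <- function(fasta, table) {
  seqs <- Biostrings::readBStringSet(fasta)
  if (length(seqs) != 1) stop("FASTA must hold exactly one sequence",
                              call. = FALSE)
  tab <- readr::read_tsv(table, show_col_types = FALSE,
                         col_types = readr::cols(
                           taxon = readr::col_character(),
                           gene = readr::col_character(),
                           start = readr::col_integer(),
                           end = readr::col_integer(),
                           strand = readr::col_character()
                         ))
  if (anyDuplicated(tab$gene)) {
    stop("duplicate gene name(s) in table: ",
         paste(unique(tab$gene[duplicated(tab$gene)]), collapse = ", "),
         call. = FALSE)
  }
  norm <- normalize_gene_name(tab$gene)
  mito_genome(
    as.character(seqs[[1]]),
    tibble::tibble(gene = norm$gene, category = norm$category,
                   start = tab$start, end = tab$end, strand = tab$strand),
    taxon = tab$taxon[1],
    accession = NA_character_
  )
}

#' Write a mitogenome as FASTA + gene table
#'
#' Inverse of [read_gene_table()]: coordinates and strands round-trip
#' exactly.
#'
#' @param genome A [mito_genome()].
#' @param fasta,table Output paths.
#' @return Invisibly, the paths.
#' @export
write_gene_table <- function(genome, fasta, table) {
  stopifnot(inherits(genome, "mito_genome"))
  seqs <- Biostrings::BStringSet(stats::setNames(genome$sequence,
                                                 genome$taxon))
  Biostrings::writeXStringSet(seqs, fasta, width = 70)
  out <- dplyr::mutate(
    genome$features[, c("gene", "start", "end", "strand")],
    taxon = genome$taxon, .before = 1
  )
  readr::write_tsv(out, table)
  invisible(c(fasta = fasta, table = table))
}

# ---------------------------------------------------------------------------
# Gene order

#' Build a gene-order specification
#'
#' A `gene_order` is a signed circular permutation: a tibble of
#' `(gene, strand)` rows in circular order with a linearization anchor used
#' only for display. Equality of gene orders is rotation-invariant; use
#' [order_equal()].
#'
#' @param gene Character vector of gene names (no duplicates).
#' @param strand Strand per gene (`major`/`minor` or `+`/`-`).
#' @param anchor Gene used to linearize for display; defaults to `CO1` when
#'   present, else the first gene.
#' @return A tibble of class `gene_order` with columns `gene`, `strand`.
#' @export
gene_order_spec <- function(gene, strand = "major", anchor = NULL) {
  strand <- .norm_strand(rep_len(strand, length(gene)))
  if (anyDuplicated(gene)) stop("duplicate gene names in order",
                                call. = FALSE)
  if (is.null(anchor)) anchor <- if ("CO1" %in% gene) "CO1" else gene[1]
  out <- tibble::tibble(gene = gene, strand = strand)
  class(out) <- c("gene_order", class(out))
  attr(out, "anchor") <- anchor
  rotate_order(out, anchor)
}

#' Extract the gene order of an annotated genome
#'
#' Features are sorted by circular start position on the deposited strand.
#' By default only the canonical 37 genes and the control region enter the
#' order; non-canonical features (for example repeat regions) are retained
#' only when `include_noncanonical = TRUE`.
#'
#' @param genome A [mito_genome()] with at least 2 features.
#' @param include_noncanonical Keep `category == "other"` features?
#' @param include_control Keep the control region as a positional marker?
#'   Default `TRUE`.
#' @return A [gene_order_spec()].
#' @export
gene_order <- function(genome, include_noncanonical = FALSE,
                       include_control = TRUE) {
  stopifnot(inherits(genome, "mito_genome"))
  f <- genome$features
  if (!include_noncanonical) f <- f[f$category != "other", ]
  if (!include_control) f <- f[f$category != "control", ]
  if (nrow(f) < 2) stop("need at least 2 features for a gene order",
                        call. = FALSE)
  f <- f[order(f$start, f$end), ]
  gene_order_spec(f$gene, f$strand)
}

#' Rotate a gene order to a new linearization anchor
#'
#' @param order A `gene_order`.
#' @param anchor Gene to rotate to the front.
#' @return The rotated `gene_order` (an equivalent circular permutation).
#' @export
rotate_order <- function(order, anchor) {
  stopifnot(inherits(order, "gene_order"))
  i <- match(anchor, order$gene)
  if (is.na(i)) return(order)
  idx <- c(i:nrow(order), seq_len(i - 1))[seq_len(nrow(order))]
  out <- order[idx, ]
  class(out) <- class(order)
  attr(out, "anchor") <- anchor
  out
}

#' Rotation-invariant equality of gene orders
#'
#' Two gene orders are equal when one is a rotation of the other with
#' identical strands.
#'
#' @param a,b `gene_order` objects.
#' @return `TRUE` or `FALSE`.
#' @export
order_equal <- function(a, b) {
  if (nrow(a) != nrow(b)) return(FALSE)
  if (!setequal(a$gene, b$gene)) return(FALSE)
  i <- match(a$gene[1], b$gene)
  if (is.na(i)) return(FALSE)
  idx <- c(i:nrow(b), seq_len(i - 1))[seq_len(nrow(b))]
  b2 <- b[idx, ]
  all(a$gene == b2$gene) && all(a$strand == b2$strand)
}
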