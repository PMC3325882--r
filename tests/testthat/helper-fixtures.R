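# fixtures built in code: a small annotated genome and a GenBank flat file

# 60 nt circular toy genome: CO1 (major, 1..18), trnA (minor, 19..24),
# rrnS (major, 25..42), control region wrapping the origin (55..6 is not
# used here; wrap exercised separately)
toy_genome <- function() {
  seq <- paste0(
    "ATGAAACCCGGGTTTTAA",  # CO1: ATG AAA CCC GGG TTT TAA
    "AACGTT",              # trnA (deposited); reading orientation AACGTT rc
    "ACGTACGTACGTACGTAC",  # rrnS
    "GATTACAGATTACAGATT"   # unannotated spacer
  )
  mito_genome(
    seq,
    tibble::tibble(
      gene = c("CO1", "trnA", "rrnS"),
      start = c(1L, 19L, 25L),
      end = c(18L, 24L, 42L),
      strand = c("major", "minor", "major")
    ),
    taxon = "Toyus exemplaris"
  )
}

# GenBank flat-file text for a tiny record with a major CDS, a minor-strand
# tRNA, and an rRNA whose join() spans the origin
write_toy_genbank <- function(path) {
  seq <- tolower(paste0(
    "ATGAAACCCGGGTTTTAA",
    "AACGTT",
    "ACGTACGTACGTACGTAC",
    "GATTACAGATTACAGATT"
  ))
  body <- paste0("        1 ", gsub("(.{10})", "\\1 ", seq))
  lines <- c(
    "LOCUS       TOY0001                 60 bp    DNA     circular INV 01-JAN-2012",
    "DEFINITION  Toyus exemplaris mitochondrion, complete genome.",
    "ACCESSION   TOY0001",
    "  ORGANISM  Toyus exemplaris",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    '                     /organism="Toyus exemplaris"',
    "     CDS             1..18",
    '                     /gene="COX1"',
    '                     /product="cytochrome c oxidase subunit I"',
    "     tRNA            complement(19..24)",
    '                     /product="tRNA-Ala"',
    "     rRNA            join(55..60,1..6)",
    '                     /product="12S ribosomal RNA"',
    "ORIGIN",
    body,
    "//"
  )
  writeLines(lines, path)
  path
}

# ungapped toy alignment over two taxa with known codons
toy_codon_fixture <- function() {
  cds <- c(
    t1 = "ATACTAAGATGA",  # ATA CTA AGA TGA -> M L S W
    t2 = "ATGTTAAGCTGG"   # ATG TTA AGC TGG -> M L S W
  )
  aa <- aa_alignment(c(t1 = "MLSW", t2 = "MLSW"))
  list(cds = cds, aa = aa, codon = backtranslate_alignment(aa, cds))
}

expect_tibble_cols <- function(x, cols) {
  testthat::expect_true(all(cols %in% names(x)))
}
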