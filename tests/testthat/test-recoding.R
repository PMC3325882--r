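test_that("all 64 codons translate per the invertebrate mitochondrial code", {
  b <- c("T", "C", "A", "G")
  codons <- apply(expand.grid(b, b, b)[, 3:1], 1, paste, collapse = "")
  got <- vapply(codons, function(cd)
    translate_mito(cd, warn_internal_stop = FALSE), character(1))
  oracle <- Biostrings::getGeneticCode("5")  # independent published table
  expect_equal(unname(got[codons]), unname(oracle[codons]))
  # the table-5 signatures
  expect_equal(translate_mito("ATAAGAAGG"), "MSS")
  expect_equal(translate_mito("TGA"), "W")
})

test_that("ambiguity and truncation rules hold in translation", {
  expect_equal(translate_mito("ATNA"), "X")  # N codon -> X, trailing base dropped
  expect_equal(translate_mito("AT"), "")
  expect_equal(translate_mito("---ATG"), "-M")
  expect_warning(translate_mito("ATGTAAATG"), "internal stop")
})

test_that("back-translation expands amino-acid columns to codons", {
  out <- backtranslate_alignment(aa_alignment(c(t1 = "M-S")),
                                 c(t1 = "ATAAGA"))
  expect_equal(unname(out$seq["t1"]), "ATA---AGA")
  expect_s3_class(out, "codon_alignment")
  # a trailing stop codon in the CDS is tolerated
  out2 <- backtranslate_alignment(aa_alignment(c(t1 = "MS")),
                                  c(t1 = "ATAAGATAA"))
  expect_equal(unname(out2$seq["t1"]), "ATAAGA")
})

test_that("back-translation rejects mismatched coding sequences", {
  expect_error(
    backtranslate_alignment(aa_alignment(c(t1 = "MW")), c(t1 = "ATAAGA")),
    "t1.*column 2"
  )
  expect_error(
    backtranslate_alignment(aa_alignment(c(t1 = "MSS")), c(t1 = "ATAAGA")),
    "codons"
  )
})

test_that("back-translation round-trips synthetic coding sequences", {
  sim <- simulate_genome(seed = 7)
  g <- sim$genome
  set.seed(7)
  for (gn in c("CO1", "ND3", "ATP8")) {
    cds <- extract_gene_sequence(g, gn)
    # terminal stop stripped; incidental interior stops stay as tolerated `*`
    aa <- sub("\\*$", "", translate_mito(cds, warn_internal_stop = FALSE))
    # scatter gap columns into a two-row alignment of the same gene
    chars <- strsplit(aa, "")[[1]]
    gappy <- character(length(chars) + 4)
    at <- sort(sample(seq_along(gappy), 4))
    gappy[at] <- "-"
    gappy[-at] <- chars
    aln <- aa_alignment(stats::setNames(
      rep(paste(gappy, collapse = ""), 2), c("tx_a", "tx_b")
    ))
    cod <- backtranslate_alignment(aln, c(tx_a = cds, tx_b = cds))
    stripped <- gsub("-", "", cod$seq)
    expect_equal(unname(stripped[["tx_a"]]),
                 substr(cds, 1, nchar(cds) - 3))
    # gap codons are all-or-nothing and sit where the residue gaps were
    cods <- substring(cod$seq[["tx_b"]],
                      seq(1, nchar(cod$seq[["tx_b"]]), 3),
                      seq(3, nchar(cod$seq[["tx_b"]]), 3))
    expect_true(all(cods[at] == "---"))
    expect_false(any(cods[-at] == "---"))
  }
})

test_that("RY recoding hits the selected positions only and is idempotent", {
  aln <- codon_alignment(c(t1 = "ACGTAT", t2 = "GGC---"))
  r3 <- ry_recode(aln, 3)
  expect_equal(unname(r3$seq), c("ACRTAY", "GGY---"))
  expect_equal(r3$alphabet, "mixed_nt_RY")
  r123 <- ry_recode(aln, 1:3)
  expect_equal(unname(r123$seq["t1"]), "RYRYRY")
  expect_equal(r123$alphabet, "RY")
  # idempotence
  again <- ry_recode(codon_alignment(r123$seq, r123$partitions), 1:3)
  expect_equal(again$seq, r123$seq)
  # ambiguity codes become ?
  expect_equal(unname(ry_recode(codon_alignment(c(t1 = "AANTTN")), 3)$seq),
               "AA?TT?")
  expect_error(ry_recode(aln, integer(0)), "non-empty")
})

test_that("RY recoding commutes with taxon and codon-column subsetting", {
  set.seed(15)
  seqs <- vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("t", 1:4)
  aln <- codon_alignment(seqs)
  rec <- ry_recode(aln, c(1, 3))
  # taxon subsetting
  sub <- ry_recode(codon_alignment(seqs[c("t2", "t4")]), c(1, 3))
  expect_equal(sub$seq, rec$seq[c("t2", "t4")])
  # codon-column subsetting (codons 4..7 = nucleotides 10..21)
  cut <- function(v) vapply(v, function(s) substr(s, 10, 21), character(1))
  sub2 <- ry_recode(codon_alignment(cut(seqs)), c(1, 3))
  expect_equal(unname(sub2$seq), unname(cut(rec$seq)))
})

test_that("RY recoding anticommutes with reverse complement", {
  set.seed(16)
  s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  lhs <- ry_recode(codon_alignment(c(x = revcomp(s))), 1:3)$seq[["x"]]
  rhs0 <- ry_recode(codon_alignment(c(x = s)), 1:3)$seq[["x"]]
  swapped <- chartr("RY", "YR", rhs0)
  rhs <- paste(rev(strsplit(swapped, "")[[1]]), collapse = "")
  expect_equal(lhs, rhs)
})

test_that("NTE recoding targets 3rd positions plus neutral-transition 1st positions", {
  # leucine column (CTA/TTA): 1st position recoded
  leu <- codon_alignment(c(t1 = "CTA", t2 = "TTA"))
  out <- nte_recode(leu)
  expect_equal(unname(out$seq), c("YTR", "YTR"))
  # methionine column: only 3rd position recoded
  met <- codon_alignment(c(t1 = "ATG", t2 = "ATA"))
  expect_equal(unname(nte_recode(met)$seq), c("ATR", "ATR"))
  # arginine CGN column: 1st position recoded under the default predicate
  arg <- codon_alignment(c(t1 = "CGA", t2 = "CGG"))
  expect_equal(unname(nte_recode(arg)$seq), c("YGR", "YGR"))
  # mixed Leu/other column: 1st position left alone
  mixed <- codon_alignment(c(t1 = "CTA", t2 = "ATA"))
  expect_equal(unname(nte_recode(mixed)$seq), c("CTR", "ATR"))
})

test_that("NTE never recodes 2nd positions and reduces to RY3 without L/R codons", {
  set.seed(17)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("t", 1:5)
  aln <- codon_alignment(seqs)
  out <- nte_recode(aln)
  pos2 <- lapply(out$seq, function(s)
    strsplit(s, "")[[1]][seq(2, nchar(s), 3)])
  expect_false(any(unlist(pos2) %in% c("R", "Y")))
  # an alignment of non-L/R codons reduces to ry_recode at 3rd positions
  noLR <- codon_alignment(c(t1 = "ATGGGCAAATAC", t2 = "GTGGCCAATTAT"))
  expect_equal(nte_recode(noLR)$seq, ry_recode(noLR, 3)$seq)
  # the predicate is swappable
  all3 <- nte_recode(aln, predicate = function(codons) TRUE)
  pos1 <- lapply(all3$seq, function(s)
    strsplit(s, "")[[1]][seq(1, nchar(s), 3)])
  expect_true(all(unlist(pos1) %in% c("R", "Y")))
})

test_that("physiochemical recoding partitions the 20 residues into 6 groups", {
  residues <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  out <- physiochemical_recode(
    aa_alignment(c(t = paste(residues, collapse = "")))
  )
  sym <- strsplit(out$seq[["t"]], "")[[1]]
  expect_setequal(unique(sym), c("h", "a", "s", "d", "b", "c"))
  # total map: every residue got a group symbol
  expect_equal(length(sym), 20)
  expect_false(any(sym == "?"))
  # the published group memberships
  expect_equal(unique(sym[residues %in% c("V", "L", "I", "M")]), "h")
  expect_equal(unique(sym[residues %in% c("F", "Y", "W")]), "a")
  expect_equal(unique(sym[residues %in% c("S", "T", "A", "P", "G")]), "s")
  expect_equal(unique(sym[residues %in% c("D", "E", "N", "Q")]), "d")
  expect_equal(unique(sym[residues %in% c("H", "R", "K")]), "b")
  expect_equal(sym[residues == "C"], "c")
})

test_that("physiochemical recoding preserves shape and gap pattern", {
  aln <- aa_alignment(c(t1 = "MV-LX*", t2 = "--CW-F"))
  out <- physiochemical_recode(aln)
  expect_equal(nchar(out$seq), nchar(aln$seq))
  expect_equal(gsub("[^-]", "x", out$seq), gsub("[^-]", "x", aln$seq))
  expect_equal(unname(out$seq), c("hh-h??", "--ca-a"))
  expect_error(physiochemical_recode(aa_alignment(c(t1 = "MJ"))), "unknown")
})

test_that("concatenation tracks partitions and gap-fills absent taxa", {
  a1 <- aa_alignment(c(t1 = "MKGHAW", t2 = "MKGH-W"))
  a2 <- aa_alignment(c(t1 = "VVIPPLMKV", t3 = "VVIPPLMKW"))
  expect_message(sup <- concatenate_partitions(list(g1 = a1, g2 = a2)),
                 "absent")
  expect_equal(nchar(sup$seq[["t1"]]), 15)
  expect_equal(sup$partitions$gene, c("g1", "g2"))
  expect_equal(sup$partitions$start, c(1L, 7L))
  expect_equal(sup$partitions$end, c(6L, 15L))
  expect_equal(substr(sup$seq[["t3"]], 1, 6), "------")
  expect_equal(substr(sup$seq[["t2"]], 7, 15), "---------")
  # shuffling gene order permutes partitions but not per-gene content
  sup2 <- suppressMessages(concatenate_partitions(list(g2 = a2, g1 = a1)))
  slice <- function(sup, gene, taxon) {
    p <- sup$partitions[sup$partitions$gene == gene, ]
    substr(sup$seq[[taxon]], p$start, p$end)
  }
  for (gn in c("g1", "g2")) {
    for (tx in c("t1", "t2", "t3")) {
      expect_equal(slice(sup, gn, tx), slice(sup2, gn, tx))
    }
  }
  # inconsistent alphabets refuse to concatenate
  ry <- ry_recode(codon_alignment(c(t1 = "ACGACG")), 1:3)
  expect_error(concatenate_partitions(list(g1 = a1, g2 = ry)),
               "alphabet")
})

test_that("recoded matrices round-trip through FASTA and relaxed PHYLIP", {
  aln <- nte_recode(codon_alignment(c(
    taxon_one = "CTAATGGGATTA", taxon_two = "TTAATAGGcCTA"
  )))
  fa <- withr::local_tempfile(fileext = ".fasta")
  ph <- withr::local_tempfile(fileext = ".phy")
  write_fasta_alignment(aln, fa)
  write_phylip_alignment(aln, ph)
  back_fa <- read_fasta_alignment(fa, alphabet = aln$alphabet)
  back_ph <- read_phylip_alignment(ph, alphabet = aln$alphabet)
  expect_equal(back_fa$seq, aln$seq)
  expect_equal(back_ph$seq, aln$seq)
  expect_equal(back_fa$alphabet, aln$alphabet)
  # partition file dialect
  pf <- withr::local_tempfile(fileext = ".txt")
  write_partition_file(tibble::tibble(gene = c("CO1", "ND5"),
                                      start = c(1L, 10L), end = c(9L, 24L)),
                       pf)
  expect_equal(readLines(pf), c("CO1 = 1-9", "ND5 = 10-24"))
})
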