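#' Canonical mitochondrial gene names
#'
#' The 37 canonical metazoan mitochondrial genes (13 protein-coding genes,
#' 22 tRNAs, 2 rRNAs) plus `CONTROL_REGION`, with their categories. The two
#' serine and leucine tRNAs are distinguished by anticodon family:
#' `trnL1` = Leu(CUN), `trnL2` = Leu(UUR), `trnS1` = Ser(AGN),
#' `trnS2` = Ser(UCN).
#'
#' @return A tibble with columns `gene` and `category`
#'   (`PCG`, `tRNA`, `rRNA`, `control`).
#' @export
#' @examples
#' canonical_genes()
canonical_genes <- function() {
  tibble::tibble(
    gene = c(
      "ATP6", "ATP8", "CO1", "CO2", "CO3", "CYTB",
      "ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
      paste0("trn", c(
        "A", "C", "D", "E", "F", "G", "H", "I", "K", "L1", "L2",
        "M", "N", "P", "Q", "R", "S1", "S2", "T", "V", "W", "Y"
      )),
      "rrnL", "rrnS",
      "CONTROL_REGION"
    ),
    category = c(
      rep("PCG", 13), rep("tRNA", 22), rep("rRNA", 2), "control"
    )
  )
}

# amino-acid letter -> canonical tRNA suffix (unambiguous ones only)
.aa_to_trn <- c(
  A = "trnA", C = "trnC", D = "trnD", E = "trnE", F = "trnF", G = "trnG",
  H = "trnH", I = "trnI", K = "trnK", M = "trnM", N = "trnN", P = "trnP",
  Q = "trnQ", R = "trnR", T = "trnT", V = "trnV", W = "trnW", Y = "trnY"
)

.aa3_to_aa1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

# squashed-synonym -> canonical name lookup.  Keys are uppercased with all
# non-alphanumerics removed, so "tRNA-Ser (UCN)" and "trnS2" meet in the
# middle.  Product-style names from GenBank CDS/rRNA features are included.
.gene_synonyms <- local({
  syn <- list(
    ATP6 = c(
      "ATP6", "ATPASE6", "ATP SYNTHASE F0 SUBUNIT 6", "ATP SYNTHASE 6",
      "ATPASE SUBUNIT 6", "ATP SYNTHASE SUBUNIT 6", "MTATP6", "A6"
    ),
    ATP8 = c(
      "ATP8", "ATPASE8", "ATP SYNTHASE F0 SUBUNIT 8", "ATP SYNTHASE 8",
      "ATPASE SUBUNIT 8", "ATP SYNTHASE SUBUNIT 8", "MTATP8", "A8"
    ),
    CO1 = c(
      "CO1", "COI", "COX1", "COXI", "CO 1",
      "CYTOCHROME C OXIDASE SUBUNIT 1", "CYTOCHROME C OXIDASE SUBUNIT I",
      "CYTOCHROME OXIDASE SUBUNIT 1", "CYTOCHROME OXIDASE SUBUNIT I", "MTCO1"
    ),
    CO2 = c(
      "CO2", "COII", "COX2", "COXII",
      "CYTOCHROME C OXIDASE SUBUNIT 2", "CYTOCHROME C OXIDASE SUBUNIT II",
      "CYTOCHROME OXIDASE SUBUNIT 2", "CYTOCHROME OXIDASE SUBUNIT II", "MTCO2"
    ),
    CO3 = c(
      "CO3", "COIII", "COX3", "COXIII",
      "CYTOCHROME C OXIDASE SUBUNIT 3", "CYTOCHROME C OXIDASE SUBUNIT III",
      "CYTOCHROME OXIDASE SUBUNIT 3", "CYTOCHROME OXIDASE SUBUNIT III", "MTCO3"
    ),
    CYTB = c(
      "CYTB", "COB", "CYB", "CYT B", "CYTOCHROME B", "CYTOCHROME-B",
      "CB", "MTCYB"
    ),
    ND1 = c("ND1", "NAD1", "NADH1", "NADH DEHYDROGENASE SUBUNIT 1", "NDH1"),
    ND2 = c("ND2", "NAD2", "NADH2", "NADH DEHYDROGENASE SUBUNIT 2", "NDH2"),
    ND3 = c("ND3", "NAD3", "NADH3", "NADH DEHYDROGENASE SUBUNIT 3", "NDH3"),
    ND4 = c("ND4", "NAD4", "NADH4", "NADH DEHYDROGENASE SUBUNIT 4", "NDH4"),
    ND4L = c(
      "ND4L", "NAD4L", "NADH4L", "NADH DEHYDROGENASE SUBUNIT 4L", "NDH4L"
    ),
    ND5 = c("ND5", "NAD5", "NADH5", "NADH DEHYDROGENASE SUBUNIT 5", "NDH5"),
    ND6 = c("ND6", "NAD6", "NADH6", "NADH DEHYDROGENASE SUBUNIT 6", "NDH6"),
    rrnL = c(
      "RRNL", "16S", "16S RRNA", "16S RIBOSOMAL RNA", "LRRNA", "L-RRNA",
      "LSU RRNA", "LSU", "LARGE SUBUNIT RIBOSOMAL RNA", "RRN16", "MTRNR2",
      "16S LARGE SUBUNIT RIBOSOMAL RNA"
    ),
    rrnS = c(
      "RRNS", "12S", "12S RRNA", "12S RIBOSOMAL RNA", "SRRNA", "S-RRNA",
      "SSU RRNA", "SSU", "SMALL SUBUNIT RIBOSOMAL RNA", "RRN12", "MTRNR1",
      "12S SMALL SUBUNIT RIBOSOMAL RNA"
    ),
    CONTROL_REGION = c(
      "CONTROL REGION", "CONTROLREGION", "D-LOOP", "DLOOP", "CR",
      "A+T RICH REGION", "AT RICH REGION", "AT-RICH REGION",
      "LARGE NON-CODING REGION", "LNR", "PUTATIVE CONTROL REGION"
    ),
    trnL1 = c(
      "TRNL1", "TRNL CUN", "TRNA-LEU CUN", "TRNA LEU CUN", "TRNLEU CUN",
      "L1", "LEU1", "TRNA-LEU1", "TRNL-CUN", "TRNA-LEU(CUN)"
    ),
    trnL2 = c(
      "TRNL2", "TRNL UUR", "TRNA-LEU UUR", "TRNA LEU UUR", "TRNLEU UUR",
      "L2", "LEU2", "TRNA-LEU2", "TRNL-UUR", "TRNA-LEU(UUR)"
    ),
    trnS1 = c(
      "TRNS1", "TRNS AGN", "TRNA-SER AGN", "TRNA SER AGN", "TRNSER AGN",
      "S1", "SER1", "TRNA-SER1", "TRNS-AGN", "TRNA-SER(AGN)", "TRNA-SER AGY",
      "TRNS AGY"
    ),
    trnS2 = c(
      "TRNS2", "TRNS UCN", "TRNA-SER UCN", "TRNA SER UCN", "TRNSER UCN",
      "S2", "SER2", "TRNA-SER2", "TRNS-UCN", "TRNA-SER(UCN)"
    )
  )
  # single-copy tRNAs: trnX, tRNA-Xxx, tRNA-X, bare letter left out (too risky
  # except via explicit "trnX" form)
  for (aa in names(.aa_to_trn)) {
    canon <- .aa_to_trn[[aa]]
    aa3 <- names(.aa3_to_aa1)[.aa3_to_aa1 == aa]
    syn[[canon]] <- c(
      paste0("TRN", aa), paste0("TRNA-", aa3), paste0("TRNA ", aa3),
      paste0("TRNA-", aa), paste0("TRN", aa3), aa3
    )
  }
  squash <- function(x) gsub("[^A-Z0-9]+", "", toupper(x))
  keys <- unlist(lapply(names(syn), function(n) {
    stats::setNames(rep(n, length(syn[[n]])), squash(syn[[n]]))
  }))
  keys[!duplicated(names(keys))]
})

#' Normalize a gene name to its canonical identifier
#'
#' Maps the common synonyms found in GenBank annotations (`COX1`, `COI`,
#' `cytochrome c oxidase subunit I`, `l-rRNA`, `16S`, `tRNA-Ser(UCN)`,
#' `trnS2`, ...) onto the canonical 37-gene vocabulary of
#' [canonical_genes()]. Matching is case-insensitive and ignores punctuation.
#' Unmappable names are passed through unchanged with `category = "other"`
#' and a warning.
#'
#' @param raw Character vector of gene labels.
#' @param warn Warn on unmappable names? Default `TRUE`.
#' @return A tibble with columns `input`, `gene`, `category`.
#' @export
#' @examples
#' normalize_gene_name(c("COX1", "tRNA-Ser(UCN)", "l-rRNA"))
normalize_gene_name <- function(raw, warn = TRUE) {
  stopifnot(is.character(raw))
  squash <- gsub("[^A-Z0-9]+", "", toupper(raw))
  canon <- unname(.gene_synonyms[squash])
  unknown <- is.na(canon)
  # recognized non-canonical annotations: no canonical name, but no warning
  known_other <- squash %in% c("REPEATREGION", "REPORIGIN", "ORIGIN",
                               "MISCFEATURE", "NCR", "INTERGENICSPACER")
  unknown <- unknown & !known_other
  if (any(unknown) && warn) {
    warning(
      "unrecognized gene name(s), kept with category 'other': ",
      paste(unique(raw[unknown]), collapse = ", "),
      call. = FALSE
    )
  }
  canon[is.na(canon)] <- raw[is.na(canon)]
  reg <- canonical_genes()
  cat_lookup <- stats::setNames(reg$category, reg$gene)
  category <- unname(cat_lookup[canon])
  category[is.na(category)] <- "other"
  tibble::tibble(input = raw, gene = canon, category = category)
}

# internal scalar helpers
.gene_category <- function(gene) {
  reg <- canonical_genes()
  out <- reg$category[match(gene, reg$gene)]
  out[is.na(out)] <- "other"
  out
}

.is_canonical <- function(gene) gene %in% canonical_genes()$gene
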