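#' Tally nucleotides in a sequence
#'
#' Exact counts of `A`, `C`, `G`, `T`; every other character (ambiguity
#' codes, gaps) is counted as `ambiguous`.
#'
#' @param seq Single nucleotide string (case-insensitive).
#' @return One-row tibble with columns `A`, `C`, `G`, `T`, `ambiguous`.
#' @export
#' @examples
#' count_nucleotides("AACGT")
count_nucleotides <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  s <- toupper(seq)
  n <- nchar(s)
  a <- stringr::str_count(s, stringr::fixed("A"))
  c_ <- stringr::str_count(s, stringr::fixed("C"))
  g <- stringr::str_count(s, stringr::fixed("G"))
  t_ <- stringr::str_count(s, stringr::fixed("T"))
  tibble::tibble(
    A = a, C = c_, G = g, T = t_,
    ambiguous = n - a - c_ - g - t_
  )
}

#' Complement a nucleotide count table
#'
#' Swaps `A` with `T` and `C` with `G`; `ambiguous` is unchanged. This is
#' the count-level equivalent of reading the opposite strand, used so that
#' skew for minor-strand genes is expressed in their own reading
#' orientation.
#'
#' @param counts Data frame with columns `A`, `C`, `G`, `T` (and optionally
#'   `ambiguous`); extra columns are preserved.
#' @return The complemented counts.
#' @export
complement_counts <- function(counts) {
  out <- tibble::as_tibble(counts)
  stopifnot(all(c("A", "C", "G", "T") %in% names(out)))
  tmp <- out$A; out$A <- out$T; out$T <- tmp
  tmp <- out$C; out$C <- out$G; out$G <- tmp
  out
}

#' AT and CG skew of nucleotide counts
#'
#' AT skew = (A - T)/(A + T); CG skew = (C - G)/(C + G). A component is
#' undefined (`NA`) when its denominator is zero. Ambiguous characters are
#' excluded from both numerator and denominator. Positive values indicate an
#' excess of A (or C) on the examined strand.
#'
#' @param counts Data frame with columns `A`, `C`, `G`, `T` (row-wise).
#' @return Tibble with columns `at_skew`, `cg_skew` (one row per input row).
#' @export
#' @examples
#' nucleotide_skew(count_nucleotides("AACG"))
nucleotide_skew <- function(counts) {
  counts <- tibble::as_tibble(counts)
  at <- counts$A + counts$T
  cg <- counts$C + counts$G
  tibble::tibble(
    at_skew = ifelse(at > 0, (counts$A - counts$T) / at, NA_real_),
    cg_skew = ifelse(cg > 0, (counts$C - counts$G) / cg, NA_real_)
  )
}

#' Nucleotide counts by codon position
#'
#' Splits a coding sequence (already in reading orientation, starting at
#' codon position 1) into the three codon positions and tallies each. A
#' trailing partial codon (length not divisible by 3, e.g. a truncated stop
#' codon completed by polyadenylation) is dropped with a message.
#'
#' @param cds Single nucleotide string.
#' @param quiet Suppress the partial-codon message?
#' @return Tibble with columns `position` (1,2,3), `A`, `C`, `G`, `T`,
#'   `ambiguous`.
#' @export
#' @examples
#' codon_position_counts("ATGAAA")
codon_position_counts <- function(cds, quiet = FALSE) {
  stopifnot(is.character(cds), length(cds) == 1)
  n <- nchar(cds)
  keep <- n - n %% 3L
  if (keep < n && !quiet) {
    message("dropping trailing partial codon (", n %% 3L, " nt)")
  }
  chars <- strsplit(substr(toupper(cds), 1, keep), "", fixed = TRUE)[[1]]
  pos <- rep_len(1:3, keep)
  dplyr::bind_cols(
    tibble::tibble(position = 1:3),
    dplyr::bind_rows(lapply(1:3, function(p) {
      count_nucleotides(paste(chars[pos == p], collapse = ""))
    }))
  )
}

#' Per-gene, per-codon-position skew table
#'
#' For every protein-coding gene the sequence is extracted in reading
#' orientation (minor-strand genes reverse-complemented, which realises the
#' complement rule for minor-strand skew), split by codon position, and
#' tallied; rRNA, tRNA and control features get a single `"all"` row. Two
#' summary rows are appended: `all-PCG` (counts pooled across all PCGs per
#' position and overall) and `genome` (the entire major strand read once,
#' overlapping genes not double-counted).
#'
#' @param genome An annotated [mito_genome()] with at least one PCG.
#' @param quiet Suppress partial-codon messages?
#' @return A tibble of class `skew_tbl` with columns `gene`, `category`,
#'   `strand`, `position` (`"1"`, `"2"`, `"3"`, `"all"`), `A`, `C`, `G`,
#'   `T`, `ambiguous`, `at_skew`, `cg_skew`, in genome gene order.
#' @export
gene_skew_table <- function(genome, quiet = TRUE) {
  stopifnot(inherits(genome, "mito_genome"))
  f <- genome$features[order(genome$features$start), ]
  f <- f[f$category != "other", ]
  if (!any(f$category == "PCG")) {
    stop("genome has no annotated protein-coding gene", call. = FALSE)
  }
  rows <- purrr::pmap(f, function(gene, category, start, end, strand) {
    seq <- extract_gene_sequence(
      genome, tibble::tibble(start = start, end = end, strand = strand)
    )
    if (category == "PCG") {
      if (nchar(seq) < 3) {
        warning("PCG ", gene, " shorter than one codon; skipped",
                call. = FALSE)
        return(NULL)
      }
      pos <- codon_position_counts(seq, quiet = quiet)
      all_row <- dplyr::summarise(
        pos, dplyr::across(c(A, C, G, T, ambiguous), sum)
      )
      counts <- dplyr::bind_rows(
        dplyr::mutate(pos, position = as.character(position)),
        dplyr::mutate(all_row, position = "all")
      )
    } else {
      counts <- dplyr::mutate(count_nucleotides(seq), position = "all")
    }
    dplyr::mutate(counts, gene = gene, category = category, strand = strand)
  })
  tab <- dplyr::bind_rows(rows)

  pcg <- tab[tab$category == "PCG", ]
  pooled <- dplyr::summarise(
    dplyr::group_by(pcg, position),
    dplyr::across(c(A, C, G, T, ambiguous), sum), .groups = "drop"
  )
  pooled <- dplyr::mutate(pooled, gene = "all-PCG", category = "summary",
                          strand = "major")
  genome_counts <- dplyr::mutate(
    count_nucleotides(genome$sequence),
    position = "all", gene = "genome", category = "summary", strand = "major"
  )
  tab <- dplyr::bind_rows(tab, pooled, genome_counts)
  tab <- dplyr::bind_cols(tab, nucleotide_skew(tab))
  tab <- dplyr::select(
    tab, gene, category, strand, position, A, C, G, T, ambiguous,
    at_skew, cg_skew
  )
  class(tab) <- c("skew_tbl", class(tab))
  attr(tab, "taxon") <- genome$taxon
  tab
}

#' Pooled skew across protein-coding genes
#'
#' Sums nucleotide counts (not per-gene skews) across all PCG rows of a
#' skew table at the requested codon position, then applies the skew formula
#' once. `mode = "mean"` instead averages the per-gene skew values
#' unweighted, as a sensitivity analysis.
#'
#' @param table A `skew_tbl` from [gene_skew_table()].
#' @param position `"1"`, `"2"`, `"3"` or `"all"`.
#' @param mode `"pooled"` (default) or `"mean"`.
#' @return One-row tibble with `at_skew`, `cg_skew`.
#' @export
pooled_skew <- function(table, position = "3",
                        mode = c("pooled", "mean")) {
  mode <- match.arg(mode)
  position <- as.character(position)
  rows <- table[table$category == "PCG" & table$position == position, ]
  if (nrow(rows) == 0) stop("no PCG rows at position ", position,
                            call. = FALSE)
  if (mode == "pooled") {
    nucleotide_skew(
      dplyr::summarise(rows, dplyr::across(c(A, C, G, T), sum))
    )
  } else {
    tibble::tibble(
      at_skew = mean(rows$at_skew, na.rm = TRUE),
      cg_skew = mean(rows$cg_skew, na.rm = TRUE)
    )
  }
}

#' Whole-major-strand AT content and skew
#'
#' Computed on the entire deposited (major-strand) sequence.
#' `at_content = (A+T)/(A+C+G+T)`, ambiguous characters excluded.
#'
#' @param genome A [mito_genome()].
#' @return One-row tibble: `at_content`, `at_skew`, `cg_skew`.
#' @export
genome_strand_skew <- function(genome) {
  stopifnot(inherits(genome, "mito_genome"))
  counts <- count_nucleotides(genome$sequence)
  tot <- counts$A + counts$C + counts$G + counts$T
  dplyr::bind_cols(
    tibble::tibble(at_content = (counts$A + counts$T) / tot),
    nucleotide_skew(counts)
  )
}

#' Classify third-position skew into bias categories
#'
#' Using the conventional threshold of +/- 0.2: `none` when both |AT| and
#' |CG| skew are within the threshold; `CA` when at least one component
#' exceeds +threshold and none falls below -threshold (excess C and/or A);
#' `GT` for the mirror case; `mixed` when the two components exceed the
#' threshold in opposite directions.
#'
#' @param at_skew,cg_skew Numeric vectors (third-position skews).
#' @param threshold Non-skew band half-width, default 0.2.
#' @return Character vector over `{"CA","GT","none","mixed"}`.
#' @export
#' @examples
#' classify_skew_category(0.1, 0.15)   # none
#' classify_skew_category(-0.5, -0.3)  # GT
classify_skew_category <- function(at_skew, cg_skew, threshold = 0.2) {
  if (anyNA(at_skew) || anyNA(cg_skew)) {
    stop("skew components must be defined for classification", call. = FALSE)
  }
  up <- (at_skew > threshold) | (cg_skew > threshold)
  down <- (at_skew < -threshold) | (cg_skew < -threshold)
  dplyr::case_when(
    up & down ~ "mixed",
    up ~ "CA",
    down ~ "GT",
    .default = "none"
  )
}

#' Write a skew table as TSV
#'
#' Fixed column order and 4-decimal float formatting so repeated runs are
#' byte-identical.
#'
#' @param table A `skew_tbl`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_skew_table <- function(table, path) {
  out <- dplyr::mutate(
    tibble::as_tibble(table),
    dplyr::across(c(at_skew, cg_skew), ~ sprintf("%.4f", .x))
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Plot per-gene skew in genome order
#'
#' Bar chart of AT and CG skew per gene and codon position, genes in genome
#' order, styled after the classic per-gene skew panels.
#'
#' @param object A `skew_tbl` from [gene_skew_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.skew_tbl <- function(object, ...) {
  d <- object[object$category == "PCG", ]
  d$gene <- factor(d$gene, levels = unique(d$gene))
  d <- tidyr::pivot_longer(
    d, c("at_skew", "cg_skew"),
    names_to = "measure", values_to = "skew"
  )
  d$measure <- ifelse(d$measure == "at_skew", "AT skew", "CG skew")
  ggplot2::ggplot(d, ggplot2::aes(x = position, y = skew, fill = measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~gene) +
    ggplot2::scale_fill_manual(values = c("AT skew" = "#2166ac",
                                          "CG skew" = "#b2182b")) +
    ggplot2::labs(x = "codon position", y = "skew", fill = NULL) +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
}
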