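#' Multi-genome skew report
#'
#' Writes one per-genome skew TSV (the [gene_skew_table()] dialect, genes
#' in genome order) plus a cross-taxon matrix with PCGs in alphabetical
#' order, so genes can be compared across otherwise rearranged genomes.
#' Output is deterministic: fixed ordering and 4-decimal float formatting.
#'
#' @param genomes List of [mito_genome()] objects (at least one).
#' @param dir Output directory (created if needed).
#' @param threshold Non-skew band half-width for the bias category column.
#' @return Invisibly, a list with `files` (paths written) and `matrix`
#'   (the cross-taxon tibble).
#' @export
skew_report <- function(genomes, dir, threshold = 0.2) {
  stopifnot(length(genomes) >= 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- purrr::map(genomes, gene_skew_table)
  taxa <- vapply(genomes, function(g) g$taxon, character(1))
  files <- purrr::map2_chr(tables, taxa, function(tab, taxon) {
    path <- file.path(dir, paste0(.slug(taxon), "_skew.tsv"))
    write_skew_table(tab, path)
    path
  })
  mat <- purrr::map2(tables, taxa, function(tab, taxon) {
    d <- tab[tab$category == "PCG", ]
    dplyr::mutate(
      d[base::order(d$gene, d$position),
        c("gene", "strand", "position", "at_skew", "cg_skew")],
      taxon = taxon, .before = 1
    )
  })
  mat <- dplyr::bind_rows(mat)
  wide <- tidyr::pivot_wider(
    mat,
    names_from = c("gene", "position"),
    values_from = c("at_skew", "cg_skew", "strand"),
    names_glue = "{gene}.p{position}.{.value}",
    names_vary = "slowest"
  )
  # taxon-level third-position bias category
  cat3 <- purrr::map2(tables, taxa, function(tab, taxon) {
    s <- pooled_skew(tab, "3")
    tibble::tibble(taxon = taxon, at_skew3 = s$at_skew, cg_skew3 = s$cg_skew,
                   category = classify_skew_category(s$at_skew, s$cg_skew,
                                                     threshold))
  })
  wide <- dplyr::left_join(dplyr::bind_rows(cat3), wide, by = "taxon")
  matrix_path <- file.path(dir, "skew_matrix.tsv")
  out <- dplyr::mutate(
    wide, dplyr::across(dplyr::where(is.numeric), ~ sprintf("%.4f", .x))
  )
  readr::write_tsv(out, matrix_path)
  invisible(list(files = c(files, matrix_path), matrix = wide))
}

.slug <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

.skew_colors <- c(CA = "blue", GT = "red", none = "purple", mixed = "grey")

#' Annotate a Newick tree with skew bias categories
#'
#' Emits the input topology unchanged -- token for token, apart from
#' inserted leaf comments -- with each annotated leaf tagged
#' `[&category=...,color=...]` (blue = CA bias, red = GT bias,
#' purple = no strong skew, grey = mixed), plus a leaf-table TSV. The tree
#' is never re-estimated.
#'
#' @param newick Path to a Newick file.
#' @param annotations Tibble with columns `taxon` and `category` (from
#'   [classify_skew_category()]).
#' @param output Output path for the annotated Newick; the leaf table is
#'   written next to it with suffix `_leaves.tsv`.
#' @return Invisibly, paths written.
#' @export
tree_annotate <- function(newick, annotations, output) {
  txt <- paste(readLines(newick, warn = FALSE), collapse = "\n")
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse Newick input", call. = FALSE)
  leaves <- tree$tip.label
  if (nrow(annotations) == 0) {
    warning("empty annotation list; topology passed through unchanged",
            call. = FALSE)
  }
  ann <- dplyr::mutate(tibble::as_tibble(annotations),
                       taxon = stringr::str_squish(taxon))
  unmatched <- setdiff(ann$taxon, leaves)
  if (length(unmatched)) {
    near <- purrr::map_chr(unmatched, function(u) {
      d <- utils::adist(u, leaves, ignore.case = TRUE)
      paste0(u, " (nearest: ", leaves[which.min(d)], ")")
    })
    stop("annotated taxa not found among tree leaves: ",
         paste(near, collapse = "; "), call. = FALSE)
  }
  out <- txt
  for (i in seq_len(nrow(ann))) {
    tag <- sprintf("[&category=%s,color=%s]", ann$category[i],
                   .skew_colors[[ann$category[i]]])
    # leaf labels are followed by one of : , ) ;
    out <- stringr::str_replace(
      out,
      paste0("(?<![A-Za-z0-9_.])", stringr::str_escape(ann$taxon[i]),
             "(?=[:,);])"),
      paste0(ann$taxon[i], tag)
    )
  }
  writeLines(out, output)
  leaf_path <- sub("\\.[^.]*$", "", output)
  leaf_path <- paste0(leaf_path, "_leaves.tsv")
  leaf_tab <- tibble::tibble(taxon = leaves)
  leaf_tab <- dplyr::left_join(leaf_tab, ann, by = "taxon")
  if ("category" %in% names(leaf_tab)) {
    leaf_tab$color <- unname(.skew_colors[leaf_tab$category])
  }
  readr::write_tsv(leaf_tab, leaf_path)
  invisible(c(newick = output, leaves = leaf_path))
}

#' Per-taxon third-position skew annotation
#'
#' Convenience wrapper producing the input [tree_annotate()] expects from a
#' list of genomes: pooled third-position skews and the resulting bias
#' category per taxon.
#'
#' @param genomes List of [mito_genome()] objects.
#' @param threshold Non-skew band half-width, default 0.2.
#' @param mode Pooling mode passed to [pooled_skew()].
#' @return Tibble `taxon`, `at_skew3`, `cg_skew3`, `category`.
#' @export
taxon_skew_annotation <- function(genomes, threshold = 0.2,
                                  mode = "pooled") {
  purrr::map(genomes, function(g) {
    s <- pooled_skew(gene_skew_table(g), "3", mode = mode)
    tibble::tibble(
      taxon = g$taxon, at_skew3 = s$at_skew, cg_skew3 = s$cg_skew,
      category = classify_skew_category(s$at_skew, s$cg_skew, threshold)
    )
  }) |> dplyr::bind_rows()
}
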