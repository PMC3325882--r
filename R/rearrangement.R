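#' The ancestral chelicerate gene arrangement
#'
#' The horseshoe-crab-type arrangement of the 37 mitochondrial genes plus
#' control region shared by Xiphosura and several arachnid orders, used as
#' the comparison reference for rearrangement analysis. Its major strand
#' carries 9 protein-coding genes and 13 tRNA genes. Shipped as a versioned
#' data file (`inst/extdata/ancestral_chelicerate_order.tsv`) rather than
#' hard-coded.
#'
#' @param include_control Keep the control region as a positional marker?
#'   Default `TRUE`.
#' @return A [gene_order_spec()] anchored at CO1.
#' @export
#' @examples
#' anc <- ancestral_chelicerate_order()
#' table(anc$strand)
ancestral_chelicerate_order <- function(include_control = TRUE) {
  path <- system.file("extdata", "ancestral_chelicerate_order.tsv",
                      package = "mitoarch", mustWork = TRUE)
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!include_control) tab <- tab[tab$gene != "CONTROL_REGION", ]
  gene_order_spec(tab$gene, tab$strand, anchor = "CO1")
}

#' Compare a gene order against a reference arrangement
#'
#' Classifies every gene shared by the two circular orders as `ancestral`,
#' `translocated`, `inverted_in_place` or `translocated_and_inverted`;
#' genes present in only one order are `absent`. Location and strand are
#' scored as independent axes.
#'
#' Two location criteria are available. In `neighbor_pair` mode (default) a
#' gene is ancestral in location iff its ordered (upstream, downstream)
#' neighbors on the circle of shared genes match the reference; this is
#' local, so one moved gene also disturbs the pair context of its old and
#' new flanking genes. In `shared_block` mode both orders are contracted
#' into maximal shared synteny blocks (signed, circular) and the smallest
#' set of blocks whose removal reconciles the two circles is reported as
#' moved; genes inside a block inherit the block status, so a clean
#' translocation of k genes flags exactly those k genes.
#'
#' Both modes are rotation-invariant. By default the control region and
#' non-canonical features are excluded from the neighbor context.
#'
#' @param query,reference `gene_order` objects (see [gene_order()],
#'   [gene_order_spec()], [ancestral_chelicerate_order()]).
#' @param mode `"neighbor_pair"` or `"shared_block"`.
#' @param include_control Include the control region in the comparison?
#'   Default `FALSE` (gene locations are counted among the 37 genes).
#' @param reference_label Label recorded on the result.
#' @param relabel Optional named character vector renaming query genes
#'   before comparison (e.g. `c(trnM = "trnQ")` to tolerate an ambiguous
#'   tRNA-Gln / tRNA-Met annotation).
#' @param max_deletion_set Search bound for `shared_block` mode: maximum
#'   number of blocks considered removable. Default 8.
#' @return A tibble of class `arrangement_cmp` with columns `gene`,
#'   `category`, `reference_strand`, `query_strand`, `status`, and
#'   attributes `mode` and `reference`.
#' @export
compare_arrangements <- function(query, reference = ancestral_chelicerate_order(),
                                 mode = c("neighbor_pair", "shared_block"),
                                 include_control = FALSE,
                                 reference_label = "reference",
                                 relabel = NULL,
                                 max_deletion_set = 8) {
  mode <- match.arg(mode)
  stopifnot(inherits(query, "gene_order"), inherits(reference, "gene_order"))
  q <- tibble::as_tibble(query)
  r <- tibble::as_tibble(reference)
  if (!is.null(relabel)) {
    hit <- q$gene %in% names(relabel)
    q$gene[hit] <- unname(relabel[q$gene[hit]])
  }
  if (!include_control) {
    q <- q[q$gene != "CONTROL_REGION", ]
    r <- r[r$gene != "CONTROL_REGION", ]
  }
  q <- q[.is_canonical(q$gene) | q$gene == "CONTROL_REGION", ]
  r <- r[.is_canonical(r$gene) | r$gene == "CONTROL_REGION", ]
  if (anyDuplicated(q$gene) || anyDuplicated(r$gene)) {
    stop("duplicate genes in order", call. = FALSE)
  }
  shared <- intersect(q$gene, r$gene)
  if (length(shared) < 3) stop("need at least 3 shared genes", call. = FALSE)
  qs <- q[q$gene %in% shared, ]
  rs <- r[r$gene %in% shared, ]

  loc_moved <- switch(mode,
    neighbor_pair = .np_moved(qs, rs),
    shared_block = .sb_moved(qs, rs, max_deletion_set)
  )
  strand_flip <- qs$strand != rs$strand[match(qs$gene, rs$gene)]
  status <- dplyr::case_when(
    loc_moved & strand_flip ~ "translocated_and_inverted",
    loc_moved ~ "translocated",
    strand_flip ~ "inverted_in_place",
    .default = "ancestral"
  )
  out <- tibble::tibble(
    gene = qs$gene,
    category = .gene_category(qs$gene),
    reference_strand = rs$strand[match(qs$gene, rs$gene)],
    query_strand = qs$strand,
    status = status
  )
  absent <- union(setdiff(q$gene, shared), setdiff(r$gene, shared))
  if (length(absent)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      gene = absent,
      category = .gene_category(absent),
      reference_strand = r$strand[match(absent, r$gene)],
      query_strand = q$strand[match(absent, q$gene)],
      status = "absent"
    ))
  }
  class(out) <- c("arrangement_cmp", class(out))
  attr(out, "mode") <- mode
  attr(out, "reference") <- reference_label
  out
}

# circular neighbors by canonical name: for each gene its (upstream,
# downstream) pair must match the reference
.np_moved <- function(qs, rs) {
  nbr <- function(ord) {
    n <- nrow(ord)
    up <- ord$gene[c(n, seq_len(n - 1))]
    down <- ord$gene[c(seq_len(n)[-1], 1)]
    stats::setNames(paste(up, down, sep = "|"), ord$gene)
  }
  qn <- nbr(qs)
  rn <- nbr(rs)
  unname(qn[qs$gene] != rn[qs$gene])
}

# shared_block mode: contract into maximal common signed blocks on the
# circle, then brute-force the smallest block deletion set that makes the
# remaining signed circular sequences identical (orientation mismatches in
# the remainder are in-place inversions, handled upstream via strand flags).
.sb_moved <- function(qs, rs, max_deletion_set = 8) {
  n <- nrow(qs)
  rpos <- match(qs$gene, rs$gene)          # reference position of each query gene
  rstr <- rs$strand[rpos]
  flip <- qs$strand != rstr                # strand changed relative to reference

  # adjacency i -> i+1 (circular) stays inside one block when the two genes
  # are also adjacent in the reference in a compatible orientation:
  #   forward: ref positions consecutive, neither flipped or both not flipped
  #   reversed: ref positions reverse-consecutive, both flipped
  nref <- nrow(rs)
  succ <- function(p) p %% nref + 1L
  joined <- logical(n)
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    fwd <- !flip[i] && !flip[j] && succ(rpos[i]) == rpos[j]
    rev_ <- flip[i] && flip[j] && succ(rpos[j]) == rpos[i]
    joined[i] <- fwd || rev_
  }
  if (all(joined)) return(rep(FALSE, n))   # identical up to rotation/inversion

  # cut circle at block boundaries
  cuts <- which(!joined)                   # boundary after position i
  block_id <- integer(n)
  bid <- 0L
  start <- cuts[length(cuts)] %% n + 1L    # first block starts after last cut
  i <- start
  repeat {
    bid <- bid + 1L
    repeat {
      block_id[i] <- bid
      if (!joined[i]) break
      i <- i %% n + 1L
    }
    i <- i %% n + 1L
    if (i == start) break
  }
  nb <- bid
  # block order around the query circle, starting from block at `start`
  blocks <- split(seq_len(n), block_id)    # query row indices per block
  # representative: first query index of block in circular walk
  walk <- ((start - 1L + seq_len(n) - 1L) %% n) + 1L
  block_seq <- unique(block_id[walk])      # circular order of block ids

  # per-block reference anchor: ref position of first gene, orientation
  b_first <- vapply(block_seq, function(b) {
    idx <- walk[block_id[walk] == b]
    idx[1]
  }, integer(1))
  b_len <- vapply(blocks, length, integer(1))[as.character(block_seq)]
  b_flip <- flip[b_first]                  # whole block shares orientation
  # reference start/end positions of each block (in reference reading order)
  b_rstart <- ifelse(b_flip, rpos[b_first] - b_len + 1L, rpos[b_first])
  b_rstart <- ((b_rstart - 1L) %% nref) + 1L
  b_rend <- ((b_rstart + b_len - 2L) %% nref) + 1L

  # does keeping blocks `keep` (in query circular order) reconcile the two
  # circles?  The kept blocks must appear in the same circular order in the
  # reference.
  ref_order_ok <- function(keep) {
    k <- length(keep)
    if (k <= 1) return(TRUE)
    starts <- b_rstart[keep]
    ends <- b_rend[keep]
    # successive kept blocks must follow each other around the reference
    # circle without overlap and in consistent rotational order
    rel <- ((starts - starts[1]) %% nref)
    if (is.unsorted(rel)) return(FALSE)
    # blocks must not interleave: end of block i must come before start of
    # block i+1 going around from starts[1]
    rel_end <- ((ends - starts[1]) %% nref)
    all(rel_end >= rel) && !is.unsorted(pmax(rel, rel_end)) &&
      all(utils::head(rel_end, -1) < rel[-1])
  }

  ord <- seq_along(block_seq)
  # try deletion sets of increasing size (prefer deleting fewest genes)
  best <- NULL
  max_k <- min(length(ord) - 1L, max_deletion_set)
  for (k in 0:max_k) {
    sets <- utils::combn(ord, k, simplify = FALSE)
    # prefer deleting fewer genes among same-k sets
    if (k > 0) {
      sizes <- vapply(sets, function(s) sum(b_len[s]), numeric(1))
      sets <- sets[order(sizes)]
    }
    for (s in sets) {
      keep <- setdiff(ord, s)
      if (ref_order_ok(keep)) { best <- s; break }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) {
    warning("shared_block search bound reached; falling back to ",
            "neighbor_pair location calls", call. = FALSE)
    return(.np_moved(qs, rs))
  }
  moved_blocks <- block_seq[best]
  moved <- logical(n)
  for (b in moved_blocks) moved[blocks[[as.character(b)]]] <- TRUE
  moved
}

#' Summarize a rearrangement comparison
#'
#' Counts non-ancestral genes by gene class. "Different location" is
#' `translocated` plus `translocated_and_inverted`; strand changes
#' (`inverted_in_place` plus `translocated_and_inverted`) are counted
#' separately, since location and strand are independent axes.
#'
#' @param cmp An `arrangement_cmp` from [compare_arrangements()].
#' @return Tibble with columns `category`, `n_genes`,
#'   `different_location`, `strand_changed`, `ancestral`.
#' @export
summarize_rearrangement <- function(cmp) {
  stopifnot(inherits(cmp, "arrangement_cmp"))
  d <- cmp[cmp$status != "absent" & cmp$category %in% c("PCG", "tRNA", "rRNA"), ]
  dplyr::summarise(
    dplyr::group_by(d, category),
    n_genes = dplyr::n(),
    different_location = sum(status %in%
      c("translocated", "translocated_and_inverted")),
    strand_changed = sum(status %in%
      c("inverted_in_place", "translocated_and_inverted")),
    ancestral = sum(status == "ancestral"),
    .groups = "drop"
  )
}

#' @export
#' @rdname compare_arrangements
#' @param x An `arrangement_cmp`.
#' @param ... Unused.
glance.arrangement_cmp <- function(x, ...) {
  d <- x[x$status != "absent", ]
  tibble::tibble(
    mode = attr(x, "mode"),
    reference = attr(x, "reference"),
    n_shared = nrow(d),
    n_different_location = sum(d$status %in%
      c("translocated", "translocated_and_inverted")),
    n_strand_changed = sum(d$status %in%
      c("inverted_in_place", "translocated_and_inverted")),
    n_ancestral = sum(d$status == "ancestral")
  )
}

#' Write an arrangement comparison report
#'
#' TSV with one row per gene plus a commented per-class summary block.
#'
#' @param cmp An `arrangement_cmp`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_arrangement_report <- function(cmp, path) {
  s <- summarize_rearrangement(cmp)
  hdr <- c(
    paste0("# mode: ", attr(cmp, "mode"), "; reference: ",
           attr(cmp, "reference")),
    sprintf("# %s: %d genes, %d different location, %d strand changed",
            s$category, s$n_genes, s$different_location, s$strand_changed)
  )
  writeLines(hdr, path)
  readr::write_tsv(tibble::as_tibble(cmp), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' Plot an arrangement comparison
#'
#' Linearized gene map colored by rearrangement status (greens for moved
#' genes, yellows for strand changes), mirroring the conventional circular
#' map coloring.
#'
#' @param object An `arrangement_cmp`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.arrangement_cmp <- function(object, ...) {
  d <- object[object$status != "absent", ]
  d$gene <- factor(d$gene, levels = d$gene)
  d$y <- ifelse(d$query_strand == "major", 1, -1)
  ggplot2::ggplot(d, ggplot2::aes(x = gene, y = y, fill = status)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::scale_fill_manual(values = c(
      ancestral = "grey80", translocated = "#4daf4a",
      inverted_in_place = "#ffd92f", translocated_and_inverted = "#a6d854"
    )) +
    ggplot2::labs(x = NULL, y = "strand", fill = "status") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
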