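# run code under a local RNG seed without disturbing the caller's stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Base-composition specification
#'
#' Parameterizes an i.i.d. nucleotide model by AT content and the two skews.
#' The implied base probabilities are
#' `pA = at * (1 + at_skew) / 2`, `pT = at * (1 - at_skew) / 2`,
#' `pC = (1 - at) * (1 + cg_skew) / 2`, `pG = (1 - at) * (1 - cg_skew) / 2`;
#' the constructor checks they are valid. This is the generative inverse of
#' the skew formulas: sequences drawn from a spec have expected AT/CG skew
#' equal to the spec's values.
#'
#' @param at_content AT fraction in (0, 1) (or exactly 0/1 for degenerate
#'   specs).
#' @param at_skew,cg_skew Skews in \[-1, 1\].
#' @return A `composition_spec` (one-row tibble with the four base
#'   probabilities attached).
#' @export
#' @examples
#' composition_spec(0.75, 0.2, 0.25)
composition_spec <- function(at_content = 0.75, at_skew = 0.2,
                             cg_skew = 0.25) {
  stopifnot(
    length(at_content) == 1, length(at_skew) == 1, length(cg_skew) == 1,
    at_content >= 0, at_content <= 1,
    abs(at_skew) <= 1, abs(cg_skew) <= 1
  )
  p <- c(
    A = at_content * (1 + at_skew) / 2,
    C = (1 - at_content) * (1 + cg_skew) / 2,
    G = (1 - at_content) * (1 - cg_skew) / 2,
    T = at_content * (1 - at_skew) / 2
  )
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-12)
  out <- tibble::tibble(at_content = at_content, at_skew = at_skew,
                        cg_skew = cg_skew)
  attr(out, "prob") <- p
  class(out) <- c("composition_spec", class(out))
  out
}

#' Simulate a nucleotide sequence with specified composition and skew
#'
#' I.i.d. draws from the base probabilities implied by a
#' [composition_spec()]. The same seed always yields the same sequence.
#'
#' @param length Number of bases (>= 1).
#' @param spec A [composition_spec()].
#' @param seed Optional integer seed (local to this call).
#' @return A nucleotide string.
#' @export
simulate_skewed_sequence <- function(length, spec = composition_spec(),
                                     seed = NULL) {
  stopifnot(length >= 1, inherits(spec, "composition_spec"))
  p <- attr(spec, "prob")
  .with_seed(seed, {
    paste(sample(names(p), length, replace = TRUE, prob = p),
          collapse = "")
  })
}

#' Default gene length plan
#'
#' Realistic invertebrate mitochondrial gene lengths (PCG lengths divisible
#' by 3; compact tRNAs and rRNAs in the range reported for pseudoscorpions).
#' Total: 14,724 nt for the 37 genes + control region.
#'
#' @return Named integer vector of lengths, one per canonical gene.
#' @export
default_gene_lengths <- function() {
  pcg <- c(
    ATP6 = 675L, ATP8 = 159L, CO1 = 1539L, CO2 = 684L, CO3 = 789L,
    CYTB = 1137L, ND1 = 936L, ND2 = 1023L, ND3 = 354L, ND4 = 1338L,
    ND4L = 297L, ND5 = 1719L, ND6 = 522L
  )
  trna <- stats::setNames(
    rep(66L, 22),
    grep("^trn", canonical_genes()$gene, value = TRUE)
  )
  c(pcg, trna, rrnL = 1000L, rrnS = 700L, CONTROL_REGION = 400L)
}

#' Default per-class composition specs
#'
#' Non-coding classes share the genome-wide composition (AT 0.75, AT skew
#' 0.20, CG skew 0.25). PCGs get per-codon-position specs emulating the
#' typical arthropod pattern: CA bias at 1st and 3rd positions, a CT bias
#' (negative AT skew) at 2nd positions, and the strongest CG skew at 3rd
#' positions.
#'
#' @return List with elements `tRNA`, `rRNA`, `control`, `other`
#'   ([composition_spec()]s) and `PCG` (list of three specs, one per codon
#'   position).
#' @export
default_class_specs <- function() {
  base <- composition_spec(0.75, 0.2, 0.25)
  list(
    PCG = list(
      composition_spec(0.70, 0.15, 0.20),   # position 1
      composition_spec(0.70, -0.30, 0.10),  # position 2
      composition_spec(0.80, 0.20, 0.50)    # position 3
    ),
    tRNA = base, rRNA = base, control = base, other = base
  )
}

.draw_gene <- function(gene, category, len, specs) {
  if (category == "PCG") {
    stopifnot(len %% 3L == 0L)
    ncod <- len %/% 3L
    pos <- lapply(specs$PCG, function(sp) {
      strsplit(simulate_skewed_sequence(ncod, sp), "", fixed = TRUE)[[1]]
    })
    chars <- as.vector(rbind(pos[[1]], pos[[2]], pos[[3]]))
    # overwrite start and stop codons (6 of `len` bases) so every PCG has a
    # proper reading frame; interior codons stay pure i.i.d. draws -- under
    # AT-rich specs a few percent are incidental stop codons, which the
    # translation layer flags rather than rejects (any rejection scheme
    # would bias the composition the generator is meant to guarantee)
    chars[1:3] <- c("A", "T", "G")
    chars[(len - 2):len] <- c("T", "A", "A")
    paste(chars, collapse = "")
  } else {
    sp <- specs[[category]]
    if (is.null(sp)) sp <- specs$other
    simulate_skewed_sequence(len, sp)
  }
}

#' Simulate an annotated mitochondrial genome
#'
#' Lays the genes of `order` contiguously around a circle. Every gene is
#' drawn in its reading orientation from the spec for its class (so the
#' reading-orientation composition matches the spec); minor-strand genes
#' are then reverse-complemented into the deposited strand. PCGs get an
#' `ATG` start and `TAA` stop overwritten after drawing. Optionally a
#' tandem repeat region (annotated `category = "other"`) is inserted after
#' a named gene.
#'
#' @param order A [gene_order_spec()]; default the ancestral chelicerate
#'   arrangement.
#' @param lengths Named lengths per gene; default [default_gene_lengths()].
#' @param specs Per-class composition specs; default
#'   [default_class_specs()].
#' @param repeat_region `NULL`, or a list with `unit_length`, `copies`,
#'   `after` (gene name). The unit is drawn once and tandem-repeated.
#' @param taxon Taxon label for the genome.
#' @param seed Optional integer seed (local to this call).
#' @param max_length Safety cap on total genome length.
#' @return List with elements `genome` (a [mito_genome()]) and `config`
#'   (tibble echoing the per-gene plan).
#' @export
#' @examples
#' sim <- simulate_genome(seed = 1)
#' sim$genome
simulate_genome <- function(order = ancestral_chelicerate_order(),
                            lengths = default_gene_lengths(),
                            specs = default_class_specs(),
                            repeat_region = NULL,
                            taxon = "synthetic",
                            seed = NULL,
                            max_length = 100000L) {
  stopifnot(inherits(order, "gene_order"))
  .with_seed(seed, {
    genes <- order$gene
    strands <- order$strand
    cats <- .gene_category(genes)
    len <- lengths[genes]
    if (anyNA(len)) {
      stop("no length planned for: ",
           paste(genes[is.na(len)], collapse = ", "), call. = FALSE)
    }
    total <- sum(len) +
      if (!is.null(repeat_region))
        repeat_region$unit_length * repeat_region$copies else 0L
    if (total > max_length) {
      stop("planned genome length ", total, " exceeds cap ", max_length,
           call. = FALSE)
    }
    pieces <- character(0)
    feats <- list()
    pos <- 1L
    add_piece <- function(name, category, seq, strand) {
      pieces[[length(pieces) + 1]] <<- seq
      feats[[length(feats) + 1]] <<- tibble::tibble(
        gene = name, category = category, start = pos,
        end = pos + nchar(seq) - 1L, strand = strand
      )
      pos <<- pos + nchar(seq)
    }
    for (i in seq_along(genes)) {
      reading <- .draw_gene(genes[i], cats[i], len[[i]], specs)
      deposited <- if (strands[i] == "minor") revcomp(reading) else reading
      add_piece(genes[i], cats[i], deposited, strands[i])
      if (!is.null(repeat_region) && genes[i] == repeat_region$after) {
        unit <- simulate_skewed_sequence(repeat_region$unit_length,
                                         specs$other)
        add_piece("repeat_region", "other",
                  strrep(unit, repeat_region$copies), "major")
      }
    }
    genome <- mito_genome(
      paste(pieces, collapse = ""), dplyr::bind_rows(feats),
      taxon = taxon
    )
    config <- dplyr::mutate(genome$features,
                            length = end - start + 1L, taxon = taxon)
    list(genome = genome, config = config)
  })
}

#' Apply random rearrangement events to a gene order
#'
#' Samples non-overlapping contiguous gene blocks and applies strand
#' inversions in place (block order reversed, strands flipped) and
#' translocations to new circular positions, recording the expected
#' per-gene status as ground truth. Translocated blocks keep their
#' orientation. Event sites are kept well separated (every backbone
#' segment between two event sites retains more genes than the largest
#' event block), so the minimal explanation of the resulting order is
#' unique and `shared_block` comparison can recover the truth exactly.
#'
#' @param order A [gene_order_spec()].
#' @param n_translocations,n_inversions Event counts.
#' @param block_size Integer range `c(min, max)` of genes per event block.
#' @param seed Optional integer seed (local to this call).
#' @return List with `order` (the rearranged `gene_order`) and `truth`
#'   (tibble `event`, `type`, `gene`, `expected_status`).
#' @export
#' @examples
#' r <- apply_rearrangements(ancestral_chelicerate_order(),
#'                           n_translocations = 1, seed = 7)
#' r$truth
apply_rearrangements <- function(order, n_translocations = 0,
                                 n_inversions = 0, block_size = c(1, 2),
                                 seed = NULL) {
  stopifnot(inherits(order, "gene_order"), length(block_size) == 2)
  n_events <- n_translocations + n_inversions
  genes <- order$gene
  strands <- order$strand
  n <- length(genes)
  if (n_events == 0) {
    truth <- tibble::tibble(event = integer(), type = character(),
                            gene = character(), expected_status = character())
    return(list(order = order, truth = truth))
  }
  maxb <- max(block_size)
  gap <- maxb + 2L  # min circular distance between any two event sites
  if (n_events * (maxb + gap) + gap > n) {
    stop("infeasible: too many/large events for order of size ", n,
         call. = FALSE)
  }
  .with_seed(seed, {
    size_range <- seq(block_size[1], block_size[2])
    sizes <- if (length(size_range) == 1) {
      rep(size_range, n_events)  # sample() would misread a scalar
    } else {
      sample(size_range, n_events, replace = TRUE)
    }
    types <- sample(c(rep("inversion", n_inversions),
                      rep("translocation", n_translocations)))

    # Special "sites" live on the gaps after original position i (i in 1..n,
    # circular). Each event block occupies its two flanking gaps; each
    # translocation additionally claims an insertion gap. All claimed gaps
    # must be pairwise >= `gap` apart so backbone segments stay larger than
    # any block.
    claimed <- integer(0)
    far_enough <- function(g) {
      all(pmin((g - claimed) %% n, (claimed - g) %% n) >= gap)
    }
    blocks <- vector("list", n_events)
    ins_after <- integer(n_events)  # original position the block lands after
    for (k in seq_len(n_events)) {
      placed <- FALSE
      for (try in 1:1000) {
        s <- sample.int(n - sizes[k] + 1L, 1)       # non-wrapping block
        flank <- c((s - 1L) %% n, (s + sizes[k] - 1L) %% n)
        flank[flank == 0L] <- n
        if (!all(vapply(flank, far_enough, logical(1)))) next
        claimed <- c(claimed, flank)
        blocks[[k]] <- s:(s + sizes[k] - 1L)
        if (types[k] == "translocation") {
          cand <- setdiff(seq_len(n), unlist(blocks))
          cand <- cand[vapply(cand, far_enough, logical(1))]
          if (length(cand) == 0) {
            claimed <- utils::head(claimed, -2)
            blocks[k] <- list(NULL)
            next
          }
          ins_after[k] <- if (length(cand) == 1) cand else sample(cand, 1)
          claimed <- c(claimed, ins_after[k])
        }
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place well-separated event blocks",
                        call. = FALSE)
    }

    flip <- function(s) ifelse(s == "major", "minor", "major")
    cur <- tibble::tibble(gene = genes, strand = strands,
                          slot = as.numeric(seq_len(n)))
    truth <- list()
    for (k in seq_len(n_events)) {
      idx <- blocks[[k]]
      if (types[k] == "inversion") {
        cur$gene[idx] <- rev(cur$gene[idx])
        cur$strand[idx] <- flip(rev(cur$strand[idx]))
        status <- "inverted_in_place"
      } else {
        # re-slot the block just after original position ins_after[k];
        # fractional slots keep multi-gene blocks in order
        cur$slot[idx] <- ins_after[k] + seq_along(idx) / (length(idx) + 1)
        status <- "translocated"
      }
      truth[[k]] <- tibble::tibble(
        event = k, type = types[k], gene = genes[idx],
        expected_status = status
      )
    }
    cur <- cur[base::order(cur$slot), ]  # `order` argument shadows base::order
    new_order <- gene_order_spec(cur$gene, cur$strand,
                                 anchor = attr(order, "anchor"))
    list(order = new_order, truth = dplyr::bind_rows(truth))
  })
}
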