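# independent neighbor-pair oracle: plain loops, no package internals
oracle_neighbor_status <- function(q_genes, q_strands, r_genes, r_strands) {
  shared <- intersect(q_genes, r_genes)
  qg <- q_genes[q_genes %in% shared]
  qs <- q_strands[q_genes %in% shared]
  rg <- r_genes[r_genes %in% shared]
  rs <- r_strands[r_genes %in% shared]
  nb <- function(genes) {
    n <- length(genes)
    res <- list()
    for (i in seq_len(n)) {
      up <- genes[if (i == 1) n else i - 1]
      dn <- genes[if (i == n) 1 else i + 1]
      res[[genes[i]]] <- c(up, dn)
    }
    res
  }
  qn <- nb(qg)
  rn <- nb(rg)
  out <- character(length(qg))
  names(out) <- qg
  for (g in qg) {
    moved <- !identical(qn[[g]], rn[[g]])
    flipped <- qs[match(g, qg)] != rs[match(g, rg)]
    out[g] <- if (moved && flipped) "translocated_and_inverted"
      else if (moved) "translocated"
      else if (flipped) "inverted_in_place"
      else "ancestral"
  }
  out
}

cmp_status <- function(cmp) {
  stats::setNames(cmp$status, cmp$gene)
}

test_that("the packaged ancestral arrangement matches the chelicerate ground plan", {
  anc <- ancestral_chelicerate_order()
  genes <- anc$gene[anc$gene != "CONTROL_REGION"]
  expect_equal(sort(genes), sort(canonical_genes()$gene[
    canonical_genes()$category != "control"]))
  expect_equal(length(genes), 37)
  major <- anc[anc$strand == "major" & anc$gene != "CONTROL_REGION", ]
  cat <- table(canonical_genes()$category[
    match(major$gene, canonical_genes()$gene)])
  expect_equal(unname(cat[["PCG"]]), 9)
  expect_equal(unname(cat[["tRNA"]]), 13)
  expect_true(order_equal(anc, rotate_order(anc, "ND2")))
})

test_that("comparison is reflexive: any order against itself is all ancestral", {
  anc <- ancestral_chelicerate_order()
  for (mode in c("neighbor_pair", "shared_block")) {
    cmp <- compare_arrangements(anc, anc, mode = mode)
    expect_true(all(cmp$status == "ancestral"), info = mode)
  }
  scrambled <- apply_rearrangements(anc, 2, 1, seed = 3)$order
  for (mode in c("neighbor_pair", "shared_block")) {
    cmp <- compare_arrangements(scrambled, scrambled, mode = mode)
    expect_true(all(cmp$status == "ancestral"), info = mode)
  }
})

test_that("statuses are invariant under rotation of either order", {
  anc <- ancestral_chelicerate_order()
  q <- apply_rearrangements(anc, 1, 1, seed = 17)$order
  base <- cmp_status(compare_arrangements(q, anc))
  for (anchor in c("ND2", "rrnS", "trnW")) {
    a <- cmp_status(compare_arrangements(rotate_order(q, anchor), anc))
    b <- cmp_status(compare_arrangements(q, rotate_order(anc, anchor)))
    expect_equal(a[names(base)], base)
    expect_equal(b[names(base)], base)
  }
})

test_that("neighbor-pair statuses match an exhaustive 5-gene oracle", {
  ref <- letters[1:5]
  # rename onto canonical gene names so category lookups work
  canon <- c("CO1", "CO2", "CO3", "ND1", "ND2")
  names(canon) <- ref
  rs <- rep("major", 5)
  ref_order <- gene_order_spec(canon[ref], rs)
  # enumerate every single-gene move to every non-trivial circular position
  for (gi in 1:5) {
    for (at in 0:3) {
      rest <- ref[-gi]
      q <- append(rest, ref[gi], after = at)
      q_order <- gene_order_spec(canon[q], rep("major", 5))
      got <- cmp_status(compare_arrangements(q_order, ref_order,
                                             mode = "neighbor_pair"))
      want <- oracle_neighbor_status(canon[q], rep("major", 5),
                                     canon[ref], rs)
      expect_equal(got[names(want)], want,
                   info = paste(q, collapse = ""))
    }
  }
})

test_that("moving one gene flags it and damages only its flank context", {
  # reference (a,b,c,d,e); move c between e and a
  canon <- c(a = "CO1", b = "CO2", c = "CO3", d = "ND1", e = "ND2")
  ref_order <- gene_order_spec(unname(canon), "major")
  q_order <- gene_order_spec(canon[c("a", "b", "d", "e", "c")], "major")
  got <- cmp_status(compare_arrangements(q_order, ref_order,
                                         mode = "neighbor_pair"))
  expect_equal(unname(got["CO3"]), "translocated")
  want <- oracle_neighbor_status(canon[c("a", "b", "d", "e", "c")],
                                 rep("major", 5), unname(canon),
                                 rep("major", 5))
  expect_equal(got[names(want)], want)
})

test_that("shared-block mode flags exactly the moved block", {
  anc <- ancestral_chelicerate_order()
  ra <- apply_rearrangements(anc, n_translocations = 1, n_inversions = 0,
                             block_size = c(2, 2), seed = 23)
  cmp <- compare_arrangements(ra$order, anc, mode = "shared_block")
  st <- cmp_status(cmp)
  moved <- names(st)[st != "ancestral"]
  truth_genes <- intersect(ra$truth$gene, names(st))
  expect_length(truth_genes, 2)
  expect_setequal(moved, truth_genes)
  expect_true(all(st[truth_genes] == "translocated"))
})

test_that("strand inversion alone is never reported as translocation", {
  anc <- ancestral_chelicerate_order()
  # single-gene inversions: clean in both modes (a strand flip leaves every
  # name-neighbor context intact)
  for (seed in 1:5) {
    ra <- apply_rearrangements(anc, 0, 2, block_size = c(1, 1), seed = seed)
    for (mode in c("neighbor_pair", "shared_block")) {
      st <- cmp_status(compare_arrangements(ra$order, anc, mode = mode))
      tg <- intersect(ra$truth$gene, names(st))
      expect_true(all(st[tg] == "inverted_in_place"),
                  info = paste(mode, seed))
      expect_false(any(grepl("translocated", st)), info = paste(mode, seed))
    }
  }
  # multi-gene inversions reverse gene order inside the block; the block
  # criterion still recovers them as pure in-place inversions
  for (seed in 6:10) {
    ra <- apply_rearrangements(anc, 0, 1, block_size = c(2, 3), seed = seed)
    st <- cmp_status(compare_arrangements(ra$order, anc,
                                          mode = "shared_block"))
    tg <- intersect(ra$truth$gene, names(st))
    expect_true(all(st[tg] == "inverted_in_place"), info = seed)
    expect_false(any(grepl("translocated", st)), info = seed)
  }
})

test_that("genes absent from one order are reported absent, not guessed", {
  canon <- c("CO1", "CO2", "CO3", "ND1", "ND2")
  ref_order <- gene_order_spec(canon, "major")
  q_order <- gene_order_spec(canon[1:4], "major")
  cmp <- compare_arrangements(q_order, ref_order)
  expect_equal(cmp$status[cmp$gene == "ND2"], "absent")
  expect_true(all(cmp$status[cmp$gene != "ND2"] == "ancestral"))
})

test_that("rearrangement summaries count location and strand independently", {
  anc <- ancestral_chelicerate_order()
  cmp <- compare_arrangements(anc, anc)
  s <- summarize_rearrangement(cmp)
  expect_equal(sum(s$different_location), 0)
  expect_equal(sum(s$strand_changed), 0)
  expect_equal(sum(s$n_genes), 37)

  ra <- apply_rearrangements(anc, 1, 1, block_size = c(1, 1), seed = 41)
  cmp2 <- compare_arrangements(ra$order, anc, mode = "shared_block")
  s2 <- summarize_rearrangement(cmp2)
  expect_equal(sum(s2$different_location), 1)
  expect_equal(sum(s2$strand_changed), 1)
  g <- glance(cmp2)
  expect_equal(g$n_different_location, 1)
  expect_equal(g$n_strand_changed, 1)
  expect_equal(g$n_ancestral, 35)
})

test_that("ambiguous tRNA labeling can be tolerated via relabeling", {
  anc <- ancestral_chelicerate_order()
  q <- tibble::as_tibble(anc)
  q$gene[q$gene == "trnQ"] <- "trnX_ambig"
  q_order <- gene_order_spec(q$gene, q$strand)
  # without relabeling trnQ is absent; with it, fully ancestral
  cmp <- compare_arrangements(q_order, anc)
  expect_true("absent" %in% cmp$status[cmp$gene %in% c("trnQ", "trnX_ambig")])
  cmp2 <- compare_arrangements(q_order, anc, relabel = c(trnX_ambig = "trnQ"))
  expect_true(all(cmp2$status == "ancestral"))
})

test_that("comparison requires at least 3 shared genes", {
  a <- gene_order_spec(c("CO1", "CO2", "CO3"), "major")
  b <- gene_order_spec(c("CO1", "CO2", "ND1"), "major")
  expect_error(compare_arrangements(a, b), "3 shared")
})
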