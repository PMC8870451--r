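# Identity, clustering, NJ (with ape as independent oracle), bootstrap,
# position patterns.

test_that("pairwise identity follows the gap-excluded convention", {
  aln <- aligned_sequences(c("s1", "s2", "s3"),
                           c("ACDE", "ACDF", "AC-E"))
  idm <- pairwise_identity(aln)
  expect_equal(idm["s1", "s2"], 0.75)
  expect_equal(idm["s1", "s3"], 1.0)     # 3 comparable columns, all match
  expect_equal(diag(unclass(idm)), c(s1 = 1, s2 = 1, s3 = 1))
  expect_equal(unclass(idm), t(unclass(idm)))
  expect_identical(attr(idm, "denominator"), "gap_excluded")

  # brute-force per-column oracle on random sequences
  set.seed(2)
  chars <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
  seqs <- vapply(1:4, function(i)
    paste(sample(chars, 60, replace = TRUE), collapse = ""), "")
  aln2 <- aligned_sequences(paste0("q", 1:4), seqs)
  idm2 <- pairwise_identity(aln2)
  for (i in 1:3) for (j in (i + 1):4) {
    a <- strsplit(seqs[i], "")[[1]]; b <- strsplit(seqs[j], "")[[1]]
    ok <- a != "-" & b != "-"
    expect_equal(idm2[i, j], sum(a[ok] == b[ok]) / sum(ok))
  }
})

test_that("all-gap pairs are flagged undefined and the CDF behaves", {
  aln <- aligned_sequences(c("a", "b", "c"),
                           c("AC--", "--DE", "ACDE"))
  idm <- pairwise_identity(aln)
  expect_true(is.na(idm["a", "b"]))
  expect_equal(nrow(attr(idm, "undefined_pairs")), 1)
  cdf <- identity_cdf(idm)
  x <- seq(0, 1, 0.01)
  expect_true(all(diff(cdf(x)) >= 0))
  expect_equal(cdf(1), 1)
})

test_that("greedy clustering partitions and respects the threshold", {
  # two sequences at 95% identity -> one cluster
  s <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 2), collapse = "")
  s2 <- s; substr(s2, 1, 2) <- "GG"
  aln <- aligned_sequences(c("a", "b"), c(s, s2))
  expect_length(greedy_cluster(aln)$clusters, 1)

  # A~B at 95%, both ~40% to C -> two clusters
  sC <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  while (sum(strsplit(sC, "")[[1]] == strsplit(s, "")[[1]]) / 40 > 0.5)
    sC <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  aln3 <- aligned_sequences(c("A", "B", "C"), c(s, s2, sC))
  cl3 <- greedy_cluster(aln3)
  expect_length(cl3$clusters, 2)

  # threshold 1.0 with all-distinct sequences -> all singletons
  aln4 <- aligned_sequences(c("x", "y", "z"),
                            c("AAAA", "AAAC", "AACC"))
  expect_length(greedy_cluster(aln4, threshold = 1)$clusters, 3)
  expect_error(greedy_cluster(aln4, threshold = 1.4), "threshold")

  # partition + member-representative identity invariant on generated data
  fam <- gen_sequence_family(sequence_evolution_spec(
    "(((a:0.02,b:0.02):0.3,(c:0.02,d:0.02):0.3):0.1,(e:0.02,f:0.02):0.35);",
    root_sequence = paste(rep("ACDEFGHIKLMNPQRSTVWY", 5), collapse = ""),
    seed = 21))
  idm <- pairwise_identity(fam$alignment)
  cl <- greedy_cluster(fam$alignment, idm, threshold = 0.9)
  expect_setequal(unlist(cl$clusters), fam$alignment$ids)
  expect_equal(sum(lengths(cl$clusters)), length(fam$alignment$ids))
  for (k in seq_along(cl$clusters))
    for (m in cl$clusters[[k]])
      expect_gte(idm[m, cl$representatives[k]], 0.9)
})

test_that("NJ recovers additive trees exactly and matches the ape oracle", {
  td <- tree_distance("((A:0.1,B:0.2):0.05,(C:0.15,D:0.1):0.07);")
  mine <- nj_tree(td$D)
  expect_equal(ape::dist.topo(mine, ape::unroot(td$tree)), 0,
               ignore_attr = TRUE)
  # branch lengths: compare path-length matrices (machine precision)
  expect_equal(ape::cophenetic.phylo(mine)[rownames(td$D), colnames(td$D)],
               td$D, tolerance = 1e-10)

  # larger random additive trees, against ape::nj as independent oracle
  for (seed in 1:5) {
    set.seed(seed)
    tr <- ape::rtree(7)
    D <- ape::cophenetic.phylo(tr)
    mine <- nj_tree(D)
    oracle <- ape::nj(as.dist(D))
    expect_equal(ape::dist.topo(mine, oracle), 0, ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(mine)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("NJ degenerate and ultrametric cases", {
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  expect_warning(tr2 <- nj_tree(D2), "2 taxa")
  expect_equal(sum(tr2$edge.length), 0.4)

  # ultrametric 3 taxa: the closest pair joins first (cherry together)
  D3 <- matrix(c(0, 0.2, 1, 0.2, 0, 1, 1, 1, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- nj_tree(D3)
  coph <- ape::cophenetic.phylo(tr3)
  expect_equal(coph["a", "b"], 0.2)
  expect_error(nj_tree(D3 - 0.01), "non-negative")
})

test_that("bootstrap: concordant alignments give 100% support; determinism", {
  # every column supports AB | CD
  aln <- aligned_sequences(c("A", "B", "C", "D"),
                           c(strrep("A", 30),
                             paste0("C", strrep("A", 29)),
                             paste0("E", strrep("D", 29)),
                             strrep("D", 30)))
  bs <- bootstrap_support(aln, n_reps = 30, seed = 1)
  internal <- bs$support[-1]  # drop the trivial root "split"
  expect_true(all(internal == 100))

  # single-column alignment: supports are 0 or 100
  aln1 <- aligned_sequences(c("A", "B", "C", "D"), c("A", "A", "D", "D"))
  bs1 <- bootstrap_support(aln1, n_reps = 20, seed = 2)
  expect_true(all(bs1$support[-1] %in% c(0, 100)))

  # same seed -> identical supports; taxon order must not matter
  bs2 <- bootstrap_support(aln, n_reps = 30, seed = 1)
  expect_identical(bs$support, bs2$support)
  perm <- c(3, 1, 4, 2)
  aln_p <- aligned_sequences(aln$ids[perm], aln$seqs[perm])
  bs3 <- bootstrap_support(aln_p, n_reps = 30, seed = 1)
  expect_true(all(bs3$support[-1] == 100))
  expect_error(bootstrap_support(aln, n_reps = 0, seed = 1), "n_reps")
})

test_that("position patterns map anchors through gaps and validate them", {
  aln <- aligned_sequences(
    c("ref", "s2", "s3", "s4"),
    c("AC-DEF", "ACGDEF", "ACGNEF", "ACGNEF"),
    clade = c("one", "one", "two", "two"))
  # reference residue 3 is 'D', which sits in alignment column 4
  pat <- position_patterns(aln, "ref", anchors = c("3.35" = 3L),
                           anchor_residues = c("3.35" = "D"))
  expect_equal(unname(pat$columns["3.35"]), 4L)
  expect_identical(pat$table$residue[pat$table$id == "s3"], "N")
  cons <- pat$consensus
  expect_identical(cons$residue[cons$clade == "two"], "N")
  expect_identical(cons$residue[cons$clade == "one"], "D")
  fr <- pat$frequencies[["3.35"]]
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr["N"]), 0.5)

  expect_error(position_patterns(aln, "ref", anchors = c("3.35" = 3L),
                                 anchor_residues = c("3.35" = "Q")),
               "declared")
  expect_error(position_patterns(aln, "ref", anchors = c("9.99" = 99L)),
               "outside")
  # invariant column -> single residue at frequency 1
  pat2 <- position_patterns(aln, "ref", anchors = c("2.50" = 1L))
  expect_equal(unname(pat2$frequencies[["2.50"]]["A"]), 1)
})

test_that("FASTA alignment I/O round-trips", {
  fam <- gen_sequence_family(sequence_evolution_spec(
    "((a:0.05,b:0.05):0.1,(c:0.05,d:0.05):0.1);",
    root_sequence = paste(rep("ACDEFGHIKLMNPQRSTVWY", 2), collapse = ""),
    seed = 3))
  td <- withr::local_tempdir()
  write_fasta_alignment(fam$alignment, file.path(td, "aln.fasta"))
  back <- read_fasta_alignment(file.path(td, "aln.fasta"))
  expect_identical(back$ids, fam$alignment$ids)
  expect_identical(back$seqs, fam$alignment$seqs)
})
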