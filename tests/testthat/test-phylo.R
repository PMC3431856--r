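toy_aln <- function() {
  aa_alignment(c(t1 = "MKVLMKVLAA", t2 = "MKVLMKVLAA",
                 t3 = "MKILMRVLAA", t4 = "MKILMRVLTT"))
}

test_that("alignment container validates shape and concatenates blocks", {
  expect_error(aa_alignment(c(a = "MK", b = "MKV")), "equal length")
  expect_error(aa_alignment(c("MK", "MK")), "unique taxon names")
  b1 <- aa_alignment(c(a = strrep("M", 10), b = strrep("K", 10)))
  b2 <- aa_alignment(c(b = strrep("V", 20), a = strrep("L", 20)))
  cc <- concatenate_pcgs(list(g1 = b1, g2 = b2))
  expect_equal(nchar(cc[["a"]]), 30L)
  expect_equal(cc[["a"]], paste0(strrep("M", 10), strrep("L", 20)))
  blocks <- attr(cc, "blocks")
  expect_equal(blocks$start, c(1L, 11L))
  expect_equal(blocks$end, c(10L, 30L))
  b3 <- aa_alignment(c(x = "MMMM", y = "KKKK"))
  expect_error(concatenate_pcgs(list(g1 = b1, g2 = b3)), "g2")
  # 13 blocks: column positions map back to their source blocks
  set.seed(1)
  bl <- lapply(1:13, function(i)
    aa_alignment(setNames(replicate(3, rand_seq(5, c(M = .5, K = .5))),
                          c("a", "b", "c"))))
  cc13 <- concatenate_pcgs(bl)
  map <- attr(cc13, "blocks")
  for (i in c(1, 7, 13)) {
    expect_equal(substr(cc13[["a"]], map$start[i], map$end[i]),
                 unclass(bl[[i]])[["a"]])
  }
})

test_that("p and Poisson distances follow their closed forms with complete
          deletion of gapped columns", {
  aln <- aa_alignment(c(a = "MKVLMKVLMK", b = "MKVLMKVLVV"))
  D <- aa_distance(aln, "p")
  expect_equal(D["a", "b"], 0.2)
  expect_equal(aa_distance(aln, "poisson")["a", "b"], -log(0.8))
  gapped <- aa_alignment(c(a = "MKVL-KVLMK", b = "MKIL-KVLMK",
                           c = "MKVL-KVLMK"))
  expect_equal(aa_distance(gapped, "p")["a", "b"], 1 / 9)
  same <- aa_alignment(c(a = "MMMM", b = "MMMM"))
  expect_equal(aa_distance(same, "poisson")["a", "b"], 0)
  allgap <- aa_alignment(c(a = "----", b = "MMMM"))
  expect_error(aa_distance(allgap), "zero comparable")
})

test_that("neighbor joining solves the 3-taxon system and recovers additive
          trees exactly, matching ape::nj topologies", {
  D <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 2))

  set.seed(13)
  for (n in c(5, 8, 12)) {
    true <- ape::unroot(ape::rtree(n))
    true$edge.length <- runif(nrow(true$edge), 0.05, 0.6)
    D <- cophenetic(true)
    got <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(got), true), 0,
                 ignore_attr = TRUE)
    # branch lengths reproduce the path metric
    expect_equal(cophenetic(got)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
    # independent cross-check against ape's implementation
    expect_equal(ape::dist.topo(ape::unroot(ape::nj(D)), ape::unroot(got)), 0,
                 ignore_attr = TRUE)
  }
  flat <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(flat) <- 0
  t1 <- neighbor_joining(flat)
  t2 <- neighbor_joining(flat)
  expect_equal(write_newick(t1), write_newick(t2))  # deterministic tie-break
})

test_that("Fitch score counts column changes, treats gaps as wildcards, and
          is invariant under rerooting", {
  tr <- read_newick("((a,b),(c,d));")
  expect_equal(fitch_score(tr, aa_alignment(
    c(a = "A", b = "A", c = "T", d = "T"))), 1L)
  expect_equal(fitch_score(tr, aa_alignment(
    c(a = "M", b = "M", c = "M", d = "M"))), 0L)
  expect_equal(fitch_score(tr, aa_alignment(
    c(a = "A", b = "-", c = "T", d = "T"))), 1L)
  set.seed(3)
  aln <- aa_alignment(setNames(replicate(6, rand_seq(30,
    c(M = .3, K = .3, V = .2, L = .2))), paste0("t", 1:6)))
  tr6 <- ape::unroot(ape::rtree(6, tip.label = paste0("t", 1:6)))
  s1 <- fitch_score(tr6, aln)
  rerooted <- ape::root(tr6, outgroup = "t3", resolve.root = TRUE)
  expect_equal(fitch_score(rerooted, aln), s1)
  expect_lte(s1, 5 * 30)
  # cross-check against phangorn
  skip_if_not_installed("phangorn")
  pd <- phangorn::phyDat(setNames(strsplit(unclass(aln), ""), names(aln)),
                         type = "AA")
  expect_equal(phangorn::parsimony(tr6, pd), s1, ignore_attr = TRUE)
})

test_that("NNI search attains the exhaustive-search optimum on 5-taxon
          instances and never increases the score", {
  set.seed(23)
  taxa <- paste0("t", 1:5)
  all_trees <- phangorn::allTrees(5, rooted = FALSE, tip.label = taxa)
  for (rep in 1:6) {
    aln <- aa_alignment(setNames(replicate(5, rand_seq(20,
      c(M = .3, K = .3, V = .2, A = .2))), taxa))
    best_exhaustive <- min(vapply(all_trees, fitch_score, numeric(1),
                                  aln = aln))
    start <- neighbor_joining(aa_distance(aln, "poisson"))
    found <- nni_search(start, aln)
    expect_equal(attr(found, "fitch_score"), best_exhaustive)
    expect_lte(attr(found, "fitch_score"), fitch_score(start, aln))
    # identity on an already-optimal start
    again <- nni_search(found, aln)
    expect_equal(attr(again, "fitch_score"), attr(found, "fitch_score"))
  }
})

test_that("bootstrap supports are sensible and the consensus keeps only
          majority splits", {
  # every column supports the same resolved tree -> all supports 100
  aln <- aa_alignment(c(a = strrep("M", 20), b = strrep("M", 20),
                        c = strrep("K", 20), d = strrep("K", 20),
                        e = strrep("V", 20)))
  bs <- bootstrap_support(aln, "nj", replicates = 25, seed = 2)
  tab <- attr(bs, "split_support")
  expect_true(all(tab$support == 100))
  expect_true(all(as.numeric(bs$node.label[bs$node.label != ""]) >= 50))
  # one replicate -> supports are 0 or 100
  bs1 <- bootstrap_support(toy_aln(), "nj", replicates = 1, seed = 5)
  expect_true(all(attr(bs1, "split_support")$support %in% c(0, 100)))
  # reproducible given the seed
  bs2 <- bootstrap_support(toy_aln(), "nj", replicates = 10, seed = 7)
  bs3 <- bootstrap_support(toy_aln(), "nj", replicates = 10, seed = 7)
  expect_equal(attr(bs2, "split_support"), attr(bs3, "split_support"))
})

test_that("newick io round-trips topology, lengths and supports", {
  txt <- "((A:1,B:1):0.5,C:2);"
  tr <- read_newick(txt)
  expect_equal(write_newick(tr), txt)
  tri <- read_newick("(A:1,B:2,C:3);")
  expect_equal(tri$Nnode, 1L)
  expect_equal(write_newick(tri), "(A:1,B:2,C:3);")
  set.seed(9)
  big <- ape::rtree(17)
  big$edge.length <- round(big$edge.length, 6)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(big, path)
  back <- read_newick(path = path)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(big)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(big$edge.length))
})
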