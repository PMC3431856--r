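# Concatenated-protein phylogenetics: p/Poisson distances, neighbor joining,
# Fitch parsimony with NNI hill-climbing, nonparametric bootstrap with
# majority-rule consensus. Trees are ape `phylo` objects throughout.

#' Construct an aligned amino-acid matrix
#'
#' @param seqs Named character vector of aligned amino-acid sequences
#'   (gap symbol `-`); all the same length, names unique.
#' @return An `aa_alignment` object (the validated named vector).
#' @export
aa_alignment <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    abort("alignment rows must have unique taxon names")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    abort(sprintf("aligned rows must have equal length (saw %s)",
                  paste(unique(lens), collapse = ", ")))
  }
  structure(toupper(seqs), class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("<aa_alignment> %d taxa x %d columns\n", length(x), nchar(x[1])))
  invisible(x)
}

alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

#' Read an amino-acid alignment from FASTA or relaxed PHYLIP
#'
#' @param path File path.
#' @param format `"fasta"` (default) or `"phylip"` (sequential, relaxed
#'   names).
#' @return An [aa_alignment].
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::readAAStringSet(path)
    return(aa_alignment(setNames(as.character(ss), names(ss))))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- lines[-1]
  parts <- strsplit(trimws(body), "\\s+")
  seqs <- setNames(
    vapply(parts, function(p) paste(p[-1], collapse = ""), character(1)),
    vapply(parts, `[[`, character(1), 1))
  if (length(seqs) != hdr[1]) abort("PHYLIP header taxon count does not match rows")
  aa_alignment(seqs)
}

#' Concatenate per-gene alignment blocks into a supermatrix
#'
#' @param blocks Named (or unnamed) list of [aa_alignment] objects over an
#'   identical taxon set.
#' @return An [aa_alignment] with attribute `"blocks"`, a tibble mapping each
#'   block to its column range in the supermatrix.
#' @export
concatenate_pcgs <- function(blocks) {
  stopifnot(length(blocks) >= 1)
  taxa <- sort(names(blocks[[1]]))
  nm <- names(blocks) %||% paste0("block", seq_along(blocks))
  for (i in seq_along(blocks)) {
    if (!setequal(names(blocks[[i]]), taxa)) {
      abort(sprintf("block '%s' has a different taxon set", nm[i]))
    }
  }
  widths <- vapply(blocks, function(b) nchar(b[[1]]), integer(1))
  ends <- cumsum(widths)
  seqs <- vapply(taxa, function(tx)
    paste(vapply(blocks, function(b) unclass(b)[[tx]], character(1)),
          collapse = ""), character(1))
  out <- aa_alignment(seqs)
  attr(out, "blocks") <- tibble(block = nm,
                                start = unname(ends - widths + 1L),
                                end = unname(ends))
  out
}

#' Pairwise amino-acid distances
#'
#' Columns containing a gap (`-`) or `X`/`?` in any row are removed
#' (complete deletion) before computing the proportion of differing sites
#' `p`; the Poisson correction is `-ln(1 - p)`, reported `NA` when `p = 1`.
#'
#' @param aln An [aa_alignment] with at least 2 taxa.
#' @param model `"poisson"` (default) or `"p"`.
#' @return Symmetric numeric matrix with taxon dimnames.
#' @export
aa_distance <- function(aln, model = c("poisson", "p")) {
  model <- match.arg(model)
  aa_distance_core(alignment_matrix(aln), model)
}

aa_distance_core <- function(m, model) {
  if (nrow(m) < 2) abort("at least two taxa are required")
  keep <- colSums(m == "-" | m == "X" | m == "?") == 0
  if (!any(keep)) abort("zero comparable columns after complete deletion")
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- mean(m[i, ] != m[j, ])
      d <- if (model == "p") p else if (p < 1) -log(1 - p) else NA_real_
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor joining
#'
#' Saitou-Nei agglomeration on a symmetric distance matrix: at each step the
#' pair minimising the Q criterion is joined (ties broken by lowest row then
#' column index). Negative branch lengths are clamped to zero; the total
#' clamped deficit is recorded in attribute `"negative_deficit"`.
#'
#' @param D Symmetric distance matrix with taxon dimnames, >= 3 taxa, no
#'   missing entries.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  if (anyNA(D)) abort("distance matrix contains missing values")
  if (!isSymmetric(unname(D))) abort("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3) abort("neighbor joining requires at least 3 taxa")
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) { deficit <<- deficit + (-x); 0 } else x
  }
  # active nodes carry a growing newick fragment
  frag <- labels
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    li <- clamp(li); lj <- clamp(lj)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], li, frag[j], lj)
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    D <- D2
  }
  la <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], la, frag[2], lb, frag[3], lc)
  tree <- ape::read.tree(text = txt)
  attr(tree, "negative_deficit") <- deficit
  tree
}

aa_bits <- local({
  letters20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  bits <- setNames(bitwShiftL(1L, 0:19), letters20)
  function() bits
})

#' Fitch parsimony score of a tree
#'
#' Sum over alignment columns of the minimum number of state changes under
#' Fitch's bottom-up union/intersection pass. Gaps and ambiguous states
#' (`-`, `X`, `?`) are wildcards. The score is invariant under rerooting.
#'
#' @param tree A `phylo` whose tips match the alignment taxa.
#' @param aln An [aa_alignment].
#' @return Integer parsimony length.
#' @export
fitch_score <- function(tree, aln) {
  m <- alignment_matrix(aln)
  if (!setequal(rownames(m), tree$tip.label)) {
    abort("tree tips and alignment taxa differ")
  }
  bits <- aa_bits()
  wildcard <- sum(bits)
  ncol_aln <- ncol(m)
  enc <- matrix(wildcard, nrow(m), ncol_aln)
  known <- m %in% names(bits)
  enc[known] <- bits[m[known]]
  rownames(enc) <- rownames(m)

  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  state <- matrix(0L, ntip + nnode, ncol_aln)
  state[seq_len(ntip), ] <- enc[tree$tip.label, , drop = FALSE]
  filled <- c(rep(TRUE, ntip), rep(FALSE, nnode))
  changes <- integer(ncol_aln)
  for (k in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    if (!filled[parent]) {
      state[parent, ] <- state[child, ]
      filled[parent] <- TRUE
    } else {
      inter <- bitwAnd(state[parent, ], state[child, ])
      empty <- inter == 0L
      changes <- changes + empty
      state[parent, ] <- ifelse(empty,
                                bitwOr(state[parent, ], state[child, ]),
                                inter)
    }
  }
  sum(changes)
}

# the two NNI rearrangements across one internal edge of an unrooted tree,
# realised by swapping child subtrees in the edge matrix
nni_neighbors <- function(tree) {
  ntip <- length(tree$tip.label)
  internal <- tree$edge[, 1] > ntip & tree$edge[, 2] > ntip
  out <- list()
  for (k in which(internal)) {
    u <- tree$edge[k, 1]; v <- tree$edge[k, 2]
    v_children <- which(tree$edge[, 1] == v)
    u_children <- setdiff(which(tree$edge[, 1] == u), k)
    if (length(v_children) < 2 || length(u_children) < 1) next
    c3 <- u_children[1]
    for (ci in v_children[1:2]) {
      t2 <- tree
      tmp <- t2$edge[ci, 2]
      t2$edge[ci, 2] <- t2$edge[c3, 2]
      t2$edge[c3, 2] <- tmp
      out[[length(out) + 1]] <- t2
    }
  }
  out
}

#' Parsimony search over nearest-neighbor interchanges
#'
#' Hill climbing with plateau exploration and short lookahead: from the
#' current tree every NNI rearrangement is scored; a strictly better
#' neighbor is adopted immediately (lowest score, first encountered in edge
#' order); equal-scoring neighbors are expanded breadth-first (up to
#' `max_plateau` distinct topologies) to cross score plateaus; and when
#' neither helps, chains of two then three interchanges are examined, which
#' spans the entire five-taxon tree space and escapes narrow score ridges
#' on larger trees. Deterministic given the start tree and the fixed move
#' ordering.
#'
#' @param start A `phylo` start tree (e.g. from [neighbor_joining()]).
#' @param aln An [aa_alignment].
#' @param max_plateau Maximum number of equal-score topologies explored
#'   before accepting the current optimum (default 100).
#' @return A `phylo` with attribute `"fitch_score"`.
#' @export
nni_search <- function(start, aln, max_plateau = 100) {
  topo_key <- function(t) paste(sort(tree_splits(t)), collapse = ";")
  cur <- start
  cur_score <- fitch_score(cur, aln)
  repeat {
    improved <- FALSE
    queue <- list(cur)
    seen <- topo_key(cur)
    while (length(queue) > 0 && length(seen) <= max_plateau) {
      node <- queue[[1]]
      queue <- queue[-1]
      nb <- nni_neighbors(node)
      if (length(nb) == 0) break
      scores <- vapply(nb, fitch_score, numeric(1), aln = aln)
      best <- which.min(scores)
      if (scores[best] < cur_score) {
        cur <- nb[[best]]
        cur_score <- scores[best]
        improved <- TRUE
        break
      }
      for (k in which(scores == cur_score)) {
        key <- topo_key(nb[[k]])
        if (!key %in% seen) {
          seen <- c(seen, key)
          queue[[length(queue) + 1]] <- nb[[k]]
        }
      }
    }
    if (!improved) {
      # multi-step lookahead: short chains of interchanges can cross score
      # ridges that no single move crosses (depth 3 spans the whole
      # five-taxon tree space)
      for (depth in 2:3) {
        frontier <- list(cur)
        for (step in seq_len(depth - 1)) {
          frontier <- unlist(lapply(frontier, nni_neighbors),
                             recursive = FALSE)
        }
        best2 <- NULL
        best2_score <- cur_score
        for (t1 in frontier) {
          for (t2 in nni_neighbors(t1)) {
            s2 <- fitch_score(t2, aln)
            if (s2 < best2_score) {
              best2 <- t2
              best2_score <- s2
            }
          }
        }
        if (!is.null(best2)) {
          cur <- best2
          cur_score <- best2_score
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  attr(cur, "fitch_score") <- cur_score
  cur
}

# canonical split representation: the side not containing the first taxon
# (alphabetically), as a collapsed sorted name string
tree_splits <- function(tree, taxa = sort(tree$tip.label)) {
  anchor <- taxa[1]
  ntip <- length(tree$tip.label)
  internal_edges <- which(tree$edge[, 2] > ntip)
  desc <- vector("list", ntip + tree$Nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  splits <- character(0)
  for (k in internal_edges) {
    side <- desc[[tree$edge[k, 2]]]
    if (anchor %in% side) side <- setdiff(taxa, side)
    if (length(side) < 2 || length(side) > length(taxa) - 2) next
    splits <- c(splits, paste(sort(side), collapse = "|"))
  }
  unique(splits)
}

# build a tree from nested compatible clusters (none containing the anchor)
consensus_from_splits <- function(taxa, clusters, support) {
  anchor_side <- setdiff(taxa, character(0))
  members <- lapply(clusters, function(s) strsplit(s, "|", fixed = TRUE)[[1]])
  ord <- order(vapply(members, length, integer(1)), decreasing = TRUE)
  members <- members[ord]; support <- support[ord]
  build <- function(set, avail) {
    tops <- Filter(function(i) all(members[[i]] %in% set) &&
                     length(members[[i]]) < length(set), avail)
    used <- character(0)
    parts <- character(0)
    for (i in tops) {
      if (length(intersect(members[[i]], used)) > 0) next
      sub <- build(members[[i]], setdiff(tops, i))
      parts <- c(parts, paste0(sub, support[i]))
      used <- c(used, members[[i]])
    }
    singles <- setdiff(set, used)
    paste0("(", paste(c(sort(singles), parts), collapse = ","), ")")
  }
  txt <- paste0(build(taxa, seq_along(members)), ";")
  ape::read.tree(text = txt)
}

#' Bootstrap support and majority-rule consensus
#'
#' Alignment columns are resampled with replacement `replicates` times; a
#' tree is built per replicate (`"nj"`: Poisson distance + neighbor joining;
#' `"mp"`: NJ start + NNI parsimony search), and each internal split's
#' support is the percentage of replicate trees containing it. The reported
#' tree is the 50% majority-rule consensus with supports as node labels.
#'
#' @param aln An [aa_alignment].
#' @param builder `"nj"` or `"mp"`.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed driving the resampling.
#' @return A `phylo` consensus tree with node labels = support (%); the full
#'   split-support table is in attribute `"split_support"`.
#' @export
bootstrap_support <- function(aln, builder = c("nj", "mp"),
                              replicates = 1000, seed = 1) {
  builder <- match.arg(builder)
  stopifnot(replicates >= 1)
  rows <- alignment_matrix(aln)
  ncols <- ncol(rows)
  taxa <- sort(names(aln))
  build1 <- function(m) {
    D <- aa_distance_core(m, "poisson")
    if (anyNA(D)) {
      # saturated pairs (p = 1) in a replicate: substitute a distance beyond
      # every finite one so the replicate still yields a tree
      D[is.na(D)] <- 2 * max(c(D[is.finite(D)], 1))
    }
    t0 <- neighbor_joining(D)
    if (builder == "mp") {
      a <- aa_alignment(setNames(apply(m, 1, collapse_chars), rownames(m)))
      t0 <- nni_search(t0, a)
    }
    t0
  }
  counts <- new.env(parent = emptyenv())
  set.seed(seed)
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncols, ncols, replace = TRUE)
    for (s in tree_splits(build1(rows[, cols, drop = FALSE]), taxa)) {
      counts[[s]] <- get0(s, envir = counts, ifnotfound = 0L) + 1L
    }
  }
  tab <- tibble(split = ls(counts),
                support = 100 * vapply(ls(counts), function(s) counts[[s]],
                                       integer(1)) / replicates)
  tab <- arrange(tab, dplyr::desc(.data$support), .data$split)
  # strict-majority splits are mutually compatible; at exactly 50% admit
  # greedily while compatible
  compatible <- function(a, b) {
    A <- strsplit(a, "|", fixed = TRUE)[[1]]
    B <- strsplit(b, "|", fixed = TRUE)[[1]]
    length(intersect(A, B)) == 0 || all(A %in% B) || all(B %in% A)
  }
  kept <- character(0)
  for (i in seq_len(nrow(tab))) {
    if (tab$support[i] < 50) break
    if (tab$support[i] == 50 &&
        !all(vapply(kept, compatible, logical(1), b = tab$split[i]))) next
    kept <- c(kept, tab$split[i])
  }
  cons <- consensus_from_splits(taxa, kept,
                                round(tab$support[match(kept, tab$split)]))
  attr(cons, "split_support") <- tab
  cons
}

#' Write / read a tree in Newick format
#'
#' Thin wrappers over `ape::write.tree` / `ape::read.tree`; round trips
#' preserve topology, branch lengths and node-label supports.
#'
#' @param tree A `phylo`.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) ape::write.tree(tree) else ape::write.tree(tree, file = path)
}

#' @param text Newick string (or `path` to read from).
#' @rdname write_newick
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (!is.null(path)) ape::read.tree(path) else ape::read.tree(text = text)
}
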