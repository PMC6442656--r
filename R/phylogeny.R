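# Rooted maximum-parsimony sample phylogenies from mutation
# presence/absence, with the germline (blood) sample as outgroup.
# Topology search is an exact branch-and-bound over rooted topologies that
# collects *all* equally parsimonious trees; scoring and per-edge mutation
# assignment are a unit-cost Sankoff dynamic programme vectorised over
# characters, with UNKNOWN cells treated as missing data.

#' Build the samples-by-mutations presence matrix
#'
#' Tumour-mass cells come from the detection rule on WES counts; blood is
#' germline and forced ABSENT. Margin/SVZ cells are PRESENT when detected
#' by any assay; otherwise the absence-test decision is consulted: ABSENT
#' stays ABSENT, while UNDETERMINED (including untestable and uncovered
#' SNVs) becomes UNKNOWN so the mutation is excluded from the parsimony
#' cost at that leaf rather than dropped globally.
#'
#' @param observations Observation table (all assays).
#' @param sample_sheet Sample metadata for one patient.
#' @param absence_results Output of [run_absence_test()] (may be `NULL`
#'   when there are no margin/SVZ samples).
#' @param rule Detection rule.
#' @param variants Variant ids forming the columns; default all observed.
#' @param assay Assay used for tumour-mass presence calls, default WES.
#' @return Integer matrix: samples in rows, variants in columns, cells
#'   1 (present), 0 (absent), NA (unknown).
#' @export
build_presence_matrix <- function(observations, sample_sheet,
                                  absence_results = NULL,
                                  rule = detection_rule(),
                                  variants = NULL, assay = "WES") {
  if (is.null(variants)) variants <- sort(unique(observations$variant_id))
  samples <- sample_sheet$sample_id
  pmat <- matrix(0L, length(samples), length(variants),
                 dimnames = list(samples, variants))
  for (i in seq_along(samples)) {
    s <- samples[i]
    cls <- sample_sheet$region_class[i]
    if (cls == "BLOOD") next
    o <- observations[observations$sample_id == s & observations$depth > 0, ,
                      drop = FALSE]
    if (cls == "T") o <- o[o$assay == assay, , drop = FALSE]
    if (nrow(o) == 0)
      stop("sample ", s, " has zero covered SNVs")
    det <- o$variant_id[is_detected(o$alt_count, o$depth, rule)]
    pmat[i, colnames(pmat) %in% det] <- 1L
    if (cls %in% c("M", "SVZ") && !is.null(absence_results)) {
      ar <- absence_results[absence_results$target_sample_id == s, ,
                            drop = FALSE]
      und <- ar$variant_id[ar$decision == "UNDETERMINED"]
      pmat[i, colnames(pmat) %in% setdiff(und, det)] <- NA_integer_
    }
  }
  pmat
}

# -- Sankoff machinery -------------------------------------------------------

# Unit-cost Sankoff costs for binary characters. Returns per-node cost
# matrices for states 0 and 1 (nodes x characters) and the root index.
.sankoff_costs <- function(tree, pmat) {
  tree <- stats::reorder(tree, "postorder")
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  nc <- ncol(pmat)
  tipm <- pmat[tree$tip.label, , drop = FALSE]
  C0 <- matrix(0, nn, nc)
  C1 <- matrix(0, nn, nc)
  C0[seq_len(nt), ] <- ifelse(is.na(tipm) | tipm == 0L, 0, Inf)
  C1[seq_len(nt), ] <- ifelse(is.na(tipm) | tipm == 1L, 0, Inf)
  e <- tree$edge
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1]; ch <- e[i, 2]
    C0[p, ] <- C0[p, ] + pmin(C0[ch, ], C1[ch, ] + 1)
    C1[p, ] <- C1[p, ] + pmin(C1[ch, ], C0[ch, ] + 1)
  }
  root <- e[nrow(e), 1]
  list(tree = tree, C0 = C0, C1 = C1, root = root, n_tip = nt)
}

#' Parsimony score of a tree given a presence matrix
#'
#' Minimum number of character state changes (gains plus losses) needed to
#' explain the matrix on the tree; UNKNOWN cells are missing data and never
#' force a change. The score does not depend on the rooting.
#'
#' @param tree A `phylo` whose tips are exactly the matrix rows.
#' @param pmat Presence matrix from [build_presence_matrix()].
#' @return Integer parsimony score.
#' @export
fitch_score <- function(tree, pmat) {
  if (!setequal(tree$tip.label, rownames(pmat)))
    stop("tree tips and matrix rows disagree")
  sk <- .sankoff_costs(tree, pmat)
  sc <- pmin(sk$C0[sk$root, ], sk$C1[sk$root, ])
  as.integer(sum(sc[is.finite(sc)]))
}

# Minimum-change state assignment by Sankoff backtracking. Root ties go to
# state 0 (germline/ancestral); elsewhere ties keep the parent state, so
# ambiguous changes are placed tipward and missing-data leaves inherit
# their neighbourhood. Returns per-edge change counts and gain/loss lists.
.assign_changes <- function(tree, pmat) {
  sk <- .sankoff_costs(tree, pmat)
  tree <- sk$tree
  nt <- sk$n_tip
  nn <- nt + tree$Nnode
  nc <- ncol(pmat)
  S <- matrix(NA_integer_, nn, nc)
  S[sk$root, ] <- ifelse(sk$C0[sk$root, ] <= sk$C1[sk$root, ], 0L, 1L)
  e <- tree$edge
  gains <- vector("list", nrow(e))
  losses <- vector("list", nrow(e))
  len <- integer(nrow(e))
  for (i in rev(seq_len(nrow(e)))) {
    p <- e[i, 1]; ch <- e[i, 2]
    sp <- S[p, ]
    cost0 <- sk$C0[ch, ] + (sp != 0L)
    cost1 <- sk$C1[ch, ] + (sp != 1L)
    sc <- ifelse(cost0 < cost1, 0L, ifelse(cost1 < cost0, 1L, sp))
    S[ch, ] <- sc
    g <- which(sp == 0L & sc == 1L)
    l <- which(sp == 1L & sc == 0L)
    gains[[i]] <- colnames(pmat)[g]
    losses[[i]] <- colnames(pmat)[l]
    len[i] <- length(g) + length(l)
  }
  tree$edge.length <- len
  list(tree = tree, gains = gains, losses = losses,
       score = as.integer(sum(len)))
}

# Canonical topology-only Newick string (children sorted recursively);
# used to break ties among equally parsimonious trees deterministically.
.canonical_newick <- function(tree) {
  nt <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= nt) return(tree$tip.label[node])
    subs <- sort(vapply(kids[[as.character(node)]], rec, character(1)))
    paste0("(", paste(subs, collapse = ","), ")")
  }
  rec(setdiff(tree$edge[, 1], tree$edge[, 2])[1])
}

# -- Exact branch-and-bound topology search ---------------------------------
#
# Rooted-at-outgroup binary topologies over the non-outgroup taxa are
# enumerated by sequential insertion; a partial tree's Fitch score (on its
# taxon subset) lower-bounds every completion, so branches scoring above
# the incumbent are pruned. All equally parsimonious trees are collected.
# Fitch state sets are 2-bit masks (1 = {0}, 2 = {1}, 3 = {0,1}),
# vectorised over characters.

.fitch_nested <- function(node, tipstates) {
  if (!is.list(node)) return(list(s = tipstates[[node]], cost = 0L))
  l <- .fitch_nested(node[[1]], tipstates)
  r <- .fitch_nested(node[[2]], tipstates)
  inter <- bitwAnd(l$s, r$s)
  un <- inter == 0L
  list(s = ifelse(un, bitwOr(l$s, r$s), inter),
       cost = l$cost + r$cost + sum(un))
}

.all_insertions <- function(tree, taxon) {
  res <- list(list(tree, taxon))
  if (is.list(tree)) {
    for (i in 1:2) {
      for (sub in .all_insertions(tree[[i]], taxon)) {
        nt <- tree
        nt[[i]] <- sub
        res[[length(res) + 1L]] <- nt
      }
    }
  }
  res
}

.nested_newick <- function(node) {
  if (!is.list(node)) return(node)
  paste0("(", .nested_newick(node[[1]]), ",", .nested_newick(node[[2]]), ")")
}

# All maximum-parsimony trees, rooted on the outgroup.
.mp_trees <- function(pmat, outgroup) {
  taxa <- setdiff(rownames(pmat), outgroup)
  code <- function(row) ifelse(is.na(row), 3L, row + 1L)
  tipstates <- lapply(c(taxa, outgroup), function(s) code(pmat[s, ]))
  names(tipstates) <- c(taxa, outgroup)
  best <- Inf
  found <- list()
  rec <- function(tree, remaining) {
    sc <- .fitch_nested(list(outgroup, tree), tipstates)$cost
    if (sc > best) return(invisible())
    if (length(remaining) == 0) {
      if (sc < best) {
        best <<- sc
        found <<- list()
      }
      found[[length(found) + 1L]] <<- tree
      return(invisible())
    }
    for (nt in .all_insertions(tree, remaining[1]))
      rec(nt, remaining[-1])
    invisible()
  }
  if (length(taxa) == 1) found <- list(taxa[1]) else
    rec(taxa[1], taxa[-1])
  lapply(found, function(tr)
    ape::read.tree(text = paste0("(", outgroup, ",",
                                 .nested_newick(tr), ");")))
}

#' Exact maximum-parsimony tree rooted on the germline
#'
#' Branch-and-bound search over topologies (exact; refuses more than 12
#' non-blood samples), Fitch/Sankoff scoring with UNKNOWN as missing data,
#' deterministic tie-break by the lexicographically smallest canonical
#' Newick form. Branch lengths are the mutations assigned to each edge by
#' minimum-change backtracking; internal edges carrying zero mutations are
#' collapsed, so e.g. identical samples yield a star tree.
#'
#' @param pmat Presence matrix from [build_presence_matrix()].
#' @param outgroup Row name of the blood (germline) sample.
#' @return A rooted `phylo` with mutation-count branch lengths and
#'   attributes `parsimony_score` and `edge_mutations` (data frame listing
#'   the gains/losses on each edge).
#' @export
parsimony_tree <- function(pmat, outgroup = "BLOOD") {
  if (!outgroup %in% rownames(pmat))
    stop("outgroup ", outgroup, " is not a row of the matrix")
  if (nrow(pmat) - 1 > 12)
    stop("more than 12 non-blood samples: exact search refused ",
         "(heuristic search is out of scope)")
  if (nrow(pmat) < 3) stop("need at least two non-blood samples")
  if (ncol(pmat) < 1) stop("presence matrix has no characters")
  if (is.null(colnames(pmat)))
    colnames(pmat) <- paste0("c", seq_len(ncol(pmat)))
  if (any(!is.na(pmat[outgroup, ]) & pmat[outgroup, ] != 0L))
    warning("outgroup row is not all-ABSENT; it will still be used as root")
  cands <- .mp_trees(pmat, outgroup)
  keys <- vapply(cands, .canonical_newick, character(1))
  best <- .assign_changes(cands[[order(keys)[1]]], pmat)
  tree <- best$tree
  # collapse internal edges with zero assigned mutations, then re-assign
  tree2 <- ape::di2multi(tree, tol = 0.5)
  if (tree2$Nnode < tree$Nnode) {
    best <- .assign_changes(tree2, pmat)
    tree <- best$tree
  }
  e <- tree$edge
  nt <- length(tree$tip.label)
  lab <- function(n) if (n <= nt) tree$tip.label[n] else paste0("node", n)
  attr(tree, "edge_mutations") <- data.frame(
    parent = vapply(e[, 1], lab, character(1)),
    child = vapply(e[, 2], lab, character(1)),
    n_gains = vapply(best$gains, length, integer(1)),
    n_losses = vapply(best$losses, length, integer(1)),
    gains = vapply(best$gains, paste, character(1), collapse = ","),
    losses = vapply(best$losses, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  attr(tree, "parsimony_score") <- best$score
  tree
}

#' Per-branch mutation assignments of a parsimony tree
#'
#' @param tree Output of [parsimony_tree()].
#' @return Data frame with one row per edge: parent, child, gain/loss
#'   counts and comma-separated mutation lists.
#' @export
branch_mutations <- function(tree) {
  bm <- attr(tree, "edge_mutations")
  if (is.null(bm)) stop("tree carries no mutation assignment")
  bm
}

# Clade keys (sorted tip labels of every internal node except the root).
.clade_keys <- function(tree, drop_root = TRUE) {
  nt <- length(tree$tip.label)
  nodes <- (nt + 1L):(nt + tree$Nnode)
  desc <- phangorn::Descendants(tree, nodes, type = "tips")
  keys <- vapply(desc, function(d)
    paste(sort(tree$tip.label[d]), collapse = "|"), character(1))
  names(keys) <- nodes
  if (drop_root) {
    root <- setdiff(tree$edge[, 1], tree$edge[, 2])
    keys <- keys[names(keys) != as.character(root)]
  }
  keys
}

#' Bootstrap support for the maximum-parsimony tree
#'
#' Columns of the presence matrix are resampled with replacement
#' `n_replicates` times; each replicate is re-solved exactly and every
#' clade of the full-data tree is credited with the fraction of that
#' replicate's equally parsimonious trees that contain it. Supports are
#' the percentage of replicates so credited, written as integer internal
#' node labels (the root, which is trivially present, gets none).
#'
#' @param pmat Presence matrix.
#' @param outgroup Blood sample row name.
#' @param n_replicates Number of bootstrap replicates, default 1000.
#' @param seed Optional RNG seed for reproducible resampling.
#' @return The full-data [parsimony_tree()] with `node.label` supports and
#'   attribute `n_replicates`.
#' @export
bootstrap_support <- function(pmat, outgroup = "BLOOD", n_replicates = 1000,
                              seed = NULL) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ref <- parsimony_tree(pmat, outgroup)
  keys <- .clade_keys(ref)
  hits <- stats::setNames(numeric(length(keys)), names(keys))
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(ncol(pmat), replace = TRUE)
    reps <- .mp_trees(pmat[, cols, drop = FALSE], outgroup)
    rep_keys <- lapply(reps, .clade_keys, drop_root = FALSE)
    frac <- vapply(keys, function(k)
      mean(vapply(rep_keys, function(rk) k %in% rk, logical(1))),
      numeric(1))
    hits <- hits + frac
  }
  supp <- as.integer(round(100 * hits / n_replicates))
  nt <- length(ref$tip.label)
  lab <- rep("", ref$Nnode)
  lab[as.integer(names(keys)) - nt] <- as.character(supp)
  ref$node.label <- lab
  attr(ref, "n_replicates") <- n_replicates
  ref
}

#' Mutation distance from the root to a leaf's attachment point
#'
#' Sum of branch lengths (assigned mutations) from the root to the
#' immediate parent of a leaf. Used to check whether the infiltrative
#' margin attaches rootward of the tumour-mass samples.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param leaf Tip label.
#' @return Numeric distance.
#' @export
leaf_attachment_depth <- function(tree, leaf) {
  i <- match(leaf, tree$tip.label)
  if (is.na(i)) stop("no leaf called ", leaf)
  nt <- length(tree$tip.label)
  root <- nt + 1L
  d <- 0
  node <- tree$edge[tree$edge[, 2] == i, 1]
  while (node != root) {
    j <- which(tree$edge[, 2] == node)
    d <- d + tree$edge.length[j]
    node <- tree$edge[j, 1]
  }
  d
}
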