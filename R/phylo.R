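#' Read a protein alignment from FASTA
#'
#' @param path Aligned FASTA (gap character `-`); all rows must have equal
#'   length.
#' @return Named character vector of aligned sequences.
#' @export
read_protein_alignment <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  out <- setNames(toupper(as.character(aln)), sub("\\s.*$", "", names(aln)))
  check_alignment(out)
  out
}

check_alignment <- function(aln) {
  stopifnot(is.character(aln), !is.null(names(aln)))
  if (length(unique(nchar(aln))) != 1L) {
    stop("aligned sequences must all have the same length", call. = FALSE)
  }
  invisible(aln)
}

# residues that do not count as comparable sites
NONCOMPARABLE <- c("-", ".", "?", "X", "B", "Z")

#' Poisson-corrected distance between two aligned protein sequences
#'
#' The observed proportion of differing sites p is computed over positions
#' where both sequences carry an unambiguous residue (pairwise deletion of
#' gaps and X/B/Z), then corrected for multiple hits: `d = -ln(1 - p)`.
#'
#' @param a,b Aligned amino-acid strings of equal length.
#' @return Non-negative distance. Errors when no sites are comparable or
#'   the pair is saturated (p >= 1).
#' @export
poisson_distance <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  ok <- !(ca %in% NONCOMPARABLE) & !(cb %in% NONCOMPARABLE)
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites between the pair", call. = FALSE)
  p <- sum(ca[ok] != cb[ok]) / n
  if (p >= 1) stop("saturated pair (p >= 1): distance undefined", call. = FALSE)
  -log(1 - p)
}

# distance matrix from a character matrix (rows = sequences)
pdist_from_charmat <- function(mat, deletion) {
  if (deletion == "complete") {
    keep <- !apply(mat, 2L, function(col) any(col %in% NONCOMPARABLE))
    mat <- mat[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !(mat[i, ] %in% NONCOMPARABLE) & !(mat[j, ] %in% NONCOMPARABLE)
      m <- sum(ok)
      if (m == 0L) {
        stop("no comparable sites between ", rownames(mat)[i], " and ",
             rownames(mat)[j], call. = FALSE)
      }
      p <- sum(mat[i, ok] != mat[j, ok]) / m
      if (p >= 1) {
        stop("saturated pair ", rownames(mat)[i], "/", rownames(mat)[j],
             call. = FALSE)
      }
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  d
}

#' Poisson-corrected distance matrix for an alignment
#'
#' @param aln Named character vector of aligned sequences.
#' @param deletion Gap treatment: `"pairwise"` (default) drops gapped or
#'   ambiguous sites per pair; `"complete"` drops every column containing
#'   any gap or ambiguity first.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
poisson_dist <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  check_alignment(aln)
  mat <- do.call(rbind, strsplit(aln, ""))
  rownames(mat) <- names(aln)
  pdist_from_charmat(mat, deletion)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d Symmetric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  lines <- c(format(nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste(c(sprintf("%-10s", rownames(d)[i]),
                       sprintf("%.6f", d[i, ])), collapse = " ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: repeatedly joins the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with branch
#' lengths from the standard NJ formulas. Exact ties in Q are broken by the
#' smallest (i, j) index pair. Negative branch lengths are clamped to zero
#' with the deficit transferred to the sister branch, preserving the joined
#' pair's path length.
#'
#' @param d Symmetric distance matrix (zero diagonal, dimnames = taxon
#'   labels, >= 3 taxa).
#' @return An unrooted `phylo` tree (trifurcating root node).
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 3L)
  if (max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  node <- labels
  D <- unname(d)
  while (length(node) > 3L) {
    n <- length(node)
    r <- rowSums(D)
    best_i <- best_j <- 1L
    best_q <- Inf
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        q <- (n - 2) * D[i, j] - r[i] - r[j]
        if (q < best_q - 1e-12) {
          best_q <- q
          best_i <- i
          best_j <- j
        }
      }
    }
    i <- best_i
    j <- best_j
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) {
      lj <- lj + li
      li <- 0
    }
    if (lj < 0) {
      li <- li + lj
      lj <- 0
    }
    merged <- paste0("(", node[i], ":", fmt(li), ",", node[j], ":", fmt(lj), ")")
    keep <- setdiff(seq_len(n), c(i, j))
    new_d <- (D[i, keep] + D[j, keep] - D[i, j]) / 2
    D <- rbind(cbind(D[keep, keep, drop = FALSE], new_d), c(new_d, 0))
    node <- c(node[keep], merged)
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  newick <- paste0("(", node[1], ":", fmt(la), ",", node[2], ":", fmt(lb),
                   ",", node[3], ":", fmt(lc), ");")
  ape::read.tree(text = newick)
}

# canonical bipartition keys for the internal edges of an unrooted tree:
# each key is the sorted tip set on the side not containing the
# alphabetically first label
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n + tree$Nnode)
  for (t in seq_len(n)) desc[[t]] <- tips[t]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]
    ch <- po$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  ref <- sort(tips)[1]
  keys <- character(0)
  nodes <- integer(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    if (child <= n) next
    set <- sort(desc[[child]])
    if (length(set) < 2L || length(set) > n - 2L) next
    if (ref %in% set) set <- sort(setdiff(tips, set))
    keys <- c(keys, paste(set, collapse = "|"))
    nodes <- c(nodes, child)
  }
  tibble(node = nodes, bipartition = keys)
}

#' Bootstrap support for a neighbour-joining protein tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Poisson-distance NJ tree per replicate, and reports for every internal
#' bipartition of the original tree the percentage of completed replicates
#' recovering it. Replicates producing an uncomparable or saturated pair
#' are skipped and excluded from the denominator.
#'
#' @param aln Named character vector of aligned sequences (>= 3).
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param deletion Gap treatment passed to the distance computation.
#' @return A list of class `nj_bootstrap`: `tree` (the original `phylo`
#'   with per-node support as `node.label`), `support` (tibble
#'   `bipartition`, `support_pct`), `n_completed`, `n_skipped`.
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = 1L,
                              deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  check_alignment(aln)
  mat <- do.call(rbind, strsplit(aln, ""))
  rownames(mat) <- names(aln)
  tree <- nj_tree(pdist_from_charmat(mat, deletion))
  bip <- tree_bipartitions(tree)
  counts <- setNames(numeric(nrow(bip)), bip$bipartition)
  completed <- 0L
  skipped <- 0L
  L <- ncol(mat)
  withr::with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      dr <- tryCatch(pdist_from_charmat(mat[, cols, drop = FALSE], deletion),
                     error = function(e) NULL)
      if (is.null(dr)) {
        skipped <- skipped + 1L
        next
      }
      rk <- tree_bipartitions(nj_tree(dr))$bipartition
      hit <- names(counts) %in% rk
      counts[hit] <- counts[hit] + 1
      completed <- completed + 1L
    }
  })
  support_pct <- if (completed > 0L) 100 * counts / completed else counts * NA
  tree$node.label <- rep("", tree$Nnode)
  n_tips <- length(tree$tip.label)
  tree$node.label[bip$node - n_tips] <-
    formatC(support_pct[bip$bipartition], format = "f", digits = 0)
  list_out <- list(tree = tree,
                   support = tibble(bipartition = bip$bipartition,
                                    support_pct = unname(support_pct)),
                   n_completed = completed, n_skipped = skipped)
  structure(list_out, class = "nj_bootstrap")
}

#' @export
print.nj_bootstrap <- function(x, ...) {
  cat("<nj_bootstrap> ", length(x$tree$tip.label), " taxa, ",
      x$n_completed, " completed replicate(s), ", x$n_skipped,
      " skipped\n", sep = "")
  print(x$support)
  invisible(x)
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` or `nj_bootstrap` (support values become internal
#'   node labels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  if (inherits(tree, "nj_bootstrap")) tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}
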