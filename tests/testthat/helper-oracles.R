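# Independent oracles used by the tests. These deliberately re-derive results
# by brute force / enumeration, sharing only the stated conventions (scoring,
# tie-breaks) with the implementation under test.

# -- full-matrix glocal alignment oracle (match +1 / mismatch -1 / gap -2,
#    free terminal gaps, terminal gaps excluded from aln_len) ----------------
oracle_align <- function(a, b) {
  # canonical order, as documented for align_pair symmetry
  swap <- if (nchar(a) != nchar(b)) nchar(a) > nchar(b) else a > b
  if (swap) { tmp <- a; a <- b; b <- tmp }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  ok <- function(x) x %in% c("A", "C", "G", "T")
  S <- matrix(0, la + 1, lb + 1)
  P <- matrix(3L, la + 1, lb + 1) # 0 diag, 1 up, 2 left, 3 start
  for (i in 1:la) for (j in 1:lb) {
    m <- ok(av[i]) && av[i] == bv[j]
    cand <- c(S[i, j] + ifelse(m, 1, -1), S[i, j + 1] - 2, S[i + 1, j] - 2)
    w <- which.max(cand) # first max: diag preferred, then up, then left
    S[i + 1, j + 1] <- cand[w]
    P[i + 1, j + 1] <- w - 1L
  }
  # end cell: best over column lb (rows 0..la-1 in order), then the last row
  best <- S[1, lb + 1]; bi <- 0L; bj <- lb
  if (la >= 2) for (i in 1:(la - 1)) {
    if (S[i + 1, lb + 1] > best) { best <- S[i + 1, lb + 1]; bi <- i; bj <- lb }
  }
  for (j in 0:lb) if (S[la + 1, j + 1] > best) { best <- S[la + 1, j + 1]; bi <- la; bj <- j }
  i <- bi; j <- bj; alen <- 0L; mm <- 0L
  while (i > 0 && j > 0) {
    d <- P[i + 1, j + 1]
    if (d == 3) break
    alen <- alen + 1L
    if (d == 0) {
      if (!(ok(av[i]) && av[i] == bv[j])) mm <- mm + 1L
      i <- i - 1; j <- j - 1
    } else if (d == 1) { mm <- mm + 1L; i <- i - 1 }
    else { mm <- mm + 1L; j <- j - 1 }
  }
  list(identity = if (alen > 0) 100 * (alen - mm) / alen else 0,
       aln_len = alen, mismatches = mm, score = best)
}

# -- brute-force RBM oracle over two gene tables ----------------------------
oracle_rbm <- function(ga, gb, id_floor = 70, min_cov = 0.5) {
  hits <- list()
  for (i in seq_len(nrow(ga))) for (j in seq_len(nrow(gb))) {
    st <- oracle_align(ga$seq[i], gb$seq[j])
    if (st$aln_len >= min_cov * min(nchar(ga$seq[i]), nchar(gb$seq[j])) &&
        st$identity >= id_floor) {
      hits[[length(hits) + 1]] <- data.frame(
        i = i, j = j, identity = st$identity, aln_len = st$aln_len,
        mismatches = st$mismatches)
    }
  }
  if (length(hits) == 0) return(NULL)
  h <- do.call(rbind, hits)
  pick_best <- function(rows, other_ids) {
    o <- order(-rows$identity, -rows$aln_len, other_ids)
    rows[o[1], , drop = FALSE]
  }
  best_a <- lapply(split(h, h$i), function(r) pick_best(r, gb$gene_id[r$j]))
  best_b <- lapply(split(h, h$j), function(r) pick_best(r, ga$gene_id[r$i]))
  out <- list()
  for (r in best_a) {
    rb <- best_b[[as.character(r$j)]]
    if (!is.null(rb) && rb$i == r$i) out[[length(out) + 1]] <- r
  }
  do.call(rbind, out)
}

# -- random nucleotide sequences and simple mutagenesis ---------------------
random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

mutate_seq <- function(seq, n_sub = 0, n_indel = 0) {
  v <- strsplit(seq, "")[[1]]
  if (n_sub > 0) {
    pos <- sample(length(v), n_sub)
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  if (n_indel > 0) {
    for (t in seq_len(n_indel)) {
      p <- sample(length(v), 1)
      if (runif(1) < 0.5) v <- v[-p]
      else v <- append(v, sample(c("A", "C", "G", "T"), 1), after = p)
    }
  }
  paste(v, collapse = "")
}

# -- exhaustive unrooted topology enumeration + OLS branch fit --------------
# trees are edge lists over nodes; leaves 1..n, internal nodes n+1, ...
enumerate_topologies <- function(n) {
  # start from the 3-leaf star, insert leaves 4..n on every edge; internal
  # node ids start above the final leaf count so they never clash with leaves
  base <- list(edges = rbind(c(n + 1, 1), c(n + 1, 2), c(n + 1, 3)),
               next_node = n + 2L, n_leaf = 3L)
  trees <- list(base)
  for (leaf in seq(4, length.out = max(0, n - 3))) {
    new_trees <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edges))) {
        ed <- tr$edges
        u <- ed[e, 1]; v <- ed[e, 2]
        mid <- tr$next_node
        ed <- ed[-e, , drop = FALSE]
        ed <- rbind(ed, c(u, mid), c(mid, v), c(mid, leaf))
        new_trees[[length(new_trees) + 1]] <-
          list(edges = ed, next_node = mid + 1L, n_leaf = tr$n_leaf + 1L)
      }
    }
    trees <- new_trees
  }
  trees
}

# path indicator matrix: rows = leaf pairs, cols = edges. The path between
# two leaves is the symmetric difference of their root paths (root = node 1).
tree_path_matrix <- function(tr, n) {
  ed <- tr$edges
  n_nodes <- max(ed)
  n_edges <- nrow(ed)
  adj <- vector("list", n_nodes)
  for (e in seq_len(n_edges)) {
    adj[[ed[e, 1]]] <- rbind(adj[[ed[e, 1]]], c(ed[e, 2], e))
    adj[[ed[e, 2]]] <- rbind(adj[[ed[e, 2]]], c(ed[e, 1], e))
  }
  root_path <- matrix(FALSE, n_nodes, n_edges)
  visited <- logical(n_nodes)
  visited[1] <- TRUE
  queue <- 1L
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    for (k in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][k, 1]; e <- adj[[u]][k, 2]
      if (!visited[v]) {
        visited[v] <- TRUE
        root_path[v, ] <- root_path[u, ]
        root_path[v, e] <- TRUE
        queue <- c(queue, v)
      }
    }
  }
  pairs <- t(utils::combn(n, 2))
  X <- matrix(0, nrow(pairs), n_edges)
  for (r in seq_len(nrow(pairs))) {
    X[r, ] <- as.numeric(xor(root_path[pairs[r, 1], ], root_path[pairs[r, 2], ]))
  }
  X
}

# least-squares fit of branch lengths for each topology; returns the
# topology (edge list) with minimal residual sum of squares
oracle_best_topology <- function(d) {
  n <- nrow(d)
  dv <- d[lower.tri(d)]
  # lower.tri order differs from combn order; build consistently
  pairs <- t(utils::combn(n, 2))
  dv <- d[cbind(pairs[, 1], pairs[, 2])]
  best <- NULL
  for (tr in enumerate_topologies(n)) {
    X <- tree_path_matrix(tr, n)
    fit <- stats::lm.fit(X, dv)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) best <- list(tr = tr, rss = rss, coef = fit$coefficients)
  }
  best
}

# convert an enumerated topology to an ape::phylo (unrooted, arbitrary lengths)
topology_to_phylo <- function(tr, labels) {
  ed <- tr$edges
  nodes <- sort(unique(as.vector(ed)))
  n <- tr$n_leaf
  internal <- setdiff(nodes, seq_len(n))
  remap <- integer(max(nodes))
  remap[seq_len(n)] <- seq_len(n)
  remap[internal] <- n + seq_along(internal)
  phy <- list(edge = cbind(remap[ed[, 1]], remap[ed[, 2]]),
              tip.label = labels, Nnode = length(internal),
              edge.length = rep(1, nrow(ed)))
  class(phy) <- "phylo"
  ape::reorder.phylo(phy)
}

# random additive tree: random topology with uniform branch lengths; returns
# the phylo and its exact cophenetic distance matrix
random_additive_tree <- function(n, labels = paste0("t", seq_len(n))) {
  tr <- ape::rtree(n, rooted = FALSE, tip.label = labels)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 2)
  list(tree = tr, d = ape::cophenetic.phylo(tr)[labels, labels])
}

# -- tiny hand-built gene tables --------------------------------------------
toy_genes <- function(genome_id, seqs, len_spacer = 100) {
  lens <- nchar(seqs)
  starts <- cumsum(c(0, head(lens + len_spacer, -1)))
  tibble::tibble(
    gene_id = sprintf("%s_c1_%d", genome_id, seq_along(seqs)),
    genome_id = genome_id,
    contig_id = paste0(genome_id, "_c1"),
    start = as.integer(starts), end = as.integer(starts + lens),
    strand = 1L, seq = seqs)
}
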