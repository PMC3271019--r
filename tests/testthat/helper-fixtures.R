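# Shared fixtures and independent oracles used across the suite.

# records data.frame from leaf labels: labels starting with "v" are viral,
# "m" metazoan, anything else other_eukaryote
records_for <- function(labels, lengths = 100L) {
  data.frame(protein_id = labels,
             species = paste0("sp_", labels),
             taxon_class = ifelse(grepl("^v", labels), "virus",
                                  ifelse(grepl("^m", labels), "metazoa",
                                         "other_eukaryote")),
             length = rep_len(as.integer(lengths), length(labels)),
             stringsAsFactors = FALSE)
}

# caterpillar with one leaf at every depth 1..(max_depth-1) and two leaves
# at max_depth; labels Lxx by depth
caterpillar_tree <- function(max_depth = 19L) {
  s <- sprintf("(L%02da,L%02db)", max_depth, max_depth)
  for (d in rev(seq_len(max_depth - 1L))) s <- sprintf("(L%02d,%s)", d, s)
  read_tree(text = paste0(s, ";"))
}

# random rooted binary tree over given labels, built independently of the
# package generator
random_tree <- function(labels) {
  stopifnot(length(labels) >= 2L)
  s <- sprintf("(%s,%s)", labels[1L], labels[2L])
  placed <- labels[1:2]
  for (lab in labels[-(1:2)]) {
    pick <- placed[sample.int(length(placed), 1L)]
    s <- sub(pick, sprintf("(%s,%s)", pick, lab), s, fixed = TRUE)
    placed <- c(placed, lab)
  }
  read_tree(text = paste0(s, ";"))
}

# --- independent oracles -------------------------------------------------

# leaf depths by explicit parent-pointer walking from every leaf to the root
oracle_leaf_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- ntip + 1L
  d <- integer(ntip)
  for (i in seq_len(ntip)) {
    node <- i
    while (node != root) {
      node <- parent[node]
      d[i] <- d[i] + 1L
    }
  }
  names(d) <- tree$tip.label
  d
}

# viral clusters by exhaustively testing every node's descendant leaf set
oracle_viral_clusters <- function(tree, records) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  cls <- records$taxon_class[match(tree$tip.label, records$protein_id)]
  tips_of <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    unlist(lapply(kids, tips_of))
  }
  parent <- integer(n)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- ntip + 1L
  all_viral <- vapply(seq_len(n),
                      function(nd) all(cls[tips_of(nd)] == "virus"), TRUE)
  vc <- which(all_viral & (seq_len(n) == root | !all_viral[pmax(parent, 1L)]))
  lapply(vc, function(nd) sort(tree$tip.label[tips_of(nd)]))
}

# KS D by scanning every pooled breakpoint
oracle_ks_D <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  max(abs(vapply(xs, function(x) mean(a <= x) - mean(b <= x), 0)))
}

# hypergeometric upper tail by direct summation of the mass function
oracle_hyper_tail <- function(k, K, n, N) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# binomial upper tail by direct summation
oracle_binom_tail <- function(k, n, p) {
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

# exhaustive overlap-resolution oracle: enumerate every subset (n <= 8),
# keep the pairwise-compatible maximal ones, and pick the subset whose
# priority-rank vector (desc score, longer, smaller start) is
# lexicographically smallest
oracle_resolve_overlaps <- function(hits) {
  n <- nrow(hits)
  score <- hits$score
  score[is.na(score)] <- -Inf
  len <- hits$end - hits$start + 1L
  prio <- order(-score, -len, hits$start)
  rank <- match(seq_len(n), prio)
  compat <- function(idx) {
    if (length(idx) < 2L) return(TRUE)
    prs <- utils::combn(idx, 2L)
    all(hits$end[prs[1L, ]] < hits$start[prs[2L, ]] |
          hits$start[prs[1L, ]] > hits$end[prs[2L, ]])
  }
  subsets <- lapply(seq_len(2^n) - 1L,
                    function(m) which(bitwAnd(m, 2^(seq_len(n) - 1L)) > 0))
  good <- Filter(compat, subsets)
  maximal <- Filter(function(s) {
    extra <- setdiff(seq_len(n), s)
    !any(vapply(extra, function(e) compat(c(s, e)), TRUE))
  }, good)
  keys <- lapply(maximal, function(s) sort(rank[s]))
  best <- 1L
  for (i in seq_along(keys)[-1L]) {
    a <- keys[[best]]; b <- keys[[i]]
    L <- max(length(a), length(b))
    av <- c(a, rep(Inf, L - length(a))); bv <- c(b, rep(Inf, L - length(b)))
    diffpos <- which(av != bv)[1L]
    if (!is.na(diffpos) && bv[diffpos] < av[diffpos]) best <- i
  }
  sort(maximal[[best]])
}

write_lines_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
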