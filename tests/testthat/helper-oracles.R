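# Independent oracles used across the test suite. Each is a deliberately
# naive reimplementation on a different code path from the package.

# exhaustive affine-gap global alignment score: pure recursion over all
# monotone alignments (no memoization), gap run of length L costs
# open + extend*(L-1), end gaps penalized
oracle_nw_score <- function(a, b, submat, open = 10, extend = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, submat[av[i], bv[j]] + rec(i + 1, j + 1, "D"))
    }
    if (i <= length(av)) {
      cost <- if (last == "U") extend else open
      best <- max(best, rec(i + 1, j, "U") - cost)
    }
    if (j <= length(bv)) {
      cost <- if (last == "L") extend else open
      best <- max(best, rec(i, j + 1, "L") - cost)
    }
    best
  }
  rec(1, 1, "D")
}

# union-find connected components over a node universe
oracle_components <- function(nodes, edge_a, edge_b) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_along(edge_a)) {
    ra <- find(edge_a[k]); rb <- find(edge_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, "")
  split(nodes, roots)
}

# brute-force S/TQ cluster-domain finder: mark every subset of exactly
# min_motifs motifs whose span fits, merge subsets sharing a motif
oracle_scd <- function(positions, min_motifs = 3, max_span = 100) {
  pos <- sort(unique(positions))
  m <- length(pos)
  if (m < min_motifs) return(list())
  combs <- utils::combn(m, min_motifs)
  ok <- which(apply(combs, 2, function(ix)
    pos[max(ix)] - pos[min(ix)] + 1 <= max_span))
  if (!length(ok)) return(list())
  groups <- lapply(ok, function(c_i) combs[, c_i])
  # iterated merging of groups sharing any motif index
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    i <- 1
    while (i < length(groups)) {
      j <- i + 1
      while (j <= length(groups)) {
        if (length(intersect(groups[[i]], groups[[j]]))) {
          groups[[i]] <- sort(union(groups[[i]], groups[[j]]))
          groups[[j]] <- NULL
          changed <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
  }
  lapply(groups, function(ix) pos[sort(ix)])
}

# hypergeometric upper tail by direct combinatorial summation
oracle_hyper_upper <- function(k, K, N, n) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# textbook Yates chi-square
oracle_chi2_yates <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((pmax(abs(tab - E) - 0.5, 0))^2 / E)
}

# independent moderated-t recomputation for one protein from raw cells
oracle_moderated_t <- function(xs, xc, d0, s0_sq) {
  n1 <- length(xs); n2 <- length(xc)
  delta <- mean(xs) - mean(xc)
  sg <- (sum((xs - mean(xs))^2) + sum((xc - mean(xc))^2)) / (n1 + n2 - 2)
  dg <- n1 + n2 - 2
  spost <- if (is.infinite(d0)) s0_sq else (d0 * s0_sq + dg * sg) / (d0 + dg)
  t <- delta / sqrt(spost * (1 / n1 + 1 / n2))
  p <- if (is.infinite(d0)) 2 * pnorm(-abs(t)) else 2 * pt(-abs(t), d0 + dg)
  list(t = t, p = p, delta = delta, sg = sg)
}

# small evidence table builder for acceptance-logic tests
make_evidence <- function(...) {
  rows <- list(...)
  if (length(rows) == 0L)
    return(data.frame(dataset_id = character(), tissue = character(),
                      channel = character(), replicate = integer(),
                      protein_id = character(), peptide_seq = character(),
                      identified = integer(), peak_area = numeric(),
                      mod_positions = character(), mod_probs = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(rows, function(r) {
    data.frame(dataset_id = r$ds, tissue = r$tissue %||% "anther",
               channel = r$ch, replicate = r$rep %||% 1L,
               protein_id = r$prot, peptide_seq = r$pep,
               identified = r$id %||% 1L,
               peak_area = r$area %||% 1000,
               mod_positions = "", mod_probs = "",
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})
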