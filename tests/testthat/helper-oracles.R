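# Independent brute-force oracles used to validate the interval algebra,
# Fisher/BH statistics and classification rules. Everything here works at
# per-base or enumeration resolution on small genomes and never calls the
# package implementations it checks.

toy_layout <- function(len = 10000, n_chrom = 1) {
  genome_layout(paste0("chr", seq_len(n_chrom)), rep(len, n_chrom))
}

# Random peak table on a small single-chromosome genome.
random_peaks <- function(n, len = 10000, max_w = 400) {
  if (n == 0) return(peaks(character(), numeric(), numeric())[0, ])
  s <- sample.int(len - max_w, n, replace = TRUE) - 1
  w <- sample.int(max_w, n, replace = TRUE)
  peaks(rep("chr1", n), s, s + w)
}

# --- per-base interval oracles (single chromosome) ----------------------

# boolean coverage over [0, len)
base_cover <- function(x, len) {
  v <- logical(len)
  for (i in seq_len(nrow(x))) v[(x$start[i] + 1):x$end[i]] <- TRUE
  v
}

runs_to_peaks <- function(v) {
  r <- rle(v)
  e <- cumsum(r$lengths)
  s <- e - r$lengths
  keep <- r$values
  peaks(rep("chr1", sum(keep)), s[keep], e[keep])
}

# merge-with-gap oracle: repeat pairwise merging until fixpoint
oracle_merge <- function(x, gap = 0) {
  iv <- Map(c, x$start, x$end)
  repeat {
    merged <- FALSE
    for (i in seq_along(iv)) {
      if (merged) break
      for (j in seq_along(iv)) {
        if (i >= j) next
        sep <- max(iv[[i]][1], iv[[j]][1]) - min(iv[[i]][2], iv[[j]][2])
        if (sep <= gap) {
          iv[[i]] <- c(min(iv[[i]][1], iv[[j]][1]),
                       max(iv[[i]][2], iv[[j]][2]))
          iv <- iv[-j]
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  s <- vapply(iv, `[`, numeric(1), 1)
  e <- vapply(iv, `[`, numeric(1), 2)
  o <- order(s)
  peaks(rep("chr1", length(s)), s[o], e[o])
}

# overlap components oracle via union-find over both sets
oracle_components <- function(a, b) {
  mk <- function(x, lab) {
    data.frame(set = rep(lab, nrow(x)), row = seq_len(nrow(x)),
               start = x$start, end = x$end)
  }
  all <- rbind(mk(a, "a"), mk(b, "b"))
  n <- nrow(all)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && all$start[i] < all$end[j] && all$start[j] < all$end[i]) {
      parent[find(i)] <- find(j)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), root)
  both <- Filter(function(idx) length(unique(all$set[idx])) == 2, comps)
  matched <- function(lab) {
    v <- unlist(lapply(both, function(idx) {
      all$row[idx][all$set[idx] == lab]
    }))
    sort(unique(as.integer(c(v, integer(0)))))
  }
  list(n_components = length(both),
       a_matched = matched("a"), b_matched = matched("b"))
}

oracle_subtract <- function(x, y, len) {
  runs_to_peaks(base_cover(x, len) & !base_cover(y, len))
}

# regions covered by >= k of the per-clone interval sets
oracle_recurrent <- function(clone_list, len, k) {
  depth <- integer(len)
  for (x in clone_list) depth <- depth + base_cover(x, len)
  runs_to_peaks(depth >= k)
}

oracle_mean_signal <- function(values, bin_width, start, end) {
  pos <- start:(end - 1)
  mean(values[floor(pos / bin_width) + 1])
}

# --- statistics oracles -------------------------------------------------

# one-sided hypergeometric tail by explicit enumeration
oracle_fisher <- function(cu, ct, lu, lt) {
  k <- cu + ct
  xs <- max(0, k - lt):min(k, lu)
  probs <- choose(lu, xs) * choose(lt, k - xs) / choose(lu + lt, k)
  sum(probs[xs >= cu])
}

# naive O(n^2) BH step-up
oracle_bh <- function(p) {
  n <- length(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    ri <- sum(p <= p[i]) # rank with ties sharing the max rank
    cand <- vapply(seq_len(n), function(j) {
      rj <- sum(p <= p[j])
      if (p[j] >= p[i]) p[j] * n / rj else Inf
    }, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

# independent re-coding of the fold-change labelling rule
oracle_fc_label <- function(ctrl, kd, cutoff, pc) {
  out <- character(length(ctrl))
  for (i in seq_along(ctrl)) {
    a <- ctrl[i] + pc
    b <- kd[i] + pc
    out[i] <- if (a / b > cutoff) "decreased"
    else if (b / a > cutoff) "increased"
    else "unchanged"
  }
  out
}
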