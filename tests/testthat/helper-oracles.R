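# Independent oracles used across the suite. These deliberately avoid the
# package's own index/aligner code paths.

# quadratic both-strand window scan: every window of every reference is
# compared against the species sequence and its reverse complement
brute_force_hits <- function(species_vec, refs) {
  rc_manual <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  rows <- list()
  k <- 0L
  for (sp in unique(species_vec)) {
    L <- nchar(sp)
    rcsp <- rc_manual(sp)
    for (rn in names(refs)) {
      R <- refs[[rn]]
      if (nchar(R) < L) next
      starts <- 0:(nchar(R) - L)
      win <- substring(R, starts + 1L, starts + L)
      for (p in starts[win == sp]) {
        k <- k + 1L
        rows[[k]] <- data.frame(species = sp, reference = rn, position = p,
                                strand = "sense", stringsAsFactors = FALSE)
      }
      for (p in starts[win == rcsp]) {
        k <- k + 1L
        rows[[k]] <- data.frame(species = sp, reference = rn, position = p,
                                strand = "antisense", stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (k) do.call(rbind, rows) else
    data.frame(species = character(0), reference = character(0),
               position = integer(0), strand = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$species, out$reference, out$position, out$strand), ]
  rownames(out) <- NULL
  out
}

# exhaustive enumeration of all global alignments (match/mismatch
# scores, affine gap cost open + g * extend per gap run of length g);
# returns the optimal score. Exponential -- tiny sequences only.
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               open = 4, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i == length(A) && j == length(B)) return(0)
    best <- -Inf
    if (i < length(A) && j < length(B)) {
      s <- if (A[i + 1] == B[j + 1]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "d"))
    }
    if (i < length(A)) {
      g <- if (prev == "u") ext else open + ext
      best <- max(best, -g + rec(i + 1, j, "u"))
    }
    if (j < length(B)) {
      g <- if (prev == "l") ext else open + ext
      best <- max(best, -g + rec(i, j + 1, "l"))
    }
    best
  }
  rec(0L, 0L, "d")
}

# rank computation from first principles (sort-based, ties averaged),
# then plain Pearson on the ranks
spearman_brute <- function(x, y) {
  rk <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    i <- 1L
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1L
      r[o[i:j]] <- mean(i:j)
      i <- j + 1L
    }
    r
  }
  rx <- rk(x); ry <- rk(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# small standard bundle for pipeline tests (kept lighter than the default
# study conditions)
small_bundle <- function(seed, nesting_rate = 0) {
  synthetic_bundle(seed, n_copies = c(30L, 20L), background_length = 20000L,
                   nesting_rate = nesting_rate)
}
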