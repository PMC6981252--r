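# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct formula
# evaluation, or a reference library, never the function under test.

# O(n^2) DMR oracle: every maximal interval of >= min_cpgs significant CpGs
# whose consecutive gaps are all <= max_gap.
brute_force_dmrs <- function(chrom, pos, max_gap = 1000, min_cpgs = 2) {
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  n <- length(pos)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (chrom[j] != chrom[i]) break
      idx <- i:j
      if (length(idx) < min_cpgs) next
      gaps <- diff(pos[idx])
      if (any(gaps > max_gap)) next
      # maximal: cannot extend left or right
      left_ok <- i == 1 || chrom[i - 1] != chrom[i] ||
        pos[i] - pos[i - 1] > max_gap
      right_ok <- j == n || chrom[j + 1] != chrom[j] ||
        pos[j + 1] - pos[j] > max_gap
      if (left_ok && right_ok) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom[i], start = pos[i], end = pos[j],
          n_probes = length(idx))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_probes = integer(0)))
  }
  res <- unique(do.call(rbind, out))
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Hypergeometric upper tail by direct summation of the mass function
# written out with choose(); independent of phyper.
hyper_upper_sum <- function(N, n_a, n_b, k) {
  i <- k:min(n_a, n_b)
  sum(choose(n_b, i) * choose(N - n_b, n_a - i)) / choose(N, n_a)
}

# Full enumeration over all subsets of size n_a (only feasible for small N):
# the exact fraction of draws with >= k overlap with a fixed set of size n_b.
hyper_upper_enum <- function(N, n_a, n_b, k) {
  sets <- utils::combn(N, n_a)
  inb <- colSums(sets <= n_b)   # WLOG set B = 1..n_b
  mean(inb >= k)
}

# Nearest-edge island scan: literal distance minimisation over all islands.
brute_island_relation <- function(pos, islands) {
  if (nrow(islands) == 0L) return(list(relation = "OpenSea", distance = Inf))
  p0 <- pos - 1
  dists <- vapply(seq_len(nrow(islands)), function(i) {
    s <- islands$start[i]; e <- islands$end[i]
    if (p0 >= s && p0 < e) 0
    else if (p0 < s) s - p0
    else p0 - e + 1
  }, numeric(1))
  d <- min(dists)
  rel <- if (d == 0) "Island" else if (d <= 2000) "Shore"
         else if (d <= 4000) "Shelf" else "OpenSea"
  list(relation = rel, distance = d)
}

# Window-by-window O/E rescan of a sequence (naive substring counting).
brute_window_oe <- function(seq, start, window = 200L) {
  w <- substr(seq, start, start + window - 1L)
  ch <- strsplit(w, "")[[1]]
  nC <- sum(ch == "C"); nG <- sum(ch == "G")
  nCG <- sum(ch[-length(ch)] == "C" & ch[-1] == "G")
  if (nC * nG == 0) 0 else nCG * window / (nC * nG)
}

# Small paired beta fixture with a manifest, used by several files.
make_tiny_paired <- function(n_probes = 60L, n_donors = 4L, seed = 42L) {
  cfg <- sim_config(n_probes = n_probes, n_donors = n_donors,
                    fraction_planted_dml = 0.2, dmr_count = 2L,
                    n_tissue_specific = 5L, n_genes = 6L,
                    disease_size = 10L, disease_overlap = 3L, seed = seed)
  sim <- simulate_manifest(cfg)
  paired <- simulate_paired_betas(sim, cfg)
  list(cfg = cfg, sim = sim, paired = paired)
}
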