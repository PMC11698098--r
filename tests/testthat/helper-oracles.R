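## Independent oracles used to freeze expected values: deliberately written
## from first principles, not via the code paths they check.

## average ranks by direct counting (ties get the mean of their positions)
hand_rank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

## Spearman via Pearson on hand-computed average ranks
spearman_oracle <- function(x, y) {
  rx <- hand_rank(x)
  ry <- hand_rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

## two-tailed Fisher p by binomial-coefficient enumeration over the full
## conditional support
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

## build a single-strand genome sequence with an exact base composition and
## count a base by character tallying (the FASTA-composition oracle)
composition_sequence <- function(length_bp, gc_fraction) {
  n_gc <- round(length_bp * gc_fraction)
  n_at <- length_bp - n_gc
  paste(c(rep("A", ceiling(n_at / 2)), rep("T", floor(n_at / 2)),
          rep("G", ceiling(n_gc / 2)), rep("C", floor(n_gc / 2))),
        collapse = "")
}

count_base <- function(seq, base) {
  sum(strsplit(seq, "")[[1]] == base)
}

## small genome table builder for trait tests
toy_genomes <- function(presence, completeness = 100, contamination = 0,
                        clade = "I", taxon = "SAR11") {
  n <- nrow(presence)
  out <- data.frame(
    genome_id = sprintf("g%02d", seq_len(n)), taxon = taxon,
    clade = rep_len(clade, n),
    completeness = rep_len(completeness, n),
    contamination = rep_len(contamination, n)
  )
  for (g in colnames(presence)) out[[g]] <- presence[, g]
  out
}

## a uniform sample_gene_counts with constant densities
toy_sample <- function(gene_count = 50, gene_length = 500, ribo_count = 50,
                       ribo_length = 500, n_ribo = 14, depth = 10,
                       genes = c("geneA", "geneB")) {
  counts <- stats::setNames(rep_len(gene_count, length(genes)), genes)
  lens <- stats::setNames(rep_len(gene_length, length(genes)), genes)
  rn <- sprintf("ribo%02d", seq_len(n_ribo))
  sample_gene_counts(
    sample_id = "s1", station_id = "st1", depth = depth,
    counts = counts, hmm_lengths = lens,
    ribo_counts = stats::setNames(rep_len(ribo_count, n_ribo), rn),
    ribo_lengths = stats::setNames(rep_len(ribo_length, n_ribo), rn)
  )
}
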