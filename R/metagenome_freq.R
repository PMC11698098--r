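## Metagenome frequency module: single-copy-core normalization of gene hit
## counts into gene-per-genome frequencies, surface aggregation, environment
## correlations, and correlation-based gene grouping.

#' One metagenome sample's gene hit counts
#'
#' Bundles a sample's per-gene HMM hit counts with the HMM amino-acid
#' lengths, the hit counts of the 14 single-copy ribosomal proteins used as
#' the genome-abundance reference, and environmental metadata. Fewer than 14
#' ribosomal entries triggers a degraded-confidence warning and flag.
#'
#' @param sample_id,station_id Labels.
#' @param depth Sample depth in meters.
#' @param counts Named non-negative hit counts per target gene.
#' @param hmm_lengths Named HMM amino-acid lengths (> 0) covering `counts`.
#' @param ribo_counts Named hit counts of the single-copy ribosomal proteins.
#' @param ribo_lengths Named amino-acid lengths of the ribosomal proteins.
#' @param env Named list/vector of environmental variables (may hold `NA`).
#' @return Object of class `sample_gene_counts`.
#' @export
sample_gene_counts <- function(sample_id, station_id, depth, counts,
                               hmm_lengths, ribo_counts, ribo_lengths,
                               env = list()) {
  assert_numeric(counts, "counts", lower = 0)
  assert_numeric(hmm_lengths, "hmm_lengths", lower = 0, strict_lower = TRUE)
  assert_numeric(ribo_counts, "ribo_counts", lower = 0)
  assert_numeric(ribo_lengths, "ribo_lengths", lower = 0, strict_lower = TRUE)
  if (is.null(names(counts)) || is.null(names(hmm_lengths)) ||
      is.null(names(ribo_counts)) || is.null(names(ribo_lengths))) {
    stop("counts and lengths must be named vectors", call. = FALSE)
  }
  miss <- setdiff(names(counts), names(hmm_lengths))
  if (length(miss)) {
    stop("no HMM length for gene(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  miss <- setdiff(names(ribo_counts), names(ribo_lengths))
  if (length(miss)) {
    stop("no length for ribosomal protein(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  degraded <- length(ribo_counts) < 14L
  if (degraded) {
    warning(sprintf(
      "only %d ribosomal proteins (14 expected): core median is degraded",
      length(ribo_counts)), call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id),
         station_id = as.character(station_id),
         depth = depth, counts = counts, hmm_lengths = hmm_lengths,
         ribo_counts = ribo_counts, ribo_lengths = ribo_lengths,
         env = env, degraded = degraded),
    class = "sample_gene_counts"
  )
}

#' @export
print.sample_gene_counts <- function(x, ...) {
  cat(sprintf(
    "<sample_gene_counts> %s (station %s, %.0f m): %d genes, %d core genes\n",
    x$sample_id, x$station_id, x$depth, length(x$counts),
    length(x$ribo_counts)))
  invisible(x)
}

## internal: median length-normalized single-copy core signal of one sample.
## With 14 core genes the median is the midpoint of the 7th and 8th order
## statistics. raw = TRUE skips the length normalization of the cores.
core_median_density <- function(s, raw = FALSE) {
  if (raw) {
    stats::median(s$ribo_counts)
  } else {
    stats::median(s$ribo_counts / s$ribo_lengths[names(s$ribo_counts)])
  }
}

#' Gene-per-genome frequency from metagenome hit counts
#'
#' Estimates the fraction of cells of the focal taxon carrying each gene:
#' the gene's hit count is divided by its HMM amino-acid length (a length
#' density), then by the median length density of the single-copy ribosomal
#' proteins, which proxies one copy per genome. Frequencies are returned
#' unclipped -- values above 1 can arise for multi-copy or mis-mapped genes.
#' The estimator is exactly invariant under a common rescaling of all counts
#' (sequencing depth) and linear in the focal gene's count.
#'
#' @param s A [sample_gene_counts()].
#' @param genes Genes to estimate; default all genes in `s$counts`.
#' @param raw_core_median If `TRUE`, the ribosomal reference is the median of
#'   raw counts rather than length densities (compatibility switch; carries
#'   core length bias).
#' @return Named numeric frequencies; `NaN` (with a warning) when the core
#'   median signal is zero.
#' @export
genome_frequency <- function(s, genes = NULL, raw_core_median = FALSE) {
  stopifnot(inherits(s, "sample_gene_counts"))
  if (is.null(genes)) genes <- names(s$counts)
  miss <- setdiff(genes, names(s$counts))
  if (length(miss)) {
    stop("sample has no counts for gene(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  denom <- core_median_density(s, raw = raw_core_median)
  if (denom == 0) {
    warning("median single-copy core signal is zero: frequencies are NaN",
            call. = FALSE)
    return(stats::setNames(rep(NaN, length(genes)), genes))
  }
  dens <- s$counts[genes] / s$hmm_lengths[genes]
  dens / denom
}

#' Long-format frequency table over many samples
#'
#' @param samples List of [sample_gene_counts()] objects.
#' @param genes Genes to include; default: genes of the first sample.
#' @inheritParams genome_frequency
#' @return data.frame with columns `sample_id`, `station_id`, `depth`, one
#'   environmental column per variable found in the samples, `gene`, and
#'   `frequency`.
#' @export
frequency_table <- function(samples, genes = NULL, raw_core_median = FALSE) {
  stopifnot(length(samples) > 0)
  if (is.null(genes)) genes <- names(samples[[1]]$counts)
  env_vars <- unique(unlist(lapply(samples, function(s) names(s$env))))
  rows <- lapply(samples, function(s) {
    f <- genome_frequency(s, genes, raw_core_median = raw_core_median)
    d <- data.frame(sample_id = s$sample_id, station_id = s$station_id,
                    depth = s$depth, gene = genes, frequency = unname(f))
    for (v in env_vars) {
      d[[v]] <- if (v %in% names(s$env)) as.numeric(s$env[[v]]) else NA_real_
    }
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "raw_core_median") <- raw_core_median
  out
}

#' Per-station surface means of gene frequencies
#'
#' Averages per-sample frequencies over the samples within the upper
#' `max_depth` meters of the water column at each station; deeper samples
#' are excluded and stations with no qualifying sample are omitted with a
#' notice. The result is invariant to the ordering of samples.
#'
#' @param freq_table Long table from [frequency_table()] (needs columns
#'   `station_id`, `depth`, `gene`, `frequency`).
#' @param max_depth Depth cutoff in meters (default 100).
#' @return data.frame with columns `station_id`, `gene`, `n_samples`,
#'   `frequency`.
#' @export
surface_aggregate <- function(freq_table, max_depth = 100) {
  req <- c("station_id", "depth", "gene", "frequency")
  miss <- setdiff(req, names(freq_table))
  if (length(miss)) {
    stop("freq_table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- freq_table$depth <= max_depth
  dropped <- setdiff(unique(freq_table$station_id),
                     unique(freq_table$station_id[keep]))
  if (length(dropped)) {
    message("station(s) with no sample above ", max_depth, " m omitted: ",
            paste(dropped, collapse = ", "))
  }
  sub <- freq_table[keep, , drop = FALSE]
  key <- interaction(sub$station_id, sub$gene, drop = TRUE)
  pieces <- lapply(split(seq_len(nrow(sub)), key), function(idx) {
    data.frame(station_id = sub$station_id[idx[1]], gene = sub$gene[idx[1]],
               n_samples = length(idx),
               frequency = mean(sub$frequency[idx]))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$station_id, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation with an environmental variable
#'
#' Pearson correlation of average-ranked data (ties receive average ranks).
#' Pairs with a missing value in either vector are dropped; fewer than three
#' complete pairs, or zero variance in either ranked vector, yields `NaN`
#' with a warning.
#'
#' @param freq Gene frequency vector.
#' @param env Paired environmental values (same length).
#' @return Spearman's rank correlation in `[-1, 1]`, or `NaN`.
#' @export
spearman_env <- function(freq, env) {
  if (length(freq) != length(env)) {
    stop("`freq` and `env` must have equal length", call. = FALSE)
  }
  ok <- !is.na(freq) & !is.na(env)
  if (sum(ok) < 3) {
    warning("fewer than 3 complete pairs: correlation is NaN", call. = FALSE)
    return(NaN)
  }
  x <- freq[ok]
  y <- env[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation is NaN", call. = FALSE)
    return(NaN)
  }
  stats::cor(x, y, method = "spearman")
}

#' Group genes by correlation of their frequencies
#'
#' Single-linkage grouping over the gene-gene Pearson correlation matrix:
#' two genes share a group whenever a chain of pairwise correlations at or
#' above `threshold` connects them (connected components of the thresholded
#' correlation graph). Constant gene columns cannot be correlated and become
#' singletons, with a notice. The result is deterministic: genes are sorted
#' lexicographically within groups and groups are numbered by their first
#' member.
#'
#' @param freq_matrix Numeric matrix, samples x genes (column names are gene
#'   names); at least 2 genes and 3 samples.
#' @param threshold Pearson correlation at/above which genes are linked
#'   (default 0.7).
#' @param overrides Optional named character vector forcing genes into the
#'   group of another gene (name = gene to move, value = gene whose group it
#'   joins), used to encode curated grouping decisions that off-diagonal
#'   evidence (e.g. biogeography) supports despite a sub-threshold
#'   correlation.
#' @return data.frame with columns `gene` and `group` (integer ids).
#' @export
group_by_correlation <- function(freq_matrix, threshold = 0.7,
                                 overrides = NULL) {
  m <- as.matrix(freq_matrix)
  if (ncol(m) < 2 || nrow(m) < 3) {
    stop("need at least 2 genes and 3 samples", call. = FALSE)
  }
  genes <- colnames(m)
  if (is.null(genes)) {
    stop("freq_matrix must have gene column names", call. = FALSE)
  }
  constant <- apply(m, 2, function(x) stats::sd(x) == 0)
  if (any(constant)) {
    message("constant gene column(s) isolated as singletons: ",
            paste(genes[constant], collapse = ", "))
  }
  suppressWarnings(r <- stats::cor(m))
  adj <- !is.na(r) & r >= threshold
  diag(adj) <- TRUE
  adj[constant, ] <- FALSE
  adj[, constant] <- FALSE
  ## connected components via repeated expansion (boolean matrix closure)
  comp <- rep(NA_integer_, length(genes))
  next_id <- 0L
  for (i in order(genes)) {
    if (!is.na(comp[i])) next
    next_id <- next_id + 1L
    members <- i
    repeat {
      reach <- which(apply(adj[members, , drop = FALSE], 2, any))
      reach <- setdiff(reach, members)
      if (!length(reach)) break
      members <- c(members, reach)
    }
    if (constant[i]) members <- i
    comp[members] <- next_id
  }
  if (!is.null(overrides)) {
    for (g in names(overrides)) {
      gi <- match(g, genes)
      ti <- match(overrides[[g]], genes)
      if (is.na(gi) || is.na(ti)) {
        warning("override refers to unknown gene: ", g, " -> ",
                overrides[[g]], call. = FALSE)
        next
      }
      comp[gi] <- comp[ti]
    }
  }
  ## renumber groups by lexicographically first member
  firsts <- vapply(split(genes, comp), min, character(1))
  relabel <- stats::setNames(rank(firsts, ties.method = "first"),
                             names(firsts))
  out <- data.frame(gene = genes,
                    group = as.integer(relabel[as.character(comp)]))
  out[order(out$group, out$gene), , drop = FALSE]
}
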