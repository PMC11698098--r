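## Genome trait module: quality filtering, trait frequencies, universality
## classification, clade breakdowns, phylometabolic matrices.

GENOME_META_COLS <- c("genome_id", "taxon", "clade", "completeness",
                      "contamination")

## internal: names of the 0/1 gene presence columns of a genome table
gene_columns <- function(genomes) {
  setdiff(names(genomes), GENOME_META_COLS)
}

validate_genomes <- function(genomes) {
  miss <- setdiff(c("genome_id", "completeness", "contamination"),
                  names(genomes))
  if (length(miss)) {
    stop("genome table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  assert_numeric(genomes$completeness, "completeness", lower = 0, upper = 100)
  assert_numeric(genomes$contamination, "contamination", lower = 0)
  invisible(genomes)
}

#' Genome quality score
#'
#' The MAG/SAG quality score `completeness - 5 * contamination` (both in
#' percent) that weighs contamination five-fold against completeness.
#'
#' @param completeness Percent completeness, 0--100.
#' @param contamination Percent contamination, >= 0.
#' @return Numeric score.
#' @export
quality_score <- function(completeness, contamination) {
  assert_numeric(completeness, "completeness", lower = 0, upper = 100)
  assert_numeric(contamination, "contamination", lower = 0)
  completeness - 5 * contamination
}

#' Quality-filter a genome set
#'
#' Retains genomes whose quality score (`completeness - 5 * contamination`)
#' is at least `threshold`; genomes scoring strictly below are excluded. The
#' boundary case (score exactly equal to the threshold) is retained, and the
#' input order is preserved. The filter is idempotent.
#'
#' @param genomes data.frame with columns `genome_id`, `completeness`,
#'   `contamination` (plus any trait columns, carried through).
#' @param threshold Minimum retained quality score (default 30).
#' @return The retained subset of `genomes`.
#' @export
quality_filter <- function(genomes, threshold = 30) {
  validate_genomes(genomes)
  keep <- quality_score(genomes$completeness, genomes$contamination) >=
    threshold
  genomes[keep, , drop = FALSE]
}

#' Observed trait frequency in a genome set
#'
#' Percentage of genomes in which each gene is called present. Genes with no
#' column in the table count as absent in every genome. Note that in
#' incomplete genomes (MAGs/SAGs) the observed frequency understates the true
#' frequency by roughly the factor mean completeness / 100; see
#' [classify_universality()].
#'
#' @param genomes data.frame of genome records with 0/1 gene columns.
#' @param genes Character vector of genes to tally; defaults to every
#'   non-metadata column.
#' @return Named numeric vector of percentages.
#' @export
gene_frequency <- function(genomes, genes = NULL) {
  if (nrow(genomes) == 0L) {
    stop("cannot compute frequencies on an empty genome set", call. = FALSE)
  }
  if (is.null(genes)) genes <- gene_columns(genomes)
  vapply(genes, function(g) {
    if (!g %in% names(genomes)) return(0)
    100 * sum(genomes[[g]] > 0, na.rm = TRUE) / nrow(genomes)
  }, numeric(1))
}

#' Classify a trait as near-universal, subgroup-restricted, or absent
#'
#' In incomplete genome collections a truly universal gene is observed at a
#' frequency close to the mean genome completeness rather than 100%. A trait
#' is therefore called `"near-universal"` when its observed frequency reaches
#' within `tolerance` percentage points of the mean completeness, `"absent"`
#' at frequency zero, and `"subgroup"` otherwise. The classification is
#' monotone in frequency.
#'
#' @param freq Observed frequency/ies in percent (0--100).
#' @param mean_completeness Mean genome completeness in percent.
#' @param tolerance Band below mean completeness still called near-universal
#'   (percentage points, default 10).
#' @return Character vector with values `"near-universal"`, `"subgroup"`,
#'   `"absent"`.
#' @export
classify_universality <- function(freq, mean_completeness, tolerance = 10) {
  assert_numeric(freq, "freq", lower = 0, upper = 100)
  assert_numeric(mean_completeness, "mean_completeness", lower = 0,
                 upper = 100)
  ifelse(freq == 0, "absent",
         ifelse(freq >= mean_completeness - tolerance,
                "near-universal", "subgroup"))
}

#' Completeness-corrected trait frequency
#'
#' Estimates the true fraction of genomes carrying a gene by dividing the
#' observed frequency by the mean completeness, under the model that a
#' present gene is recovered in an assembly with probability equal to the
#' genome's completeness.
#'
#' @param genomes Genome table (see [gene_frequency()]).
#' @param genes Genes to estimate; default all.
#' @return Named vector of estimated true frequencies on the 0--1 scale
#'   (may exceed 1 slightly through sampling noise).
#' @export
corrected_frequency <- function(genomes, genes = NULL) {
  obs <- gene_frequency(genomes, genes)
  obs / mean(genomes$completeness)
}

#' Build a trait catalog
#'
#' A catalog maps functional categories (purine assimilation, the energy,
#' carbon, and nitrogen harvesting portions of purine catabolism, allantoin
#' transport and catabolism, urease, pyrimidine usage) to their member genes,
#' and flags which genes encode transporters.
#'
#' @param categories Named list of character vectors (category -> genes).
#' @param transporters Character vector of transporter gene names.
#' @return Object of class `trait_catalog`.
#' @export
trait_catalog <- function(categories, transporters = character()) {
  if (!is.list(categories) || is.null(names(categories)) ||
      any(!nzchar(names(categories)))) {
    stop("`categories` must be a named list of gene name vectors",
         call. = FALSE)
  }
  if (any(lengths(categories) == 0L)) {
    stop("every category must contain at least one gene", call. = FALSE)
  }
  structure(list(categories = lapply(categories, as.character),
                 transporters = as.character(transporters)),
            class = "trait_catalog")
}

#' @export
print.trait_catalog <- function(x, ...) {
  cat(sprintf("<trait_catalog> %d categories, %d genes (%d transporters)\n",
              length(x$categories), length(catalog_genes(x)),
              length(x$transporters)))
  invisible(x)
}

#' Genes of a trait catalog, in category order
#' @param catalog A [trait_catalog()].
#' @return Character vector of unique gene names.
#' @export
catalog_genes <- function(catalog) {
  stopifnot(inherits(catalog, "trait_catalog"))
  unique(unlist(catalog$categories, use.names = FALSE))
}

#' Read a trait catalog from JSON
#'
#' Expects an object with a `categories` member (category -> array of gene
#' names) and an optional `transporters` array.
#'
#' @param path Path to a JSON file.
#' @return A [trait_catalog()].
#' @export
read_trait_catalog <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  trait_catalog(as.list(x$categories),
                transporters = if (is.null(x$transporters)) character()
                               else x$transporters)
}

#' Trait frequencies by clade and functional category
#'
#' Computes per-gene observed frequencies within each clade, plus a category
#' aggregate. The default aggregate is the mean of member-gene frequencies;
#' `"intersection"` instead reports the frequency of genomes carrying every
#' member gene (an operon-complete call). Genomes with a missing or
#' `"unknown"` clade label are omitted with a notice; clade labels are
#' matched exactly after whitespace trimming.
#'
#' @param genomes Genome table (see [gene_frequency()]).
#' @param catalog A [trait_catalog()].
#' @param aggregate `"mean"` or `"intersection"`.
#' @return data.frame with columns `clade`, `n_genomes`, `unit`
#'   (`"gene"`/`"category"`), `name`, `frequency` (percent).
#' @export
clade_breakdown <- function(genomes, catalog,
                            aggregate = c("mean", "intersection")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(catalog, "trait_catalog"))
  if (!"clade" %in% names(genomes)) {
    stop("genome table lacks a `clade` column", call. = FALSE)
  }
  clade <- trimws(as.character(genomes$clade))
  usable <- !is.na(clade) & nzchar(clade) & clade != "unknown"
  if (!any(usable)) {
    stop("no genomes with a known clade label", call. = FALSE)
  }
  if (any(!usable)) {
    message(sum(!usable), " genome(s) without a clade label omitted")
  }
  genes <- catalog_genes(catalog)
  pieces <- lapply(split(which(usable), clade[usable]), function(idx) {
    sub <- genomes[idx, , drop = FALSE]
    gf <- gene_frequency(sub, genes)
    cf <- vapply(names(catalog$categories), function(cat) {
      members <- catalog$categories[[cat]]
      if (aggregate == "mean") {
        mean(gene_frequency(sub, members))
      } else {
        present <- vapply(members, function(g) {
          if (!g %in% names(sub)) rep(FALSE, nrow(sub)) else sub[[g]] > 0
        }, logical(nrow(sub)))
        100 * sum(apply(as.matrix(present), 1, all)) / nrow(sub)
      }
    }, numeric(1))
    data.frame(
      clade = clade[idx[1]],
      n_genomes = nrow(sub),
      unit = c(rep("gene", length(gf)), rep("category", length(cf))),
      name = c(names(gf), names(cf)),
      frequency = unname(c(gf, cf))
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Phylometabolic presence/absence matrix
#'
#' Arranges per-genome gene presence calls into a matrix whose rows follow
#' the leaf order of a genome phylogeny (or the input order when no tree is
#' given) and whose columns are grouped by catalog category. Tree leaves
#' without a genome record, and genomes missing from the tree, are never
#' silently dropped: they are listed in the attached reconciliation report.
#'
#' @param genomes Genome table (see [gene_frequency()]).
#' @param catalog Optional [trait_catalog()] fixing the column set/order;
#'   default: all gene columns in input order.
#' @param tree Optional `ape::phylo` object or path to a newick file whose
#'   tip labels are genome ids.
#' @return Integer 0/1 matrix (genomes x genes) with attributes `report`
#'   (list with `tips_without_genome`, `genomes_not_in_tree`) and `category`
#'   (per-column category label, when a catalog is given).
#' @export
phylometabolic_matrix <- function(genomes, catalog = NULL, tree = NULL) {
  validate_genomes(genomes)
  if (is.null(catalog)) {
    genes <- gene_columns(genomes)
    category <- NULL
  } else {
    stopifnot(inherits(catalog, "trait_catalog"))
    genes <- catalog_genes(catalog)
    category <- vapply(genes, function(g) {
      names(catalog$categories)[vapply(catalog$categories,
                                       function(m) g %in% m, logical(1))][1]
    }, character(1))
  }
  ids <- as.character(genomes$genome_id)
  report <- list(tips_without_genome = character(),
                 genomes_not_in_tree = character())
  if (!is.null(tree)) {
    if (is.character(tree)) tree <- ape::read.tree(tree)
    stopifnot(inherits(tree, "phylo"))
    tips <- tree$tip.label
    report$tips_without_genome <- setdiff(tips, ids)
    report$genomes_not_in_tree <- setdiff(ids, tips)
    row_ids <- tips[tips %in% ids]
  } else {
    row_ids <- ids
  }
  m <- matrix(0L, nrow = length(row_ids), ncol = length(genes),
              dimnames = list(row_ids, genes))
  idx <- match(row_ids, ids)
  for (g in genes) {
    if (g %in% names(genomes)) {
      m[, g] <- as.integer(genomes[[g]][idx] > 0)
    }
  }
  attr(m, "report") <- report
  if (!is.null(category)) attr(m, "category") <- category
  m
}
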