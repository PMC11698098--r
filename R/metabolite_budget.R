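## Exometabolite budget module: extraction-efficiency correction, DNA base
## incorporation, exudation ratios, intracellular molarities.

#' Correct extract concentrations for solid-phase extraction efficiency
#'
#' Converts a measured extract concentration into the concentration in the
#' original spent medium via `conc_media = 100 * conc_extract / ef_percent`.
#' The correction is applied only when the extraction efficiency exceeds 1%
#' because extraction efficiencies below that are too uncertain to invert;
#' such compounds are reported uncorrected and flagged.
#'
#' @param conc_extract Measured concentration(s) in the extract (ng/mL).
#' @param ef_percent Extraction efficiency on the 0--100 scale.
#' @param hypothetical_100x If `TRUE`, uncorrected compounds (EF% <= 1) are
#'   additionally scaled by the fixed factor 100 -- the theoretical correction
#'   for an extraction efficiency of exactly 1% -- as a display aid for
#'   judging the scale of compounds that cannot be corrected. The `corrected`
#'   flag stays `FALSE` for these values.
#' @return A data.frame with columns `conc_media` (ng/mL), `corrected`
#'   (logical: was the EF% correction applied), and `hypothetical` (logical:
#'   was the 100x display scaling applied).
#' @examples
#' correct_extraction(2.0, 50)    # -> 4.0, corrected
#' correct_extraction(2.0, 0.5)   # -> 2.0, uncorrected
#' @export
correct_extraction <- function(conc_extract, ef_percent,
                               hypothetical_100x = FALSE) {
  assert_numeric(conc_extract, "conc_extract", lower = 0, allow_na = TRUE)
  assert_numeric(ef_percent, "ef_percent", lower = 0, upper = 100)
  n <- max(length(conc_extract), length(ef_percent))
  conc_extract <- rep_len(conc_extract, n)
  ef_percent <- rep_len(ef_percent, n)
  corrected <- ef_percent > 1
  conc_media <- ifelse(corrected, 100 * conc_extract / ef_percent, conc_extract)
  hypothetical <- rep(FALSE, n)
  if (isTRUE(hypothetical_100x)) {
    conc_media[!corrected] <- conc_extract[!corrected] * 100
    hypothetical <- !corrected
  }
  data.frame(conc_media = conc_media, corrected = corrected,
             hypothetical = hypothetical)
}

#' Extraction correction factor
#'
#' The multiplier `100 / EF%` implied by the extraction-efficiency formula.
#' At EF% = 1 this is exactly 100, the hypothetical correction factor used to
#' display the scale of compounds whose efficiencies are below the 1%
#' correction floor.
#'
#' @param ef_percent Extraction efficiency on the 0--100 scale (must be > 0).
#' @return The dimensionless correction factor.
#' @export
extraction_correction_factor <- function(ef_percent) {
  assert_numeric(ef_percent, "ef_percent", lower = 0, upper = 100,
                 strict_lower = TRUE)
  100 / ef_percent
}

#' Describe a strain and culture context
#'
#' Bundles the per-strain quantities needed to convert concentrations into
#' per-cell and per-genome terms: cell counts, culture and extract volumes,
#' genome length and GC content, dry mass and cell volume.
#'
#' @param strain Strain label.
#' @param genome_length Chromosome length in base pairs (> 0).
#' @param gc_fraction GC content as a fraction in `[0, 1]` (the closed
#'   interval admits degenerate compositions, e.g. an all-GC duplex has no
#'   thymidine incorporation).
#' @param cells_total Total cells captured/produced (optional, > 0 where used).
#' @param culture_volume,extract_volume Volumes in mL.
#' @param dry_mass Cellular dry mass, fg per cell.
#' @param cell_volume Cell volume, um^3 per cell.
#' @param chromosomes_per_cell Chromosome copies per cell (default 1, the
#'   standard assumption for *Prochlorococcus*).
#' @return An object of class `strain_context`.
#' @export
strain_context <- function(strain, genome_length, gc_fraction,
                           cells_total = NA_real_, culture_volume = NA_real_,
                           extract_volume = NA_real_, dry_mass = NA_real_,
                           cell_volume = NA_real_, chromosomes_per_cell = 1) {
  assert_numeric(genome_length, "genome_length", lower = 0, strict_lower = TRUE)
  assert_numeric(gc_fraction, "gc_fraction", lower = 0, upper = 1)
  assert_numeric(chromosomes_per_cell, "chromosomes_per_cell", lower = 1)
  if (!is.na(cell_volume)) {
    assert_numeric(cell_volume, "cell_volume", lower = 0, strict_lower = TRUE)
  }
  structure(
    list(strain = as.character(strain), genome_length = genome_length,
         gc_fraction = gc_fraction, cells_total = cells_total,
         culture_volume = culture_volume, extract_volume = extract_volume,
         dry_mass = dry_mass, cell_volume = cell_volume,
         chromosomes_per_cell = chromosomes_per_cell),
    class = "strain_context"
  )
}

#' @export
print.strain_context <- function(x, ...) {
  cat(sprintf("<strain_context> %s: %d bp, GC %.1f%%, %g chromosome(s)/cell\n",
              x$strain, round(x$genome_length), 100 * x$gc_fraction,
              x$chromosomes_per_cell))
  invisible(x)
}

#' Moles of a DNA base incorporated during growth
#'
#' Computes the moles of base A, T, G, or C incorporated into newly
#' synthesized genomes, from the genome length, GC fraction, and the net
#' number of cells produced. Under the default `"duplex"` convention a
#' double-stranded genome of L bp contains `L * (1 - GC) / 2` T residues per
#' base identity (A = T and G = C pairing forces the symmetric split), so the
#' four bases sum to L. The `"per-strand"` convention omits the division by
#' 2, counting both strands of each base pair.
#'
#' @param ctx A [strain_context()].
#' @param base One of `"A"`, `"T"`, `"G"`, `"C"`.
#' @param cells_new Net number of cells produced over the experiment
#'   (final minus initial count; >= 0). May be a vector.
#' @param convention `"duplex"` (default) or `"per-strand"`.
#' @return Moles of the base incorporated into DNA.
#' @export
base_incorporation <- function(ctx, base, cells_new,
                               convention = c("duplex", "per-strand")) {
  stopifnot(inherits(ctx, "strain_context"))
  convention <- match.arg(convention)
  assert_numeric(cells_new, "cells_new", lower = 0)
  base <- toupper(as.character(base))
  if (length(base) != 1L || !base %in% c("A", "T", "G", "C")) {
    stop("`base` must be one of 'A', 'T', 'G', 'C'", call. = FALSE)
  }
  frac <- if (base %in% c("G", "C")) ctx$gc_fraction else 1 - ctx$gc_fraction
  divisor <- if (convention == "duplex") 2 else 1
  per_chromosome <- ctx$genome_length * frac / divisor
  cells_new * ctx$chromosomes_per_cell * per_chromosome / .avogadro
}

#' Exudation-to-incorporation ratio
#'
#' The extracellular pool of a base-containing compound expressed as a
#' fraction of the total amount of that base incorporated into DNA over the
#' experiment -- the dimensionless budget quantity used to judge whether
#' exudation is large relative to biosynthetic demand.
#'
#' @param extracellular_moles Moles of the compound in the spent medium.
#' @param incorporated_moles Moles of the corresponding base incorporated
#'   into DNA (must be > 0).
#' @return The ratio (>= 0).
#' @export
exudation_ratio <- function(extracellular_moles, incorporated_moles) {
  assert_numeric(extracellular_moles, "extracellular_moles", lower = 0)
  assert_numeric(incorporated_moles, "incorporated_moles", lower = 0)
  if (any(incorporated_moles == 0)) {
    stop("`incorporated_moles` must be > 0: the ratio is undefined otherwise",
         call. = FALSE)
  }
  extracellular_moles / incorporated_moles
}

#' Intracellular molar concentration of a metabolite
#'
#' Converts an extract concentration into a cytosolic molarity:
#' ng/mL in the cell extract -> fg per cell (via extract volume and total
#' cells captured) -> mol per cell (via molar mass) -> mol/L (via cell
#' volume, um^3 -> L).
#'
#' @param conc_extract Concentration in the cell extract, ng/mL.
#' @param extract_volume Extract volume, mL.
#' @param cells_total Total cells captured on the filter (> 0).
#' @param molar_mass Molar mass of the metabolite, g/mol (> 0).
#' @param cell_volume Cell volume, um^3 (> 0).
#' @return Molar concentration (mol/L).
#' @examples
#' # 1 ng/mL in 1 mL over 1e6 cells of 0.18 um^3, adenine (135.13 g/mol)
#' intracellular_molarity(1, 1, 1e6, 135.13, 0.18)  # ~0.0411 M
#' @export
intracellular_molarity <- function(conc_extract, extract_volume, cells_total,
                                   molar_mass, cell_volume) {
  assert_numeric(conc_extract, "conc_extract", lower = 0)
  assert_numeric(extract_volume, "extract_volume", lower = 0,
                 strict_lower = TRUE)
  assert_numeric(cells_total, "cells_total", lower = 0, strict_lower = TRUE)
  assert_numeric(molar_mass, "molar_mass", lower = 0, strict_lower = TRUE)
  assert_numeric(cell_volume, "cell_volume", lower = 0, strict_lower = TRUE)
  fg_per_cell <- conc_extract * extract_volume / cells_total * 1e6 # ng -> fg
  mol_per_cell <- fg_per_cell * 1e-15 / molar_mass                 # fg -> g
  mol_per_cell / (cell_volume * 1e-15)                             # um^3 -> L
}

#' Scale a cell volume by relative dry mass
#'
#' Estimates the volume of a strain without a direct measurement by scaling a
#' reference strain's measured volume by the ratio of cellular dry masses.
#'
#' @param ref_volume Measured volume of the reference strain, um^3.
#' @param ref_mass Dry mass of the reference strain, fg per cell.
#' @param target_mass Dry mass of the target strain, fg per cell.
#' @return Estimated volume of the target strain, um^3.
#' @examples
#' scale_cell_volume(0.2, 66, 60) # 0.18 um^3
#' scale_cell_volume(0.2, 66, 91) # 0.28 um^3
#' @export
scale_cell_volume <- function(ref_volume, ref_mass, target_mass) {
  assert_numeric(ref_volume, "ref_volume", lower = 0, strict_lower = TRUE)
  assert_numeric(ref_mass, "ref_mass", lower = 0, strict_lower = TRUE)
  assert_numeric(target_mass, "target_mass", lower = 0, strict_lower = TRUE)
  ref_volume * target_mass / ref_mass
}

#' Summarize metabolite replicates
#'
#' Mean and SD of extract concentrations across biological replicates.
#' Measurements flagged `"detected"` (seen in a single replicate, not
#' quantifiable) or `"nd"` (not detected) enter as missing values, never as
#' zeros, so they do not bias means or SDs; the per-compound detection status
#' reflects the strongest call among replicates.
#'
#' @param measurements data.frame with columns `compound`, `replicate_id`,
#'   `conc_extract`, `ef_percent`, `detected` (one of `"quantified"`,
#'   `"detected"`, `"nd"`).
#' @return data.frame with one row per compound: `n_quantified`,
#'   `mean_conc_extract`, `sd_conc_extract`, `ef_percent`, `status`.
#' @export
summarize_replicates <- function(measurements) {
  req <- c("compound", "replicate_id", "conc_extract", "ef_percent", "detected")
  miss <- setdiff(req, names(measurements))
  if (length(miss)) {
    stop("measurements lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok_status <- c("quantified", "detected", "nd")
  if (!all(measurements$detected %in% ok_status)) {
    stop("`detected` must be one of: ", paste(ok_status, collapse = ", "),
         call. = FALSE)
  }
  conc <- ifelse(measurements$detected == "quantified",
                 measurements$conc_extract, NA_real_)
  out <- lapply(split(seq_len(nrow(measurements)), measurements$compound),
                function(idx) {
    x <- conc[idx]
    status_rank <- match(measurements$detected[idx], ok_status)
    data.frame(
      compound = measurements$compound[idx[1]],
      n_quantified = sum(!is.na(x)),
      mean_conc_extract = if (all(is.na(x))) NA_real_ else
        mean(x, na.rm = TRUE),
      sd_conc_extract = if (sum(!is.na(x)) < 2) NA_real_ else
        stats::sd(x, na.rm = TRUE),
      ef_percent = measurements$ef_percent[idx[1]],
      status = ok_status[min(status_rank)]
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Full exudation budget for a culture experiment
#'
#' Runs the complete budget path for a set of measured exometabolites:
#' replicate summary, extraction-efficiency correction, conversion of media
#' concentrations to moles, DNA base incorporation from cell counts and
#' genome GC content, and the exudation-to-incorporation ratio.
#'
#' @param measurements Replicate-level measurements as in
#'   [summarize_replicates()].
#' @param ctx A [strain_context()] with `culture_volume` set.
#' @param cells_new Net cells produced over the experiment (final - initial).
#' @param compound_info data.frame with columns `compound`, `molar_mass`
#'   (g/mol), and `base` (the DNA base each compound is normalized to:
#'   thymidine and adenine-containing compounds to the AT content, guanine to
#'   the GC content).
#' @param convention Base-counting convention, see [base_incorporation()].
#' @param hypothetical_100x Apply the 100x display scaling to uncorrectable
#'   compounds, see [correct_extraction()].
#' @return data.frame with one row per compound: media concentration,
#'   correction flags, extracellular and incorporated moles, and the
#'   exudation ratio.
#' @export
exudation_budget <- function(measurements, ctx, cells_new, compound_info,
                             convention = c("duplex", "per-strand"),
                             hypothetical_100x = FALSE) {
  stopifnot(inherits(ctx, "strain_context"))
  convention <- match.arg(convention)
  if (is.na(ctx$culture_volume)) {
    stop("`ctx$culture_volume` is required for the budget path", call. = FALSE)
  }
  smry <- summarize_replicates(measurements)
  smry <- merge(smry, compound_info, by = "compound", sort = FALSE)
  corr <- correct_extraction(smry$mean_conc_extract, smry$ef_percent,
                             hypothetical_100x = hypothetical_100x)
  ## ng/mL * mL -> ng -> g -> mol
  extracellular_moles <- corr$conc_media * ctx$culture_volume * 1e-9 /
    smry$molar_mass
  incorporated_moles <- vapply(smry$base, function(b) {
    base_incorporation(ctx, b, cells_new, convention = convention)
  }, numeric(1))
  ratio <- ifelse(is.na(extracellular_moles), NA_real_,
                  extracellular_moles / incorporated_moles)
  data.frame(
    compound = smry$compound,
    status = smry$status,
    conc_media = corr$conc_media,
    corrected = corr$corrected,
    hypothetical = corr$hypothetical,
    extracellular_moles = extracellular_moles,
    incorporated_moles = incorporated_moles,
    exudation_ratio = ratio
  )
}
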