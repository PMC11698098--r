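## Synthetic-data module: seeded generators emulating every input the
## pipeline consumes, each returning the planted ground truth alongside the
## data so recovery tests never re-derive truth from outputs.

#' Default SAR11 true trait frequencies
#'
#' Genus-wide true (pre-dropout) frequencies for a SAR11-like genome set:
#' purine assimilation genes universal; the purine catabolism operon,
#' allantoin transport/catabolism, urease, and pyrimidine usage genes
#' restricted to subgroups at the relative levels seen in curated marine
#' genome collections.
#'
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
sar11_gene_freqs <- function() {
  c(
    ## assimilation: transporter + phosphoribosyltransferase, universal
    purine_ncs2_permease = 1.00,
    purine_mfs_permease  = 1.00,
    purine_pprt          = 1.00,
    ## energy-harvesting portion of the catabolism operon
    xdh_mo               = 0.25,
    xdh_fad              = 0.25,
    urate_oxidase        = 0.25,
    hiuH                 = 0.25,
    ## nitrogen-harvesting deaminases
    purine_deaminase_1   = 0.25,
    purine_deaminase_2   = 0.25,
    ## carbon harvesting / allantoin catabolism
    allantoinase         = 0.30,
    allantoicase         = 0.30,
    ureidoglycolate_lyase = 0.30,
    ## allantoin uptake
    allantoin_ncs1_permease = 0.17,
    ## urea breakdown
    urease               = 0.07,
    ## pyrimidine usage
    thymidine_kinase     = 0.04,
    pyrimidine_abc_transporter = 0.04
  )
}

#' Trait catalog matching the default SAR11 generator genes
#' @return A [trait_catalog()].
#' @export
sar11_trait_catalog <- function() {
  trait_catalog(
    categories = list(
      purine_assimilation = c("purine_ncs2_permease", "purine_mfs_permease",
                              "purine_pprt"),
      purine_catabolism_energy = c("xdh_mo", "xdh_fad", "urate_oxidase",
                                   "hiuH"),
      purine_catabolism_nitrogen = c("purine_deaminase_1",
                                     "purine_deaminase_2"),
      purine_catabolism_carbon = c("allantoinase", "allantoicase",
                                   "ureidoglycolate_lyase"),
      allantoin_transport = "allantoin_ncs1_permease",
      allantoin_catabolism = c("allantoinase", "allantoicase",
                               "ureidoglycolate_lyase"),
      urease = "urease",
      pyrimidine_usage = c("thymidine_kinase", "pyrimidine_abc_transporter")
    ),
    transporters = c("purine_ncs2_permease", "purine_mfs_permease",
                     "allantoin_ncs1_permease", "pyrimidine_abc_transporter")
  )
}

#' The 14 single-copy ribosomal proteins and their amino-acid lengths
#'
#' Canonical approximate lengths (aa) of the universal single-copy
#' ribosomal proteins used as the genome-abundance reference.
#'
#' @return Named integer vector of 14 lengths.
#' @export
sar11_ribosomal_proteins <- function() {
  c(rplB = 275, rplC = 209, rplD = 201, rplE = 179, rplF = 177,
    rplN = 122, rplP = 138, rplR = 117, rplV = 110, rpsC = 232,
    rpsH = 130, rpsJ = 102, rpsQ = 84, rpsS = 92)
}

#' Simulate a genome collection with completeness-driven gene dropout
#'
#' Each genome draws a completeness (percent) and contamination; each gene
#' is truly present with its planted frequency (per clade when
#' `clade_profiles` is given) and, when truly present, is *observed* with
#' probability completeness/100, independently across genes. This is the
#' dropout model under which a universal gene is observed at a frequency
#' equal to the mean completeness.
#'
#' @param n Number of genomes (default 186, a SAR11-collection scale).
#' @param seed Integer seed; identical seed and parameters give identical
#'   output.
#' @param taxon Taxon label.
#' @param gene_freqs Named true frequencies in `[0, 1]`
#'   (default [sar11_gene_freqs()]); ignored for clades listed in
#'   `clade_profiles`.
#' @param clade_probs Named clade sampling probabilities (default: a single
#'   `"I"` clade).
#' @param clade_profiles Optional named list clade -> named frequency vector
#'   overriding `gene_freqs` within that clade.
#' @param completeness_range Uniform range of completeness in percent
#'   (default `c(50, 95)`, mean ~72%).
#' @param contamination_mean Mean of the exponential contamination draw in
#'   percent (default 0.5).
#' @return List with `genomes` (data.frame: metadata plus one 0/1 column per
#'   gene) and `truth` (list: `true_presence` logical matrix, `completeness`,
#'   `gene_freqs`, `clade_profiles`).
#' @export
gen_genomes <- function(n = 186, seed = NULL, taxon = "SAR11",
                        gene_freqs = sar11_gene_freqs(),
                        clade_probs = c(I = 1),
                        clade_profiles = NULL,
                        completeness_range = c(50, 95),
                        contamination_mean = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  genes <- names(gene_freqs)
  clades <- sample(names(clade_probs), n, replace = TRUE,
                   prob = clade_probs)
  completeness <- stats::runif(n, completeness_range[1],
                               completeness_range[2])
  contamination <- stats::rexp(n, rate = 1 / contamination_mean)
  true_presence <- matrix(FALSE, nrow = n, ncol = length(genes),
                          dimnames = list(NULL, genes))
  observed <- true_presence
  for (i in seq_len(n)) {
    freqs <- gene_freqs
    if (!is.null(clade_profiles) && clades[i] %in% names(clade_profiles)) {
      prof <- clade_profiles[[clades[i]]]
      freqs[names(prof)] <- prof
    }
    truth_i <- stats::runif(length(genes)) < freqs[genes]
    obs_i <- truth_i & (stats::runif(length(genes)) < completeness[i] / 100)
    true_presence[i, ] <- truth_i
    observed[i, ] <- obs_i
  }
  genomes <- data.frame(
    genome_id = sprintf("%s_%04d", taxon, seq_len(n)),
    taxon = taxon, clade = clades,
    completeness = completeness, contamination = contamination
  )
  for (g in genes) genomes[[g]] <- as.integer(observed[, g])
  list(genomes = genomes,
       truth = list(true_presence = true_presence,
                    completeness = completeness,
                    gene_freqs = gene_freqs,
                    clade_profiles = clade_profiles))
}

#' Default transect model of true gene frequencies vs nitrogen
#'
#' Returns a function mapping inorganic nitrogen concentration (umol/kg) to
#' named true gene/genome frequencies: purine assimilation uniform and
#' universal; nitrogen-harvesting genes declining with nitrogen;
#' energy/carbon-harvesting and allantoin-transport genes rising with
#' nitrogen -- the opposing environmental trends that distinguish the
#' purine-usage functions along ocean nutrient gradients.
#'
#' @return Function `f(nitrogen) -> named numeric vector`.
#' @export
sar11_transect_model <- function() {
  clamp <- function(x, lo = 0.02, hi = 1.2) pmin(hi, pmax(lo, x))
  function(nitrogen) {
    c(
      purine_mfs_permease = 1.0,
      purine_pprt = 1.0,
      purine_deaminase_1 = clamp(0.50 - 0.045 * nitrogen),
      purine_deaminase_2 = clamp(0.48 - 0.043 * nitrogen),
      xdh_mo = clamp(0.12 + 0.050 * nitrogen),
      xdh_fad = clamp(0.12 + 0.048 * nitrogen),
      allantoicase = clamp(0.10 + 0.055 * nitrogen),
      allantoin_ncs1_permease = clamp(0.05 + 0.045 * nitrogen),
      urease = clamp(0.12 - 0.010 * nitrogen)
    )
  }
}

#' Simulate a metagenome transect with Poisson hit counts
#'
#' Stations span a nitrogen gradient; each sample's true gene frequencies
#' come from `freq_model` evaluated at its nitrogen concentration, jittered
#' by a lognormal station/sample effect. Gene hit counts are drawn as
#' `Poisson(depth_factor * frequency * hmm_length)` and ribosomal-protein
#' counts as `Poisson(depth_factor * length)` (one copy per genome), the
#' count model under which the length-and-core-median estimator of
#' [genome_frequency()] is unbiased. A finite `overdispersion` switches the
#' counts to negative binomial with that size parameter.
#'
#' @param n_stations Number of stations (default 30).
#' @param samples_per_station Samples per station (default 3).
#' @param seed Integer seed.
#' @param freq_model Function nitrogen -> named frequencies (default
#'   [sar11_transect_model()]).
#' @param hmm_lengths Named HMM lengths; default 300 aa per modeled gene.
#' @param depth_factor Expected core coverage per aa (default 100).
#' @param depth_range Sampling depth range in meters (default `c(5, 200)`).
#' @param nitrogen_surface_range Surface nitrogen range across stations,
#'   umol/kg (default `c(0.05, 8)`).
#' @param nitrogen_depth_slope Added nitrogen per meter of depth
#'   (default 0.02).
#' @param biological_cv Lognormal sd (log scale) of the per-sample frequency
#'   jitter (default 0.15).
#' @param overdispersion Negative-binomial size; `Inf` (default) = Poisson.
#' @return List with `samples` (list of [sample_gene_counts()]) and `truth`
#'   (data.frame of per-sample true frequencies and covariates).
#' @export
gen_metagenome <- function(n_stations = 30, samples_per_station = 3,
                           seed = NULL, freq_model = sar11_transect_model(),
                           hmm_lengths = NULL, depth_factor = 100,
                           depth_range = c(5, 200),
                           nitrogen_surface_range = c(0.05, 8),
                           nitrogen_depth_slope = 0.02,
                           biological_cv = 0.15, overdispersion = Inf) {
  if (!is.null(seed)) set.seed(seed)
  genes <- names(freq_model(0))
  if (is.null(hmm_lengths)) {
    hmm_lengths <- stats::setNames(rep(300, length(genes)), genes)
  }
  ribo_lengths <- sar11_ribosomal_proteins()
  draw <- function(lambda) {
    if (is.infinite(overdispersion)) stats::rpois(length(lambda), lambda)
    else stats::rnbinom(length(lambda), mu = lambda, size = overdispersion)
  }
  surface_n <- seq(nitrogen_surface_range[1], nitrogen_surface_range[2],
                   length.out = n_stations)
  samples <- list()
  truth_rows <- list()
  for (st in seq_len(n_stations)) {
    for (sm in seq_len(samples_per_station)) {
      depth <- stats::runif(1, depth_range[1], depth_range[2])
      nitrogen <- surface_n[st] * exp(stats::rnorm(1, 0, 0.1)) +
        nitrogen_depth_slope * depth
      f_true <- freq_model(nitrogen) *
        exp(stats::rnorm(length(genes), 0, biological_cv))
      counts <- stats::setNames(
        draw(depth_factor * f_true * hmm_lengths[genes]), genes)
      ribo_counts <- stats::setNames(draw(depth_factor * ribo_lengths),
                                     names(ribo_lengths))
      sid <- sprintf("S%02d_%02d", st, sm)
      samples[[sid]] <- sample_gene_counts(
        sample_id = sid, station_id = sprintf("ST%02d", st), depth = depth,
        counts = counts, hmm_lengths = hmm_lengths,
        ribo_counts = ribo_counts, ribo_lengths = ribo_lengths,
        env = list(nitrogen_umol_kg = nitrogen)
      )
      truth_rows[[sid]] <- data.frame(
        sample_id = sid, station_id = sprintf("ST%02d", st), depth = depth,
        nitrogen_umol_kg = nitrogen, gene = genes,
        true_frequency = unname(f_true))
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(samples = samples, truth = truth)
}

#' Simulate a diel transcript series
#'
#' Each gene's expected count follows a raised cosine over the diel cycle,
#' `baseline * (1 + rel_amplitude * cos(w * (t - acrophase)))`, multiplied
#' by lognormal noise whose log-sd is `rel_amplitude / snr` (so `snr` is the
#' oscillation amplitude in units of the noise SD). Taxon totals emulate a
#' whole transcriptome in which the modeled genes are only a `coverage`
#' share: the total is flat at `n_genes * baseline / coverage` (the many
#' unmodeled genes average out each other's rhythms) unless
#' `total_amplitude` plants a residual community-level oscillation.
#'
#' @param seed Integer seed.
#' @param acrophases Named planted acrophases in hours (default: two
#'   *Prochlorococcus* DNA polymerase genes peaking at 19 h, two RNA
#'   polymerase genes at 22 h, and a SAR11 purine transporter at 22 h --
#'   3 h after the DNA polymerase peak).
#' @param taxa Named taxon of each gene.
#' @param period Period in hours (default 24).
#' @param interval Sampling interval in hours (default 2).
#' @param duration Series duration in hours (default 72).
#' @param baseline Mean count at mesor (default 500).
#' @param rel_amplitude Relative oscillation amplitude in `[0, 1]`
#'   (default 0.8).
#' @param snr Amplitude-to-noise ratio (default 3).
#' @param coverage Fraction of the taxon transcriptome the genes represent
#'   (default 0.05).
#' @param total_amplitude Relative amplitude of a residual oscillation in
#'   the taxon total, acrophase 12 h (default 0: flat totals).
#' @return List with `series` (a [diel_series()]) and `truth` (list of
#'   planted acrophases and parameters).
#' @export
gen_diel <- function(seed = NULL,
                     acrophases = c(dnaE = 19, dnaN = 19, rpoB = 22,
                                    rpoC2 = 22, purine_mfs_permease = 22),
                     taxa = c(dnaE = "Prochlorococcus",
                              dnaN = "Prochlorococcus",
                              rpoB = "Prochlorococcus",
                              rpoC2 = "Prochlorococcus",
                              purine_mfs_permease = "SAR11"),
                     period = 24, interval = 2, duration = 72,
                     baseline = 500, rel_amplitude = 0.8, snr = 3,
                     coverage = 0.05, total_amplitude = 0) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = interval)
  w <- 2 * pi / period
  sdlog <- if (is.infinite(snr)) 0 else rel_amplitude / snr
  genes <- names(acrophases)
  counts <- t(vapply(genes, function(g) {
    mu <- baseline * (1 + rel_amplitude * cos(w * (t - acrophases[[g]])))
    mu * exp(stats::rnorm(length(t), -sdlog^2 / 2, sdlog))
  }, numeric(length(t))))
  colnames(counts) <- sprintf("t%03d", t)
  taxa <- taxa[genes]
  totals <- t(vapply(unique(taxa), function(tx) {
    n_tx <- sum(taxa == tx)
    n_tx * baseline / coverage *
      (1 + total_amplitude * cos(w * (t - 12)))
  }, numeric(length(t))))
  colnames(totals) <- colnames(counts)
  list(series = diel_series(t, counts, totals, taxa),
       truth = list(acrophases = acrophases, period = period, snr = snr,
                    rel_amplitude = rel_amplitude, sdlog = sdlog,
                    coverage = coverage, total_amplitude = total_amplitude))
}

## internal: lagged logistic growth trajectory
logistic_growth <- function(t, n0, capacity, mu, lag = 0) {
  te <- pmax(0, t - lag)
  capacity / (1 + (capacity / n0 - 1) * exp(-mu * te))
}

#' Simulate adenine-amendment growth curves
#'
#' Logistic growth with multiplicative lognormal counting noise. Adenine
#' inhibits the growth rate through a Hill-type multiplier
#' `1 / (1 + (dose / k_inhibit)^hill)`, and depresses the per-cell DNA
#' fluorescence signal through the same monotone dose response, emulating
#' dose-dependent inhibition of DNA synthesis. The glycine-depleted medium
#' uses a lower inhibition constant, so inhibition sets in at lower doses.
#'
#' @param seed Integer seed.
#' @param mu Uninhibited growth rate, 1/day (default 0.4).
#' @param n0 Starting density, cells/mL (default 5e5).
#' @param capacity Carrying capacity, cells/mL (default 2e8).
#' @param lag Growth lag in days (default 0).
#' @param adenine_conc Molar adenine doses including 0 for the control.
#' @param k_inhibit Named per-medium inhibition constants, molar.
#' @param hill Hill exponent (default 1).
#' @param times Sampling times in days.
#' @param noise_cv Multiplicative counting noise sd (default 0.05).
#' @param n_replicates Biological replicates per condition (default 3).
#' @param media Media to simulate.
#' @return List with `curves` (long data.frame: `time_days`, `density`,
#'   `condition`, `adenine_molar`, `replicate`), `cytometry` (per-condition
#'   mean/SD of bead-normalized DNA fluorescence and FALS), and `truth`
#'   (planted rates per condition and the suggested exponential-phase
#'   window).
#' @export
gen_growth <- function(seed = NULL, mu = 0.4, n0 = 5e5, capacity = 2e8,
                       lag = 0,
                       adenine_conc = c(0, 1e-9, 1e-7, 1e-5),
                       k_inhibit = c(balanced = 5e-6,
                                     `glycine-depleted` = 2e-7),
                       hill = 1, times = seq(0, 16, by = 1),
                       noise_cv = 0.05, n_replicates = 3,
                       media = names(k_inhibit)) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  truth_rows <- list()
  cyto_rows <- list()
  for (medium in media) {
    for (dose in adenine_conc) {
      inhibition <- 1 / (1 + (dose / k_inhibit[[medium]])^hill)
      mu_eff <- mu * inhibition
      for (rep_i in seq_len(n_replicates)) {
        mean_d <- logistic_growth(times, n0, capacity, mu_eff, lag)
        density <- mean_d * exp(stats::rnorm(length(times),
                                             -noise_cv^2 / 2, noise_cv))
        rows[[length(rows) + 1L]] <- data.frame(
          time_days = times, density = density, condition = medium,
          adenine_molar = dose, replicate = sprintf("r%d", rep_i))
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        condition = medium, adenine_molar = dose, mu_effective = mu_eff,
        inhibition = inhibition)
      ## bead-normalized per-cell DNA signal tracks the inhibition; FALS
      ## (cell size) rises as division is blocked before biosynthesis stops
      cyto_rows[[length(cyto_rows) + 1L]] <- data.frame(
        condition = medium, adenine_molar = dose,
        dna_fluorescence_mean = 1.0 * (0.55 + 0.45 * inhibition) *
          exp(stats::rnorm(1, 0, 0.02)),
        dna_fluorescence_sd = 0.05,
        fals_mean = 1.0 * (1 + 0.4 * (1 - inhibition)) *
          exp(stats::rnorm(1, 0, 0.02)),
        fals_sd = 0.08,
        timepoint_label = "mid-exponential")
    }
  }
  ## the exponential window ends where the fastest (uninhibited) condition
  ## reaches ~20% of capacity, before saturation bends the log-linear fit
  t20 <- lag + log((capacity / n0 - 1) * 0.25) / mu
  window <- c(min(times) + lag, min(max(times), t20))
  list(curves = do.call(rbind, rows),
       cytometry = do.call(rbind, cyto_rows),
       truth = list(rates = do.call(rbind, truth_rows),
                    phase_window = window, mu = mu,
                    k_inhibit = k_inhibit, hill = hill))
}

#' Simulate a post-washing regrowth experiment
#'
#' Each replicate lags with its condition's planted probability; lagged
#' replicates stay at baseline (with counting noise) for `lag_duration`
#' days before growing, others resume immediately. Used for lag
#' classification and the exact-test comparisons of lag incidence.
#'
#' @param seed Integer seed.
#' @param n_replicates Replicates per condition (default 6).
#' @param p_lag Named per-condition lag probabilities
#'   (default `c(control = 0.7, adenine = 0.15)`).
#' @param lag_duration Days lagged replicates remain flat (default 3).
#' @param mu Post-resumption growth rate, 1/day (default 0.4).
#' @param n0 Post-wash starting density (default 1e6).
#' @param capacity Carrying capacity (default 2e8).
#' @param times Days since resuspension (default 0:10).
#' @param noise_cv Counting noise sd (default 0.05).
#' @return List with `curves` (long data.frame: `condition`, `replicate`,
#'   `time_days`, `density`) and `truth` (data.frame of planted lag flags).
#' @export
gen_wash_experiment <- function(seed = NULL, n_replicates = 6,
                                p_lag = c(control = 0.7, adenine = 0.15),
                                lag_duration = 3, mu = 0.4, n0 = 1e6,
                                capacity = 2e8, times = 0:10,
                                noise_cv = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  truth <- list()
  for (cond in names(p_lag)) {
    for (rep_i in seq_len(n_replicates)) {
      lagged <- stats::runif(1) < p_lag[[cond]]
      mean_d <- logistic_growth(times, n0, capacity, mu,
                                lag = if (lagged) lag_duration else 0)
      density <- mean_d * exp(stats::rnorm(length(times),
                                           -noise_cv^2 / 2, noise_cv))
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, replicate = sprintf("r%d", rep_i),
        time_days = times, density = density)
      truth[[length(truth) + 1L]] <- data.frame(
        condition = cond, replicate = sprintf("r%d", rep_i),
        lagged = lagged)
    }
  }
  list(curves = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Default compound table for the exudation simulator
#'
#' Molar masses, DNA bases, extraction efficiencies, and planted
#' exudation-to-incorporation ratios for the four focal exometabolites.
#' Thymidine's planted ratio of 0.45 reflects extracellular production near
#' half of DNA incorporation; adenine and guanine have extraction
#' efficiencies below the 1% correction floor.
#'
#' @return data.frame with columns `compound`, `molar_mass`, `base`,
#'   `ef_percent`, `true_ratio`.
#' @export
default_compounds <- function() {
  data.frame(
    compound = c("thymidine", "adenine", "guanine",
                 "methylthioadenosine"),
    molar_mass = c(242.23, 135.13, 151.13, 297.33),
    base = c("T", "A", "G", "A"),
    ef_percent = c(9, 0.6, 0.5, 5),
    true_ratio = c(0.45, 0.40, 0.30, 0.05)
  )
}

#' Simulate exometabolite measurements with planted budgets
#'
#' Works backwards from planted exudation ratios: the true moles of each
#' compound in the spent medium are `true_ratio` times the moles of the
#' corresponding base incorporated into DNA (from the strain context and net
#' cell yield); the true media concentration follows from the molar mass and
#' culture volume; and the measured extract concentration is the media
#' concentration times EF%/100, with lognormal measurement noise per
#' replicate.
#'
#' @param seed Integer seed.
#' @param ctx A [strain_context()] with `culture_volume` set.
#' @param cells_new Net cells produced over the experiment.
#' @param compounds Compound table as in [default_compounds()].
#' @param n_replicates Biological replicates (default 3).
#' @param noise_cv Lognormal measurement noise sd (default 0.1; 0 gives an
#'   exact round trip through [correct_extraction()] for EF% > 1).
#' @param convention Base-counting convention, see [base_incorporation()].
#' @return List with `measurements` (replicate-level data.frame as consumed
#'   by [summarize_replicates()]) and `truth` (per-compound true media
#'   concentrations, moles, and planted ratios).
#' @export
gen_metabolites <- function(seed = NULL, ctx, cells_new,
                            compounds = default_compounds(),
                            n_replicates = 3, noise_cv = 0.1,
                            convention = c("duplex", "per-strand")) {
  convention <- match.arg(convention)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(ctx, "strain_context"))
  if (is.na(ctx$culture_volume)) {
    stop("`ctx$culture_volume` is required", call. = FALSE)
  }
  incorporated <- vapply(compounds$base, function(b) {
    base_incorporation(ctx, b, cells_new, convention = convention)
  }, numeric(1))
  extracellular_moles <- compounds$true_ratio * incorporated
  conc_media <- extracellular_moles * compounds$molar_mass /
    ctx$culture_volume * 1e9 # mol -> ng/mL
  rows <- list()
  for (i in seq_len(nrow(compounds))) {
    for (rep_i in seq_len(n_replicates)) {
      noise <- if (noise_cv > 0) {
        exp(stats::rnorm(1, -noise_cv^2 / 2, noise_cv))
      } else 1
      rows[[length(rows) + 1L]] <- data.frame(
        compound = compounds$compound[i],
        replicate_id = sprintf("r%d", rep_i),
        conc_extract = conc_media[i] * compounds$ef_percent[i] / 100 * noise,
        ef_percent = compounds$ef_percent[i],
        detected = "quantified")
    }
  }
  list(measurements = do.call(rbind, rows),
       truth = data.frame(compound = compounds$compound,
                          conc_media = conc_media,
                          extracellular_moles = extracellular_moles,
                          incorporated_moles = incorporated,
                          true_ratio = compounds$true_ratio))
}
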