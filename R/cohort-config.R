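#' @importClassesFrom Biostrings AAStringSet
#' @importFrom Biostrings AAStringSet writeXStringSet readAAStringSet
#'   pairwiseAlignment nmatch letterFrequency width
NULL

## Default per-group amino-acid composition (percent frequencies of the 20
## residues in essential vs viable proteins of the non-culled study sets),
## used as Dirichlet base measures so synthetic proteins reproduce the
## residue-usage shifts (more D/E/K/Q/S in essential, more L/C/F/V/W in
## viable).
.AA_FREQ_DEFAULT <- matrix(c(
  ## essential, viable
  6.87, 6.74,   # A
  1.88, 2.08,   # C
  4.91, 4.73,   # D
  6.68, 6.22,   # E
  3.39, 3.80,   # F
  6.43, 6.49,   # G
  2.48, 2.39,   # H
  4.06, 4.24,   # I
  5.67, 5.15,   # K
  9.31, 10.00,  # L
  2.19, 2.21,   # M
  3.63, 3.50,   # N
  5.86, 5.72,   # P
  4.48, 4.25,   # Q
  5.41, 5.38,   # R
  8.01, 7.78,   # S
  5.14, 5.24,   # T
  5.89, 6.25,   # V
  1.01, 1.31,   # W
  2.73, 2.83    # Y
), ncol = 2, byrow = TRUE,
  dimnames = list(AA_STANDARD, c("essential", "viable")))

## Default Bernoulli annotation rates per group: UniProt keyword, signal
## peptide, subcellular location and housekeeping/tissue-enrichment
## frequencies of the two study groups.
.ANNOTATION_RATES_DEFAULT <- data.frame(
  flag = c("phosphoprotein", "glycoprotein", "acetylation", "transcription",
           "signal_peptide", "housekeeping", "tissue_enriched",
           "loc_nucleus", "loc_cytoplasm", "loc_plasma_membrane",
           "loc_membrane", "loc_extracellular", "loc_mitochondrion",
           "loc_er", "loc_golgi", "loc_lysosome", "loc_peroxisome",
           "loc_cell_junction", "loc_cell_projection"),
  essential = c(0.514, 0.213, 0.289, 0.278,
                0.164, 0.117, 0.342,
                0.482, 0.333, 0.131, 0.090, 0.073, 0.051,
                0.054, 0.048, 0.008, 0.004, 0.060, 0.036),
  viable = c(0.355, 0.382, 0.129, 0.115,
             0.291, 0.163, 0.438,
             0.236, 0.294, 0.233, 0.158, 0.146, 0.042,
             0.056, 0.043, 0.023, 0.006, 0.058, 0.038),
  stringsAsFactors = FALSE
)

## Per-class enzyme annotation rates (oxidoreductase, transferase, hydrolase,
## lyase, isomerase, ligase); column remainders are non-enzymes.
.ENZYME_RATES_DEFAULT <- matrix(c(
  0.034, 0.037,
  0.135, 0.101,
  0.081, 0.109,
  0.0131, 0.0110,
  0.0069, 0.0067,
  0.029, 0.012
), ncol = 2, byrow = TRUE,
  dimnames = list(c("oxidoreductase", "transferase", "hydrolase",
                    "lyase", "isomerase", "ligase"),
                  c("essential", "viable")))

## Fraction of genes with nonzero ESTs per developmental stage per group
## (the complements are the zero-inflation probabilities).
.EXPRESSED_FRACTION_DEFAULT <- matrix(c(
  0.420, 0.209,   # oocyte
  0.263, 0.105,   # unfertilized ovum
  0.353, 0.178,   # zygote
  0.455, 0.232,   # cleavage
  0.436, 0.197,   # morula
  0.598, 0.304,   # blastocyst
  0.224, 0.083,   # egg cylinder
  0.571, 0.293,   # gastrula
  0.838, 0.541,   # organogenesis
  0.973, 0.864,   # fetus
  0.850, 0.707,   # neonate
  0.924, 0.878,   # juvenile
  0.959, 0.941    # adult
), ncol = 2, byrow = TRUE,
  dimnames = list(DEVELOPMENTAL_STAGES, c("essential", "viable")))

## Sampling weights over the 16 taxon age groups for the most-recent
## duplication (or singleton) age: essential mass shifted toward the oldest
## groups (Bilateria 937, Opisthokonta 1215), viable toward Murinae/Theria
## and Euteleostomi.
.MRD_WEIGHTS_DEFAULT <- matrix(c(
  0.63, 2.17,    # Murinae 25
  0.00, 0.09,    # Rodentia 77
  0.00, 0.06,    # Sciurognathi 78
  0.24, 0.06,    # Glires 86
  0.55, 0.51,    # Euarchontoglires 92
  11.60, 11.23,  # Eutheria 104
  1.25, 2.80,    # Theria 162
  3.45, 5.03,    # Mammalia 167
  5.41, 4.79,    # Amniota 296
  1.41, 2.56,    # Tetrapoda 371
  31.58, 41.69,  # Euteleostomi 400
  1.80, 2.74,    # Sarcopterygii 414
  13.48, 14.80,  # Vertebrata 535
  4.00, 3.25,    # Chordata 722
  15.67, 6.08,   # Bilateria 937
  8.93, 2.14     # Opisthokonta 1215
), ncol = 2, byrow = TRUE,
  dimnames = list(TAXON_AGES$taxon, c("essential", "viable")))

#' Configure the synthetic cohort generator
#'
#' Builds a [CohortConfig] whose defaults are the study conditions: 1,301
#' essential and 3,451 viable genes, the reported per-group medians for gene
#' length (28,913 / 21,629 bp), exon length, exon and transcript counts and
#' GC content, per-group amino-acid composition, annotation-flag rates
#' (signal peptide 16.4% / 29.1%, phosphoprotein 51.4% / 35.5%, nuclear
#' localisation 48.2% / 23.6%, ...), stage-wise expressed fractions, a
#' degree-biased PPI attachment advantage for essential nodes, and age-group
#' weights favouring old (Bilateria/Opisthokonta) origins for essential
#' genes.
#'
#' Distribution families (dispersion parameters are free choices, exposed
#' here): log-normal lengths, truncated Poisson counts, Beta GC,
#' Dirichlet-multinomial residue composition, Bernoulli flags and
#' zero-inflated gamma-Poisson (negative binomial) EST counts.
#'
#' @param nEssential,nViable Group sizes.
#' @param geneLengthMedian,exonLengthMedian Numeric pairs
#'   `c(essential, viable)`, bp.
#' @param geneLengthSdlog,exonLengthSdlog Log-scale standard deviations.
#' @param exonCountMean,transcriptCountMean Numeric pairs; Poisson means
#'   (counts truncated at >= 1).
#' @param gcMean GC fraction pair; `gcConcentration` the Beta concentration.
#' @param aaDirichletAlpha 20 x 2 positive matrix of Dirichlet parameters.
#' @param annotationRates Data frame `flag`/`essential`/`viable` of rates.
#' @param enzymeClassRates 6 x 2 matrix of enzyme-class rates.
#' @param tmRate Pair: probability of any transmembrane segment.
#' @param expressedFraction 13 x 2 matrix of per-stage expressed fractions.
#' @param expressionMean Pair: mean EST count of expressed cells.
#' @param expressionDispersion Negative binomial `size`.
#' @param ppiFitnessMultiplier Essential-node attachment fitness (>= 1).
#' @param ppiEdgesPerNode Edges per incoming node in the attachment process.
#' @param treeDuplicationProb Probability a gene has duplication ancestors.
#' @param mrdAgeWeights 16 x 2 non-negative weight matrix over the taxon ages.
#' @param seed Integer seed.
#' @return A validated [CohortConfig].
#' @examples
#' cfg <- cohortConfig(nEssential = 50, nViable = 50, seed = 1)
#' cfg
#' @export
cohortConfig <- function(nEssential = 1301L, nViable = 3451L,
                         geneLengthMedian = c(28913, 21629),
                         geneLengthSdlog = 0.9,
                         exonLengthMedian = c(3398, 2780),
                         exonLengthSdlog = 0.55,
                         exonCountMean = c(11, 8),
                         transcriptCountMean = c(4, 2),
                         gcMean = c(0.4646, 0.4716),
                         gcConcentration = 200,
                         aaDirichletAlpha = .AA_FREQ_DEFAULT,
                         annotationRates = .ANNOTATION_RATES_DEFAULT,
                         enzymeClassRates = .ENZYME_RATES_DEFAULT,
                         tmRate = c(0.20, 0.34),
                         expressedFraction = .EXPRESSED_FRACTION_DEFAULT,
                         expressionMean = c(8, 4),
                         expressionDispersion = 0.8,
                         ppiFitnessMultiplier = 2,
                         ppiEdgesPerNode = 3L,
                         treeDuplicationProb = 0.7,
                         mrdAgeWeights = .MRD_WEIGHTS_DEFAULT,
                         seed = 1L) {
  cfg <- new("CohortConfig",
    nEssential = as.integer(nEssential), nViable = as.integer(nViable),
    geneLengthMedian = as.numeric(geneLengthMedian),
    geneLengthSdlog = geneLengthSdlog,
    exonLengthMedian = as.numeric(exonLengthMedian),
    exonLengthSdlog = exonLengthSdlog,
    exonCountMean = as.numeric(exonCountMean),
    transcriptCountMean = as.numeric(transcriptCountMean),
    gcMean = as.numeric(gcMean), gcConcentration = gcConcentration,
    aaDirichletAlpha = aaDirichletAlpha,
    annotationRates = annotationRates,
    enzymeClassRates = enzymeClassRates,
    tmRate = as.numeric(tmRate),
    expressedFraction = expressedFraction,
    expressionMean = as.numeric(expressionMean),
    expressionDispersion = expressionDispersion,
    ppiFitnessMultiplier = ppiFitnessMultiplier,
    ppiEdgesPerNode = as.integer(ppiEdgesPerNode),
    treeDuplicationProb = treeDuplicationProb,
    mrdAgeWeights = mrdAgeWeights,
    seed = as.integer(seed))
  msg <- validObject(cfg, test = TRUE)
  if (is.character(msg)) stop("invalid cohort configuration: ", msg[1L])
  cfg
}

#' A null (no-effect) generator configuration
#'
#' Returns a [CohortConfig] in which both groups share identical parameters
#' (the viable values everywhere), so every downstream two-group comparison
#' holds under the null hypothesis. Used for type-I error calibration.
#'
#' @param nEssential,nViable Group sizes.
#' @param seed Integer seed.
#' @param ... Further overrides passed to [cohortConfig()].
#' @return A [CohortConfig] with no group differences.
#' @export
nullCohortConfig <- function(nEssential = 200L, nViable = 200L, seed = 1L, ...) {
  ar <- .ANNOTATION_RATES_DEFAULT
  ar$essential <- ar$viable
  ez <- .ENZYME_RATES_DEFAULT; ez[, "essential"] <- ez[, "viable"]
  aa <- .AA_FREQ_DEFAULT; aa[, "essential"] <- aa[, "viable"]
  ef <- .EXPRESSED_FRACTION_DEFAULT; ef[, "essential"] <- ef[, "viable"]
  mw <- .MRD_WEIGHTS_DEFAULT; mw[, "essential"] <- mw[, "viable"]
  cohortConfig(nEssential = nEssential, nViable = nViable,
               geneLengthMedian = c(21629, 21629),
               exonLengthMedian = c(2780, 2780),
               exonCountMean = c(8, 8), transcriptCountMean = c(2, 2),
               gcMean = c(0.4716, 0.4716),
               aaDirichletAlpha = aa, annotationRates = ar,
               enzymeClassRates = ez, tmRate = c(0.34, 0.34),
               expressedFraction = ef, expressionMean = c(4, 4),
               ppiFitnessMultiplier = 1, mrdAgeWeights = mw,
               seed = seed, ...)
}
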