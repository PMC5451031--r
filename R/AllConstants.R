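# Shared constants: residue chemistry, residue category sets, the canonical
# developmental stages and the phylogenetic age groups.

#' @importFrom methods new validObject is slot
#' @importFrom stats chisq.test fisher.test ks.test median p.adjust phyper
#'   pnorm rbeta rbinom rgamma rlnorm rnbinom rpois runif sd setNames t.test
#'   wilcox.test rnorm quantile
#' @importFrom utils combn head read.delim write.table
NULL

## 20 standard amino acids, one-letter, alphabetical
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## B (Asx) and Z (Glx) are tolerated on input and counted in the residue
## category sets that list them, but excluded from the 20-aa frequency
## denominator.
AA_ALPHABET22 <- c(AA_STANDARD, "B", "Z")

## EMBOSS-compatible average residue masses (Da); a free peptide adds one
## water (18.01524 Da).
AA_MASS <- c(
  A = 71.0788,  C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519,  H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167,  Q = 128.1307, R = 156.1875,
  S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760,
  B = 114.5962, Z = 128.6231
)
MASS_WATER <- 18.01524

## EMBOSS-compatible pK values for the Henderson-Hasselbalch net-charge
## function used to solve the isoelectric point.
PK_POSITIVE <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
PK_NEGATIVE <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

## The nine residue categories with their exact membership sets.
AA_CATEGORIES <- list(
  tiny      = c("A", "C", "G", "S", "T"),
  small     = c("A", "B", "C", "D", "G", "N", "P", "S", "T", "V"),
  aliphatic = c("I", "L", "V"),
  aromatic  = c("F", "H", "W", "Y"),
  non_polar = c("A", "C", "F", "G", "I", "L", "M", "P", "V", "W", "Y"),
  polar     = c("D", "E", "H", "K", "N", "Q", "R", "S", "T", "Z"),
  charged   = c("B", "D", "E", "H", "K", "R", "Z"),
  basic     = c("H", "K", "R"),
  acidic    = c("B", "D", "E", "Z")
)

## The 13 developmental stages, in canonical order.
DEVELOPMENTAL_STAGES <- c(
  "oocyte", "unfertilized ovum", "zygote", "cleavage", "morula",
  "blastocyst", "egg cylinder", "gastrula", "organogenesis", "fetus",
  "neonate", "juvenile", "adult"
)

## The 16 phylogenetic age groups (taxon, age in MYA), youngest to oldest.
TAXON_AGES <- data.frame(
  taxon = c("Murinae", "Rodentia", "Sciurognathi", "Glires",
            "Euarchontoglires", "Eutheria", "Theria", "Mammalia",
            "Amniota", "Tetrapoda", "Euteleostomi", "Sarcopterygii",
            "Vertebrata", "Chordata", "Bilateria", "Opisthokonta"),
  age = c(25, 77, 78, 86, 92, 104, 162, 167, 296, 371, 400, 414,
          535, 722, 937, 1215),
  stringsAsFactors = FALSE
)

#' Phylogenetic age groups
#'
#' The 16 taxon age groups used to bin gene evolutionary ages, from the
#' youngest (Murinae, 25 MYA) to the oldest (Opisthokonta, 1215 MYA).
#'
#' @return A data frame with columns `taxon` and `age` (million years ago),
#'   sorted by strictly increasing age.
#' @examples
#' taxonAgeTable()
#' @export
taxonAgeTable <- function() {
  TAXON_AGES
}

#' Canonical developmental stages
#'
#' The ordered names of the 13 mouse developmental stages over which
#' EST counts are tabulated, from oocyte to adult.
#'
#' @return Character vector of length 13.
#' @export
developmentalStages <- function() {
  DEVELOPMENTAL_STAGES
}
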