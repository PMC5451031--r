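# Protein-sequence features: residue frequencies, the nine residue-category
# percentages, molecular weight, charge and isoelectric point, with
# EMBOSS-compatible constants (see constants.R).

.checkResidues <- function(chars) {
  bad <- which(!(chars %in% AA_ALPHABET22))
  if (length(bad))
    stop("invalid residue '", chars[bad[1L]], "' at position ", bad[1L],
         " (alphabet is the 20 standard amino acids plus B and Z)")
}

.seqChars <- function(sequence) {
  if (is(sequence, "AAString") || is(sequence, "AAStringSet"))
    sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  .checkResidues(chars)
  chars
}

#' Amino-acid frequencies
#'
#' Percentage frequency of each of the 20 standard residues. The denominator
#' is the number of standard residues in the sequence; ambiguity codes B and
#' Z are tolerated but excluded.
#'
#' @param sequence A single amino-acid string (or `AAString`).
#' @return Named numeric vector of 20 percentages summing to 100.
#' @examples
#' aaFrequencies("LLKK")
#' @export
aaFrequencies <- function(sequence) {
  chars <- .seqChars(sequence)
  std <- chars[chars %in% AA_STANDARD]
  if (!length(std)) stop("sequence contains no standard residue")
  counts <- table(factor(std, levels = AA_STANDARD))
  100 * as.numeric(counts) / length(std) -> f
  setNames(f, AA_STANDARD)
}

.categoryPercent <- function(chars) {
  n <- length(chars)
  vapply(AA_CATEGORIES, function(set) 100 * sum(chars %in% set) / n,
         numeric(1))
}

#' Net charge of a peptide
#'
#' Unit-charge convention: (Lys + Arg + half of His) minus (Asp + Glu).
#'
#' @param sequence A single amino-acid string.
#' @return A single numeric charge.
#' @export
proteinCharge <- function(sequence) {
  chars <- .seqChars(sequence)
  sum(chars == "K") + sum(chars == "R") + 0.5 * sum(chars == "H") -
    sum(chars == "D") - sum(chars == "E")
}

#' Average molecular weight of a peptide
#'
#' Sum of average residue masses plus one water.
#'
#' @param sequence A single amino-acid string.
#' @return Molecular weight in Da.
#' @examples
#' proteinMW("GG")  # 2 x 57.0519 + 18.015 ~ 132.12
#' @export
proteinMW <- function(sequence) {
  chars <- .seqChars(sequence)
  sum(AA_MASS[chars]) + MASS_WATER
}

.netChargeAtPH <- function(counts, pH) {
  pos <- c(Nterm = 1, counts[c("K", "R", "H")])
  neg <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  sum(pos / (1 + 10^(pH - PK_POSITIVE))) -
    sum(neg / (1 + 10^(PK_NEGATIVE - pH)))
}

#' Isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge of the free peptide
#' (termini plus C, D, E, H, K, R, Y side chains, EMBOSS-compatible pK
#' values) is zero, solved by bisection on \[0, 14\].
#'
#' @param sequence A single amino-acid string.
#' @param tol Bisection tolerance in pH units.
#' @return The isoelectric pH.
#' @export
isoelectricPoint <- function(sequence, tol = 1e-4) {
  chars <- .seqChars(sequence)
  counts <- vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                   function(a) sum(chars == a), numeric(1))
  lo <- 0; hi <- 14
  for (i in seq_len(100L)) {
    mid <- (lo + hi) / 2
    if (.netChargeAtPH(counts, mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Pepstats-style protein feature vector
#'
#' Computes the full protein feature set for one sequence: residue count,
#' molecular weight, charge, isoelectric point, the 20 amino-acid percentage
#' frequencies and the nine residue-category percentages (tiny, small,
#' aliphatic, aromatic, non-polar, polar, charged, basic, acidic). Category
#' membership uses the exact sets: tiny ACGST; small ABCDGNPSTV; aliphatic
#' ILV; aromatic FHWY; non-polar ACFGILMPVWY; polar DEHKNQRSTZ; charged
#' BDEHKRZ; basic HKR; acidic BDEZ. Category denominators include B/Z;
#' the 20-residue frequencies exclude them.
#'
#' @param sequence A single amino-acid string (20 standard letters; B and Z
#'   tolerated).
#' @return A list with elements `length`, `mw`, `charge`, `pI`, `aa_freq`
#'   (20 percentages) and `category_freq` (9 percentages).
#' @examples
#' f <- pepstatsFeatures("ACDEFGHIKLMNPQRSTVWY")
#' f$category_freq[["non_polar"]]  # 55: 11 of the 20 residues
#' @export
pepstatsFeatures <- function(sequence) {
  chars <- .seqChars(sequence)
  list(
    length = length(chars),
    mw = sum(AA_MASS[chars]) + MASS_WATER,
    charge = sum(chars == "K") + sum(chars == "R") + 0.5 * sum(chars == "H") -
      sum(chars == "D") - sum(chars == "E"),
    pI = isoelectricPoint(sequence),
    aa_freq = aaFrequencies(sequence),
    category_freq = .categoryPercent(chars))
}

#' Protein feature table for a sequence set
#'
#' Applies [pepstatsFeatures()] across an `AAStringSet` (or named character
#' vector) and returns a flat per-protein table.
#'
#' @param proteins An [Biostrings::AAStringSet] or named character vector.
#' @return Data frame: `protein_id`, `length`, `mw`, `charge`, `pI`, one
#'   column per residue (`freq_A` ... `freq_Y`) and one per category
#'   (`cat_tiny` ... `cat_acidic`).
#' @export
proteinFeatureTable <- function(proteins) {
  seqs <- as.character(proteins)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%04d", seq_along(seqs))
  rows <- lapply(seqs, pepstatsFeatures)
  out <- data.frame(
    protein_id = ids,
    length = vapply(rows, `[[`, numeric(1), "length"),
    mw = vapply(rows, `[[`, numeric(1), "mw"),
    charge = vapply(rows, `[[`, numeric(1), "charge"),
    pI = vapply(rows, `[[`, numeric(1), "pI"),
    stringsAsFactors = FALSE)
  aa <- t(vapply(rows, `[[`, numeric(20), "aa_freq"))
  colnames(aa) <- paste0("freq_", AA_STANDARD)
  cat9 <- t(vapply(rows, `[[`, numeric(9), "category_freq"))
  colnames(cat9) <- paste0("cat_", names(AA_CATEGORIES))
  rownames(out) <- NULL
  cbind(out, aa, cat9)
}
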