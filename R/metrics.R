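#' Hill diversity number
#'
#' Effective number of equally abundant taxa at diversity order `q`:
#' `(sum p_i^q)^(1/(1-q))` for `q != 1`, and the exponentiated Shannon
#' entropy in the limit `q = 1` (with `0*log(0) := 0`). `q = 0` gives
#' richness, `q = 2` the inverse Simpson index.
#'
#' @param p abundance vector (renormalized internally; zeros dropped)
#' @param q diversity order, `q >= 0`
#' @return the Hill number
#' @export
hill_diversity <- function(p, q) {
  if (q < 0) stop("q must be non-negative")
  if (any(p < 0)) stop("abundances must be non-negative")
  p <- p[p > 0]
  if (!length(p)) stop("profile has no positive abundance")
  p <- p / sum(p)
  if (abs(q - 1) < 1e-10) exp(-sum(p * log(p)))
  else sum(p^q)^(1 / (1 - q))
}

#' Hill evenness
#'
#' Evenness of order `q`, the Hill number relative to richness:
#' `qD / 0D`, in `(0, 1]`.
#'
#' @inheritParams hill_diversity
#' @return evenness in `(0, 1]`
#' @export
evenness <- function(p, q) {
  hill_diversity(p, q) / hill_diversity(p, 0)
}

#' Community profile container
#'
#' @param labels taxon labels
#' @param abundance relative abundances (renormalized to sum 1)
#' @param copy_number optional 16S rRNA operon copies per genome, per taxon
#' @param order optional taxonomic order annotation, per taxon
#' @return a `community_profile` data.frame
#' @export
community_profile <- function(labels, abundance, copy_number = NULL,
                              order = NULL) {
  if (any(abundance < 0)) stop("abundances must be non-negative")
  s <- sum(abundance)
  if (s <= 0) stop("profile has no positive abundance")
  if (!is.null(copy_number) && any(copy_number < 1, na.rm = TRUE))
    stop("copy numbers must be >= 1")
  out <- data.frame(label = labels, abundance = abundance / s,
                    stringsAsFactors = FALSE)
  if (!is.null(copy_number)) out$copy_number <- copy_number
  if (!is.null(order)) out$order <- order
  class(out) <- c("community_profile", "data.frame")
  out
}

#' Correct gene-level abundances for 16S rRNA operon copy number
#'
#' Converts relative marker-gene abundances to relative genome abundances by
#' dividing each taxon's abundance by its operon copy number and
#' renormalizing. Missing copy numbers fall back to `fallback` (e.g. a
#' higher-rank average).
#'
#' @param profile a [community_profile()] with a `copy_number` column
#' @param fallback copy number used where the column is `NA`; `NULL` makes
#'   missing values an error
#' @return the corrected profile
#' @export
copy_number_correct <- function(profile, fallback = NULL) {
  if (is.null(profile$copy_number)) stop("profile has no copy_number column")
  cn <- profile$copy_number
  if (anyNA(cn)) {
    if (is.null(fallback)) stop("missing copy numbers and no fallback given")
    cn[is.na(cn)] <- fallback
  }
  w <- profile$abundance / cn
  profile$abundance <- w / sum(w)
  profile
}

## Orders carrying the mrtA isoenzyme gene, which doubles their apparent
## mcrA-based abundance.
MRTA_ORDERS <- c("Methanobacteriales", "Methanococcales")

#' Correct methanogen T-RF abundances for the mrtA gene duplicate
#'
#' Members of the Methanobacteriales and Methanococcales carry one mrtA copy
#' in addition to mcrA, so their fragment abundances are halved before
#' renormalization. Other order labels pass through unchanged.
#'
#' @param profile a [community_profile()] with an `order` column
#' @return the corrected profile
#' @export
mrta_correct <- function(profile) {
  if (is.null(profile$order)) stop("profile has no order annotation")
  w <- profile$abundance
  dup <- profile$order %in% MRTA_ORDERS
  w[dup] <- w[dup] / 2
  profile$abundance <- w / sum(w)
  profile
}

#' Carbon-13 pathway ratio from a labeled-acetate assay
#'
#' The ratio of 13C-labeled CO2 to 13C-labeled CH4 produced from
#' methyl-labeled acetate discriminates acetoclastic methanogenesis
#' (methyl carbon ends up in CH4, ratio well below 1) from syntrophic
#' acetate oxidation followed by hydrogenotrophic methanogenesis (ratio
#' above 1).
#'
#' @param labeled_co2,labeled_ch4 labeled gas amounts (any common unit)
#' @return list with `ratio` and `pathway`
#'   (`"acetoclastic"`, `"oxidative"`, or `"ambiguous"` at ratio 1)
#' @export
c13_pathway_ratio <- function(labeled_co2, labeled_ch4) {
  if (labeled_co2 < 0 || labeled_ch4 < 0) stop("inputs must be non-negative")
  if (labeled_co2 == 0 && labeled_ch4 == 0) stop("both inputs are zero")
  ratio <- if (labeled_ch4 == 0) Inf else labeled_co2 / labeled_ch4
  pathway <- if (ratio < 1) "acetoclastic" else if (ratio > 1) "oxidative"
             else "ambiguous"
  list(ratio = ratio, pathway = pathway)
}

## stoichiometric COD factors, gO2 per g acid, and molar masses, g/mol
VFA_COD_PER_G <- c(ac = 64 / 60.05, pro = 112 / 74.08, bu = 160 / 88.11)
VFA_MOLAR_MASS <- c(ac = 60.05, pro = 74.08, bu = 88.11)

#' Convert a COD-based VFA mixture to mass and molar terms
#'
#' Uses stoichiometric oxygen demands (64 g/mol acetic, 112 g/mol propionic,
#' 160 g/mol butyric acid) to express a COD-fraction mixture as per-acid
#' mass and molar concentrations plus mass and mol fractions.
#'
#' @param cod_fractions named COD fractions for `ac`, `pro`, `bu` (sum 1)
#' @param total_cod total concentration, gCOD/L
#' @return list with per-acid `cod` (gCOD/L), `mass` (g/L), `molar` (mol/L),
#'   `total_mass` (g/L), `total_molar` (mol/L), `mass_fractions`,
#'   `mol_fractions`
#' @export
vfa_unit_convert <- function(cod_fractions = c(ac = 0.45, pro = 0.10,
                                               bu = 0.45),
                             total_cod = 1) {
  if (!all(names(cod_fractions) %in% names(VFA_COD_PER_G)))
    stop("unknown acid label; use ac, pro, bu")
  if (abs(sum(cod_fractions) - 1) > 1e-9) stop("cod_fractions must sum to 1")
  cod <- total_cod * cod_fractions
  mass <- cod / VFA_COD_PER_G[names(cod)]
  molar <- mass / VFA_MOLAR_MASS[names(cod)]
  list(cod = cod, mass = mass, molar = molar,
       total_mass = sum(mass), total_molar = sum(molar),
       mass_fractions = mass / sum(mass),
       mol_fractions = molar / sum(molar))
}
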