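# Destrieux parcellation vocabulary: 74 gyral/sulcal regions per hemisphere,
# 148 cortical nodes in total.  Abbreviations follow the G/S/L/P naming used
# in morphometric network studies (G = gyrus, S = sulcus, L = lateral
# fissure segments, P = pole).

.destrieux74 <- data.frame(
  index = 1:74,
  abbreviation = c(
    "GSF", "GSOI", "GSP", "GSS", "GSTF", "GSCA", "GSCMA", "GSCMP",
    "GCPD", "GCPV", "GC", "GFIOper", "GFIOrb", "GFIT", "GFM", "GFS",
    "GILSCI", "GIS", "GOM", "GOS", "GOTLF", "GOTML", "GOTMP", "GO",
    "GPIA", "GPIS", "GPS", "GPost", "GPCen", "GPCun", "GR", "GS",
    "GTSGTT", "GTSL", "GTSPP", "GTSPT", "GTI", "GTM", "LFAH", "LFAV",
    "LFP", "PO", "PT", "SCal", "SCen", "SCM", "SCIA", "SCII", "SCIS",
    "SCTA", "SCTP", "SFI", "SFM", "SFS", "SIPJ", "SIPT", "SOML",
    "SOST", "SOA", "SOTL", "SOTML", "SOL", "SOMO", "SOHS", "SPO",
    "SPer", "SPost", "SPIP", "SPSP", "SSO", "SSP", "STI", "STS", "STT"
  ),
  name = c(
    "Frontomarginal gyrus (of Wernicke) and sulcus",
    "Inferior occipital gyrus (O3) and sulcus",
    "Paracentral lobule and sulcus",
    "Subcentral gyrus (central operculum) and sulci",
    "Transverse frontopolar gyri and sulci",
    "Anterior part of the cingulate gyrus and sulcus (ACC)",
    "Middle-anterior part of the cingulate gyrus and sulcus (aMCC)",
    "Middle-posterior part of the cingulate gyrus and sulcus (pMCC)",
    "Posterior-dorsal part of the cingulate gyrus (dPCC)",
    "Posterior-ventral part of the cingulate gyrus (vPCC)",
    "Cuneus (O6)",
    "Opercular part of the inferior frontal gyrus",
    "Orbital part of the inferior frontal gyrus",
    "Triangular part of the inferior frontal gyrus",
    "Middle frontal gyrus (F2)",
    "Superior frontal gyrus (F1)",
    "Long insular gyrus and central sulcus of the insula",
    "Short insular gyri",
    "Middle occipital gyrus (O2, lateral occipital gyrus)",
    "Superior occipital gyrus (O1)",
    "Lateral occipitotemporal gyrus (fusiform gyrus, O4-T4)",
    "Lingual gyrus, lingual part of the medial occipitotemporal gyrus (O5)",
    "Parahippocampal gyrus (T5)",
    "Orbital gyri",
    "Angular gyrus",
    "Supramarginal gyrus",
    "Superior parietal lobule (lateral part of P1)",
    "Postcentral gyrus",
    "Precentral gyrus",
    "Precuneus (medial part of P1)",
    "Straight gyrus, gyrus rectus",
    "Subcallosal area, subcallosal gyrus",
    "Anterior transverse temporal gyrus (of Heschl)",
    "Lateral aspect of the superior temporal gyrus",
    "Planum polare of the superior temporal gyrus",
    "Planum temporale of the superior temporal gyrus",
    "Inferior temporal gyrus (T3)",
    "Middle temporal gyrus (T2)",
    "Horizontal ramus of the anterior segment of the lateral sulcus",
    "Vertical ramus of the anterior segment of the lateral sulcus",
    "Posterior ramus of the lateral sulcus",
    "Occipital pole",
    "Temporal pole",
    "Calcarine sulcus",
    "Central sulcus (Rolando's fissure)",
    "Marginal branch of the cingulate sulcus",
    "Anterior segment of the circular sulcus of the insula",
    "Inferior segment of the circular sulcus of the insula",
    "Superior segment of the circular sulcus of the insula",
    "Anterior transverse collateral sulcus",
    "Posterior transverse collateral sulcus",
    "Inferior frontal sulcus",
    "Middle frontal sulcus",
    "Superior frontal sulcus",
    "Sulcus intermedius primus (of Jensen)",
    "Intraparietal sulcus and transverse parietal sulci",
    "Middle occipital sulcus and lunatus sulcus",
    "Superior occipital sulcus and transverse occipital sulcus",
    "Anterior occipital sulcus and preoccipital notch",
    "Lateral occipitotemporal sulcus",
    "Medial occipitotemporal sulcus (collateral sulcus) and lingual sulcus",
    "Lateral orbital sulcus",
    "Medial orbital sulcus (olfactory sulcus)",
    "Orbital sulci (H-shaped sulci)",
    "Parietooccipital sulcus",
    "Pericallosal sulcus",
    "Postcentral sulcus",
    "Inferior part of the precentral sulcus",
    "Superior part of the precentral sulcus",
    "Suborbital sulcus",
    "Subparietal sulcus",
    "Inferior temporal sulcus",
    "Superior temporal sulcus (parallel sulcus)",
    "Transverse temporal sulcus"
  ),
  stringsAsFactors = FALSE
)

#' Destrieux atlas region table
#'
#' The 74 gyral/sulcal cortical regions of the Destrieux parcellation, one
#' row per region, with the short abbreviation used as column name in cohort
#' tables.  The full 148-node vocabulary is obtained by prefixing each
#' abbreviation with the hemisphere (`lh_`, `rh_`); see
#' [destrieux_labels()].
#'
#' @return A data frame with columns `index`, `abbreviation` and `name`.
#' @export
#' @examples
#' head(destrieux_atlas())
destrieux_atlas <- function() {
  .destrieux74
}

#' Region labels for cohort tables
#'
#' @param hemispheres If `TRUE` (default) return the 148 hemisphere-prefixed
#'   labels (`lh_GSF`, ..., `rh_STT`), left hemisphere first; otherwise the
#'   74 bare abbreviations.
#' @return Character vector of unique region labels in atlas order.
#' @export
#' @examples
#' length(destrieux_labels())    # 148
#' destrieux_labels()[1:3]
destrieux_labels <- function(hemispheres = TRUE) {
  abb <- .destrieux74$abbreviation
  if (!hemispheres) {
    return(abb)
  }
  c(paste0("lh_", abb), paste0("rh_", abb))
}
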