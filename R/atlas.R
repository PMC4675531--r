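#' The 82-region whole-brain atlas
#'
#' Returns the canonical parcellation table used throughout the package:
#' 34 cortical regions (Desikan-Killiany naming) plus 7 subcortical
#' structures (nucleus accumbens, amygdala, caudate, hippocampus, pallidum,
#' putamen, thalamus) per hemisphere. Regions 1--41 are left-hemisphere,
#' 42--82 are their right-hemisphere mirrors, in matching order.
#'
#' Role flags are packaged with the atlas so that downstream code can address
#' region groups without free-text matching:
#' \describe{
#'   \item{temporal}{the nine temporal-lobe cortical regions}
#'   \item{subcortical}{the seven non-cortical structures}
#'   \item{clinical_target}{the three regions removed in a standard
#'     amygdalohippocampectomy: hippocampus, amygdala, parahippocampal gyrus}
#' }
#'
#' @return A data.frame with 82 rows and columns `index`, `label`, `base`
#'   (hemisphere-free region name), `hemisphere` (`"left"`/`"right"`),
#'   `temporal`, `subcortical`, `clinical_target` (logicals).
#' @examples
#' atlas <- load_atlas()
#' sum(atlas$subcortical)                     # 14
#' atlas$label[atlas$clinical_target & atlas$hemisphere == "left"]
#' @export
load_atlas <- function() {
  cortical <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal"
  )
  subcortical <- c(
    "accumbens", "amygdala", "caudate", "hippocampus", "pallidum",
    "putamen", "thalamus"
  )
  temporal <- c(
    "bankssts", "entorhinal", "fusiform", "inferiortemporal",
    "middletemporal", "parahippocampal", "superiortemporal", "temporalpole",
    "transversetemporal"
  )
  clinical <- c("hippocampus", "amygdala", "parahippocampal")

  base <- c(cortical, subcortical)
  tab <- data.frame(
    index = seq_len(82L),
    label = c(paste0("lh_", base), paste0("rh_", base)),
    base = rep(base, 2L),
    hemisphere = rep(c("left", "right"), each = 41L),
    stringsAsFactors = FALSE
  )
  tab$temporal <- tab$base %in% temporal
  tab$subcortical <- tab$base %in% subcortical
  tab$clinical_target <- tab$base %in% clinical
  class(tab) <- c("atlas_table", "data.frame")
  tab
}

#' Map a region index to its contralateral mirror
#'
#' @param index integer vector of atlas indices (1--82).
#' @return The indices of the mirrored regions. The map is an involution:
#'   `mirror_region(mirror_region(i)) == i`.
#' @examples
#' mirror_region(1)    # 42
#' mirror_region(42)   # 1
#' @export
mirror_region <- function(index) {
  stopifnot(all(index >= 1L & index <= 82L))
  ifelse(index <= 41L, index + 41L, index - 41L)
}

#' Atlas indices of named region groups
#'
#' Convenience lookup used by the synthetic-cohort generator and the
#' resection planner.
#'
#' @param atlas an atlas table from [load_atlas()].
#' @param base character vector of hemisphere-free region names.
#' @param hemisphere `"left"`, `"right"`, or `"both"`.
#' @return Integer atlas indices.
#' @export
region_indices <- function(atlas, base, hemisphere = c("left", "right", "both")) {
  hemisphere <- match.arg(hemisphere)
  unknown <- setdiff(base, atlas$base)
  if (length(unknown) > 0L) {
    stop("unknown region name(s): ", paste(unknown, collapse = ", "))
  }
  sel <- atlas$base %in% base
  if (hemisphere != "both") sel <- sel & atlas$hemisphere == hemisphere
  atlas$index[sel]
}

# Default atrophy set: the left temporal/subcortical regions that act as
# typical early-escape sites in left mesial temporal lobe epilepsy.
atrophy_region_names <- function() {
  c("temporalpole", "amygdala", "hippocampus", "parahippocampal",
    "putamen", "thalamus")
}

# Default structural hubs boosted by the generator.
hub_region_names <- function() {
  c("thalamus", "insula")
}
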