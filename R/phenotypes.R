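#' Cell phenotype and channel vocabularies
#'
#' The assay images four co-registered fluorescence channels: DAPI (nuclear
#' stain), pan-cytokeratin (CK), vimentin (VIM), and a multiplexed CD45/CD31
#' channel (both antibodies share the far-red dye, so leukocyte and
#' endothelial signal land in one plane). Ten cell phenotypes are modelled:
#' seven rare classes (CTC, imCTC, pcCTC, CEC, Mega-like, Fibro-like,
#' L-Nuclei) and three leukocyte subclasses (Lymph, Mono, Gran).
#'
#' @return Character vectors of channel and phenotype names.
#' @export
cyto_channels <- function() c("DAPI", "CK", "VIM", "CD45CD31")

#' @rdname cyto_channels
#' @export
cyto_phenotypes <- function() {
  c("CTC", "imCTC", "pcCTC", "CEC", "Mega-like", "Fibro-like",
    "L-Nuclei", "Lymph", "Mono", "Gran")
}

#' @rdname cyto_channels
#' @export
rare_phenotypes <- function() {
  c("CTC", "imCTC", "pcCTC", "CEC", "Mega-like", "Fibro-like", "L-Nuclei")
}

#' @rdname cyto_channels
#' @export
wbc_phenotypes <- function() c("Lymph", "Mono", "Gran")

# Marker expression states per phenotype. DAPI is positive for every class.
# imCTC and pcCTC share one IF profile (DAPI+ CK+ CD45/31+); the generator
# separates them by CD45/31 intensity tier and size, a synthetic convention.
.marker_states <- list(
  "CTC"        = c(DAPI = TRUE,  CK = TRUE,  VIM = FALSE, CD45CD31 = FALSE),
  "imCTC"      = c(DAPI = TRUE,  CK = TRUE,  VIM = FALSE, CD45CD31 = TRUE),
  "pcCTC"      = c(DAPI = TRUE,  CK = TRUE,  VIM = FALSE, CD45CD31 = TRUE),
  "CEC"        = c(DAPI = TRUE,  CK = FALSE, VIM = TRUE,  CD45CD31 = TRUE),
  "Mega-like"  = c(DAPI = TRUE,  CK = FALSE, VIM = FALSE, CD45CD31 = TRUE),
  "Fibro-like" = c(DAPI = TRUE,  CK = FALSE, VIM = TRUE,  CD45CD31 = FALSE),
  "L-Nuclei"   = c(DAPI = TRUE,  CK = FALSE, VIM = FALSE, CD45CD31 = FALSE),
  "Lymph"      = c(DAPI = TRUE,  CK = FALSE, VIM = FALSE, CD45CD31 = TRUE),
  "Mono"       = c(DAPI = TRUE,  CK = FALSE, VIM = FALSE, CD45CD31 = TRUE),
  "Gran"       = c(DAPI = TRUE,  CK = FALSE, VIM = FALSE, CD45CD31 = TRUE)
)

# Location (meanlog) of the lognormal intensity amplitude per channel, on the
# 16-bit count scale, for channels in the "positive" state. Tiers within the
# positive state separate phenotypes that share marker combinations
# (imCTC high CD45/31 vs pcCTC dim CD45/31; Lymph/Mono/Gran intensity tiers).
.positive_meanlog <- list(
  "CTC"        = c(DAPI = 10.0, CK = 9.9,  VIM = NA,  CD45CD31 = NA),
  "imCTC"      = c(DAPI = 10.0, CK = 9.8,  VIM = NA,  CD45CD31 = 9.6),
  "pcCTC"      = c(DAPI = 10.0, CK = 9.8,  VIM = NA,  CD45CD31 = 8.4),
  "CEC"        = c(DAPI = 10.0, CK = NA,   VIM = 9.8, CD45CD31 = 9.3),
  "Mega-like"  = c(DAPI = 10.1, CK = NA,   VIM = NA,  CD45CD31 = 9.5),
  "Fibro-like" = c(DAPI = 10.0, CK = NA,   VIM = 9.7, CD45CD31 = NA),
  "L-Nuclei"   = c(DAPI = 10.2, CK = NA,   VIM = NA,  CD45CD31 = NA),
  "Lymph"      = c(DAPI = 9.9,  CK = NA,   VIM = NA,  CD45CD31 = 9.8),
  "Mono"       = c(DAPI = 9.9,  CK = NA,   VIM = NA,  CD45CD31 = 9.0),
  "Gran"       = c(DAPI = 9.9,  CK = NA,   VIM = NA,  CD45CD31 = 8.2)
)

# Size model: mean nucleus and cytoplasm radii in pixels. Rare phenotypes are
# drawn larger than leukocytes, reflecting the characteristically large size
# of tumor-associated cells relative to blood cells.
.size_params <- list(
  "CTC"        = c(nucleus = 8.5, cyto = 12.0),
  "imCTC"      = c(nucleus = 8.0, cyto = 11.5),
  "pcCTC"      = c(nucleus = 8.0, cyto = 11.5),
  "CEC"        = c(nucleus = 8.0, cyto = 12.5),
  "Mega-like"  = c(nucleus = 11.0, cyto = 14.0),
  "Fibro-like" = c(nucleus = 8.5, cyto = 13.0),
  "L-Nuclei"   = c(nucleus = 11.0, cyto = 11.5),
  "Lymph"      = c(nucleus = 4.5, cyto = 5.5),
  "Mono"       = c(nucleus = 6.5, cyto = 8.0),
  "Gran"       = c(nucleus = 5.5, cyto = 7.0)
)

.negative_meanlog <- 6.0   # ~400 counts of autofluorescence-like signal
.negative_sdlog   <- 0.40
.positive_sdlog   <- 0.30

#' Default marker profile for a phenotype
#'
#' Returns the generative profile used by the synthetic slide simulator: the
#' binary expression state of each channel, lognormal intensity parameters
#' (location/spread of log amplitude on the 16-bit count scale), and size
#' parameters (nucleus and cytoplasm radii in pixels).
#'
#' Expression states follow the assay's phenotype definitions: e.g. CTC =
#' DAPI+ CK+ only; CEC = DAPI+ VIM+ CD45/31+; L-Nuclei = DAPI+ only; all
#' leukocyte subclasses are DAPI+ CD45/31+. DAPI is positive for every
#' phenotype, and channels in the negative state still emit a low
#' autofluorescence-like amplitude.
#'
#' @param phenotype One of [cyto_phenotypes()].
#' @return An object of class `marker_profile`: a list with elements
#'   `phenotype`, `positive` (named logical), `meanlog`, `sdlog` (named
#'   numeric per channel), `nucleus_r`, `cyto_r` (pixels), and
#'   `radius_cv` (relative sd of drawn radii).
#' @examples
#' marker_profile("CTC")$positive
#' @export
marker_profile <- function(phenotype) {
  if (length(phenotype) != 1L || !phenotype %in% cyto_phenotypes()) {
    stop("unknown phenotype: ", paste(phenotype, collapse = ", "),
         "; expected one of ", paste(cyto_phenotypes(), collapse = ", "))
  }
  pos <- .marker_states[[phenotype]]
  ml <- .positive_meanlog[[phenotype]]
  ml[!pos] <- .negative_meanlog
  sl <- ifelse(pos, .positive_sdlog, .negative_sdlog)
  names(sl) <- names(pos)
  sz <- .size_params[[phenotype]]
  structure(list(
    phenotype = phenotype,
    positive = pos,
    meanlog = ml,
    sdlog = sl,
    nucleus_r = unname(sz["nucleus"]),
    cyto_r = unname(sz["cyto"]),
    radius_cv = 0.10
  ), class = "marker_profile")
}

#' @export
print.marker_profile <- function(x, ...) {
  ch <- names(x$positive)
  tags <- paste0(ch, ifelse(x$positive, "+", "-"))
  cat("<marker_profile> ", x$phenotype, ": ", paste(tags, collapse = " "),
      "\n  nucleus r = ", x$nucleus_r, " px, cytoplasm r = ", x$cyto_r,
      " px\n", sep = "")
  invisible(x)
}
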