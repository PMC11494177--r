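# Age-band bookkeeping. The model's native resolution is sex x 5-year band
# (matching annual population snapshots); the reporting streams are coarser
# projections of it:
#   broad bands: 0-65, 65-75, 75-85, 85+   (weekly state-level stream)
#   fine bands:  0-30, 5-year bands 30-95, 95+ (weekly national stream)

#' Five-year age bands used as the model's native age resolution
#'
#' @return Character vector of 20 band labels, `"0-5"` through `"90-95"`, `"95+"`.
#' @export
age_bands_5yr <- function() {
  c(paste0(seq(0, 90, 5), "-", seq(5, 95, 5)), "95+")
}

band_lower <- function(band) {
  as.numeric(sub("[-+].*$", "", band))
}

#' Broad age bands of the weekly state-level reporting stream
#' @return Character vector `c("0-65", "65-75", "75-85", "85+")`.
#' @export
age_bands_broad <- function() c("0-65", "65-75", "75-85", "85+")

#' Fine age bands of the weekly national reporting stream
#' @return Character vector: `"0-30"`, 5-year bands from `"30-35"` to `"90-95"`, `"95+"`.
#' @export
age_bands_fine <- function() {
  c("0-30", paste0(seq(30, 85, 5), "-", seq(35, 90, 5)), "90-95", "95+")
}

#' Map 5-year age bands onto coarser reporting bands
#'
#' @param band Character vector of 5-year band labels (see [age_bands_5yr()]).
#' @param scheme `"broad"` or `"fine"`.
#' @return Character vector of the coarser band containing each input band.
#' @export
age_band_to <- function(band, scheme = c("broad", "fine")) {
  scheme <- match.arg(scheme)
  lo <- band_lower(band)
  bad <- !(band %in% age_bands_5yr())
  if (any(bad)) {
    abort(sprintf("unknown 5-year age band(s): %s",
                  paste(unique(band[bad]), collapse = ", ")))
  }
  if (scheme == "broad") {
    cut(lo, breaks = c(-1, 64, 74, 84, Inf), labels = age_bands_broad()) |>
      as.character()
  } else {
    ifelse(lo < 30, "0-30", band)
  }
}

# Table of the 40 model strata (sex x 5-year band) with their stream bands and
# response-function group (sex x broad band -> 8 groups).
stratum_table <- function() {
  s <- expand_grid(sex = c("f", "m"), age_band = age_bands_5yr())
  s$broad_band <- age_band_to(s$age_band, "broad")
  s$fine_band <- age_band_to(s$age_band, "fine")
  s$group <- paste(s$sex, s$broad_band, sep = ":")
  s$stratum <- paste(s$sex, s$age_band, sep = ":")
  s
}

# midpoint age of a 5-year band, for parametric rate curves (95+ -> 97.5)
band_midpoint <- function(band) {
  lo <- band_lower(band)
  ifelse(band == "95+", 97.5, lo + 2.5)
}
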