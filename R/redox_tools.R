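#' Degree of oxidation of a glutathione buffer
#'
#' `OxD = 2[GSSG] / ([GSH] + 2[GSSG])`, in [0, 1]. Note that the true
#' redox potential depends on the total glutathione as well, since GSSG
#' formation is bimolecular; OxD alone parameterizes the couple's
#' composition, not its potential.
#'
#' @param gsh reduced glutathione (mM), >= 0.
#' @param gssg oxidized glutathione (mM), >= 0; not both zero.
#' @return OxD fraction in [0, 1].
#' @export
oxd <- function(gsh, gssg) {
  if (any(gsh < 0) || any(gssg < 0))
    stop("gsh and gssg must be >= 0", call. = FALSE)
  tot <- gsh + 2 * gssg
  if (any(tot == 0)) stop("OxD undefined: both GSH and GSSG are zero",
                          call. = FALSE)
  2 * gssg / tot
}

#' Speciate a glutathione buffer from OxD and total
#'
#' Inverts the OxD definition: `[GSSG] = OxD * total / 2`,
#' `[GSH] = total * (1 - OxD)`, so that `oxd(speciate(x, T)) == x` and
#' `[GSH] + 2[GSSG] == total`.
#'
#' @param oxd_value degree of oxidation in [0, 1].
#' @param total total glutathione `[GSH] + 2[GSSG]` (mM), > 0.
#' @return Named numeric vector `c(gsh =, gssg =)` in mM.
#' @export
speciate <- function(oxd_value, total) {
  if (any(oxd_value < 0) || any(oxd_value > 1))
    stop("oxd must be in [0, 1]", call. = FALSE)
  if (any(total <= 0)) stop("total glutathione must be > 0", call. = FALSE)
  c(gsh = total * (1 - oxd_value), gssg = oxd_value * total / 2)
}

#' Estimate metabolite concentration in the lens free-water fraction
#'
#' Converts a tissue content in umol per gram of wet tissue to an
#' effective molar concentration in the unbound ("free") water fraction:
#' `c = m / (water_fraction * free_water_fraction)`, reading umol per mL
#' of free water as mM (free-water density taken as 1 g/mL). The standard
#' error scales by the same factor (linear propagation).
#'
#' @param tissue_umol_per_g metabolite content (umol/g wet tissue).
#' @param se its standard error (umol/g); default 0.
#' @param water_fraction g water per g tissue (default 0.6).
#' @param free_water_fraction unbound fraction of the water (default 0.5).
#' @return List with `concentration_mM`, `se_mM`, and the inputs.
#' @examples
#' # healthy human lens nucleus: 24.6 +/- 6.7 umol/g -> 82 +/- 22 mM
#' lens_free_water_concentration(24.6, 6.7)
#' @export
lens_free_water_concentration <- function(tissue_umol_per_g, se = 0,
                                          water_fraction = 0.6,
                                          free_water_fraction = 0.5) {
  if (water_fraction <= 0 || water_fraction > 1 ||
      free_water_fraction <= 0 || free_water_fraction > 1)
    stop("water fractions must be in (0, 1]", call. = FALSE)
  if (tissue_umol_per_g < 0 || se < 0)
    stop("content and se must be >= 0", call. = FALSE)
  fac <- 1 / (water_fraction * free_water_fraction)
  list(concentration_mM = tissue_umol_per_g * fac, se_mM = se * fac,
       tissue_umol_per_g = tissue_umol_per_g, se_umol_per_g = se,
       water_fraction = water_fraction,
       free_water_fraction = free_water_fraction)
}

#' Build a PEGylation gel lane from thiol-class fractions
#'
#' Maps a free-thiol class distribution (as from
#' [soluble_thiol_distribution()]) to gel bands indexed by PEG count
#' (= free thiols per molecule). For intramolecular-disulfide chemistry
#' only `n_cys`, `n_cys - 2` and `n_cys - 4` are attainable; any mass at
#' another count is an error.
#'
#' Band *fractions* are relative within the lane (they sum to 1); band
#' *intensities* scale with the amount of soluble protein loaded, so lanes
#' from endpoints with different soluble pools can be compared the way gel
#' images are: `intensity = fraction * load`.
#'
#' @param thiol_fractions named numeric vector (names = free-thiol count),
#'   nonnegative, summing to 1.
#' @param n_cys cysteines per molecule.
#' @param label lane label.
#' @param load soluble protein loaded (arbitrary units, e.g. uM in the
#'   sampled bulk solution; default 1).
#' @return A `gel_lane`: data.frame with `band_peg_count`, `fraction`,
#'   `intensity` (descending PEG count), with attributes `n_cys`, `label`
#'   and `load`.
#' @export
pegylation_lane <- function(thiol_fractions, n_cys, label = "", load = 1) {
  counts <- as.integer(names(thiol_fractions))
  if (any(is.na(counts)))
    stop("thiol_fractions must be named by free-thiol count",
         call. = FALSE)
  if (any(thiol_fractions < 0) ||
      abs(sum(thiol_fractions) - 1) > 1e-8)
    stop("fractions must be nonnegative and sum to 1", call. = FALSE)
  attainable <- n_cys - c(0L, 2L, 4L)
  attainable <- attainable[attainable >= 0L]
  bad <- counts[!counts %in% attainable & thiol_fractions > 0]
  if (length(bad))
    stop("unattainable free-thiol count(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (load < 0) stop("load must be >= 0", call. = FALSE)
  full <- stats::setNames(numeric(length(attainable)),
                          as.character(attainable))
  full[as.character(counts)] <- thiol_fractions
  lane <- data.frame(band_peg_count = as.integer(names(full)),
                     fraction = unname(full),
                     intensity = unname(full) * load)
  lane <- lane[order(-lane$band_peg_count), ]
  rownames(lane) <- NULL
  attr(lane, "n_cys") <- n_cys
  attr(lane, "label") <- label
  attr(lane, "load") <- load
  class(lane) <- c("gel_lane", "data.frame")
  lane
}

#' Simulate a limited-PEGylation marker lane
#'
#' Markers are made by limited PEGylation of wild-type protein (six free
#' thiols), modelled as independent per-thiol labelling: the band
#' intensities follow `Binomial(n_cys, p)` over PEG counts 0..`n_cys`.
#'
#' @param n_cys thiols per molecule (default 6).
#' @param labeling_probability per-thiol labelling probability in [0, 1].
#' @param label lane label.
#' @param load protein loaded (arbitrary units; default 1).
#' @return A `gel_lane` data.frame over all counts 0..`n_cys`.
#' @export
marker_lane <- function(n_cys = 6, labeling_probability = 0.5,
                        label = "marker", load = 1) {
  p <- labeling_probability
  if (p < 0 || p > 1)
    stop("labeling_probability must be in [0, 1]", call. = FALSE)
  counts <- n_cys:0
  frac <- stats::dbinom(counts, n_cys, p)
  lane <- data.frame(band_peg_count = counts, fraction = frac,
                     intensity = frac * load)
  rownames(lane) <- NULL
  attr(lane, "n_cys") <- n_cys
  attr(lane, "label") <- label
  attr(lane, "load") <- load
  class(lane) <- c("gel_lane", "data.frame")
  lane
}

#' Write a gel lane to CSV
#'
#' @param lane a `gel_lane`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lane_csv <- function(lane, path) {
  utils::write.csv(as.data.frame(lane), path, row.names = FALSE)
  invisible(path)
}
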