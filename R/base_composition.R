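#' Pair of dye-specific fluorescence ratios for one specimen
#'
#' Fluorescence of an intercalating dye (PI) tracks total DNA content, while
#' an AT-selective dye (DAPI) also depends on base composition: with a binding
#' site of `binding_length` consecutive AT pairs, its signal is proportional
#' to genome size times (AT fraction)^n. A specimen measured with both dyes
#' against the same standard therefore carries enough information to recover
#' its GC content from the discrepancy between the two ratios.
#'
#' @param ratio_at_dye sample/standard fluorescence ratio under the
#'   AT-selective dye.
#' @param ratio_intercalating sample/standard ratio under the intercalating
#'   dye.
#' @param standard a [standard_ref()] of known GC content.
#' @param binding_length number of consecutive AT base pairs per dye binding
#'   site (default 4, the conventional DAPI value).
#' @return An object of class `dye_pair`.
#' @export
dye_pair <- function(ratio_at_dye, ratio_intercalating,
                     standard = standard_ref(), binding_length = 4L) {
  gs_assert(is.finite(ratio_at_dye) && ratio_at_dye > 0 &&
            is.finite(ratio_intercalating) && ratio_intercalating > 0,
            "invalid-ratios", "dye ratios must be positive")
  gs_assert(binding_length >= 1, "invalid-argument", "binding_length must be >= 1")
  stopifnot(inherits(standard, "standard_ref"))
  structure(list(ratio_at_dye = ratio_at_dye,
                 ratio_intercalating = ratio_intercalating,
                 standard = standard, binding_length = binding_length),
            class = "dye_pair")
}

#' Expected AT-dye/intercalating-dye ratio quotient under the binding model
#'
#' Forward model: under the binding-length model the quotient of the two
#' sample/standard ratios equals `(p_sample / p_standard)^binding_length`,
#' strictly increasing in the sample AT fraction.
#'
#' @param p_sample sample AT fraction in (0,1).
#' @param p_standard standard AT fraction in (0,1).
#' @param binding_length binding-site length in AT base pairs.
#' @return The expected quotient ratio_at_dye / ratio_intercalating.
#' @export
forward_dye_ratio <- function(p_sample, p_standard, binding_length = 4L) {
  gs_assert(all(p_sample > 0 & p_sample < 1) && all(p_standard > 0 & p_standard < 1),
            "invalid-fraction", "AT fractions must lie in (0,1)")
  gs_assert(binding_length >= 1, "invalid-argument", "binding_length must be >= 1")
  (p_sample / p_standard)^binding_length
}

#' AT fraction of the sample genome from a dye pair
#'
#' Inverts the binding-length model:
#' `p_s = p_st * (ratio_at / ratio_int)^(1/binding_length)` where `p_st` is
#' the standard's AT fraction. A result outside (0,1) — possible with noisy
#' ratios — is clipped to the open unit interval and flagged via the
#' `"qc_flag"` attribute (`OUT_OF_RANGE`) rather than raised.
#'
#' @param d a [dye_pair()].
#' @return AT fraction in (0,1), possibly with attribute `qc_flag`.
#' @export
at_proportion <- function(d) {
  stopifnot(inherits(d, "dye_pair"))
  p_st <- 1 - d$standard$gc_percent / 100
  q <- d$ratio_at_dye / d$ratio_intercalating
  if (!is.finite(q) || q <= 0)
    gs_error("invalid-ratios", "ratio quotient must be positive")
  p_s <- p_st * q^(1 / d$binding_length)
  if (p_s <= 0 || p_s >= 1) {
    p_s <- min(max(p_s, 1e-9), 1 - 1e-9)
    attr(p_s, "qc_flag") <- "OUT_OF_RANGE"
  }
  p_s
}

#' GC content (percent) of the sample genome from a dye pair
#'
#' @param d a [dye_pair()].
#' @return GC percent; carries the `qc_flag` attribute of [at_proportion()]
#'   when the underlying AT fraction was out of range.
#' @export
#' @examples
#' # a specimen responding identically to both dyes has the standard's GC
#' gc_percent(dye_pair(1.3, 1.3))  # 38.5
gc_percent <- function(d) {
  p <- at_proportion(d)
  out <- 100 * (1 - as.numeric(p))
  attr(out, "qc_flag") <- attr(p, "qc_flag")
  out
}

#' Add GC estimates to a paired measurement table
#'
#' Joins AT-selective and intercalating rows of the same specimen and
#' computes per-specimen GC. Specimens with only an AT-selective measurement
#' yield relative genome size only: they are tagged `RELATIVE` and their GC
#' is `NA`, since a single AT-dependent dye cannot separate size from base
#' composition.
#'
#' @param measurements data.frame from [measure_histogram()] rows, one row
#'   per specimen per dye.
#' @param standard a [standard_ref()].
#' @param binding_length see [dye_pair()].
#' @return data.frame with one row per specimen: specimen_id, species, sex,
#'   c1_pg (intercalating-dye value when available), gc_percent, flags.
#' @export
gc_from_measurements <- function(measurements, standard = standard_ref(),
                                 binding_length = 4L) {
  stopifnot(is.data.frame(measurements))
  out <- lapply(split(measurements, measurements$specimen_id), function(g) {
    at <- g[g$dye == "AT_SELECTIVE", , drop = FALSE]
    ic <- g[g$dye == "INTERCALATING", , drop = FALSE]
    row <- data.frame(specimen_id = g$specimen_id[1], species = g$species[1],
                      sex = g$sex[1], c1_pg = NA_real_,
                      gc_percent = NA_real_, flags = "",
                      stringsAsFactors = FALSE)
    if (nrow(ic) >= 1) row$c1_pg <- ic$c1_pg[1]
    if (nrow(ic) >= 1 && nrow(at) >= 1) {
      g_pc <- gc_percent(dye_pair(at$ratio[1], ic$ratio[1], standard,
                                  binding_length))
      row$gc_percent <- as.numeric(g_pc)
      if (!is.null(attr(g_pc, "qc_flag"))) row$flags <- attr(g_pc, "qc_flag")
    } else if (nrow(at) >= 1 && nrow(ic) == 0) {
      row$c1_pg <- at$c1_pg[1]
      row$flags <- "RELATIVE"
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
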