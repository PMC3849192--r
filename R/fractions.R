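## Fraction unbound in plasma, brain homogenate, and brain slice.

#' Fraction unbound in plasma from equilibrium dialysis
#'
#' Ratio of the analyte response on the buffer side to the response on the
#' plasma side after equilibrium dialysis. Values outside `(0, 1]` are
#' clipped with a warning rather than rejected (slight signal excess on the
#' buffer side occurs with assay noise).
#'
#' @param signal_buffer Analyte response on the buffer side (area units).
#' @param signal_plasma Analyte response on the plasma side (> 0).
#'
#' @return `fu_pl`, dimensionless in `[0, 1]`.
#' @examples
#' fu_plasma(25, 500)
#' @export
fu_plasma <- function(signal_buffer, signal_plasma) {
  check_number(signal_buffer, "signal_buffer", 0)
  if (!is.numeric(signal_plasma) || length(signal_plasma) != 1L ||
      is.na(signal_plasma) || signal_plasma <= 0) {
    stop_kpuu("invalid assay: plasma-side signal must be positive")
  }
  fu <- signal_buffer / signal_plasma
  if (fu == 0) {
    warning("buffer signal below quantification: fu_pl = 0", call. = FALSE)
  }
  if (fu > 1) {
    warning(sprintf("buffer/plasma ratio %.3g > 1; clipped to 1", fu),
            call. = FALSE)
    fu <- 1
  }
  fu
}

#' Fraction unbound in brain from diluted homogenate dialysis
#'
#' Equilibrium dialysis of diluted brain homogenate yields an apparent
#' unbound fraction `fu_app = C_buffer / C_homog`. The unbound fraction in
#' undiluted brain tissue is recovered with the standard dilution
#' correction
#' \deqn{f_u = \frac{1/D}{(1/f_{u,app} - 1) + 1/D}}
#' where `D` is the homogenate dilution factor (10 for a 10% homogenate).
#' Setting `D = 1` disables the correction.
#'
#' @param C_buffer Buffer-side concentration, µM (>= 0).
#' @param C_homog Homogenate-side concentration, µM (> 0).
#' @param D Dilution factor (>= 1, default 10).
#'
#' @return `fu_br`, dimensionless in `(0, 1]`.
#' @examples
#' fu_brain_homogenate(0.5, 1.0)        # fu_app 0.5, 10% homogenate -> 0.0909
#' fu_brain_homogenate(0.3, 1.0, D = 1) # undiluted: identity
#' @export
fu_brain_homogenate <- function(C_buffer, C_homog, D = 10) {
  check_number(C_buffer, "C_buffer", 0)
  if (!is.numeric(C_homog) || length(C_homog) != 1L || is.na(C_homog) ||
      C_homog <= 0) {
    stop_kpuu("invalid assay: homogenate-side concentration must be positive")
  }
  check_number(D, "D", 1)
  fu_app <- C_buffer / C_homog
  if (fu_app <= 0) {
    stop_kpuu("apparent unbound fraction is zero: below quantification, ",
              "undiluted fraction underflows")
  }
  if (fu_app > 1) {
    warning(sprintf("apparent fu %.3g > 1; clipped to 1", fu_app),
            call. = FALSE)
    fu_app <- 1
  }
  (1 / D) / ((1 / fu_app - 1) + 1 / D)
}

#' Unbound volume of distribution and fraction unbound from brain slices
#'
#' Brain slices incubated in buffer take up drug by distribution and
#' binding; after incubation the slice is homogenised and its drug content
#' measured. The unbound volume of distribution is
#' \deqn{V_{u,brain} = C_{slice}/C_{ECF} - V_0}
#' where \eqn{C_{slice}} is the amount of drug per gram of slice,
#' \eqn{C_{ECF}} the buffer concentration (representing the free brain ECF
#' concentration), and \eqn{V_0} the volume of buffer adhering to the slice
#' surface (0.106 mL/g, i.e. on average 10.6% adherent water, determined
#' with inulin). The unbound fraction is its reciprocal,
#' \eqn{f_{u,brain} = 1/V_{u,brain}}.
#'
#' @param C_slice_homog Measured concentration in the slice homogenate,
#'   µM-equivalent. Multiplied by `D_slice` to obtain the per-gram slice
#'   content (slices are homogenised in 9 volumes of buffer, so
#'   `D_slice = 10` by default). Pass the per-gram content directly with
#'   `D_slice = 1`.
#' @param C_ECF Buffer concentration, µM (> 0).
#' @param V0 Water adhesion volume, mL/g, in `(0, 1)` (default 0.106).
#' @param D_slice Slice homogenate dilution factor (default 10).
#'
#' @return A list with `Vu_brain` (mL/g) and `fu_brain` (dimensionless).
#'   `fu_brain > 1` (apparent exclusion from slice water) is allowed but
#'   flagged with a warning as a possible assay artifact.
#' @examples
#' fu_brain_slice(0.21, C_ECF = 1)  # Vu = 1.994 mL/g, fu = 0.5015
#' @export
fu_brain_slice <- function(C_slice_homog, C_ECF, V0 = 0.106, D_slice = 10) {
  check_number(C_slice_homog, "C_slice_homog", 0)
  if (!is.numeric(C_ECF) || length(C_ECF) != 1L || is.na(C_ECF) || C_ECF <= 0) {
    stop_kpuu("buffer (ECF) concentration must be positive")
  }
  if (!is.numeric(V0) || length(V0) != 1L || is.na(V0) || V0 <= 0 || V0 >= 1) {
    stop_kpuu("`V0` must be in (0, 1) mL/g")
  }
  check_number(D_slice, "D_slice", 1)
  C_slice <- D_slice * C_slice_homog
  Vu <- C_slice / C_ECF - V0
  if (Vu <= 0) {
    stop_kpuu("slice uptake indistinguishable from adherent water ",
              "(C_slice/C_ECF <= V0): Vu,brain not positive")
  }
  fu <- 1 / Vu
  if (fu > 1) {
    warning(sprintf("fu_brain = %.3g > 1 (Vu < 1 mL/g): possible assay artifact",
                    fu), call. = FALSE)
  }
  list(Vu_brain = Vu, fu_brain = fu)
}

#' Unbound brain concentration from a total brain concentration
#'
#' Multiplies the total in vivo brain concentration by the fraction unbound
#' in brain to yield the unbound (free) brain concentration.
#'
#' @param fu_brain Fraction unbound in brain (> 0; values above 1 allowed).
#' @param C_tot_brain Total brain concentration, µM (>= 0).
#' @return `Cu_brain` in the units of `C_tot_brain`.
#' @examples
#' cu_brain_from_total(0.01, 12)
#' @export
cu_brain_from_total <- function(fu_brain, C_tot_brain) {
  check_number(fu_brain, "fu_brain", 0)
  check_number(C_tot_brain, "C_tot_brain", 0)
  fu_brain * C_tot_brain
}
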